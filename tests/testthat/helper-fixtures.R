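# Shared fixture builders. Everything is generated in code; expensive
# default-design pipeline runs are cached so several test files can reuse
# them.

.run_cache <- new.env(parent = emptyenv())

# Full default-design pipeline run (simulate -> filter -> profiles ->
# correlation -> PCIT -> network -> assignment -> partition), cached by
# (seed, noise_sd).
default_run <- function(seed = 101, noise_sd = 0) {
  key <- paste0("run_", seed, "_", noise_sd)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  design <- synthetic_design(seed = seed, noise_sd = noise_sd)
  sim <- simulate_dataset(design)
  filt <- gcn_gene_filter(sim$deg)
  profiles <- deg_to_profiles(sim$deg[sim$deg$gene %in% filt$kept, ],
                              design$tissues, design$days)
  r <- pearson_profiles(profiles)
  pc <- pcit_mask(r)
  assignment <- assign_tissue(profiles)
  net <- build_network(r, pc$mask, assignment)
  part <- subnetwork_partition(net, assignment)
  out <- list(design = design, sim = sim, filt = filt, profiles = profiles,
              r = r, pcit = pc, assignment = assignment, net = net,
              part = part)
  .run_cache[[key]] <- out
  out
}

# A small expression set: 2 tissues x 3 days x 2 replicates with
# hand-settable values.
toy_expression <- function(values = NULL, genes = c("g1", "g2"),
                           tissues = c("endometrium", "ovary"),
                           days = c(0, 6, 12), replicates = 2) {
  samples <- expand.grid(replicate = seq_len(replicates), day = days,
                         tissue = tissues, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("tissue", "day", "replicate")]
  samples$sample_id <- sprintf("%s_d%02d_r%d", samples$tissue, samples$day,
                               samples$replicate)
  if (is.null(values)) {
    values <- matrix(seq_len(length(genes) * nrow(samples)),
                     nrow = length(genes))
  }
  dimnames(values) <- list(genes, samples$sample_id)
  expression_matrix(values, samples, tissues = tissues, days = days)
}

# Profile matrix with explicit entries; conditions follow the declared
# order tissues x ascending non-baseline days.
toy_profiles <- function(m, tissues = c("endometrium", "ovary", "oviduct"),
                         days = c(0, 3, 6, 9, 12, 15, 18)) {
  labs <- paste(rep(tissues, each = length(days) - 1),
                rep(sort(days[days != 0]), length(tissues)), sep = ":")
  colnames(m) <- labs
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  deg <- data.frame(
    gene = rep(rownames(m), times = ncol(m)),
    tissue = rep(rep(tissues, each = length(days) - 1), each = nrow(m)),
    day = rep(rep(sort(days[days != 0]), length(tissues)), each = nrow(m)),
    log2fc = as.vector(m), q = 0, stringsAsFactors = FALSE)
  deg_to_profiles(deg, tissues, days)
}

# Random PSD correlation matrix built as a sample correlation of random
# data (n genes, n + extra observations).
random_corr <- function(n, extra = 5) {
  x <- matrix(rnorm(n * (n + extra)), ncol = n)
  r <- cor(x)
  dimnames(r) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  r
}

# Small random attributed graph for interchange round-trips.
random_graph <- function(n = 10, p = 0.3) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("gene", seq_len(n))
  igraph::V(g)$tissue <- sample(c("endometrium", "ovary", "oviduct"), n,
                                replace = TRUE)
  igraph::V(g)$max_abs_log2fc <- round(runif(n, 0, 8), 6)
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$r <- round(runif(igraph::ecount(g), -1, 1), 6)
  }
  g
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
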