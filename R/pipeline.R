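#' Run the full co-expression network pipeline
#'
#' Config-driven driver chaining the stages: simulate (or load) ->
#' stringent DEG filter -> log2FC profiles -> Pearson correlation -> PCIT
#' -> thresholded network -> tissue assignment -> sub-network partition /
#' bridging genes / core network -> profile clustering. Every stage's
#' output is persisted as TSV/GraphML in `out_dir` (if given) and the
#' counts are collected in a machine-readable summary. The pipeline is a
#' pure function of the config: all randomness flows from its seed.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognised fields (all optional unless stated):
#'   \describe{
#'     \item{simulate}{logical; if TRUE a [synthetic_design()] is built
#'       from the `design` sub-list and simulated.}
#'     \item{design}{arguments for [synthetic_design()] (used when
#'       `simulate` is TRUE).}
#'     \item{deg, expression, metadata}{input file paths (required when
#'       `simulate` is FALSE: either `deg`, or `expression` + `metadata`).}
#'     \item{filter}{arguments for [gcn_filter_config()].}
#'     \item{network}{list: `threshold` (default 0.90), `mode`
#'       ("abs"/"r2").}
#'     \item{clustering}{list: `k` (default 5), `max_iter` (default 1000).}
#'     \item{seed}{integer; overrides `design$seed` and seeds clustering.}
#'   }
#' @param out_dir Output directory (created); if NULL nothing is written.
#' @return A list with the in-memory stage results (`dataset`, `filter`,
#'   `profiles`, `correlation`, `pcit`, `network`, `assignment`,
#'   `partition`, `clusters`) and `summary` (named counts).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  truth <- NULL
  if (isTRUE(config$simulate)) {
    design_args <- config$design %||% list()
    design_args$seed <- seed
    design <- do.call(synthetic_design, design_args)
    dataset <- simulate_dataset(design)
    deg <- dataset$deg
    truth <- dataset$truth
    tissues <- design$tissues
    days <- design$days
    if (!is.null(out_dir)) {
      write_expression(dataset$expression,
                       file.path(out_dir, "expression.tsv"),
                       file.path(out_dir, "metadata.tsv"))
      write_deg(deg, file.path(out_dir, "deg.tsv"))
      write_truth(truth, file.path(out_dir, "truth.tsv"))
    }
  } else {
    dataset <- NULL
    if (!is.null(config$deg)) {
      deg <- read_deg(config$deg)
    } else if (!is.null(config$expression) && !is.null(config$metadata)) {
      expr <- read_expression(config$expression, config$metadata)
      profiles <- log2fc_profiles(expr)
      deg <- profiles_to_deg(profiles)
      dataset <- list(expression = expr)
    } else {
      stop("config field `deg` (or `expression` + `metadata`) is required ",
           "when simulate is false")
    }
    tissues <- config$tissues %||% unique(deg$tissue)
    days <- as.integer(config$days %||% sort(unique(c(0, deg$day))))
  }

  filter_cfg <- do.call(gcn_filter_config, config$filter %||% list())
  filt <- gcn_gene_filter(deg, annotation = NULL, config = filter_cfg)
  deg_kept <- deg[deg$gene %in% filt$kept, , drop = FALSE]
  profiles <- deg_to_profiles(deg_kept, tissues, days)
  if (!is.null(out_dir)) {
    write_profiles(profiles, file.path(out_dir, "profiles.tsv"))
    write.table(filt$report, file.path(out_dir, "filter_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(filt$kept, file.path(out_dir, "kept_genes.txt"))
  }

  r <- pearson_profiles(profiles)
  pc <- pcit_mask(r)
  assignment <- assign_tissue(profiles)
  net_cfg <- config$network %||% list()
  net <- build_network(r, pc$mask, assignment,
                       threshold = net_cfg$threshold %||% 0.90,
                       mode = net_cfg$mode %||% "abs")
  part <- subnetwork_partition(net, assignment)

  cl_cfg <- config$clustering %||% list()
  clusters <- kmeans_profiles(median_center(profiles),
                              k = cl_cfg$k %||% 5,
                              max_iter = cl_cfg$max_iter %||% 1000,
                              seed = seed)

  if (!is.null(out_dir)) {
    export_graph(net, file.path(out_dir, "network.graphml"))
    export_graph(part$core, file.path(out_dir, "core.graphml"))
    export_graph(net, file.path(out_dir, "network.sif"), format = "sif",
                 node_attr_path = file.path(out_dir, "node_attributes.tsv"),
                 edge_attr_path = file.path(out_dir, "edge_attributes.tsv"))
    writeLines(part$bridging, file.path(out_dir, "bridging_genes.txt"))
    write.table(data.frame(gene = names(clusters$cluster),
                           cluster = unname(clusters$cluster)),
                file.path(out_dir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  non_isolated <- sum(igraph::degree(net) > 0)
  summary <- list(
    seed = seed,
    genes_total = length(unique(deg$gene)),
    genes_kept = length(filt$kept),
    removed_by_rule = as.list(filt$counts[-1]),
    network_nodes = igraph::vcount(net),
    network_nodes_connected = non_isolated,
    network_edges = igraph::ecount(net),
    subnetworks = lapply(part$subnetworks, function(g) {
      list(nodes = igraph::vcount(g), edges = igraph::ecount(g))
    }),
    bridging_genes = length(part$bridging),
    bridge_connectivity = part$bridge_connectivity,
    core_subclusters = part$n_core_subclusters,
    clustering_k = clusters$k)
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(dataset = dataset, truth = truth, filter = filt,
       profiles = profiles, correlation = r, pcit = pc, network = net,
       assignment = assignment, partition = part, clusters = clusters,
       summary = summary)
}

## DEG-shaped table from a profile matrix (no q-values available: q = 0
## so that downstream significance filtering is a no-op for this path).
profiles_to_deg <- function(profiles) {
  cc <- parse_conditions(colnames(profiles))
  m <- as.matrix(profiles)
  data.frame(gene = rep(rownames(m), times = ncol(m)),
             tissue = rep(cc$tissue, each = nrow(m)),
             day = rep(cc$day, each = nrow(m)),
             log2fc = as.vector(m),
             q = 0,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
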