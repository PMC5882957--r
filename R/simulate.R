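#' Synthetic study design
#'
#' Describes a multi-tissue time-course expression experiment with planted
#' tissue-specific temporal co-expression modules, planted bridging genes
#' and unstructured background genes. The defaults emulate a 3-tissue x
#' 7-day x 3-replicate oestrous-cycle design whose five planted archetypes
#' total 904 network-input genes (892 module genes + 12 bridging genes).
#'
#' Bridging genes mix two archetypes from two different tissues. They are
#' planted in groups per tissue pair, each group split into two
#' sign-mirrored subgroups: a gene of the second subgroup carries the
#' negation of the pair signal with the primary/secondary dominance
#' reversed. Group members are then almost perfectly (anti-)correlated over
#' the full condition vector while the two subgroups attain their maximum
#' fold change in different tissues. This is what makes bridges recoverable
#' at a high |r| edge threshold; see the methods vignette for the
#' correlation geometry behind these choices.
#'
#' @param tissues Ordered tissue labels.
#' @param days Integer sampling days including the baseline day 0 once.
#' @param replicates Replicates per tissue x day (>= 1).
#' @param archetypes List of [archetype()] objects; default
#'   [default_archetypes()].
#' @param module_sizes Named integer vector, genes per archetype.
#' @param n_bridging Number of planted bridging genes.
#' @param bridge_pairs List of length-2 character vectors naming the two
#'   archetypes (from two distinct tissues) each bridge group mixes.
#' @param n_background Number of unstructured genes (true log2FC 0).
#' @param effect_size Peak |log2FC| of the planted signal.
#' @param noise_sd SD of additive log2-scale noise per replicate.
#' @param amplitude_range Range of the per-gene uniform amplitude factor
#'   multiplying `effect_size`; the lower bound times `effect_size` should
#'   stay above any downstream fold-change cut-off.
#' @param profile_jitter_sd SD of the per-gene perturbation of the
#'   archetype multipliers (gene-level kinetic heterogeneity). Perturbed
#'   profiles are renormalised to peak multiplier 1, so every planted gene
#'   still attains the full effect size at its peak condition.
#' @param bridge_secondary_scale Relative strength of a bridging gene's
#'   secondary archetype (0 < s <= 1).
#' @param baseline_log_mean,baseline_log_sd Log-normal (natural-log)
#'   parameters of the baseline FPKM distribution.
#' @param baseline_min Lower truncation of the baseline FPKM distribution
#'   (default 200): stringent-fold-change network genes are robustly
#'   expressed, and a bounded-below baseline keeps the +1 pseudocount
#'   distortion of observed log2FC small relative to the planted signal.
#' @param tissue_offset_log2 Half-width (log2 scale) of the uniform
#'   per-gene per-tissue baseline offset; cancels exactly in within-tissue
#'   fold changes.
#' @param q_active_max Upper bound of q-values drawn for active
#'   gene x condition pairs.
#' @param q_inactive_min Lower bound of q-values drawn for inactive pairs.
#' @param active_abs_log2fc A gene x condition pair is "active" (small q)
#'   iff its planted |log2FC| reaches this threshold.
#' @param seed Integer random seed governing all draws.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(tissues = c("endometrium", "ovary", "oviduct"),
                             days = c(0, 3, 6, 9, 12, 15, 18),
                             replicates = 3,
                             archetypes = c(default_archetypes(days),
                                            bridge_archetypes(days)),
                             module_sizes = c(endometrium_up = 198,
                                              endometrium_down = 176,
                                              ovary_up = 198,
                                              ovary_down = 176,
                                              oviduct_down = 132),
                             n_bridging = 24,
                             bridge_pairs = NULL,
                             n_background = 600,
                             effect_size = 4.0,
                             noise_sd = 0.5,
                             amplitude_range = c(0.85, 1),
                             profile_jitter_sd = 0.10,
                             bridge_secondary_scale = 0.85,
                             baseline_log_mean = log(500),
                             baseline_log_sd = 0.7,
                             baseline_min = 200,
                             tissue_offset_log2 = 2,
                             q_active_max = 0.01,
                             q_inactive_min = 0.2,
                             active_abs_log2fc = 3.0,
                             seed = 1L) {
  days <- as.integer(days)
  if (sum(days == 0L) != 1L) {
    stop("`days` must contain the baseline day 0 exactly once; got: ",
         paste(days, collapse = ", "))
  }
  ## tolerate list-shaped values as produced by YAML configs
  module_sizes <- unlist(module_sizes)
  if (!is.null(bridge_pairs)) {
    bridge_pairs <- lapply(bridge_pairs, function(p) unlist(p))
  }
  if (replicates < 1) stop("`replicates` must be >= 1")
  for (v in c(module_sizes, n_bridging, n_background)) {
    if (!is.finite(v) || v < 0) stop("all gene counts must be finite and >= 0")
  }
  if (!is.finite(effect_size) || effect_size <= 0) stop("`effect_size` must be > 0")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!(q_active_max > 0 && q_active_max < q_inactive_min &&
        q_inactive_min <= 1)) {
    stop("need 0 < q_active_max < q_inactive_min <= 1")
  }
  if (bridge_secondary_scale <= 0 || bridge_secondary_scale > 1) {
    stop("`bridge_secondary_scale` must lie in (0, 1]")
  }
  if (length(amplitude_range) != 2 || amplitude_range[1] > amplitude_range[2] ||
      amplitude_range[1] <= 0) {
    stop("`amplitude_range` must be an increasing positive pair")
  }
  if (is.null(names(module_sizes)) ||
      !all(names(module_sizes) %in% names(archetypes))) {
    stop("`module_sizes` must be named by archetype id")
  }
  arch_tissue <- vapply(archetypes, `[[`, character(1), "tissue")
  if (!all(arch_tissue %in% tissues)) {
    stop("archetype tissues must be among the declared tissues")
  }
  if (is.null(bridge_pairs)) {
    bridge_ids <- c("endometrium_early", "ovary_early", "oviduct_early",
                    "endometrium_late")
    bridge_pairs <- if (all(bridge_ids %in% names(archetypes))) {
      ## opposite-sign pairs: each bridge is up in one tissue and down in
      ## the other, so its sign-mirrored partner peaks upward in the other
      ## tissue and the max-|FC| rule splits every group across two tissues
      list(c("endometrium_early", "ovary_early"),
           c("endometrium_late", "oviduct_early"),
           c("ovary_early", "oviduct_early"))
    } else {
      default_bridge_pairs(archetypes)
    }
  }
  for (p in bridge_pairs) {
    if (length(p) != 2 || !all(p %in% names(archetypes))) {
      stop("each bridge pair must name two known archetypes")
    }
    if (arch_tissue[[p[1]]] == arch_tissue[[p[2]]]) {
      stop("bridge pair (", p[1], ", ", p[2],
           ") must span two distinct tissues")
    }
  }
  if (!is.finite(profile_jitter_sd) || profile_jitter_sd < 0) {
    stop("`profile_jitter_sd` must be >= 0")
  }
  structure(list(tissues = tissues, days = days, replicates = replicates,
                 archetypes = archetypes, module_sizes = module_sizes,
                 n_bridging = n_bridging, bridge_pairs = bridge_pairs,
                 n_background = n_background, effect_size = effect_size,
                 noise_sd = noise_sd, amplitude_range = amplitude_range,
                 profile_jitter_sd = profile_jitter_sd,
                 bridge_secondary_scale = bridge_secondary_scale,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 baseline_min = baseline_min,
                 tissue_offset_log2 = tissue_offset_log2,
                 q_active_max = q_active_max,
                 q_inactive_min = q_inactive_min,
                 active_abs_log2fc = active_abs_log2fc,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

## Cross-tissue archetype pairs used for bridge groups when none are given:
## one pair per unordered tissue pair, cycling over the available archetypes.
default_bridge_pairs <- function(archetypes) {
  tis <- vapply(archetypes, `[[`, character(1), "tissue")
  ids <- names(archetypes)
  tissues <- unique(tis)
  pairs <- list()
  if (length(tissues) < 2) stop("bridging needs archetypes in >= 2 tissues")
  used <- setNames(integer(length(tissues)), tissues)
  for (i in seq_len(length(tissues) - 1)) {
    for (j in seq(i + 1, length(tissues))) {
      a <- ids[tis == tissues[i]]
      b <- ids[tis == tissues[j]]
      pairs[[length(pairs) + 1L]] <-
        c(a[used[tissues[i]] %% length(a) + 1L],
          b[used[tissues[j]] %% length(b) + 1L])
      used[tissues[i]] <- used[tissues[i]] + 1L
      used[tissues[j]] <- used[tissues[j]] + 1L
    }
  }
  pairs
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("synthetic design: ", length(x$tissues), " tissues x ",
      length(x$days), " days x ", x$replicates, " replicates\n",
      "  module genes: ", sum(x$module_sizes),
      ", bridging: ", x$n_bridging,
      ", background: ", x$n_background, "\n",
      "  effect ", x$effect_size, ", noise sd ", x$noise_sd,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a planted multi-tissue expression dataset
#'
#' Generates an FPKM expression matrix, a differential-expression table and
#' the planted ground truth for a [synthetic_design()]. Module genes follow
#' one archetype in that archetype's tissue and are flat elsewhere; bridging
#' genes mix two archetypes from two tissues (secondary at
#' `bridge_secondary_scale` strength); background genes are flat everywhere.
#' FPKM for gene g in (tissue t, day d, replicate) is
#' `baseline_g * offset_gt * 2^(signal_g(t, d) + N(0, noise_sd))`, where
#' `signal_g(t, d)` is the planted log2FC (amplitude x effect x archetype
#' multiplier) and `offset_gt` is the per-tissue baseline offset. The DEG
#' table's log2FC is recomputed from replicate-mean FPKM with pseudocount 1
#' against day 0 of the same tissue; q-values are drawn uniformly below
#' `q_active_max` where the planted |log2FC| reaches `active_abs_log2fc`
#' and uniformly above `q_inactive_min` otherwise.
#'
#' All randomness flows from `design$seed`; identical designs give
#' identical output.
#'
#' @param design A [synthetic_design()].
#' @return A list with components `expression` ([expression_matrix()]),
#'   `deg` (data frame: gene, tissue, day, log2fc, q), `truth`
#'   (`synthetic_truth`: `$genes` data frame and `$true_log2fc` matrix) and
#'   `design`.
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed)
  tissues <- design$tissues
  days <- design$days
  nonbase <- sort(days[days != 0L])
  conds <- condition_labels(tissues, days)
  arcs <- design$archetypes
  arch_tissue <- vapply(arcs, `[[`, character(1), "tissue")

  module_genes <- unlist(lapply(names(design$module_sizes), function(id) {
    n <- design$module_sizes[[id]]
    if (n > 0) sprintf("%s_%03d", id, seq_len(n)) else character(0)
  }))
  bridge_genes <- if (design$n_bridging > 0) {
    sprintf("bridge_%03d", seq_len(design$n_bridging))
  } else character(0)
  bg_genes <- if (design$n_background > 0) {
    sprintf("background_%03d", seq_len(design$n_background))
  } else character(0)
  genes <- c(module_genes, bridge_genes, bg_genes)
  ng <- length(genes)
  if (ng == 0) stop("design contains no genes")

  primary <- c(rep(names(design$module_sizes), design$module_sizes),
               rep(NA_character_, design$n_bridging),
               rep(NA_character_, design$n_background))
  secondary <- rep(NA_character_, ng)
  is_bridging <- c(rep(FALSE, length(module_genes)),
                   rep(TRUE, design$n_bridging),
                   rep(FALSE, design$n_background))
  orientation <- rep(NA_integer_, ng)
  if (design$n_bridging > 0) {
    npairs <- length(design$bridge_pairs)
    pair_idx <- rep(seq_len(npairs),
                    each = ceiling(design$n_bridging / npairs))[
                      seq_len(design$n_bridging)]
    ## within each group, alternate the sign-mirrored subgroups
    orient <- unlist(lapply(split(seq_len(design$n_bridging), pair_idx),
                            function(i) ifelse(seq_along(i) %% 2L == 1L,
                                               1L, -1L)),
                     use.names = FALSE)
    bi <- which(is_bridging)
    for (j in seq_along(bi)) {
      p <- design$bridge_pairs[[pair_idx[j]]]
      ## the mirrored subgroup carries the negated signal with reversed
      ## dominance, so it peaks upward-or-downward in the *other* tissue
      if (orient[j] == -1L) p <- rev(p)
      primary[bi[j]] <- p[1]
      secondary[bi[j]] <- p[2]
      orientation[bi[j]] <- orient[j]
    }
  }

  ## RNG draw order is fixed: amplitudes, profile jitter, baselines,
  ## tissue offsets, replicate noise, q-values.
  amplitude <- runif(ng, design$amplitude_range[1], design$amplitude_range[2])
  amplitude[is.na(primary)] <- 0
  nnb <- length(nonbase)
  if (design$profile_jitter_sd > 0) {
    jit1 <- matrix(rnorm(ng * nnb, 0, design$profile_jitter_sd), nrow = ng)
    jit2 <- matrix(rnorm(ng * nnb, 0, design$profile_jitter_sd), nrow = ng)
  } else {
    jit1 <- jit2 <- matrix(0, nrow = ng, ncol = nnb)
  }
  ## baseline FPKM: log-normal truncated below at baseline_min
  p0 <- stats::plnorm(design$baseline_min, design$baseline_log_mean,
                      design$baseline_log_sd)
  baseline <- stats::qlnorm(runif(ng, p0, 1), design$baseline_log_mean,
                            design$baseline_log_sd)
  offsets <- matrix(2 ^ runif(ng * length(tissues), -design$tissue_offset_log2,
                              design$tissue_offset_log2),
                    nrow = ng, dimnames = list(genes, tissues))

  true_fc <- matrix(0, nrow = ng, ncol = length(conds),
                    dimnames = list(genes, conds))
  ## realized per-gene profile: archetype multipliers plus gene-level
  ## jitter, renormalised so the peak multiplier is exactly 1
  realize <- function(v, w) {
    u <- v + w
    mx <- max(abs(u))
    if (mx > 0) u / mx else u
  }
  add_signal <- function(i, arch_id, scale, jit) {
    a <- arcs[[arch_id]]
    cols <- paste(a$tissue, nonbase, sep = ":")
    prof <- realize(a$profile[as.character(nonbase)], jit[i, ])
    true_fc[i, cols] <<- true_fc[i, cols] +
      amplitude[i] * design$effect_size * scale * prof
  }
  for (i in seq_len(ng)) {
    o <- if (is.na(orientation[i])) 1 else orientation[i]
    if (!is.na(primary[i])) add_signal(i, primary[i], o, jit1)
    if (!is.na(secondary[i])) {
      add_signal(i, secondary[i], o * design$bridge_secondary_scale, jit2)
    }
  }

  samples <- expand.grid(replicate = seq_len(design$replicates),
                         day = sort(days), tissue = tissues,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("tissue", "day", "replicate")]
  samples$sample_id <- sprintf("%s_d%02d_r%d", samples$tissue, samples$day,
                               samples$replicate)
  ns <- nrow(samples)

  signal <- matrix(0, nrow = ng, ncol = ns,
                   dimnames = list(genes, samples$sample_id))
  nb_cols <- samples$day != 0L
  signal[, nb_cols] <- true_fc[, paste(samples$tissue[nb_cols],
                                       samples$day[nb_cols], sep = ":")]
  noise <- if (design$noise_sd > 0) {
    matrix(rnorm(ng * ns, 0, design$noise_sd), nrow = ng)
  } else matrix(0, nrow = ng, ncol = ns)
  values <- baseline * offsets[, samples$tissue] * 2 ^ (signal + noise)
  dimnames(values) <- list(genes, samples$sample_id)

  expr <- expression_matrix(values, samples[, c("sample_id", "tissue",
                                                "day", "replicate")],
                            tissues = tissues, days = days)

  ## DEG table from replicate-mean FPKM with pseudocount 1 vs day 0.
  deg <- expand.grid(day = nonbase, tissue = tissues,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  deg_list <- vector("list", nrow(deg))
  for (r in seq_len(nrow(deg))) {
    t <- deg$tissue[r]; d <- deg$day[r]
    m_d <- rowMeans(values[, samples$tissue == t & samples$day == d,
                           drop = FALSE])
    m_0 <- rowMeans(values[, samples$tissue == t & samples$day == 0L,
                           drop = FALSE])
    deg_list[[r]] <- data.frame(gene = genes, tissue = t, day = d,
                                log2fc = log2((m_d + 1) / (m_0 + 1)),
                                stringsAsFactors = FALSE)
  }
  deg <- do.call(rbind, deg_list)
  rownames(deg) <- NULL
  active <- abs(true_fc[cbind(match(deg$gene, genes),
                              match(paste(deg$tissue, deg$day, sep = ":"),
                                    conds))]) >= design$active_abs_log2fc
  deg$q <- ifelse(active,
                  runif(nrow(deg), 0, design$q_active_max),
                  runif(nrow(deg), design$q_inactive_min, 1))

  truth <- structure(list(
    genes = data.frame(gene = genes,
                       archetype = ifelse(is.na(primary), "background",
                                          primary),
                       secondary_archetype = secondary,
                       tissue = ifelse(is.na(primary), NA_character_,
                                       arch_tissue[primary]),
                       is_bridging = is_bridging,
                       orientation = orientation,
                       amplitude = amplitude,
                       stringsAsFactors = FALSE),
    true_log2fc = true_fc,
    tissues = tissues, days = days), class = "synthetic_truth")

  list(expression = expr, deg = deg, truth = truth, design = design)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic truth: ", nrow(x$genes), " genes (",
      sum(x$genes$archetype != "background"), " planted, ",
      sum(x$genes$is_bridging), " bridging)\n", sep = "")
  invisible(x)
}

#' Write / read a synthetic ground-truth table
#'
#' The truth table is a UTF-8 tab-separated file with one row per gene:
#' archetype memberships, bridging flags, amplitudes and the planted
#' log2FC for every condition (columns named `tissue:day`). `read_truth()`
#' reconstructs the `synthetic_truth` object losslessly.
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` returns
#'   a `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  df <- truth$genes
  fc <- truth$true_log2fc
  num <- as.data.frame(apply(fc, 2, function(x) sprintf("%.17g", x),
                             simplify = FALSE), check.names = FALSE,
                       stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    num <- as.data.frame(setNames(rep(list(character(0)), ncol(fc)),
                                  colnames(fc)), check.names = FALSE)
  }
  df$amplitude <- sprintf("%.17g", df$amplitude)
  out <- cbind(df, num)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("gene", "archetype", "secondary_archetype", "tissue",
                 "is_bridging", "orientation", "amplitude")
  if (!all(meta_cols %in% names(df))) {
    stop("not a truth table: missing columns ",
         paste(setdiff(meta_cols, names(df)), collapse = ", "))
  }
  cond_cols <- setdiff(names(df), meta_cols)
  fc <- as.matrix(df[, cond_cols, drop = FALSE])
  storage.mode(fc) <- "double"
  rownames(fc) <- df$gene
  genes <- df[, meta_cols]
  genes$gene <- as.character(genes$gene)
  genes$is_bridging <- as.logical(genes$is_bridging)
  genes$secondary_archetype <- as.character(genes$secondary_archetype)
  genes$tissue <- as.character(genes$tissue)
  genes$orientation <- as.integer(genes$orientation)
  cc <- parse_conditions(cond_cols)
  structure(list(genes = genes, true_log2fc = fc,
                 tissues = unique(cc$tissue),
                 days = sort(unique(c(0L, cc$day)))),
            class = "synthetic_truth")
}
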