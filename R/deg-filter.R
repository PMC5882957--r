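#' Configuration of the stringent network-input gene filter
#'
#' Three rules select genes for co-expression network construction:
#' R1 — significant FDR (q < `q_max`) in at least one tissue x day;
#' R2 — not an excluded biotype and not a multi-symbol de novo transcript;
#' R3 — |log2FC| >= `min_abs_log2fc` in at least one tissue x day.
#'
#' @param q_max FDR cut-off (default 0.05).
#' @param min_abs_log2fc Stringent fold-change cut-off (default 3.0).
#' @param excluded_biotypes Biotype labels removed outright (default rRNA).
#' @param exclude_multi_symbol Remove de novo transcripts mapping to more
#'   than two gene symbols (default TRUE).
#' @return A `gcn_filter_config` list.
#' @export
gcn_filter_config <- function(q_max = 0.05, min_abs_log2fc = 3.0,
                              excluded_biotypes = "rRNA",
                              exclude_multi_symbol = TRUE) {
  if (!(q_max > 0 && q_max <= 1)) stop("need 0 < q_max <= 1")
  if (min_abs_log2fc < 0) stop("`min_abs_log2fc` must be >= 0")
  structure(list(q_max = q_max, min_abs_log2fc = min_abs_log2fc,
                 excluded_biotypes = excluded_biotypes,
                 exclude_multi_symbol = isTRUE(exclude_multi_symbol)),
            class = "gcn_filter_config")
}

#' Stringent three-rule gene filter for network construction
#'
#' Keeps a gene iff it (R1) reaches q < `q_max` in at least one
#' tissue x day, (R2) is not an excluded biotype nor a de novo transcript
#' with more than two gene symbols, and (R3) reaches
#' |log2FC| >= `min_abs_log2fc` in at least one tissue x day. Removed genes
#' are attributed to the first failing rule in the order R1, R2, R3 (the
#' attribution order affects only the report, not the kept set).
#'
#' Genes absent from `annotation` are treated as an unexcluded "unknown"
#' biotype with one symbol.
#'
#' @param deg DEG table (gene, tissue, day, log2fc, q).
#' @param annotation Optional data frame with columns `gene`, `biotype`,
#'   `n_symbols`, `is_de_novo`.
#' @param config A [gcn_filter_config()].
#' @return List with `kept` (character vector), `report` (data frame of
#'   gene, rule for removed genes) and `counts` (per-rule removal counts).
#' @export
gcn_gene_filter <- function(deg, annotation = NULL,
                            config = gcn_filter_config()) {
  if (is.null(deg) || nrow(deg) == 0) stop("empty DEG table")
  stopifnot(inherits(config, "gcn_filter_config"))
  genes <- unique(deg$gene)
  best_q <- tapply(deg$q, deg$gene, min)[genes]
  max_fc <- tapply(abs(deg$log2fc), deg$gene, max)[genes]

  biotype <- rep("unknown", length(genes))
  n_symbols <- rep(1L, length(genes))
  de_novo <- rep(FALSE, length(genes))
  if (!is.null(annotation)) {
    need <- c("gene", "biotype", "n_symbols", "is_de_novo")
    if (!all(need %in% names(annotation))) {
      stop("annotation must have columns ", paste(need, collapse = ", "))
    }
    i <- match(genes, annotation$gene)
    hit <- !is.na(i)
    biotype[hit] <- annotation$biotype[i[hit]]
    n_symbols[hit] <- annotation$n_symbols[i[hit]]
    de_novo[hit] <- annotation$is_de_novo[i[hit]]
  }

  pass1 <- best_q < config$q_max
  pass2 <- !(biotype %in% config$excluded_biotypes) &
    !(config$exclude_multi_symbol & de_novo & n_symbols > 2)
  pass3 <- max_fc >= config$min_abs_log2fc

  rule <- rep(NA_character_, length(genes))
  rule[!pass1] <- "R1_no_significant_q"
  rule[is.na(rule) & !pass2] <- "R2_biotype_or_multi_symbol"
  rule[is.na(rule) & !pass3] <- "R3_below_min_abs_log2fc"

  kept <- genes[is.na(rule)]
  removed <- !is.na(rule)
  report <- data.frame(gene = genes[removed], rule = rule[removed],
                       best_q = unname(best_q[removed]),
                       max_abs_log2fc = unname(max_fc[removed]),
                       stringsAsFactors = FALSE)
  counts <- c(kept = length(kept),
              R1_no_significant_q = sum(rule == "R1_no_significant_q",
                                        na.rm = TRUE),
              R2_biotype_or_multi_symbol =
                sum(rule == "R2_biotype_or_multi_symbol", na.rm = TRUE),
              R3_below_min_abs_log2fc =
                sum(rule == "R3_below_min_abs_log2fc", na.rm = TRUE))
  list(kept = kept, report = report, counts = counts)
}

#' DEG counts per condition and tissue-overlap counts
#'
#' Counts, per (tissue, day), the genes significant at `q < q_max`, and,
#' per day, the genes significant in each pair of tissues simultaneously.
#'
#' @param deg DEG table.
#' @param q_max Significance cut-off (default 0.05).
#' @return List with `per_condition` (tissue, day, n) and `overlaps`
#'   (tissue_a, tissue_b, day, n).
#' @export
count_degs <- function(deg, q_max = 0.05) {
  if (is.null(deg) || nrow(deg) == 0) {
    return(list(per_condition = data.frame(tissue = character(0),
                                           day = integer(0), n = integer(0)),
                overlaps = data.frame(tissue_a = character(0),
                                      tissue_b = character(0),
                                      day = integer(0), n = integer(0))))
  }
  sig <- deg[deg$q < q_max, , drop = FALSE]
  tissues <- unique(deg$tissue)
  days <- sort(unique(deg$day))
  grid <- expand.grid(tissue = tissues, day = days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n <- mapply(function(t, d) {
    sum(sig$tissue == t & sig$day == d)
  }, grid$tissue, grid$day)
  ov <- list()
  if (length(tissues) >= 2) {
    for (i in seq_len(length(tissues) - 1)) {
      for (j in seq(i + 1, length(tissues))) {
        for (d in days) {
          a <- sig$gene[sig$tissue == tissues[i] & sig$day == d]
          b <- sig$gene[sig$tissue == tissues[j] & sig$day == d]
          ov[[length(ov) + 1L]] <- data.frame(
            tissue_a = tissues[i], tissue_b = tissues[j], day = d,
            n = length(intersect(a, b)), stringsAsFactors = FALSE)
        }
      }
    }
  }
  overlaps <- if (length(ov)) do.call(rbind, ov) else {
    data.frame(tissue_a = character(0), tissue_b = character(0),
               day = integer(0), n = integer(0))
  }
  list(per_condition = grid, overlaps = overlaps)
}
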