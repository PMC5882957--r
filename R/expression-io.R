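#' Construct a validated expression matrix
#'
#' An `expression_matrix` couples a genes x samples FPKM matrix with
#' per-sample metadata (tissue, day, replicate) and the declared tissue and
#' day orders.
#'
#' @param values Numeric genes x samples matrix of FPKM (>= 0, finite),
#'   with unique row and column names.
#' @param samples Data frame with columns `sample_id`, `tissue`, `day`,
#'   `replicate`; one row per column of `values`.
#' @param tissues Declared tissue order (default: order of appearance).
#' @param days Declared day set (default: sorted unique days).
#' @return An object of class `expression_matrix` with components `values`,
#'   `samples`, `tissues`, `days`.
#' @export
expression_matrix <- function(values, samples, tissues = NULL, days = NULL) {
  stopifnot(is.matrix(values), is.data.frame(samples))
  need <- c("sample_id", "tissue", "day", "replicate")
  if (!all(need %in% names(samples))) {
    stop("sample metadata must have columns ", paste(need, collapse = ", "))
  }
  samples$day <- as.integer(samples$day)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression values must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  missing_meta <- setdiff(colnames(values), samples$sample_id)
  if (length(missing_meta)) {
    stop("sample(s) in matrix but not metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  missing_mat <- setdiff(samples$sample_id, colnames(values))
  if (length(missing_mat)) {
    stop("sample(s) in metadata but not matrix: ",
         paste(missing_mat, collapse = ", "))
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(tissues)) tissues <- unique(samples$tissue)
  if (is.null(days)) days <- sort(unique(samples$day))
  bad_t <- !samples$tissue %in% tissues
  if (any(bad_t)) {
    stop("unknown tissue for sample(s): ",
         paste(samples$sample_id[bad_t], collapse = ", "))
  }
  bad_d <- !samples$day %in% days
  if (any(bad_d)) {
    stop("unknown day for sample(s): ",
         paste(samples$sample_id[bad_d], collapse = ", "))
  }
  neg <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative or non-finite FPKM for gene(s): ",
         paste(unique(rownames(values)[neg[, 1]]), collapse = ", "))
  }
  structure(list(values = values, samples = samples,
                 tissues = tissues, days = as.integer(days)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples; tissues: ", paste(x$tissues, collapse = ", "),
      "; days: ", paste(x$days, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write an expression matrix with sample metadata
#'
#' The matrix file is tab-separated with a `gene` column followed by one
#' column per sample; the metadata file is tab-separated with columns
#' `sample_id`, `tissue`, `day`, `replicate`.
#'
#' @param matrix_path,metadata_path File paths.
#' @param tissues,days Optional declared orders (passed to
#'   [expression_matrix()]).
#' @return An `expression_matrix`.
#' @export
read_expression <- function(matrix_path, metadata_path,
                            tissues = NULL, days = NULL) {
  mat <- read.delim(matrix_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!"gene" %in% names(mat)) stop("matrix file must have a `gene` column")
  values <- as.matrix(mat[, setdiff(names(mat), "gene"), drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- mat$gene
  samples <- read.delim(metadata_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  expression_matrix(values, samples, tissues = tissues, days = days)
}

#' @rdname read_expression
#' @param expr An `expression_matrix`.
#' @export
write_expression <- function(expr, matrix_path, metadata_path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  write.table(expr$samples, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(matrix_path, metadata_path))
}

#' Per-gene log2 fold-change profiles against the baseline day
#'
#' For each gene, tissue and non-baseline day, computes
#' `log2((mean FPKM at day d + 1) / (mean FPKM at baseline + 1))`, where
#' means are arithmetic means over replicates within the same tissue. The
#' pseudocount of 1 stabilises low-expression ratios. Baseline-day columns
#' are identically zero by construction and therefore excluded.
#'
#' @param expr An [expression_matrix()].
#' @param baseline_day Baseline day (default 0); every tissue must have
#'   samples on it.
#' @return A profile matrix (genes x conditions, columns `tissue:day`).
#' @export
log2fc_profiles <- function(expr, baseline_day = 0) {
  stopifnot(inherits(expr, "expression_matrix"))
  s <- expr$samples
  no_base <- expr$tissues[!vapply(expr$tissues, function(t) {
    any(s$tissue == t & s$day == baseline_day)
  }, logical(1))]
  if (length(no_base)) {
    stop("tissue(s) lacking baseline (day ", baseline_day, ") samples: ",
         paste(no_base, collapse = ", "))
  }
  nonbase <- sort(expr$days[expr$days != baseline_day])
  conds <- condition_labels(expr$tissues, expr$days, baseline_day)
  out <- matrix(NA_real_, nrow = nrow(expr$values), ncol = length(conds),
                dimnames = list(rownames(expr$values), conds))
  for (t in expr$tissues) {
    m0 <- rowMeans(expr$values[, s$tissue == t & s$day == baseline_day,
                               drop = FALSE])
    for (d in nonbase) {
      sel <- s$tissue == t & s$day == d
      if (!any(sel)) {
        stop("no samples for tissue ", t, " at day ", d)
      }
      md <- rowMeans(expr$values[, sel, drop = FALSE])
      out[, paste(t, d, sep = ":")] <- log2((md + 1) / (m0 + 1))
    }
  }
  new_profile_matrix(out, expr$tissues, expr$days, baseline_day)
}

#' Profile matrix from an upstream DEG table
#'
#' Adapter for the case where log2 fold changes are supplied by upstream
#' differential-expression software rather than recomputed from FPKM.
#'
#' @param deg Data frame with columns `gene`, `tissue`, `day`, `log2fc`
#'   (and optionally `q`).
#' @param tissues,days Declared orders defining the condition columns.
#' @param fill `"strict"` (default): every gene must have a record for
#'   every non-baseline (tissue, day); `"zero"`: missing entries become 0.
#' @param baseline_day Baseline day excluded from the columns.
#' @return A profile matrix (genes x conditions).
#' @export
deg_to_profiles <- function(deg, tissues, days, fill = c("strict", "zero"),
                            baseline_day = 0) {
  fill <- match.arg(fill)
  need <- c("gene", "tissue", "day", "log2fc")
  if (!all(need %in% names(deg))) {
    stop("DEG table must have columns ", paste(need, collapse = ", "))
  }
  days <- as.integer(days)
  deg <- deg[deg$day != baseline_day, , drop = FALSE]
  conds <- condition_labels(tissues, days, baseline_day)
  genes <- unique(deg$gene)
  key <- paste(deg$tissue, deg$day, sep = ":")
  unknown <- !key %in% conds
  if (any(unknown)) {
    stop("DEG record(s) outside the declared design: ",
         paste(unique(key[unknown]), collapse = ", "))
  }
  idx <- cbind(match(deg$gene, genes), match(key, conds))
  if (anyDuplicated(idx)) {
    d <- deg[duplicated(idx), , drop = FALSE][1, ]
    stop("duplicate DEG record for (", d$gene, ", ", d$tissue, ", ",
         d$day, ")")
  }
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(conds),
                dimnames = list(genes, conds))
  out[idx] <- deg$log2fc
  if (anyNA(out)) {
    if (fill == "zero") {
      out[is.na(out)] <- 0
    } else {
      miss <- which(is.na(out), arr.ind = TRUE)[1, ]
      stop("missing DEG record for (", genes[miss[1]], ", ",
           conds[miss[2]], ") under strict fill policy")
    }
  }
  new_profile_matrix(out, tissues, days, baseline_day)
}

#' Row-wise z-score transform
#'
#' Centres each row to mean 0 and scales to sample standard deviation 1
#' (divisor n - 1). Constant rows, which have no scale, map to all-zero
#' rows.
#'
#' @param m Numeric matrix with at least 2 columns.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("z-scoring needs at least 2 columns")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  out <- (m - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

#' Median-centre matrix rows
#'
#' Subtracts each row's median, the standard preprocessing for expression
#' k-means clustering. Idempotent.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape with zero row medians.
#' @export
median_center <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 1) stop("median centring needs at least 1 column")
  m - apply(m, 1, median)
}

#' Select genes reaching a fold-change bin
#'
#' Returns the genes whose maximum |log2FC| over all conditions reaches
#' `log2(fc_threshold)`, i.e. the genes in the fold-change bin
#' `>= fc_threshold`. Selected sets are nested as the threshold grows.
#'
#' @param profiles A profile matrix (genes x conditions of log2FC).
#' @param fc_threshold Fold-change threshold (> 1), e.g. 2, 4, 8, ... 256.
#' @return Character vector of selected gene ids.
#' @export
select_fc_bins <- function(profiles, fc_threshold) {
  if (!is.numeric(fc_threshold) || fc_threshold <= 1) {
    stop("`fc_threshold` must be > 1")
  }
  m <- as.matrix(profiles)
  rownames(m)[apply(abs(m), 1, max) >= log2(fc_threshold)]
}

#' Read / write a profile matrix as TSV
#'
#' Columns are headed `tissue:day`; the first column is `gene`.
#'
#' @param profiles A profile matrix.
#' @param path File path.
#' @return `write_profiles()` returns `path` invisibly; `read_profiles()`
#'   the profile matrix.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(gene = rownames(profiles), as.matrix(profiles),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  cc <- parse_conditions(colnames(m))
  new_profile_matrix(m, unique(cc$tissue), c(0L, sort(unique(cc$day))))
}

#' Read / write a DEG table as TSV
#'
#' @param deg Data frame with columns `gene`, `tissue`, `day`, `log2fc`, `q`.
#' @param path File path.
#' @export
write_deg <- function(deg, path) {
  write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_deg
#' @export
read_deg <- function(path) {
  deg <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene", "tissue", "day", "log2fc", "q")
  if (!all(need %in% names(deg))) {
    stop("DEG file must have columns ", paste(need, collapse = ", "))
  }
  if (any(deg$q < 0 | deg$q > 1, na.rm = TRUE)) {
    stop("q-values must lie in [0, 1]")
  }
  deg
}
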