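#' Seeded k-means clustering of expression profiles
#'
#' Lloyd iterations with Euclidean distance on (typically median-centred)
#' profile rows. Initial centres are a seeded deterministic sample of k
#' distinct rows, so the result is reproducible from the seed.
#'
#' @param m Numeric matrix (genes x conditions), e.g. after
#'   [median_center()].
#' @param k Number of clusters (default 5).
#' @param max_iter Maximum Lloyd iterations (default 1000).
#' @param seed Integer seed for the initial centre draws.
#' @param nstart Number of seeded restarts; the solution with the lowest
#'   total within-cluster sum of squares is kept (Lloyd iterations from a
#'   single random start are prone to poor local optima).
#' @return An object of class `cluster_result`: `cluster` (named integer
#'   vector in 1..k), `k`, `centers`, `withinss`, `tot_withinss`, `iter`,
#'   `seed`.
#' @export
kmeans_profiles <- function(m, k = 5, max_iter = 1000, seed = 1L,
                            nstart = 10) {
  m <- as.matrix(m)
  if (nrow(m) == 0) stop("empty matrix")
  if (k > nrow(m)) stop("k (", k, ") exceeds the number of genes (",
                        nrow(m), ")")
  set.seed(seed)
  best <- NULL
  for (i in seq_len(nstart)) {
    ord <- sample.int(nrow(m))
    centers <- unique_rows_first(m, ord, k)
    fit <- suppressWarnings(
      kmeans(m, centers = m[centers, , drop = FALSE], iter.max = max_iter,
             algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(list(cluster = setNames(best$cluster, rownames(m)), k = k,
                 centers = best$centers, withinss = best$withinss,
                 tot_withinss = best$tot.withinss, iter = best$iter,
                 seed = seed),
            class = "cluster_result")
}

## first k row indices (in the order given) with pairwise-distinct rows
unique_rows_first <- function(m, ord, k) {
  picked <- integer(0)
  for (i in ord) {
    if (!any(vapply(picked, function(j) all(m[i, ] == m[j, ]), logical(1)))) {
      picked <- c(picked, i)
    }
    if (length(picked) == k) return(picked)
  }
  stop("fewer than k (", k, ") distinct rows")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("k-means: k = ", x$k, ", sizes ",
      paste(tabulate(x$cluster, x$k), collapse = "/"),
      ", total within-SS ", signif(x$tot_withinss, 6), "\n", sep = "")
  invisible(x)
}

#' Choose the number of clusters by mean silhouette width
#'
#' Runs [kmeans_profiles()] for each candidate k and returns the k with the
#' highest mean silhouette width (ties broken towards the smaller k).
#'
#' @param m Numeric matrix (genes x conditions).
#' @param k_range Candidate cluster counts, within 2..nrow(m)-1.
#' @param max_iter,seed Passed to [kmeans_profiles()].
#' @return List with `k` (chosen) and `scores` (data frame k, mean
#'   silhouette width, total within-SS).
#' @export
choose_k <- function(m, k_range = 2:8, max_iter = 1000, seed = 1L) {
  m <- as.matrix(m)
  if (any(k_range < 2) || any(k_range > nrow(m) - 1)) {
    stop("`k_range` must lie within 2..", nrow(m) - 1)
  }
  d <- dist(m)
  scores <- lapply(k_range, function(k) {
    cl <- kmeans_profiles(m, k = k, max_iter = max_iter, seed = seed)
    sil <- cluster::silhouette(as.integer(cl$cluster), d)
    data.frame(k = k, mean_silhouette = mean(sil[, "sil_width"]),
               tot_withinss = cl$tot_withinss)
  })
  scores <- do.call(rbind, scores)
  best <- scores$k[which.max(scores$mean_silhouette)]
  list(k = best, scores = scores)
}

#' Sample PCA on log-scale expression
#'
#' Column-mean-centred principal component analysis via singular value
#' decomposition, without scaling. Rows are samples.
#'
#' @param x Numeric samples x genes matrix, usually `log2(FPKM + 1)`.
#' @return List with `scores` (samples x components), `explained`
#'   (non-increasing variance fractions summing to <= 1) and `sdev`.
#' @export
pca_samples <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  xc <- sweep(x, 2, colMeans(x))
  sv <- La.svd(xc)
  d <- sv$d
  scores <- xc %*% t(sv$vt)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores, explained = d^2 / sum(d^2),
       sdev = d / sqrt(nrow(x) - 1))
}

#' Partitioning around medoids for samples
#'
#' Classic PAM (build + swap) on Euclidean distances between sample
#' vectors. PAM is deterministic; the seed is part of the interface for
#' symmetry with the other clustering entry points.
#'
#' @param x Numeric samples x genes matrix.
#' @param k Number of clusters (default 3, one per tissue).
#' @param seed Unused by PAM itself; recorded in the result.
#' @return List with `cluster` (named), `medoids` (sample ids), `k`, `seed`.
#' @export
pam_samples <- function(x, k = 3, seed = 1L) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k (", k, ") exceeds the number of samples (",
                        nrow(x), ")")
  if (k == nrow(x)) {
    ## degenerate case: every sample is its own medoid
    return(list(cluster = setNames(seq_len(k), rownames(x)),
                medoids = rownames(x), k = k, seed = seed))
  }
  fit <- cluster::pam(x, k = k, metric = "euclidean")
  list(cluster = fit$clustering, medoids = rownames(x)[fit$id.med],
       k = k, seed = seed)
}

#' Condition-versus-condition correlation matrix over a gene set
#'
#' Pearson correlation between every pair of condition columns, computed
#' across the genes of `gene_set`. Zero-variance columns have no defined
#' correlation; their off-diagonal entries are set to 0 and the conditions
#' are reported in the `flagged` attribute.
#'
#' @param profiles Profile matrix (genes x conditions).
#' @param gene_set Character vector of >= 3 genes, subset of the rows.
#' @return Symmetric condition x condition correlation matrix with unit
#'   diagonal and attribute `flagged`.
#' @export
condition_corr_matrix <- function(profiles, gene_set) {
  m <- as.matrix(profiles)
  missing <- setdiff(gene_set, rownames(m))
  if (length(missing)) {
    stop("gene(s) not in profiles: ", paste(missing, collapse = ", "))
  }
  if (length(gene_set) < 3) stop("gene set too small (need >= 3 genes)")
  sub <- m[gene_set, , drop = FALSE]
  flagged <- colnames(sub)[apply(sub, 2, sd) == 0]
  cc <- suppressWarnings(cor(sub))
  cc[is.na(cc)] <- 0
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  attr(cc, "flagged") <- flagged
  cc
}

#' Per-condition expression-wave summary for a gene set
#'
#' Five-number summary of log2FC per (tissue, day) over the gene set, plus
#' the count of genes with |log2FC| strictly greater than
#' `highlight_abs_fc` (the "black dot" highlight rule).
#'
#' @param profiles Profile matrix.
#' @param gene_set Nonempty character vector of genes.
#' @param highlight_abs_fc Highlight threshold (default 3.0, strict >).
#' @return Data frame with tissue, day, min/q1/median/q3/max and
#'   `n_highlight`.
#' @export
wave_summary <- function(profiles, gene_set, highlight_abs_fc = 3.0) {
  if (length(gene_set) == 0) stop("empty gene set")
  m <- as.matrix(profiles)[gene_set, , drop = FALSE]
  cc <- parse_conditions(colnames(m))
  stats <- t(apply(m, 2, quantile, probs = c(0, 0.25, 0.5, 0.75, 1)))
  data.frame(tissue = cc$tissue, day = cc$day,
             min = stats[, 1], q1 = stats[, 2], median = stats[, 3],
             q3 = stats[, 4], max = stats[, 5],
             n_highlight = apply(abs(m) > highlight_abs_fc, 2, sum),
             row.names = NULL, stringsAsFactors = FALSE)
}
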