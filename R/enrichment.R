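#' Gene-set collection with a declared universe
#'
#' Members outside the universe are dropped (and counted) in an explicit
#' intersection step, so that enrichment arithmetic is always performed
#' against a consistent background.
#'
#' @param sets Named list of character vectors (set id -> members), or a
#'   list of lists with `description` and `genes`.
#' @param universe Character vector: the background gene universe.
#' @param descriptions Optional named character vector of set descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  if (is.null(names(sets))) stop("`sets` must be named by set id")
  dropped <- integer(length(sets))
  names(dropped) <- names(sets)
  members <- lapply(names(sets), function(id) {
    g <- unique(sets[[id]])
    keep <- g[g %in% universe]
    dropped[id] <<- length(g) - length(keep)
    keep
  })
  names(members) <- names(sets)
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = members, universe = universe,
                 descriptions = descriptions, dropped = dropped),
            class = "gene_set_collection")
}

#' Read / write gene sets in GMT format
#'
#' GMT is tab-separated: set id, description, then member genes.
#'
#' @param path File path.
#' @param universe Universe passed to [gene_set_collection()]; defaults to
#'   the union of all members.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop("malformed GMT line(s) (need id, description, >=1 gene): ",
         paste(which(bad), collapse = ", "))
  }
  ids <- vapply(parts, `[`, character(1), 1L)
  desc <- setNames(vapply(parts, `[`, character(1), 2L), ids)
  sets <- setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe, desc)
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Hypergeometric gene-set enrichment
#'
#' For each set, computes the exact hypergeometric upper-tail probability
#' P\[X >= k\] of observing k query hits given a query of size n, a set of
#' size K and a universe of size N, the fold enrichment (k/n)/(K/N) and the
#' Benjamini-Hochberg q-value across all tested sets. Sets are flagged
#' `passing` if -log10(p) exceeds `min_neglog10p` and the hit count exceeds
#' `min_count` (both strict, matching the usual display cut-offs).
#'
#' @param query Character vector of query genes; intersected with the
#'   universe first.
#' @param collection A [gene_set_collection()].
#' @param min_count Hit-count cut-off (strict >, default 3).
#' @param min_neglog10p -log10 p cut-off (strict >, default 1.0).
#' @return Data frame with one row per set: k, n, K, N, fold_enrichment,
#'   p, q, passing; sorted by p.
#' @export
hypergeom_enrich <- function(query, collection, min_count = 3,
                             min_neglog10p = 1.0) {
  stopifnot(inherits(collection, "gene_set_collection"))
  N <- length(collection$universe)
  if (N == 0) stop("empty universe")
  query <- unique(query)
  query <- query[query %in% collection$universe]
  n <- length(query)
  if (n == 0) stop("empty query after intersection with the universe")
  rows <- lapply(names(collection$sets), function(id) {
    members <- collection$sets[[id]]
    K <- length(members)
    k <- sum(query %in% members)
    fold <- if (K > 0) (k / n) / (K / N) else NA_real_
    ## upper tail P[X >= k]; k = 0 gives p = 1 by convention
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id,
               description = unname(collection$descriptions[id]),
               k = k, n = n, K = K, N = N, fold_enrichment = fold, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$passing <- (-log10(out$p) > min_neglog10p) & (out$k > min_count)
  out[order(out$p), , drop = FALSE]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; order-preserving with respect
#' to the input positions and clipped to 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Relative qPCR expression by the 2^-ddCT method
#'
#' Normalises the target CT against the geometric mean of the reference
#' gene CTs per sample (dCT), subtracts the calibrator sample's dCT (ddCT)
#' and reports RQ = 2^-ddCT. The calibrator's RQ is exactly 1.
#'
#' @param qpcr Data frame with columns `sample`, `gene`, `ct`.
#' @param target Target gene id.
#' @param reference_genes Character vector of reference gene ids; every
#'   sample must have a CT for each.
#' @param calibrator Sample id of the calibrator condition.
#' @return Data frame with `sample`, `dct`, `ddct`, `rq`.
#' @export
relative_expression_ddct <- function(qpcr, target, reference_genes,
                                     calibrator) {
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(qpcr))) {
    stop("qPCR table must have columns ", paste(need, collapse = ", "))
  }
  samples <- unique(qpcr$sample)
  if (!calibrator %in% samples) {
    stop("calibrator sample not in table: ", calibrator)
  }
  dct <- vapply(samples, function(s) {
    sub <- qpcr[qpcr$sample == s, , drop = FALSE]
    refs <- sub$ct[match(reference_genes, sub$gene)]
    if (anyNA(refs)) {
      stop("sample ", s, " missing reference CT for: ",
           paste(reference_genes[is.na(refs)], collapse = ", "))
    }
    tct <- sub$ct[match(target, sub$gene)]
    if (is.na(tct)) stop("sample ", s, " missing target CT for ", target)
    tct - exp(mean(log(refs)))
  }, numeric(1))
  ddct <- dct - dct[[calibrator]]
  data.frame(sample = samples, dct = unname(dct), ddct = unname(ddct),
             rq = 2 ^ -unname(ddct), stringsAsFactors = FALSE)
}

#' Cross-platform fold-change concordance
#'
#' Pearson correlation and ordinary least-squares regression of one
#' platform's log2 fold changes on the other's, over gene x condition
#' pairs matched by position. Pairs with missing values are dropped and
#' counted.
#'
#' @param a,b Numeric vectors of matched log2FC values (e.g. RNA-seq and
#'   qPCR), same length.
#' @return List with `r`, `r_squared`, `slope`, `intercept`, `n`,
#'   `n_dropped`.
#' @export
platform_concordance <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  ok <- is.finite(a) & is.finite(b)
  n_dropped <- sum(!ok)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need >= 3 matched pairs (have ", length(a), ")")
  fit <- lm(b ~ a)
  r <- cor(a, b)
  list(r = r, r_squared = r^2,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(a), n_dropped = n_dropped)
}
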