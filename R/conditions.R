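## Condition labels: a condition is a (tissue, day) pair, written "tissue:day".
## The declared column order of every profile matrix is the tissue order
## crossed with ascending non-baseline days.

condition_labels <- function(tissues, days, baseline_day = 0) {
  days <- sort(unique(as.integer(days)))
  days <- days[days != baseline_day]
  paste(rep(tissues, each = length(days)),
        rep(days, times = length(tissues)), sep = ":")
}

parse_conditions <- function(labels) {
  parts <- strsplit(labels, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed condition label(s): ", paste(labels[bad], collapse = ", "))
  }
  data.frame(condition = labels,
             tissue = vapply(parts, `[`, character(1), 1L),
             day = as.integer(vapply(parts, `[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}

## Profile matrices are plain numeric matrices (genes x conditions) carrying
## the declared tissue/day order as attributes.
new_profile_matrix <- function(m, tissues, days, baseline_day = 0) {
  stopifnot(is.matrix(m))
  expected <- condition_labels(tissues, days, baseline_day)
  if (!identical(colnames(m), expected)) {
    stop("profile columns must follow the declared condition order (",
         paste(utils::head(expected, 3), collapse = ", "), ", ...)")
  }
  if (any(!is.finite(m))) stop("profile matrix contains non-finite values")
  structure(m,
            tissues = tissues,
            days = sort(unique(as.integer(days))),
            baseline_day = baseline_day,
            class = c("profile_matrix", class(m)))
}

profile_tissues <- function(profiles) {
  tis <- attr(profiles, "tissues")
  if (is.null(tis)) unique(parse_conditions(colnames(profiles))$tissue) else tis
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("log2FC profile matrix: ", nrow(x), " genes x ", ncol(x),
      " conditions (", paste(profile_tissues(x), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}
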