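#' Gene-gene Pearson correlation over the full condition vector
#'
#' Correlates every pair of gene profiles across the concatenated
#' tissue x day condition columns. Rows with zero variance have no defined
#' correlation and are rejected (or dropped under `zero_variance =
#' "drop"`).
#'
#' @param profiles Profile matrix (genes x conditions), >= 3 columns.
#' @param zero_variance `"error"` (default) or `"drop"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_profiles <- function(profiles, zero_variance = c("error", "drop")) {
  zero_variance <- match.arg(zero_variance)
  m <- as.matrix(profiles)
  if (ncol(m) < 3) stop("need >= 3 condition columns")
  v <- apply(m, 1, sd)
  if (any(v == 0)) {
    if (zero_variance == "error") {
      stop("zero-variance profile for gene(s): ",
           paste(rownames(m)[v == 0], collapse = ", "))
    }
    m <- m[v > 0, , drop = FALSE]
  }
  r <- cor(t(m))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' PCIT significance mask for a correlation matrix
#'
#' Implements the partial correlation and information theory (PCIT)
#' algorithm for deciding which pairwise co-expression correlations are
#' significant. For every unordered gene trio \{x, y, z\} the three
#' first-order partial correlations are computed, e.g.
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) /
#'       \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)},}
#' and the trio tolerance is the average of the three \eqn{|partial /
#' direct|} ratios. The edge (x, y) is flagged non-significant if some
#' third gene z satisfies \eqn{|r_{xy}| < \epsilon |r_{xz}|} and
#' \eqn{|r_{xy}| < \epsilon |r_{yz}|} (strict inequalities: ties are
#' retained). Edges never eliminated by any trio are significant; with only
#' two genes the single edge is significant.
#'
#' Numerical guards: ratio terms with |direct| < 1e-12 are skipped and the
#' tolerance averages the remaining terms; square-root arguments are
#' clamped at 0; a partial correlation whose denominator vanishes
#' (collinear conditioning gene) is set to 0; edges with |r| < 1e-8 are
#' non-significant outright.
#'
#' @param r Symmetric correlation matrix with unit diagonal.
#' @return List with `mask` (logical symmetric matrix, diagonal FALSE) and
#'   `diagnostics` (trio count, tolerance summary, significant edge count).
#' @seealso [pcit_mask_ref()] for the literal reference implementation.
#' @export
pcit_mask <- function(r) {
  r <- check_corr_matrix(r)
  n <- nrow(r)
  if (n < 2) {
    mask <- matrix(FALSE, n, n, dimnames = dimnames(r))
    return(list(mask = mask,
                diagnostics = list(n_genes = n, n_trios = 0,
                                   eps_mean = NA_real_, eps_min = NA_real_,
                                   eps_max = NA_real_, n_significant = 0)))
  }
  res <- pcit_mask_cpp(r)
  mask <- res$mask
  dimnames(mask) <- dimnames(r)
  list(mask = mask,
       diagnostics = list(n_genes = n, n_trios = res$n_trios,
                          eps_mean = res$eps_mean, eps_min = res$eps_min,
                          eps_max = res$eps_max,
                          n_significant = res$n_significant))
}

#' Literal triple-loop PCIT reference implementation
#'
#' Plain-R restatement of the PCIT elimination rule, written independently
#' of the optimized kernel and kept as a cross-check oracle. Quadratic in
#' memory, cubic in time; intended for small matrices.
#'
#' @inheritParams pcit_mask
#' @return Logical significance mask (symmetric, diagonal FALSE).
#' @export
pcit_mask_ref <- function(r) {
  r <- check_corr_matrix(r)
  n <- nrow(r)
  elim <- matrix(FALSE, n, n)
  partial <- function(rxy, rxz, ryz) {
    den <- sqrt(max(1 - rxz^2, 0) * max(1 - ryz^2, 0))
    if (den < 1e-12) return(0)
    (rxy - rxz * ryz) / den
  }
  if (n >= 3) {
    for (x in 1:(n - 2)) {
      for (y in (x + 1):(n - 1)) {
        for (z in (y + 1):n) {
          rxy <- r[x, y]; rxz <- r[x, z]; ryz <- r[y, z]
          terms <- c()
          pxy <- partial(rxy, rxz, ryz)
          pxz <- partial(rxz, rxy, ryz)
          pyz <- partial(ryz, rxy, rxz)
          if (abs(rxy) >= 1e-12) terms <- c(terms, abs(pxy / rxy))
          if (abs(rxz) >= 1e-12) terms <- c(terms, abs(pxz / rxz))
          if (abs(ryz) >= 1e-12) terms <- c(terms, abs(pyz / ryz))
          eps <- if (length(terms)) mean(terms) else 0
          if (abs(rxy) < eps * abs(rxz) && abs(rxy) < eps * abs(ryz)) {
            elim[x, y] <- elim[y, x] <- TRUE
          }
          if (abs(rxz) < eps * abs(rxy) && abs(rxz) < eps * abs(ryz)) {
            elim[x, z] <- elim[z, x] <- TRUE
          }
          if (abs(ryz) < eps * abs(rxy) && abs(ryz) < eps * abs(rxz)) {
            elim[y, z] <- elim[z, y] <- TRUE
          }
        }
      }
    }
  }
  mask <- !elim & abs(r) >= 1e-8
  diag(mask) <- FALSE
  dimnames(mask) <- dimnames(r)
  mask
}

check_corr_matrix <- function(r, tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("correlation matrix must be square")
  if (any(!is.finite(r))) stop("correlation matrix has non-finite entries")
  if (max(abs(r - t(r))) > tol) stop("correlation matrix is not symmetric")
  if (max(abs(diag(r) - 1)) > tol) {
    stop("correlation matrix must have unit diagonal")
  }
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}
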