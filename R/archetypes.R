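#' Default planted expression archetypes
#'
#' Returns the five temporal expression archetypes used by the synthetic-data
#' generator, mimicking the expression-profile clusters characteristic of
#' cycling reproductive tissues: endometrial up- and down-regulation peaking
#' mid-cycle (days 6-12), ovarian up- and down-regulation spanning days 3-12,
#' and a broad oviductal down-regulation. Each archetype is a vector of
#' signed multipliers in \[-1, 1\], one per day, anchored at exactly 0 on the
#' baseline day; a gene's planted log2 fold change is the archetype
#' multiplier scaled by the design effect size and the gene's amplitude.
#'
#' Multipliers for day grids other than the default are obtained by linear
#' interpolation of the canonical shapes on days 0,3,...,18.
#'
#' @param days Integer vector of sampling days; must contain the baseline
#'   day `baseline_day` exactly once.
#' @param baseline_day Baseline day (default 0); the multiplier there is 0.
#' @return A named list of `archetype` objects with fields `id`, `tissue`
#'   and `profile` (named by day).
#' @examples
#' arcs <- default_archetypes(c(0, 3, 6, 9, 12, 15, 18))
#' vapply(arcs, function(a) a$profile[["0"]], numeric(1)) # all zero
#' @export
default_archetypes <- function(days = c(0, 3, 6, 9, 12, 15, 18),
                               baseline_day = 0) {
  days <- as.integer(days)
  if (length(days) == 0 || sum(days == baseline_day) != 1L) {
    stop("`days` must contain the baseline day ", baseline_day,
         " exactly once; got: ", paste(days, collapse = ", "))
  }
  knots <- c(0, 3, 6, 9, 12, 15, 18)
  shapes <- list(
    endometrium_up = c(0, 0.25, 1, 1, 1, 0.25, 0),
    endometrium_down = -c(0, 0.25, 1, 1, 1, 0.25, 0),
    ovary_up = c(0, 0.5, 1, 1, 0.75, 0.25, 0),
    ovary_down = -c(0, 0.5, 1, 1, 0.75, 0.25, 0),
    oviduct_down = -c(0, 0.5, 0.75, 1, 0.75, 0.5, 0.25))
  tissues <- c(endometrium_up = "endometrium", endometrium_down = "endometrium",
               ovary_up = "ovary", ovary_down = "ovary",
               oviduct_down = "oviduct")
  out <- lapply(names(shapes), function(id) {
    prof <- stats::approx(knots, shapes[[id]], xout = days, rule = 2)$y
    prof[days == baseline_day] <- 0
    archetype(id, tissues[[id]], setNames(prof, days))
  })
  setNames(out, names(shapes))
}

#' Construct an expression archetype
#'
#' @param id Archetype label.
#' @param tissue Tissue in which the archetype is expressed.
#' @param profile Named numeric vector of signed multipliers in \[-1, 1\],
#'   one per day; the baseline day's entry must be 0.
#' @return An object of class `archetype`.
#' @export
archetype <- function(id, tissue, profile) {
  if (is.null(names(profile))) stop("archetype profile must be named by day")
  if (any(abs(profile) > 1)) stop("archetype multipliers must lie in [-1, 1]")
  structure(list(id = id, tissue = tissue, profile = profile),
            class = "archetype")
}

#' Bridge-specific expression archetypes
#'
#' Temporal programs used only by planted bridging genes: early-phase
#' responses (peaking around days 3-6) and a late endometrial response,
#' phase-shifted away from the module archetypes of [default_archetypes()].
#' Giving bridging genes their own cross-tissue program keeps their
#' correlation with module genes well below the network edge threshold
#' while bridge group members remain mutually (anti-)correlated; the signs
#' are chosen so that every default tissue pair mixes one up- and one
#' down-regulated component.
#'
#' @inheritParams default_archetypes
#' @return A named list of `archetype` objects.
#' @export
bridge_archetypes <- function(days = c(0, 3, 6, 9, 12, 15, 18),
                              baseline_day = 0) {
  days <- as.integer(days)
  if (length(days) == 0 || sum(days == baseline_day) != 1L) {
    stop("`days` must contain the baseline day ", baseline_day,
         " exactly once; got: ", paste(days, collapse = ", "))
  }
  knots <- c(0, 3, 6, 9, 12, 15, 18)
  early <- c(0, 1, 1, 0.75, 0.5, 0.25, 0)
  late <- c(0, 0, 0.25, 0.5, 0.75, 1, 1)
  shapes <- list(endometrium_early = early,
                 ovary_early = -early,
                 oviduct_early = early,
                 endometrium_late = -late)
  tissues <- c(endometrium_early = "endometrium", ovary_early = "ovary",
               oviduct_early = "oviduct", endometrium_late = "endometrium")
  out <- lapply(names(shapes), function(id) {
    prof <- stats::approx(knots, shapes[[id]], xout = days, rule = 2)$y
    prof[days == baseline_day] <- 0
    archetype(id, tissues[[id]], setNames(prof, days))
  })
  setNames(out, names(shapes))
}

#' @export
print.archetype <- function(x, ...) {
  cat("archetype ", x$id, " (", x$tissue, "): ",
      paste(sprintf("%g", x$profile), collapse = " "), "\n", sep = "")
  invisible(x)
}
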