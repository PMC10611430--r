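# Competition-derived statistics: relative fitness as the ratio of
# Malthusian growth parameters, and the assortment index of genotypic
# enrichment after settling selection.

#' Bundle competition counts
#'
#' Counts of the two competing strains at the start and end of an assay
#' interval. Snowflake competitions typically count whole clusters and floc
#' competitions deflocculated cells; any consistent unit is accepted and
#' recorded.
#'
#' @param evolved_initial,evolved_final,ancestor_initial,ancestor_final
#'   strictly positive counts, measured at the same two time points for
#'   both strains.
#' @param unit optional label for the counting unit (e.g. \code{"cells"},
#'   \code{"clusters"}).
#' @return A \code{"competition_counts"} object.
#' @export
competition_counts <- function(evolved_initial, evolved_final,
                               ancestor_initial, ancestor_final,
                               unit = "cells") {
  for (nm in c("evolved_initial", "evolved_final", "ancestor_initial",
               "ancestor_final"))
    check_number(get(nm), nm, lower = 0, allow_boundary = FALSE)
  structure(list(evolved_initial = evolved_initial,
                 evolved_final = evolved_final,
                 ancestor_initial = ancestor_initial,
                 ancestor_final = ancestor_final,
                 unit = unit),
            class = "competition_counts")
}

#' @export
print.competition_counts <- function(x, ...) {
  cat(sprintf("Competition counts (%s): evolved %g -> %g, ancestor %g -> %g\n",
              x$unit, x$evolved_initial, x$evolved_final,
              x$ancestor_initial, x$ancestor_final))
  invisible(x)
}

#' Relative fitness from Malthusian growth parameters
#'
#' The ratio of the two strains' Malthusian parameters over the same
#' interval:
#' \deqn{w = \frac{\ln(\mathrm{evolved\_final} / \mathrm{evolved\_initial})}
#'            {\ln(\mathrm{ancestor\_final} / \mathrm{ancestor\_initial})}.}
#' \code{w = 1} means the strains grew identically; \code{w = 2} means the
#' evolved strain's log growth factor was twice the ancestor's. An optional
#' \code{normalizer} (e.g. the fitness measured in an ancestor-vs-ancestor
#' control competition) divides the result.
#'
#' @param counts a [competition_counts()] (or
#'   [gen_competition_counts()] result).
#' @param normalizer optional positive fitness to normalize by.
#' @return Relative fitness \code{w} (dimensionless).
#' @examples
#' malthusian_fitness(competition_counts(100, 400, 100, 200))  # 2
#' @export
malthusian_fitness <- function(counts, normalizer = NULL) {
  stopifnot(inherits(counts, "competition_counts"))
  denom <- log(counts$ancestor_final / counts$ancestor_initial)
  if (denom == 0)
    stop("ancestor did not grow: Malthusian fitness is undefined ",
         "(zero denominator)", call. = FALSE)
  w <- log(counts$evolved_final / counts$evolved_initial) / denom
  if (!is.null(normalizer)) {
    check_number(normalizer, "normalizer", lower = 0, allow_boundary = FALSE)
    w <- w / normalizer
  }
  w
}

#' Assortment of a focal strain after settling selection
#'
#' A frequency-controlled index of genotypic enrichment among survivors of
#' settling selection:
#' \deqn{A = \frac{f_{set} - f_{pop}}{1 - f_{pop}},}
#' where \eqn{f_{set}} and \eqn{f_{pop}} are the focal strain's frequency
#' after settling selection and in the general population. \code{A = 1}
#' when the settled fraction is pure focal strain, \code{A = 0} when
#' settling does not change the frequency, and negative values (down to
#' \eqn{-f_{pop} / (1 - f_{pop})}) indicate depletion. Clonal clusters
#' competing against a distinct genotype canonically reach \code{A = 1};
#' well-mixed aggregates sit near 0.
#'
#' @param f_set focal-strain frequency after settling selection, in
#'   \eqn{[0, 1]}.
#' @param f_pop focal-strain frequency in the general population, in
#'   \eqn{[0, 1)}.
#' @return Assortment (dimensionless).
#' @examples
#' assortment(f_set = 0.5, f_pop = 0.25)  # 1/3
#' @export
assortment <- function(f_set, f_pop) {
  check_number(f_set, "f_set", lower = 0, upper = 1)
  check_number(f_pop, "f_pop", lower = 0, upper = 1,
               allow_boundary = TRUE)
  if (f_pop >= 1)
    stop("`f_pop` must be < 1 (assortment is undefined when the focal ",
         "strain is already the whole population)", call. = FALSE)
  (f_set - f_pop) / (1 - f_pop)
}
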