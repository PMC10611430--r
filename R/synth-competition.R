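# Synthetic two-strain competition assays with a programmed true relative
# fitness, for round-trip validation of the Malthusian fitness estimator.

#' Generate competition count tables with known true fitness
#'
#' Simulates a head-to-head competition between an evolved strain and its
#' ancestor over one assay interval. The ancestor grows by
#' \code{generations_ancestor} doublings; the evolved strain's Malthusian
#' parameter is \code{true_fitness} times the ancestor's, i.e.
#' \deqn{\mathrm{evolved\_final} = \mathrm{evolved\_initial} \cdot
#'   e^{w \cdot g \ln 2}, \quad
#'   \mathrm{ancestor\_final} = \mathrm{ancestor\_initial} \cdot 2^{g}.}
#' With \code{count_noise = "none"} the estimator recovers \code{w}
#' exactly; with \code{"poisson"} the two final counts are Poisson draws
#' around their expectations (counting noise), and recovery is unbiased
#' only on average.
#'
#' @param initial_count_evolved,initial_count_ancestor starting counts
#'   (> 0; cells or whole clusters, any consistent unit).
#' @param true_fitness programmed relative fitness \code{w} (> 0).
#' @param generations_ancestor ancestor doublings over the assay (> 0).
#' @param count_noise \code{"none"} or \code{"poisson"}.
#' @param seed optional integer seed.
#' @return A \code{"competition_counts"} object (see
#'   [competition_counts()]) with attribute \code{true_fitness}.
#' @seealso [malthusian_fitness()]
#' @examples
#' cc <- gen_competition_counts(true_fitness = 2, generations_ancestor = 1)
#' malthusian_fitness(cc)  # 2
#' @export
gen_competition_counts <- function(initial_count_evolved = 100,
                                   initial_count_ancestor = 100,
                                   true_fitness = 1,
                                   generations_ancestor = 5,
                                   count_noise = c("none", "poisson"),
                                   seed = NULL) {
  count_noise <- match.arg(count_noise)
  check_number(initial_count_evolved, "initial_count_evolved", lower = 0,
               allow_boundary = FALSE)
  check_number(initial_count_ancestor, "initial_count_ancestor", lower = 0,
               allow_boundary = FALSE)
  check_number(true_fitness, "true_fitness", lower = 0,
               allow_boundary = FALSE)
  check_number(generations_ancestor, "generations_ancestor", lower = 0,
               allow_boundary = FALSE)
  g <- generations_ancestor
  anc_final <- initial_count_ancestor * 2^g
  evo_final <- initial_count_evolved * exp(true_fitness * g * log(2))
  if (count_noise == "poisson") {
    final <- with_seed(seed, rpois(2, c(evo_final, anc_final)))
    evo_final <- max(1, final[1])
    anc_final <- max(1, final[2])
  }
  out <- competition_counts(evolved_initial = initial_count_evolved,
                            evolved_final = evo_final,
                            ancestor_initial = initial_count_ancestor,
                            ancestor_final = anc_final)
  attr(out, "true_fitness") <- true_fitness
  out
}
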