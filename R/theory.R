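# Analytic extinction theory for a rare mutant lineage passing through one
# round of group selection.
#
# Setting: a population of N equal-weight groups, of which k contain at
# least one mutant cell. Settling selection keeps a fraction f of the
# groups, drawn without replacement. The mutant lineage goes extinct iff
# none of the k marked groups is drawn — the zero-success probability of a
# hypergeometric draw.

#' Exact extinction probability of a mutant lineage in one selection round
#'
#' Probability that a without-replacement draw of \code{round(f * N)} groups
#' from \code{N} total contains none of the \code{k} groups carrying mutant
#' cells, i.e. the hypergeometric zero-success probability
#' \deqn{p_e = \prod_{i=0}^{fN-1} \frac{N - k - i}{N - i}.}
#'
#' The product is evaluated in log space so it does not underflow for large
#' populations. The number of draws is \code{f * N} rounded to the nearest
#' integer, with a minimum of one draw (selection always keeps something).
#'
#' @param N total number of groups (positive integer).
#' @param k number of groups containing at least one mutant cell
#'   (integer, \code{0 <= k <= N}).
#' @param f fraction of groups surviving selection, in (0, 1).
#' @return Extinction probability in \eqn{[0, 1]}.
#' @seealso [extinction_prob_approx()] for the large-\code{N} exponential
#'   approximation, [mutant_group_count()] for life-cycle-dependent \code{k}.
#' @examples
#' extinction_prob_exact(N = 4, k = 1, f = 0.5)   # 0.5
#' extinction_prob_exact(N = 1e4, k = 100, f = 0.01)
#' @export
extinction_prob_exact <- function(N, k, f) {
  check_count(N, "N", minimum = 1)
  check_count(k, "k", minimum = 0)
  check_number(f, "f", lower = 0, upper = 1, allow_boundary = FALSE)
  if (k > N)
    stop("`k` cannot exceed the total number of groups `N`", call. = FALSE)
  draws <- max(1, round(f * N))
  if (draws > N)
    stop("number of selected groups exceeds `N`", call. = FALSE)
  if (k == 0) return(1)
  if (draws > N - k) return(0)  # pigeonhole: some mutant group must be drawn
  i <- seq_len(draws) - 1
  exp(sum(log(N - k - i) - log(N - i)))
}

#' Approximate extinction probability for large populations
#'
#' Large-\code{N} limit of [extinction_prob_exact()]:
#' \deqn{p_e \approx e^{-k f / (1 - f)},}
#' showing that the chance a mutant lineage is lost at the group-selection
#' bottleneck decays exponentially in the number of mutant-bearing groups
#' \code{k}. This is the quantity that separates life cycles: clonal
#' development concentrates a mutant lineage into few groups (small
#' \code{k}), aggregation spreads it over many (large \code{k}).
#'
#' @param k number of groups containing at least one mutant cell
#'   (non-negative integer).
#' @param f fraction of groups surviving selection, in (0, 1).
#' @return Approximate extinction probability in \eqn{(0, 1]}.
#' @examples
#' extinction_prob_approx(k = 2, f = 0.01)    # ~0.98  (clonal, 100 cells / 50)
#' extinction_prob_approx(k = 100, f = 0.01)  # ~0.364 (aggregative)
#' @export
extinction_prob_approx <- function(k, f) {
  check_count(k, "k", minimum = 0)
  check_number(f, "f", lower = 0, upper = 1, allow_boundary = FALSE)
  exp(-k * f / (1 - f))
}

#' Number of mutant-bearing groups under each developmental mode
#'
#' Converts a mutant cell count into the number of groups that carry at
#' least one mutant cell, under the rare-mutant idealization of each life
#' cycle: aggregative development scatters cells independently, so each of
#' the \code{m} mutant cells sits in its own group (\code{k = m}); clonal
#' development keeps the lineage together, packing mutants into as few
#' groups as possible (\code{k = ceiling(m / mean_group_size)}; a partially
#' filled group still counts).
#'
#' @param m number of mutant cells (non-negative integer).
#' @param mean_group_size mean cells per group (>= 1).
#' @param mode \code{"clonal"} or \code{"aggregative"}.
#' @return Number of mutant-bearing groups \code{k} (integer).
#' @examples
#' mutant_group_count(100, 50, "clonal")       # 2
#' mutant_group_count(100, 50, "aggregative")  # 100
#' @export
mutant_group_count <- function(m, mean_group_size,
                               mode = c("clonal", "aggregative")) {
  mode <- match.arg(mode)
  check_count(m, "m", minimum = 0)
  check_number(mean_group_size, "mean_group_size", lower = 1)
  if (m == 0) return(0)
  if (mode == "aggregative") m else ceiling(m / mean_group_size)
}
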