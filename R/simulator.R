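# Stochastic simulation of a mutant lineage through repeated rounds of
# exponential batch growth, life-cycle-specific allocation of mutant cells
# into multicellular groups, and size-weighted settling selection.
#
# One round:
#   grow      -- both lineages grow exponentially until the population has
#                increased growth_fold-fold; mutants grow at rate
#                lambda * (1 + s_c)
#   allocate  -- clonal: mutants packed into randomly chosen groups, at
#                most one mixed group; aggregative: mutant cells scattered
#                uniformly over cells, so larger groups carry more mutants
#   select    -- groups drawn without replacement with probability
#                proportional to n + (1 + s_g) * m until a fraction
#                survival_fraction of cells is kept; the overshoot is
#                removed by proportional down-scaling of every selected
#                group

#' Simulation parameters for a mutant-lineage life cycle
#'
#' @param mode developmental mode, \code{"clonal"} or \code{"aggregative"}.
#' @param growth_rate exponential growth rate \eqn{\lambda} of ancestral
#'   cells (per unit time, > 0). Only the product \eqn{\lambda t} matters
#'   for the growth outcome, so the default 1 fixes the time unit.
#' @param s_c cell-level selection coefficient: mutants grow at rate
#'   \eqn{\lambda (1 + s_c)} (> -1).
#' @param s_g group-survival coefficient: each mutant cell adds
#'   \eqn{(1 + s_g)} instead of 1 to its group's selection weight (>= 0).
#' @param growth_fold factor by which the population grows per round
#'   (default 100).
#' @param survival_fraction fraction of cells kept at settling selection
#'   (default 1/100).
#' @param rounds number of growth + selection rounds (default 5).
#' @param initial_mutants mutant cells present at the very start of the
#'   first growth phase (default 1: a newly arisen mutant).
#' @param n_groups number of groups the population forms at carrying
#'   capacity (default 1000); sets the population scale
#'   (roughly \code{n_groups * mean group size} cells after growth).
#' @param seed optional integer master seed.
#' @return A \code{"sim_params"} object.
#' @seealso [run_lineage()], [run_ensemble()]
#' @export
sim_params <- function(mode = c("clonal", "aggregative"), growth_rate = 1,
                       s_c = 0, s_g = 0, growth_fold = 100,
                       survival_fraction = 1 / 100, rounds = 5,
                       initial_mutants = 1, n_groups = 1000, seed = NULL) {
  mode <- match.arg(mode)
  check_number(growth_rate, "growth_rate", lower = 0, allow_boundary = FALSE)
  check_number(s_c, "s_c", lower = -1, allow_boundary = FALSE)
  check_number(s_g, "s_g", lower = 0)
  check_number(growth_fold, "growth_fold", lower = 1, allow_boundary = FALSE)
  check_number(survival_fraction, "survival_fraction", lower = 0, upper = 1,
               allow_boundary = FALSE)
  check_count(rounds, "rounds", minimum = 1)
  check_count(initial_mutants, "initial_mutants", minimum = 0)
  check_count(n_groups, "n_groups", minimum = 1)
  structure(list(mode = mode, growth_rate = growth_rate, s_c = s_c,
                 s_g = s_g, growth_fold = growth_fold,
                 survival_fraction = survival_fraction,
                 rounds = as.integer(rounds),
                 initial_mutants = initial_mutants,
                 n_groups = as.integer(n_groups), seed = seed),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0("Life-cycle simulation: %s development, s_c=%.3g, ",
                     "s_g=%.3g,\n  %gx growth, %.3g survival, %d round(s), ",
                     "%d group(s) at capacity\n"),
              x$mode, x$s_c, x$s_g, x$growth_fold, x$survival_fraction,
              x$rounds, x$n_groups))
  invisible(x)
}

#' A population of multicellular groups
#'
#' @param n_ancestral,n_mutant non-negative integer vectors of per-group
#'   ancestral and mutant cell counts; every group must hold at least one
#'   cell.
#' @return A \code{"group_population"} object with elements \code{n}
#'   (ancestral) and \code{m} (mutant).
#' @export
group_population <- function(n_ancestral, n_mutant = numeric(length(n_ancestral))) {
  if (length(n_ancestral) != length(n_mutant))
    stop("ancestral and mutant vectors must have equal length", call. = FALSE)
  if (length(n_ancestral) == 0)
    stop("a group population must contain at least one group", call. = FALSE)
  if (any(n_ancestral < 0) || any(n_mutant < 0) ||
      any(n_ancestral + n_mutant < 1))
    stop("each group needs non-negative counts and at least one cell",
         call. = FALSE)
  structure(list(n = as.numeric(n_ancestral), m = as.numeric(n_mutant)),
            class = "group_population")
}

#' @export
print.group_population <- function(x, ...) {
  cat(sprintf("Group population: %d group(s), %g cell(s), %g mutant (freq %.4g)\n",
              length(x$n), sum(x$n) + sum(x$m), sum(x$m),
              sum(x$m) / (sum(x$n) + sum(x$m))))
  invisible(x)
}

#' Grow a mixed population to carrying capacity
#'
#' Both lineages grow exponentially from a total of \code{I} cells
#' (\code{m} of them mutant) until the total has increased by
#' \code{params$growth_fold}; the stopping time \eqn{t^*} solves
#' \deqn{(I - m) e^{\lambda t^*} + m e^{\lambda (1 + s_c) t^*}
#'   = \mathrm{growth\_fold} \cdot I,}
#' found by bracketed root solving (closed form when \code{s_c = 0}). The
#' mutant count at that time is \eqn{m e^{\lambda (1 + s_c) t^*}}.
#'
#' @param I total cells at the start of growth (> 0).
#' @param m mutant cells at the start of growth (\code{0 <= m <= I}).
#' @param params a [sim_params()].
#' @param rounding \code{"stochastic"} (floor plus Bernoulli on the
#'   fractional part; integral and unbiased, uses the current RNG) or
#'   \code{"none"} (return the continuous solution).
#' @return A list with \code{total} and \code{mutants} after growth.
#' @examples
#' p <- sim_params("clonal", s_c = 0)
#' grow_population(1, 1, p)  # 100-fold growth of a pure mutant cell
#' @export
grow_population <- function(I, m, params,
                            rounding = c("stochastic", "none")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(params, "sim_params"))
  check_number(I, "I", lower = 0, allow_boundary = FALSE)
  check_number(m, "m", lower = 0)
  if (m > I) stop("`m` cannot exceed the total population `I`", call. = FALSE)
  lam <- params$growth_rate
  s_c <- params$s_c
  G <- params$growth_fold
  total <- G * I
  if (m == 0) {
    mutants <- 0
  } else if (s_c == 0 || m == I) {
    # one effective growth rate: every lineage scales by G
    mutants <- m * G
  } else {
    t_anc <- log(G) / lam                 # all-ancestral stopping time
    t_mut <- log(G) / (lam * (1 + s_c))   # all-mutant stopping time
    interval <- sort(c(t_anc, t_mut))
    fn <- function(t) (I - m) * exp(lam * t) + m * exp(lam * (1 + s_c) * t) -
      total
    sol <- tryCatch(
      uniroot(fn, interval = interval, extendInt = "upX",
              tol = .Machine$double.eps^0.5 * max(1, interval[2])),
      error = function(e)
        stop("growth-time solver failed to converge: ", conditionMessage(e),
             sprintf(" (I=%g, m=%g, lambda=%g, s_c=%g, fold=%g)",
                     I, m, lam, s_c, G), call. = FALSE))
    mutants <- m * exp(lam * (1 + s_c) * sol$root)
  }
  mutants <- min(mutants, total)
  if (rounding == "stochastic") {
    total <- round(total)
    mutants <- min(round_stochastic(mutants), total)
  }
  list(total = total, mutants = mutants)
}

#' Allocate mutant cells into groups under clonal development
#'
#' Clonal groups are genetically uniform: groups are picked uniformly at
#' random and filled entirely with mutant cells until the mutants run out,
#' so at most one group ends up mixed (the partially filled last one).
#' Biologically the filled groups are propagules of the original mutant
#' cluster.
#'
#' @param sizes integer vector of group sizes (cells).
#' @param m mutant cells to allocate (\code{0 <= m <= sum(sizes)}).
#' @return A [group_population()]. Uses the current RNG stream.
#' @export
allocate_clonal <- function(sizes, m) {
  check_allocation(sizes, m)
  N <- length(sizes)
  mut <- numeric(N)
  if (m > 0) {
    perm <- sample.int(N)
    cs <- cumsum(sizes[perm])
    full <- findInterval(m, cs)          # groups filled completely
    if (full > 0) mut[perm[seq_len(full)]] <- sizes[perm[seq_len(full)]]
    rest <- m - if (full > 0) cs[full] else 0
    if (rest > 0) mut[perm[full + 1]] <- rest
  }
  group_population(sizes - mut, mut)
}

#' Allocate mutant cells into groups under aggregative development
#'
#' Aggregation mixes cells at random: the \code{m} mutant cells are a
#' uniform random subset of all cells, so the expected number of mutants
#' in a group is proportional to its size (groups "select cells weighted
#' by size", with capacity respected exactly).
#'
#' @inheritParams allocate_clonal
#' @return A [group_population()]. Uses the current RNG stream.
#' @export
allocate_aggregative <- function(sizes, m) {
  check_allocation(sizes, m)
  N <- length(sizes)
  total <- sum(sizes)
  mut <- numeric(N)
  if (m > 0) {
    cells <- sample.int(total, m)        # which cells are mutant
    grp <- findInterval(cells - 1, cumsum(sizes)) + 1
    mut <- tabulate(grp, nbins = N)
  }
  group_population(sizes - mut, mut)
}

check_allocation <- function(sizes, m) {
  if (length(sizes) == 0 || any(sizes < 1) || any(sizes != round(sizes)))
    stop("`sizes` must be a non-empty vector of integer group sizes >= 1",
         call. = FALSE)
  check_count(m, "m", minimum = 0)
  if (m > sum(sizes))
    stop("more mutant cells than cells in the population", call. = FALSE)
  invisible(TRUE)
}

#' Settling selection on a group population
#'
#' Groups are drawn without replacement with probability proportional to
#' their selection weight \eqn{n + (1 + s_g) m} (size, plus an extra
#' \eqn{s_g} per mutant cell) until the drawn groups hold at least
#' \code{survival_fraction} of all cells. The overshoot beyond the target
#' cell count is removed by scaling every selected group's ancestral and
#' mutant counts by a common factor (stochastic rounding keeps counts
#' integral and the mutant:ancestral ratio unbiased); groups scaled to
#' zero cells are dropped.
#'
#' Sequential weighted sampling without replacement is realized with
#' exponential sort keys (\code{rexp(N) / w}), which draws the same
#' distribution as successive renormalized-weight draws.
#'
#' @param pop a [group_population()].
#' @param s_g group-survival coefficient (>= 0).
#' @param survival_fraction fraction of cells to keep, in (0, 1).
#' @return The surviving [group_population()]. Uses the current RNG
#'   stream.
#' @export
settle_select <- function(pop, s_g, survival_fraction) {
  stopifnot(inherits(pop, "group_population"))
  check_number(s_g, "s_g", lower = 0)
  check_number(survival_fraction, "survival_fraction", lower = 0, upper = 1,
               allow_boundary = FALSE)
  sizes <- pop$n + pop$m
  total <- sum(sizes)
  target <- max(1, round(survival_fraction * total))
  w <- pop$n + (1 + s_g) * pop$m
  ord <- order(rexp(length(w)) / w)      # successive weighted WOR sampling
  cum <- cumsum(sizes[ord])
  npick <- sum(cum < target) + 1
  sel <- ord[seq_len(npick)]
  scale <- min(1, target / cum[npick])
  n_new <- round_stochastic(pop$n[sel] * scale)
  m_new <- round_stochastic(pop$m[sel] * scale)
  keep <- n_new + m_new >= 1
  if (!any(keep)) {
    # all rounded away (only possible at tiny targets): keep one cell of
    # the first-drawn group's majority lineage
    if (pop$m[sel][1] >= pop$n[sel][1]) m_new[1] <- 1 else n_new[1] <- 1
    keep[1] <- TRUE
  }
  group_population(n_new[keep], m_new[keep])
}
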