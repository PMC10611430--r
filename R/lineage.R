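# Multi-round mutant-lineage fate: iterate growth, group formation and
# settling selection, tracking mutant frequency until extinction, fixation
# or the round limit.

#' Simulate the fate of one mutant lineage
#'
#' Runs \code{params$rounds} rounds of growth, mode-specific allocation
#' and settling selection. The group structure is re-drawn from
#' \code{sizes_source} at the start of every round (only the surviving
#' mutant and total cell counts carry over), reflecting that groups
#' re-form from the transferred cells each day. Group sizes are drawn
#' until they tile the grown population exactly (the last group is trimmed
#' to fit).
#'
#' The lineage starts as \code{params$initial_mutants} cells in a
#' pre-growth population of \code{n_groups * mean size / growth_fold}
#' cells, i.e. the mutant arises at the very start of a growth phase —
#' the most favourable moment for it to escape the bottleneck.
#'
#' @param params a [sim_params()].
#' @param sizes_source a [size_spec()] describing the group-size
#'   distribution.
#' @param seed optional integer seed (overrides \code{params$seed}).
#' @return A \code{"sim_result"}: list with \code{extinct}, \code{fixed},
#'   \code{mutant_frequency_by_round} (frequency after each completed
#'   selection), \code{rounds_completed} and \code{replicate_seed}.
#' @examples
#' p <- sim_params("clonal", s_c = 0.5, rounds = 5, n_groups = 200, seed = 1)
#' run_lineage(p, size_spec("lognormal", mean_size = 50))
#' @export
run_lineage <- function(params, sizes_source, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"), inherits(sizes_source, "size_spec"))
  with_seed(seed, run_lineage_impl(params, sizes_source, seed))
}

run_lineage_impl <- function(params, sizes_source, seed) {
  mean_size <- sizes_source$mean_size
  I <- max(1, round(params$n_groups * mean_size / params$growth_fold))
  m <- min(params$initial_mutants, I)
  freq <- numeric(0)
  extinct <- m == 0
  fixed <- FALSE
  r <- 0
  while (!extinct && !fixed && r < params$rounds) {
    r <- r + 1
    gp <- grow_population(I, m, params)
    total <- gp$total
    m <- min(gp$mutants, total)
    sizes <- draw_sizes_to_total(sizes_source, total)
    pop <- if (params$mode == "clonal") allocate_clonal(sizes, m) else
      allocate_aggregative(sizes, m)
    pop <- settle_select(pop, params$s_g, params$survival_fraction)
    m <- sum(pop$m)
    I <- m + sum(pop$n)
    freq <- c(freq, m / I)
    extinct <- m == 0
    fixed <- m == I
  }
  if (params$initial_mutants == 0 && r == 0) {
    # no mutant ever existed: record one round of zero frequency
    freq <- 0
    r <- 1
  }
  structure(list(extinct = extinct, fixed = fixed,
                 mutant_frequency_by_round = freq,
                 rounds_completed = r, replicate_seed = seed),
            class = "sim_result")
}

# draw group sizes until they cover `total` cells; trim the last group
draw_sizes_to_total <- function(spec, total) {
  est <- ceiling(1.2 * total / spec$mean_size) + 10
  sizes <- draw_sizes(spec, est)
  while (sum(sizes) < total)
    sizes <- c(sizes, draw_sizes(spec, est))
  cs <- cumsum(sizes)
  k <- sum(cs < total) + 1
  sizes <- sizes[seq_len(k)]
  excess <- cs[k] - total
  sizes[k] <- sizes[k] - excess
  if (sizes[k] < 1) sizes <- sizes[seq_len(k - 1)]
  sizes
}

#' @export
print.sim_result <- function(x, ...) {
  outcome <- if (x$fixed) "FIXED" else if (x$extinct) "EXTINCT" else
    "segregating"
  cat(sprintf("Lineage %s after %d round(s); frequency trajectory: %s\n",
              outcome, x$rounds_completed,
              paste(signif(x$mutant_frequency_by_round, 3), collapse = " ")))
  invisible(x)
}

#' Ensemble of independent mutant-lineage simulations
#'
#' Runs [run_lineage()] over \code{n_replicates} independently seeded
#' replicates and aggregates outcome fractions and trajectories.
#' Trajectories of replicates that ended early are padded with their
#' absorbing value (0 after extinction, 1 after fixation).
#'
#' @inheritParams run_lineage
#' @param n_replicates number of replicate lineages (>= 1).
#' @param seed master seed for the ensemble (overrides
#'   \code{params$seed}); replicate seeds are derived from it.
#' @return A \code{"lineage_ensemble"}: list with
#'   \code{extinction_fraction}, \code{fixation_fraction},
#'   \code{mean_trajectory}, \code{trajectories} (replicates x rounds
#'   matrix) and \code{results} (the individual \code{"sim_result"}s).
#' @examples
#' p <- sim_params("aggregative", s_c = 1, rounds = 3, n_groups = 100)
#' run_ensemble(p, size_spec("lognormal"), n_replicates = 20, seed = 7)
#' @export
run_ensemble <- function(params, sizes_source, n_replicates,
                         seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  check_count(n_replicates, "n_replicates", minimum = 1)
  rep_seeds <- with_seed(seed,
    sample.int(.Machine$integer.max, n_replicates, replace = TRUE))
  results <- lapply(rep_seeds, function(s)
    run_lineage(params, sizes_source, seed = s))
  traj <- vapply(results, function(r) {
    f <- r$mutant_frequency_by_round
    pad <- if (r$fixed) 1 else if (r$extinct) 0 else f[length(f)]
    c(f, rep(pad, params$rounds - length(f)))
  }, numeric(params$rounds))
  # vapply returns a plain vector when rounds == 1; always make the
  # trajectory matrix replicates x rounds
  traj <- if (is.matrix(traj)) t(traj) else matrix(traj, ncol = 1)
  structure(list(
    extinction_fraction = mean(vapply(results, `[[`, logical(1), "extinct")),
    fixation_fraction = mean(vapply(results, `[[`, logical(1), "fixed")),
    mean_trajectory = colMeans(traj),
    trajectories = traj,
    results = results,
    params = params, n_replicates = n_replicates, seed = seed),
    class = "lineage_ensemble")
}

#' @export
print.lineage_ensemble <- function(x, ...) {
  cat(sprintf(paste0("Lineage ensemble (%s, s_c=%.3g, s_g=%.3g, %d ",
                     "replicates):\n  extinct %.1f%%, fixed %.1f%%, mean ",
                     "final frequency %.4g\n"),
              x$params$mode, x$params$s_c, x$params$s_g, x$n_replicates,
              100 * x$extinction_fraction, 100 * x$fixation_fraction,
              x$mean_trajectory[length(x$mean_trajectory)]))
  invisible(x)
}
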