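# Stochastic life-cycle simulator: growth, allocation, selection, fate

test_that("growth reaches carrying capacity with the right mutant count", {
  p0 <- sim_params("clonal", s_c = 0)
  expect_equal(grow_population(1, 1, p0, rounding = "none"),
               list(total = 100, mutants = 100))
  expect_equal(grow_population(40, 0, p0, rounding = "none"),
               list(total = 4000, mutants = 0))

  # two-exponential stopping time against an independent bisection oracle
  for (s_c in c(-0.5, 0.3, 1)) {
    p <- sim_params("clonal", s_c = s_c, growth_rate = 1)
    got <- grow_population(1000, 1, p, rounding = "none")$mutants
    want <- bisect_growth_mutants(1000, 1, lambda = 1, s_c = s_c, fold = 100)
    expect_equal(got, want, tolerance = 1e-6)
  }

  # stochastic rounding is integral and unbiased
  p <- sim_params("clonal", s_c = 1)
  m_cont <- grow_population(1000, 1, p, rounding = "none")$mutants
  set.seed(1)
  m_int <- replicate(4000, grow_population(1000, 1, p)$mutants)
  expect_true(all(m_int == floor(m_int)))
  expect_lt(abs(mean(m_int) - m_cont), 3 * stats::sd(m_int) / sqrt(4000) + 1e-9)

  expect_error(grow_population(10, 11, p0), "exceed")
})

test_that("clonal allocation fills whole groups with at most one mixed group", {
  set.seed(2)
  pop <- allocate_clonal(rep(50, 40), 100)
  expect_equal(sum(pop$m), 100)
  expect_equal(sum(pop$m == 50), 2)       # exactly two groups fully mutant
  expect_equal(sum(pop$m > 0 & pop$n > 0), 0)

  pop0 <- allocate_clonal(rep(50, 10), 0)
  expect_true(all(pop0$m == 0))

  # m = 75 over groups of 50: one full group plus one 25/25 mixed group
  pop75 <- allocate_clonal(rep(50, 10), 75)
  expect_equal(sort(pop75$m[pop75$m > 0]), c(25, 50))

  # at most one mixed group, exact conservation, for any m and
  # heterogeneous sizes
  sizes <- c(3, 7, 20, 50, 120)
  violations <- 0
  for (i in seq_len(2000)) {
    m <- sample.int(sum(sizes), 1)
    pop <- allocate_clonal(sizes, m)
    ok <- sum(pop$n) + sum(pop$m) == sum(sizes) &&
      sum(pop$m) == m && sum(pop$m > 0 & pop$n > 0) <= 1
    violations <- violations + !ok
  }
  expect_equal(violations, 0)

  expect_error(allocate_clonal(rep(10, 3), 31), "more mutant")
})

test_that("aggregative allocation scatters mutants in proportion to group size", {
  set.seed(3)
  sat <- allocate_aggregative(c(5, 9, 30), 44)
  expect_true(all(sat$n == 0))

  none <- allocate_aggregative(c(5, 9, 30), 0)
  expect_true(all(none$m == 0))

  # expected mutants per group proportional to size (hypergeometric mean)
  draws <- replicate(4000, allocate_aggregative(c(100, 50), 30)$m)
  m_big <- mean(draws[1, ])
  m_small <- mean(draws[2, ])
  # exact means are 20 and 10; allow 3 SE of the Monte-Carlo average
  se_big <- stats::sd(draws[1, ]) / sqrt(4000)
  expect_lt(abs(m_big - 20), 3 * se_big)
  expect_lt(abs(m_big - 2 * m_small), 6 * se_big)
  expect_true(all(colSums(draws) == 30))
})

test_that("settling selection keeps the target biomass and respects weights", {
  # a 1/8 cell target over eight identical groups keeps exactly one group
  set.seed(4)
  n_kept <- replicate(500, {
    surv <- settle_select(group_population(rep(25, 8)), s_g = 0,
                          survival_fraction = 0.125)
    length(surv$n)
  })
  expect_true(all(n_kept == 1))

  # weighted draw: group weights 90 vs 10, one group taken; the big group
  # is tagged with mutant cells (same weight at s_g = 0) to identify it
  set.seed(5)
  first <- replicate(4000, {
    pop <- group_population(c(0, 10), c(90, 0))
    surv <- settle_select(pop, s_g = 0, survival_fraction = 0.05)
    sum(surv$m) > 0
  })
  p_hat <- mean(first)
  expect_lt(abs(p_hat - 0.9), 3 * sqrt(0.9 * 0.1 / 4000))

  # single group must survive
  one <- settle_select(group_population(100, 0), 0, 0.5)
  expect_equal(length(one$n), 1)

  # selection never increases the population, and hits the cell target
  set.seed(6)
  for (i in 1:50) {
    sizes <- sample(10:100, 20, replace = TRUE)
    muts <- pmin(sizes, sample(0:30, 20, replace = TRUE))
    pop <- group_population(sizes - muts, muts)
    surv <- settle_select(pop, s_g = 2, survival_fraction = 0.1)
    total <- sum(sizes)
    kept <- sum(surv$n) + sum(surv$m)
    expect_lte(kept, total)
    # stochastic rounding moves each group's two counts by < 1 cell each
    expect_lte(abs(kept - round(0.1 * total)), 2 * length(surv$n))
  }

  expect_error(settle_select(group_population(10), 0, 1), "outside")
})

test_that("uniform-weight selection shows no group preference (chi-square)", {
  # tag one of six equal-weight groups with a single mutant cell and track
  # how often it survives a one-group bottleneck: should be 1/6
  set.seed(7)
  tagged <- replicate(6000, {
    pop <- group_population(c(rep(30, 5), 29), c(rep(0, 5), 1))
    sum(settle_select(pop, 0, 1 / 6)$m) > 0
  })
  expect_gt(stats::chisq.test(c(sum(tagged), 6000 - sum(tagged)),
                              p = c(1 / 6, 5 / 6))$p.value, 0.01)
})

test_that("lineage fate trajectories terminate and book-keep correctly", {
  p0 <- sim_params("clonal", initial_mutants = 0, rounds = 3, n_groups = 50,
                   seed = 1)
  r0 <- run_lineage(p0, size_spec("fixed", 50))
  expect_true(r0$extinct)
  expect_true(all(r0$mutant_frequency_by_round == 0))

  # no selection, no sampling: the survival target covers every cell, so
  # neutral mutant frequency stays exactly constant across rounds
  pc <- sim_params("clonal", s_c = 0, growth_fold = 2,
                   survival_fraction = 0.9999, rounds = 4, n_groups = 1,
                   initial_mutants = 50, seed = 2)
  rc <- run_lineage(pc, size_spec("fixed", 200))
  expect_equal(rc$mutant_frequency_by_round,
               rep(0.5, rc$rounds_completed))

  # absorbing states: extinct => 0, fixed => 1
  set.seed(8)
  for (i in 1:40) {
    p <- sim_params(sample(c("clonal", "aggregative"), 1), s_c = 1,
                    rounds = 3, n_groups = 100, seed = i)
    r <- run_lineage(p, size_spec("lognormal", 50, 0.5))
    f <- r$mutant_frequency_by_round
    expect_lte(length(f), 3)
    if (r$extinct) expect_equal(f[length(f)], 0)
    if (r$fixed) expect_equal(f[length(f)], 1)
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("ensembles aggregate replicates reproducibly", {
  p <- sim_params("aggregative", s_c = 0.5, rounds = 3, n_groups = 100)
  e1 <- run_ensemble(p, size_spec("lognormal", 50, 0.5), 30, seed = 11)
  e2 <- run_ensemble(p, size_spec("lognormal", 50, 0.5), 30, seed = 11)
  expect_identical(e1$trajectories, e2$trajectories)
  expect_equal(e1$extinction_fraction +
                 mean(!vapply(e1$results, `[[`, logical(1), "extinct")), 1)

  single <- run_ensemble(p, size_spec("lognormal", 50, 0.5), 1, seed = 3)
  expect_equal(single$extinction_fraction,
               as.numeric(single$results[[1]]$extinct))
  expect_equal(nrow(single$trajectories), 1)
})

test_that("neutral lineages drift as a martingale over one full round", {
  # clonal with equal group sizes and aggregative with lognormal sizes are
  # both exchangeable under s_c = s_g = 0, so mean frequency is conserved
  for (cfg in list(list(mode = "clonal", spec = size_spec("fixed", 50)),
                   list(mode = "aggregative",
                        spec = size_spec("lognormal", 50, 0.5)))) {
    p <- sim_params(cfg$mode, s_c = 0, s_g = 0, rounds = 1, n_groups = 400,
                    initial_mutants = 4)
    f0 <- 4 / (400 * 50 / 100)
    e <- run_ensemble(p, cfg$spec, 3000, seed = 21)
    final <- e$trajectories[, 1]
    se <- stats::sd(final) / sqrt(length(final))
    expect_lt(abs(mean(final) - f0), 3 * se)
  }
})

test_that("clonal extinction dominates aggregative extinction for beneficial mutants", {
  spec <- size_spec("lognormal", 50, 0.5)
  for (s_c in c(0.5, 1)) {
    ec <- run_ensemble(sim_params("clonal", s_c = s_c, rounds = 5,
                                  n_groups = 300), spec, 150, seed = 31)
    ea <- run_ensemble(sim_params("aggregative", s_c = s_c, rounds = 5,
                                  n_groups = 300), spec, 150, seed = 31)
    expect_gte(ec$extinction_fraction, ea$extinction_fraction)
  }
})

test_that("qualitative orderings are robust to bottleneck size", {
  spec <- size_spec("lognormal", 50, 0.5)
  for (sf in c(1 / 50, 1 / 100, 1 / 200)) {
    ec <- run_ensemble(sim_params("clonal", s_c = 1, rounds = 5,
                                  survival_fraction = sf, n_groups = 300),
                       spec, 120, seed = 41)
    ea <- run_ensemble(sim_params("aggregative", s_c = 1, rounds = 5,
                                  survival_fraction = sf, n_groups = 300),
                       spec, 120, seed = 41)
    expect_gte(ec$extinction_fraction, ea$extinction_fraction)
  }
})
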