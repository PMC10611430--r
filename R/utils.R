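# internal helpers shared across modules

# run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream so seeded generators do not perturb global randomness
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# scalar checks -------------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_boundary = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  ok <- if (allow_boundary) x >= lower && x <= upper else x > lower && x < upper
  if (!ok)
    stop(sprintf("`%s` = %g is outside its valid range %s%g, %g%s",
                 name, x,
                 if (allow_boundary) "[" else "(", lower, upper,
                 if (allow_boundary) "]" else ")"),
         call. = FALSE)
  x
}

check_count <- function(x, name, minimum = 0L) {
  check_number(x, name, lower = minimum)
  if (x != round(x))
    stop(sprintf("`%s` must be an integer count", name), call. = FALSE)
  as.numeric(x)
}

# stochastic rounding: floor plus a Bernoulli draw on the fractional part;
# unbiased, keeps counts integral (uses the current RNG stream)
round_stochastic <- function(x) {
  f <- floor(x)
  frac <- x - f
  f + (runif(length(x)) < frac)
}
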