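# Group-size distributions. Real experiments measure these (e.g. by flow
# cytometry); here they are generated with known ground truth, or supplied
# verbatim as an empirical list.

#' Specify a group-size distribution
#'
#' Describes how per-group sizes (cells per multicellular group) are drawn.
#' Three families are supported: \code{"lognormal"} (the default synthetic
#' family: right-skewed and strictly positive, qualitatively matching
#' observed cluster-size histograms), \code{"fixed"} (every group exactly
#' \code{mean_size} cells — useful for analytic cross-checks), and
#' \code{"empirical"} (sizes resampled with replacement from a user-supplied
#' list, for users with measured distributions).
#'
#' For the lognormal family \code{dispersion} is the log-scale standard
#' deviation \code{sdlog}; \code{meanlog} is chosen so the distribution mean
#' equals \code{mean_size} (\code{meanlog = log(mean_size) - sdlog^2 / 2}).
#' Sampled sizes are rounded to integers and floored at one cell.
#'
#' @param family \code{"lognormal"}, \code{"fixed"} or \code{"empirical"}.
#' @param mean_size mean cells per group (> 0). Ignored for
#'   \code{"empirical"}.
#' @param dispersion log-scale SD for the lognormal family
#'   (dimensionless, >= 0).
#' @param n_groups default number of groups to draw (positive integer).
#' @param sizes integer vector of observed sizes, required for
#'   \code{"empirical"}.
#' @return An object of class \code{"size_spec"}.
#' @seealso [gen_group_sizes()]
#' @export
size_spec <- function(family = c("lognormal", "fixed", "empirical"),
                      mean_size = 50, dispersion = 0.5, n_groups = 1000,
                      sizes = NULL) {
  family <- match.arg(family)
  check_count(n_groups, "n_groups", minimum = 1)
  if (family == "empirical") {
    if (is.null(sizes) || length(sizes) == 0 || any(!is.finite(sizes)) ||
        any(sizes < 1))
      stop("`sizes` must be a non-empty vector of sizes >= 1 for the ",
           "empirical family", call. = FALSE)
    sizes <- as.numeric(round(sizes))
    mean_size <- mean(sizes)
  } else {
    check_number(mean_size, "mean_size", lower = 0, allow_boundary = FALSE)
    check_number(dispersion, "dispersion", lower = 0)
  }
  structure(
    list(family = family, mean_size = mean_size, dispersion = dispersion,
         n_groups = as.integer(n_groups), sizes = sizes),
    class = "size_spec")
}

#' Draw group sizes from a size specification
#'
#' @param spec a [size_spec()].
#' @param n_groups number of groups to draw; defaults to
#'   \code{spec$n_groups}.
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG stream is left untouched.
#' @return Integer vector of group sizes (cells per group), all >= 1.
#' @examples
#' gen_group_sizes(size_spec("fixed", mean_size = 50), n_groups = 5)
#' gen_group_sizes(size_spec("lognormal", mean_size = 50, dispersion = 0.5),
#'                 n_groups = 10, seed = 1)
#' @export
gen_group_sizes <- function(spec, n_groups = spec$n_groups, seed = NULL) {
  stopifnot(inherits(spec, "size_spec"))
  check_count(n_groups, "n_groups", minimum = 1)
  with_seed(seed, draw_sizes(spec, n_groups))
}

# internal unseeded draw, used by the simulator on its own RNG stream
draw_sizes <- function(spec, n) {
  switch(spec$family,
    fixed = rep.int(max(1, round(spec$mean_size)), n),
    lognormal = {
      sdlog <- spec$dispersion
      meanlog <- log(spec$mean_size) - sdlog^2 / 2
      pmax(1, round(rlnorm(n, meanlog = meanlog, sdlog = sdlog)))
    },
    empirical = sample(spec$sizes, n, replace = TRUE))
}

#' @export
print.size_spec <- function(x, ...) {
  cat(sprintf("Group-size spec: family=%s, mean=%.3g, dispersion=%.3g, n_groups=%d\n",
              x$family, x$mean_size, x$dispersion, x$n_groups))
  invisible(x)
}
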