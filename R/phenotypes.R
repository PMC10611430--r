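# Group-level phenotype statistics: settling rate from an image stack,
# flocculation efficiency from a single well-mixed frame, and the
# biomass-weighted mean group size from per-group size values.

#' Settling rate from a video stack
#'
#' Tracks the displacement of biomass down the frame: for each frame the
#' per-column minimum is subtracted (removing any static illumination
#' gradient) and the intensity-weighted vertical centroid of the remaining
#' signal is computed; the settling rate is the least-squares slope of
#' centroid position against time. Positive values mean downward motion.
#' The estimate is invariant to uniform intensity scaling of the frames.
#'
#' @param video a [video_stack()] (e.g. from [gen_settling_video()] or
#'   [read_video()]).
#' @return Settling rate in pixels/second, or length/second when the
#'   stack carries a \code{pixel_scale}.
#' @examples
#' v <- gen_settling_video(height = 120, width = 10, n_frames = 30,
#'                         front_speed = 2, noise_sd = 0)
#' settling_rate(v)  # 2
#' @export
settling_rate <- function(video) {
  stopifnot(inherits(video, "video_stack"))
  frames <- video$frames
  d <- dim(frames)
  rows <- seq_len(d[1])
  centroid <- vapply(seq_len(d[3]), function(t) {
    f <- frames[, , t]
    f <- sweep(f, 2, apply(f, 2, min))   # per-column background
    mass <- rowSums(f)
    tot <- sum(mass)
    if (tot <= 0) return(NA_real_)
    sum(rows * mass) / tot
  }, numeric(1))
  if (all(is.na(centroid)))
    stop("no biomass detected after background subtraction", call. = FALSE)
  time <- (seq_len(d[3]) - 1) * video$frame_interval
  fit <- lm(centroid ~ time)
  rate <- unname(coef(fit)[2])
  if (!is.null(video$pixel_scale)) rate <- rate * video$pixel_scale
  rate
}

#' Flocculation efficiency of a well-mixed frame
#'
#' Quantifies how heterogeneously biomass is distributed in a single
#' well-mixed frame: cells gathered in flocs make optically dense patches
#' against clearer medium, inflating the spread of pixel intensities.
#' The statistic is the coefficient of variation (population SD / mean) of
#' pixel intensity — scale-free, so invariant to uniform illumination
#' changes. The raw pixel variance is available via
#' \code{statistic = "variance"}.
#'
#' @param frame a numeric intensity matrix (one video frame).
#' @param statistic \code{"cv"} (default) or \code{"variance"}.
#' @return Dimensionless CV (or raw variance). Higher means more biomass
#'   bound in flocs.
#' @examples
#' flocculation_efficiency(matrix(c(0, 2, 0, 2), 2))  # 1
#' @export
flocculation_efficiency <- function(frame, statistic = c("cv", "variance")) {
  statistic <- match.arg(statistic)
  if (length(frame) == 0 || any(!is.finite(frame)))
    stop("`frame` must be a non-empty finite intensity matrix",
         call. = FALSE)
  mu <- mean(frame)
  v <- mean((frame - mu)^2)              # population variance
  if (statistic == "variance") return(v)
  if (mu == 0)
    stop("frame has zero mean intensity: coefficient of variation is ",
         "undefined", call. = FALSE)
  sqrt(v) / mu
}

#' Biomass-weighted mean group size
#'
#' Large groups hold more biomass than small ones, so the plain mean of
#' per-group sizes under-represents where the biomass lives. This
#' statistic bins the size distribution (default 100 equal-width bins
#' spanning the sample range), computes the fraction of total biomass in
#' each bin (sum of sizes in the bin over the grand total), and returns
#' the biomass-fraction-weighted mean of the bin centers:
#' \deqn{\bar{s}_w = \sum_b \frac{\sum_{i \in b} s_i}{\sum_i s_i} c_b.}
#' It always dominates the arithmetic mean (equality only when all sizes
#' are equal) and is insensitive to the bin count.
#'
#' @param values positive per-group size values, e.g. forward-scatter
#'   readings used as a cluster-size proxy.
#' @param n_bins number of equal-width bins (>= 1, default 100).
#' @return Biomass-weighted mean size, in the units of \code{values}.
#' @examples
#' biomass_weighted_mean_size(c(1, 3), n_bins = 1000)  # ~2.5
#' @export
biomass_weighted_mean_size <- function(values, n_bins = 100) {
  if (length(values) == 0 || any(!is.finite(values)) || any(values <= 0))
    stop("`values` must be non-empty, finite and positive", call. = FALSE)
  check_count(n_bins, "n_bins", minimum = 1)
  lo <- min(values)
  hi <- max(values)
  if (lo == hi) return(lo)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  bin <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  biomass <- vapply(split(values, factor(bin, levels = seq_len(n_bins))),
                    sum, numeric(1))
  sum(biomass / sum(values) * centers)
}
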