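# Synthetic settling videos: a dense biomass band on a dark background,
# moving down the frame at a programmed speed, standing in for recorded
# cuvette time-lapses. Biomass is encoded as intensity (background 0,
# band 1 before noise), so total intensity is conserved across frames.

#' Generate a synthetic settling video
#'
#' Produces a grayscale image stack in which a horizontal band of intensity
#' 1 (the sedimenting biomass) moves downward by \code{front_speed} pixels
#' per frame over a background of 0, with optional additive Gaussian pixel
#' noise. The intensity-weighted vertical centroid of the band therefore
#' moves at exactly \code{front_speed} px/frame (plus noise), giving a
#' known ground truth for [settling_rate()].
#'
#' Pixel values are clamped to \eqn{[0, 1]} after noise so frames remain
#' valid grayscale images.
#'
#' @param height,width frame dimensions in pixels.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval seconds between frames.
#' @param front_speed downward band speed in pixels/frame (>= 0). The band
#'   must stay inside the frame: \code{band_frac * height +
#'   front_speed * (n_frames - 1) <= height}.
#' @param band_frac band thickness as a fraction of frame height
#'   (default 0.5).
#' @param noise_sd SD of additive Gaussian pixel noise (intensity units).
#' @param pixel_scale optional physical length per pixel, carried as
#'   metadata.
#' @param seed optional integer seed.
#' @return An object of class \code{"video_stack"}: a list with
#'   \code{frames} (a \code{height x width x n_frames} array),
#'   \code{frame_interval} and \code{pixel_scale}.
#' @seealso [settling_rate()], [write_video()]
#' @examples
#' v <- gen_settling_video(height = 60, width = 8, n_frames = 10,
#'                         front_speed = 2, noise_sd = 0, seed = 1)
#' settling_rate(v)  # 2 px/s at the default 1 s frame interval
#' @export
gen_settling_video <- function(height = 200, width = 40, n_frames = 50,
                               frame_interval = 1, front_speed = 1,
                               band_frac = 0.5, noise_sd = 0,
                               pixel_scale = NULL, seed = NULL) {
  check_count(height, "height", minimum = 2)
  check_count(width, "width", minimum = 1)
  check_count(n_frames, "n_frames", minimum = 2)
  check_number(frame_interval, "frame_interval", lower = 0,
               allow_boundary = FALSE)
  check_number(front_speed, "front_speed", lower = 0)
  check_number(band_frac, "band_frac", lower = 0, upper = 1,
               allow_boundary = FALSE)
  check_number(noise_sd, "noise_sd", lower = 0)
  band_px <- max(1, round(band_frac * height))
  travel <- front_speed * (n_frames - 1)
  if (band_px + travel > height)
    stop(sprintf(paste0("band (%d px) would exit the frame: top-of-band ",
                        "travel %.1f px exceeds the %d px available"),
                 band_px, travel, height - band_px),
         call. = FALSE)

  frames <- with_seed(seed, {
    a <- array(0, dim = c(height, width, n_frames))
    rows <- seq_len(height)
    for (t in seq_len(n_frames)) {
      top <- (t - 1) * front_speed
      # fractional band edges: partial intensity at boundary rows conserves
      # total biomass for non-integer front positions
      cover <- pmin(rows, top + band_px) - pmax(rows - 1, top)
      a[, , t] <- pmax(0, pmin(1, cover))
    }
    if (noise_sd > 0) {
      a <- a + stats::rnorm(length(a), sd = noise_sd)
      a <- pmin(pmax(a, 0), 1)   # array first: pmin/pmax keep its dim
    }
    a
  })
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_scale = pixel_scale),
            class = "video_stack")
}

#' Assemble a video stack from frames
#'
#' @param frames a \code{height x width x n_frames} numeric array, or a
#'   list of equally sized matrices.
#' @param frame_interval seconds between frames.
#' @param pixel_scale optional physical length per pixel.
#' @return A \code{"video_stack"} object.
#' @export
video_stack <- function(frames, frame_interval = 1, pixel_scale = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1)
      stop("all frames must have identical dimensions", call. = FALSE)
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3 || dim(frames)[3] < 2)
    stop("`frames` must be a height x width x n_frames array with >= 2 frames",
         call. = FALSE)
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("frame intensities must be finite and >= 0", call. = FALSE)
  check_number(frame_interval, "frame_interval", lower = 0,
               allow_boundary = FALSE)
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_scale = pixel_scale),
            class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Video stack: %d frame(s) of %d x %d px, %.3g s/frame%s\n",
              d[3], d[1], d[2], x$frame_interval,
              if (is.null(x$pixel_scale)) "" else
                sprintf(", %.3g length/px", x$pixel_scale)))
  invisible(x)
}

#' Write / read a video stack as multi-page grayscale TIFF
#'
#' Intensities are clamped to \eqn{[0, 1]} on write (the TIFF grayscale
#' range). Frame interval and pixel scale are not stored in the file and
#' must be supplied again on read.
#'
#' @param video a \code{"video_stack"}.
#' @param path TIFF file path.
#' @return \code{write_video}: the path, invisibly. \code{read_video}: a
#'   \code{"video_stack"}.
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "video_stack"))
  pages <- lapply(seq_len(dim(video$frames)[3]),
                  function(t) pmin(pmax(video$frames[, , t], 0), 1))
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' @rdname write_video
#' @param frame_interval,pixel_scale metadata for the stack read back.
#' @export
read_video <- function(path, frame_interval = 1, pixel_scale = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3)
    p[, , 1] else p)  # collapse any RGB to first channel
  video_stack(pages, frame_interval = frame_interval,
              pixel_scale = pixel_scale)
}
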