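#' Construct a calibrated image stack
#'
#' A thin container for a T x H x W time-lapse intensity array with its
#' physical calibration.
#'
#' @param data Numeric array `[frame, row, col]` (a matrix is promoted to a
#'   single-frame stack). Intensities must be non-negative.
#' @param pixel_size_um Pixel size, um.
#' @param frame_interval_s Frame interval, s.
#' @param channel Channel label (e.g. `"FRET"`, `"mTFP1"`, `"beads"`).
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, pixel_size_um = 0.2, frame_interval_s = 10,
                        channel = "unknown") {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  stopifnot(length(dim(data)) == 3L)
  if (any(data < 0, na.rm = TRUE)) abort("intensities must be >= 0.")
  check_scalar_number(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  check_scalar_number(frame_interval_s, "frame_interval_s", 0,
                      strict_lower = TRUE)
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %s: %d frames of %d x %d px (%g um/px, %g s)\n",
              x$channel, d[1], d[2], d[3], x$pixel_size_um,
              x$frame_interval_s))
  invisible(x)
}

n_frames <- function(stack) dim(stack$data)[1]

get_frame <- function(stack, t) stack$data[t, , ]

# 2D median filter with the given radius, tolerant of any value range and of
# NAs (EBImage's filter expects [0, 1] data).
median_filter_2d <- function(frame, radius) {
  if (radius < 1) return(frame)
  na_mask <- !is.finite(frame)
  work <- frame
  if (any(na_mask)) work[na_mask] <- median(frame[!na_mask])
  rng <- range(work)
  if (diff(rng) == 0) return(frame)
  scaled <- (work - rng[1]) / diff(rng)
  out <- EBImage::medianFilter(t(scaled), size = radius)
  out <- t(out) * diff(rng) + rng[1]
  out[na_mask] <- NA_real_
  out
}

#' Compute a FRET/donor ratio stack
#'
#' Ratiometric biosensor readout: both channels are background-subtracted
#' and median-smoothed, the ratio is taken pixelwise, and the ratio is
#' median-smoothed again. Pixels whose denominator falls below an epsilon of
#' the channel's dynamic range are marked missing (`NA`), never infinite.
#'
#' @param num Numerator stack (FRET channel), an [image_stack()].
#' @param den Denominator stack (donor channel), same geometry.
#' @param background Scalar background, or length-2 `c(num, den)` per
#'   channel. Must be non-negative.
#' @param median_radius_px Median filter radius in pixels (default 1,
#'   i.e. 3 x 3); 0 disables smoothing.
#' @return An `image_stack` of ratio values (channel `"ratio"`), `NA`
#'   outside the measurable region.
#' @export
compute_fret_ratio <- function(num, den, background = 0,
                               median_radius_px = 1) {
  stopifnot(inherits(num, "image_stack"), inherits(den, "image_stack"))
  if (!all(dim(num$data) == dim(den$data))) {
    abort("numerator and denominator stacks must match in geometry.")
  }
  if (any(background < 0)) abort("`background` must be non-negative.")
  if (median_radius_px < 0) abort("`median_radius_px` must be >= 0.")
  bg <- rep(background, length.out = 2)

  out <- array(NA_real_, dim = dim(num$data))
  eps <- 1e-6 * max(diff(range(den$data)), 1e-300)
  for (t in seq_len(n_frames(num))) {
    a <- get_frame(num, t) - bg[1]
    b <- get_frame(den, t) - bg[2]
    if (median_radius_px > 0) {
      a <- median_filter_2d(a, median_radius_px)
      b <- median_filter_2d(b, median_radius_px)
    }
    r <- a / b
    r[b <= eps] <- NA_real_
    if (median_radius_px > 0) r <- median_filter_2d(r, median_radius_px)
    r[r < 0] <- 0
    out[t, , ] <- r
  }
  image_stack(pmax(out, 0), num$pixel_size_um, num$frame_interval_s,
              channel = "ratio")
}

#' Register a stack against a reference frame (stage-drift correction)
#'
#' Per-frame translation offsets are estimated by the cross-correlation peak
#' with parabolic subpixel refinement, and the shifts are applied by bilinear
#' interpolation. Translation only (stage drift has no rotation component).
#' A frame with no signal is flagged as failed and carries the previous
#' frame's offset forward.
#'
#' @param stack An [image_stack()].
#' @param reference Reference frame (matrix, same H x W); defaults to the
#'   first frame.
#' @return List: `stack` (registered `image_stack`) and `offsets` tibble
#'   (`frame`, `dx_px`, `dy_px`, `failed`).
#' @export
register_stack <- function(stack, reference = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(reference)) reference <- get_frame(stack, 1)
  if (!all(dim(reference) == dim(stack$data)[2:3])) {
    abort("reference must match the stack frame geometry.")
  }
  nt <- n_frames(stack)
  out <- stack$data
  offs <- tibble(frame = seq_len(nt) - 1L, dx_px = 0, dy_px = 0,
                 failed = FALSE)
  prev <- c(dx = 0, dy = 0)
  max_shift <- floor(min(dim(reference)) / 4)
  for (t in seq_len(nt)) {
    fr <- get_frame(stack, t)
    pk <- correlation_peak(reference, fr, max_shift)
    if (is.null(pk)) {
      offs$failed[t] <- TRUE
      pk <- prev
    }
    prev <- pk
    offs$dx_px[t] <- pk[["dx"]]
    offs$dy_px[t] <- pk[["dy"]]
    if (abs(pk[["dx"]]) > 1e-9 || abs(pk[["dy"]]) > 1e-9) {
      out[t, , ] <- shift_frame(fr, -pk[["dx"]], -pk[["dy"]])
    }
  }
  list(stack = image_stack(pmax(out, 0), stack$pixel_size_um,
                           stack$frame_interval_s, stack$channel),
       offsets = offs)
}

# Bilinear translation of a frame by (dx, dy) pixels (columns, rows);
# out-of-view pixels are filled with 0.
shift_frame <- function(frame, dx, dy) {
  out <- EBImage::translate(t(frame), v = c(dx, dy), filter = "bilinear",
                            bg.col = 0)
  t(out)
}
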