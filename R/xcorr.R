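#' Lagged cross-correlation of paired event series
#'
#' For each paired series (one per event or window), computes the Pearson
#' correlation between `x(t)` and `y(t + lag)` over their overlapping
#' segment at every lag on a symmetric grid of multiples of `dt_s` up to
#' `max_lag_s`; the ensemble curve is the per-lag average over series. A
#' positive peak lag therefore means `y` follows `x`. Series are z-scored
#' per series before correlating (Pearson correlation is affine-invariant,
#' so this only stabilises degenerate cases).
#'
#' @param x,y Lists of numeric vectors (paired, equal sampling), or a single
#'   pair of numeric vectors.
#' @param max_lag_s Maximum lag in seconds (default 120).
#' @param dt_s Sampling interval in seconds.
#' @param min_overlap Minimum overlapping points for a series to contribute
#'   at a lag (default 4).
#' @param x_name,y_name Labels stored in the result.
#' @return An `xcorr_result`: tibble-backed object with fields `lags_s`,
#'   `corr` (mean over series), `n_pairs` (contributing series per lag), and
#'   labels. `tidy()` returns the per-lag tibble.
#' @export
#' @examples
#' t <- seq(0, 240, by = 10)
#' x <- replicate(20, rnorm(length(t)), simplify = FALSE)
#' y <- purrr::map(x, ~ c(rep(0, 4), head(.x, -4))) # y lags x by 4 frames
#' r <- cross_correlate(x, y, max_lag_s = 120, dt_s = 10)
#' peak_lag(r)
cross_correlate <- function(x, y, max_lag_s = 120, dt_s,
                            min_overlap = 4, x_name = "x", y_name = "y") {
  if (is.numeric(x)) x <- list(x)
  if (is.numeric(y)) y <- list(y)
  if (length(x) != length(y)) abort("`x` and `y` must be paired lists.")
  check_scalar_number(dt_s, "dt_s", 0, strict_lower = TRUE)
  max_shift <- floor(max_lag_s / dt_s + 1e-9)
  shifts <- seq(-max_shift, max_shift)

  corr_sum <- numeric(length(shifts))
  n_pairs <- integer(length(shifts))
  for (i in seq_along(x)) {
    xi <- as.numeric(x[[i]])
    yi <- as.numeric(y[[i]])
    if (length(xi) != length(yi)) {
      abort("paired series must have equal length.")
    }
    n <- length(xi)
    for (k in seq_along(shifts)) {
      s <- shifts[k]
      # correlate x(t) with y(t + s): x indices i, y indices i + s
      ix <- seq(max(1L, 1L - s), min(n, n - s))
      if (length(ix) < min_overlap) next
      xv <- xi[ix]
      yv <- yi[ix + s]
      ok <- !is.na(xv) & !is.na(yv)
      if (sum(ok) < min_overlap) next
      sx <- sd(xv[ok])
      sy <- sd(yv[ok])
      if (sx < 1e-12 || sy < 1e-12) next
      corr_sum[k] <- corr_sum[k] + stats::cor(xv[ok], yv[ok])
      n_pairs[k] <- n_pairs[k] + 1L
    }
  }
  corr <- ifelse(n_pairs > 0, corr_sum / n_pairs, NA_real_)
  structure(list(
    lags_s = shifts * dt_s, corr = corr, n_pairs = n_pairs,
    x_name = x_name, y_name = y_name, dt_s = dt_s
  ), class = "xcorr_result")
}

#' @export
print.xcorr_result <- function(x, ...) {
  pk <- peak_lag(x)
  cat(sprintf("<xcorr_result> %s vs %s, lags %g..%g s; peak %+.0f s (r = %.3f)\n",
              x$x_name, x$y_name, min(x$lags_s), max(x$lags_s),
              pk, x$corr[match(pk, x$lags_s)]))
  invisible(x)
}

#' Lag of the cross-correlation extremum
#'
#' @param result An [cross_correlate()] result.
#' @param mode `"max"` (default) or `"min"`.
#' @return Lag in seconds; ties broken toward the smallest absolute lag.
#' @export
peak_lag <- function(result, mode = c("max", "min")) {
  stopifnot(inherits(result, "xcorr_result"))
  mode <- match.arg(mode)
  v <- result$corr
  if (all(is.na(v))) abort("empty cross-correlation result.")
  target <- if (mode == "max") max(v, na.rm = TRUE) else min(v, na.rm = TRUE)
  cand <- which(abs(v - target) < 1e-12)
  lags <- result$lags_s[cand]
  lags[which.min(abs(lags))]
}

#' Cross-correlate two signals around detected events
#'
#' Extracts, per event, the two signal slabs in a relative-time window at a
#' given depth and runs [cross_correlate()] on the paired per-event series.
#'
#' @param table Window series table.
#' @param events Event tibble.
#' @param x_signal,y_signal Column names to correlate (`y` vs `x`).
#' @param anchor Anchor passed to [align_ensembles()].
#' @param depth Depth window to use (default 2).
#' @param window_s Relative-time extraction window (default `c(-120, 120)`).
#' @param max_lag_s Maximum lag (default 120).
#' @return An `xcorr_result`.
#' @export
event_cross_correlation <- function(table, events, x_signal, y_signal,
                                    anchor = "protrusion_onset", depth = 2,
                                    window_s = c(-120, 120), max_lag_s = 120) {
  ex <- align_ensembles(table, events, x_signal, anchor,
                        window_s = window_s, depths = depth)
  ey <- align_ensembles(table, events, y_signal, anchor,
                        window_s = window_s, depths = depth)
  xs <- purrr::map(seq_len(ex$n_events), ~ ex$data[.x, 1, ])
  ys <- purrr::map(seq_len(ey$n_events), ~ ey$data[.x, 1, ])
  cross_correlate(xs, ys, max_lag_s = max_lag_s, dt_s = infer_dt(table),
                  x_name = x_signal, y_name = y_signal)
}
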