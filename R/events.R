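#' Cubic smoothing spline for window time series
#'
#' Smooths a single time series with a natural cubic smoothing spline in the
#' classic penalized form: minimise
#' `p * sum((y - f)^2) + (1 - p) * integral(f'')^2`.
#' `p = 1` interpolates the data exactly; as `p -> 0` the fit tends to the
#' least-squares straight line. Evaluated at the original sample times.
#'
#' @param y Numeric series (>= 4 points).
#' @param p Smoothing parameter in `(0, 1]` (default 0.5).
#' @param time Optional sample times; defaults to `0:(n-1)`.
#' @return Numeric vector of smoothed values, same length as `y`.
#' @export
#' @examples
#' t <- 0:40
#' y <- sin(t / 6) + rnorm(41, 0, 0.2)
#' ys <- smooth_series(y, p = 0.5, time = t)
smooth_series <- function(y, p = 0.5, time = NULL) {
  if (length(y) < 4L) abort("`y` must have at least 4 points.")
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    abort("`p` must be in (0, 1].")
  }
  if (is.null(time)) time <- seq_along(y) - 1
  if (anyNA(y)) {
    ok <- !is.na(y)
    if (sum(ok) < 4L) return(y)
    out <- y
    out[ok] <- drop(csaps_operator(time[ok], p) %*% y[ok])
    return(out)
  }
  drop(csaps_operator(time, p) %*% y)
}

# Hat matrix of the penalized smoothing spline: (I + a K)^{-1} with
# K = Q R^{-1} Q^T (Green & Silverman) and a = (1 - p) / p. Cached per
# (times, p) since the pipeline smooths many series on one time grid.
csaps_operator <- local({
  cache <- new.env(parent = emptyenv())
  function(time, p) {
    key <- paste(format(p, digits = 17), length(time),
                 format(time[1]), format(time[length(time)]),
                 format(sum(time)), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    n <- length(time)
    h <- diff(time)
    if (any(h <= 0)) abort("`time` must be strictly increasing.")
    a <- (1 - p) / p
    if (a == 0) {
      op <- diag(n)
    } else {
      Q <- matrix(0, n, n - 2L)
      R <- matrix(0, n - 2L, n - 2L)
      for (j in seq_len(n - 2L)) {
        Q[j, j] <- 1 / h[j]
        Q[j + 1L, j] <- -1 / h[j] - 1 / h[j + 1L]
        Q[j + 2L, j] <- 1 / h[j + 1L]
        R[j, j] <- (h[j] + h[j + 1L]) / 3
        if (j < n - 2L) {
          R[j, j + 1L] <- h[j + 1L] / 6
          R[j + 1L, j] <- h[j + 1L] / 6
        }
      }
      K <- Q %*% solve(R, t(Q))
      op <- solve(diag(n) + a * K)
    }
    if (length(ls(cache)) > 32L) rm(list = ls(cache), envir = cache)
    cache[[key]] <- op
    op
  }
})

# Smooth each column of Y (time x series) with the same operator.
csaps_matrix <- function(Y, p, time = NULL) {
  if (is.null(time)) time <- seq_len(nrow(Y)) - 1
  csaps_operator(time, p) %*% Y
}

#' Detect protrusion and retraction events in an edge displacement series
#'
#' Phases are delimited by alternating local extrema of the (smoothed)
#' displacement series: a minimum-to-maximum phase is a protrusion, a
#' maximum-to-minimum phase a retraction. The phase onset is the starting
#' extremum, the end the next extremum, and Vmax the frame of maximal
#' absolute edge velocity within the phase (ties broken toward the earliest
#' frame). Phases moving less than `min_distance_um` or lasting less than
#' `min_duration_s` are discarded.
#'
#' @param displacement Smoothed displacement series (um).
#' @param dt_s Frame interval (s).
#' @param velocity Optional velocity series (um/s); defaults to the central
#'   difference of `displacement` (unbiased location of the velocity
#'   extremum on symmetric ramps).
#' @param min_distance_um Minimal retained distance (default 1 um; smaller
#'   phases are discarded).
#' @param min_duration_s Minimal retained duration (default 60 s).
#' @param sector Optional sector id stored in the output.
#' @return Tibble with one row per retained event: `sector`, `type`
#'   (`"protrusion"` or `"retraction"`), `onset_frame`, `vmax_frame`,
#'   `end_frame` (0-based), `onset_s`, `vmax_s`, `end_s`, `distance_um`
#'   (magnitude), `duration_s`.
#' @export
#' @examples
#' t <- seq(0, 480, by = 10)
#' x <- 2 * sin(2 * pi * t / 240)
#' detect_events(x, dt_s = 10)
detect_events <- function(displacement, dt_s, velocity = NULL,
                          min_distance_um = 1, min_duration_s = 60,
                          sector = NA_integer_) {
  n <- length(displacement)
  if (n < 2L) return(empty_events())
  if (is.null(velocity)) velocity <- central_diff(displacement, dt_s)

  d <- diff(displacement)
  s <- sign(d)
  nz <- which(s != 0)
  if (!length(nz)) return(empty_events())
  # carry signs across plateaus (leading zeros take the first nonzero sign)
  s[seq_len(nz[1L])] <- s[nz[1L]]
  if (length(s) >= 2L) {
    for (i in 2:length(s)) if (s[i] == 0) s[i] <- s[i - 1L]
  }

  # extremum at frame i (0-based) where the carried sign flips at increment i
  flips <- which(diff(s) != 0) # increment index; extremum between d[i], d[i+1]
  extrema <- c(0L, flips, n - 1L)

  rows <- list()
  tol <- 1e-9
  for (k in seq_len(length(extrema) - 1L)) {
    a <- extrema[k]
    b <- extrema[k + 1L]
    # trim plateaus at the phase ends: onset is where motion starts, the end
    # where it stops (extrema of a flat-topped series are whole plateaus)
    moving <- which(abs(d[(a + 1L):b]) > 1e-12) # increments a..b-1, 0-based a+i-1
    if (length(moving)) {
      a <- a + moving[1L] - 1L
      b <- a - moving[1L] + 1L + moving[length(moving)]
    }
    delta <- displacement[b + 1L] - displacement[a + 1L]
    type <- if (delta > 0) "protrusion" else "retraction"
    dist <- abs(delta)
    dur <- (b - a) * dt_s
    if (dist + tol < min_distance_um || dur + tol < min_duration_s) next
    ph <- seq(a, max(a, b - 1L)) # candidate vmax frames (0-based)
    v <- velocity[ph + 1L]
    vmax <- ph[if (type == "protrusion") which.max(v) else which.min(v)]
    rows[[length(rows) + 1L]] <- tibble(
      sector = sector, type = type,
      onset_frame = a, vmax_frame = vmax, end_frame = b,
      onset_s = a * dt_s, vmax_s = vmax * dt_s, end_s = b * dt_s,
      distance_um = dist, duration_s = dur
    )
  }
  if (!length(rows)) empty_events() else bind_rows(rows)
}

empty_events <- function() {
  tibble(
    sector = integer(), type = character(),
    onset_frame = integer(), vmax_frame = integer(), end_frame = integer(),
    onset_s = numeric(), vmax_s = numeric(), end_s = numeric(),
    distance_um = numeric(), duration_s = numeric()
  )
}

#' Detect events for every sector of a window series table
#'
#' Applies [detect_events()] to each sector's displacement series (optionally
#' smoothing it first with [smooth_series()]).
#'
#' @param table A window series table (see [make_window_series()]).
#' @param smoothing_p Smoothing-spline parameter; `NULL` to skip smoothing.
#' @inheritParams detect_events
#' @return Tibble of events across sectors.
#' @export
detect_events_table <- function(table, smoothing_p = NULL,
                                min_distance_um = 1, min_duration_s = 60) {
  dt <- infer_dt(table)
  per_sector <- table |>
    filter(.data$depth == min(.data$depth)) |>
    arrange(.data$sector, .data$frame)
  split(per_sector, per_sector$sector) |>
    purrr::map(function(df) {
      disp <- df$displacement_um
      if (!is.null(smoothing_p)) {
        disp <- smooth_series(disp, p = smoothing_p, time = df$time_s)
      }
      detect_events(disp, dt_s = dt, min_distance_um = min_distance_um,
                    min_duration_s = min_duration_s,
                    sector = df$sector[1L])
    }) |>
    bind_rows()
}

infer_dt <- function(table) {
  tt <- sort(unique(table$time_s))
  if (length(tt) < 2L) abort("table must contain at least two frames.")
  dt <- diff(tt)
  if (max(dt) - min(dt) > 1e-6) abort("frames are not regularly spaced.")
  dt[1L]
}

#' z-score normalization of a series
#'
#' Centers and scales to zero mean and unit SD over the full series. A series
#' with (near-)zero spread cannot be normalized and is returned as all-`NA`
#' so downstream ensembles exclude it.
#'
#' @param x Numeric series (>= 2 points).
#' @return Normalized series; all-`NA` (with attribute `degenerate = TRUE`)
#'   when the spread is zero.
#' @export
#' @examples
#' z <- znormalize(c(1, 2, 3, 4))
#' mean(z); sd(z)
znormalize <- function(x) {
  if (length(x) < 2L) abort("`x` must have at least 2 points.")
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s < 1e-12) {
    out <- rep(NA_real_, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (x - m) / s
}

#' z-score normalize signal columns of a window table per (sector, depth)
#'
#' @param table Window series table.
#' @param cols Character vector of columns to normalize.
#' @return The table with the named columns normalized within each
#'   (cell_id, sector, depth) series.
#' @export
znormalize_table <- function(table, cols = c("rac1", "rhoa", "traction_pa")) {
  cols <- intersect(cols, names(table))
  table |>
    group_by(.data$cell_id, .data$sector, .data$depth) |>
    mutate(across(dplyr::all_of(cols), ~ as.numeric(znormalize(.x)))) |>
    ungroup()
}

#' Align per-window series into an event-anchored ensemble
#'
#' For each event of the anchor's type, extracts the (depth x relative time)
#' slab of the chosen signal centred on the anchor frame (protrusion or
#' retraction onset or Vmax). Samples outside the movie are missing; the
#' ensemble mean is computed over available entries.
#'
#' @param table Window series table (z-normalize first if desired).
#' @param events Event tibble from [detect_events_table()].
#' @param signal Column name to align (e.g. `"rac1"`).
#' @param anchor One of `"protrusion_onset"`, `"protrusion_vmax"`,
#'   `"retraction_onset"`, `"retraction_vmax"`.
#' @param window_s Relative time window, default `c(-120, 120)` seconds.
#' @param depths Depth indices to include (default: all in the table).
#' @return An `aligned_ensemble` object: fields `data` (array
#'   events x depths x times), `rel_time_s`, `depths`, `anchor`, `signal`,
#'   `n_events`, `mean` (depths x times matrix), `events`.
#' @export
align_ensembles <- function(table, events, signal, anchor,
                            window_s = c(-120, 120), depths = NULL) {
  anchor <- match.arg(anchor, c("protrusion_onset", "protrusion_vmax",
                                "retraction_onset", "retraction_vmax"))
  want_type <- sub("_(onset|vmax)$", "", anchor)
  anchor_col <- if (grepl("onset$", anchor)) "onset_frame" else "vmax_frame"
  ev <- events[events$type == want_type, , drop = FALSE]
  if (!nrow(ev)) abort("no events of the anchor type.")
  if (!signal %in% names(table)) abort(sprintf("no column `%s` in table.", signal))

  dt <- infer_dt(table)
  rel_frames <- seq(round(window_s[1] / dt), round(window_s[2] / dt))
  rel_time <- rel_frames * dt

  sectors <- sort(unique(table$sector))
  if (is.null(depths)) depths <- sort(unique(table$depth))
  frames <- sort(unique(table$frame))
  n_f <- length(frames)

  # dense value cube indexed [frame, sector, depth]
  cube <- array(NA_real_, dim = c(n_f, length(sectors), length(depths)))
  idx <- cbind(match(table$frame, frames), match(table$sector, sectors),
               match(table$depth, depths))
  keep <- complete.cases(idx)
  cube[idx[keep, , drop = FALSE]] <- table[[signal]][keep]

  out <- array(NA_real_,
               dim = c(nrow(ev), length(depths), length(rel_frames)))
  for (i in seq_len(nrow(ev))) {
    s_i <- match(ev$sector[i], sectors)
    if (is.na(s_i)) next
    f <- ev[[anchor_col]][i] + rel_frames # 0-based target frames
    j <- match(f, frames)
    ok <- !is.na(j)
    out[i, , ok] <- t(cube[j[ok], s_i, , drop = FALSE][, 1, , drop = TRUE])
  }

  mean_map <- apply(out, c(2, 3), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  structure(list(
    data = out, rel_time_s = rel_time, depths = depths, anchor = anchor,
    signal = signal, n_events = nrow(ev), mean = mean_map, events = ev
  ), class = "aligned_ensemble")
}

#' @export
print.aligned_ensemble <- function(x, ...) {
  cat(sprintf("<aligned_ensemble> %s of %s: %d events, depths %s, t = %g..%g s\n",
              x$anchor, x$signal, x$n_events,
              paste(range(x$depths), collapse = ".."),
              min(x$rel_time_s), max(x$rel_time_s)))
  invisible(x)
}

#' Ensemble mean with bootstrap confidence intervals
#'
#' Bootstraps events (not time points) with replacement and returns
#' percentile confidence bands for the ensemble mean at every
#' (depth, relative time) cell.
#'
#' @param ensemble An [align_ensembles()] result.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Seed for the resampling.
#' @return The ensemble with `lower` and `upper` matrices (depths x times)
#'   added, plus `n_boot`, `level`, `seed`.
#' @export
ensemble_mean_ci <- function(ensemble, n_boot = 1000, level = 0.95,
                             seed = NULL) {
  stopifnot(inherits(ensemble, "aligned_ensemble"))
  n_ev <- ensemble$n_events
  if (n_ev < 2L) abort("need at least 2 events to bootstrap.")
  dims <- dim(ensemble$data)
  M <- matrix(ensemble$data, nrow = n_ev) # events x (depth*time)
  has <- !is.na(M)
  M0 <- ifelse(has, M, 0)

  boots <- with_seed(seed, {
    W <- matrix(0L, n_boot, n_ev)
    for (b in seq_len(n_boot)) {
      W[b, ] <- tabulate(sample.int(n_ev, n_ev, replace = TRUE), n_ev)
    }
    num <- W %*% M0
    den <- W %*% has
    num / ifelse(den > 0, den, NA_real_)
  })

  alpha <- (1 - level) / 2
  qs <- apply(boots, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  ensemble$lower <- matrix(qs[1, ], dims[2], dims[3])
  ensemble$upper <- matrix(qs[2, ], dims[2], dims[3])
  ensemble$n_boot <- n_boot
  ensemble$level <- level
  ensemble$seed <- seed
  ensemble
}

#' Flag frames with inconsistent temporal alignment
#'
#' Quality-control step comparing the traction profile across sectors in a
#' fixed depth window between neighbouring frames. A frame is flagged as a
#' `duplicate` when its profile is numerically identical to the previous
#' frame's, and as `decorrelated` when the across-sector correlation with the
#' previous frame drops below `min_cor` (candidate dropped or corrupted
#' frames). Report-only: the table is never mutated.
#'
#' @param table Window series table with a `traction_pa` column.
#' @param depth Depth window used for the comparison (default 5).
#' @param min_cor Correlation threshold (default 0.2).
#' @return Tibble: `frame`, `cor_prev`, `flag` (`"ok"`, `"duplicate"`,
#'   `"decorrelated"`).
#' @export
refine_temporal_alignment <- function(table, depth = 5, min_cor = 0.2) {
  df <- table |>
    filter(.data$depth == !!depth) |>
    arrange(.data$frame, .data$sector)
  if (!nrow(df)) abort(sprintf("no rows at depth %d.", depth))
  prof <- df |>
    tidyr::pivot_wider(id_cols = "sector", names_from = "frame",
                       values_from = "traction_pa") |>
    select(-"sector") |>
    as.matrix()
  frames <- sort(unique(df$frame))
  out <- tibble(frame = frames, cor_prev = NA_real_, flag = "ok")
  for (k in seq_along(frames)[-1]) {
    a <- prof[, k - 1L]
    b <- prof[, k]
    cc <- suppressWarnings(stats::cor(a, b, use = "complete.obs"))
    out$cor_prev[k] <- cc
    if (max(abs(a - b), na.rm = TRUE) < 1e-12) {
      out$flag[k] <- "duplicate"
    } else if (is.finite(cc) && cc < min_cor) {
      out$flag[k] <- "decorrelated"
    }
  }
  out
}
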