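#' Segment the cell in every frame of a stack
#'
#' Per-frame global Otsu threshold on the (FRET-channel) intensities,
#' keeping the largest connected component, filling holes and lightly
#' smoothing the outline with a morphological opening. One cell per movie is
#' assumed.
#'
#' @param stack An [image_stack()] (or ratio stack); `NA` pixels are treated
#'   as background.
#' @param opening_radius_px Radius of the smoothing opening (default 2; 0
#'   disables it).
#' @return A `cell_mask_stack`: logical `[frame, row, col]` array plus
#'   calibration and a per-frame `failed` flag (no foreground found).
#' @export
segment_cell <- function(stack, opening_radius_px = 2) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- n_frames(stack)
  d <- dim(stack$data)
  masks <- array(FALSE, dim = d)
  failed <- logical(nt)
  for (t in seq_len(nt)) {
    fr <- get_frame(stack, t)
    fr[!is.finite(fr)] <- 0
    rng <- range(fr)
    if (diff(rng) == 0) {
      failed[t] <- TRUE
      next
    }
    sc <- (fr - rng[1]) / diff(rng)
    img <- t(sc) # EBImage convention: [x, y]
    th <- EBImage::otsu(EBImage::Image(img))
    bw <- img > th
    if (!any(bw)) {
      failed[t] <- TRUE
      next
    }
    if (opening_radius_px > 0) {
      bw <- EBImage::opening(bw, EBImage::makeBrush(2 * opening_radius_px + 1,
                                                    "disc"))
    }
    lab <- EBImage::bwlabel(bw)
    if (max(lab) == 0) {
      failed[t] <- TRUE
      next
    }
    sizes <- tabulate(lab[lab > 0])
    keep <- which.max(sizes)
    bw <- lab == keep
    bw <- EBImage::fillHull(bw)
    masks[t, , ] <- t(as.array(bw)) > 0
  }
  structure(list(data = masks, pixel_size_um = stack$pixel_size_um,
                 frame_interval_s = stack$frame_interval_s, failed = failed),
            class = "cell_mask_stack")
}

#' @export
print.cell_mask_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cell_mask_stack> %d frames of %d x %d px; %d failed\n",
              d[1], d[2], d[3], sum(x$failed)))
  invisible(x)
}

# Ordered boundary coordinates (row, col; 1-based pixel centers) of the
# largest object in a logical mask, smoothed with a circular moving average
# so chain-code stair-stepping does not inflate the perimeter estimate, and
# pushed half a pixel outward along the local normal: boundary-pixel centers
# sit ~0.5 px inside the true mask interface.
mask_contour <- function(mask, smooth_window = 7) {
  oc <- EBImage::ocontour(EBImage::bwlabel(t(mask) * 1))
  if (!length(oc)) return(NULL)
  xy <- oc[[which.max(vapply(oc, nrow, integer(1)))]] # (x, y), 0-based
  pts <- cbind(row = xy[, 2] + 1, col = xy[, 1] + 1)
  n <- nrow(pts)
  if (n >= smooth_window && smooth_window > 1) {
    k <- smooth_window %/% 2
    idx <- function(i) ((i - 1) %% n) + 1
    sm <- pts
    for (off in setdiff(-k:k, 0)) {
      sm <- sm + pts[idx(seq_len(n) + off), ]
    }
    pts <- sm / (2 * k + 1)
  }
  if (n >= 5) {
    idx <- function(i) ((i - 1) %% n) + 1
    tang <- pts[idx(seq_len(n) + 1), ] - pts[idx(seq_len(n) - 1), ]
    nrm <- cbind(-tang[, 2], tang[, 1])
    len <- sqrt(rowSums(nrm^2))
    len[len < 1e-9] <- 1
    nrm <- nrm / len
    # orient outward: probe the mask just off each point
    probe <- round(pts + 1.5 * nrm)
    probe[, 1] <- pmin(pmax(probe[, 1], 1), nrow(mask))
    probe[, 2] <- pmin(pmax(probe[, 2], 1), ncol(mask))
    inside <- mask[probe]
    flip <- mean(inside) > 0.5
    if (flip) nrm <- -nrm
    pts <- pts + 0.5 * nrm
  }
  pts
}

contour_arclength <- function(pts) {
  n <- nrow(pts)
  seg <- sqrt(rowSums((pts - pts[c(2:n, 1), ])^2))
  list(cum = cumsum(c(0, seg[-n])), total = sum(seg), seg = seg)
}

#' Build the edge-sector x depth window grid for a mask stack
#'
#' The cell edge is divided into `S = round(perimeter / sector_width_um)`
#' sectors of equal arc length (the count is fixed on the first frame);
#' depth windows are 1-um bands of inward distance from the contour. Sectors
#' are propagated across frames by anchoring sector 1 at the contour point
#' nearest the previous frame's sector-1 anchor and re-dividing the arc
#' length equally.
#'
#' @param masks A `cell_mask_stack` from [segment_cell()].
#' @param sector_width_um Target sector width along the edge (default 1).
#' @param depth_um Depth-band thickness (default 1).
#' @param n_depths Number of depth bands (default 10).
#' @return A `window_grid`: per-frame `sector_map` and `depth_map` integer
#'   label matrices (`NA` outside the cell or beyond the last band),
#'   contours, per-frame sector anchor, `n_sectors`, and parameters.
#' @export
build_window_grid <- function(masks, sector_width_um = 1, depth_um = 1,
                              n_depths = 10) {
  stopifnot(inherits(masks, "cell_mask_stack"))
  px <- masks$pixel_size_um
  nt <- dim(masks$data)[1]
  frames <- vector("list", nt)
  n_sectors <- NULL
  anchor_pt <- NULL

  for (t in seq_len(nt)) {
    mask <- masks$data[t, , ]
    if (!any(mask)) abort(sprintf("empty mask at frame %d.", t - 1))
    pts <- mask_contour(mask)
    arc <- contour_arclength(pts)
    per_um <- arc$total * px
    if (is.null(n_sectors)) {
      n_sectors <- max(1L, round(per_um / sector_width_um))
      if (per_um < sector_width_um || per_um < 2 * depth_um) {
        abort("cell is smaller than a single window.")
      }
      start_i <- 1L
    } else {
      d2 <- rowSums(sweep(pts, 2, anchor_pt)^2)
      start_i <- which.min(d2)
    }
    anchor_pt <- pts[start_i, ]

    n <- nrow(pts)
    ord <- c(start_i:n, seq_len(start_i - 1L))
    pts_o <- pts[ord, , drop = FALSE]
    arc_o <- contour_arclength(pts_o)
    # sector index of each contour point by arc-length fraction
    frac <- arc_o$cum / arc_o$total
    sec_of_pt <- pmin(floor(frac * n_sectors) + 1L, n_sectors)

    # pixel labels
    inside <- which(mask, arr.ind = TRUE)
    dist_in <- t(as.matrix(EBImage::distmap(t(mask)))) # px to background
    depth_idx <- ceiling((dist_in[inside] - 0.5) * px / depth_um + 1e-9)
    depth_idx[depth_idx < 1L] <- 1L
    depth_idx[depth_idx > n_depths] <- NA_integer_

    sec_idx <- nearest_contour_sector(inside, pts_o, sec_of_pt)

    sector_map <- matrix(NA_integer_, nrow(mask), ncol(mask))
    depth_map <- matrix(NA_integer_, nrow(mask), ncol(mask))
    sector_map[inside] <- sec_idx
    depth_map[inside] <- depth_idx

    frames[[t]] <- list(
      contour = pts_o, sector_of_point = sec_of_pt,
      sector_map = sector_map, depth_map = depth_map,
      perimeter_um = per_um, anchor = anchor_pt
    )
  }
  structure(list(frames = frames, n_sectors = n_sectors,
                 sector_width_um = sector_width_um, depth_um = depth_um,
                 n_depths = n_depths, pixel_size_um = px),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d sectors x %d depths over %d frames (%g um windows)\n",
              x$n_sectors, x$n_depths, length(x$frames), x$sector_width_um))
  invisible(x)
}

# Sector label of each interior pixel = sector of its nearest contour point.
# Chunked to bound memory.
nearest_contour_sector <- function(pixels, pts, sec_of_pt, chunk = 4000L) {
  n <- nrow(pixels)
  out <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(pixels[s:e, 1], pts[, 1], "-")^2 +
      outer(pixels[s:e, 2], pts[, 2], "-")^2
    out[s:e] <- sec_of_pt[max.col(-d2, ties.method = "first")]
  }
  out
}

#' Per-sector edge displacement and velocity series
#'
#' For every sector, the mean normal edge displacement between consecutive
#' frames is measured as the signed area swept by the edge within the
#' sector's wedge (gained pixels minus lost pixels, assigned to sectors by
#' nearest contour point) divided by the sector arc length. Positive =
#' outward = protrusion. Increments accumulate into a displacement series;
#' velocity is the forward difference over the frame interval.
#'
#' @param masks A `cell_mask_stack`.
#' @param grid A [build_window_grid()] result.
#' @param dt_s Frame interval (s); defaults to the stack's.
#' @return Tibble: `sector`, `frame` (0-based), `time_s`,
#'   `displacement_um`, `velocity_um_per_s`.
#' @export
compute_edge_dynamics <- function(masks, grid, dt_s = NULL) {
  stopifnot(inherits(masks, "cell_mask_stack"), inherits(grid, "window_grid"))
  if (is.null(dt_s)) dt_s <- masks$frame_interval_s
  nt <- dim(masks$data)[1]
  if (nt < 2L) abort("need at least 2 frames.")
  px <- masks$pixel_size_um
  S <- grid$n_sectors

  incr <- matrix(0, nt - 1L, S)
  for (t in seq_len(nt - 1L)) {
    m0 <- masks$data[t, , ]
    m1 <- masks$data[t + 1L, , ]
    fr <- grid$frames[[t]]
    arc_um <- fr$perimeter_um / S
    gained <- which(m1 & !m0, arr.ind = TRUE)
    lost <- which(m0 & !m1, arr.ind = TRUE)
    counts <- numeric(S)
    if (nrow(gained)) {
      sec_g <- nearest_contour_sector(gained, fr$contour, fr$sector_of_point)
      tab <- tabulate(sec_g, S)
      counts <- counts + tab
    }
    if (nrow(lost)) {
      sec_l <- fr$sector_map[lost]
      miss <- is.na(sec_l)
      if (any(miss)) {
        sec_l[miss] <- nearest_contour_sector(lost[miss, , drop = FALSE],
                                              fr$contour, fr$sector_of_point)
      }
      counts <- counts - tabulate(sec_l, S)
    }
    incr[t, ] <- counts * px^2 / arc_um
  }
  disp <- apply(rbind(0, incr), 2, cumsum)
  purrr::map_dfr(seq_len(S), function(s) {
    tibble(
      sector = s, frame = seq_len(nt) - 1L,
      time_s = (seq_len(nt) - 1L) * dt_s,
      displacement_um = disp[, s],
      velocity_um_per_s = finite_diff(disp[, s], dt_s)
    )
  })
}

#' Window-mean sampling of a map stack
#'
#' Mean of the map values over each (sector, depth) window's pixels, per
#' frame. Windows with fewer than `min_defined` of their pixels defined are
#' marked missing.
#'
#' @param stack An [image_stack()] (e.g. a ratio stack or traction-magnitude
#'   stack), `NA` = undefined.
#' @param grid A [build_window_grid()] result with matching geometry.
#' @param signal Name for the value column (default `"value"`).
#' @param min_defined Minimum defined-pixel fraction (default 0.25).
#' @return Tibble: `sector`, `depth`, `frame` (0-based), `<signal>`.
#' @export
sample_window_means <- function(stack, grid, signal = "value",
                                min_defined = 0.25) {
  stopifnot(inherits(stack, "image_stack"), inherits(grid, "window_grid"))
  nt <- min(n_frames(stack), length(grid$frames))
  out <- purrr::map_dfr(seq_len(nt), function(t) {
    fr <- get_frame(stack, t)
    g <- grid$frames[[t]]
    keep <- !is.na(g$sector_map) & !is.na(g$depth_map)
    idx <- interaction(g$sector_map[keep], g$depth_map[keep], drop = FALSE)
    vals <- fr[keep]
    def <- tapply(!is.na(vals), idx, sum)
    tot <- tapply(vals, idx, length)
    mu <- tapply(vals, idx, function(v) mean(v, na.rm = TRUE))
    key <- do.call(rbind, strsplit(names(mu), ".", fixed = TRUE))
    ok <- is.finite(mu) & (def / tot >= min_defined)
    tibble(
      sector = as.integer(key[, 1]), depth = as.integer(key[, 2]),
      frame = t - 1L,
      !!signal := ifelse(ok, as.numeric(mu), NA_real_)
    )
  })
  arrange(out, .data$sector, .data$depth, .data$frame)
}

#' Migration speed from the cell's center of area
#'
#' Tracks the mask centroid, smooths the path with a smoothing spline, and
#' returns the mean speed of the smoothed path in um/hour.
#'
#' @param masks A `cell_mask_stack`.
#' @param dt_s Frame interval (s); defaults to the stack's.
#' @param smoothing_p Path smoothing parameter (default 0.5; `NULL` for no
#'   smoothing).
#' @return List: `speed_um_per_hour`, `path` tibble (`frame`, `x_um`,
#'   `y_um`, smoothed coordinates).
#' @export
track_cell_center <- function(masks, dt_s = NULL, smoothing_p = 0.5) {
  stopifnot(inherits(masks, "cell_mask_stack"))
  if (is.null(dt_s)) dt_s <- masks$frame_interval_s
  nt <- dim(masks$data)[1]
  if (nt < 2L) abort("need at least 2 frames.")
  px <- masks$pixel_size_um
  cent <- t(vapply(seq_len(nt), function(t) {
    w <- which(masks$data[t, , ], arr.ind = TRUE)
    c(mean(w[, 2]), mean(w[, 1])) * px
  }, numeric(2)))
  xs <- cent[, 1]
  ys <- cent[, 2]
  if (!is.null(smoothing_p) && nt >= 4) {
    xs <- smooth_series(xs, p = smoothing_p)
    ys <- smooth_series(ys, p = smoothing_p)
  }
  steps <- sqrt(diff(xs)^2 + diff(ys)^2)
  speed <- mean(steps) / dt_s * 3600
  list(
    speed_um_per_hour = speed,
    path = tibble(frame = seq_len(nt) - 1L, x_um = cent[, 1],
                  y_um = cent[, 2], x_smooth_um = xs, y_smooth_um = ys)
  )
}

#' Assemble a window series table from movie-level products
#'
#' Joins window-mean signal samples with the per-sector edge dynamics into
#' the tidy per-(sector, depth, frame) table used by the event and
#' correlation analyses.
#'
#' @param signal_samples Tibble from [sample_window_means()] (one or more,
#'   pre-joined by the caller if several signals).
#' @param edge_dynamics Tibble from [compute_edge_dynamics()].
#' @param dt_s Frame interval (s).
#' @param cell_id Cell identifier (default 1).
#' @return A window series table.
#' @export
window_series_from_movie <- function(signal_samples, edge_dynamics, dt_s,
                                     cell_id = 1L) {
  signal_samples |>
    left_join(edge_dynamics |>
                select("sector", "frame", "displacement_um",
                       "velocity_um_per_s"),
              by = c("sector", "frame")) |>
    mutate(cell_id = cell_id, time_s = .data$frame * dt_s) |>
    select("cell_id", "sector", "depth", "frame", "time_s",
           dplyr::everything()) |>
    arrange(.data$sector, .data$depth, .data$frame)
}
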