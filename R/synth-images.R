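#' Render a reference/deformed fiducial bead image pair
#'
#' Forward model for traction-force microscopy fixtures: beads are scattered
#' uniformly over the field, rendered as amplitude-jittered 2D Gaussian
#' spots, and the deformed image moves every bead by the displacement field
#' interpolated at its position. The displacement can come from a traction
#' map through the elastic forward model ([fttc_forward()]) or be injected
#' directly (e.g. a rigid shift), bypassing elasticity.
#'
#' @param config A [synth_config()] (bead density, spot width, pixel size,
#'   substrate elasticity, seed).
#' @param image_px Image side length in pixels (square frames).
#' @param traction Optional [traction_map()] whose forward displacement
#'   deforms the beads; its grid must tile the image
#'   (`spacing_um = grid_spacing_px * pixel_size_um`).
#' @param displacement Optional [displacement_field()] in um, used directly
#'   instead of `traction`.
#' @param grid_spacing_px Node spacing of the traction/displacement grid in
#'   pixels (default 8) when `traction` is given.
#' @return List: `reference` and `deformed` image matrices (rows = y),
#'   `true_displacement` (the [displacement_field()] used, um), `beads`
#'   tibble (`x_px`, `y_px`, `amplitude`, `dx_px`, `dy_px`).
#' @export
make_bead_pair <- function(config, image_px = 256, traction = NULL,
                           displacement = NULL, grid_spacing_px = 8) {
  stopifnot(inherits(config, "synth_config"))
  if (config$bead_density_per_um2 <= 0) {
    abort("`bead_density_per_um2` must be positive.")
  }
  px <- config$pixel_size_um

  if (is.null(displacement)) {
    if (is.null(traction)) {
      nn <- image_px / grid_spacing_px
      traction <- traction_map(matrix(0, nn, nn), matrix(0, nn, nn),
                               spacing_um = grid_spacing_px * px)
    }
    params <- elastic_params(config$youngs_modulus_pa, config$poisson_ratio)
    displacement <- fttc_forward(traction, params)
  }
  if (abs(displacement$spacing_um / px - round(displacement$spacing_um / px)) >
        1e-6) {
    abort("displacement grid spacing must be an integer number of pixels.")
  }

  n_beads <- max(1L, round(config$bead_density_per_um2 * (image_px * px)^2))
  beads <- with_seed(derive_seed(config$noise_seed, "beads"), {
    tibble(
      x_px = runif(n_beads, 1, image_px),
      y_px = runif(n_beads, 1, image_px),
      amplitude = runif(n_beads, 0.6, 1)
    )
  })

  sp_px <- displacement$spacing_um / px
  beads$dx_px <- interp_grid(displacement$u, sp_px, beads$x_px, beads$y_px) / px
  beads$dy_px <- interp_grid(displacement$v, sp_px, beads$x_px, beads$y_px) / px

  reference <- render_beads(beads$x_px, beads$y_px, beads$amplitude,
                            image_px, config$psf_sigma_px)
  deformed <- render_beads(beads$x_px + beads$dx_px, beads$y_px + beads$dy_px,
                           beads$amplitude, image_px, config$psf_sigma_px)
  list(reference = reference, deformed = deformed,
       true_displacement = displacement, beads = beads)
}

# Bilinear interpolation of a grid field (node (1,1) at pixel (1,1), nodes
# `spacing_px` apart) at pixel coordinates; clamped at the borders.
interp_grid <- function(G, spacing_px, x_px, y_px) {
  gx <- (x_px - 1) / spacing_px + 1
  gy <- (y_px - 1) / spacing_px + 1
  gx <- pmin(pmax(gx, 1), ncol(G))
  gy <- pmin(pmax(gy, 1), nrow(G))
  x0 <- pmin(floor(gx), ncol(G) - 1L)
  y0 <- pmin(floor(gy), nrow(G) - 1L)
  fx <- gx - x0
  fy <- gy - y0
  G[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    G[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    G[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    G[cbind(y0 + 1, x0 + 1)] * fx * fy
}

# Additively render Gaussian spots at subpixel positions.
render_beads <- function(x, y, amp, image_px, sigma) {
  img <- matrix(0, image_px, image_px)
  r <- ceiling(4 * sigma)
  for (i in seq_along(x)) {
    cx <- x[i]
    cy <- y[i]
    jj <- max(1, floor(cx - r)):min(image_px, ceiling(cx + r))
    ii <- max(1, floor(cy - r)):min(image_px, ceiling(cy + r))
    gx <- exp(-0.5 * ((jj - cx) / sigma)^2)
    gy <- exp(-0.5 * ((ii - cy) / sigma)^2)
    img[ii, jj] <- img[ii, jj] + amp[i] * outer(gy, gx)
  }
  img
}

#' Render a synthetic cell movie with scheduled edge events
#'
#' A star-convex cell is rendered per frame: its radius per angular sector
#' follows the cumulative displacement of the sector's event schedule (the
#' same generative model as [make_window_series()]). Two biosensor channels
#' are produced whose pixelwise ratio inside the cell encodes the true
#' Rac1-GTP signal of the nearest angular sector, so the full imaging ->
#' segmentation -> windowing -> event pipeline can be validated against the
#' schedule.
#'
#' @param config A [synth_config()]; `n_sectors` angular sectors are mapped
#'   to equal angle wedges.
#' @param image_px Image side (default 160).
#' @param base_radius_um Resting cell radius (default 12).
#' @param intensity_in,intensity_out Donor-channel intensity inside/outside
#'   the cell (defaults 1000 and 100).
#' @param ratio_offset Constant added to the Rac1 signal in the rendered
#'   FRET/donor ratio (default 1), keeping the FRET channel bright enough
#'   for threshold segmentation even at the Rac1 nadir; the measured ratio
#'   minus this offset equals the true Rac1 signal.
#' @param schedule Optional explicit event schedule (see
#'   [make_window_series()]).
#' @return List: `mtfp` and `fret` [image_stack()]s, `truth` (as in
#'   [make_window_series()], plus `true_masks` logical array and
#'   `radius_um` matrix frame x sector).
#' @export
make_cell_movie <- function(config, image_px = 160, base_radius_um = 12,
                            intensity_in = 1000, intensity_out = 100,
                            ratio_offset = 1, schedule = NULL) {
  stopifnot(inherits(config, "synth_config"))
  px <- config$pixel_size_um
  sim <- make_window_series(config, schedule = schedule)
  truth <- sim$truth
  nt <- config$n_frames
  S <- config$n_sectors

  # radius per (frame, sector) from the noiseless displacement series
  disp <- truth$true_signals |>
    select("sector", "frame", "displacement_um") |>
    tidyr::pivot_wider(names_from = "sector", values_from = "displacement_um") |>
    select(-"frame") |>
    as.matrix()
  radius_um <- base_radius_um + disp
  if (max(radius_um) / px > image_px / 2 - 2) {
    abort("cell radius exceeds the field of view.")
  }

  rac1 <- truth$true_signals |>
    select("sector", "frame", "rac1") |>
    tidyr::pivot_wider(names_from = "sector", values_from = "rac1") |>
    select(-"frame") |>
    as.matrix()

  ctr <- (image_px + 1) / 2
  jj <- matrix(seq_len(image_px), image_px, image_px, byrow = TRUE)
  ii <- matrix(seq_len(image_px), image_px, image_px)
  r_px <- sqrt((ii - ctr)^2 + (jj - ctr)^2)
  theta <- atan2(ii - ctr, jj - ctr) # [-pi, pi]
  sec_of_px <- pmin(floor((theta + pi) / (2 * pi) * S) + 1L, S)

  mtfp <- array(0, dim = c(nt, image_px, image_px))
  fret <- array(0, dim = c(nt, image_px, image_px))
  masks <- array(FALSE, dim = c(nt, image_px, image_px))
  noise <- config$noise_sd * intensity_in * 0.02

  frames <- with_seed(derive_seed(config$noise_seed, "movie"), {
    for (t in seq_len(nt)) {
      rad_px <- radius_um[t, ] / px
      inside <- r_px <= matrix(rad_px[sec_of_px], image_px, image_px)
      masks[t, , ] <- inside
      m <- matrix(intensity_out, image_px, image_px)
      m[inside] <- intensity_in
      ratio <- matrix(1, image_px, image_px)
      ratio[inside] <- rac1[t, ][sec_of_px[inside]] + ratio_offset
      f <- m * ratio
      if (noise > 0) {
        m <- m + matrix(rnorm(image_px^2, 0, noise), image_px)
        f <- f + matrix(rnorm(image_px^2, 0, noise), image_px)
      }
      mtfp[t, , ] <- pmax(m, 0)
      fret[t, , ] <- pmax(f, 0)
    }
    list(mtfp = mtfp, fret = fret, masks = masks)
  })

  truth$true_masks <- frames$masks
  truth$radius_um <- radius_um
  truth$ratio_offset <- ratio_offset
  list(
    mtfp = image_stack(frames$mtfp, px, config$frame_interval_s, "mTFP1"),
    fret = image_stack(frames$fret, px, config$frame_interval_s, "FRET"),
    truth = truth
  )
}
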