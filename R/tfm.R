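#' Elastic substrate parameters for traction reconstruction
#'
#' @param youngs_modulus_pa Young's modulus in pascal (default 6900, a
#'   6.9 kPa polyacrylamide gel).
#' @param poisson_ratio Poisson ratio in `[0, 0.5]` (default 0.5,
#'   incompressible-gel convention).
#' @param reg_lambda Dimensionless zeroth-order Tikhonov weight, relative to
#'   the largest kernel gain (default 0.02, chosen by L-curve on the
#'   package's synthetic smooth-patch fixture). `0` disables regularization.
#' @return An `elastic_params` object.
#' @export
elastic_params <- function(youngs_modulus_pa = 6900, poisson_ratio = 0.5,
                           reg_lambda = 0.02) {
  check_scalar_number(youngs_modulus_pa, "youngs_modulus_pa", 0,
                      strict_lower = TRUE)
  check_scalar_number(poisson_ratio, "poisson_ratio", 0, 0.5)
  check_scalar_number(reg_lambda, "reg_lambda", 0)
  structure(list(youngs_modulus_pa = youngs_modulus_pa,
                 poisson_ratio = poisson_ratio,
                 reg_lambda = reg_lambda),
            class = "elastic_params")
}

#' Construct a regular-grid displacement field
#'
#' @param u,v Matrices (rows = y, cols = x) of displacement components, um.
#' @param spacing_um Grid spacing, um.
#' @param valid Optional logical matrix of node validity.
#' @return A `displacement_field` object.
#' @export
displacement_field <- function(u, v, spacing_um, valid = NULL) {
  stopifnot(is.matrix(u), is.matrix(v), all(dim(u) == dim(v)))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(u), ncol(u))
  structure(list(
    u = u, v = v, valid = valid, spacing_um = spacing_um,
    x_um = (seq_len(ncol(u)) - 1) * spacing_um,
    y_um = (seq_len(nrow(u)) - 1) * spacing_um
  ), class = "displacement_field")
}

#' Construct a regular-grid traction map
#'
#' @param tx,ty Matrices (rows = y, cols = x) of traction components, Pa.
#' @param spacing_um Grid spacing, um.
#' @return A `traction_map` object (with a `magnitude` matrix).
#' @export
traction_map <- function(tx, ty, spacing_um) {
  stopifnot(is.matrix(tx), is.matrix(ty), all(dim(tx) == dim(ty)))
  structure(list(
    tx = tx, ty = ty, magnitude = sqrt(tx^2 + ty^2),
    spacing_um = spacing_um,
    x_um = (seq_len(ncol(tx)) - 1) * spacing_um,
    y_um = (seq_len(nrow(tx)) - 1) * spacing_um
  ), class = "traction_map")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %d x %d nodes @ %g um; |u| max %.3g um; %d invalid\n",
              nrow(x$u), ncol(x$u), x$spacing_um,
              max(sqrt(x$u^2 + x$v^2), na.rm = TRUE), sum(!x$valid)))
  invisible(x)
}

#' @export
print.traction_map <- function(x, ...) {
  cat(sprintf("<traction_map> %d x %d nodes @ %g um; |t| max %.4g Pa\n",
              nrow(x$tx), ncol(x$tx), x$spacing_um, max(x$magnitude)))
  invisible(x)
}

# Angular wavenumbers for an n-point grid with spacing h (um) -> rad/um.
fft_wavenumbers <- function(n, h) {
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / (n * h)
  2 * pi * f
}

# Boussinesq half-space kernel entries at wavevector (kx, ky); G is the
# symmetric 2x2 matrix with u_hat = G t_hat, units um/Pa when E is in Pa and
# k in rad/um (the 1e6-independent scale cancels in the round trip).
fttc_kernel <- function(kx_grid, ky_grid, E, nu) {
  KX <- matrix(kx_grid, nrow = length(ky_grid), ncol = length(kx_grid),
               byrow = TRUE)
  KY <- matrix(ky_grid, nrow = length(ky_grid), ncol = length(kx_grid))
  K2 <- KX^2 + KY^2
  K <- sqrt(K2)
  pref <- 2 * (1 + nu) / (E * K^3)
  pref[1, 1] <- 0 # DC handled separately
  list(
    g11 = pref * ((1 - nu) * K2 + nu * KY^2),
    g12 = -pref * nu * KX * KY,
    g22 = pref * ((1 - nu) * K2 + nu * KX^2),
    K = K
  )
}

#' Forward elastic problem: traction to substrate surface displacement
#'
#' Displacement produced on an elastic half-space by a surface traction
#' field, computed in Fourier space with the Boussinesq Green function.
#' No regularization; the DC (rigid translation) component is zero.
#'
#' @param traction A [traction_map()].
#' @param params An [elastic_params()].
#' @return A [displacement_field()] on the same grid (um).
#' @export
fttc_forward <- function(traction, params) {
  stopifnot(inherits(traction, "traction_map"),
            inherits(params, "elastic_params"))
  h <- traction$spacing_um
  ker <- fttc_kernel(fft_wavenumbers(ncol(traction$tx), h),
                     fft_wavenumbers(nrow(traction$tx), h),
                     params$youngs_modulus_pa, params$poisson_ratio)
  tx_h <- fft(traction$tx)
  ty_h <- fft(traction$ty)
  u_h <- ker$g11 * tx_h + ker$g12 * ty_h
  v_h <- ker$g12 * tx_h + ker$g22 * ty_h
  u_h[1, 1] <- 0
  v_h[1, 1] <- 0
  n <- length(tx_h)
  displacement_field(
    u = Re(fft(u_h, inverse = TRUE)) / n,
    v = Re(fft(v_h, inverse = TRUE)) / n,
    spacing_um = h
  )
}

#' Inverse elastic problem: displacement to traction (regularized FTTC)
#'
#' Reconstructs the surface traction from a gridded displacement field by
#' inverting the Boussinesq relation in Fourier space with zeroth-order
#' Tikhonov regularization. Invalid nodes must be gap-filled first (see
#' [fill_field_gaps()]); the DC component is set to zero so the recovered
#' field carries no net translation.
#'
#' @param field A [displacement_field()] (um).
#' @param params An [elastic_params()]; `reg_lambda` is relative to the
#'   largest kernel gain on this grid.
#' @param pad Taper-pad the field to twice its extent before the FFT and
#'   crop the result (default `TRUE`). Measured fields are not periodic;
#'   without padding the wrap-around discontinuity leaks broadband error
#'   into the reconstruction near the field border.
#' @return A [traction_map()] (Pa).
#' @export
fttc_inverse <- function(field, params, pad = TRUE) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(params, "elastic_params"))
  if (params$reg_lambda < 0) abort("`reg_lambda` must be >= 0.")
  if (any(!field$valid)) field <- fill_field_gaps(field)
  nr0 <- nrow(field$u)
  nc0 <- ncol(field$u)
  if (pad) {
    u_p <- taper_pad(field$u)
    field <- displacement_field(u_p, taper_pad(field$v), field$spacing_um)
  }
  h <- field$spacing_um
  ker <- fttc_kernel(fft_wavenumbers(ncol(field$u), h),
                     fft_wavenumbers(nrow(field$u), h),
                     params$youngs_modulus_pa, params$poisson_ratio)
  u_h <- fft(field$u)
  v_h <- fft(field$v)
  # normalized Tikhonov weight: relative to the largest kernel gain
  gmax <- max(abs(ker$g11[-1]), abs(ker$g22[-1]))
  lam2 <- (params$reg_lambda * gmax)^2
  a <- ker$g11
  b <- ker$g12
  d <- ker$g22
  # solve (G^T G + lam^2 I) t = G^T u per frequency (G symmetric)
  A11 <- a^2 + b^2 + lam2
  A12 <- b * (a + d)
  A22 <- b^2 + d^2 + lam2
  r1 <- a * u_h + b * v_h
  r2 <- b * u_h + d * v_h
  det <- A11 * A22 - A12^2
  det[det == 0] <- Inf
  tx_h <- (A22 * r1 - A12 * r2) / det
  ty_h <- (A11 * r2 - A12 * r1) / det
  tx_h[1, 1] <- 0
  ty_h[1, 1] <- 0
  n <- length(u_h)
  tx <- Re(fft(tx_h, inverse = TRUE)) / n
  ty <- Re(fft(ty_h, inverse = TRUE)) / n
  if (pad) {
    tx <- tx[seq_len(nr0), seq_len(nc0)]
    ty <- ty[seq_len(nr0), seq_len(nc0)]
  }
  traction_map(tx = tx, ty = ty, spacing_um = h)
}

# Extend a matrix to double extent: the added margin carries the edge values
# tapered to zero with a half-cosine, leaving no wrap-around discontinuity.
taper_pad <- function(M) {
  nr <- nrow(M)
  nc <- ncol(M)
  out <- matrix(0, 2 * nr, 2 * nc)
  out[seq_len(nr), seq_len(nc)] <- M
  ramp_r <- 0.5 * (1 + cos(pi * seq_len(nr) / nr))
  ramp_c <- 0.5 * (1 + cos(pi * seq_len(nc) / nc))
  # wrap-aware taper: margin interpolates between opposite edges
  for (i in seq_len(nr)) {
    w <- ramp_r[i]
    out[nr + i, seq_len(nc)] <- M[nr, ] * w + M[1, ] * (1 - w)
  }
  for (j in seq_len(nc)) {
    w <- ramp_c[j]
    out[, nc + j] <- out[, nc] * w + out[, 1] * (1 - w)
  }
  out
}

#' Fill invalid nodes of a displacement field by neighbour interpolation
#'
#' Iteratively replaces invalid nodes with the mean of their valid 8-neighbour
#' values until the field is complete (bilinear-equivalent for isolated gaps).
#'
#' @param field A [displacement_field()].
#' @return A complete field with `valid` all `TRUE`.
#' @export
fill_field_gaps <- function(field) {
  u <- field$u
  v <- field$v
  ok <- field$valid & is.finite(u) & is.finite(v)
  u[!ok] <- NA
  v[!ok] <- NA
  for (pass in seq_len(64)) {
    miss <- which(is.na(u), arr.ind = TRUE)
    if (!nrow(miss)) break
    nr <- nrow(u)
    nc <- ncol(u)
    for (m in seq_len(nrow(miss))) {
      i <- miss[m, 1]
      j <- miss[m, 2]
      ii <- max(1, i - 1):min(nr, i + 1)
      jj <- max(1, j - 1):min(nc, j + 1)
      nu <- u[ii, jj]
      nv <- v[ii, jj]
      if (any(is.finite(nu))) {
        u[i, j] <- mean(nu, na.rm = TRUE)
        v[i, j] <- mean(nv, na.rm = TRUE)
      }
    }
  }
  u[is.na(u)] <- 0
  v[is.na(v)] <- 0
  displacement_field(u, v, field$spacing_um)
}

#' Estimate a bead displacement field by window correlation (PIV)
#'
#' Normalized cross-correlation of interrogation windows between a deformed
#' bead image and its cell-free reference, with Gaussian/parabolic subpixel
#' peak refinement and a normalized-median outlier test (outliers replaced
#' by the local median and flagged invalid).
#'
#' @param image Deformed bead frame (matrix, rows = y).
#' @param reference Reference (relaxed substrate) frame, same size.
#' @param window_px Interrogation window size (default 32, must be >= 8).
#' @param spacing_px Node spacing (default 8).
#' @param pixel_size_um Pixel size, um (default 0.2).
#' @param max_shift_px Largest admissible shift (default `window_px / 4`).
#' @param passes Correlation passes (default 2). The second pass re-centers
#'   the interrogation windows symmetrically around the first-pass
#'   displacement (central window offset), cancelling the first-order bias
#'   that displacement gradients across a window otherwise induce.
#' @return A [displacement_field()] in um, spacing `spacing_px * pixel_size_um`.
#' @export
estimate_displacement_field <- function(image, reference, window_px = 32,
                                        spacing_px = 8, pixel_size_um = 0.2,
                                        max_shift_px = window_px / 4,
                                        passes = 2) {
  stopifnot(all(dim(image) == dim(reference)))
  if (window_px < 8) abort("`window_px` must be >= 8.")
  nr <- nrow(image)
  nc <- ncol(image)
  half <- window_px / 2
  ys <- seq(half + 1, nr - half, by = spacing_px)
  xs <- seq(half + 1, nc - half, by = spacing_px)
  u <- matrix(NA_real_, length(ys), length(xs))
  v <- matrix(NA_real_, length(ys), length(xs))
  valid <- matrix(FALSE, length(ys), length(xs))

  grab <- function(M, cy, cx) {
    rows <- (cy - half):(cy + half - 1)
    cols <- (cx - half):(cx + half - 1)
    if (rows[1] < 1 || cols[1] < 1 || rows[length(rows)] > nr ||
          cols[length(cols)] > nc) {
      return(NULL)
    }
    M[rows, cols]
  }

  for (iy in seq_along(ys)) {
    for (ix in seq_along(xs)) {
      w_ref <- grab(reference, ys[iy], xs[ix])
      w_img <- grab(image, ys[iy], xs[ix])
      pk <- correlation_peak(w_ref, w_img, max_shift_px)
      if (!is.null(pk)) {
        u[iy, ix] <- pk["dx"]
        v[iy, ix] <- pk["dy"]
        valid[iy, ix] <- TRUE
      }
    }
  }
  st <- normalized_median_filter(u, v, valid)

  # image-deformation iterations: warp the deformed image back by the
  # current field estimate and correlate the residual, so displacement
  # gradients within an interrogation window no longer bias the estimate
  for (pass in seq_len(max(0, passes - 1))) {
    u_fill <- fill_matrix_na(st$u)
    v_fill <- fill_matrix_na(st$v)
    warped <- warp_image(image, u_fill, v_fill, ys[1], xs[1], spacing_px)
    u2 <- st$u
    v2 <- st$v
    for (iy in seq_along(ys)) {
      for (ix in seq_along(xs)) {
        if (is.na(u_fill[iy, ix])) next
        w_ref <- grab(reference, ys[iy], xs[ix])
        w_img <- grab(warped, ys[iy], xs[ix])
        pk <- correlation_peak(w_ref, w_img, 3)
        if (!is.null(pk)) {
          u2[iy, ix] <- u_fill[iy, ix] + pk["dx"]
          v2[iy, ix] <- v_fill[iy, ix] + pk["dy"]
        }
      }
    }
    st <- normalized_median_filter(u2, v2, st$valid | !is.na(u2))
  }

  displacement_field(st$u * pixel_size_um, st$v * pixel_size_um,
                     spacing_px * pixel_size_um, valid = st$valid)
}

# Replace NA entries by the mean of available 8-neighbours (iterated).
fill_matrix_na <- function(M) {
  for (pass in seq_len(32)) {
    miss <- which(is.na(M), arr.ind = TRUE)
    if (!nrow(miss)) break
    for (k in seq_len(nrow(miss))) {
      i <- miss[k, 1]
      j <- miss[k, 2]
      nb <- M[max(1, i - 1):min(nrow(M), i + 1),
              max(1, j - 1):min(ncol(M), j + 1)]
      if (any(is.finite(nb))) M[i, j] <- mean(nb, na.rm = TRUE)
    }
  }
  M
}

# Sample `image` at x + u(x) (pixel-unit displacement field on the PIV node
# grid, bilinearly interpolated over pixels): beads move back onto their
# reference positions where the field estimate is accurate.
warp_image <- function(image, u_px, v_px, y0, x0, spacing_px) {
  nr <- nrow(image)
  nc <- ncol(image)
  xp <- rep(seq_len(nc), each = nr)
  yp <- rep(seq_len(nr), nc)
  gx <- (xp - x0) / spacing_px + 1
  gy <- (yp - y0) / spacing_px + 1
  gx <- pmin(pmax(gx, 1), ncol(u_px))
  gy <- pmin(pmax(gy, 1), nrow(u_px))
  x0i <- pmin(floor(gx), ncol(u_px) - 1L)
  y0i <- pmin(floor(gy), nrow(u_px) - 1L)
  fx <- gx - x0i
  fy <- gy - y0i
  bilin <- function(G) {
    G[cbind(y0i, x0i)] * (1 - fx) * (1 - fy) +
      G[cbind(y0i, x0i + 1)] * fx * (1 - fy) +
      G[cbind(y0i + 1, x0i)] * (1 - fx) * fy +
      G[cbind(y0i + 1, x0i + 1)] * fx * fy
  }
  sx <- xp + bilin(u_px)
  sy <- yp + bilin(v_px)
  sx <- pmin(pmax(sx, 1), nc)
  sy <- pmin(pmax(sy, 1), nr)
  xs0 <- pmin(floor(sx), nc - 1L)
  ys0 <- pmin(floor(sy), nr - 1L)
  wx <- sx - xs0
  wy <- sy - ys0
  vals <- image[cbind(ys0, xs0)] * (1 - wx) * (1 - wy) +
    image[cbind(ys0, xs0 + 1)] * wx * (1 - wy) +
    image[cbind(ys0 + 1, xs0)] * (1 - wx) * wy +
    image[cbind(ys0 + 1, xs0 + 1)] * wx * wy
  matrix(vals, nr, nc)
}

# Circular cross-correlation peak of two windows with subpixel refinement.
# Returns c(dx, dy): shift of `img` content relative to `ref`.
correlation_peak <- function(ref, img, max_shift) {
  ref <- ref - mean(ref)
  img <- img - mean(img)
  s_ref <- sqrt(sum(ref^2))
  s_img <- sqrt(sum(img^2))
  if (s_ref < 1e-9 || s_img < 1e-9) return(NULL) # flat window: no beads
  n <- nrow(ref)
  cc <- Re(fft(Conj(fft(ref)) * fft(img), inverse = TRUE)) / length(ref)
  cc <- cc / (s_ref * s_img)
  # admissible circular shifts
  shift_of <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  dy_all <- shift_of(seq_len(n), n)
  dx_all <- shift_of(seq_len(ncol(ref)), ncol(ref))
  mask <- outer(abs(dy_all) <= max_shift, abs(dx_all) <= max_shift, "&")
  cc_m <- ifelse(mask, cc, -Inf)
  pk <- which(cc_m == max(cc_m), arr.ind = TRUE)[1, ]
  dy0 <- dy_all[pk[1]]
  dx0 <- dx_all[pk[2]]

  refine_subpixel_ncc(ref, img, dx0, dy0)
}

# Subpixel refinement around an integer peak by Fourier upsampling of the
# exact (zero-padded, non-circular) normalized cross-correlation of a
# shrunken template against the full window. The NCC with per-shift local
# mean and energy attains its maximum at the true displacement for a rigid
# shift (Cauchy-Schwarz), so locating the max of its band-limited
# interpolant avoids the shape-model bias of 3-point peak fits.
refine_subpixel_ncc <- function(ref, img, dx0, dy0) {
  n <- nrow(ref)
  N <- 2L * n
  m <- min(max(abs(dx0), abs(dy0)) + 2, floor(n / 4))
  tpl <- ref[(1 + m):(n - m), (1 + m):(n - m)]
  tpl <- tpl - mean(tpl)
  s_tpl <- sqrt(sum(tpl^2))
  if (s_tpl < 1e-9) return(NULL)
  tp <- matrix(0, N, N)
  tp[(1 + m):(n - m), (1 + m):(n - m)] <- tpl
  sup <- matrix(0, N, N)
  sup[(1 + m):(n - m), (1 + m):(n - m)] <- 1
  ip <- matrix(0, N, N)
  ip[1:n, 1:n] <- img
  n_t <- sum(sup)

  S <- Conj(fft(tp)) * fft(ip)
  Fs <- Conj(fft(sup))
  SM <- Fs * fft(ip)
  SQ <- Fs * fft(ip^2)
  ks <- c(0:(N / 2), (-N / 2 + 1):(-1))

  ncc_grid <- function(sx, sy) {
    Wy <- exp(1i * 2 * pi * outer(ks, sy) / N)
    Wx <- exp(1i * 2 * pi * outer(ks, sx) / N)
    up <- function(Sp) Re(t(Wy) %*% Sp %*% Wx) / N^2
    Cf <- up(S)
    Mf <- up(SM)
    Qf <- up(SQ)
    varf <- Qf - Mf^2 / n_t
    varf[varf < 1e-12] <- Inf
    Cf / (s_tpl * sqrt(varf))
  }
  # two-stage zoom: 0.05 px then 0.005 px
  sx1 <- seq(dx0 - 1, dx0 + 1, by = 0.05)
  sy1 <- seq(dy0 - 1, dy0 + 1, by = 0.05)
  g1 <- ncc_grid(sx1, sy1)
  # guard against interpolation ripple on (near-)identical content: if the
  # integer-lag correlation is already essentially perfect, refinement is
  # meaningless and its ripple would inject false subpixel motion
  ncc0 <- g1[which(abs(sy1 - dy0) < 1e-9), which(abs(sx1 - dx0) < 1e-9)]
  if (max(g1) - ncc0 < 1e-4) return(c(dx = dx0, dy = dy0))
  pk1 <- which(g1 == max(g1), arr.ind = TRUE)[1, ]
  p1 <- c(sx1[pk1[2]], sy1[pk1[1]])
  sx2 <- seq(p1[1] - 0.05, p1[1] + 0.05, by = 0.005)
  sy2 <- seq(p1[2] - 0.05, p1[2] + 0.05, by = 0.005)
  g2 <- ncc_grid(sx2, sy2)
  pk2 <- which(g2 == max(g2), arr.ind = TRUE)[1, ]
  c(dx = sx2[pk2[2]], dy = sy2[pk2[1]])
}

# Westerweel-style normalized median test; outliers replaced by the local
# median and marked invalid.
normalized_median_filter <- function(u, v, valid, threshold = 2, eps = 0.1) {
  nr <- nrow(u)
  nc <- ncol(u)
  test_one <- function(M) {
    res <- matrix(FALSE, nr, nc)
    med <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        ii <- max(1, i - 1):min(nr, i + 1)
        jj <- max(1, j - 1):min(nc, j + 1)
        ctr <- M[i, j]
        nb_idx <- expand.grid(ii = ii, jj = jj)
        nb_idx <- nb_idx[!(nb_idx$ii == i & nb_idx$jj == j), ]
        nb_o <- M[cbind(nb_idx$ii, nb_idx$jj)]
        nb_o <- nb_o[!is.na(nb_o)]
        if (length(nb_o) < 3 || is.na(ctr)) next
        m <- median(nb_o)
        r <- median(abs(nb_o - m))
        med[i, j] <- m
        if (abs(ctr - m) / (r + eps) > threshold) res[i, j] <- TRUE
      }
    }
    list(out = res, med = med)
  }
  tu <- test_one(u)
  tv <- test_one(v)
  bad <- (tu$out | tv$out) & valid
  u[bad] <- tu$med[bad]
  v[bad] <- tv$med[bad]
  valid[bad] <- FALSE
  list(u = u, v = v, valid = valid)
}

#' Gaussian smoothing of a displacement field on its node grid
#'
#' Standard post-filtering of a correlation-estimated field before traction
#' reconstruction: node-level estimation jitter is broadband and is
#' amplified by the inverse elastic operator in proportion to the
#' wavenumber, while genuine substrate displacement is smooth on the scale
#' of several nodes, so a light low-pass acts almost entirely on the noise.
#'
#' @param field A [displacement_field()].
#' @param sigma_nodes Gaussian SD in node units (default 1; 0 is a no-op).
#' @return The smoothed [displacement_field()].
#' @export
smooth_displacement_field <- function(field, sigma_nodes = 1) {
  stopifnot(inherits(field, "displacement_field"))
  if (sigma_nodes <= 0) return(field)
  if (any(!field$valid)) field <- fill_field_gaps(field)
  r <- ceiling(3 * sigma_nodes)
  k <- dnorm(-r:r, 0, sigma_nodes)
  k <- k / sum(k)
  sm1 <- function(M) {
    pad <- function(v) c(rep(v[1], r), v, rep(v[length(v)], r))
    out <- M
    for (i in seq_len(nrow(M))) {
      out[i, ] <- stats::filter(pad(M[i, ]), k)[(r + 1):(r + ncol(M))]
    }
    for (j in seq_len(ncol(M))) {
      out[, j] <- stats::filter(pad(out[, j]), k)[(r + 1):(r + nrow(M))]
    }
    out
  }
  displacement_field(sm1(field$u), sm1(field$v), field$spacing_um,
                     valid = field$valid)
}

#' Mean traction magnitude within a region
#'
#' @param map A [traction_map()].
#' @param mask Logical matrix matching the map grid.
#' @return Mean traction magnitude (Pa) over the masked nodes.
#' @export
mean_traction_in_region <- function(map, mask) {
  stopifnot(inherits(map, "traction_map"))
  if (!any(mask)) abort("region mask is empty.")
  mean(map$magnitude[mask])
}
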