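# Shared fixture builders (everything is generated in code at test time).

# Stack a list of matrices into an image_stack (frame-major array).
mk_stack <- function(frames, pixel_size_um = 0.2, frame_interval_s = 10,
                     channel = "test") {
  arr <- array(0, c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
  image_stack(arr, pixel_size_um, frame_interval_s, channel)
}

# Rasterized disk mask.
mk_disk <- function(r_px, n = 128, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  jj <- matrix(seq_len(n), n, n, byrow = TRUE)
  ii <- matrix(seq_len(n), n, n)
  sqrt((ii - cy)^2 + (jj - cx)^2) <= r_px
}

# Wrap logical frames into a cell_mask_stack.
mk_mask_stack <- function(masks, pixel_size_um = 0.2, frame_interval_s = 10) {
  arr <- array(FALSE, c(length(masks), nrow(masks[[1]]), ncol(masks[[1]])))
  for (t in seq_along(masks)) arr[t, , ] <- masks[[t]]
  structure(list(data = arr, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 failed = rep(FALSE, length(masks))),
            class = "cell_mask_stack")
}

# Random bead-like test image (Gaussian spots) for registration tests.
mk_spot_image <- function(n = 96, n_spots = 150, sigma = 1.5, seed = 2) {
  set.seed(seed)
  img <- matrix(0, n, n)
  for (k in seq_len(n_spots)) {
    x <- runif(1, 10, n - 10)
    y <- runif(1, 10, n - 10)
    jj <- floor(x - 4):ceiling(x + 4)
    ii <- floor(y - 4):ceiling(y + 4)
    img[ii, jj] <- img[ii, jj] +
      outer(exp(-0.5 * ((ii - y) / sigma)^2), exp(-0.5 * ((jj - x) / sigma)^2))
  }
  img
}

# Half-cosine single-event displacement series sampled at dt; the series
# spans exactly the event (no flat padding).
mk_halfcos_series <- function(amplitude_um, duration_s, dt_s = 10) {
  t <- seq(0, duration_s, by = dt_s)
  amplitude_um * 0.5 * (1 - cos(pi * t / duration_s))
}

# Smooth zero-net Gaussian traction dipole on an n x n node grid.
mk_dipole <- function(n, amp = 500, sigma = 8, spacing_um = 1.6,
                      sep = 8) {
  xg <- 0:(n - 1)
  g <- function(cx, cy) {
    outer(xg, xg, function(i, j) exp(-((i - cy)^2 + (j - cx)^2) / (2 * sigma^2)))
  }
  tx <- amp * g(n / 2 - sep, n / 2) - amp * g(n / 2 + sep, n / 2)
  tx <- tx - mean(tx)
  traction_map(tx, matrix(0, n, n), spacing_um)
}

# Interpolate a node-grid matrix at pixel positions (for truth comparison).
interp_nodes <- function(G, spacing_px, xs_px, ys_px) {
  outer(ys_px, xs_px, function(y, x) {
    edgeforce:::interp_grid(G, spacing_px, x, y)
  })
}
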