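test_that("zero displacement reconstructs zero traction and vice versa", {
  z <- matrix(0, 16, 16)
  par <- elastic_params()
  tr <- fttc_inverse(displacement_field(z, z, 1.6), par)
  expect_equal(max(tr$magnitude), 0)
  u <- fttc_forward(traction_map(z, z, 1.6), par)
  expect_equal(max(abs(u$u)), 0)
})

test_that("the forward/inverse operators are linear and scale with 1/E", {
  tm <- mk_dipole(32, amp = 300, sigma = 5)
  par0 <- elastic_params(6900, 0.5, reg_lambda = 0)
  u <- fttc_forward(tm, par0)
  rec1 <- fttc_inverse(u, par0, pad = FALSE)
  rec2 <- fttc_inverse(displacement_field(2 * u$u, 2 * u$v, u$spacing_um),
                       par0, pad = FALSE)
  expect_equal(rec2$tx, 2 * rec1$tx, tolerance = 1e-9)
  u_half_e <- fttc_forward(tm, elastic_params(3450, 0.5))
  expect_equal(u_half_e$u, 2 * u$u, tolerance = 1e-12)
})

test_that("the periodic forward-inverse round trip is exact without regularization", {
  tm <- mk_dipole(32, amp = 300, sigma = 5)
  par0 <- elastic_params(6900, 0.5, reg_lambda = 0)
  rec <- fttc_inverse(fttc_forward(tm, par0), par0, pad = FALSE)
  rel <- sqrt(mean((rec$tx - tm$tx)^2 + (rec$ty - tm$ty)^2)) /
    sqrt(mean(tm$tx^2 + tm$ty^2))
  expect_lt(rel, 1e-4)
})

test_that("a point +x traction yields a u-field mirror-symmetric about its row", {
  n <- 32
  tx <- matrix(0, n, n)
  tx[17, 17] <- 100
  u <- fttc_forward(traction_map(tx, matrix(0, n, n), 1.6), elastic_params())
  above <- u$u[17 + 1:6, 17]
  below <- u$u[17 - 1:6, 17]
  expect_equal(above, below, tolerance = 1e-9)
})

test_that("increasing regularization never increases total traction power", {
  tm <- mk_dipole(32, amp = 300, sigma = 5)
  u <- fttc_forward(tm, elastic_params())
  pow <- vapply(c(0, 0.01, 0.05, 0.2, 1), function(l) {
    sum(fttc_inverse(u, elastic_params(6900, 0.5, l))$magnitude^2)
  }, numeric(1))
  expect_true(all(diff(pow) <= 1e-9))
})

test_that("net force vanishes under the zero-DC convention", {
  tm <- mk_dipole(32, amp = 300, sigma = 5)
  u <- fttc_forward(tm, elastic_params())
  rec <- fttc_inverse(u, elastic_params(), pad = FALSE)
  expect_lt(abs(sum(rec$tx)) + abs(sum(rec$ty)), 1e-6 * sum(rec$magnitude))
})

test_that("PIV recovers an injected integer shift in physical units", {
  cfg <- synth_config(seed = 3)
  fld <- displacement_field(matrix(3 * 0.2, 16, 16), matrix(0, 16, 16), 1.6)
  bp <- make_bead_pair(cfg, image_px = 128, displacement = fld)
  df <- estimate_displacement_field(bp$deformed, bp$reference,
                                    window_px = 32, spacing_px = 8,
                                    pixel_size_um = 0.2, passes = 1)
  expect_equal(mean(df$u), 0.6, tolerance = 0.01)
  expect_equal(mean(abs(df$v)), 0, tolerance = 0.01)
})

test_that("an image identical to its reference yields a zero field", {
  cfg <- synth_config(seed = 4)
  bp <- make_bead_pair(cfg, image_px = 96)
  df <- estimate_displacement_field(bp$deformed, bp$reference,
                                    window_px = 32, spacing_px = 8)
  expect_lt(max(abs(c(df$u, df$v))), 1e-6)
})

test_that("a flat (bead-free) window is flagged invalid", {
  cfg <- synth_config(seed = 4)
  bp <- make_bead_pair(cfg, image_px = 128)
  img <- bp$reference
  img[40:90, 40:90] <- 0
  ref <- bp$reference
  ref[40:90, 40:90] <- 0
  df <- estimate_displacement_field(img, ref, window_px = 32, spacing_px = 8,
                                    passes = 1)
  expect_true(any(!df$valid))
})

test_that("PIV on a rendered smooth field stays below 0.1 px RMS", {
  tm <- mk_dipole(40, amp = 350, sigma = 6, spacing_um = 1.6)
  cfg <- synth_config(seed = 11)
  bp <- make_bead_pair(cfg, image_px = 320, traction = tm, grid_spacing_px = 8)
  df <- estimate_displacement_field(bp$deformed, bp$reference,
                                    window_px = 32, spacing_px = 8,
                                    pixel_size_um = 0.2)
  ys <- seq(17, 320 - 16, by = 8)
  UT <- interp_nodes(bp$true_displacement$u, 8, ys, ys)
  VT <- interp_nodes(bp$true_displacement$v, 8, ys, ys)
  rms_px <- sqrt(mean((df$u - UT)^2 + (df$v - VT)^2)) / 0.2
  expect_lt(rms_px, 0.1)
})

test_that("gap filling interpolates invalid nodes from their neighbours", {
  u <- matrix(1, 8, 8)
  valid <- matrix(TRUE, 8, 8)
  u[4, 4] <- 999
  valid[4, 4] <- FALSE
  filled <- fill_field_gaps(displacement_field(u, u, 1.6, valid))
  expect_equal(filled$u[4, 4], 1)
  expect_true(all(filled$valid))
})

test_that("mean traction in a region follows closed-form values", {
  m <- matrix(100, 8, 8)
  tm <- traction_map(m, matrix(0, 8, 8), 1.6)
  expect_equal(mean_traction_in_region(tm, matrix(TRUE, 8, 8)), 100)
  half <- matrix(c(rep(0, 32), rep(200, 32)), 8, 8)
  tm2 <- traction_map(half, matrix(0, 8, 8), 1.6)
  expect_equal(mean_traction_in_region(tm2, matrix(TRUE, 8, 8)), 100)
  expect_error(mean_traction_in_region(tm, matrix(FALSE, 8, 8)), "empty")
})

test_that("reconstruction is consistent across grid resolutions on smooth fields", {
  # same physical dipole sampled at h and h/2; exact displacement input
  par <- elastic_params(6900, 0.5, 0.005)
  tm1 <- mk_dipole(32, amp = 300, sigma = 4, spacing_um = 3.2, sep = 4)
  tm2 <- mk_dipole(64, amp = 300, sigma = 8, spacing_um = 1.6, sep = 8)
  r1 <- fttc_inverse(fttc_forward(tm1, par), par, pad = FALSE)
  r2 <- fttc_inverse(fttc_forward(tm2, par), par, pad = FALSE)
  coarse <- r2$magnitude[seq(1, 63, by = 2), seq(1, 63, by = 2)]
  rel <- sqrt(mean((coarse - r1$magnitude)^2)) / sqrt(mean(r1$magnitude^2))
  expect_lt(rel, 0.15)
})
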