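test_that("identical config and seed reproduce the table bit-for-bit", {
  cfg <- synth_config(n_sectors = 4, n_frames = 60, n_depths = 2, seed = 7)
  a <- make_window_series(cfg)
  b <- make_window_series(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$event_schedule, b$truth$event_schedule)
})

test_that("noise seed varies noise while the schedule seed pins the biology", {
  base <- synth_config(n_sectors = 4, n_frames = 60, n_depths = 1, seed = 7)
  alt <- synth_config(n_sectors = 4, n_frames = 60, n_depths = 1, seed = 7,
                      noise_seed = 991L)
  a <- make_window_series(base)
  b <- make_window_series(alt)
  expect_identical(a$truth$event_schedule, b$truth$event_schedule)
  expect_false(identical(a$table$rac1, b$table$rac1))
})

test_that("a noiseless scheduled protrusion produces an exact monotone ramp", {
  sched <- tibble::tibble(sector = 1L, type = "protrusion", onset_s = 100,
                          vmax_s = 160, end_s = 220, amplitude_um = 2)
  cfg <- synth_config(n_sectors = 1, n_frames = 40, n_depths = 1,
                      noise_sd = 0, seed = 1)
  sim <- make_window_series(cfg, schedule = sched)
  d <- sim$table$displacement_um
  expect_true(all(diff(d) >= 0))
  expect_equal(max(d) - min(d), 2)
  # velocity telescopes back to displacement
  dt <- 10
  expect_equal(d[1] + cumsum(sim$table$velocity_um_per_s[-length(d)]) * dt,
               d[-1], tolerance = 1e-12)
})

test_that("with zero noise every generated signal equals its ground truth", {
  cfg <- synth_config(n_sectors = 3, n_frames = 80, n_depths = 1,
                      noise_sd = 0, seed = 12)
  sim <- make_window_series(cfg)
  tab <- dplyr::arrange(sim$table, sector, frame)
  tru <- dplyr::arrange(sim$truth$true_signals, sector, frame)
  prof <- sim$truth$depth_profiles
  expect_equal(tab$displacement_um, tru$displacement_um, tolerance = 1e-12)
  expect_equal(tab$rac1 - 1, prof$gtpase[1] * (tru$rac1 - 1), tolerance = 1e-12)
  expect_equal(tab$traction_pa - 100, prof$force[1] * (tru$traction_pa - 100),
               tolerance = 1e-12)
})

test_that("per-sector cumulative displacement equals the sum of signed amplitudes", {
  cfg <- synth_config(n_sectors = 6, n_frames = 150, n_depths = 1,
                      noise_sd = 0, seed = 3)
  sim <- make_window_series(cfg)
  final <- sim$table |>
    dplyr::group_by(sector) |>
    dplyr::summarise(d = displacement_um[dplyr::n()], .groups = "drop")
  sched <- sim$truth$event_schedule |>
    dplyr::group_by(sector) |>
    dplyr::summarise(a = sum(amplitude_um), .groups = "drop")
  joined <- dplyr::left_join(final, sched, by = "sector")
  joined$a[is.na(joined$a)] <- 0
  expect_equal(joined$d, joined$a, tolerance = 1e-9)
})

test_that("the force series is the Rac1 series delayed by the configured lag", {
  sched <- tibble::tibble(sector = 1L, type = "protrusion", onset_s = 150,
                          vmax_s = 210, end_s = 270, amplitude_um = 2)
  cfg <- synth_config(n_sectors = 1, n_frames = 50, n_depths = 1,
                      noise_sd = 0, rac1_to_force_lag_s = 40, seed = 1)
  sim <- make_window_series(cfg, schedule = sched)
  tru <- sim$truth$true_signals
  shift <- 4 # 40 s / 10 s
  f <- (tru$traction_pa - 100) / cfg$force_coupling
  r <- tru$rac1 - 1
  n <- length(f)
  expect_equal(f[(shift + 1):n], r[1:(n - shift)], tolerance = 1e-12)
})

test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(n_frames = 1), "n_frames")
  expect_error(synth_config(n_sectors = 0), "n_sectors")
  expect_error(synth_config(poisson_ratio = 0.7), "poisson_ratio")
  expect_error(synth_config(frame_interval_s = 0), "frame_interval_s")
  cfg <- synth_config(bead_density_per_um2 = -1)
  expect_error(make_bead_pair(cfg, image_px = 64), "bead_density")
})

test_that("zero traction leaves the bead pair identical", {
  cfg <- synth_config(seed = 5, n_frames = 2)
  bp <- make_bead_pair(cfg, image_px = 96)
  expect_equal(bp$reference, bp$deformed, tolerance = 1e-12)
})

test_that("a rigid injected displacement moves every bead by the same vector", {
  cfg <- synth_config(seed = 5, n_frames = 2)
  fld <- displacement_field(matrix(0.3, 12, 12), matrix(-0.1, 12, 12),
                            spacing_um = 1.6)
  bp <- make_bead_pair(cfg, image_px = 96, displacement = fld)
  expect_equal(unique(round(bp$beads$dx_px, 9)), 0.3 / 0.2)
  expect_equal(unique(round(bp$beads$dy_px, 9)), -0.1 / 0.2)
})

test_that("perturbation dataset tags events with their activation offset", {
  cfg <- synth_config(frame_interval_s = 5, n_frames = 160, n_depths = 1,
                      noise_sd = 0.2, seed = 8)
  pd <- make_perturbation_dataset(cfg, offsets_s = c(-10, -15), effect = 0.02,
                                  n_control = 20, n_per_group = 10)
  expect_setequal(unique(pd$truth$perturbed_schedule$offset_group), c(-10, -15))
  expect_equal(nrow(pd$truth$perturbed_schedule), 20)
  # control events all end before the activation time
  expect_true(all(pd$truth$control_schedule$end_s < pd$truth$t_act_s))
})

test_that("the injected effect is exactly an additive velocity step after activation", {
  cfg <- synth_config(frame_interval_s = 5, n_frames = 160, n_depths = 1,
                      noise_sd = 0.2, seed = 8)
  pd0 <- make_perturbation_dataset(cfg, offsets_s = c(-10), effect = 0,
                                   n_control = 10, n_per_group = 10)
  pd2 <- make_perturbation_dataset(cfg, offsets_s = c(-10), effect = 0.02,
                                   n_control = 10, n_per_group = 10)
  expect_identical(pd0$control, pd2$control)
  after <- pd0$perturbed$time_s >= pd0$truth$t_act_s
  expect_equal(pd2$perturbed$velocity_um_per_s[after],
               pd0$perturbed$velocity_um_per_s[after] + 0.02,
               tolerance = 1e-12)
  expect_equal(pd2$perturbed$velocity_um_per_s[!after],
               pd0$perturbed$velocity_um_per_s[!after], tolerance = 1e-12)
})
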