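test_that("smoothing spline limits: interpolation at p = 1, straight line as p -> 0", {
  set.seed(1)
  t <- seq(0, 300, by = 10)
  y <- rnorm(length(t))
  expect_equal(smooth_series(y, p = 1, time = t), y, tolerance = 1e-9)
  line <- unname(stats::lm(y ~ t)$fitted.values)
  expect_equal(smooth_series(y, p = 1e-9, time = t), line, tolerance = 1e-2)
})

test_that("a straight ramp passes through the spline unchanged at any p", {
  t <- seq(0, 300, by = 10)
  ramp <- 0.5 + 0.02 * t
  for (p in c(0.1, 0.5, 0.9)) {
    expect_equal(smooth_series(ramp, p = p, time = t), ramp, tolerance = 1e-6)
  }
})

test_that("spline output matches stats::smooth.spline at a matched lambda", {
  # independent reference: smooth.spline solves the same penalized problem
  set.seed(4)
  t <- seq_len(50) - 1
  y <- sin(t / 5) + rnorm(50, 0, 0.3)
  p <- 0.3
  ours <- smooth_series(y, p = p, time = t)
  # smooth.spline's lambda is on x scaled to [0,1]: integral penalty rescales
  # by (range)^3 relative to our parameterization
  lam <- (1 - p) / p / diff(range(t))^3
  ref <- stats::smooth.spline(t, y, lambda = lam, all.knots = TRUE,
                              keep.stuff = FALSE)
  expect_equal(ours, predict(ref, t)$y, tolerance = 1e-3)
})

test_that("sinusoidal displacement yields full-period events with closed-form properties", {
  t <- seq(0, 480, by = 10)
  x <- 2 * sin(2 * pi * t / 240)
  ev <- detect_events(x, dt_s = 10)
  full <- ev[ev$duration_s == 120, ]
  expect_equal(nrow(full), 3)
  expect_equal(unique(full$distance_um), 4)
  # Vmax at the zero crossings (extremal slope)
  expect_equal(full$vmax_frame, c(12, 24, 36))
  # peak speed close to the analytic 2 * 2*pi/240
  v <- edgeforce:::central_diff(x, 10)
  expect_lt(abs(max(abs(v[full$vmax_frame + 1])) - 2 * 2 * pi / 240), 0.002)
})

test_that("distance and duration filters discard exactly the printed thresholds", {
  t <- seq(0, 480, by = 10)
  # peak-to-peak 0.8 um < 1 um: everything discarded
  ev_small <- detect_events(0.4 * sin(2 * pi * t / 240), dt_s = 10)
  expect_equal(nrow(ev_small), 0)
  # 80-s period: 40-s phases < 1 min discarded
  ev_fast <- detect_events(2 * sin(2 * pi * t / 80), dt_s = 10)
  expect_equal(nrow(ev_fast), 0)
  # boundary cases retained under the >= convention
  keep <- detect_events(mk_halfcos_series(1, 60), dt_s = 10)
  expect_equal(nrow(keep), 1)
})

test_that("a monotone drift below 1 um yields no events", {
  x <- seq(0, 0.8, length.out = 30)
  expect_equal(nrow(detect_events(x, dt_s = 10)), 0)
})

test_that("raising the distance threshold never increases retained events", {
  set.seed(9)
  x <- cumsum(rnorm(200, 0, 0.3))
  n_kept <- vapply(c(0.5, 1, 2, 4), function(th) {
    nrow(detect_events(smooth_series(x, 0.5), dt_s = 10, min_distance_um = th))
  }, numeric(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("retained and discarded phases tile the timeline without overlap", {
  set.seed(9)
  x <- smooth_series(cumsum(rnorm(200, 0, 0.3)), 0.5)
  ev <- detect_events(x, dt_s = 10, min_distance_um = 0, min_duration_s = 0)
  ev <- ev[order(ev$onset_frame), ]
  if (nrow(ev) > 1) {
    expect_true(all(ev$onset_frame[-1] >= ev$end_frame[-nrow(ev)]))
  }
  expect_true(all(ev$onset_frame < ev$vmax_frame | ev$duration_s == 0 |
                    ev$vmax_frame <= ev$end_frame))
})

test_that("z-normalization is affine-invariant and flags degenerate series", {
  set.seed(2)
  x <- rnorm(30)
  z <- znormalize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(znormalize(3 * x + 7), z, tolerance = 1e-12)
  zc <- znormalize(rep(5, 10))
  expect_true(all(is.na(zc)))
  expect_true(isTRUE(attr(zc, "degenerate")))
})

test_that("a single event's ensemble mean is that event's slab", {
  cfg <- synth_config(n_sectors = 1, n_frames = 60, n_depths = 2,
                      noise_sd = 0, seed = 1)
  sched <- tibble::tibble(sector = 1L, type = "protrusion", onset_s = 250,
                          vmax_s = 310, end_s = 370, amplitude_um = 2)
  sim <- make_window_series(cfg, schedule = sched)
  ev <- detect_events_table(sim$table)
  ens <- align_ensembles(sim$table, ev, "rac1", "protrusion_onset")
  expect_equal(ens$n_events, 1)
  expect_equal(ens$mean, ens$data[1, , ], tolerance = 1e-12)
  # relative time 0 is the anchor's own frame
  i0 <- which(ens$rel_time_s == 0)
  d2 <- sim$table[sim$table$depth == 2, ]
  expect_equal(ens$mean[2, i0], d2$rac1[d2$frame == ev$onset_frame[1]])
})

test_that("ensemble means locate the generator's Rac1 anchors", {
  cfg <- synth_config(n_sectors = 60, n_frames = 181, n_depths = 2,
                      noise_sd = 1, seed = 77)
  sim <- make_window_series(cfg)
  ev <- detect_events_table(sim$table)
  z <- znormalize_table(sim$table)
  ens_on <- align_ensembles(z, ev, "rac1", "protrusion_onset", depths = 2)
  expect_lte(abs(ens_on$rel_time_s[which.max(ens_on$mean[1, ])] + 40), 10)
  ens_vm <- align_ensembles(z, ev, "rac1", "protrusion_vmax", depths = 2)
  expect_lte(abs(ens_vm$rel_time_s[which.min(ens_vm$mean[1, ])]), 10)
})

test_that("bootstrap CI collapses for identical events and is seed-reproducible", {
  dat <- array(rep(sin(seq(0, 3, length.out = 25)), each = 20),
               dim = c(20, 1, 25))
  ens <- structure(list(data = dat, rel_time_s = (0:24) * 10, depths = 1,
                        anchor = "protrusion_onset", signal = "x",
                        n_events = 20, mean = apply(dat, c(2, 3), mean),
                        events = NULL), class = "aligned_ensemble")
  ci <- ensemble_mean_ci(ens, n_boot = 200, seed = 1)
  expect_equal(ci$lower, ci$upper, tolerance = 1e-12)
  ci2 <- ensemble_mean_ci(ens, n_boot = 200, seed = 1)
  expect_identical(ci$lower, ci2$lower)
})

test_that("bootstrap CI width matches normal theory for iid Gaussian events", {
  set.seed(5)
  dat <- array(rnorm(100 * 25), dim = c(100, 1, 25))
  ens <- structure(list(data = dat, rel_time_s = (0:24) * 10, depths = 1,
                        anchor = "protrusion_onset", signal = "x",
                        n_events = 100, mean = apply(dat, c(2, 3), mean),
                        events = NULL), class = "aligned_ensemble")
  ci <- ensemble_mean_ci(ens, n_boot = 1000, seed = 2)
  widths <- ci$upper[1, ] - ci$lower[1, ]
  expect_equal(mean(widths), 2 * 1.96 / sqrt(100), tolerance = 0.2)
})

test_that("temporal-alignment QC flags duplicated and corrupted frames only", {
  cfg <- synth_config(n_sectors = 40, n_frames = 40, n_depths = 5,
                      noise_sd = 0.05, seed = 14)
  sim <- make_window_series(cfg)
  # real traction maps have persistent spatial structure across sectors;
  # emulate it so frame-to-frame profile correlation is informative
  sim$table$traction_pa <- sim$table$traction_pa + 2 * sim$table$sector
  rep_clean <- refine_temporal_alignment(sim$table, depth = 5)
  expect_true(all(rep_clean$flag == "ok"))

  dup <- sim$table
  for (col in c("rac1", "rhoa", "traction_pa")) {
    src <- dup[dup$frame == 19, col][[1]]
    dup[dup$frame == 20, col] <- src
  }
  rep_dup <- refine_temporal_alignment(dup, depth = 5)
  expect_equal(rep_dup$flag[rep_dup$frame == 20], "duplicate")

  shuf <- sim$table
  set.seed(3)
  rows <- shuf$frame == 25
  shuf$traction_pa[rows] <- sample(shuf$traction_pa[rows])
  rep_shuf <- refine_temporal_alignment(shuf, depth = 5)
  expect_equal(rep_shuf$flag[rep_shuf$frame == 25], "decorrelated")
})
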