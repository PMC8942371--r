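pd_cache <- NULL
get_pd <- function() {
  if (is.null(pd_cache)) {
    cfg <- synth_config(frame_interval_s = 5, n_frames = 220, n_depths = 2,
                        noise_sd = 0.3, seed = 21)
    pd_cache <<- make_perturbation_dataset(
      cfg, offsets_s = c(-10, -15, -20, -25), effect = 0.02,
      n_control = 100, n_per_group = 25)
  }
  pd_cache
}

test_that("control extraction reports the mean time to Vmax", {
  ev <- tibble::tibble(onset_s = c(0, 0), vmax_s = c(50, 70))
  expect_equal(mean(ev$vmax_s - ev$onset_s), 60)
  pd <- get_pd()
  ctl <- build_controls(pd$control, pd$truth$t_act_s)
  expect_gt(nrow(ctl$events), 50)
  # detected mean time-to-Vmax near the design value (uniform 90-240 s / 2)
  expect_lt(abs(ctl$mean_t_vmax_s - 82.5), 8)
  expect_error(build_controls(pd$control, t_act_s = 5), "no control events")
})

test_that("offset grouping follows the nearest-within-tolerance rule", {
  ev <- tibble::tibble(onset_s = c(0, 0, 0), sector = 1:3,
                       type = "protrusion")
  # t_act - (onset + mean_t_vmax) = -10 exactly
  g1 <- group_by_offset(ev[1, ], t_act_s = 90, mean_t_vmax_s = 100,
                        offsets_s = c(-10, -15))
  expect_equal(g1$offset_group, -10)
  # -5 with tolerance 2.5: outside both bins
  g2 <- group_by_offset(ev[1, ], t_act_s = 95, mean_t_vmax_s = 100,
                        offsets_s = c(-10, -15), tolerance_s = 2.5)
  expect_equal(nrow(g2), 0)
  # -12.4 sits 2.4 s from -10: inside the inclusive 2.5-s window
  g24 <- group_by_offset(ev[1, ], t_act_s = 87.6, mean_t_vmax_s = 100,
                         offsets_s = c(-10, -15), tolerance_s = 2.5)
  expect_equal(g24$offset_group, -10)
  # -13.0: within 2.5 of -15 only
  g3 <- group_by_offset(ev[1, ], t_act_s = 87, mean_t_vmax_s = 100,
                        offsets_s = c(-10, -15), tolerance_s = 2.5)
  expect_equal(g3$offset_group, -15)
  expect_error(group_by_offset(ev, 0, 0, c(-10, -10)), "distinct")
})

test_that("DID difference vanishes when the perturbed set is the control set", {
  pd <- get_pd()
  ctl <- build_controls(pd$control, pd$truth$t_act_s)
  ev <- ctl$events
  ev$offset_group <- -10
  did <- did_curves(pd$control, ev, ctl, "velocity")
  expect_lt(max(abs(did$differences$diff), na.rm = TRUE), 1e-9)
})

test_that("DID recovers the injected velocity effect in every offset group", {
  pd <- get_pd()
  ctl <- build_controls(pd$control, pd$truth$t_act_s)
  pe <- detect_events_table(pd$perturbed)
  pg <- group_by_offset(pe, pd$truth$t_act_s, pd$truth$expected_t_vmax_s,
                        pd$truth$offsets_s)
  expect_equal(sort(unique(pg$offset_group)), sort(pd$truth$offsets_s))
  did <- did_curves(pd$perturbed, pg, ctl, "velocity")
  for (g in pd$truth$offsets_s) {
    late <- did$differences[did$differences$offset_group == g &
                              did$differences$rel_time_s > 60, ]
    expect_lt(abs(mean(late$diff) - 0.02), 0.008)
  }
})

test_that("the distance DID curve integrates the velocity DID curve", {
  pd <- get_pd()
  ctl <- build_controls(pd$control, pd$truth$t_act_s)
  pe <- detect_events_table(pd$perturbed)
  pg <- group_by_offset(pe, pd$truth$t_act_s, pd$truth$expected_t_vmax_s,
                        pd$truth$offsets_s)
  dv <- did_curves(pd$perturbed, pg, ctl, "velocity")
  dd <- did_curves(pd$perturbed, pg, ctl, "distance")
  g <- pd$truth$offsets_s[1]
  v <- dv$differences[dv$differences$offset_group == g, ]
  d <- dd$differences[dd$differences$offset_group == g, ]
  # cumulative sum of velocity differences * dt reproduces distance diff
  integ <- cumsum(dplyr::lag(v$diff, default = 0)) * 5
  expect_equal(d$diff, integ, tolerance = 0.05)
})

test_that("cellwise traction ratios and paired test behave as constructed", {
  ct <- tidyr::expand_grid(cell_id = 1:20, time_s = seq(0, 600, by = 5)) |>
    dplyr::mutate(traction_pa = 100)
  r0 <- traction_change_cellwise(ct, t_act_s = 300)
  expect_equal(unique(r0$ratios$ratio), 1)
  expect_null(r0$test)

  set.seed(6)
  ct2 <- ct |>
    dplyr::mutate(traction_pa = (100 + (time_s >= 300) * 50) *
                    (1 + rnorm(dplyr::n(), 0, 0.05)))
  r1 <- traction_change_cellwise(ct2, t_act_s = 300)
  expect_equal(r1$mean_ratio, 1.5, tolerance = 0.05)
  expect_lt(r1$test$p.value, 0.01)

  # invariance of the ratio under global rescaling
  ct3 <- ct2 |> dplyr::mutate(traction_pa = 3 * traction_pa)
  r3 <- traction_change_cellwise(ct3, t_act_s = 300)
  expect_equal(r3$ratios$ratio, r1$ratios$ratio, tolerance = 1e-12)
})

test_that("cellwise ratios require both time spans", {
  ct <- tibble::tibble(cell_id = 1, time_s = seq(0, 100, 5), traction_pa = 100)
  expect_error(traction_change_cellwise(ct, t_act_s = 300), "spans")
})

test_that("windowwise traction change detects an injected force step", {
  cfg <- synth_config(frame_interval_s = 5, n_frames = 220, n_depths = 2,
                      noise_sd = 0.1, seed = 31)
  pd <- make_perturbation_dataset(cfg, offsets_s = c(-10, -15), effect = 0,
                                  force_effect_pa = 30,
                                  n_control = 40, n_per_group = 20)
  ev_p <- detect_events_table(pd$perturbed)
  ev_c <- detect_events_table(pd$control)
  res <- traction_change_windowwise(pd$perturbed, ev_p, pd$control, ev_c,
                                    pd$truth$t_act_s, recent_window_s = 200)
  expect_lt(abs(res$difference - 30), 12)
  expect_lt(res$test$p.value, 0.05)
  expect_error(
    traction_change_windowwise(pd$perturbed, ev_p[0, ], pd$control, ev_c,
                               pd$truth$t_act_s),
    "no events")
})

test_that("resampling FDR is seed-deterministic and warns for tiny n_iter", {
  set.seed(2)
  ctrl <- matrix(rnorm(40 * 10), 40)
  pert <- matrix(rnorm(10 * 10), 10)
  a <- fdr_resampling(ctrl, pert, n_iter = 200, seed = 9)
  b <- fdr_resampling(ctrl, pert, n_iter = 200, seed = 9)
  expect_identical(a$q_grouped, b$q_grouped)
  expect_identical(a$significant, b$significant)
  w <- fdr_resampling(ctrl, pert, n_iter = 50, seed = 9)
  expect_true(length(w$warnings) > 0)
  expect_error(fdr_resampling(ctrl, pert[1, , drop = FALSE]), "at least 2")
})

test_that("FDR declares a strong shift significant but not the null", {
  set.seed(12)
  ctrl <- matrix(rnorm(60 * 25), 60)
  pert_null <- matrix(rnorm(20 * 25), 20)
  r0 <- fdr_resampling(ctrl, pert_null, n_iter = 500, seed = 4)
  expect_false(r0$significant)
  r1 <- fdr_resampling(ctrl, pert_null + 3, n_iter = 500, seed = 4)
  expect_true(r1$significant)
})

test_that("Storey q-values agree with Benjamini-Hochberg when pi0 is forced high", {
  set.seed(8)
  p <- runif(2000) # pure null: pi0 estimate near 1
  q <- storey_qvalue(p)
  bh <- p.adjust(p, "BH")
  expect_equal(q, bh, tolerance = 0.15)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})
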