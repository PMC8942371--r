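#' Generate a synthetic optogenetic perturbation dataset
#'
#' Emulates local photoactivation experiments: a control population of
#' unperturbed events, and perturbed populations in which activation starts
#' at fixed offsets relative to the expected Vmax time of the ongoing event
#' (e.g. -10/-15/-20/-25 s, i.e. before Vmax). The injected effect is an
#' additive change in edge velocity from the activation time onward, plus an
#' optional traction-force step.
#'
#' Each sector carries exactly one event; the perturbation movie cadence
#' defaults to the configured `frame_interval_s` (use 5 s for the
#' photoactivation protocol).
#'
#' @param config A [synth_config()] (set `frame_interval_s = 5` for the
#'   photoactivation cadence).
#' @param offsets_s Activation offsets relative to expected Vmax, seconds
#'   (negative = before Vmax), e.g. `c(-10, -15, -20, -25)`.
#' @param effect Additive velocity increment (um/s) applied from activation
#'   onward in perturbed events; sign models activating vs inhibiting light.
#' @param type `"protrusion"` or `"retraction"` events.
#' @param n_control Number of control events.
#' @param n_per_group Number of perturbed events per offset group.
#' @param force_effect_pa Additive traction change (Pa) from activation
#'   onward in perturbed events (default 0).
#' @return List: `control` and `perturbed` window tables, and `truth` with
#'   `t_act_s`, per-event schedules (perturbed carries `offset_group`),
#'   `effect`, `mean_duration_s`, and the config.
#' @export
make_perturbation_dataset <- function(config, offsets_s = c(-10, -15, -20, -25),
                                      effect = 0.02, type = "protrusion",
                                      n_control = 120, n_per_group = 40,
                                      force_effect_pa = 0) {
  stopifnot(inherits(config, "synth_config"))
  type <- match.arg(type, c("protrusion", "retraction"))
  dt <- config$frame_interval_s
  n_frames <- config$n_frames
  total_s <- (n_frames - 1L) * dt
  mean_dur <- mean(config$event_duration_s)
  # design-expected onset-to-Vmax time, snapped to the frame grid so that
  # activation offsets are exact multiples of the cadence
  mean_t_vmax <- round(mean_dur / 2 / dt) * dt
  t_act <- round(total_s * 0.6 / dt) * dt

  draw_events <- function(n, onset_fun) {
    amp <- runif(n, config$event_amplitude_um[1], config$event_amplitude_um[2])
    if (type != "protrusion") amp <- -amp
    tibble(
      sector = seq_len(n),
      type = .env$type,
      onset_s = onset_fun(n),
      dur = runif(n, config$event_duration_s[1], config$event_duration_s[2]),
      amplitude_um = amp
    ) |>
      mutate(
        onset_s = round(.data$onset_s / dt) * dt,
        vmax_s = .data$onset_s + .data$dur / 2,
        end_s = .data$onset_s + .data$dur
      ) |>
      select("sector", "type", "onset_s", "vmax_s", "end_s", "amplitude_um")
  }

  build <- function(schedule, perturbed, cfg = config) {
    cfg$n_sectors <- nrow(schedule)
    sim <- make_window_series(cfg, schedule = schedule)
    tab <- sim$table
    if (perturbed && (effect != 0 || force_effect_pa != 0)) {
      after <- tab$time_s >= t_act
      tab$velocity_um_per_s[after] <- tab$velocity_um_per_s[after] + effect
      # rebuild displacement as the integral of the modified velocity
      tab <- tab |>
        group_by(.data$sector, .data$depth) |>
        arrange(.data$frame, .by_group = TRUE) |>
        mutate(displacement_um = .data$displacement_um[1L] +
                 c(0, cumsum(.data$velocity_um_per_s[-n()] * dt))) |>
        ungroup() |>
        arrange(.data$sector, .data$depth, .data$frame)
      tab$traction_pa[tab$time_s >= t_act] <-
        tab$traction_pa[tab$time_s >= t_act] + force_effect_pa
    }
    list(table = tab, schedule = sim$truth$event_schedule)
  }

  ctrl_seed <- derive_seed(config$schedule_seed, "ctrl")
  pert_seed <- derive_seed(config$schedule_seed, "pert")

  ctrl_sched <- with_seed(ctrl_seed, {
    # control events complete before activation
    draw_events(n_control, function(n) {
      runif(n, 2 * dt, max(2 * dt, t_act - config$event_duration_s[2] - 2 * dt))
    })
  })
  cfgc <- config
  cfgc$noise_seed <- derive_seed(config$noise_seed, "ctrl")
  cfgc$n_sectors <- n_control
  ctrl <- list(table = make_window_series(cfgc, schedule = ctrl_sched)$table,
               schedule = ctrl_sched)

  pert_sched <- with_seed(pert_seed, {
    n_pert <- length(offsets_s) * n_per_group
    grp <- rep(offsets_s, each = n_per_group)
    sched <- draw_events(n_pert, function(n) rep(0, n))
    dur <- sched$end_s - sched$onset_s
    # activation hits at `offset` relative to the population-expected Vmax
    sched$onset_s <- round((t_act - mean_t_vmax - grp) / dt) * dt
    sched$vmax_s <- sched$onset_s + dur / 2
    sched$end_s <- sched$onset_s + dur
    sched$offset_group <- grp
    sched
  })
  cfgp <- config
  cfgp$noise_seed <- derive_seed(config$noise_seed, "pert")
  cfgp$n_sectors <- nrow(pert_sched)
  pert_built <- build(pert_sched[setdiff(names(pert_sched), "offset_group")],
                      perturbed = TRUE, cfg = cfgp)
  pert_built$schedule <- pert_sched

  list(
    control = ctrl$table,
    perturbed = pert_built$table,
    truth = list(
      t_act_s = t_act,
      expected_t_vmax_s = mean_t_vmax,
      control_schedule = ctrl$schedule,
      perturbed_schedule = pert_built$schedule,
      effect = effect,
      force_effect_pa = force_effect_pa,
      mean_duration_s = mean_dur,
      offsets_s = offsets_s,
      config = config
    )
  )
}

#' Extract onset-aligned control events and the mean time to Vmax
#'
#' Detects events in a control window table, keeps those fully completed
#' before the activation time (unperturbed controls), aligns their velocity
#' and cumulative-distance series on the event onset, and reports the mean
#' onset-to-Vmax time.
#'
#' @param table Control window series table.
#' @param t_act_s Activation time (s); only events ending before it are kept.
#' @param type `"protrusion"` or `"retraction"`.
#' @param horizon_s Length of the onset-aligned extract (default 120 s).
#' @param smoothing_p Optional displacement smoothing before detection.
#' @return List: `events` (kept control events), `aligned` (tibble:
#'   `event_id`, `rel_time_s`, `velocity_um_per_s`, `distance_um`),
#'   `mean_t_vmax_s`.
#' @export
build_controls <- function(table, t_act_s, type = "protrusion",
                           horizon_s = 120, smoothing_p = NULL) {
  ev <- detect_events_table(table, smoothing_p = smoothing_p)
  ev <- ev[ev$type == type & ev$end_s <= t_act_s, , drop = FALSE]
  if (!nrow(ev)) abort("no control events before the activation time.")
  aligned <- align_event_series(table, ev, horizon_s)
  list(events = ev, aligned = aligned,
       mean_t_vmax_s = mean(ev$vmax_s - ev$onset_s))
}

# Onset-aligned velocity and running-distance extraction for a set of events.
align_event_series <- function(table, events, horizon_s) {
  dt <- infer_dt(table)
  base <- table |>
    filter(.data$depth == min(.data$depth)) |>
    arrange(.data$sector, .data$frame)
  n_rel <- round(horizon_s / dt)
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    df <- base[base$sector == events$sector[i], , drop = FALSE]
    a <- events$onset_frame[i]
    rel <- 0:n_rel
    j <- match(a + rel, df$frame)
    vel <- df$velocity_um_per_s[j]
    disp <- df$displacement_um[j]
    tibble(
      event_id = i, sector = events$sector[i], rel_time_s = rel * dt,
      velocity_um_per_s = vel,
      distance_um = disp - disp[1L]
    )
  })
}

#' Group perturbed events by activation offset
#'
#' Assigns each event to the offset group whose nominal offset
#' `t_act - (onset + mean_t_vmax)` it matches within `tolerance_s`; events
#' matching no group are dropped.
#'
#' @param events Event tibble (needs `onset_s`).
#' @param t_act_s Activation time (s).
#' @param mean_t_vmax_s Mean onset-to-Vmax time from [build_controls()].
#' @param offsets_s Nominal offsets (s), e.g. `c(-10, -15, -20, -25)`.
#' @param tolerance_s Half-width of the matching window (default 2.5 s, half
#'   the 5-s photoactivation frame interval).
#' @return The events with an `offset_group` column; ungrouped events removed.
#' @export
group_by_offset <- function(events, t_act_s, mean_t_vmax_s, offsets_s,
                            tolerance_s = 2.5) {
  if (anyDuplicated(offsets_s)) abort("`offsets_s` must be distinct.")
  delta <- t_act_s - (events$onset_s + mean_t_vmax_s)
  nearest <- offsets_s[apply(abs(outer(delta, offsets_s, "-")), 1, which.min)]
  ok <- abs(delta - nearest) <= tolerance_s + 1e-9
  events$offset_group <- ifelse(ok, nearest, NA_real_)
  events[!is.na(events$offset_group), , drop = FALSE]
}

#' Difference-in-difference curves for perturbed event groups
#'
#' Onset-aligned mean velocity (or running distance) per offset group minus
#' the control mean at each relative time.
#'
#' @param perturbed_table Perturbed window series table.
#' @param grouped_events Output of [group_by_offset()] on the perturbed
#'   events.
#' @param controls Output of [build_controls()].
#' @param quantity `"velocity"` or `"distance"`.
#' @param horizon_s Curve length (default 120 s).
#' @return A `did_result`: `rel_time_s`, `control` tibble (mean, n),
#'   `differences` tibble (`offset_group`, `rel_time_s`, `diff`, `n`),
#'   `quantity`.
#' @export
did_curves <- function(perturbed_table, grouped_events, controls,
                       quantity = c("velocity", "distance"),
                       horizon_s = 120) {
  quantity <- match.arg(quantity)
  col <- if (quantity == "velocity") "velocity_um_per_s" else "distance_um"
  if (!nrow(grouped_events)) abort("no grouped perturbed events.")

  pert_aligned <- align_event_series(perturbed_table, grouped_events,
                                     horizon_s) |>
    left_join(
      tibble(event_id = seq_len(nrow(grouped_events)),
             offset_group = grouped_events$offset_group),
      by = "event_id"
    )

  ctrl_mean <- controls$aligned |>
    group_by(.data$rel_time_s) |>
    summarise(mean = mean(.data[[col]], na.rm = TRUE), n = sum(!is.na(.data[[col]])),
              .groups = "drop")

  diffs <- pert_aligned |>
    group_by(.data$offset_group, .data$rel_time_s) |>
    summarise(mean = mean(.data[[col]], na.rm = TRUE),
              n = sum(!is.na(.data[[col]])), .groups = "drop") |>
    left_join(ctrl_mean |> select("rel_time_s", ctrl_mean = "mean"),
              by = "rel_time_s") |>
    mutate(diff = .data$mean - .data$ctrl_mean) |>
    select("offset_group", "rel_time_s", "diff", "n")

  structure(list(
    rel_time_s = sort(unique(ctrl_mean$rel_time_s)),
    control = ctrl_mean,
    differences = diffs,
    quantity = quantity
  ), class = "did_result")
}

#' @export
print.did_result <- function(x, ...) {
  cat(sprintf("<did_result> %s; control n = %d; groups: %s\n",
              x$quantity, max(x$control$n),
              paste(sort(unique(x$differences$offset_group)), collapse = ", ")))
  invisible(x)
}

#' Per-cell traction change around a perturbation
#'
#' For each cell, the mean traction in the perturbed region is averaged over
#' a pre-activation span (default 0--1 min before) and a post-activation span
#' (default 3--4 min after); the after/before ratio is computed per cell and
#' a paired t test is run across cells.
#'
#' @param cell_traction Tibble with columns `cell_id`, `time_s`,
#'   `traction_pa` (mean traction in the perturbed region per frame).
#' @param t_act_s Activation time (s).
#' @param before_s,after_s Length-2 windows relative to `t_act_s`, seconds
#'   (defaults `c(-60, 0)` and `c(180, 240)`).
#' @return List: `ratios` tibble (`cell_id`, `before_pa`, `after_pa`,
#'   `ratio`), `test` (paired t test on after vs before), `mean_ratio`.
#' @export
traction_change_cellwise <- function(cell_traction, t_act_s,
                                     before_s = c(-60, 0),
                                     after_s = c(180, 240)) {
  ratios <- cell_traction |>
    group_by(.data$cell_id) |>
    summarise(
      before_pa = mean(.data$traction_pa[
        .data$time_s >= t_act_s + before_s[1] &
          .data$time_s <= t_act_s + before_s[2]], na.rm = TRUE),
      after_pa = mean(.data$traction_pa[
        .data$time_s >= t_act_s + after_s[1] &
          .data$time_s <= t_act_s + after_s[2]], na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(ratio = .data$after_pa / .data$before_pa)
  if (any(!is.finite(ratios$ratio))) {
    abort("both time spans must be covered for every cell.")
  }
  test <- if (nrow(ratios) >= 2 &&
                sd(ratios$after_pa - ratios$before_pa) > 0) {
    t.test(ratios$after_pa, ratios$before_pa, paired = TRUE)
  } else {
    NULL
  }
  list(ratios = ratios, test = test, mean_ratio = mean(ratios$ratio))
}

#' Window-wise traction change: perturbed vs phase-matched control sectors
#'
#' Compares the traction change over `horizon_s` after activation, in the
#' chosen depth window of sectors whose events started within
#' `recent_window_s` before activation, against the traction change over the
#' same horizon in phase-matched control windows (same sectors, same phase
#' type, measured from their unperturbed onsets).
#'
#' @param table Perturbed window series table.
#' @param events Events detected in `table`.
#' @param control_table Control window series table.
#' @param control_events Events detected in `control_table`.
#' @param t_act_s Activation time (s).
#' @param horizon_s Change horizon (default 120 s = 2 min).
#' @param depth Depth window (default 2, i.e. 1--2 um from the edge).
#' @param type Phase type compared (default `"protrusion"`).
#' @param recent_window_s Events must have started within this many seconds
#'   before activation (default 20).
#' @return List: `perturbed` and `control` per-window change tibbles,
#'   `difference` of group means (Pa), `test` (Welch two-sample t test).
#' @export
traction_change_windowwise <- function(table, events, control_table,
                                       control_events, t_act_s,
                                       horizon_s = 120, depth = 2,
                                       type = "protrusion",
                                       recent_window_s = 20) {
  pert_ev <- events[events$type == type &
                      events$onset_s >= t_act_s - recent_window_s &
                      events$onset_s < t_act_s, , drop = FALSE]
  if (!nrow(pert_ev)) {
    abort("no events initiated within the pre-activation window.")
  }
  ctrl_ev <- control_events[control_events$type == type, , drop = FALSE]
  if (!nrow(ctrl_ev)) abort("no phase-matched control events.")

  change_at <- function(tab, sectors, start_s) {
    purrr::map_dbl(seq_along(sectors), function(i) {
      df <- tab[tab$sector == sectors[i] & tab$depth == depth, , drop = FALSE]
      t0 <- start_s[i]
      f0 <- df$traction_pa[which.min(abs(df$time_s - t0))]
      f1 <- df$traction_pa[which.min(abs(df$time_s - (t0 + horizon_s)))]
      f1 - f0
    })
  }

  pert_change <- change_at(table, pert_ev$sector, rep(t_act_s, nrow(pert_ev)))
  ctrl_change <- change_at(control_table, ctrl_ev$sector, ctrl_ev$onset_s)

  test <- t.test(pert_change, ctrl_change)
  list(
    perturbed = tibble(sector = pert_ev$sector, change_pa = pert_change),
    control = tibble(sector = ctrl_ev$sector, change_pa = ctrl_change),
    difference = mean(pert_change) - mean(ctrl_change),
    test = test
  )
}
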