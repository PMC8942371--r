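#' Generate synthetic per-window signaling and force time series
#'
#' Simulates the table a windowed movie analysis would produce: per edge
#' sector, a schedule of alternating protrusion/retraction events drives the
#' edge displacement (half-cosine ramps, so edge velocity peaks at the event
#' midpoint = Vmax), and Rac1-GTP, RhoA-GTP and traction-force signals are
#' built from Gaussian activity bumps tied to the anchor events:
#'
#' * Rac1-GTP rises `rac1_to_onset_lead_s` before each protrusion onset,
#'   dips to a nadir at protrusion Vmax and peaks at retraction Vmax;
#' * RhoA-GTP mirrors Rac1-GTP advanced by `rhoa_to_rac1_lead_s`, with the
#'   Vmax bumps inverted in sign;
#' * traction force follows Rac1-GTP delayed by `rac1_to_force_lag_s`
#'   (plus an optional RhoA coupling, off by default).
#'
#' Signals are replicated across depth windows with a fixed depth profile
#' (GTPase activity concentrated within ~2 um of the edge, traction force
#' peaking 4--6 um inward) and i.i.d. Gaussian noise is added per
#' (sector, depth) series.
#'
#' @param config A [synth_config()].
#' @param schedule Optional event-schedule tibble (columns `sector`, `type`,
#'   `onset_s`, `vmax_s`, `end_s`, `amplitude_um`) to use instead of drawing
#'   one; useful for fully controlled fixtures.
#' @return A list with components
#'   * `table`: tibble with columns `cell_id`, `sector`, `depth`, `frame`
#'     (0-based), `time_s`, `rac1`, `rhoa`, `traction_pa`,
#'     `displacement_um` (per sector, depth-independent),
#'     `velocity_um_per_s` (forward difference of displacement);
#'   * `truth`: list with `event_schedule` (tibble: `sector`, `type`,
#'     `onset_s`, `vmax_s`, `end_s`, `amplitude_um`), `true_signals`
#'     (noiseless per-sector tibble), `depth_profiles`, and the `config`.
#' @export
#' @examples
#' sim <- make_window_series(synth_config(n_sectors = 3, n_frames = 60,
#'                                        n_depths = 2, seed = 7))
#' dplyr::count(sim$truth$event_schedule, type)
make_window_series <- function(config, schedule = NULL) {
  stopifnot(inherits(config, "synth_config"))
  dt <- config$frame_interval_s
  t_grid <- (seq_len(config$n_frames) - 1L) * dt
  total_s <- max(t_grid)

  if (is.null(schedule)) {
    schedule <- with_seed(config$schedule_seed,
                          make_event_schedule(config, total_s))
  } else {
    schedule <- as_tibble(schedule)
    needed <- c("sector", "type", "onset_s", "vmax_s", "end_s", "amplitude_um")
    if (!all(needed %in% names(schedule))) {
      abort("user-supplied `schedule` lacks required columns.")
    }
    if (any(!(schedule$onset_s < schedule$vmax_s &
                schedule$vmax_s <= schedule$end_s))) {
      abort("schedule must satisfy onset_s < vmax_s <= end_s.")
    }
  }

  sig <- sector_true_signals(schedule, t_grid, config)

  noisy <- with_seed(config$noise_seed, {
    n_sd <- config$noise_sd
    v_sd <- config$velocity_noise_sd
    purrr::map(seq_len(config$n_sectors), function(s) {
      base <- sig[[s]]
      disp <- base$displacement_um
      if (v_sd > 0) {
        incr <- diff(disp) + rnorm(length(disp) - 1L, 0, v_sd)
        disp <- c(disp[1L], disp[1L] + cumsum(incr))
      }
      vel <- finite_diff(disp, dt)
      depth_tables <- purrr::map(seq_len(config$n_depths), function(d) {
        prof <- depth_profiles(config$n_depths)
        tibble(
          cell_id = 1L,
          sector = s,
          depth = d,
          frame = seq_along(t_grid) - 1L,
          time_s = t_grid,
          rac1 = 1 + prof$gtpase[d] * base$rac1_sig +
            rnorm(length(t_grid), 0, n_sd),
          rhoa = 1 + prof$gtpase[d] * base$rhoa_sig +
            rnorm(length(t_grid), 0, n_sd),
          traction_pa = 100 + prof$force[d] * base$force_sig +
            rnorm(length(t_grid), 0, n_sd * config$force_coupling),
          displacement_um = disp,
          velocity_um_per_s = vel
        )
      })
      bind_rows(depth_tables)
    })
  })

  true_signals <- bind_rows(purrr::imap(sig, function(b, s) {
    tibble(
      sector = s, frame = seq_along(t_grid) - 1L, time_s = t_grid,
      rac1 = 1 + b$rac1_sig, rhoa = 1 + b$rhoa_sig,
      traction_pa = 100 + b$force_sig,
      displacement_um = b$displacement_um,
      velocity_um_per_s = finite_diff(b$displacement_um, dt)
    )
  }))

  list(
    table = bind_rows(noisy),
    truth = list(
      event_schedule = schedule,
      true_signals = true_signals,
      depth_profiles = depth_profiles(config$n_depths),
      config = config
    )
  )
}

# Relative signal weight per 1-um depth window: GTPase activity concentrated
# within 2 um of the edge; traction force peaking 4-6 um inward.
depth_profiles <- function(n_depths) {
  gtpase <- c(0.8, 1, 0.75, 0.5, 0.3, 0.2, 0.12, 0.08, 0.05, 0.03)
  force <- c(0.5, 0.65, 0.8, 1, 1, 0.85, 0.65, 0.5, 0.4, 0.3)
  pad <- function(p) {
    if (n_depths <= length(p)) p[seq_len(n_depths)]
    else c(p, rep(p[length(p)], n_depths - length(p)))
  }
  list(gtpase = pad(gtpase), force = pad(force))
}

# Draw a per-sector schedule of alternating protrusion/retraction events,
# separated by quiescent gaps, covering [0, total_s].
make_event_schedule <- function(config, total_s) {
  rows <- purrr::map(seq_len(config$n_sectors), function(s) {
    t_cursor <- runif(1, config$event_gap_s[1], config$event_gap_s[2])
    type <- if (runif(1) < 0.5) "protrusion" else "retraction"
    out <- list()
    repeat {
      dur <- runif(1, config$event_duration_s[1], config$event_duration_s[2])
      amp <- runif(1, config$event_amplitude_um[1], config$event_amplitude_um[2])
      # anchor onsets on the acquisition grid: an off-grid onset is observed
      # at the frame below it, which would bias every event-aligned time by
      # half a frame interval
      onset <- round(t_cursor / config$frame_interval_s) *
        config$frame_interval_s
      if (onset + dur > total_s) break
      out[[length(out) + 1L]] <- tibble(
        sector = s, type = type,
        onset_s = onset, vmax_s = onset + dur / 2,
        end_s = onset + dur,
        amplitude_um = if (type == "protrusion") amp else -amp
      )
      t_cursor <- t_cursor + dur +
        runif(1, config$event_gap_s[1], config$event_gap_s[2])
      type <- if (type == "protrusion") "retraction" else "protrusion"
    }
    bind_rows(out)
  })
  proto <- tibble(sector = integer(), type = character(),
                  onset_s = numeric(), vmax_s = numeric(),
                  end_s = numeric(), amplitude_um = numeric())
  bind_rows(proto, rows)
}

# Noiseless per-sector signal construction from an event schedule.
sector_true_signals <- function(schedule, t_grid, config) {
  dt <- config$frame_interval_s
  g <- config$bump_gain
  sg <- config$bump_sigma_s
  lag_frames <- config$rac1_to_force_lag_s / dt

  purrr::map(seq_len(config$n_sectors), function(s) {
    ev <- schedule[schedule$sector == s, , drop = FALSE]
    disp <- rep(0, length(t_grid))
    rac1 <- rep(0, length(t_grid))
    rhoa <- rep(0, length(t_grid))
    if (nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        e <- ev[i, ]
        disp <- disp + halfcos_ramp(t_grid, e$onset_s, e$end_s - e$onset_s,
                                    e$amplitude_um)
        if (e$type == "protrusion") {
          rac1 <- rac1 +
            g * gauss_bump(t_grid, e$onset_s - config$rac1_to_onset_lead_s, sg) -
            g * gauss_bump(t_grid, e$vmax_s, sg)
          rhoa <- rhoa +
            g * gauss_bump(t_grid,
                           e$onset_s - config$rac1_to_onset_lead_s -
                             config$rhoa_to_rac1_lead_s, sg) +
            g * gauss_bump(t_grid, e$vmax_s - config$rhoa_to_rac1_lead_s, sg)
        } else {
          rac1 <- rac1 + g * gauss_bump(t_grid, e$vmax_s, sg)
          rhoa <- rhoa -
            g * gauss_bump(t_grid, e$vmax_s - config$rhoa_to_rac1_lead_s, sg)
        }
      }
    }
    # Traction force follows Rac1 by an integer (or interpolated) frame lag.
    force <- config$force_coupling * shift_series(rac1, lag_frames) +
      config$rhoa_force_coupling * shift_series(rhoa, lag_frames)
    list(displacement_um = disp, rac1_sig = rac1, rhoa_sig = rhoa,
         force_sig = force)
  })
}

# Delay a series by `shift` frames (edge padding); non-integer shifts are
# linearly interpolated.
shift_series <- function(x, shift) {
  n <- length(x)
  idx <- seq_len(n) - shift
  if (abs(shift - round(shift)) < 1e-9) {
    x[pmin(pmax(round(idx), 1L), n)]
  } else {
    approx(seq_len(n), x, xout = pmin(pmax(idx, 1), n))$y
  }
}
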