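#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the synthetic movie / time-series generator:
#' acquisition cadence and calibration, substrate elasticity, the lead/lag
#' structure tying RhoA-GTP, Rac1-GTP, edge motion and traction force
#' together, event-size distributions, noise levels and seeds.
#'
#' The temporal defaults encode the signaling chronology the generator
#' emulates: RhoA-GTP changes lead Rac1-GTP by 20--30 s (default 25 s),
#' Rac1-GTP rises about 40 s before protrusion onset, reaches a nadir at
#' protrusion Vmax and a peak at retraction Vmax, and traction force follows
#' Rac1-GTP with a lag of about 40 s. The substrate default is a 6.9 kPa
#' polyacrylamide gel imaged at 10-s intervals (5 s for optogenetic
#' perturbation movies).
#'
#' @param frame_interval_s Frame interval in seconds (default 10).
#' @param pixel_size_um Pixel size in micrometres (default 0.2).
#' @param youngs_modulus_pa Substrate Young's modulus in pascal (default 6900).
#' @param poisson_ratio Substrate Poisson ratio in `[0, 0.5]` (default 0.5,
#'   the incompressible-gel convention).
#' @param rhoa_to_rac1_lead_s Seconds by which RhoA-GTP dynamics lead
#'   Rac1-GTP (default 25).
#' @param rac1_to_onset_lead_s Seconds by which the Rac1-GTP rise precedes
#'   protrusion onset (default 40).
#' @param rac1_to_force_lag_s Seconds by which traction force lags Rac1-GTP
#'   (default 40).
#' @param event_amplitude_um Length-2 numeric, uniform range of event
#'   distances in micrometres (default `c(1.5, 4)`).
#' @param event_duration_s Length-2 numeric, uniform range of event durations
#'   in seconds (default `c(90, 240)`).
#' @param event_gap_s Length-2 numeric, uniform range of quiescent gaps
#'   between consecutive events in seconds (default `c(60, 180)`).
#' @param bump_sigma_s Width (SD, seconds) of the Gaussian activity bumps
#'   attached to the anchor events (default 15).
#' @param bump_gain Amplitude (arbitrary units) of the activity bumps
#'   (default 1).
#' @param force_coupling Gain coupling traction force to lagged Rac1-GTP
#'   (default 30 Pa per Rac1 unit).
#' @param rhoa_force_coupling Optional extra coupling of force to RhoA-GTP;
#'   default 0 (off). Negative values reproduce the observed negative
#'   RhoA--force correlation.
#' @param noise_sd Per-signal additive Gaussian noise SD in signal units
#'   (default 0.5).
#' @param velocity_noise_sd Additive noise SD on edge displacement
#'   increments, micrometres (default 0).
#' @param bead_density_per_um2 Fiducial bead density for rendered bead
#'   images (default 1.5 per square micrometre).
#' @param psf_sigma_px Gaussian spot SD in pixels for bead rendering
#'   (default 1.5).
#' @param n_sectors Number of edge sectors (default 60).
#' @param n_depths Number of 1-um depth windows (default 10).
#' @param n_frames Number of frames (default 121).
#' @param seed Master seed; `schedule_seed` and `noise_seed` are derived from
#'   it unless given, so noise can be varied with the event schedule pinned.
#' @param schedule_seed,noise_seed Optional explicit sub-seeds.
#'
#' @return An object of class `synth_config` (a named list).
#' @export
#' @examples
#' cfg <- synth_config(n_sectors = 4, n_frames = 60, seed = 1)
#' cfg$rac1_to_force_lag_s
synth_config <- function(frame_interval_s = 10,
                         pixel_size_um = 0.2,
                         youngs_modulus_pa = 6900,
                         poisson_ratio = 0.5,
                         rhoa_to_rac1_lead_s = 25,
                         rac1_to_onset_lead_s = 40,
                         rac1_to_force_lag_s = 40,
                         event_amplitude_um = c(1.5, 4),
                         event_duration_s = c(90, 240),
                         event_gap_s = c(60, 180),
                         bump_sigma_s = 15,
                         bump_gain = 1,
                         force_coupling = 30,
                         rhoa_force_coupling = 0,
                         noise_sd = 0.5,
                         velocity_noise_sd = 0,
                         bead_density_per_um2 = 1.5,
                         psf_sigma_px = 1.5,
                         n_sectors = 60,
                         n_depths = 10,
                         n_frames = 121,
                         seed = 1L,
                         schedule_seed = NULL,
                         noise_seed = NULL) {
  check_scalar_number(frame_interval_s, "frame_interval_s", 0, strict_lower = TRUE)
  check_scalar_number(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  check_scalar_number(youngs_modulus_pa, "youngs_modulus_pa", 0, strict_lower = TRUE)
  check_scalar_number(poisson_ratio, "poisson_ratio", 0, 0.5)
  check_scalar_number(rhoa_to_rac1_lead_s, "rhoa_to_rac1_lead_s", 0)
  check_scalar_number(rac1_to_onset_lead_s, "rac1_to_onset_lead_s", 0)
  check_scalar_number(rac1_to_force_lag_s, "rac1_to_force_lag_s", 0)
  check_scalar_number(bump_sigma_s, "bump_sigma_s", 0, strict_lower = TRUE)
  check_scalar_number(noise_sd, "noise_sd", 0)
  check_scalar_number(velocity_noise_sd, "velocity_noise_sd", 0)
  if (length(event_amplitude_um) != 2L || any(event_amplitude_um <= 0)) {
    abort("`event_amplitude_um` must be a positive length-2 range.")
  }
  if (length(event_duration_s) != 2L || any(event_duration_s <= 0)) {
    abort("`event_duration_s` must be a positive length-2 range.")
  }
  if (length(event_gap_s) != 2L || any(event_gap_s < 0)) {
    abort("`event_gap_s` must be a non-negative length-2 range.")
  }
  if (!is.numeric(n_sectors) || n_sectors < 1) {
    abort("`n_sectors` must be a positive integer.")
  }
  if (!is.numeric(n_frames) || n_frames < 2) {
    abort("`n_frames` must be an integer >= 2.")
  }
  if (!is.numeric(n_depths) || n_depths < 1) {
    abort("`n_depths` must be a positive integer.")
  }

  cfg <- list(
    frame_interval_s = frame_interval_s,
    pixel_size_um = pixel_size_um,
    youngs_modulus_pa = youngs_modulus_pa,
    poisson_ratio = poisson_ratio,
    rhoa_to_rac1_lead_s = rhoa_to_rac1_lead_s,
    rac1_to_onset_lead_s = rac1_to_onset_lead_s,
    rac1_to_force_lag_s = rac1_to_force_lag_s,
    event_amplitude_um = as.numeric(event_amplitude_um),
    event_duration_s = as.numeric(event_duration_s),
    event_gap_s = as.numeric(event_gap_s),
    bump_sigma_s = bump_sigma_s,
    bump_gain = bump_gain,
    force_coupling = force_coupling,
    rhoa_force_coupling = rhoa_force_coupling,
    noise_sd = noise_sd,
    velocity_noise_sd = velocity_noise_sd,
    bead_density_per_um2 = bead_density_per_um2,
    psf_sigma_px = psf_sigma_px,
    n_sectors = as.integer(n_sectors),
    n_depths = as.integer(n_depths),
    n_frames = as.integer(n_frames),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    schedule_seed = if (is.null(schedule_seed)) {
      derive_seed(seed, "schedule")
    } else {
      as.integer(schedule_seed)
    },
    noise_seed = if (is.null(noise_seed)) {
      derive_seed(seed, "noise")
    } else {
      as.integer(noise_seed)
    }
  )
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d sectors x %d depths x %d frames @ %g s, %g um/px\n",
              x$n_sectors, x$n_depths, x$n_frames,
              x$frame_interval_s, x$pixel_size_um))
  cat(sprintf("  substrate E = %g Pa, nu = %g\n",
              x$youngs_modulus_pa, x$poisson_ratio))
  cat(sprintf("  leads/lags (s): RhoA->Rac1 %g, Rac1->onset %g, Rac1->force %g\n",
              x$rhoa_to_rac1_lead_s, x$rac1_to_onset_lead_s,
              x$rac1_to_force_lag_s))
  cat(sprintf("  seeds: master %s, schedule %s, noise %s\n",
              x$seed %||% "NULL", x$schedule_seed %||% "NULL",
              x$noise_seed %||% "NULL"))
  invisible(x)
}
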