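# broom-style tidiers for the package's result objects.

#' Tidy an aligned ensemble into a long tibble
#'
#' @param x An [align_ensembles()] result.
#' @param ... Unused.
#' @return Tibble: `depth`, `rel_time_s`, `mean`, and `lower`/`upper` when
#'   [ensemble_mean_ci()] has been run.
#' @export
tidy.aligned_ensemble <- function(x, ...) {
  # x$mean is depths x times; expand_grid varies rel_time fastest
  out <- tidyr::expand_grid(depth = x$depths, rel_time_s = x$rel_time_s)
  out$mean <- as.vector(t(x$mean))
  if (!is.null(x$lower)) {
    out$lower <- as.vector(t(x$lower))
    out$upper <- as.vector(t(x$upper))
  }
  out
}

#' @export
glance.aligned_ensemble <- function(x, ...) {
  tibble(anchor = x$anchor, signal = x$signal, n_events = x$n_events,
         n_depths = length(x$depths), t_min_s = min(x$rel_time_s),
         t_max_s = max(x$rel_time_s),
         level = x$level %||% NA_real_, n_boot = x$n_boot %||% NA_integer_)
}

#' Tidy a lagged cross-correlation result
#'
#' @param x A [cross_correlate()] result.
#' @param ... Unused.
#' @return Tibble: `lag_s`, `corr`, `n`.
#' @export
tidy.xcorr_result <- function(x, ...) {
  tibble(lag_s = x$lags_s, corr = x$corr, n = x$n_pairs)
}

#' @export
glance.xcorr_result <- function(x, ...) {
  pk <- peak_lag(x)
  tibble(x_name = x$x_name, y_name = x$y_name,
         peak_lag_s = pk, peak_corr = x$corr[match(pk, x$lags_s)],
         min_lag_s = min(x$lags_s), max_lag_s = max(x$lags_s))
}

#' Tidy difference-in-difference curves
#'
#' @param x A [did_curves()] result.
#' @param ... Unused.
#' @return Long tibble: control rows (`offset_group = NA`, absolute mean)
#'   and per-group difference rows.
#' @export
tidy.did_result <- function(x, ...) {
  bind_rows(
    x$control |>
      mutate(offset_group = NA_real_, curve = "control") |>
      select("curve", "offset_group", "rel_time_s", value = "mean", "n"),
    x$differences |>
      mutate(curve = "difference") |>
      select("curve", "offset_group", "rel_time_s", value = "diff", "n")
  )
}

#' @export
glance.did_result <- function(x, ...) {
  tibble(quantity = x$quantity,
         n_control = max(x$control$n),
         n_groups = dplyr::n_distinct(x$differences$offset_group))
}

#' Tidy a resampling FDR result
#'
#' @param x An [fdr_resampling()] result.
#' @param ... Unused.
#' @return Tibble with per-time-point mean P and Q values for grouped and
#'   randomized data.
#' @export
tidy.fdr_result <- function(x, ...) {
  tibble(
    time_index = seq_len(ncol(x$p_grouped)),
    p_grouped = colMeans(x$p_grouped, na.rm = TRUE),
    p_randomized = colMeans(x$p_randomized, na.rm = TRUE),
    q_grouped = colMeans(x$q_grouped, na.rm = TRUE),
    q_randomized = colMeans(x$q_randomized, na.rm = TRUE)
  )
}

#' @export
glance.fdr_result <- function(x, ...) {
  tibble(mean_q_grouped = x$mean_q_grouped, threshold = x$threshold,
         significant = x$significant, n_iter = x$n_iter,
         spread_stat = x$spread_stat, threshold_mode = x$threshold_mode)
}

#' Tidy a displacement field into node records
#'
#' @param x A [displacement_field()].
#' @param ... Unused.
#' @return Tibble: `x_um`, `y_um`, `u_um`, `v_um`, `valid`.
#' @export
tidy.displacement_field <- function(x, ...) {
  tidyr::expand_grid(y_um = x$y_um, x_um = x$x_um) |>
    mutate(u_um = as.vector(t(x$u)), v_um = as.vector(t(x$v)),
           valid = as.vector(t(x$valid)))
}

#' Tidy a traction map into node records
#'
#' @param x A [traction_map()].
#' @param ... Unused.
#' @return Tibble: `x_um`, `y_um`, `t_x_pa`, `t_y_pa`, `magnitude_pa`.
#' @export
tidy.traction_map <- function(x, ...) {
  tidyr::expand_grid(y_um = x$y_um, x_um = x$x_um) |>
    mutate(t_x_pa = as.vector(t(x$tx)), t_y_pa = as.vector(t(x$ty)),
           magnitude_pa = as.vector(t(x$magnitude)))
}
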