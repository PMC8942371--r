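#' Resampling-based FDR comparison of perturbed vs control time series
#'
#' Implements a subsample-and-compare procedure for unequal group sizes:
#' because the control population is much larger than the perturbed one, the
#' control group is randomly subsampled to the perturbed size `n_iter`
#' times. In every iteration and at every time point, the spread of the
#' grouped data (each series' absolute deviation from its own group mean) is
#' compared to the spread of the pooled two-group data (absolute deviation
#' from the pooled mean) with a two-sample t test, yielding a P value per
#' time point; a label-shuffled regrouping of the same data yields a
#' matching randomized (null) P value. Q values are computed from both P
#' sets with the Storey positive-FDR procedure; the significance threshold
#' is the `threshold_pct` percentile (default 0.1%) of the randomized Q
#' values, and the comparison is declared significant when the mean grouped
#' Q value falls below that threshold.
#'
#' @param control Numeric matrix, control series in rows (n_control x T).
#' @param perturbed Numeric matrix, perturbed series in rows
#'   (n_perturbed x T), same T.
#' @param n_iter Number of control subsamples (default 10000).
#' @param threshold_pct Percentile (in percent) of randomized Q values used
#'   as the significance threshold (default 0.1). Set
#'   `threshold_mode = "fixed"` to use `threshold_pct / 100` as a fixed
#'   cutoff instead.
#' @param threshold_mode `"percentile"` (default) or `"fixed"`.
#' @param spread_stat How series spread is summarised before the t test:
#'   `"abs"` (absolute deviations, Levene-type, default) or `"sq"`
#'   (squared deviations).
#' @param seed Seed for all resampling.
#' @return An `fdr_result` list: `p_grouped`, `p_randomized` (n_iter x T
#'   matrices), `q_grouped`, `q_randomized`, `threshold`, `mean_q_grouped`,
#'   `significant`, plus metadata (`n_iter`, `seed`, warnings).
#' @export
fdr_resampling <- function(control, perturbed, n_iter = 10000,
                           threshold_pct = 0.1,
                           threshold_mode = c("percentile", "fixed"),
                           spread_stat = c("abs", "sq"), seed = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  spread_stat <- match.arg(spread_stat)
  control <- as.matrix(control)
  perturbed <- as.matrix(perturbed)
  if (ncol(control) != ncol(perturbed)) {
    abort("control and perturbed must share the time axis.")
  }
  n_p <- nrow(perturbed)
  n_c <- nrow(control)
  if (n_p < 2L) abort("need at least 2 perturbed series.")
  if (n_c < n_p) abort("control group must be at least as large as perturbed.")
  warnings <- character()
  if (n_iter < 100) {
    warnings <- c(warnings, sprintf("n_iter = %d is small; P/Q estimates unstable.",
                                    n_iter))
  }

  nt <- ncol(control)
  res <- with_seed(seed, {
    p_grp <- matrix(NA_real_, n_iter, nt)
    p_rnd <- matrix(NA_real_, n_iter, nt)
    for (it in seq_len(n_iter)) {
      sub <- control[sample.int(n_c, n_p), , drop = FALSE]
      p_grp[it, ] <- spread_pvalues(sub, perturbed, spread_stat)
      pool <- rbind(sub, perturbed)
      sh <- sample.int(2L * n_p)
      p_rnd[it, ] <- spread_pvalues(pool[sh[seq_len(n_p)], , drop = FALSE],
                                    pool[sh[-seq_len(n_p)], , drop = FALSE],
                                    spread_stat)
    }
    list(p_grp = p_grp, p_rnd = p_rnd)
  })

  q_grp <- matrix(storey_qvalue(as.vector(res$p_grp)), n_iter, nt)
  q_rnd <- matrix(storey_qvalue(as.vector(res$p_rnd)), n_iter, nt)

  threshold <- if (threshold_mode == "percentile") {
    quantile(q_rnd, probs = threshold_pct / 100, na.rm = TRUE, names = FALSE)
  } else {
    threshold_pct / 100
  }
  mean_q <- mean(q_grp, na.rm = TRUE)

  structure(list(
    p_grouped = res$p_grp, p_randomized = res$p_rnd,
    q_grouped = q_grp, q_randomized = q_rnd,
    threshold = threshold, mean_q_grouped = mean_q,
    significant = isTRUE(mean_q < threshold),
    n_iter = n_iter, threshold_pct = threshold_pct,
    threshold_mode = threshold_mode, spread_stat = spread_stat,
    seed = seed, warnings = warnings
  ), class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("<fdr_result> mean grouped Q = %.4g vs threshold %.4g -> %s\n",
              x$mean_q_grouped, x$threshold,
              if (x$significant) "significant" else "not significant"))
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

# Per-time-point P values comparing within-group spread to pooled spread.
# Sample 1: |x - own group mean| for every series in both groups;
# sample 2: |x - pooled mean|. Two-sample t statistic per column, vectorized.
spread_pvalues <- function(a, b, spread_stat = "abs") {
  na <- nrow(a)
  nb <- nrow(b)
  ma <- colMeans(a)
  mb <- colMeans(b)
  mp <- (na * ma + nb * mb) / (na + nb)
  dev_within <- rbind(sweep(a, 2, ma), sweep(b, 2, mb))
  dev_pooled <- rbind(sweep(a, 2, mp), sweep(b, 2, mp))
  if (spread_stat == "abs") {
    dev_within <- abs(dev_within)
    dev_pooled <- abs(dev_pooled)
  } else {
    dev_within <- dev_within^2
    dev_pooled <- dev_pooled^2
  }
  n <- nrow(dev_within)
  m1 <- colMeans(dev_within)
  m2 <- colMeans(dev_pooled)
  v1 <- colSums(sweep(dev_within, 2, m1)^2) / (n - 1L)
  v2 <- colSums(sweep(dev_pooled, 2, m2)^2) / (n - 1L)
  se <- sqrt(v1 / n + v2 / n)
  tt <- (m2 - m1) / se
  df <- (v1 / n + v2 / n)^2 /
    ((v1 / n)^2 / (n - 1L) + (v2 / n)^2 / (n - 1L))
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  p[!is.finite(p)] <- 1
  p
}

#' Storey positive-FDR Q values
#'
#' Q values from a vector of P values by the Storey procedure, with the null
#' proportion pi0 estimated by the smoother method (natural cubic spline of
#' pi0(lambda) over lambda = 0.05..0.95, evaluated at the largest lambda).
#'
#' @param p Numeric vector of P values.
#' @param lambda Grid for the pi0 smoother.
#' @return Vector of Q values, same order as `p`.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (!m) return(p)
  if (m < 100 || all(pv >= max(lambda))) {
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- min(max(predict(fit, x = max(lambda))$y, 0), 1)
    if (pi0 <= 0) pi0 <- 1e-8
  }
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * pv[o] / seq(m, 1)
  q <- pmin(cummin(q), 1)[ro]
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  out
}
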