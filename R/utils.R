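# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic code in the package funnels through
# this so identical (config, seed) pairs are bit-reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream label, staying within
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L) + 1L
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x))
  }
  invisible(x)
}

# Unnormalized Gaussian bump centred at t0 with width sigma (seconds).
gauss_bump <- function(t, t0, sigma) {
  exp(-0.5 * ((t - t0) / sigma)^2)
}

# Half-cosine displacement ramp: 0 at onset, `amplitude` at onset + duration,
# velocity maximal at the midpoint. Signed amplitude encodes direction.
halfcos_ramp <- function(t, onset, duration, amplitude) {
  s <- (t - onset) / duration
  s <- pmin(pmax(s, 0), 1)
  amplitude * 0.5 * (1 - cos(pi * s))
}

# Forward-difference velocity on a regular grid (last value repeated), so
# that displacement telescopes exactly from the velocity series.
finite_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(diff(x), x[n] - x[n - 1L]) / dt
}

# Central-difference velocity (one-sided at the ends): unbiased extremum
# location on symmetric ramps; used for Vmax detection.
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 3L) return(finite_diff(x, dt))
  c(x[2L] - x[1L], (x[3:n] - x[1:(n - 2L)]) / 2, x[n] - x[n - 1L]) / dt
}
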