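# Brute-force reference implementations and random-input generators used by
# the property and acceptance tests. These deliberately avoid the package's
# vectorized window machinery: intervals are differenced by hand and the
# median is taken from an explicit sort, so they constitute an independent
# route to the same quantities.

# Earliest-valid-window search by explicit enumeration.
brute_force_estimate <- function(tt, z, th_c, rr_min = 2, rr_max = 140,
                                 max_duration = 60) {
  n <- length(tt)
  if (n >= z + 1) {
    for (k in (z + 1):n) {
      if (tt[k] - tt[1] > max_duration) break
      iv <- numeric(z)
      for (j in seq_len(z)) iv[j] <- tt[k - z + j] - tt[k - z + j - 1]
      s <- sort(iv)
      med <- if (z %% 2 == 1) s[(z + 1) / 2] else (s[z / 2] + s[z / 2 + 1]) / 2
      C <- 100 * max(abs(iv - med)) / med
      rr <- 60 / med
      if (C <= th_c && rr >= rr_min && rr <= rr_max) {
        return(list(completed = TRUE, rr = rr, efficiency = tt[k] - tt[1],
                    taps_used = k))
      }
    }
  }
  list(completed = FALSE, rr = NA_real_, efficiency = max_duration,
       taps_used = NA_integer_)
}

# Per-window consistency/rate table by the same explicit enumeration; lets a
# test sweep every threshold without re-enumerating windows.
brute_window_stats <- function(tt, z, max_duration = 60) {
  n <- length(tt)
  out <- NULL
  if (n >= z + 1) {
    for (k in (z + 1):n) {
      if (tt[k] - tt[1] > max_duration) break
      iv <- numeric(z)
      for (j in seq_len(z)) iv[j] <- tt[k - z + j] - tt[k - z + j - 1]
      s <- sort(iv)
      med <- if (z %% 2 == 1) s[(z + 1) / 2] else (s[z / 2] + s[z / 2 + 1]) / 2
      out <- rbind(out, c(k = k, elapsed = tt[k] - tt[1],
                          C = 100 * max(abs(iv - med)) / med, rr = 60 / med))
    }
  }
  if (is.null(out)) {
    data.frame(k = integer(), elapsed = numeric(), C = numeric(), rr = numeric())
  } else {
    as.data.frame(out)
  }
}

# Earliest acceptance per threshold from a brute_window_stats table.
brute_first_valid <- function(stats, th_c, rr_min = 2, rr_max = 140) {
  ok <- stats$C <= th_c & stats$rr >= rr_min & stats$rr <= rr_max
  which(ok)[1]
}

# Random tap log with lognormal intervals and occasional large outliers,
# exercising accept, reject and fail paths of the estimator.
random_tap_times <- function(n_taps = sample(5:40, 1)) {
  iv <- stats::rlnorm(n_taps - 1, meanlog = log(1.5), sdlog = 0.35)
  big <- stats::runif(n_taps - 1) < 0.12
  iv[big] <- iv[big] * stats::runif(sum(big), 1.8, 3.2)
  cumsum(c(0, iv))
}

# Constant-spacing helper used by fixture tests.
constant_taps <- function(n, spacing = 1.5, start = 0) {
  start + spacing * (seq_len(n) - 1)
}
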