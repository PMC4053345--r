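# Accuracy ----------------------------------------------------------------

#' Normalized root mean square error of estimated vs reference rates
#'
#' `NRMSE = 100 * sqrt( mean( ((RR - RR_ref) / RR_ref)^2 ) )`, in percent.
#' The relative error is taken per observation against that observation's own
#' reference, so an NRMSE of 5.6% corresponds to an RMS error of about 2.2
#' breaths/min at a reference rate of 40 breaths/min.
#'
#' @param rr Estimated rates, breaths/min.
#' @param rr_ref Reference rates, breaths/min, same length, all positive.
#' @return NRMSE in percent.
#' @examples
#' nrmse(42, 40) # 5
#' @export
nrmse <- function(rr, rr_ref) {
  if (length(rr) < 1 || length(rr) != length(rr_ref)) {
    stop("rr and rr_ref must be non-empty and of equal length", call. = FALSE)
  }
  if (anyNA(rr) || anyNA(rr_ref) || any(rr_ref <= 0)) {
    stop("rates must be non-missing and references positive", call. = FALSE)
  }
  100 * sqrt(mean(((rr - rr_ref) / rr_ref)^2))
}

# Efficiency ---------------------------------------------------------------

#' Efficiency and completion-rate statistics for a batch of estimates
#'
#' Efficiency E is the time from the first tap to the reported rate.
#' Observations that did not complete contribute `E = max_duration` to every
#' efficiency statistic and reduce the completion rate
#' `CR = 100 * (n - n_fail) / n`. The 95th percentile uses linear
#' interpolation between order statistics.
#'
#' @param estimates A list of `rr_estimate` objects (see [estimate_rr()]).
#' @param max_duration Failure-penalty time in seconds (default 60).
#' @return A list with `n`, `n_fail`, `e_median`, `e_mean`, `e_p95` (seconds)
#'   and `cr` (percent).
#' @export
efficiency_stats <- function(estimates, max_duration = 60) {
  if (length(estimates) < 1) stop("at least one estimate is required", call. = FALSE)
  completed <- vapply(estimates, function(e) isTRUE(e$completed), logical(1))
  e <- vapply(estimates, function(x) x$efficiency, numeric(1))
  e[!completed] <- max_duration
  summarize_e(e, completed)
}

summarize_e <- function(e, completed) {
  n <- length(e)
  n_fail <- sum(!completed)
  list(
    n = n, n_fail = n_fail,
    e_median = stats::median(e), e_mean = mean(e),
    e_p95 = unname(stats::quantile(e, 0.95, type = 7)),
    cr = 100 * (n - n_fail) / n
  )
}

# Agreement ----------------------------------------------------------------

#' Bland-Altman agreement between estimated and reference rates
#'
#' Differences are estimate minus reference. The limits of agreement are the
#' bias plus/minus twice the sample standard deviation of the differences.
#'
#' @param rr Estimated rates, breaths/min.
#' @param rr_ref Reference rates, same length (>= 2).
#' @return An object of class `bland_altman`: list with `bias`, `sd`,
#'   `loa_low`, `loa_high` (breaths/min) and `n`.
#' @examples
#' bland_altman(c(41, 39), c(40, 40)) # bias 0, sd 1.414
#' @export
bland_altman <- function(rr, rr_ref) {
  if (length(rr) < 2 || length(rr) != length(rr_ref)) {
    stop("bland_altman requires at least 2 paired observations", call. = FALSE)
  }
  d <- rr - rr_ref
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(bias = bias, sd = s, loa_low = bias - 2 * s, loa_high = bias + 2 * s,
         n = length(d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.2f breaths/min, SD %.2f; limits of agreement [%.2f, %.2f]\n",
    x$n, x$bias, x$sd, x$loa_low, x$loa_high
  ))
  invisible(x)
}

# Batch replay -------------------------------------------------------------

#' Evaluate one (z, Th_C) configuration over a collection of tap logs
#'
#' Runs the streaming estimator on every log and aggregates accuracy (NRMSE,
#' over completed observations only), efficiency and completion rate.
#'
#' @inheritParams estimate_rr
#' @param logs A list of [tap_log] objects.
#' @return A one-row data frame with columns `z`, `th_c` (`NA` when the
#'   threshold is disabled), `n`, `n_fail`, `cr`, `nrmse`, `e_median`,
#'   `e_mean`, `e_p95`.
#' @export
evaluate_config <- function(logs, z = 4, th_c = 13, rr_min = 2, rr_max = 140,
                            max_duration = 60) {
  if (length(logs) < 1) stop("logs must be non-empty", call. = FALSE)
  ests <- lapply(logs, estimate_rr, z = z, th_c = th_c, rr_min = rr_min,
                 rr_max = rr_max, max_duration = max_duration)
  es <- efficiency_stats(ests, max_duration)
  done <- vapply(ests, function(e) e$completed, logical(1))
  acc <- if (any(done)) {
    nrmse(vapply(ests[done], function(e) e$rr, numeric(1)),
          vapply(logs[done], function(l) l$rr_ref, numeric(1)))
  } else {
    NA_real_
  }
  th <- normalize_th_c(th_c)
  data.frame(
    z = as.integer(z), th_c = if (is.infinite(th)) NA_real_ else th,
    n = es$n, n_fail = es$n_fail, cr = es$cr, nrmse = acc,
    e_median = es$e_median, e_mean = es$e_mean, e_p95 = es$e_p95
  )
}

# Precompute, for every log and every grid cell, the outcome of the streaming
# estimator: completion, efficiency (failure-penalized) and the reported rate.
# One window profile per (log, z) serves every threshold, which keeps the
# full sensitivity grid and the cross-validation affordable.
replay_matrices <- function(logs, z_values, th_c_values, rr_min = 2,
                            rr_max = 140, max_duration = 60) {
  cells <- expand.grid(th_c = th_c_values, z = z_values)[, c("z", "th_c")]
  n_logs <- length(logs)
  n_cells <- nrow(cells)
  E <- matrix(max_duration, n_logs, n_cells)
  RR <- matrix(NA_real_, n_logs, n_cells)
  done <- matrix(FALSE, n_logs, n_cells)
  th_by_z <- split(seq_len(n_cells), cells$z)
  for (i in seq_len(n_logs)) {
    tt <- logs[[i]]$tap_times
    for (z in z_values) {
      cols <- th_by_z[[as.character(z)]]
      prof <- window_profile(tt, z, max_duration)
      if (nrow(prof) == 0) next
      ok <- prof$rr >= rr_min & prof$rr <= rr_max
      for (ci in cols) {
        j <- which(ok & prof$consistency <= cells$th_c[ci])[1]
        if (!is.na(j)) {
          E[i, ci] <- prof$elapsed[j]
          RR[i, ci] <- prof$rr[j]
          done[i, ci] <- TRUE
        }
      }
    }
  }
  rr_ref <- vapply(logs, function(l) l$rr_ref, numeric(1))
  list(cells = cells, E = E, rr = RR, completed = done, rr_ref = rr_ref,
       max_duration = max_duration)
}

# Summarize a subset of logs (rows) for every cell of a replay_matrices object.
summarize_cells <- function(mat, rows = seq_len(nrow(mat$E))) {
  E <- mat$E[rows, , drop = FALSE]
  done <- mat$completed[rows, , drop = FALSE]
  relsq <- ((mat$rr[rows, , drop = FALSE] - mat$rr_ref[rows]) / mat$rr_ref[rows])^2
  relsq[!done] <- NA
  n <- nrow(E)
  n_fail <- n - colSums(done)
  acc <- 100 * sqrt(colMeans(relsq, na.rm = TRUE))
  acc[colSums(done) == 0] <- NA_real_
  data.frame(
    z = as.integer(mat$cells$z),
    th_c = ifelse(is.infinite(mat$cells$th_c), NA_real_, mat$cells$th_c),
    n = n, n_fail = n_fail, cr = 100 * (n - n_fail) / n, nrmse = acc,
    e_median = apply(E, 2, stats::median),
    e_mean = colMeans(E),
    e_p95 = apply(E, 2, function(x) unname(stats::quantile(x, 0.95, type = 7)))
  )
}

#' Sensitivity grid over set size and consistency threshold
#'
#' Replays every tap log through the streaming estimator for each combination
#' of set size `z` and consistency threshold `Th_C`, plus (optionally) the
#' threshold-disabled column, and aggregates NRMSE, efficiency and completion
#' rate per cell. Also computes a reference NRMSE from the median of all
#' intervals each log accumulated within the measurement window (the
#' "use every tap" benchmark), stored in the `reference_nrmse` attribute.
#'
#' @inheritParams evaluate_config
#' @param z_values Integer set sizes to scan (default 2 to 15).
#' @param th_c_values Consistency thresholds in percent (default 2 to 30).
#' @param include_disabled Add the threshold-disabled column per z.
#' @return A data frame of class `rr_grid`, one row per (z, th_c) cell with
#'   the columns of [evaluate_config()]; `th_c` is `NA` for disabled rows.
#' @examples
#' logs <- lapply(1:5, function(s) simulate_taps(40, seed = s))
#' g <- replay_grid(logs, z_values = c(3, 4), th_c_values = c(10, 13))
#' @export
replay_grid <- function(logs, z_values = 2:15, th_c_values = 2:30,
                        include_disabled = TRUE, rr_min = 2, rr_max = 140,
                        max_duration = 60) {
  if (length(logs) < 1) stop("logs must be non-empty", call. = FALSE)
  th <- as.numeric(th_c_values)
  if (include_disabled) th <- c(th, Inf)
  mat <- replay_matrices(logs, z_values, th, rr_min, rr_max, max_duration)
  out <- summarize_cells(mat)
  ref_rr <- vapply(logs, function(l) {
    tt <- l$tap_times
    tt <- tt[tt - tt[1] <= max_duration]
    if (length(tt) < 2) NA_real_ else 60 / stats::median(diff(tt))
  }, numeric(1))
  keep <- !is.na(ref_rr)
  ref <- if (any(keep)) {
    nrmse(ref_rr[keep], vapply(logs, function(l) l$rr_ref, numeric(1))[keep])
  } else {
    NA_real_
  }
  structure(out, class = c("rr_grid", "data.frame"), reference_nrmse = ref)
}

#' @export
print.rr_grid <- function(x, ...) {
  cat(sprintf("Sensitivity grid: %d cells (z %d-%d; Th_C %s)\n",
              nrow(x), min(x$z), max(x$z),
              paste0(range(x$th_c, na.rm = TRUE), collapse = "-")))
  ok <- !is.na(x$nrmse)
  if (any(ok)) {
    best <- x[ok, ][which.min(x$nrmse[ok]), ]
    cat(sprintf("  lowest NRMSE %.2f%% at z = %d, Th_C = %s (CR %.1f%%, mean E %.1f s)\n",
                best$nrmse, best$z,
                if (is.na(best$th_c)) "off" else sprintf("%g%%", best$th_c),
                best$cr, best$e_mean))
  }
  if (!is.na(attr(x, "reference_nrmse"))) {
    cat(sprintf("  all-taps reference NRMSE: %.2f%%\n", attr(x, "reference_nrmse")))
  }
  invisible(x)
}

#' Plot accuracy and efficiency surfaces of a sensitivity grid
#'
#' Draws NRMSE (and optionally mean efficiency) against the consistency
#' threshold, one line per set size, on base graphics.
#'
#' @param x An `rr_grid` from [replay_grid()].
#' @param what `"nrmse"` or `"e_mean"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.rr_grid <- function(x, what = c("nrmse", "e_mean"), ...) {
  what <- match.arg(what)
  g <- x[!is.na(x$th_c), ]
  wide <- tapply(g[[what]], list(g$th_c, g$z), mean)
  graphics::matplot(as.numeric(rownames(wide)), wide, type = "l", lty = 1,
                    xlab = "consistency threshold Th_C (%)",
                    ylab = if (what == "nrmse") "NRMSE (%)" else "mean E (s)",
                    ...)
  invisible(x)
}

# Descriptive regression --------------------------------------------------

#' Linear trend summary of a sensitivity grid
#'
#' Ordinary least squares fits of NRMSE and of median efficiency on the set
#' size z and the consistency threshold, over the threshold-enabled cells
#' with a defined NRMSE. Descriptive only: it reports the direction and
#' strength of the accuracy and efficiency trends across the grid.
#'
#' @param grid An `rr_grid` from [replay_grid()].
#' @return An object of class `rr_grid_lm`: list with `nrmse_fit` and
#'   `e_median_fit` (both `lm`), their coefficient tables and R-squared.
#' @export
regression_summary <- function(grid) {
  g <- as.data.frame(grid)
  g <- g[!is.na(g$th_c) & !is.na(g$nrmse), ]
  if (length(unique(g$z)) < 2 || length(unique(g$th_c)) < 2) {
    stop("grid must contain at least 2 distinct z and th_c levels", call. = FALSE)
  }
  f1 <- stats::lm(nrmse ~ z + th_c, data = g)
  f2 <- stats::lm(e_median ~ z + th_c, data = g)
  structure(
    list(
      nrmse_fit = f1, e_median_fit = f2,
      nrmse_coef = summary(f1)$coefficients,
      e_median_coef = summary(f2)$coefficients,
      nrmse_r2 = summary(f1)$r.squared,
      e_median_r2 = summary(f2)$r.squared
    ),
    class = "rr_grid_lm"
  )
}

#' @export
print.rr_grid_lm <- function(x, ...) {
  cat("Linear trends across the sensitivity grid\n")
  cat(sprintf("  NRMSE ~ z + Th_C: R^2 = %.3f; slope in z %+.3f, in Th_C %+.3f\n",
              x$nrmse_r2, stats::coef(x$nrmse_fit)["z"],
              stats::coef(x$nrmse_fit)["th_c"]))
  cat(sprintf("  median E ~ z + Th_C: R^2 = %.3f; slope in z %+.3f, in Th_C %+.3f\n",
              x$e_median_r2, stats::coef(x$e_median_fit)["z"],
              stats::coef(x$e_median_fit)["th_c"]))
  invisible(x)
}
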