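#' Inter-tap intervals from tap timestamps
#'
#' @param tap_times Strictly increasing numeric vector of tap timestamps in
#'   seconds, length at least 2.
#' @return Numeric vector of successive differences, one element shorter than
#'   the input, all positive.
#' @examples
#' intervals_from_taps(c(0, 1.0, 2.2, 3.6, 5.6))
#' @export
intervals_from_taps <- function(tap_times) {
  tap_times <- tap_times_of(tap_times)
  if (length(tap_times) < 2) {
    stop("at least 2 tap timestamps are required to form an interval", call. = FALSE)
  }
  iv <- diff(tap_times)
  if (any(iv <= 0)) {
    stop("tap timestamps must be strictly increasing", call. = FALSE)
  }
  iv
}

#' Median inter-tap interval
#'
#' The middle order statistic for an odd number of intervals, the arithmetic
#' mean of the two middle order statistics for an even number.
#'
#' @param intervals Numeric vector of positive interval durations in seconds.
#' @return The median interval in seconds.
#' @examples
#' median_interval(c(1.0, 1.2, 1.4, 2.0)) # 1.3
#' @export
median_interval <- function(intervals) {
  if (length(intervals) < 1) {
    stop("at least one interval is required", call. = FALSE)
  }
  if (anyNA(intervals) || any(intervals <= 0)) {
    stop("all intervals must be positive and non-missing", call. = FALSE)
  }
  stats::median(intervals)
}

#' Consistency of a set of tap intervals
#'
#' Consistency C is the maximum percentage absolute deviation of any interval
#' in the set from the set's median interval:
#' `C = 100 * max_i |I_i - Imed| / Imed`. C is zero exactly when all
#' intervals are equal, and is invariant to rescaling all intervals by a
#' common positive factor.
#'
#' @param intervals Numeric vector of positive interval durations, length >= 2.
#' @return Consistency in percent (>= 0).
#' @examples
#' consistency(c(1.0, 1.1, 1.0)) # 10
#' @export
consistency <- function(intervals) {
  if (length(intervals) < 2) {
    stop("consistency requires at least 2 intervals", call. = FALSE)
  }
  med <- median_interval(intervals)
  100 * max(abs(intervals - med)) / med
}

#' Respiratory rate from a median interval
#'
#' @param median_interval Positive median inter-breath interval in seconds.
#' @return Respiratory rate in breaths/min, `60 / median_interval`.
#' @examples
#' rr_from_median(1.5) # 40
#' @export
rr_from_median <- function(median_interval) {
  if (length(median_interval) != 1 || is.na(median_interval) || median_interval <= 0) {
    stop("median_interval must be a single positive number", call. = FALSE)
  }
  60 / median_interval
}

#' Evaluate one set of intervals against a consistency threshold
#'
#' A set is accepted when its consistency is equal to or lower than the
#' threshold (the boundary case accepts).
#'
#' @param intervals Numeric vector of positive intervals, length >= 2.
#' @param th_c Consistency threshold in percent; `Inf` disables the test.
#' @return A list with `accepted` (logical) and `set`, an `interval_set`
#'   object carrying the intervals, their median and consistency.
#' @examples
#' evaluate_set(c(1.0, 1.13, 1.0, 1.0), th_c = 13)$accepted # TRUE at boundary
#' @export
evaluate_set <- function(intervals, th_c) {
  th_c <- normalize_th_c(th_c)
  set <- interval_set(intervals)
  list(accepted = set$consistency <= th_c, set = set)
}

#' Interval set with its summary statistics
#'
#' @param intervals Numeric vector of positive intervals, length >= 2.
#' @return An object of class `interval_set`: list with `intervals`,
#'   `median_interval` (seconds) and `consistency` (percent).
#' @export
interval_set <- function(intervals) {
  structure(
    list(
      intervals = as.numeric(intervals),
      median_interval = median_interval(intervals),
      consistency = consistency(intervals)
    ),
    class = "interval_set"
  )
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf(
    "Interval set: z = %d, median %.3f s (RR %.1f breaths/min), consistency %.1f%%\n",
    length(x$intervals), x$median_interval, 60 / x$median_interval, x$consistency
  ))
  invisible(x)
}

# th_c may be given as a number (percent), Inf, NA, NULL, or the string "off";
# the last three disable the consistency test. Canonical internal form is Inf.
normalize_th_c <- function(th_c) {
  if (is.null(th_c) || length(th_c) == 0) return(Inf)
  if (is.character(th_c)) {
    if (tolower(th_c) %in% c("off", "none", "disabled")) return(Inf)
    th_c <- suppressWarnings(as.numeric(th_c))
  }
  if (is.na(th_c)) return(Inf)
  if (th_c <= 0) stop("th_c must be positive (or 'off' to disable)", call. = FALSE)
  as.numeric(th_c)
}

# Per-window statistics for one tap log at a fixed set size z: for every tap
# index k >= z+1 whose elapsed time from the first tap is within max_duration,
# the consistency and RR of the z most recent intervals ending at tap k.
# This is the workhorse shared by estimate_rr() and the grid replay.
window_profile <- function(tap_times, z, max_duration = 60) {
  n <- length(tap_times)
  empty <- data.frame(k = integer(), elapsed = numeric(), consistency = numeric(), rr = numeric())
  if (n < 2) return(empty)
  iv <- intervals_from_taps(tap_times)
  elapsed_all <- tap_times - tap_times[1]
  kmax <- max(which(elapsed_all <= max_duration)) # cap fires at the first tap beyond it
  if (kmax < z + 1) return(empty)
  W <- embed(iv[seq_len(kmax - 1)], z) # row j = intervals ending at tap j + z
  med <- apply(W, 1, stats::median)
  dev <- abs(W - med) # column recycling is by row index: med has length nrow(W)
  C <- 100 * apply(dev, 1, max) / med
  k <- seq_len(nrow(W)) + z
  data.frame(k = k, elapsed = elapsed_all[k], consistency = C, rr = 60 / med)
}

#' Streaming respiratory-rate estimate from a tap log
#'
#' Walks the taps in time order. From the (z+1)-th tap onward, the set of the
#' z most recent inter-tap intervals is evaluated after every new tap: the
#' earliest tap discards from the set and the newest appends. The first set
#' whose consistency is at or below `th_c` (always, if the threshold is
#' disabled) and whose implied rate lies within `[rr_min, rr_max]` is
#' reported: RR is 60 s divided by the set's median interval, and efficiency
#' is the elapsed time from the first tap to the accepting tap. If no set is
#' accepted by the end of the log or within `max_duration` seconds of the
#' first tap, the estimate is incomplete and efficiency is set to
#' `max_duration`.
#'
#' @param taps A [tap_log] or a bare numeric vector of tap timestamps.
#' @param z Number of intervals per set (>= 2); z + 1 taps is the minimum to
#'   complete a measurement.
#' @param th_c Consistency threshold in percent; `Inf`, `NA` or `"off"`
#'   disables the test so the first full set is accepted.
#' @param rr_min,rr_max Reportable rate range in breaths/min; a set whose
#'   rate falls outside it is treated as not valid and tapping continues.
#' @param max_duration Measurement cap in seconds, counted from the first tap.
#' @return An object of class `rr_estimate`: list with `rr` (breaths/min, `NA`
#'   if incomplete), `efficiency` (seconds), `taps_used`, `completed`,
#'   `accepted_set` (an `interval_set`, or `NULL`), and the configuration used.
#' @examples
#' estimate_rr(c(0, 1.5, 3.0, 4.5, 6.0), z = 4, th_c = 13)
#' @export
estimate_rr <- function(taps, z = 4, th_c = 13, rr_min = 2, rr_max = 140,
                        max_duration = 60) {
  tt <- tap_times_of(taps)
  if (length(tt) >= 2 && any(diff(tt) <= 0)) {
    stop("tap timestamps must be strictly increasing", call. = FALSE)
  }
  z <- as.integer(z)
  if (is.na(z) || z < 2) stop("z must be an integer >= 2", call. = FALSE)
  if (rr_min >= rr_max) stop("rr_min must be below rr_max", call. = FALSE)
  th_c <- normalize_th_c(th_c)

  prof <- window_profile(tt, z, max_duration)
  valid <- prof$consistency <= th_c & prof$rr >= rr_min & prof$rr <= rr_max
  j <- which(valid)[1]

  if (length(j) == 1 && !is.na(j)) {
    k <- prof$k[j]
    set <- interval_set(diff(tt[(k - z):k]))
    out <- list(
      rr = prof$rr[j], efficiency = prof$elapsed[j], taps_used = k,
      completed = TRUE, accepted_set = set
    )
  } else {
    consumed <- if (length(tt) == 0) 0L else sum(tt - tt[1] <= max_duration)
    out <- list(
      rr = NA_real_, efficiency = max_duration, taps_used = consumed,
      completed = FALSE, accepted_set = NULL
    )
  }
  out$config <- list(z = z, th_c = th_c, rr_min = rr_min, rr_max = rr_max,
                     max_duration = max_duration)
  if (is_tap_log(taps)) {
    out$subject_id <- taps$subject_id
    out$video_id <- taps$video_id
    out$rr_ref <- taps$rr_ref
  }
  class(out) <- "rr_estimate"
  out
}

#' @export
print.rr_estimate <- function(x, ...) {
  thc <- if (is.infinite(x$config$th_c)) "off" else sprintf("%g%%", x$config$th_c)
  if (x$completed) {
    cat(sprintf(
      "RR estimate: %.1f breaths/min (z = %d, Th_C %s)\n  efficiency %.1f s, %d taps, set consistency %.1f%%\n",
      x$rr, x$config$z, thc, x$efficiency, x$taps_used, x$accepted_set$consistency
    ))
  } else {
    cat(sprintf(
      "RR estimate: incomplete within %.0f s (z = %d, Th_C %s); efficiency set to %.0f s\n",
      x$config$max_duration, x$config$z, thc, x$config$max_duration
    ))
  }
  invisible(x)
}

#' @export
summary.rr_estimate <- function(object, ...) {
  print(object)
  if (object$completed) print(object$accepted_set)
  if (!is.null(object$rr_ref) && object$completed) {
    cat(sprintf("  reference RR %.1f breaths/min, error %+.2f breaths/min\n",
                object$rr_ref, object$rr - object$rr_ref))
  }
  invisible(object)
}
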