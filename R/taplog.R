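#' Construct a tap log
#'
#' A tap log is one observation: the ordered timestamps (seconds from session
#' start) at which an observer tapped in time with a subject's inhalations,
#' together with the reference respiratory rate obtained by expert observation.
#'
#' @param tap_times Numeric vector of tap timestamps in seconds, strictly
#'   increasing. May be empty (an observation where no taps were recorded).
#' @param rr_ref Reference respiratory rate in breaths/min; must be positive.
#' @param subject_id,video_id Opaque identifier strings.
#'
#' @return An object of class `tap_log`: a list with elements `subject_id`,
#'   `video_id`, `tap_times` and `rr_ref`.
#' @examples
#' log <- tap_log(c(0, 1.5, 3.0, 4.5), rr_ref = 40)
#' estimate_rr(log, z = 2, th_c = 13)
#' @export
tap_log <- function(tap_times, rr_ref, subject_id = "s1", video_id = "v1") {
  tap_times <- as.numeric(tap_times)
  if (anyNA(tap_times)) {
    stop("tap_times must not contain missing values", call. = FALSE)
  }
  if (length(tap_times) >= 2 && any(diff(tap_times) <= 0)) {
    stop("tap_times must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(rr_ref) || length(rr_ref) != 1 || is.na(rr_ref) || rr_ref <= 0) {
    stop("rr_ref must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      video_id = as.character(video_id),
      tap_times = tap_times,
      rr_ref = as.numeric(rr_ref)
    ),
    class = "tap_log"
  )
}

#' @export
print.tap_log <- function(x, ...) {
  cat(sprintf(
    "Tap log [subject %s, video %s]: %d taps over %.1f s, reference RR %.1f breaths/min\n",
    x$subject_id, x$video_id, length(x$tap_times),
    if (length(x$tap_times) >= 2) diff(range(x$tap_times)) else 0,
    x$rr_ref
  ))
  invisible(x)
}

is_tap_log <- function(x) inherits(x, "tap_log")

# Coerce input (tap_log or bare numeric vector) to a timestamp vector.
tap_times_of <- function(taps) {
  if (is_tap_log(taps)) taps$tap_times else as.numeric(taps)
}
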