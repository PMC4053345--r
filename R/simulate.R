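# Seed plumbing -----------------------------------------------------------

# Evaluate code under a temporary RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic substream seed from a master seed and one or two indices.
# Arithmetic stays below 2^53 so doubles are exact; result is in [1, 2^31 - 20].
derive_seed <- function(seed, i, j = 0) {
  m <- 2147483629
  s <- ((seed %% m) * 48271) %% m
  s <- (s + i * 1664525 + j * 22695477 + 12345) %% m
  as.integer(s + 1)
}

# Tapper model -------------------------------------------------------------

#' Simulate one synthetic tap log
#'
#' Emulates an observer tapping a touch screen in time with a breathing
#' subject. Inter-breath intervals are drawn from a Gamma distribution with
#' mean `60 / rr_true` and coefficient of variation `breath_cv` (constant
#' intervals when `breath_cv = 0`). Each breath is tapped with independent
#' Gaussian motor jitter (`tap_jitter_sd`); with probability `p_missed` a
#' breath is not tapped, merging two intervals; with probability `p_extra` a
#' spurious tap is inserted uniformly inside an inter-tap gap, splitting an
#' interval. Taps are truncated at `duration` seconds, and jitter is resampled
#' wherever it would break the strictly increasing order of timestamps. The
#' whole draw is reproducible from `seed`.
#'
#' @param rr_true True respiratory rate in breaths/min (> 0).
#' @param breath_cv Coefficient of variation of inter-breath intervals (>= 0).
#' @param tap_jitter_sd Standard deviation of tap timing error, seconds (>= 0).
#' @param p_missed Probability a breath goes untapped, in [0, 1).
#' @param p_extra Probability of a spurious extra tap per gap, in [0, 1).
#' @param duration Session length in seconds (> 0).
#' @param seed Integer seed for reproducibility.
#' @param subject_id,video_id Identifiers stored on the resulting log.
#' @param rr_ref Reference rate recorded on the log; defaults to `rr_true`.
#' @return A [tap_log] whose `rr_ref` is the simulated subject's true rate.
#' @examples
#' log <- simulate_taps(rr_true = 40, breath_cv = 0, tap_jitter_sd = 0,
#'                      p_missed = 0, p_extra = 0, seed = 1)
#' length(log$tap_times) # 41 taps at exact 1.5 s spacing in 60 s
#' @export
simulate_taps <- function(rr_true, breath_cv = 0.08, tap_jitter_sd = 0.06,
                          p_missed = 0.05, p_extra = 0.02, duration = 60,
                          seed = 1, subject_id = "sim", video_id = "sim",
                          rr_ref = rr_true) {
  stopifnot(rr_true > 0, breath_cv >= 0, tap_jitter_sd >= 0, duration > 0)
  if (p_missed < 0 || p_missed >= 1 || p_extra < 0 || p_extra >= 1) {
    stop("p_missed and p_extra must lie in [0, 1)", call. = FALSE)
  }
  taps <- with_seed(seed, {
    m <- 60 / rr_true
    n_gen <- ceiling(duration / m * 2) + 30
    iv <- if (breath_cv == 0) {
      rep(m, n_gen)
    } else {
      shape <- 1 / breath_cv^2
      stats::rgamma(n_gen, shape = shape, rate = shape / m)
    }
    breaths <- c(0, cumsum(iv))
    breaths <- breaths[breaths <= duration + 1e-9]

    tapped <- breaths[stats::runif(length(breaths)) >= p_missed]
    t2 <- tapped
    if (tap_jitter_sd > 0 && length(tapped) > 0) {
      t2 <- tapped + stats::rnorm(length(tapped), 0, tap_jitter_sd)
      for (iter in seq_len(10000)) {
        bad <- which(diff(t2) <= 0)
        if (length(bad) == 0) break
        redo <- unique(c(bad, bad + 1))
        t2[redo] <- tapped[redo] + stats::rnorm(length(redo), 0, tap_jitter_sd)
      }
      if (any(diff(t2) <= 0)) {
        stop("could not realize strictly increasing taps; jitter too large for the breathing rate",
             call. = FALSE)
      }
    }
    if (p_extra > 0 && length(t2) >= 2) {
      gaps <- diff(t2)
      split <- which(stats::runif(length(gaps)) < p_extra)
      if (length(split) > 0) {
        extras <- t2[split] + stats::runif(length(split), 0, 1) * gaps[split]
        t2 <- sort(c(t2, extras))
      }
    }
    if (length(t2) > 0 && min(t2) < 0) t2 <- t2 - min(t2) # session clock starts at first tap
    t2[t2 <= duration + 1e-9]
  })
  tap_log(taps, rr_ref = rr_ref, subject_id = subject_id, video_id = video_id)
}

#' Simulate a full tapping study
#'
#' Generates one tap log per (subject, video) pair, emulating a panel of
#' observers each tapping along with a set of standard videos of breathing
#' subjects. The default reference rates are those of the ten standard videos
#' (17 to 59 breaths/min). Each subject gets its own motor skill and each
#' subject watches the videos in an independently randomized order (recorded
#' in the result's `video_order` attribute). Subject-level breathing-
#' variability and jitter parameters are drawn around the supplied means with
#' lognormal spread `subject_sd`, so some simulated observers tap more
#' consistently than others. All randomness streams from `seed` through
#' per-subject substreams: any (subject, video) log can be regenerated alone.
#'
#' @param n_subjects Number of simulated observers (>= 1).
#' @param video_rrs Reference rates of the videos, breaths/min.
#' @param breath_cv,tap_jitter_sd,p_missed,p_extra,duration Mean tapper-model
#'   parameters; see [simulate_taps()].
#' @param subject_sd Lognormal sigma of the per-subject multiplicative factor
#'   applied to `breath_cv` and `tap_jitter_sd` (0 disables between-subject
#'   variation).
#' @param seed Integer master seed.
#' @return A list of [tap_log] objects of class `tap_log_list`, length
#'   `n_subjects * length(video_rrs)`, with attributes `video_order` (matrix
#'   of per-subject viewing orders) and `design` (the parameters used).
#' @examples
#' study <- simulate_study(n_subjects = 2, seed = 7)
#' length(study) # 20
#' @export
simulate_study <- function(n_subjects = 30,
                           video_rrs = c(56, 33, 59, 47, 51, 30, 38, 24, 17, 17),
                           breath_cv = 0.08, tap_jitter_sd = 0.06,
                           p_missed = 0.05, p_extra = 0.02, duration = 60,
                           subject_sd = 0.3, seed = 1) {
  stopifnot(n_subjects >= 1, length(video_rrs) >= 1, all(video_rrs > 0))
  n_videos <- length(video_rrs)
  logs <- vector("list", n_subjects * n_videos)
  order_mat <- matrix(NA_integer_, n_subjects, n_videos)
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    sseed <- derive_seed(seed, s)
    subj <- with_seed(sseed, {
      fac <- if (subject_sd > 0) exp(stats::rnorm(2, 0, subject_sd)) else c(1, 1)
      list(cv = breath_cv * fac[1], jit = tap_jitter_sd * fac[2],
           order = sample.int(n_videos))
    })
    order_mat[s, ] <- subj$order
    for (v in subj$order) {
      idx <- idx + 1L
      logs[[idx]] <- simulate_taps(
        rr_true = video_rrs[v], breath_cv = subj$cv, tap_jitter_sd = subj$jit,
        p_missed = p_missed, p_extra = p_extra, duration = duration,
        seed = derive_seed(seed, s, v),
        subject_id = sprintf("S%02d", s), video_id = sprintf("V%02d", v)
      )
    }
  }
  structure(
    logs,
    class = c("tap_log_list", "list"),
    video_order = order_mat,
    design = list(
      n_subjects = n_subjects, video_rrs = video_rrs, breath_cv = breath_cv,
      tap_jitter_sd = tap_jitter_sd, p_missed = p_missed, p_extra = p_extra,
      duration = duration, subject_sd = subject_sd, seed = seed
    )
  )
}

#' @export
print.tap_log_list <- function(x, ...) {
  n_taps <- vapply(x, function(l) length(l$tap_times), integer(1))
  cat(sprintf("Collection of %d tap logs (%d-%d taps each)\n",
              length(x), min(n_taps), max(n_taps)))
  invisible(x)
}
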