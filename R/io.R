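# Tap-log files ------------------------------------------------------------
#
# Canonical on-disk form is a long CSV, one row per tap:
#   subject_id,video_id,rr_ref,tap_time_s
# An equivalent JSON form (array of objects with a tap_times array) is read
# and written by file extension. Times are serialized at millisecond
# precision, which round-trips touch-event clocks exactly.

#' Read tap logs from CSV or JSON
#'
#' CSV input must have columns `subject_id`, `video_id`, `rr_ref`,
#' `tap_time_s` (long format, one row per tap). JSON input is an array of
#' objects with `subject_id`, `video_id`, `rr_ref` and a `tap_times` array.
#' Rows within a log are sorted by time (with a warning if they arrive out of
#' order); duplicate timestamps within a log are a validation error naming
#' the offending log. An empty file yields an empty collection with a
#' warning.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A list of [tap_log] objects of class `tap_log_list`.
#' @export
read_tap_logs <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    if (length(recs) == 0) {
      warning("no tap logs found in ", path, call. = FALSE)
      return(structure(list(), class = c("tap_log_list", "list")))
    }
    logs <- lapply(recs, function(r) {
      make_log(r$subject_id, r$video_id, as.numeric(r$rr_ref),
               as.numeric(unlist(r$tap_times)))
    })
    return(structure(logs, class = c("tap_log_list", "list")))
  }
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) data.frame())
  if (nrow(df) == 0) {
    warning("no tap logs found in ", path, call. = FALSE)
    return(structure(list(), class = c("tap_log_list", "list")))
  }
  need <- c("subject_id", "video_id", "rr_ref", "tap_time_s")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  key <- paste(df$subject_id, df$video_id, sep = "\r")
  logs <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    g <- df[idx, ]
    make_log(g$subject_id[1], g$video_id[1], g$rr_ref[1], g$tap_time_s)
  })
  names(logs) <- NULL
  structure(logs, class = c("tap_log_list", "list"))
}

make_log <- function(subject_id, video_id, rr_ref, times) {
  label <- sprintf("subject %s, video %s", subject_id, video_id)
  if (anyDuplicated(times)) {
    stop(sprintf("duplicate tap timestamps in log (%s)", label), call. = FALSE)
  }
  if (is.unsorted(times)) {
    warning(sprintf("taps out of order in log (%s); reordered by timestamp", label),
            call. = FALSE)
    times <- sort(times)
  }
  tap_log(times, rr_ref = rr_ref, subject_id = subject_id, video_id = video_id)
}

#' Write tap logs to CSV or JSON
#'
#' Inverse of [read_tap_logs()]; the format follows the file extension.
#' Timestamps are written at millisecond precision.
#'
#' @param logs A list of [tap_log] objects.
#' @param path Destination `.csv` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_tap_logs <- function(logs, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(logs, function(l) {
      list(subject_id = l$subject_id, video_id = l$video_id, rr_ref = l$rr_ref,
           tap_times = round(l$tap_times, 3))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  rows <- lapply(logs, function(l) {
    if (length(l$tap_times) == 0) return(NULL)
    data.frame(subject_id = l$subject_id, video_id = l$video_id,
               rr_ref = l$rr_ref, tap_time_s = sprintf("%.3f", l$tap_times))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(subject_id = character(), video_id = character(),
                     rr_ref = numeric(), tap_time_s = character())
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sensitivity grid as tidy CSV
#'
#' One row per (z, th_c) cell; disabled-threshold rows carry `th_c = "off"`.
#'
#' @param grid An `rr_grid` from [replay_grid()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  out <- as.data.frame(grid)
  out$th_c <- ifelse(is.na(out$th_c), "off", as.character(out$th_c))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an optimization result as JSON
#'
#' Serializes the per-fold selections, the selected parameters, the per-fold
#' test summaries for the selected and baseline configurations, and the
#' paired comparison.
#'
#' @param cv An `rr_cv` from [crossvalidate()].
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_cv_json <- function(cv, path) {
  jsonlite::write_json(
    list(
      seed = cv$seed, folds = cv$folds,
      selected = cv$selected, baseline_z = cv$baseline_z,
      cost = unclass(cv$config),
      per_fold_best = cv$per_fold_best,
      test_selected = cv$test_selected,
      test_baseline = cv$test_baseline,
      comparison = cv$comparison
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows"
  )
  invisible(path)
}
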