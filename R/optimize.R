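# Cost ---------------------------------------------------------------------

#' Cost-function configuration
#'
#' The trade-off cost is `J = w * NRMSE + E_median + E_p95`, in
#' seconds-equivalent units. The default weighting factor
#' `w = e_limit / nrmse_limit = 15 / 4 = 3.75` s per percent makes the upper
#' acceptable limits for time (15 s) and error (4%) contribute equally, so
#' error and time are balanced at those limits. Failed measurements are
#' already penalized inside the efficiency statistics through E = 60 s, so
#' the completion rate enters the cost implicitly.
#'
#' @param e_limit Upper acceptable efficiency, seconds (default 15).
#' @param nrmse_limit Upper acceptable NRMSE, percent (default 4).
#' @param weight_w Seconds per percent NRMSE; defaults to
#'   `e_limit / nrmse_limit`.
#' @return A list of class `cost_config` with `weight_w`, `e_limit`,
#'   `nrmse_limit`.
#' @export
cost_config <- function(e_limit = 15, nrmse_limit = 4,
                        weight_w = e_limit / nrmse_limit) {
  stopifnot(e_limit > 0, nrmse_limit > 0, weight_w > 0)
  structure(list(weight_w = weight_w, e_limit = e_limit,
                 nrmse_limit = nrmse_limit),
            class = "cost_config")
}

#' Trade-off cost of an evaluation summary
#'
#' @param summary A one-row data frame (or list) with `nrmse`, `e_median` and
#'   `e_p95`, as produced by [evaluate_config()] or the rows of
#'   [replay_grid()].
#' @param config A [cost_config()].
#' @return The cost `J = w * nrmse + e_median + e_p95` in seconds-equivalent;
#'   `Inf` when NRMSE is undefined because no observation completed.
#' @examples
#' cost(list(nrmse = 4, e_median = 7.5, e_p95 = 7.5)) # 30
#' @export
cost <- function(summary, config = cost_config()) {
  j <- config$weight_w * summary$nrmse + summary$e_median + summary$e_p95
  ifelse(is.na(j), Inf, j)
}

# Cross-validation ---------------------------------------------------------

#' Cross-validated selection of (z, Th_C) by cost minimization
#'
#' Observations are binned per video: each video's logs are randomly split
#' into `folds` equal groups (two observations per video per bin in the
#' reference design of 30 observations per video and 15 folds). In each of
#' the `folds` repetitions one bin is held out as the test set; the (z, Th_C)
#' cell minimizing the cost on the training bins is recorded. The selected
#' configuration is the most frequent per-fold minimizer (ties broken by
#' lower mean cost across folds, then smaller z, then smaller Th_C). Test-set
#' summaries are computed per fold for the selected configuration and for the
#' threshold-free baseline, and their per-fold NRMSE values are compared with
#' a two-sided paired t-test.
#'
#' @inheritParams replay_grid
#' @param config A [cost_config()].
#' @param folds Number of cross-validation folds (default 15).
#' @param baseline_z Set size of the threshold-free comparator (default 4).
#' @param seed Integer seed for the bin assignment.
#' @return An object of class `rr_cv`: list with `per_fold_best` (data frame,
#'   one row per fold: selected z, th_c, training cost), `selected` (list
#'   with `z` and `th_c`), `test_selected` and `test_baseline` (per-fold
#'   test-set summary data frames), `comparison` (paired t-test result from
#'   [paired_comparison()]), `assignment` (fold id per log), and `seed`.
#' @export
crossvalidate <- function(logs, z_values = 2:15, th_c_values = 2:30,
                          config = cost_config(), folds = 15, baseline_z = 4,
                          rr_min = 2, rr_max = 140, max_duration = 60,
                          seed = 1) {
  if (length(logs) < folds) stop("need at least one log per fold", call. = FALSE)
  video <- vapply(logs, function(l) l$video_id, character(1))
  counts <- table(video)
  if (any(counts %% folds != 0)) {
    stop(sprintf(
      "each video needs an observation count divisible by the fold count (%d); got: %s",
      folds, paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")
    ), call. = FALSE)
  }
  assignment <- integer(length(logs))
  with_seed(seed, {
    for (v in names(counts)) {
      idx <- which(video == v)
      per_bin <- length(idx) / folds
      assignment[idx] <- sample(rep(seq_len(folds), each = per_bin))
    }
  })

  # search grid (threshold-enabled cells) plus the baseline column appended
  th_search <- as.numeric(th_c_values)
  mat <- replay_matrices(logs, z_values, c(th_search, Inf),
                         rr_min, rr_max, max_duration)
  searchable <- is.finite(mat$cells$th_c)
  baseline_col <- which(mat$cells$z == baseline_z & is.infinite(mat$cells$th_c))
  if (length(baseline_col) != 1) {
    stop("baseline_z must be one of z_values", call. = FALSE)
  }

  per_fold <- vector("list", folds)
  test_rows <- vector("list", folds)
  train_costs <- matrix(NA_real_, folds, sum(searchable))
  for (f in seq_len(folds)) {
    train <- which(assignment != f)
    sm <- summarize_cells(mat, train)
    j <- cost(sm, config)
    j[!searchable] <- Inf
    best <- which.min(j) # cells ordered by z then th_c: ties go to smaller z, then smaller th_c
    train_costs[f, ] <- j[searchable]
    per_fold[[f]] <- data.frame(fold = f, z = sm$z[best], th_c = sm$th_c[best],
                                train_cost = j[best])
  }
  per_fold_best <- do.call(rbind, per_fold)

  # modal selection with deterministic tie-breaking
  key <- paste(per_fold_best$z, per_fold_best$th_c)
  freq <- table(key)
  cand <- names(freq)[freq == max(freq)]
  cells_s <- mat$cells[searchable, ]
  cand_idx <- match(cand, paste(cells_s$z, cells_s$th_c))
  mean_cost <- colMeans(train_costs)[cand_idx]
  ord <- order(mean_cost, cells_s$z[cand_idx], cells_s$th_c[cand_idx])
  pick <- cand_idx[ord[1]]
  selected <- list(z = as.integer(cells_s$z[pick]), th_c = cells_s$th_c[pick])
  sel_col <- which(mat$cells$z == selected$z & mat$cells$th_c == selected$th_c)

  test_selected <- test_baseline <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- which(assignment == f)
    sm <- summarize_cells(mat, test)
    test_selected[[f]] <- cbind(fold = f, sm[sel_col, ])
    test_baseline[[f]] <- cbind(fold = f, sm[baseline_col, ])
  }
  test_selected <- do.call(rbind, test_selected)
  test_baseline <- do.call(rbind, test_baseline)
  rownames(test_selected) <- rownames(test_baseline) <- NULL

  pair_ok <- !is.na(test_selected$nrmse) & !is.na(test_baseline$nrmse)
  comparison <- paired_comparison(test_selected$nrmse[pair_ok],
                                  test_baseline$nrmse[pair_ok])

  structure(
    list(
      per_fold_best = per_fold_best, selected = selected,
      test_selected = test_selected, test_baseline = test_baseline,
      comparison = comparison, assignment = assignment,
      config = config, folds = folds, baseline_z = baseline_z, seed = seed
    ),
    class = "rr_cv"
  )
}

#' @export
print.rr_cv <- function(x, ...) {
  n_sel <- sum(x$per_fold_best$z == x$selected$z &
                 x$per_fold_best$th_c == x$selected$th_c)
  cat(sprintf(
    "Cross-validated parameter selection (%d folds)\n  selected: z = %d, Th_C = %g%% (chosen in %d/%d folds)\n",
    x$folds, x$selected$z, x$selected$th_c, n_sel, x$folds
  ))
  fmt <- function(d) sprintf("NRMSE %.1f +/- %.1f%%, mean E %.1f +/- %.1f s, E95 %.1f +/- %.1f s, CR %.1f%%",
                             mean(d$nrmse, na.rm = TRUE), stats::sd(d$nrmse, na.rm = TRUE),
                             mean(d$e_mean), stats::sd(d$e_mean),
                             mean(d$e_p95), stats::sd(d$e_p95), mean(d$cr))
  cat("  test sets, selected:  ", fmt(x$test_selected), "\n")
  cat(sprintf("  test sets, z = %d no Th_C: %s\n", x$baseline_z, fmt(x$test_baseline)))
  cmp <- x$comparison
  if (isTRUE(cmp$degenerate)) {
    cat(sprintf("  paired comparison degenerate (constant difference %.3f)\n", cmp$mean_diff))
  } else {
    cat(sprintf("  paired t-test on per-fold NRMSE: t = %.2f, p = %.3g (%ssignificant at 0.05)\n",
                cmp$t, cmp$p, if (cmp$significant) "" else "not "))
  }
  invisible(x)
}

#' Paired comparison of per-fold accuracy
#'
#' Two-sided paired t-test on per-fold NRMSE values from two configurations.
#' If the differences have zero variance the test statistic is undefined; the
#' degenerate case is reported as such rather than tested.
#'
#' @param a,b Equal-length numeric vectors (length >= 2), paired by fold.
#' @param alpha Significance level (default 0.05).
#' @return A list with `t`, `p`, `significant`, `mean_diff` (`mean(a - b)`),
#'   `df`, and `degenerate`.
#' @export
paired_comparison <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("a and b must be paired vectors of equal length >= 2", call. = FALSE)
  }
  d <- a - b
  degenerate_result <- function() {
    # (numerically) constant difference: the t statistic is undefined
    # (0/0 or +/-Inf); report the shift instead of testing
    list(t = if (mean(d) == 0) 0 else NA_real_, p = NA_real_,
         significant = if (mean(d) == 0) FALSE else NA,
         mean_diff = mean(d), df = length(d) - 1L, degenerate = TRUE)
  }
  if (stats::sd(d) == 0) return(degenerate_result())
  tt <- tryCatch(stats::t.test(a, b, paired = TRUE),
                 error = function(e) NULL)
  if (is.null(tt)) return(degenerate_result())
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha, mean_diff = mean(d),
       df = unname(tt$parameter), degenerate = FALSE)
}
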