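# Report generators: correlation table, PMV comparison, gender error
# tests, signal-importance ranking.

#' RMSE and out-of-sample R-squared
#'
#' `rmse = sqrt(mean((pred - truth)^2))`; `r2 = 1 - SS_res/SS_tot` on the
#' evaluation set, so it may be negative. Zero-variance truth leaves `r2`
#' undefined (`NA` with a warning).
#'
#' @param pred,truth equal-length numeric vectors.
#' @return Named vector `(rmse, r2)`.
#' @export
metrics <- function(pred, truth) {
  if (length(pred) != length(truth) || !length(pred)) {
    stop("pred and truth must have equal non-zero length")
  }
  rmse <- sqrt(mean((pred - truth)^2))
  sst <- sum((truth - mean(truth))^2)
  r2 <- if (sst > 0) 1 - sum((pred - truth)^2) / sst else {
    warning("zero-variance truth: R^2 undefined")
    NA_real_
  }
  c(rmse = rmse, r2 = r2)
}

#' Pearson correlation of every feature with reported TS
#'
#' Exact two-tailed p-values from the t distribution with n - 2 degrees of
#' freedom; significance marks `*` (p < 0.05) and `**` (p < 0.01).
#' Constant features get an undefined `r` and are flagged.
#'
#' @param table feature table with `reported_ts`.
#' @param features feature columns to test; defaults to every
#'   [feature_names()] column present.
#' @return Data frame with `feature`, `r`, `p`, `sig`.
#' @export
correlation_table <- function(table, features = NULL) {
  features <- features %||% intersect(feature_names(), names(table))
  y <- table$reported_ts
  n <- length(y)
  if (n < 3) stop("need at least 3 rows")
  if (sd(y) == 0) stop("reported TS is constant")
  rows <- lapply(features, function(f) {
    x <- table[[f]]
    ok <- is.finite(x)
    xs <- x[ok]
    ys <- y[ok]
    m <- length(xs)
    if (m < 3 || sd(xs) == 0) {
      return(data.frame(feature = f, r = NA_real_, p = NA_real_,
                        sig = "constant", stringsAsFactors = FALSE))
    }
    r <- cor(xs, ys)
    tstat <- r * sqrt((m - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = m - 2)
    data.frame(feature = f, r = r, p = p,
               sig = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Resampled train/test comparison against the PMV baseline
#'
#' For each trial, rows are split at random into a training and a test set,
#' the backend is retrained on the selected features, and both the fitted
#' model and the (training-free) PMV baseline are scored on the same test
#' rows; averages are appended.
#'
#' @param table feature table (needs `EnvTemp`, `EnvWind`, `EnvRH` for the
#'   baseline).
#' @param model a [model_spec()].
#' @param best_features selected feature subset to retrain on.
#' @param n_trials number of resampled splits.
#' @param train_n training rows per split.
#' @param test_n test rows per split; default all remaining rows.
#' @param seed split seed.
#' @param met,clo personal parameters handed to [pmv_for_trial()].
#' @return A list of class `pmv_comparison` with `trials` (per-trial data
#'   frame), `average` and the split descriptor.
#' @export
compare_with_pmv <- function(table, model = model_spec(), best_features,
                             n_trials = 3, train_n = 72, test_n = NULL,
                             seed = 1, met = 1.0, clo = 0.5) {
  missing <- setdiff(best_features, names(table))
  if (length(missing)) {
    stop("best_features missing from table: ", paste(missing, collapse = ", "))
  }
  n <- nrow(table)
  test_n <- test_n %||% (n - train_n)
  if (n < train_n + 1 || test_n < 1) stop("table too small for the split")
  pmv_all <- pmv_for_trial(table, met = met, clo = clo)
  rows <- lapply(seq_len(n_trials), function(tr) {
    idx <- local_seed(child_seed(seed, "split", tr), sample.int(n))
    train <- idx[seq_len(train_n)]
    test <- idx[train_n + seq_len(test_n)]
    bk <- fit_backend(model, table[train, best_features, drop = FALSE],
                      table$reported_ts[train])
    pred <- predict_backend(bk, table[test, best_features, drop = FALSE])
    m_model <- metrics(pred, table$reported_ts[test])
    m_pmv <- metrics(pmv_all[test], table$reported_ts[test])
    data.frame(trial = tr, model_rmse = m_model[["rmse"]],
               model_r2 = m_model[["r2"]], pmv_rmse = m_pmv[["rmse"]],
               pmv_r2 = m_pmv[["r2"]])
  })
  trials <- do.call(rbind, rows)
  structure(list(trials = trials,
                 average = colMeans(trials[, -1, drop = FALSE]),
                 split = c(train_n = train_n, test_n = test_n, seed = seed)),
            class = "pmv_comparison")
}

#' @export
print.pmv_comparison <- function(x, ...) {
  cat("Model vs PMV baseline (resampled train/test)\n")
  print(round(x$trials, 3), row.names = FALSE)
  cat(sprintf("Average: model RMSE %.3f / R^2 %.3f; PMV RMSE %.3f / R^2 %.3f\n",
              x$average[["model_rmse"]], x$average[["model_r2"]],
              x$average[["pmv_rmse"]], x$average[["pmv_r2"]]))
  invisible(x)
}

#' Two-sample tests on signed prediction errors
#'
#' Pooled-variance two-sample t-test (Welch behind a flag) and
#' Mann-Whitney U with the tie-corrected normal approximation for Z
#' (exact enumeration available for small untied samples).
#'
#' @param err_a,err_b signed errors of the two groups.
#' @param welch use the Welch t-test instead of pooled variance.
#' @param exact exact Mann-Whitney p (small samples, no ties).
#' @return A list with `t` (statistic, df, p) and `mw` (U, Z, p).
#' @export
error_group_tests <- function(err_a, err_b, welch = FALSE, exact = FALSE) {
  if (!length(err_a) || !length(err_b)) stop("both groups must be non-empty")
  tt <- t.test(err_a, err_b, var.equal = !welch)
  n1 <- length(err_a)
  n2 <- length(err_b)
  rk <- rank(c(err_a, err_b))
  r1 <- sum(rk[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  nn <- n1 + n2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((nn + 1) - tie_term))
  z <- if (sigma > 0) (u1 - n1 * n2 / 2) / sigma else NA_real_
  p_mw <- if (exact) {
    stats::wilcox.test(err_a, err_b, exact = TRUE)$p.value
  } else {
    2 * pnorm(-abs(z))
  }
  list(t = list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value),
       mw = list(U = u1, Z = z, p = p_mw))
}

group_summary <- function(e) {
  q <- quantile(e, c(0.25, 0.5, 0.75), names = FALSE)
  c(n = length(e), mean = mean(e), sd = sd(e), median = q[2],
    q1 = q[1], q3 = q[3], rmse = sqrt(mean(e^2)))
}

#' Gender-stratified prediction error test
#'
#' Retrains the backend on a gender-stratified random split, computes
#' signed errors (predicted minus reported) on the held-out rows, and tests
#' whether male and female error distributions differ (pooled-variance
#' t-test and tie-corrected Mann-Whitney U, both two-tailed).
#'
#' @param table feature table with a `sex` column.
#' @param model a [model_spec()].
#' @param best_features features to retrain on.
#' @param counts named vector `c(train_m, train_f, test_m, test_f)`;
#'   `NULL` holds out 20% of each gender (at least one row).
#' @param seed split seed.
#' @param welch,exact test variants, see [error_group_tests()].
#' @return A list of class `gender_report` with per-group summaries, RMSEs
#'   and both tests.
#' @export
gender_error_test <- function(table, model = model_spec(), best_features,
                              counts = NULL, seed = 1, welch = FALSE,
                              exact = FALSE) {
  im <- which(table$sex == "male")
  if_ <- which(table$sex == "female")
  if (length(im) < 2 || length(if_) < 2) {
    stop("insufficient rows per gender for the requested split")
  }
  if (is.null(counts)) {
    counts <- c(train_m = length(im) - max(1L, round(0.2 * length(im))),
                train_f = length(if_) - max(1L, round(0.2 * length(if_))))
    counts <- c(counts, test_m = length(im) - counts[["train_m"]],
                test_f = length(if_) - counts[["train_f"]])
  }
  if (length(im) < counts[["train_m"]] + counts[["test_m"]] ||
      length(if_) < counts[["train_f"]] + counts[["test_f"]] ||
      counts[["test_m"]] < 1 || counts[["test_f"]] < 1) {
    stop("insufficient rows per gender for the requested split")
  }
  sm <- local_seed(child_seed(seed, "male"), sample(im))
  sf <- local_seed(child_seed(seed, "female"), sample(if_))
  train <- c(sm[seq_len(counts[["train_m"]])],
             sf[seq_len(counts[["train_f"]])])
  test_m <- sm[counts[["train_m"]] + seq_len(counts[["test_m"]])]
  test_f <- sf[counts[["train_f"]] + seq_len(counts[["test_f"]])]
  bk <- fit_backend(model, table[train, best_features, drop = FALSE],
                    table$reported_ts[train])
  err <- function(idx) {
    predict_backend(bk, table[idx, best_features, drop = FALSE]) -
      table$reported_ts[idx]
  }
  em <- err(test_m)
  ef <- err(test_f)
  tests <- error_group_tests(em, ef, welch = welch, exact = exact)
  structure(list(
    rmse = c(overall = sqrt(mean(c(em, ef)^2)),
             male = sqrt(mean(em^2)), female = sqrt(mean(ef^2))),
    male = group_summary(em), female = group_summary(ef),
    errors = list(male = em, female = ef),
    t_test = tests$t, mann_whitney = tests$mw,
    counts = counts, seed = seed), class = "gender_report")
}

#' @export
print.gender_report <- function(x, ...) {
  cat("Gender prediction-error comparison\n")
  cat(sprintf("  RMSE overall %.3f | male %.3f | female %.3f\n",
              x$rmse[["overall"]], x$rmse[["male"]], x$rmse[["female"]]))
  cat(sprintf("  t-test: t = %.3f (df %.1f), p = %.3f\n",
              x$t_test$statistic, x$t_test$df, x$t_test$p))
  cat(sprintf("  Mann-Whitney: U = %.1f, Z = %.3f, p = %.3f\n",
              x$mann_whitney$U, x$mann_whitney$Z, x$mann_whitney$p))
  invisible(x)
}

#' Default signal-wise feature groups
#'
#' The grouping of the best-performing combination by source signal: all
#' EMG amplitude descriptors, the two informative HRV features, the EEG
#' beta pair, and the chest/calf temperatures.
#'
#' @return Named list of feature-name vectors.
#' @export
signal_groups <- function() {
  list(EMG = c("EMG_MAV", "EMG_IEMG", "EMG_RMS"),
       BodyTemp = c("T3_calf", "T1_chest"),
       ECG = c("ECG_LF_HF", "ECG_SDNN"),
       EEG = c("EEG_beta_power", "EEG_beta"))
}

#' Rank physiological signals by greedy group addition
#'
#' Starts from the environment-only combination and adds, per round, the
#' whole signal-wise feature group that best improves the cross-validated
#' RMSE, until all groups are included. Ties are broken by the declared
#' group order.
#'
#' @param table feature table.
#' @param model a [model_spec()].
#' @param groups named list of signal-wise feature groups, see
#'   [signal_groups()].
#' @param protocol a [cv_protocol()].
#' @param env_features the always-included environment columns.
#' @param eval_fn optional performance lookup replacing model fitting.
#' @return A data frame of class `ranking_table`: one row per round with
#'   the cumulative signal list and rmse/r2.
#' @export
rank_signals <- function(table = NULL, model = model_spec(),
                         groups = signal_groups(),
                         protocol = cv_protocol(),
                         env_features = c("EnvTemp", "EnvWind", "EnvRH"),
                         eval_fn = NULL) {
  eval_fn <- eval_fn %||% make_eval_fn(table, model, protocol)
  if (!is.null(table)) {
    missing <- setdiff(c(env_features, unlist(groups)), names(table))
    if (length(missing)) {
      stop("features missing from table: ", paste(missing, collapse = ", "))
    }
  }
  current <- env_features
  included <- character(0)
  perf <- eval_fn(current)
  rows <- data.frame(n_signals = 0L, signals = "Environment",
                     rmse = perf$rmse, r2 = perf$r2 %||% NA_real_,
                     stringsAsFactors = FALSE)
  remaining <- names(groups)
  while (length(remaining)) {
    perfs <- lapply(remaining, function(g) eval_fn(c(current, groups[[g]])))
    j <- best_candidate(perfs)
    included <- c(included, remaining[j])
    current <- c(current, groups[[remaining[j]]])
    rows <- rbind(rows, data.frame(
      n_signals = length(included),
      signals = paste(c("Environment", included), collapse = ", "),
      rmse = perfs[[j]]$rmse, r2 = perfs[[j]]$r2 %||% NA_real_,
      stringsAsFactors = FALSE))
    remaining <- remaining[-j]
  }
  structure(rows, class = c("ranking_table", "data.frame"))
}
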