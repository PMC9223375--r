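# Shared fixtures: a fast low-rate generator profile for tests that need a
# whole cohort but not full-rate traces, plus small cached tables.

tiny_config <- function(...) {
  do.call(cohort_config, utils::modifyList(
    list(n_subjects = 3, duration = 310,
         fs = c(EMG = 250, EEG = 128, GSR = 16, TEMP = 1)),
    list(...)))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

tiny_cohort <- function() {
  cached("tiny_cohort", generate_cohort(tiny_config(), seed = 7))
}

tiny_table <- function() {
  cached("tiny_table", feature_table(tiny_cohort()))
}

# the full default cohort (20 x 8 at default sampling rates); shared by
# the recovery and correlation acceptance checks
default_cohort <- function() {
  cached("default_cohort", generate_cohort(cohort_config(), seed = 42))
}

default_table <- function() {
  cached("default_table", feature_table(default_cohort()))
}

# reduced problem size for multi-seed stability checks: same statistical
# structure, lower sampling rates and a 30-s margin before the window
fast_profile_config <- function(...) {
  do.call(cohort_config, utils::modifyList(
    list(duration = 330,
         fs = c(EMG = 500, EEG = 128, GSR = 16, TEMP = 1)),
    list(...)))
}

# a clean (uncorrupted) single trial at full default rates
clean_trial <- function() {
  cached("clean_trial", {
    co <- generate_cohort(tiny_config(n_subjects = 1, corruption_prob = 0),
                          seed = 11)
    co[[1]]
  })
}

# direct DFT band power: independent brute-force oracle for the spectral
# features (plain periodogram of the full demeaned series)
dft_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  xc <- x - mean(x)
  xf <- stats::fft(xc)
  freq <- (0:(n - 1)) * fs / n
  half <- 2:(floor(n / 2) + 1)
  p <- (Mod(xf[half])^2) * 2 / n^2
  sum(p[freq[half] > lo & freq[half] <= hi])
}

# mocked performance lookup over named feature sets; keys are sorted
# feature names joined by "+"
mock_eval <- function(lookup) {
  function(features) {
    key <- if (!length(features)) "<empty>" else
      paste(sort(features), collapse = "+")
    if (!key %in% names(lookup)) {
      stop("mock lookup missing combination: '", key, "'")
    }
    list(rmse = lookup[[key]], r2 = NA_real_)
  }
}

# exhaustive best subset under a mocked lookup (brute-force oracle)
brute_force_best <- function(features, eval_fn) {
  best <- character(0)
  best_rmse <- eval_fn(character(0))$rmse
  for (k in seq_along(features)) {
    for (combo in utils::combn(features, k, simplify = FALSE)) {
      r <- eval_fn(combo)$rmse
      if (r < best_rmse) {
        best <- combo
        best_rmse <- r
      }
    }
  }
  list(features = sort(best), rmse = best_rmse)
}
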