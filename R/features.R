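# Feature extraction: 19 physiological + 3 environmental features from the
# trailing analysis window, plus per-trial quality screening.

#' Names of the 22 extracted features, in canonical order
#'
#' Six HRV features from the ECG RR series, four EMG amplitude descriptors,
#' five EEG band features, tonic GSR, three body-temperature means and the
#' three environment variables. `ECG_LF` and `ECG_HF` are relative band
#' powers; `ECG_LF_HF` is the absolute band-power ratio.
#'
#' @return Character vector of length 22.
#' @export
feature_names <- function() {
  c("ECG_HR", "ECG_SDNN", "ECG_TP", "ECG_LF", "ECG_HF", "ECG_LF_HF",
    "EMG_IEMG", "EMG_MAV", "EMG_RMS", "EMG_SSI",
    "EEG_alpha", "EEG_beta", "EEG_AVG", "EEG_alpha_power", "EEG_beta_power",
    "GSR_avg5hz", "T1_chest", "T2_forearm", "T3_calf",
    "EnvTemp", "EnvWind", "EnvRH")
}

#' Feature-extraction configuration
#'
#' @param window trailing analysis window in seconds (default 300, i.e. the
#'   final 5 minutes of a trial).
#' @param eeg_alpha,eeg_beta,eeg_broad EEG band edges in Hz (conventional
#'   clinical alpha 8-13, beta 13-30, broadband 1-40).
#' @param emg_band EMG band-pass edges in Hz; the upper edge is dropped when
#'   the sampling rate cannot support it, leaving a high-pass.
#' @param hrv_tp,hrv_lf,hrv_hf HRV total/LF/HF band edges in Hz. With a
#'   0.003 Hz lower TP edge the LF and HF relative powers sum to at most 1
#'   without being trivially complementary.
#' @param hrv_fs tachogram resampling rate in Hz.
#' @param hrv_seg Welch segment length in seconds (50% overlap).
#' @param gsr_cutoff GSR low-pass cutoff in Hz.
#' @param edge_trim seconds trimmed from each end of filtered windows before
#'   statistics, suppressing filter edge transients.
#' @return A validated list of class `extraction_config`.
#' @export
extraction_config <- function(window = 300,
                              eeg_alpha = c(8, 13), eeg_beta = c(13, 30),
                              eeg_broad = c(1, 40),
                              emg_band = c(20, 450),
                              hrv_tp = c(0.003, 0.4), hrv_lf = c(0.04, 0.15),
                              hrv_hf = c(0.15, 0.4),
                              hrv_fs = 4, hrv_seg = 120,
                              gsr_cutoff = 5, edge_trim = 1) {
  cfg <- as.list(environment())
  for (nm in c("eeg_alpha", "eeg_beta", "eeg_broad", "emg_band",
               "hrv_tp", "hrv_lf", "hrv_hf")) {
    b <- cfg[[nm]]
    if (length(b) != 2 || diff(b) <= 0) {
      stop(sprintf("band edges '%s' must be strictly increasing", nm))
    }
  }
  stopifnot(window > 0, hrv_fs > 0, hrv_seg > 0, gsr_cutoff > 0,
            edge_trim >= 0)
  structure(cfg, class = "extraction_config")
}

# Trailing analysis window of a sampled trace.
trace_window <- function(trace, window) {
  n <- length(trace$samples)
  k <- min(n, round(window * trace$sampling_rate))
  trace$samples[(n - k + 1L):n]
}

# Trailing window of an RR series: intervals whose cumulative time falls in
# the final `window` seconds.
rr_window <- function(trace, window) {
  rr <- trace$samples
  t_end <- cumsum(rr) / 1000
  rr[t_end > (t_end[length(t_end)] - window)]
}

#' EMG time-domain amplitude features
#'
#' On the band-pass-filtered trailing window `x[1..N]`:
#' `IEMG = sum(|x|)`, `MAV = IEMG / N`, `RMS = sqrt(sum(x^2) / N)`,
#' `SSI = sum(x^2)`.
#'
#' @param trace an `EMG` `signal_trace`.
#' @param config an [extraction_config()].
#' @param filter set `FALSE` to bypass the band-pass (and edge trimming),
#'   e.g. on already-conditioned windows.
#' @return Named vector `(EMG_IEMG, EMG_MAV, EMG_RMS, EMG_SSI)`.
#' @export
emg_features <- function(trace, config = extraction_config(), filter = TRUE) {
  x <- trace_window(trace, config$window)
  if (length(x) == 0) stop("empty EMG window")
  if (filter) {
    fs <- trace$sampling_rate
    x <- if (config$emg_band[2] < fs / 2) {
      bw_filter(x, fs, config$emg_band, "pass")
    } else {
      bw_filter(x, fs, config$emg_band[1], "high")
    }
    trim <- round(config$edge_trim * fs)
    if (2 * trim < length(x)) x <- x[(trim + 1L):(length(x) - trim)]
  }
  n <- length(x)
  iemg <- sum(abs(x))
  ssi <- sum(x^2)
  c(EMG_IEMG = iemg, EMG_MAV = iemg / n, EMG_RMS = sqrt(ssi / n),
    EMG_SSI = ssi)
}

#' HRV features from an RR-interval series
#'
#' `HR = 60000 / mean(RR)`, `SDNN = sd(RR)`. The tachogram is cubic-spline
#' resampled to an even grid, and band powers come from a Welch
#' averaged-periodogram estimate: `ECG_TP` is total-band power (ms^2),
#' `ECG_LF`/`ECG_HF` are band powers relative to TP, and `ECG_LF_HF` is the
#' LF/HF power ratio. A (near-)constant series yields the degenerate result
#' `SDNN = 0` with spectral fields `NA`.
#'
#' @param trace an `ECG_RR` `signal_trace` (interval values in ms).
#' @param config an [extraction_config()].
#' @return Named vector `(ECG_HR, ECG_SDNN, ECG_TP, ECG_LF, ECG_HF,
#'   ECG_LF_HF)`; spectral entries are `NA` when undefined.
#' @export
hrv_features <- function(trace, config = extraction_config()) {
  rr <- rr_window(trace, config$window)
  if (length(rr) < 30) stop("need at least 30 RR intervals in the window")
  hr <- 60000 / mean(rr)
  sdnn <- sd(rr)
  out <- c(ECG_HR = hr, ECG_SDNN = sdnn, ECG_TP = NA_real_,
           ECG_LF = NA_real_, ECG_HF = NA_real_, ECG_LF_HF = NA_real_)
  if (sdnn < 1e-9) return(out)
  t <- cumsum(rr) / 1000
  grid <- seq(t[1], t[length(t)], by = 1 / config$hrv_fs)
  tach <- spline(t, rr, xout = grid, method = "natural")$y
  sp <- welch_psd(tach, config$hrv_fs,
                  seg_len = min(length(tach), round(config$hrv_seg * config$hrv_fs)))
  tp <- band_power(sp, config$hrv_tp[1], config$hrv_tp[2])
  lf <- band_power(sp, config$hrv_lf[1], config$hrv_lf[2])
  hf <- band_power(sp, config$hrv_hf[1], config$hrv_hf[2])
  out["ECG_TP"] <- tp
  if (tp > 0) {
    out["ECG_LF"] <- lf / tp
    out["ECG_HF"] <- hf / tp
  }
  if (hf > 0) out["ECG_LF_HF"] <- lf / hf
  out
}

#' EEG band features
#'
#' Band "averages" are mean absolute amplitudes of the zero-phase band-pass
#' filtered window (`EEG_alpha` 8-13 Hz, `EEG_beta` 13-30 Hz, `EEG_AVG`
#' broadband 1-40 Hz); relative powers are Welch band powers over the
#' broadband total.
#'
#' @param trace an `EEG` `signal_trace`.
#' @param config an [extraction_config()].
#' @return Named vector `(EEG_alpha, EEG_beta, EEG_AVG, EEG_alpha_power,
#'   EEG_beta_power)`; relative powers are `NA` for a zero signal.
#' @export
eeg_features <- function(trace, config = extraction_config()) {
  fs <- trace$sampling_rate
  if (fs < 2 * config$eeg_broad[2]) {
    stop(sprintf("EEG sampling rate %g Hz below 2x upper band edge", fs))
  }
  x <- trace_window(trace, config$window)
  trim <- round(config$edge_trim * fs)
  band_mean_abs <- function(b) {
    y <- bw_filter(x, fs, b, "pass")
    if (2 * trim < length(y)) y <- y[(trim + 1L):(length(y) - trim)]
    mean(abs(y))
  }
  alpha <- band_mean_abs(config$eeg_alpha)
  beta <- band_mean_abs(config$eeg_beta)
  avg <- band_mean_abs(config$eeg_broad)
  sp <- welch_psd(x, fs, seg_len = min(length(x), round(4 * fs)))
  total <- band_power(sp, config$eeg_broad[1], config$eeg_broad[2])
  ap <- bp <- NA_real_
  if (total > 0) {
    ap <- band_power(sp, config$eeg_alpha[1], config$eeg_alpha[2]) / total
    bp <- band_power(sp, config$eeg_beta[1], config$eeg_beta[2]) / total
  }
  c(EEG_alpha = alpha, EEG_beta = beta, EEG_AVG = avg,
    EEG_alpha_power = ap, EEG_beta_power = bp)
}

#' Tonic GSR feature
#'
#' Mean of the trailing window after 5 Hz low-pass filtering (noise-removed
#' tonic level). The filter is skipped when the sampling rate cannot
#' support the cutoff.
#'
#' @param trace a `GSR` `signal_trace`.
#' @param config an [extraction_config()].
#' @return Named scalar `GSR_avg5hz` (uS).
#' @export
gsr_feature <- function(trace, config = extraction_config()) {
  x <- trace_window(trace, config$window)
  if (length(x) == 0) stop("empty GSR window")
  fs <- trace$sampling_rate
  if (fs > 2 * config$gsr_cutoff) {
    x <- bw_filter(x, fs, config$gsr_cutoff, "low")
    trim <- round(config$edge_trim * fs)
    if (2 * trim < length(x)) x <- x[(trim + 1L):(length(x) - trim)]
  }
  c(GSR_avg5hz = mean(x))
}

#' Body-temperature and environment features
#'
#' Arithmetic means of the three temperature windows plus the trial's
#' environment values.
#'
#' @param record a `trial_record`.
#' @param config an [extraction_config()].
#' @return Named vector `(T1_chest, T2_forearm, T3_calf, EnvTemp, EnvWind,
#'   EnvRH)`.
#' @export
temp_and_env_features <- function(record, config = extraction_config()) {
  sites <- c(T1_chest = "TEMP_CHEST", T2_forearm = "TEMP_FOREARM",
             T3_calf = "TEMP_CALF")
  missing <- setdiff(sites, names(record$traces))
  if (length(missing)) {
    stop("missing temperature modality: ", paste(missing, collapse = ", "))
  }
  temps <- vapply(sites, function(m) {
    mean(trace_window(record$traces[[m]], config$window))
  }, 0)
  c(temps,
    EnvTemp = record$setting$air_temp,
    EnvWind = record$setting$wind_speed,
    EnvRH = record$setting$rh)
}

#' Quality-screening thresholds
#'
#' @param flatline_var variance floor below which a 1-second chunk counts
#'   as flat.
#' @param flatline_frac fraction of flat chunks that fails a trace.
#' @param clip_margin rail proximity as a fraction of the trace range.
#' @param clip_frac fraction of at-rail samples that fails a trace.
#' @param snr_ratio maximal allowed out-of-band/in-band power ratio.
#' @return List of class `quality_thresholds`.
#' @export
quality_thresholds <- function(flatline_var = 1e-12, flatline_frac = 0.5,
                               clip_margin = 0.001, clip_frac = 0.10,
                               snr_ratio = 0.25) {
  structure(as.list(environment()), class = "quality_thresholds")
}

# physiological in-band definition per modality, for the SNR check
quality_bands <- list(EMG = c(20, 450), EEG = c(1, 40), GSR = c(0, 5),
                      TEMP_CHEST = c(0, 0.2), TEMP_FOREARM = c(0, 0.2),
                      TEMP_CALF = c(0, 0.2))

screen_trace <- function(trace, th) {
  x <- trace$samples
  fs <- trace$sampling_rate
  chunk <- if (trace$modality == "ECG_RR") 10L else max(2L, round(fs))
  nchunk <- floor(length(x) / chunk)
  if (nchunk >= 2) {
    v <- vapply(seq_len(nchunk), function(i) {
      var(x[((i - 1L) * chunk + 1L):(i * chunk)])
    }, 0)
    if (mean(v < th$flatline_var) >= th$flatline_frac) return("flatline")
  }
  rng <- diff(range(x))
  if (rng > 0) {
    near <- (x - min(x) <= th$clip_margin * rng) |
      (max(x) - x <= th$clip_margin * rng)
    if (mean(near) >= th$clip_frac) return("clipping")
  }
  band <- quality_bands[[trace$modality]]
  if (!is.null(band) && fs / 2 > band[2]) {
    # segments of at least 64 samples so low-rate signals keep enough
    # frequency resolution inside the physiological band
    sp <- welch_psd(x - mean(x), fs,
                    seg_len = min(length(x), max(round(8 * fs), 64L)),
                    overlap = 0)
    inb <- band_power(sp, band[1], band[2])
    outb <- band_power(sp, band[2], fs / 2)
    if (inb > 0 && outb / inb > th$snr_ratio) return("low_snr")
  }
  NA_character_
}

#' Screen the quality of a trial
#'
#' Per-modality checks: flatline (sub-floor variance over at least half of
#' the window), clipping (too many samples at the rail values) and low SNR
#' (power outside the modality's physiological band exceeding the
#' calibrated fraction of in-band power). Any failing modality fails the
#' whole trial, so one impaired signal voids the sample.
#'
#' @param record a `trial_record`.
#' @param thresholds a [quality_thresholds()].
#' @return A list of class `quality_report` with `modalities` (data frame
#'   of modality, pass, reason) and `pass` (trial verdict).
#' @export
quality_screen <- function(record, thresholds = quality_thresholds()) {
  reasons <- vapply(record$traces, screen_trace, "", th = thresholds)
  tab <- data.frame(modality = names(record$traces),
                    pass = is.na(reasons),
                    reason = unname(reasons),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(modalities = tab, pass = all(tab$pass)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> trial %s\n",
              if (x$pass) "PASS" else "FAIL"))
  bad <- x$modalities[!x$modalities$pass, ]
  if (nrow(bad)) {
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("  %s: %s\n", bad$modality[i], bad$reason[i]))
    }
  }
  invisible(x)
}

#' Extract the full 22-feature vector from one trial
#'
#' Refuses trials that fail the quality screen unless `override = TRUE`.
#' Degenerate spectral quantities (e.g. from a constant RR series) are
#' returned as `NA` while the remaining features are computed.
#'
#' @param record a `trial_record`.
#' @param config an [extraction_config()].
#' @param override extract even when the quality verdict is fail.
#' @param report optional precomputed [quality_screen()] result.
#' @return Named numeric vector of length 22 in [feature_names()] order.
#' @export
extract_features <- function(record, config = extraction_config(),
                             override = FALSE, report = NULL) {
  report <- report %||% quality_screen(record)
  if (!report$pass && !override) {
    stop("trial failed quality screening; use override = TRUE to force")
  }
  v <- c(hrv_features(record$traces$ECG_RR, config),
         emg_features(record$traces$EMG, config),
         eeg_features(record$traces$EEG, config),
         gsr_feature(record$traces$GSR, config),
         temp_and_env_features(record, config))
  v[feature_names()]
}

#' Build the feature table for a cohort
#'
#' Screens every trial and assembles one row per passing trial: subject id,
#' sex, reported TS and the 22 features.
#'
#' @param cohort a `ts_cohort` (or list of `trial_record`s).
#' @param config an [extraction_config()].
#' @param thresholds a [quality_thresholds()].
#' @return A data frame; attribute `n_screened` records the cohort size
#'   before attrition.
#' @export
feature_table <- function(cohort, config = extraction_config(),
                          thresholds = quality_thresholds()) {
  rows <- list()
  for (rec in cohort) {
    qrep <- quality_screen(rec, thresholds)
    if (!qrep$pass) next
    v <- extract_features(rec, config, report = qrep)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = rec$subject$subject_id, sex = rec$subject$sex,
      trial_id = rec$trial_id, reported_ts = rec$reported_ts,
      as.list(v), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no passing trials")
  tab <- do.call(rbind, rows)
  attr(tab, "n_screened") <- length(cohort)
  tab
}
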