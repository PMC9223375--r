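# Feature extraction: closed forms, algebraic identities, spectral
# behaviour, windowing, quality screening.

test_that("EMG features match closed forms on hand windows", {
  cfg <- extraction_config()
  tr <- signal_trace("EMG", c(1, -1, 1, -1), 1)
  f <- emg_features(tr, cfg, filter = FALSE)
  expect_equal(unname(f), c(4, 1, 1, 4))

  z <- signal_trace("EMG", rep(0, 16), 1)
  expect_equal(unname(emg_features(z, cfg, filter = FALSE)), rep(0, 4))
})

test_that("EMG identities SSI = N*RMS^2 and IEMG = N*MAV hold on random windows", {
  cfg <- extraction_config()
  withr::with_seed(1, {
    for (i in 1:100) {
      n <- sample(20:200, 1)
      x <- rnorm(n, sd = runif(1, 0.1, 10))
      f <- emg_features(signal_trace("EMG", x, 1), cfg, filter = FALSE)
      expect_equal(f[["EMG_SSI"]], n * f[["EMG_RMS"]]^2, tolerance = 1e-9)
      expect_equal(f[["EMG_IEMG"]], n * f[["EMG_MAV"]], tolerance = 1e-9)
    }
  })
})

test_that("EMG filtering removes sub-band drift", {
  cfg <- extraction_config(window = 10)
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  # 50 Hz in-band tone riding on a large 1 Hz drift
  x <- sin(2 * pi * 50 * t) + 20 * sin(2 * pi * 1 * t)
  f <- emg_features(signal_trace("EMG", x, fs), cfg)
  # RMS of unit sinusoid is 1/sqrt(2); the drift would give ~14
  expect_equal(f[["EMG_RMS"]], 1 / sqrt(2), tolerance = 0.05)
})

test_that("HRV features: degenerate, tone and two-tone cases", {
  cfg <- extraction_config()
  const <- signal_trace("ECG_RR", rep(1000, 400))
  h <- hrv_features(const, cfg)
  expect_equal(h[["ECG_HR"]], 60)
  expect_equal(h[["ECG_SDNN"]], 0)
  expect_true(all(is.na(h[c("ECG_TP", "ECG_LF", "ECG_HF", "ECG_LF_HF")])))

  expect_error(hrv_features(signal_trace("ECG_RR", rep(800, 10)), cfg),
               "30 RR")

  # pure 0.30 Hz tachogram -> almost all power in the HF band
  mk_rr <- function(a_lf, a_hf) {
    t <- 0
    rr <- numeric(500)
    k <- 0
    while (t < 320) {
      k <- k + 1
      rr[k] <- 800 + a_lf * sin(2 * pi * 0.10 * t) + a_hf * sin(2 * pi * 0.30 * t)
      t <- t + rr[k] / 1000
    }
    signal_trace("ECG_RR", rr[1:k])
  }
  hf_only <- hrv_features(mk_rr(0, 50), cfg)
  expect_gt(hf_only[["ECG_HF"]], 0.9)
  expect_lt(hf_only[["ECG_LF_HF"]], 0.1)

  two_tone <- hrv_features(mk_rr(50, 50), cfg)
  expect_equal(two_tone[["ECG_LF_HF"]], 1.0, tolerance = 0.1)
})

test_that("HRV spectral estimates agree with a direct DFT oracle", {
  cfg <- extraction_config()
  t <- 0
  rr <- numeric(500)
  k <- 0
  while (t < 320) {
    k <- k + 1
    rr[k] <- 800 + 40 * sin(2 * pi * 0.10 * t) + 25 * sin(2 * pi * 0.30 * t)
    t <- t + rr[k] / 1000
  }
  trace <- signal_trace("ECG_RR", rr[1:k])
  h <- hrv_features(trace, cfg)
  # oracle: linear-interpolation resample + plain periodogram
  rrw <- rr[1:k]
  tt <- cumsum(rrw) / 1000
  grid <- seq(tt[1], tt[length(tt)], by = 0.25)
  res <- spline(tt, rrw, xout = grid, method = "natural")$y
  lf_o <- dft_band_power(res, 4, 0.04, 0.15)
  hf_o <- dft_band_power(res, 4, 0.15, 0.4)
  expect_equal(h[["ECG_LF_HF"]], lf_o / hf_o, tolerance = 0.1)
})

test_that("SDNN is shift invariant and HR halves when intervals double", {
  cfg <- extraction_config()
  # short enough that the whole series sits inside the analysis window
  # before and after the shift, so the same intervals are compared
  withr::with_seed(4, rr <- 800 + rnorm(250, sd = 40))
  h1 <- hrv_features(signal_trace("ECG_RR", rr), cfg)
  h2 <- hrv_features(signal_trace("ECG_RR", rr + 200), cfg)
  expect_equal(h1[["ECG_SDNN"]], h2[["ECG_SDNN"]], tolerance = 1e-6)
  h3 <- hrv_features(signal_trace("ECG_RR", rep(500, 700)), cfg)
  h4 <- hrv_features(signal_trace("ECG_RR", rep(1000, 400)), cfg)
  expect_equal(h3[["ECG_HR"]], 2 * h4[["ECG_HR"]])
})

test_that("EEG features: pure alpha tone, white noise normalisation, zero signal", {
  cfg <- extraction_config(window = 20)
  fs <- 128
  t <- seq(0, 20, by = 1 / fs)
  a <- 5
  tone <- signal_trace("EEG", a * sin(2 * pi * 10 * t), fs)
  f <- eeg_features(tone, cfg)
  expect_equal(f[["EEG_alpha"]], 2 * a / pi, tolerance = 0.03)
  expect_lt(f[["EEG_beta_power"]], 0.05)
  expect_gt(f[["EEG_alpha_power"]], 0.8)

  withr::with_seed(2, wn <- rnorm(20 * fs + 1))
  fw <- eeg_features(signal_trace("EEG", wn, fs), cfg)
  expect_lte(fw[["EEG_alpha_power"]] + fw[["EEG_beta_power"]], 1)
  expect_true(all(fw[c("EEG_alpha_power", "EEG_beta_power")] >= 0))

  fz <- eeg_features(signal_trace("EEG", rep(0, 20 * fs), fs), cfg)
  expect_equal(unname(fz[c("EEG_alpha", "EEG_beta", "EEG_AVG")]), rep(0, 3))
  expect_true(all(is.na(fz[c("EEG_alpha_power", "EEG_beta_power")])))

  expect_error(eeg_features(signal_trace("EEG", rnorm(100), 60), cfg),
               "sampling rate")
})

test_that("EEG relative powers agree with a direct DFT oracle on two tones", {
  cfg <- extraction_config(window = 30)
  fs <- 128
  t <- seq(0, 30, by = 1 / fs)
  x <- 4 * sin(2 * pi * 10 * t) + 2 * sin(2 * pi * 20 * t)
  f <- eeg_features(signal_trace("EEG", x, fs), cfg)
  tot_o <- dft_band_power(x, fs, 1, 40)
  expect_equal(f[["EEG_alpha_power"]], dft_band_power(x, fs, 8, 13) / tot_o,
               tolerance = 0.1)
  expect_equal(f[["EEG_beta_power"]], dft_band_power(x, fs, 13, 30) / tot_o,
               tolerance = 0.1)
})

test_that("GSR feature recovers the tonic level", {
  cfg <- extraction_config(window = 30)
  fs <- 100
  n <- 30 * fs
  expect_equal(unname(gsr_feature(signal_trace("GSR", rep(4, n), fs), cfg)), 4,
               tolerance = 1e-6)
  t <- seq_len(n) / fs
  ripple <- signal_trace("GSR", 4 + 0.5 * sin(2 * pi * 20 * t), fs)
  expect_equal(unname(gsr_feature(ripple, cfg)), 4, tolerance = 0.01)
  ramp <- signal_trace("GSR", seq(2, 6, length.out = n), fs)
  expect_equal(unname(gsr_feature(ramp, cfg)), 4, tolerance = 0.02 * 4)
})

test_that("temperature and environment features are window means and settings", {
  rec <- clean_trial()
  cfg <- extraction_config()
  f <- temp_and_env_features(rec, cfg)
  expect_equal(f[["EnvTemp"]], rec$setting$air_temp)
  expect_equal(f[["EnvRH"]], rec$setting$rh)
  expect_equal(f[["EnvWind"]], rec$setting$wind_speed)
  expect_equal(f[["T1_chest"]],
               mean(tail(rec$traces$TEMP_CHEST$samples, 300)),
               tolerance = 1e-9)

  broken <- rec
  broken$traces$TEMP_CALF <- NULL
  expect_error(temp_and_env_features(broken, cfg), "TEMP_CALF")
})

test_that("features depend only on the trailing analysis window", {
  rec <- clean_trial()
  cfg <- extraction_config()
  v1 <- extract_features(rec, cfg)
  longer <- rec
  withr::with_seed(5, {
    for (m in names(longer$traces)) {
      tr <- longer$traces[[m]]
      pre <- if (m == "ECG_RR") 700 + abs(rnorm(40, sd = 100)) else
        rnorm(round(20 * tr$sampling_rate), sd = sd(tr$samples) + 1)
      longer$traces[[m]]$samples <- c(pre, tr$samples)
    }
  })
  v2 <- extract_features(longer, cfg, override = TRUE)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("quality screen passes clean trials and names corrupted modalities", {
  rec <- clean_trial()
  expect_true(quality_screen(rec)$pass)

  flat <- rec
  flat$traces$EEG <- corrupt(rec$traces$EEG, "flatline", seed = 3)
  qf <- quality_screen(flat)
  expect_false(qf$pass)
  expect_equal(qf$modalities$reason[qf$modalities$modality == "EEG"],
               "flatline")

  clip <- rec
  clip$traces$EMG <- corrupt(rec$traces$EMG, "clipping", seed = 3)
  qc <- quality_screen(clip)
  expect_false(qc$pass)
  expect_equal(qc$modalities$reason[qc$modalities$modality == "EMG"],
               "clipping")

  noisy <- rec
  noisy$traces$GSR <- corrupt(rec$traces$GSR, "broadband", seed = 3)
  qn <- quality_screen(noisy)
  expect_false(qn$pass)
  expect_equal(qn$modalities$reason[qn$modalities$modality == "GSR"],
               "low_snr")
})

test_that("extract refuses failed trials unless overridden and keeps field order", {
  rec <- clean_trial()
  v <- extract_features(rec)
  expect_length(v, 22)
  expect_identical(names(v), feature_names())
  expect_identical(v, extract_features(rec))

  bad <- rec
  bad$traces$EEG <- corrupt(rec$traces$EEG, "flatline", seed = 1)
  expect_error(extract_features(bad), "quality")
  vo <- extract_features(bad, override = TRUE)
  expect_length(vo, 22)

  # degenerate RR series: spectral fields NA, everything else computed
  deg <- rec
  deg$traces$ECG_RR$samples <- rep(900, 400)
  vd <- extract_features(deg, override = TRUE)
  expect_true(all(is.na(vd[c("ECG_TP", "ECG_LF", "ECG_HF", "ECG_LF_HF")])))
  expect_false(anyNA(vd[c("EMG_RMS", "T1_chest", "EnvTemp")]))
})

test_that("feature table keeps one row per passing trial with screen agreement", {
  co <- tiny_cohort()
  tab <- tiny_table()
  expect_equal(nrow(tab), sum(vapply(co, `[[`, TRUE, "quality_ok")))
  expect_true(all(feature_names() %in% names(tab)))
  expect_equal(attr(tab, "n_screened"), length(co))
})

test_that("band edges must increase and window must be positive", {
  expect_error(extraction_config(eeg_alpha = c(13, 8)), "eeg_alpha")
  expect_error(extraction_config(window = -1))
})
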