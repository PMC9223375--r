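# Synthetic climate-chamber cohort: subjects, factorial design, signal
# generators, corruption process, full cohort assembly.

#' Configuration for the synthetic chamber cohort generator
#'
#' Defaults emulate the study conditions the package is built around: 20
#' healthy young adults (9 male : 11 female) each exposed once to every cell
#' of a 2x2x2 factorial of air temperature (23/27 degC), relative humidity
#' (60/80 %) and ceiling-fan level (breeze/strong), reporting thermal
#' sensation (TS) on the 7-point scale, with per-trial signal corruption
#' tuned so roughly 90 of 160 trials survive quality screening.
#'
#' Latent TS is linear in the environment factors with a Gaussian
#' subject-level offset and trial noise:
#' `latent = beta_temp*(Ta-25) + beta_wind*(v-0.6) + beta_rh*(RH-70) + offset + eps`.
#' The reported vote is the latent value rounded half-away-from-zero and
#' clipped to \[-3, 3\].
#'
#' The trial noise `eps` is decomposed into afferent pathway components
#' plus a residual: a muscular/shivering component read only by the EMG, an
#' autonomic component read only by the HRV features, and a central-arousal
#' component read only by the EEG (`pathway_sd` gives their SDs; the
#' marginal noise SD is `sqrt(noise_sd^2 + sum(pathway_sd^2))`, about 0.7
#' TS units at the defaults). Temperatures and GSR read the core thermal
#' state (environment + offset + residual). This makes each signal class
#' complementarily informative, the structure a multi-signal sensation
#' model presumes.
#'
#' Physiological responses are phenomenological, with directions matching
#' the correlation structure such data show: EMG amplitude decays
#' exponentially with its drive (more muscle activity when cold), skin
#' temperatures rise linearly (calf steeper than chest), EEG beta amplitude
#' rises, tonic GSR falls, HRV SDNN falls, and the RR-interval LF/HF ratio
#' follows a "smile curve" `c0 + c1*ts^2` (low when neutral, high when hot
#' or cold).
#'
#' @param n_subjects number of subjects (each completes all 8 settings).
#' @param male_female integer ratio used to assign sexes, default `c(9, 11)`.
#' @param beta_temp,beta_wind,beta_rh latent TS coefficients per degC, per
#'   m/s and per %RH.
#' @param subject_sd SD of the subject-level thermal offset (TS units).
#' @param noise_sd SD of the residual (pathway-free) latent noise (TS units).
#' @param pathway_sd named SDs of the emg/ecg/eeg pathway components of the
#'   latent noise.
#' @param wind_speed numeric mapping of fan levels to air speed (m/s).
#' @param duration,window trace duration and trailing analysis window (s).
#' @param fs named sampling rates (Hz) for EMG, EEG, GSR and temperatures.
#' @param rr_mean,rr_mean_trial_sd mean RR interval (ms) and its per-trial SD.
#' @param sdnn,sdnn_slope,sdnn_trial_sd prescribed SDNN (ms), its linear
#'   decrease per TS unit, and per-trial SD.
#' @param rr_jitter per-interval white jitter SD (ms).
#' @param lfhf_c0,lfhf_c1 smile-curve coefficients of the LF/HF target.
#' @param emg_sigma0,emg_decay,emg_trial_lsd EMG amplitude at TS 0 (mV),
#'   exponential decay rate per TS unit, and per-trial log-scale SD.
#' @param eeg_alpha_gain,eeg_beta_gain,eeg_beta_slope,eeg_floor,eeg_trial_lsd,eeg_gain_trial_lsd
#'   EEG component RMS amplitudes (uV), relative beta gain per TS unit,
#'   per-trial log-scale SD on the beta gain, and per-trial log-scale SD on
#'   the alpha/floor gains (keeps relative band powers realistically noisy).
#' @param gsr_base,gsr_slope,gsr_trial_sd,gsr_drift_sd tonic GSR level (uS),
#'   its decrease per TS unit, per-trial level SD, and slow-drift RMS.
#' @param temp_base,temp_slope baselines (degC) and TS slopes for chest,
#'   forearm and calf sites; chest slope below calf slope.
#' @param temp_trial_sd per-trial temperature offset SDs (degC).
#' @param temp_wander_sd,temp_wander_phi AR(1) innovation SD and coefficient
#'   of the slow temperature wander.
#' @param subject_gain_lsd log-scale SD of per-subject modality gains.
#' @param corruption_prob per-trial probability that one modality is
#'   corrupted, voiding the whole trial. The default 0.4375 reproduces the
#'   160 -> ~90 attrition of the emulated study.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 20,
                          male_female = c(9, 11),
                          beta_temp = 0.35,
                          beta_wind = 0.6,
                          beta_rh = 0,
                          subject_sd = 0.5,
                          noise_sd = 0.25,
                          pathway_sd = c(emg = 0.45, ecg = 0.35, eeg = 0.35),
                          wind_speed = c(breeze = 0.3, strong = 0.9),
                          duration = 360,
                          window = 300,
                          fs = c(EMG = 1000, EEG = 256, GSR = 32, TEMP = 1),
                          rr_mean = 800, rr_mean_trial_sd = 40,
                          sdnn = 50, sdnn_slope = 4, sdnn_trial_sd = 3,
                          rr_jitter = 5,
                          lfhf_c0 = 1.0, lfhf_c1 = 0.4,
                          emg_sigma0 = 0.05, emg_decay = 0.30,
                          emg_trial_lsd = 0.15,
                          eeg_alpha_gain = 10, eeg_beta_gain = 6,
                          eeg_beta_slope = 0.15, eeg_floor = 3,
                          eeg_trial_lsd = 0.12, eeg_gain_trial_lsd = 0.20,
                          gsr_base = 4, gsr_slope = 0.3,
                          gsr_trial_sd = 1.0, gsr_drift_sd = 0.05,
                          temp_base = c(chest = 36.0, forearm = 34.0, calf = 33.5),
                          temp_slope = c(chest = 0.10, forearm = 0.20, calf = 0.25),
                          temp_trial_sd = c(chest = 0.06, forearm = 0.50, calf = 0.15),
                          temp_wander_sd = 0.01, temp_wander_phi = 0.995,
                          subject_gain_lsd = 0.10,
                          corruption_prob = 0.4375) {
  cfg <- as.list(environment())
  stopifnot(
    n_subjects >= 1,
    length(male_female) == 2, all(male_female >= 0), sum(male_female) > 0,
    all(wind_speed > 0),
    duration >= window, window > 0,
    all(fs > 0),
    rr_mean > 0, sdnn >= 0, rr_jitter >= 0,
    noise_sd >= 0, subject_sd >= 0,
    all(pathway_sd >= 0), all(c("emg", "ecg", "eeg") %in% names(pathway_sd)),
    emg_sigma0 > 0, eeg_alpha_gain > 0, eeg_beta_gain > 0, eeg_floor >= 0,
    gsr_base > 0,
    temp_slope[["chest"]] <= temp_slope[["calf"]],
    corruption_prob >= 0, corruption_prob <= 1
  )
  if (any(!is.finite(c(beta_temp, beta_wind, beta_rh)))) {
    stop("latent coefficients must be finite")
  }
  structure(cfg, class = "cohort_config")
}

trace_units <- c(ECG_RR = "ms", EMG = "mV", EEG = "uV", GSR = "uS",
                 TEMP_CHEST = "degC", TEMP_FOREARM = "degC", TEMP_CALF = "degC")

#' Construct a signal trace
#'
#' @param modality one of `ECG_RR`, `EMG`, `EEG`, `GSR`, `TEMP_CHEST`,
#'   `TEMP_FOREARM`, `TEMP_CALF`.
#' @param samples ordered numeric samples (RR series: interval values in ms).
#' @param sampling_rate Hz; `NA` for the RR interval series.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(modality, samples, sampling_rate = NA_real_) {
  modality <- match.arg(modality, names(trace_units))
  if (length(samples) == 0) stop("samples must be non-empty")
  if (modality == "ECG_RR") {
    if (any(samples <= 0)) stop("RR intervals must all be positive")
  } else if (is.na(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be > 0 for sampled modalities")
  }
  structure(list(modality = modality, sampling_rate = sampling_rate,
                 samples = as.numeric(samples),
                 units = unname(trace_units[modality])),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s: %d samples [%s]%s\n", x$modality,
              length(x$samples), x$units,
              if (is.na(x$sampling_rate)) "" else sprintf(" @ %g Hz", x$sampling_rate)))
  invisible(x)
}

#' Build the factorial chamber design
#'
#' Every subject is paired with each cell of the 2x2x2 factorial
#' (23/27 degC x 60/80 %RH x breeze/strong fan) exactly once; the
#' within-subject setting order is shuffled by the seed. Subject profiles
#' carry a sex label (assigned by the configured ratio), a Gaussian thermal
#' offset and log-normal per-modality signal gains.
#'
#' @param n_subjects number of subjects.
#' @param seed integer root seed.
#' @param config a [cohort_config()].
#' @return A list with `subjects` (list of profiles) and `trials`
#'   (data frame of subject x setting rows in presentation order).
#' @export
make_design <- function(n_subjects, seed, config = cohort_config()) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("n_subjects must be a positive count")
  }
  n_subjects <- as.integer(n_subjects)
  ratio <- config$male_female
  n_male <- round(n_subjects * ratio[1] / sum(ratio))
  subjects <- lapply(seq_len(n_subjects), function(i) {
    local_seed(child_seed(seed, "subject", i), {
      list(
        subject_id = sprintf("S%02d", i),
        sex = if (i <= n_male) "male" else "female",
        thermal_offset = rnorm(1, 0, config$subject_sd),
        signal_gain = exp(setNames(rnorm(3, 0, config$subject_gain_lsd),
                                   c("EMG", "EEG", "GSR")))
      )
    })
  })
  settings <- expand.grid(air_temp = c(23, 27), rh = c(60, 80),
                          fan_level = c("breeze", "strong"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  settings$wind_speed <- unname(config$wind_speed[settings$fan_level])
  trials <- do.call(rbind, lapply(subjects, function(su) {
    ord <- local_seed(child_seed(seed, "order", su$subject_id),
                      sample.int(nrow(settings)))
    cbind(subject_id = su$subject_id, sex = su$sex,
          settings[ord, , drop = FALSE], row.names = NULL)
  }))
  trials$trial_id <- paste0(trials$subject_id, "_",
                            trials$air_temp, "C", trials$rh, "RH_",
                            trials$fan_level)
  list(subjects = subjects, trials = trials)
}

#' Latent and reported thermal sensation for one trial
#'
#' The trial noise is the sum of the three pathway components and a
#' residual (see [cohort_config()]); the returned `drives` give the signal
#' each modality class responds to: `core` (environment + offset +
#' residual) for temperatures and GSR, and `core` plus the matching
#' pathway component for EMG, ECG and EEG.
#'
#' @param setting a list/row with `air_temp`, `rh`, `wind_speed`.
#' @param subject a subject profile from [make_design()].
#' @param config a [cohort_config()].
#' @param seed seed for the trial-noise draws.
#' @return A list with `latent` (real), `reported` (integer in -3..3) and
#'   `drives` (named: core, emg, ecg, eeg).
#' @export
latent_ts <- function(setting, subject, config = cohort_config(), seed = 1) {
  w <- config$pathway_sd[c("emg", "ecg", "eeg")]
  draws <- local_seed(seed, rnorm(4))
  path <- draws[1:3] * w
  eps0 <- draws[4] * config$noise_sd
  core <- config$beta_temp * (setting$air_temp - 25) +
    config$beta_wind * (setting$wind_speed - 0.6) +
    config$beta_rh * (setting$rh - 70) +
    subject$thermal_offset + eps0
  latent <- core + sum(path)
  list(latent = latent,
       reported = as.integer(clip(round_half_away(latent), -3, 3)),
       drives = c(core = core, emg = core + path[[1]],
                  ecg = core + path[[2]], eeg = core + path[[3]]))
}

#' Generate an RR-interval series with prescribed SDNN and LF/HF
#'
#' The continuous tachogram is `RR(t) = m + A_LF sin(2 pi 0.10 t) +
#' A_HF sin(2 pi 0.30 t) + jitter`, emitted as successive interval values.
#' Amplitudes are solved so the LF/HF band-power ratio equals `lfhf` and the
#' series SD equals `sdnn` (jitter included).
#'
#' @param ts thermal sensation driving the smile-curve LF/HF target.
#' @param config a [cohort_config()].
#' @param seed seed for the jitter stream.
#' @param sdnn,lfhf,rr_mean optional per-trial overrides of the prescribed
#'   values (defaults derive from `config` and `ts`).
#' @return A `signal_trace` of modality `ECG_RR`.
#' @export
gen_rr_series <- function(ts, config = cohort_config(), seed = 1,
                          sdnn = NULL, lfhf = NULL, rr_mean = NULL) {
  if (config$duration < 300) stop("RR generation needs duration >= 300 s")
  m <- rr_mean %||% config$rr_mean
  s <- sdnn %||% (config$sdnn - config$sdnn_slope * ts)
  rho <- lfhf %||% (config$lfhf_c0 + config$lfhf_c1 * ts^2)
  if (s < 0) stop("prescribed SDNN is negative")
  if (rho <= 0) stop("prescribed LF/HF ratio must be positive")
  sin_var <- s^2 - config$rr_jitter^2
  if (sin_var < 0) {
    stop("unreachable SDNN target: jitter variance exceeds prescribed variance")
  }
  a_hf <- sqrt(2 * sin_var / (1 + rho))
  a_lf <- sqrt(rho) * a_hf
  n_max <- ceiling(config$duration / (max(m - s * 4, 300) / 1000)) + 8
  local_seed(seed, {
    jit <- if (config$rr_jitter > 0) rnorm(n_max, 0, config$rr_jitter) else numeric(n_max)
    rr <- numeric(n_max)
    t <- 0
    k <- 0
    while (t < config$duration && k < n_max) {
      k <- k + 1
      v <- m + a_lf * sin(2 * pi * 0.10 * t) + a_hf * sin(2 * pi * 0.30 * t) + jit[k]
      v <- max(v, 250) # physiological floor
      rr[k] <- v
      t <- t + v / 1000
    }
    signal_trace("ECG_RR", rr[seq_len(k)])
  })
}

#' Generate an EMG trace
#'
#' Zero-mean Gaussian noise whose amplitude decays exponentially with TS:
#' `sigma = sigma0 * exp(-k * ts) * gain`.
#'
#' @param ts thermal sensation.
#' @param config a [cohort_config()].
#' @param seed RNG seed.
#' @param gain subject/trial multiplicative gain (> 0).
#' @return A `signal_trace` of modality `EMG`.
#' @export
gen_emg <- function(ts, config = cohort_config(), seed = 1, gain = 1) {
  sigma <- config$emg_sigma0 * exp(-config$emg_decay * ts) * gain
  if (sigma <= 0) stop("EMG amplitude must be positive")
  n <- round(config$duration * config$fs[["EMG"]])
  local_seed(seed, signal_trace("EMG", rnorm(n, 0, sigma), config$fs[["EMG"]]))
}

#' Generate an EEG trace
#'
#' Sum of a band-limited alpha (8-13 Hz) component with fixed RMS gain, a
#' beta (13-30 Hz) component whose gain increases linearly with TS, and a
#' broadband 1-40 Hz floor.
#'
#' @inheritParams gen_emg
#' @param beta_gain,alpha_gain,floor_gain optional per-trial overrides of
#'   the component RMS amplitudes.
#' @return A `signal_trace` of modality `EEG`.
#' @export
gen_eeg <- function(ts, config = cohort_config(), seed = 1, gain = 1,
                    beta_gain = NULL, alpha_gain = NULL, floor_gain = NULL) {
  fs <- config$fs[["EEG"]]
  if (fs < 128) stop("EEG sampling rate must be >= 128 Hz")
  bg <- beta_gain %||% (config$eeg_beta_gain * (1 + config$eeg_beta_slope * ts))
  ag <- alpha_gain %||% config$eeg_alpha_gain
  fg <- floor_gain %||% config$eeg_floor
  if (bg <= 0 || ag <= 0 || fg < 0) stop("EEG amplitudes must be positive")
  n <- round(config$duration * fs)
  local_seed(seed, {
    x <- ag * gain * band_noise(n, fs, 8, 13) +
      bg * gain * band_noise(n, fs, 13, 30) +
      fg * gain * band_noise(n, fs, 1, 40)
    signal_trace("EEG", x, fs)
  })
}

#' Generate a GSR trace
#'
#' Tonic conductance `g0 - g1 * ts` plus a slow band-limited drift
#' (< 0.5 Hz).
#'
#' @inheritParams gen_emg
#' @param level optional per-trial override of the tonic level (uS).
#' @return A `signal_trace` of modality `GSR`.
#' @export
gen_gsr <- function(ts, config = cohort_config(), seed = 1, gain = 1,
                    level = NULL) {
  fs <- config$fs[["GSR"]]
  tonic <- (level %||% (config$gsr_base - config$gsr_slope * ts)) * gain
  if (tonic <= 0) stop("tonic GSR level must be positive")
  n <- round(config$duration * fs)
  local_seed(seed, {
    drift <- if (config$gsr_drift_sd > 0) {
      config$gsr_drift_sd * band_noise(n, fs, 0, 0.5)
    } else numeric(n)
    signal_trace("GSR", tonic + drift, fs)
  })
}

#' Generate the three body-temperature traces
#'
#' Each site is `baseline + slope * ts + offset + AR(1) wander`, sampled at
#' the temperature rate; the chest slope is below the calf slope.
#'
#' @inheritParams gen_emg
#' @param offsets optional named per-trial offsets (degC) for
#'   chest/forearm/calf.
#' @return A named list of `signal_trace`s (`TEMP_CHEST`, `TEMP_FOREARM`,
#'   `TEMP_CALF`).
#' @export
gen_temps <- function(ts, config = cohort_config(), seed = 1,
                      offsets = c(chest = 0, forearm = 0, calf = 0)) {
  fs <- config$fs[["TEMP"]]
  n <- round(config$duration * fs)
  sites <- c(chest = "TEMP_CHEST", forearm = "TEMP_FOREARM", calf = "TEMP_CALF")
  out <- lapply(names(sites), function(site) {
    base <- config$temp_base[[site]] + config$temp_slope[[site]] * ts +
      offsets[[site]]
    local_seed(child_seed(seed, site), {
      w <- numeric(n)
      if (config$temp_wander_sd > 0) {
        innov <- rnorm(n, 0, config$temp_wander_sd)
        phi <- config$temp_wander_phi
        w <- as.numeric(stats::filter(innov, phi, method = "recursive"))
      }
      signal_trace(sites[[site]], base + w, fs)
    })
  })
  setNames(out, unname(sites))
}

#' Corrupt a signal trace
#'
#' Produces a damaged copy the quality screen must reject; the input trace
#' is untouched. Modes: `flatline` (a constant segment covering >= 50% of
#' the trace), `clipping` (>= 20% of samples clamped to rail values) and
#' `broadband` (added white noise at 0 dB SNR across the full bandwidth).
#'
#' @param trace a `signal_trace`.
#' @param mode corruption mode.
#' @param seed RNG seed.
#' @return The corrupted `signal_trace`.
#' @export
corrupt <- function(trace, mode = c("flatline", "clipping", "broadband"),
                    seed = 1) {
  mode <- match.arg(mode)
  x <- trace$samples
  n <- length(x)
  local_seed(seed, {
    if (mode == "flatline") {
      len <- ceiling(0.6 * n)
      start <- sample.int(n - len + 1L, 1)
      x[start:(start + len - 1L)] <- x[start]
    } else if (mode == "clipping") {
      lo <- quantile(x, 0.15, names = FALSE)
      hi <- quantile(x, 0.85, names = FALSE)
      if (hi <= lo) hi <- lo + max(abs(lo), 1) * 1e-3
      x <- clip(x, lo, hi)
    } else {
      # noise power matched to the total signal power (DC included), so
      # slowly-varying tonic signals are damaged as thoroughly as
      # oscillatory ones
      s <- max(sd(x), 0.25 * mean(abs(x)))
      if (s <= 0) s <- 1
      x <- x + rnorm(n, 0, s)
      if (trace$modality == "ECG_RR") x <- pmax(x, 250)
    }
  })
  trace$samples <- x
  trace
}

# modalities eligible for each corruption mode: broadband corruption is only
# injected where the out-of-band power rule can see it
corruption_modes <- function(modality) {
  if (modality %in% c("EMG", "ECG_RR")) c("flatline", "clipping")
  else c("flatline", "clipping", "broadband")
}

gen_trial_traces <- function(drives, subject, config, seed) {
  gains <- subject$signal_gain
  sdnn_t <- max(config$sdnn - config$sdnn_slope * drives[["ecg"]] +
                  local_seed(child_seed(seed, "sdnn"),
                             rnorm(1, 0, config$sdnn_trial_sd)),
                config$rr_jitter + 1)
  rrm_t <- max(config$rr_mean +
                 local_seed(child_seed(seed, "rrm"),
                            rnorm(1, 0, config$rr_mean_trial_sd)), 400)
  beta_t <- config$eeg_beta_gain *
    max(1 + config$eeg_beta_slope * drives[["eeg"]], 0.05) *
    exp(local_seed(child_seed(seed, "beta"), rnorm(1, 0, config$eeg_trial_lsd)))
  ga <- local_seed(child_seed(seed, "eeg-gains"),
                   rnorm(2, 0, config$eeg_gain_trial_lsd))
  alpha_t <- config$eeg_alpha_gain * exp(ga[1])
  floor_t <- config$eeg_floor * exp(ga[2])
  gsr_t <- max(config$gsr_base - config$gsr_slope * drives[["core"]] +
                 local_seed(child_seed(seed, "gsr"),
                            rnorm(1, 0, config$gsr_trial_sd)), 0.5)
  emg_gain <- gains[["EMG"]] *
    exp(local_seed(child_seed(seed, "emg"), rnorm(1, 0, config$emg_trial_lsd)))
  toff <- local_seed(child_seed(seed, "toff"),
                     rnorm(3, 0, unname(config$temp_trial_sd[c("chest", "forearm", "calf")])))
  prescribed <- list(sdnn = sdnn_t, rr_mean = rrm_t,
                     lfhf = config$lfhf_c0 + config$lfhf_c1 * drives[["ecg"]]^2)
  traces <- c(
    list(
      ECG_RR = gen_rr_series(drives[["ecg"]], config,
                             child_seed(seed, "ECG_RR"),
                             sdnn = sdnn_t, rr_mean = rrm_t),
      EMG = gen_emg(drives[["emg"]], config, child_seed(seed, "EMG"),
                    gain = emg_gain),
      EEG = gen_eeg(drives[["eeg"]], config, child_seed(seed, "EEG"),
                    gain = gains[["EEG"]], beta_gain = beta_t,
                    alpha_gain = alpha_t, floor_gain = floor_t),
      GSR = gen_gsr(drives[["core"]], config, child_seed(seed, "GSR"),
                    gain = gains[["GSR"]], level = gsr_t)
    ),
    gen_temps(drives[["core"]], config, child_seed(seed, "TEMP"),
              offsets = setNames(toff, c("chest", "forearm", "calf")))
  )
  list(traces = traces, prescribed = prescribed)
}

#' Generate a full synthetic cohort
#'
#' Builds the factorial design, draws latent/reported TS per trial,
#' synthesises all seven traces, and applies the corruption process: with
#' probability `corruption_prob` one randomly chosen modality of a trial is
#' corrupted, which voids the whole trial (`quality_ok = FALSE`), emulating
#' the attrition of chamber studies where one impaired signal discards the
#' sample.
#'
#' @param config a [cohort_config()].
#' @param seed integer root seed; equal `(config, seed)` give identical
#'   cohorts.
#' @return A list of trial records of class `ts_cohort`. Each record holds
#'   `subject`, `setting`, `traces`, `latent_ts`, `reported_ts`,
#'   `quality_ok` and (when corrupted) `corruption`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  design <- make_design(config$n_subjects, seed, config)
  subjects <- setNames(design$subjects,
                       vapply(design$subjects, `[[`, "", "subject_id"))
  records <- vector("list", nrow(design$trials))
  for (i in seq_len(nrow(design$trials))) {
    row <- design$trials[i, ]
    su <- subjects[[row$subject_id]]
    setting <- list(air_temp = row$air_temp, rh = row$rh,
                    fan_level = row$fan_level, wind_speed = row$wind_speed)
    tseed <- child_seed(seed, "trial", row$trial_id)
    ts <- latent_ts(setting, su, config, child_seed(tseed, "latent"))
    gen <- gen_trial_traces(ts$drives, su, config, tseed)
    traces <- gen$traces
    corr <- NULL
    if (config$corruption_prob > 0 &&
        local_seed(child_seed(tseed, "corrupt?"),
                   runif(1)) < config$corruption_prob) {
      mod <- local_seed(child_seed(tseed, "corrupt-mod"),
                        sample(names(traces), 1))
      mode <- local_seed(child_seed(tseed, "corrupt-mode"),
                         sample(corruption_modes(traces[[mod]]$modality), 1))
      traces[[mod]] <- corrupt(traces[[mod]], mode,
                               child_seed(tseed, "corrupt-apply"))
      corr <- list(modality = mod, mode = mode)
    }
    records[[i]] <- structure(
      list(trial_id = row$trial_id, subject = su, setting = setting,
           traces = traces, latent_ts = ts$latent,
           reported_ts = ts$reported, drives = ts$drives,
           prescribed = gen$prescribed, quality_ok = is.null(corr),
           corruption = corr),
      class = "trial_record")
  }
  structure(records, class = "ts_cohort",
            seed = seed, n_subjects = config$n_subjects)
}

#' @export
print.ts_cohort <- function(x, ...) {
  ok <- sum(vapply(x, `[[`, TRUE, "quality_ok"))
  cat(sprintf("<ts_cohort> %d trials (%d subjects x 8 settings), %d clean / %d corrupted\n",
              length(x), attr(x, "n_subjects"), ok, length(x) - ok))
  invisible(x)
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s: %g degC, %g %%RH, %s fan; reported TS %d%s\n",
              x$trial_id, x$setting$air_temp, x$setting$rh,
              x$setting$fan_level, x$reported_ts,
              if (x$quality_ok) "" else sprintf(" [corrupted: %s %s]",
                                                x$corruption$modality,
                                                x$corruption$mode)))
  invisible(x)
}
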