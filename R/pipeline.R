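# Pipeline orchestration: config validation, cohort CSV IO, run_all.

#' Validate and normalise a run configuration
#'
#' Accepts a YAML file path or a nested list with optional sections
#' `cohort`, `extraction`, `model`, `protocol`, `evaluation`, plus `seed`
#' and `out_dir`. Unknown keys are rejected with the offending name;
#' defaults reproduce the emulated study design (20 subjects, 8 settings,
#' sedentary 1.0 met, 0.5 clo).
#'
#' @param config path to a YAML file, or a list.
#' @return A list of class `run_config` with fully-defaulted sub-configs.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  known <- c("cohort", "extraction", "model", "protocol", "evaluation",
             "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  check_section <- function(section, fn) {
    args <- config[[section]] %||% list()
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) {
      stop(sprintf("unknown %s key(s): %s", section,
                   paste(bad, collapse = ", ")))
    }
    # yaml reads vectors as lists; flatten scalars
    args <- lapply(args, function(a) if (is.list(a)) unlist(a) else a)
    do.call(fn, args)
  }
  model_args <- config$model %||% list()
  if (!is.null(model_args$family) &&
      !model_args$family %in% c("gpr", "linear", "svm", "tree")) {
    stop("unknown model family '", model_args$family,
         "'; allowed: gpr, linear, svm, tree")
  }
  eval_args <- config$evaluation %||% list()
  bad <- setdiff(names(eval_args),
                 c("n_trials", "train_n", "test_n", "met", "clo",
                   "gender_counts"))
  if (length(bad)) stop("unknown evaluation key(s): ",
                        paste(bad, collapse = ", "))
  structure(list(
    cohort = check_section("cohort", cohort_config),
    extraction = check_section("extraction", extraction_config),
    model = do.call(model_spec, model_args),
    protocol = check_section("protocol", cv_protocol),
    evaluation = utils::modifyList(list(n_trials = 3, train_n = 72,
                                        test_n = NULL, met = 1.0, clo = 0.5,
                                        gender_counts = NULL), eval_args),
    seed = as.integer(config$seed %||% 1L),
    out_dir = config$out_dir %||% "thermosense_run"
  ), class = "run_config")
}

#' Write a cohort to disk as plain-text CSV
#'
#' One trial-metadata CSV (`cohort.csv`) plus, optionally, per-trial
#' per-modality trace CSVs under `traces/` (`time_s,value` for sampled
#' modalities, `index,rr_ms` for the RR series).
#'
#' @param cohort a `ts_cohort`.
#' @param dir output directory (created if needed).
#' @param traces write the (large) raw trace files as well.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, traces = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(cohort, function(rec) {
    data.frame(trial_id = rec$trial_id,
               subject_id = rec$subject$subject_id, sex = rec$subject$sex,
               air_temp = rec$setting$air_temp, rh = rec$setting$rh,
               fan_level = rec$setting$fan_level,
               wind_speed = rec$setting$wind_speed,
               reported_ts = rec$reported_ts, latent_ts = rec$latent_ts,
               quality_ok = rec$quality_ok, stringsAsFactors = FALSE)
  }))
  write.csv(meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  if (traces) {
    tdir <- file.path(dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (rec in cohort) {
      for (tr in rec$traces) {
        f <- file.path(tdir, paste0(rec$trial_id, "_", tr$modality, ".csv"))
        if (tr$modality == "ECG_RR") {
          write.csv(data.frame(index = seq_along(tr$samples),
                               rr_ms = tr$samples), f, row.names = FALSE)
        } else {
          write.csv(data.frame(
            time_s = (seq_along(tr$samples) - 1) / tr$sampling_rate,
            value = tr$samples), f, row.names = FALSE)
        }
      }
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' User-supplied real data in the same schema is read identically; such
#' records carry no latent TS.
#'
#' @param dir directory holding `cohort.csv` and `traces/`.
#' @param fs named sampling rates used to reconstruct trace objects (taken
#'   from the trace time columns when present).
#' @return A `ts_cohort`.
#' @export
read_cohort <- function(dir, fs = NULL) {
  meta <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  tdir <- file.path(dir, "traces")
  records <- lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    traces <- list()
    for (mod in names(trace_units)) {
      f <- file.path(tdir, paste0(row$trial_id, "_", mod, ".csv"))
      if (!file.exists(f)) next
      d <- read.csv(f)
      traces[[mod]] <- if (mod == "ECG_RR") {
        signal_trace(mod, d$rr_ms)
      } else {
        rate <- if (nrow(d) > 1) 1 / (d$time_s[2] - d$time_s[1]) else fs[[mod]]
        signal_trace(mod, d$value, round(rate, 6))
      }
    }
    structure(list(trial_id = row$trial_id,
                   subject = list(subject_id = row$subject_id, sex = row$sex),
                   setting = list(air_temp = row$air_temp, rh = row$rh,
                                  fan_level = row$fan_level,
                                  wind_speed = row$wind_speed),
                   traces = traces, latent_ts = row$latent_ts,
                   reported_ts = row$reported_ts,
                   quality_ok = row$quality_ok, corruption = NULL),
              class = "trial_record")
  })
  structure(records, class = "ts_cohort", n_subjects = length(unique(meta$subject_id)))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline from one seeded configuration
#'
#' simulate -> extract -> select -> evaluate, writing the cohort metadata,
#' feature table, selection report and evaluation reports under the
#' configured output directory, plus a manifest with file digests. One
#' root seed determines every artifact.
#'
#' @param config a [validate_config()] result, or anything it accepts.
#' @param write_traces also write the raw per-trial trace CSVs (large).
#' @param quiet suppress progress messages.
#' @return The run manifest (named list), invisibly a side effect of the
#'   files written.
#' @export
run_all <- function(config = list(), write_traces = FALSE, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("[simulate] %d subjects x 8 settings (seed %d)",
      cfg$cohort$n_subjects, cfg$seed)
  cohort <- run_stage("simulate", generate_cohort(cfg$cohort, cfg$seed))
  write_cohort(cohort, file.path(out, "cohort"), traces = write_traces)

  say("[extract] screening and extracting features")
  tab <- run_stage("extract", feature_table(cohort, cfg$extraction))
  write.csv(tab, file.path(out, "features.csv"), row.names = FALSE)

  say("[select] %s backend, %d-fold x %d CV", cfg$model$family,
      cfg$protocol$folds, cfg$protocol$repeats)
  fit <- run_stage("select", ts_model(reported_ts ~ ., tab,
                                      family = cfg$model$family,
                                      protocol = cfg$protocol,
                                      seed = cfg$seed))
  sel_report <- list(S_best = fit$features,
                     cv_rmse = fit$performance$rmse,
                     cv_r2 = fit$performance$r2,
                     explored = nrow(fit$state$trace),
                     trace = fit$state$trace)
  jsonlite::write_json(sel_report, file.path(out, "selection.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  say("[evaluate] correlation, PMV comparison, gender, ranking")
  ev <- cfg$evaluation
  reports <- run_stage("evaluate", {
    corr <- correlation_table(tab)
    cmp <- compare_with_pmv(tab, cfg$model, fit$features,
                            n_trials = ev$n_trials,
                            train_n = min(ev$train_n, nrow(tab) - 2),
                            test_n = ev$test_n,
                            seed = cfg$seed, met = ev$met, clo = ev$clo)
    gen <- gender_error_test(tab, cfg$model, fit$features,
                             counts = ev$gender_counts, seed = cfg$seed)
    rk <- rank_signals(tab, cfg$model, protocol = cfg$protocol)
    list(correlation = corr, pmv_comparison = cmp, gender = gen, ranking = rk)
  })
  write.csv(reports$correlation, file.path(out, "correlation.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(trials = reports$pmv_comparison$trials,
         average = as.list(reports$pmv_comparison$average),
         split = as.list(reports$pmv_comparison$split)),
    file.path(out, "pmv_comparison.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  g <- reports$gender
  jsonlite::write_json(
    list(rmse = as.list(g$rmse), male = as.list(g$male),
         female = as.list(g$female), t_test = g$t_test,
         mann_whitney = g$mann_whitney, counts = as.list(g$counts)),
    file.path(out, "gender.json"), auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(reports$ranking), file.path(out, "ranking.csv"),
            row.names = FALSE)

  files <- c("cohort/cohort.csv", "features.csv", "selection.json",
             "correlation.csv", "pmv_comparison.json", "gender.json",
             "ranking.csv")
  manifest <- list(
    package = "thermosense",
    version = as.character(utils::packageVersion("thermosense")),
    seed = cfg$seed,
    stages = c("simulate", "extract", "select", "evaluate"),
    n_trials = length(cohort),
    n_passing = nrow(tab),
    selected_features = fit$features,
    digests = as.list(tools::md5sum(file.path(out, files)))
  )
  names(manifest$digests) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
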