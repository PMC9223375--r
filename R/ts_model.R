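# Fitting front-end: two-stage wrapper selection plus a refitted backend,
# returned as a classed model object.

#' Fit a thermal sensation model with wrapper feature selection
#'
#' Runs the two-stage greedy wrapper ([feature_increment()] then
#' [redundant_removal()]) over the candidate features named on the right
#' side of `formula`, refits the chosen backend on the selected subset over
#' the full table, and returns a classed model object.
#'
#' @param formula model formula; the default `reported_ts ~ .` takes every
#'   extracted feature present in `data` as a candidate.
#' @param data a feature table from [feature_table()] (or any data frame
#'   with the response and candidate columns).
#' @param family backend family, see [model_spec()].
#' @param protocol a [cv_protocol()] used for every subset evaluation.
#' @param select set `FALSE` to skip selection and fit on all candidates.
#' @param ... hyperparameter overrides passed to [model_spec()].
#' @param seed seed for stochastic fitting steps.
#' @return An object of class `ts_model` with components `features`
#'   (selected subset), `performance` (cross-validated RMSE/R^2 of the
#'   selected subset), `state` (full selection trace), `backend` (the
#'   refitted model) and `data`.
#' @seealso [predict.ts_model()], [summary.ts_model()], [plot.ts_model()]
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_subjects = 4, duration = 310,
#'                                         fs = c(EMG = 250, EEG = 128,
#'                                                GSR = 16, TEMP = 1)),
#'                           seed = 7)
#' tab <- feature_table(cohort)
#' fit <- ts_model(reported_ts ~ ., tab, family = "linear")
#' print(fit)
#' }
ts_model <- function(formula = reported_ts ~ ., data,
                     family = c("gpr", "linear", "svm", "tree"),
                     protocol = cv_protocol(), select = TRUE, ...,
                     seed = 1) {
  family <- match.arg(family)
  spec <- model_spec(family, ..., seed = seed)
  response <- all.vars(formula[[2]])
  if (!response %in% names(data)) stop("response not found in data")
  rhs <- attr(stats::terms(formula, data = data), "term.labels")
  candidates <- setdiff(intersect(rhs, names(data)),
                        c(response, "subject_id", "sex", "trial_id",
                          "latent_ts"))
  if (!length(candidates)) stop("no candidate features in data")
  tab <- data
  if (response != "reported_ts") tab$reported_ts <- data[[response]]
  if (select) {
    state <- feature_increment(tab, spec, protocol, candidates = candidates)
    state <- redundant_removal(state, tab, spec, protocol)
    features <- state$S_best
    perf <- state$best_perf
  } else {
    state <- NULL
    features <- candidates
    perf <- evaluate_subset(features, tab, spec, protocol)
  }
  backend <- fit_backend(spec,
                         if (length(features)) tab[, features, drop = FALSE] else NULL,
                         tab$reported_ts)
  structure(list(call = match.call(), family = family, spec = spec,
                 protocol = protocol, candidates = candidates,
                 features = features,
                 performance = perf, state = state, backend = backend,
                 data = tab, response = response),
            class = "ts_model")
}

#' @export
print.ts_model <- function(x, ...) {
  cat(sprintf("Thermal sensation model (%s backend)\n", x$family))
  cat(sprintf("  selected features (%d of %d candidates): %s\n",
              length(x$features), length(x$candidates),
              if (length(x$features)) paste(x$features, collapse = ", ")
              else "<none: mean predictor>"))
  cat(sprintf("  cross-validated RMSE %.3f, R^2 %.3f (%d-fold x %d)\n",
              x$performance$rmse, x$performance$r2,
              x$protocol$folds, x$protocol$repeats))
  if (!is.null(x$state)) {
    cat(sprintf("  combinations explored: %d\n", nrow(x$state$trace)))
  }
  invisible(x)
}

#' Summarise a fitted thermal sensation model
#'
#' @param object a `ts_model`.
#' @param ... unused.
#' @return A `summary.ts_model` with per-round selection summaries.
#' @export
summary.ts_model <- function(object, ...) {
  rounds <- NULL
  if (!is.null(object$state)) {
    tr <- object$state$trace
    agg <- do.call(rbind, lapply(split(tr, list(tr$stage, tr$round),
                                       drop = TRUE), function(d) {
      data.frame(stage = d$stage[1], round = d$round[1],
                 evaluated = nrow(d), best_rmse = min(d$rmse),
                 stringsAsFactors = FALSE)
    }))
    rounds <- agg[order(factor(agg$stage,
                               c("baseline", "increment", "removal")),
                        agg$round), ]
    row.names(rounds) <- NULL
  }
  structure(list(model = object, rounds = rounds), class = "summary.ts_model")
}

#' @export
print.summary.ts_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$rounds)) {
    cat("\nSelection rounds:\n")
    print(x$rounds, row.names = FALSE)
  }
  invisible(x)
}

#' Predict thermal sensation for new trials
#'
#' @param object a `ts_model`.
#' @param newdata data frame carrying the selected feature columns;
#'   defaults to the training table.
#' @param ... unused.
#' @return Numeric vector of predicted TS (unclipped).
#' @export
predict.ts_model <- function(object, newdata = NULL, ...) {
  newdata <- newdata %||% object$data
  if (length(object$features)) {
    missing <- setdiff(object$features, names(newdata))
    if (length(missing)) {
      stop("newdata lacks selected feature(s): ",
           paste(missing, collapse = ", "))
    }
    predict_backend(object$backend,
                    newdata[, object$features, drop = FALSE])
  } else {
    rep(object$backend$mean, nrow(newdata))
  }
}

#' @export
fitted.ts_model <- function(object, ...) predict(object)

#' @export
residuals.ts_model <- function(object, ...) {
  object$data$reported_ts - fitted(object)
}

#' @export
coef.ts_model <- function(object, ...) {
  if (object$family != "linear") {
    stop("coefficients are only defined for the linear backend")
  }
  coef(object$backend$fit)
}

#' Plot the selection trace of a fitted model
#'
#' Cross-validated RMSE of every evaluated combination in exploration
#' order, with the accepted `S_best` updates highlighted.
#'
#' @param x a `ts_model` fitted with `select = TRUE`.
#' @param ... passed to [plot()].
#' @export
plot.ts_model <- function(x, ...) {
  if (is.null(x$state)) stop("model was fitted without selection")
  tr <- x$state$trace
  plot(seq_len(nrow(tr)), tr$rmse, type = "p", pch = 16,
       col = ifelse(tr$is_best, "firebrick", "grey50"),
       xlab = "combination (exploration order)",
       ylab = "cross-validated RMSE", ...)
  lines(which(tr$is_best), tr$rmse[tr$is_best], col = "firebrick")
  legend("topright", pch = 16, col = c("grey50", "firebrick"),
         legend = c("evaluated", "S_best update"), bty = "n")
  invisible(x)
}
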