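# Regression backends, cross-validation protocol, and the two-stage greedy
# wrapper (feature increment, then redundant-feature removal).

#' Regression backend specification
#'
#' Four interchangeable families: ordinary least squares (`linear`),
#' Gaussian process regression with a squared-exponential kernel plus noise
#' term (`gpr`), epsilon-SVM regression with a radial kernel (`svm`), and a
#' depth-limited decision tree (`tree`). Kernel methods standardise
#' features with training-fold statistics; tree and linear fits use raw
#' values. An empty feature set always fits the mean predictor.
#'
#' @param family backend family.
#' @param ... family hyperparameter overrides (`var` for gpr; `epsilon`,
#'   `cost` for svm; `maxdepth`, `cp` for tree).
#' @param seed seed used by stochastic fitting steps.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("gpr", "linear", "svm", "tree"), ...,
                       seed = 1) {
  family <- match.arg(family)
  hp <- utils::modifyList(switch(family,
    gpr = list(var = NULL),
    svm = list(epsilon = 0.1, cost = 1),
    tree = list(maxdepth = 5, cp = 0.01),
    linear = list()
  ), list(...))
  structure(list(family = family, hyper = hp, seed = seed),
            class = "model_spec")
}

#' Cross-validation protocol descriptor
#'
#' Repeated k-fold cross-validation with a fixed seed; the scalar selection
#' criterion is the mean over repeats of the pooled per-repeat RMSE, with
#' out-of-fold R^2 reported alongside.
#'
#' @param folds number of folds.
#' @param repeats number of repeats.
#' @param seed seed controlling fold assignment.
#' @return A list of class `cv_protocol`.
#' @export
cv_protocol <- function(folds = 5, repeats = 3, seed = 1) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = folds, repeats = repeats, seed = seed),
            class = "cv_protocol")
}

# ---- backend fit/predict -------------------------------------------------

fit_backend <- function(spec, x, y) {
  if (is.null(x) || ncol(x) == 0) {
    return(structure(list(kind = "mean", mean = mean(y)), class = "ts_backend"))
  }
  x <- as.matrix(x)
  scaling <- NULL
  if (spec$family %in% c("gpr", "svm")) {
    mu <- colMeans(x)
    sg <- apply(x, 2, sd)
    sg[sg < 1e-12] <- 1
    x <- scale(x, center = mu, scale = sg)
    scaling <- list(center = mu, scale = sg)
  }
  fit <- local_seed(spec$seed, switch(spec$family,
    linear = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- y
      lm(.y ~ ., data = df)
    },
    gpr = fit_gpr(x, y, var = spec$hyper$var),
    svm = e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                     epsilon = spec$hyper$epsilon, cost = spec$hyper$cost,
                     scale = FALSE),
    tree = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "anova",
                   control = rpart::rpart.control(
                     maxdepth = spec$hyper$maxdepth, cp = spec$hyper$cp))
    }
  ))
  structure(list(kind = spec$family, fit = fit, scaling = scaling,
                 features = colnames(x)),
            class = "ts_backend")
}

predict_backend <- function(backend, newx) {
  if (backend$kind == "mean") {
    n <- if (is.null(newx)) 1L else nrow(newx)
    return(rep(backend$mean, n))
  }
  newx <- as.matrix(newx[, backend$features, drop = FALSE])
  if (!is.null(backend$scaling)) {
    newx <- scale(newx, center = backend$scaling$center,
                  scale = backend$scaling$scale)
  }
  switch(backend$kind,
    linear = ,
    tree = as.numeric(predict(backend$fit,
                              newdata = data.frame(newx, check.names = FALSE))),
    gpr = predict_gpr(backend$fit, newx),
    svm = as.numeric(predict(backend$fit, newx))
  )
}

# Gaussian process regression: squared-exponential kernel
# (median-heuristic width via kernlab::sigest) with the noise term chosen
# by maximising the log marginal likelihood over a variance grid, unless
# fixed by the caller. The posterior mean is solved directly from the
# Cholesky factor already needed for the evidence.
fit_gpr <- function(x, y, var = NULL) {
  sig <- tryCatch(as.numeric(kernlab::sigest(x, scaled = FALSE)[2]),
                  error = function(e) NA_real_)
  if (!is.finite(sig) || sig <= 0) sig <- 1
  k <- rbf_kernel(x, x, sig)
  yc <- y - mean(y)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  cand <- if (is.null(var)) {
    vy * c(1e-6, 1e-4, 0.01, 0.05, 0.1, 0.2, 0.4, 0.8)
  } else var
  best <- NULL
  best_ev <- -Inf
  for (v in cand) {
    ch <- tryCatch(chol(k + diag(v, nrow(k))), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, backsolve(ch, yc, transpose = TRUE))
    ev <- -sum(log(diag(ch))) - 0.5 * sum(yc * alpha)
    if (ev > best_ev) {
      best_ev <- ev
      best <- list(alpha = alpha, var = v)
    }
  }
  if (is.null(best)) stop("GP fit failed: kernel matrix not factorisable")
  list(xtrain = x, alpha = best$alpha, ymean = mean(y), sigma = sig,
       var = best$var)
}

rbf_kernel <- function(x, z, sigma) {
  d2 <- outer(rowSums(x^2), rowSums(z^2), `+`) - 2 * tcrossprod(x, z)
  exp(-sigma * pmax(d2, 0))
}

predict_gpr <- function(fit, newx) {
  ks <- rbf_kernel(newx, fit$xtrain, fit$sigma)
  as.numeric(ks %*% fit$alpha) + fit$ymean
}

# ---- subset evaluation ---------------------------------------------------

#' Cross-validated performance of a feature subset
#'
#' Fits the backend on each training fold and scores held-out rows;
#' reported RMSE is the mean over repeats of the pooled out-of-fold RMSE,
#' and R^2 the matching out-of-fold `1 - SS_res/SS_tot`. The empty feature
#' set is evaluated as the mean predictor and serves as the selection
#' baseline.
#'
#' @param features character vector of feature names (possibly empty).
#' @param table feature table with a `reported_ts` column.
#' @param model a [model_spec()].
#' @param protocol a [cv_protocol()].
#' @return A list with `rmse`, `r2` and the protocol descriptor.
#' @export
evaluate_subset <- function(features, table, model = model_spec(),
                            protocol = cv_protocol()) {
  unknown <- setdiff(features, names(table))
  if (length(unknown)) {
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  }
  y <- table$reported_ts
  n <- length(y)
  if (n < 2 * protocol$folds) stop("too few rows for the CV protocol")
  x_full <- if (length(features)) {
    m <- as.matrix(table[, features, drop = FALSE])
    storage.mode(m) <- "double"
    m
  } else NULL
  rmse_r <- r2_r <- numeric(protocol$repeats)
  for (r in seq_len(protocol$repeats)) {
    fold <- local_seed(child_seed(protocol$seed, "fold", r), {
      sample(rep_len(seq_len(protocol$folds), n))
    })
    pred <- numeric(n)
    for (k in seq_len(protocol$folds)) {
      tr <- fold != k
      bk <- fit_backend(model,
                        if (length(features)) x_full[tr, , drop = FALSE] else NULL,
                        y[tr])
      pred[!tr] <- if (length(features)) {
        predict_backend(bk, x_full[!tr, , drop = FALSE])
      } else {
        predict_backend(bk, data.frame(row.names = seq_len(sum(!tr))))
      }
    }
    rmse_r[r] <- sqrt(mean((pred - y)^2))
    r2_r[r] <- 1 - sum((pred - y)^2) / sum((y - mean(y))^2)
  }
  list(rmse = mean(rmse_r), r2 = mean(r2_r),
       protocol = c(folds = protocol$folds, repeats = protocol$repeats,
                    seed = protocol$seed))
}

make_eval_fn <- function(table, model, protocol) {
  function(features) evaluate_subset(features, table, model, protocol)
}

new_state <- function(candidates) {
  structure(list(S_best = character(0), T_best = character(0),
                 S_uc = candidates, Time_worse = 0L, best_perf = NULL,
                 trace = data.frame(stage = character(0), round = integer(0),
                                    features = character(0), rmse = numeric(0),
                                    r2 = numeric(0), is_best = logical(0),
                                    stringsAsFactors = FALSE)),
            class = "selection_state")
}

log_eval <- function(state, stage, round, features, perf, is_best = FALSE) {
  state$trace <- rbind(state$trace, data.frame(
    stage = stage, round = round,
    features = paste(features, collapse = "+"),
    rmse = perf$rmse, r2 = perf$r2 %||% NA_real_, is_best = is_best,
    stringsAsFactors = FALSE))
  state
}

# evaluate a list of candidate combinations; returns index of the best
# (strictly lowest rmse; ties resolved to the earliest candidate, i.e.
# lexicographic in the declared feature order)
best_candidate <- function(perfs) {
  rmses <- vapply(perfs, `[[`, 0, "rmse")
  which.min(rmses)
}

#' Stage 1 of the wrapper: greedy feature increment
#'
#' Starting from empty overall-best (`S_best`) and stepwise-best (`T_best`)
#' sets, each round evaluates `T_best + {f}` for every unselected feature
#' `f`, moves `T_best` to the best candidate, and adopts it as `S_best`
#' while it strictly improves on the best recorded performance; the first
#' non-improving round ends the stage. The baseline performance of the
#' empty set is the mean predictor.
#'
#' @param table feature table with `reported_ts` (ignored when `eval_fn`
#'   is supplied).
#' @param model a [model_spec()].
#' @param protocol a [cv_protocol()].
#' @param candidates candidate feature names; defaults to the intersection
#'   of [feature_names()] with the table columns.
#' @param eval_fn optional performance function `function(features) ->
#'   list(rmse, r2)`, e.g. a mocked lookup; replaces model fitting.
#' @return A `selection_state` with `S_best`, `T_best`, `S_uc`,
#'   `Time_worse`, `best_perf` and the full evaluation `trace`.
#' @export
feature_increment <- function(table = NULL, model = model_spec(),
                              protocol = cv_protocol(), candidates = NULL,
                              eval_fn = NULL) {
  eval_fn <- eval_fn %||% make_eval_fn(table, model, protocol)
  candidates <- candidates %||% intersect(feature_names(), names(table))
  if (length(candidates) < 1) stop("need at least one candidate feature")
  state <- new_state(candidates)
  base <- eval_fn(character(0))
  state$best_perf <- base
  state <- log_eval(state, "baseline", 0L, character(0), base, TRUE)
  round <- 0L
  repeat {
    if (!length(state$S_uc)) break
    round <- round + 1L
    combos <- lapply(state$S_uc, function(f) c(state$T_best, f))
    perfs <- lapply(combos, eval_fn)
    for (j in seq_along(combos)) {
      state <- log_eval(state, "increment", round, combos[[j]], perfs[[j]])
    }
    j <- best_candidate(perfs)
    state$T_best <- combos[[j]]
    if (perfs[[j]]$rmse < state$best_perf$rmse) {
      state$S_best <- state$T_best
      state$best_perf <- perfs[[j]]
      state$S_uc <- setdiff(state$S_uc, state$S_uc[j])
      state$trace$is_best[nrow(state$trace) - length(perfs) + j] <- TRUE
    } else {
      break
    }
  }
  state
}

#' Stage 2 of the wrapper: redundant-feature removal
#'
#' Starting from `T_best = S_best`, each round evaluates `T_best - {f}` for
#' every retained feature, moves `T_best` to the best candidate, and
#' updates `S_best` when it strictly improves (resetting the worse-step
#' counter). A non-improving round increments `Time_worse` and the search
#' continues once from the worse `T_best`; the second consecutive
#' non-improving round since the last `S_best` update ends the stage.
#'
#' @param state a `selection_state` from [feature_increment()].
#' @inheritParams feature_increment
#' @return The updated `selection_state`. States with `|S_best| <= 1` are
#'   returned unchanged (nothing removable).
#' @export
redundant_removal <- function(state, table = NULL, model = model_spec(),
                              protocol = cv_protocol(), eval_fn = NULL) {
  if (length(state$S_best) <= 1) return(state)
  eval_fn <- eval_fn %||% make_eval_fn(table, model, protocol)
  state$T_best <- state$S_best
  state$Time_worse <- 0L
  round <- 0L
  repeat {
    if (length(state$T_best) < 1) break
    round <- round + 1L
    combos <- lapply(seq_along(state$T_best),
                     function(j) state$T_best[-j])
    perfs <- lapply(combos, eval_fn)
    for (j in seq_along(combos)) {
      state <- log_eval(state, "removal", round, combos[[j]], perfs[[j]])
    }
    j <- best_candidate(perfs)
    state$T_best <- combos[[j]]
    if (perfs[[j]]$rmse < state$best_perf$rmse) {
      state$S_best <- state$T_best
      state$best_perf <- perfs[[j]]
      state$Time_worse <- 0L
      state$trace$is_best[nrow(state$trace) - length(perfs) + j] <- TRUE
    } else {
      state$Time_worse <- state$Time_worse + 1L
      if (state$Time_worse >= 2L) break
    }
    if (length(state$T_best) < 1) break
  }
  state
}

#' @export
print.selection_state <- function(x, ...) {
  cat(sprintf("<selection_state> S_best = {%s}\n",
              paste(x$S_best, collapse = ", ")))
  cat(sprintf("  best RMSE %.4g | %d combinations explored | Time_worse %d\n",
              x$best_perf$rmse, nrow(x$trace), x$Time_worse))
  invisible(x)
}
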