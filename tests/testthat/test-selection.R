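# Two-stage wrapper selection: hand-simulated traces on mocked
# performance, brute-force comparison, CV evaluation, backends.

test_that("evaluate_subset: mean baseline, perfect predictor, determinism", {
  withr::with_seed(3, {
    tab <- data.frame(reported_ts = sample(-2:2, 40, replace = TRUE),
                      noise = rnorm(40))
  })
  tab$copy <- tab$reported_ts
  proto <- cv_protocol(folds = 5, repeats = 2, seed = 9)

  base <- evaluate_subset(character(0), tab, model_spec("linear"), proto)
  expect_equal(base$rmse, sd(tab$reported_ts), tolerance = 0.1)
  expect_lt(abs(base$r2), 0.15)

  perfect <- evaluate_subset("copy", tab, model_spec("linear"), proto)
  expect_lt(perfect$rmse, 1e-6)
  expect_equal(perfect$r2, 1, tolerance = 1e-6)

  again <- evaluate_subset("copy", tab, model_spec("linear"), proto)
  expect_identical(perfect, again)

  expect_error(evaluate_subset("nope", tab, model_spec("linear"), proto),
               "unknown feature")
})

test_that("feature increment reproduces a hand-simulated greedy trace", {
  eval_fn <- mock_eval(list(
    "<empty>" = 1.00,
    "A" = 0.80, "B" = 0.90, "C" = 0.95,
    "A+B" = 0.70, "A+C" = 0.75,
    "A+B+C" = 0.72))
  st <- feature_increment(candidates = c("A", "B", "C"), eval_fn = eval_fn)
  # hand simulation: round 1 adopts {A}; round 2 adopts {A,B}; round 3
  # evaluates {A,B,C} = 0.72 > 0.70 and stops
  expect_identical(st$S_best, c("A", "B"))
  expect_equal(st$best_perf$rmse, 0.70)
  expect_identical(st$T_best, c("A", "B", "C"))
  expect_equal(nrow(st$trace), 1 + 3 + 2 + 1)
  expect_identical(st$S_uc, "C")
})

test_that("first round without improvement leaves S_best empty", {
  eval_fn <- mock_eval(list("<empty>" = 0.50, "A" = 0.60, "B" = 0.55))
  st <- feature_increment(candidates = c("A", "B"), eval_fn = eval_fn)
  expect_identical(st$S_best, character(0))
  expect_equal(st$best_perf$rmse, 0.50)
  expect_equal(nrow(st$trace), 3)
})

test_that("improvement on every addition selects all features", {
  feats <- c("A", "B", "C", "D")
  eval_fn <- function(features) list(rmse = 1 - 0.1 * length(features),
                                     r2 = NA_real_)
  st <- feature_increment(candidates = feats, eval_fn = eval_fn)
  expect_setequal(st$S_best, feats)
})

test_that("redundant removal follows the one-grace-step stop rule", {
  # case 1: no removal helps twice -> S_best unchanged, Time_worse = 2
  eval_fn <- mock_eval(list(
    "<empty>" = 1.00, "A" = 0.80, "B" = 0.90, "C" = 0.95,
    "A+B" = 0.70, "A+C" = 0.75, "A+B+C" = 0.72))
  st <- feature_increment(candidates = c("A", "B", "C"), eval_fn = eval_fn)
  st2 <- redundant_removal(st, eval_fn = eval_fn)
  expect_identical(st2$S_best, c("A", "B"))
  expect_equal(st2$Time_worse, 2L)

  # case 2: dropping a redundant feature improves -> S_best shrinks
  ev2 <- mock_eval(list(
    "<empty>" = 1.00, "A" = 0.80, "B" = 0.90, "C" = 0.95,
    "A+B" = 0.70, "A+C" = 0.75, "A+B+C" = 0.65,
    "B+C" = 0.60))
  s1 <- feature_increment(candidates = c("A", "B", "C"), eval_fn = ev2)
  expect_setequal(s1$S_best, c("A", "B", "C"))
  s2 <- redundant_removal(s1, eval_fn = ev2)
  expect_setequal(s2$S_best, c("B", "C"))
  expect_equal(s2$best_perf$rmse, 0.60)

  # case 3: first removal is worse, but removing again from the worse
  # T_best beats S_best (the grace step re-expands from current T_best)
  ev3 <- mock_eval(list(
    "<empty>" = 1.00, "A" = 0.80, "B" = 0.85, "C" = 0.90,
    "A+B" = 0.75, "A+C" = 0.78, "A+B+C" = 0.70,
    "B+C" = 0.74))
  s3 <- feature_increment(candidates = c("A", "B", "C"), eval_fn = ev3)
  expect_setequal(s3$S_best, c("A", "B", "C"))
  ev3b <- mock_eval(list(
    "<empty>" = 1.00, "A" = 0.80, "B" = 0.68, "C" = 0.90,
    "A+B" = 0.72, "A+C" = 0.78, "A+B+C" = 0.70,
    "B+C" = 0.74))
  s4 <- redundant_removal(s3, eval_fn = ev3b)
  # round 1: best removal {A,B} = 0.72 > 0.70 -> grace step, T_best {A,B}
  # round 2: {B} = 0.68 < 0.70 -> S_best updated, counter reset
  # round 3: {} = 1.0 -> second worse step only now; stops
  expect_identical(s4$S_best, "B")
  expect_equal(s4$best_perf$rmse, 0.68)

  # nothing removable: singleton states pass through unchanged
  s5 <- feature_increment(candidates = "A",
                          eval_fn = mock_eval(list("<empty>" = 1, "A" = 0.9)))
  expect_identical(redundant_removal(s5), s5)
})

test_that("S_best performance is monotone along accepted updates and the trace is complete", {
  eval_fn <- mock_eval(list(
    "<empty>" = 1.00, "A" = 0.80, "B" = 0.90, "C" = 0.95,
    "A+B" = 0.70, "A+C" = 0.75, "A+B+C" = 0.65, "B+C" = 0.60))
  st <- redundant_removal(
    feature_increment(candidates = c("A", "B", "C"), eval_fn = eval_fn),
    eval_fn = eval_fn)
  accepted <- st$trace$rmse[st$trace$is_best]
  expect_true(all(diff(accepted) <= 0))
  # every round logs each candidate exactly once
  per_round <- split(st$trace, list(st$trace$stage, st$trace$round),
                     drop = TRUE)
  for (d in per_round) expect_false(any(duplicated(d$features)))
})

test_that("greedy selection matches brute-force search on a 6-feature additive landscape", {
  feats <- LETTERS[1:6]
  gains <- c(A = 0.20, B = 0.15, C = 0.10, D = 0.05, E = -0.05, F = -0.10)
  eval_fn <- function(features) {
    list(rmse = 1 - sum(gains[features]), r2 = NA_real_)
  }
  st <- redundant_removal(
    feature_increment(candidates = feats, eval_fn = eval_fn),
    eval_fn = eval_fn)
  oracle <- brute_force_best(feats, eval_fn)
  expect_identical(sort(st$S_best), oracle$features)
  expect_equal(st$best_perf$rmse, oracle$rmse)
})

test_that("all four backends fit and predict on a small smoke table", {
  withr::with_seed(8, {
    tab <- data.frame(x1 = rnorm(10), x2 = rnorm(10))
    tab$reported_ts <- tab$x1 - 0.5 * tab$x2 + rnorm(10, sd = 0.1)
  })
  for (fam in c("linear", "gpr", "svm", "tree")) {
    fit <- ts_model(reported_ts ~ x1 + x2, tab, family = fam,
                    protocol = cv_protocol(folds = 2, repeats = 1),
                    select = FALSE)
    p <- predict(fit, tab)
    expect_length(p, 10)
    expect_true(all(is.finite(p)), info = fam)
  }
})

test_that("the Gaussian process backend interpolates noise-free data", {
  withr::with_seed(21, x <- sort(runif(25, -2, 2)))
  tab <- data.frame(x = x, reported_ts = sin(2 * x))
  fit <- ts_model(reported_ts ~ x, tab, family = "gpr",
                  protocol = cv_protocol(folds = 2, repeats = 1),
                  select = FALSE)
  expect_lt(sqrt(mean(residuals(fit)^2)), 1e-3)
})

test_that("ts_model front end selects, refits and exposes methods", {
  withr::with_seed(12, {
    n <- 60
    tab <- data.frame(good = rnorm(n), junk = rnorm(n))
    tab$reported_ts <- round(tab$good * 2 + rnorm(n, sd = 0.3))
  })
  fit <- ts_model(reported_ts ~ ., tab, family = "linear",
                  protocol = cv_protocol(folds = 5, repeats = 2, seed = 4))
  expect_s3_class(fit, "ts_model")
  expect_true("good" %in% fit$features)
  expect_false("junk" %in% fit$features)
  expect_length(fitted(fit), n)
  expect_equal(residuals(fit), tab$reported_ts - fitted(fit))
  expect_named(coef(fit))
  expect_output(print(fit), "selected features")
  s <- summary(fit)
  expect_s3_class(s, "summary.ts_model")
  expect_output(print(s), "Selection rounds")
  # deterministic: same table, protocol and seed give identical S_best
  fit2 <- ts_model(reported_ts ~ ., tab, family = "linear",
                   protocol = cv_protocol(folds = 5, repeats = 2, seed = 4))
  expect_identical(fit$features, fit2$features)
  # plotting runs without error
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
  # coef only for the linear family
  gfit <- ts_model(reported_ts ~ good, tab, family = "gpr", select = FALSE,
                   protocol = cv_protocol(folds = 2, repeats = 1))
  expect_error(coef(gfit), "linear")
})
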