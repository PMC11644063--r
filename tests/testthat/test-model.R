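feat_row <- function(rroc = 0, curvature = 0, shot_angle = 0) {
  data.frame(rroc = rroc, curvature = curvature, shot_angle = shot_angle)
}

test_that("the sigmoid score hits its anchor points and stays in (0, 1)", {
  expect_equal(psxg_score(feat_row(), psxg_params(0, 1, 1, 1)), 0.5)
  expect_equal(psxg_score(feat_row(rroc = 4), psxg_params(0, 0.5, 0, 0)),
               1 / (1 + exp(-2)))
  # overflow-safe at extreme indices, strictly inside (0, 1)
  p <- psxg_score(feat_row(rroc = c(1e6, -1e6)), psxg_params(0, 1, 0, 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("the canonical sigmoid equals the classic 1/(1 + a b^X) form", {
  set.seed(7)
  for (i in 1:20) {
    params <- psxg_params(rnorm(1), rnorm(1), rnorm(1), rnorm(1, 0, 0.05))
    f <- feat_row(runif(50, 0, 8), runif(50, 0, 1), runif(50, 0, 90))
    leg <- legacy_constants(params)
    X <- leg$c * f$rroc + leg$d * f$curvature + leg$e * f$shot_angle
    classic <- 1 / (1 / leg$u + leg$a * leg$b^X)
    expect_equal(psxg_score(f, params), classic, tolerance = 1e-12)
  }
})

test_that("score is strictly increasing in rroc for a positive weight", {
  params <- psxg_params(-2, 0.9, 0.8, -0.02)
  f <- feat_row(rroc = seq(0, 10, length.out = 200), curvature = 0.3,
                shot_angle = 20)
  expect_true(all(diff(psxg_score(f, params)) > 0))
})

test_that("noiseless targets are refitted to the generating parameters", {
  flights <- generate_routines(generator_config(n_routines = 80, seed = 13))
  feats <- compute_features(flights)
  truth <- psxg_params(-3, 0.9, 0.8, -0.02)
  target <- psxg_score(feats, truth)
  fit <- fit_psxg(feats, target)
  expect_true(fit$converged)
  expect_equal(as.numeric(fit$params), as.numeric(truth), tolerance = 1e-4)
  expect_lt(fit$sse, 1e-10)

  # deterministic: same data and init give the same solution
  fit2 <- fit_psxg(feats, target)
  expect_identical(as.numeric(fit$params), as.numeric(fit2$params))
})

test_that("fit validates its inputs", {
  flights <- generate_routines(generator_config(n_routines = 20, seed = 14))
  feats <- compute_features(flights)
  expect_error(fit_psxg(feats, rep(1.2, 20)), "\\[0, 1\\]")
  expect_error(fit_psxg(feats[1:5, ], rep(0.5, 5)), "at least 10")
})

test_that("stratified folds partition the data with balanced sizes", {
  target <- runif(10)
  f <- stratified_folds(target, k = 5, seed = 4)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(as.vector(table(f)), rep(2L, 5))
  expect_identical(f, stratified_folds(target, k = 5, seed = 4))

  # a bimodal target stratifies exactly: every fold gets 10 low, 10 high
  tgt <- c(rep(0.1, 50), rep(0.9, 50))
  f2 <- stratified_folds(tgt, k = 5, seed = 9)
  for (k in 1:5) {
    expect_equal(sum(tgt[f2 == k] == 0.1), 10)
    expect_equal(sum(tgt[f2 == k] == 0.9), 10)
  }
  expect_error(stratified_folds(runif(3), k = 5), "at least k")
  expect_error(stratified_folds(runif(10), k = 1), "k must be")
})

test_that("cross-validation is near-perfect on noiseless data and honest on noise", {
  flights <- generate_routines(generator_config(n_routines = 120, seed = 15))
  feats <- compute_features(flights)
  truth <- psxg_params(-3, 0.9, 0.8, -0.02)
  target <- psxg_score(feats, truth)
  cv <- cross_validate(feats, target, seed = 2)
  expect_true(all(cv$metrics$test_r2 > 0.999))
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)

  # target independent of the features: no generalization to find
  set.seed(77)
  null_target <- runif(120)
  cv0 <- cross_validate(feats, null_target, seed = 2)
  expect_lt(cv0$summary$test_r2_mean, 0.05)
})

test_that("standardized fits match raw fits in predictions", {
  sc <- default_scenario(seed = 17, n_routines = 200, plays = 150)
  f <- sc$features
  y <- f$goal_proportion
  raw <- fit_psxg(f, y)
  std <- fit_standardized(f, y)
  expect_true(std$converged)
  expect_equal(predict(std, f), predict(raw, f), tolerance = 1e-6)

  degenerate <- f
  degenerate$curvature <- 1
  expect_error(fit_standardized(degenerate, y), "zero variance")
})

test_that("coefficient importance ranks standardized magnitudes with a fixed tie-break", {
  sc <- default_scenario(seed = 19, n_routines = 300, plays = 200)
  std <- fit_standardized(sc$features, sc$features$goal_proportion)
  imp <- coefficient_importance(std)
  expect_equal(imp$feature[1], "rroc")
  expect_true(all(diff(imp$magnitude) <= 0))

  tied <- std
  tied$params <- psxg_params(-1, 0.5, -0.5, 0.5)
  expect_equal(coefficient_importance(tied)$feature,
               c("rroc", "curvature", "shot_angle"))

  raw <- fit_psxg(sc$features, sc$features$goal_proportion)
  expect_error(coefficient_importance(raw), "standardized")
})

test_that("the winsorized linear baseline caps into [0, 1]", {
  w <- c(0, 0.02, 0.5, -0.1)
  expect_equal(baseline_difficulty(70, 0.5, 0.5, w), 1)       # 1.6 -> 1
  expect_equal(baseline_difficulty(10, 0.4, 0.3, w), 0.37)    # interior
  expect_equal(baseline_difficulty(0, 0, 2, w), 0)            # -0.2 -> 0
  expect_error(baseline_difficulty(1, 1, 1, c(1, 2)), "length 4")
})

test_that("predict_all scores every routine but refuses broken models", {
  sc <- default_scenario(seed = 23, n_routines = 100, plays = 150)
  fit <- fit_psxg(sc$features, sc$features$goal_proportion)
  preds <- predict_all(fit, sc$features)
  expect_equal(nrow(preds), 100)
  expect_true(all(preds$psxg > 0 & preds$psxg < 1))
  expect_equal(nrow(predict_all(fit, sc$features[0, ])), 0)

  broken <- fit
  broken$converged <- FALSE
  expect_error(predict_all(broken, sc$features), "non-converged")

  # bound invariant on a wide random sweep of feature vectors
  set.seed(31)
  wide <- feat_row(runif(10000, 0, 50), runif(10000, 0, 5),
                   runif(10000, 0, 90))
  expect_true(all(predict(fit, wide) > 0 & predict(fit, wide) < 1))
})

test_that("models serialize to JSON and back without changing predictions", {
  sc <- default_scenario(seed = 29, n_routines = 100, plays = 150)
  std <- fit_standardized(sc$features, sc$features$goal_proportion)
  path <- tempfile(fileext = ".json")
  write_model(std, path)
  back <- read_model(path)
  expect_equal(as.numeric(back$params), as.numeric(std$params))
  expect_equal(predict(back, sc$features), predict(std, sc$features))
  expect_equal(back$scaler$mean$rroc, std$scaler$mean$rroc)
})
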