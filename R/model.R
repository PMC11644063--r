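#' Canonical difficulty-model parameters
#'
#' The difficulty model is a bounded sigmoid of a linear index of the three
#' features,
#' \deqn{p = \frac{1}{1 + a\, b^{X}}, \qquad
#'       X = c\,RROC + d\,curvature + e\,angle,}
#' with upper bound 1. The five constants (a, b, c, d, e) are not jointly
#' identifiable: scaling (c, d, e) by k and replacing b by b^(1/k) leaves
#' the curve unchanged. The package therefore fits the equivalent canonical
#' four-parameter logistic form
#' \deqn{p = \mathrm{logit}^{-1}(\gamma_0 + \gamma_1 RROC +
#'       \gamma_2 curvature + \gamma_3 angle)}
#' which maps back to the classic constants via `a = exp(-gamma0)`,
#' `b = exp(-1)`, `(c, d, e) = (gamma1, gamma2, gamma3)` (see
#' [legacy_constants()]).
#'
#' @param gamma0 Intercept on the log-odds scale.
#' @param gamma1,gamma2,gamma3 Log-odds weights of RROC (m/s), curvature (m)
#'   and shot angle (degrees).
#' @return Object of class `psxg_params` (a named numeric vector).
#' @export
psxg_params <- function(gamma0, gamma1, gamma2, gamma3) {
  g <- c(gamma0 = gamma0, gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3)
  if (!is.numeric(g) || length(g) != 4 || !all(is.finite(g))) {
    stop("parameters must be four finite numbers", call. = FALSE)
  }
  structure(g, class = "psxg_params")
}

#' @export
print.psxg_params <- function(x, ...) {
  cat("Sigmoid difficulty parameters (log-odds scale):\n")
  print(unclass(x))
  leg <- legacy_constants(x)
  cat(sprintf("Equivalent 1/(1 + a b^X) constants: a = %.6g, b = exp(-1), ",
              leg$a))
  cat(sprintf("(c, d, e) = (%.6g, %.6g, %.6g), u = 1\n",
              leg$c, leg$d, leg$e))
  invisible(x)
}

#' Classic five-constant form of the canonical parameters
#'
#' @param params A [psxg_params()] object.
#' @return List with elements `a`, `b`, `c`, `d`, `e`, `u` such that
#'   `1 / (1 + a * b^(c*rroc + d*curvature + e*angle))` reproduces the
#'   canonical sigmoid exactly.
#' @export
legacy_constants <- function(params) {
  g <- as.numeric(params)
  list(a = exp(-g[1]), b = exp(-1), c = g[2], d = g[3], e = g[4], u = 1)
}

# Design matrix (intercept + the three features) used by the model layer.
feature_matrix <- function(features) {
  f <- as.data.frame(features)
  miss <- setdiff(feature_names(), names(f))
  if (length(miss) > 0) {
    stop("feature table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cbind(1, as.matrix(f[, feature_names(), drop = FALSE]))
}

#' Score shots with the sigmoid difficulty model
#'
#' @param features Data frame with columns `rroc`, `curvature`, `shot_angle`.
#' @param params A [psxg_params()] object.
#' @return Difficulty scores strictly inside (0, 1), one per row. The
#'   evaluation is overflow-safe for arbitrarily large indices; results are
#'   clamped away from exact 0 and 1 at the representable limits.
#' @export
psxg_score <- function(features, params) {
  X <- feature_matrix(features)
  idx <- as.vector(X %*% as.numeric(params))
  p <- plogis(idx)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Fit the sigmoid difficulty model by Levenberg-Marquardt least squares
#'
#' Minimizes the sum of squared residuals between observed goal proportions
#' and the sigmoid difficulty score, using the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm]) with an analytic Jacobian. The loss is unweighted
#' least squares on proportions; an optional `weights` argument (e.g. play
#' counts) is available but off by default.
#'
#' @param features Feature table (columns `rroc`, `curvature`, `shot_angle`).
#' @param target Goal proportions in `[0, 1]`, one per row.
#' @param init Optional [psxg_params()] starting point. The default starts
#'   at the log-odds of the mean target (clipped to `[0.01, 0.99]`) with
#'   zero slopes, which is deterministic and inside the basin of attraction
#'   for monotone data.
#' @param tol Convergence tolerance on the relative SSE change and gradient
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 10000; the LM backend itself caps
#'   at 1024, far beyond what these fits need).
#' @param weights Optional nonnegative per-row weights.
#' @return Object of class `psxg_fit`: canonical `params`, the equivalent
#'   classic constants, `sse`, `converged`, `n_iterations`, and (for
#'   standardized fits) a `scaler`.
#' @export
fit_psxg <- function(features, target, init = NULL, tol = 1e-8,
                     max_iter = 10000, weights = NULL) {
  X <- feature_matrix(features)
  n <- nrow(X)
  if (n < 10) {
    stop("need at least 10 routines to fit the model", call. = FALSE)
  }
  if (length(target) != n || !all(is.finite(target))) {
    stop("target must be finite with one value per routine", call. = FALSE)
  }
  if (any(target < 0 | target > 1)) {
    stop("target goal proportions must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(init)) {
    m <- min(max(mean(target), 0.01), 0.99)
    start <- c(qlogis(m), 0, 0, 0)
  } else {
    start <- as.numeric(init)
  }
  w <- if (is.null(weights)) rep(1, n) else {
    if (length(weights) != n || any(weights < 0)) {
      stop("weights must be nonnegative, one per routine", call. = FALSE)
    }
    sqrt(weights)
  }
  resid_fn <- function(g) w * (target - plogis(as.vector(X %*% g)))
  jac_fn <- function(g) {
    p <- plogis(as.vector(X %*% g))
    -(w * p * (1 - p)) * X
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(
      ftol = tol, ptol = tol, gtol = tol,
      maxiter = min(max_iter, 1024)))
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("difficulty-model fit did not converge: ", fit$message,
            call. = FALSE)
  }
  r <- resid_fn(fit$par)
  grad <- -2 * as.vector(crossprod(jac_fn(fit$par), r))
  structure(list(
    params = psxg_params(fit$par[1], fit$par[2], fit$par[3], fit$par[4]),
    legacy = legacy_constants(fit$par),
    sse = sum(r^2),
    converged = converged,
    n_iterations = fit$niter,
    gradient_norm = sqrt(sum(grad^2)),
    scaler = NULL,
    n = n,
    weighted = !is.null(weights),
    info = fit$info,
    message = fit$message
  ), class = "psxg_fit")
}

#' @export
print.psxg_fit <- function(x, ...) {
  cat(sprintf("Sigmoid difficulty model fit on %d routines%s\n", x$n,
              if (!is.null(x$scaler)) " (standardized features)" else ""))
  print(x$params)
  cat(sprintf("SSE %.6g | converged: %s (%d iterations)\n",
              x$sse, x$converged, x$n_iterations))
  invisible(x)
}

#' Predict difficulty scores from a fitted model
#'
#' @param object A `psxg_fit`.
#' @param newdata Feature table with columns `rroc`, `curvature`,
#'   `shot_angle` on the original (unscaled) measurement scale; a
#'   standardized fit applies its stored scaler automatically.
#' @param ... Unused.
#' @return Numeric difficulty scores in (0, 1).
#' @export
predict.psxg_fit <- function(object, newdata, ...) {
  f <- as.data.frame(newdata)
  if (!is.null(object$scaler)) {
    for (nm in feature_names()) {
      f[[nm]] <- (f[[nm]] - object$scaler$mean[[nm]]) /
        object$scaler$sd[[nm]]
    }
  }
  psxg_score(f, object$params)
}

#' Stratified fold assignment for a continuous target
#'
#' Adapts stratified k-fold cross-validation to a continuous target by
#' quantile-binning it into strata; each stratum is shuffled under the seed
#' and dealt round-robin across the folds (the deal continues across
#' strata so fold sizes stay balanced).
#'
#' @param target Numeric target values.
#' @param k Number of folds (>= 2).
#' @param n_bins Number of quantile strata (default 5).
#' @param seed Integer seed; the same seed always yields the same folds.
#' @return Integer vector of fold labels in `1:k`, one per observation.
#' @export
stratified_folds <- function(target, k = 5, n_bins = 5, seed = 1) {
  n <- length(target)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k observations", call. = FALSE)
  breaks <- unique(quantile(target, probs = seq(0, 1, length.out = n_bins + 1),
                            type = 7, names = FALSE))
  # findInterval on the unique quantile values keeps equal target values in
  # the same stratum (cut() would collapse a two-valued target into a
  # single interval); values at the maximum form their own small stratum,
  # which the continuous round-robin deal absorbs without unbalancing folds
  bins <- findInterval(target, breaks)
  fold <- integer(n)
  with_seed(seed, {
    counter <- 0L
    for (b in sort(unique(bins))) {
      idx <- which(bins == b)
      idx <- idx[sample.int(length(idx))]
      for (i in idx) {
        fold[i] <- (counter %% k) + 1L
        counter <- counter + 1L
      }
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the difficulty model
#'
#' Refits the model on each training split and reports R-squared and RMSE on
#' both splits, per fold and as mean/sd across folds.
#'
#' @inheritParams stratified_folds
#' @param features Feature table.
#' @param target Goal proportions.
#' @param ... Passed to [fit_psxg()].
#' @return Object of class `psxg_cv` with elements `metrics` (per-fold data
#'   frame), `summary` (means and sds), `fold_assignment`, `k`, `seed`.
#' @export
cross_validate <- function(features, target, k = 5, n_bins = 5, seed = 1,
                           ...) {
  folds <- stratified_folds(target, k = k, n_bins = n_bins, seed = seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_psxg(features[tr, , drop = FALSE], target[tr], ...)
    p_tr <- predict(fit, features[tr, , drop = FALSE])
    p_te <- predict(fit, features[!tr, , drop = FALSE])
    rows[[f]] <- data.frame(
      fold = f,
      train_r2 = r_squared(target[tr], p_tr),
      test_r2 = r_squared(target[!tr], p_te),
      train_rmse = rmse(target[tr], p_tr),
      test_rmse = rmse(target[!tr], p_te))
  }
  metrics <- do.call(rbind, rows)
  summ <- list(
    train_r2_mean = mean(metrics$train_r2),
    train_r2_sd = sd(metrics$train_r2),
    test_r2_mean = mean(metrics$test_r2),
    test_r2_sd = sd(metrics$test_r2),
    train_rmse_mean = mean(metrics$train_rmse),
    train_rmse_sd = sd(metrics$train_rmse),
    test_rmse_mean = mean(metrics$test_rmse),
    test_rmse_sd = sd(metrics$test_rmse))
  structure(list(metrics = metrics, summary = summ,
                 fold_assignment = folds, k = k, seed = seed),
            class = "psxg_cv")
}

#' @export
print.psxg_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%d-fold stratified cross-validation (seed %d)\n", x$k,
              x$seed))
  cat(sprintf("  R^2  : train %.3f (sd %.3f) | test %.3f (sd %.3f)\n",
              s$train_r2_mean, s$train_r2_sd, s$test_r2_mean, s$test_r2_sd))
  cat(sprintf("  RMSE : train %.3f (sd %.4f) | test %.3f (sd %.4f)\n",
              s$train_rmse_mean, s$train_rmse_sd, s$test_rmse_mean,
              s$test_rmse_sd))
  invisible(x)
}

#' Fit the model on standardized features
#'
#' Centers and scales each feature to mean 0, sd 1 before fitting, storing
#' the scaler in the returned model. Fitted values are identical (to
#' optimizer tolerance) to the unscaled fit; the payoff is that coefficient
#' magnitudes become directly comparable across features.
#'
#' @inheritParams fit_psxg
#' @return A `psxg_fit` whose `scaler` records the per-feature mean and sd;
#'   [predict.psxg_fit()] applies it automatically.
#' @export
fit_standardized <- function(features, target, ...) {
  f <- as.data.frame(features)
  mu <- vapply(f[feature_names()], mean, numeric(1))
  sdev <- vapply(f[feature_names()], sd, numeric(1))
  if (any(sdev == 0)) {
    stop("cannot standardize: feature(s) with zero variance: ",
         paste(feature_names()[sdev == 0], collapse = ", "), call. = FALSE)
  }
  for (nm in feature_names()) f[[nm]] <- (f[[nm]] - mu[[nm]]) / sdev[[nm]]
  fit <- fit_psxg(f, target, ...)
  fit$scaler <- list(mean = as.list(mu), sd = as.list(sdev))
  fit
}

#' Feature importance from standardized coefficients
#'
#' Ranks the features by the absolute magnitude of their standardized
#' coefficients; with all features on a common (sd = 1) scale these
#' magnitudes are comparable measures of influence on the log-odds of a
#' goal. Ties are broken by the fixed feature order (rroc, curvature,
#' shot_angle).
#'
#' @param model A `psxg_fit` produced by [fit_standardized()].
#' @return Data frame with columns `feature`, `coefficient`, `magnitude`,
#'   sorted by decreasing magnitude.
#' @export
coefficient_importance <- function(model) {
  if (is.null(model$scaler)) {
    stop("coefficient_importance requires a model fitted on standardized ",
         "features (see fit_standardized)", call. = FALSE)
  }
  g <- as.numeric(model$params)[2:4]
  out <- data.frame(feature = feature_names(), coefficient = g,
                    magnitude = abs(g), stringsAsFactors = FALSE)
  out <- out[order(-out$magnitude, match(out$feature, feature_names())), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Winsorized linear difficulty baseline
#'
#' The simple pre-model baseline: a linear combination of shot speed,
#' curvature and flight duration with hand-chosen weights, winsorized into
#' `[0, 1]` (values above 1 capped at 1; the symmetric cap at 0 is applied
#' for probability semantics).
#'
#' @param speed Shot speed(s), m/s.
#' @param curvature Spin deviation(s), metres.
#' @param flight_duration Flight duration(s), seconds.
#' @param weights Numeric length 4: intercept and the three weights, in the
#'   argument order above. No defaults are provided; the weights are domain
#'   knowledge, not fitted.
#' @return Scores in `[0, 1]`.
#' @export
baseline_difficulty <- function(speed, curvature, flight_duration, weights) {
  if (!is.numeric(weights) || length(weights) != 4) {
    stop("weights must be numeric length 4 (intercept + 3 weights)",
         call. = FALSE)
  }
  score <- weights[1] + weights[2] * speed + weights[3] * curvature +
    weights[4] * flight_duration
  pmin(pmax(score, 0), 1)
}

#' Score every routine with a fitted model
#'
#' Applies a converged model to the full feature table, including routines
#' that the play-count filter excluded from fitting, so every routine gets
#' a difficulty score.
#'
#' @param model A converged `psxg_fit`.
#' @param full_table Feature table for all routines.
#' @return Data frame with `routine_id` (if present) and `psxg` in (0, 1).
#' @export
predict_all <- function(model, full_table) {
  if (!isTRUE(model$converged)) {
    stop("refusing to predict from a non-converged model; refit or pass ",
         "a better starting point", call. = FALSE)
  }
  f <- as.data.frame(full_table)
  if (nrow(f) == 0) {
    return(data.frame(routine_id = character(0), psxg = numeric(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    routine_id = if (!is.null(f$routine_id)) f$routine_id else
      as.character(seq_len(nrow(f))),
    psxg = predict(model, f),
    stringsAsFactors = FALSE)
}

#' Serialize a fitted model to JSON
#'
#' @param model A `psxg_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(
    canonical = as.list(unclass(model$params)),
    classic_constants = model$legacy,
    scaler = model$scaler,
    sse = model$sse,
    converged = model$converged,
    n_iterations = model$n_iterations,
    n = model$n,
    weighted = model$weighted,
    package_version = as.character(utils::packageVersion("psxg")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a serialized model back from JSON
#'
#' @param path Path written by [write_model()].
#' @return A `psxg_fit`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  g <- obj$canonical
  structure(list(
    params = psxg_params(g$gamma0, g$gamma1, g$gamma2, g$gamma3),
    legacy = legacy_constants(c(g$gamma0, g$gamma1, g$gamma2, g$gamma3)),
    sse = obj$sse,
    converged = isTRUE(obj$converged),
    n_iterations = obj$n_iterations,
    scaler = if (is.null(obj$scaler) || length(obj$scaler) == 0) NULL else
      list(mean = as.list(obj$scaler$mean), sd = as.list(obj$scaler$sd)),
    n = obj$n,
    weighted = isTRUE(obj$weighted)
  ), class = "psxg_fit")
}
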