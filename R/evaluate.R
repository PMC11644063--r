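#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; can be negative for predictors worse than the
#' observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2;
#'   `observed` must have nonzero variance.
#' @return R-squared, at most 1.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop("observed and predicted must have equal length >= 2", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("R-squared undefined: observed values have zero variance",
         call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Root mean square error
#'
#' @param observed,predicted Numeric vectors of equal length >= 1.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1) {
    stop("observed and predicted must have equal length >= 1", call. = FALSE)
  }
  sqrt(mean((observed - predicted)^2))
}

#' Residual table for diagnostics
#'
#' @param routine_id Routine identifiers.
#' @param observed Observed goal proportions.
#' @param psxg Model difficulty scores (the predictions).
#' @return Data frame with columns `routine_id`, `observed`, `psxg`,
#'   `residual` (= observed - psxg), suitable for residual-vs-score plots.
#' @export
residual_table <- function(routine_id, observed, psxg) {
  n <- length(routine_id)
  if (length(observed) != n || length(psxg) != n) {
    stop("routine_id, observed and psxg must have equal length",
         call. = FALSE)
  }
  data.frame(routine_id = routine_id, observed = observed, psxg = psxg,
             residual = observed - psxg, stringsAsFactors = FALSE)
}

#' Goal-mouth grid of mean values by shot placement
#'
#' Bins goal-line entry points into an `n_rows` x `n_cols` grid over the
#' goal mouth and averages a value (goal proportion, difficulty score, ...)
#' within each cell. Cells are half-open `[low, high)` with the final
#' row/column closed, so the posts and crossbar belong to the edge cells
#' and every in-mouth point maps to exactly one cell. Cells that no shot
#' entered are absent (`NA`), never zero: an empty cell and a cell of
#' always-saved shots are different things.
#'
#' @param entry_x,entry_y Entry coordinates, metres.
#' @param values Values to average, aligned with the entries.
#' @param geometry A [goal_geometry()].
#' @param n_cols,n_rows Grid resolution (defaults 20 x 16).
#' @return Object of class `goal_mouth_grid` with `cell_values` and
#'   `cell_counts` matrices (row 1 = bottom of the goal), and `n_outside`,
#'   the number of entries outside the mouth (reported, excluded from the
#'   grid).
#' @export
goal_mouth_grid <- function(entry_x, entry_y, values,
                            geometry = goal_geometry(),
                            n_cols = 20, n_rows = 16) {
  n <- length(entry_x)
  if (length(entry_y) != n || length(values) != n) {
    stop("entry coordinates and values must be aligned", call. = FALSE)
  }
  hw <- geometry$width / 2
  h <- geometry$height
  inside <- entry_x >= -hw & entry_x <= hw & entry_y >= 0 & entry_y <= h
  # snap near-integer bin coordinates before flooring so the half-open
  # convention holds at cell boundaries that are not exactly representable
  snap_floor <- function(u) {
    k <- round(u)
    u[abs(u - k) < 1e-9] <- k[abs(u - k) < 1e-9]
    floor(u)
  }
  col <- snap_floor((entry_x + hw) / geometry$width * n_cols) + 1L
  row <- snap_floor(entry_y / h * n_rows) + 1L
  col[inside & col > n_cols] <- n_cols  # x exactly at the far post
  row[inside & row > n_rows] <- n_rows  # y exactly at the crossbar
  cell_values <- matrix(NA_real_, nrow = n_rows, ncol = n_cols)
  cell_counts <- matrix(0L, nrow = n_rows, ncol = n_cols)
  if (any(inside)) {
    idx <- cbind(row[inside], col[inside])
    key <- (idx[, 2] - 1L) * n_rows + idx[, 1]
    sums <- rowsum(values[inside], key)
    cnts <- rowsum(rep(1L, sum(inside)), key)
    at <- as.integer(rownames(sums))
    cell_values[at] <- sums / cnts
    cell_counts[at] <- as.integer(cnts)
  }
  structure(list(cell_values = cell_values, cell_counts = cell_counts,
                 n_outside = sum(!inside), geometry = geometry,
                 n_cols = n_cols, n_rows = n_rows),
            class = "goal_mouth_grid")
}

#' @export
print.goal_mouth_grid <- function(x, ...) {
  cat(sprintf(
    "Goal-mouth grid %d x %d: %d entries in %d occupied cell(s), %d outside\n",
    x$n_rows, x$n_cols, sum(x$cell_counts), sum(x$cell_counts > 0),
    x$n_outside))
  invisible(x)
}

#' Export a goal-mouth grid as a CSV matrix
#'
#' Rows run top-to-bottom (high to low y, as the goal is viewed); empty
#' cells are written as empty fields, not zeros.
#'
#' @param grid A [goal_mouth_grid()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_goal_mouth_grid <- function(grid, path) {
  m <- grid$cell_values[grid$n_rows:1, , drop = FALSE]
  xmid <- (seq_len(grid$n_cols) - 0.5) / grid$n_cols * grid$geometry$width -
    grid$geometry$width / 2
  ymid <- (seq(grid$n_rows, 1) - 0.5) / grid$n_rows * grid$geometry$height
  dimnames(m) <- list(sprintf("y=%.3f", ymid), sprintf("x=%.3f", xmid))
  utils::write.csv(m, path, na = "")
  invisible(path)
}

#' Plot a goal-mouth grid heatmap
#'
#' @param x A [goal_mouth_grid()].
#' @param main Plot title.
#' @param empty_col Colour for cells no shot entered (distinct from the
#'   value scale).
#' @param ... Passed to [graphics::image()].
#' @export
plot.goal_mouth_grid <- function(x, main = "Goal-mouth heatmap",
                                 empty_col = "grey85", ...) {
  hw <- x$geometry$width / 2
  xb <- seq(-hw, hw, length.out = x$n_cols + 1)
  yb <- seq(0, x$geometry$height, length.out = x$n_rows + 1)
  graphics::image(xb, yb, matrix(0, x$n_cols, x$n_rows), col = empty_col,
                  xlab = "x (m)", ylab = "y (m)", main = main, useRaster = FALSE)
  graphics::image(xb, yb, t(x$cell_values),
                  col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  add = TRUE, ...)
  graphics::box()
  invisible(x)
}

#' Score a goalkeeping session as expected vs. actual goals conceded
#'
#' The expected number of goals conceded over a session is the sum of the
#' difficulty scores of the shots faced (equivalently mean score x number of
#' shots); e.g. a 10-shot session with mean score 0.58 carries 5.8 expected
#' goals. The skill differential is expected minus actual conceded, so a
#' larger value means the player saved more than the shot difficulty
#' predicted.
#'
#' @param psxg_values Difficulty scores of the shots faced, in (0, 1).
#' @param conceded_flags Logical, `TRUE` where a goal was conceded.
#' @return Object of class `session_score` with `n_shots`, `mean_psxg`,
#'   `expected_conceded`, `actual_conceded`, `skill_differential`.
#' @export
session_score <- function(psxg_values, conceded_flags) {
  n <- length(psxg_values)
  if (n < 1 || length(conceded_flags) != n) {
    stop("need aligned non-empty score and outcome sequences", call. = FALSE)
  }
  if (any(!is.finite(psxg_values)) || any(psxg_values < 0 | psxg_values > 1)) {
    stop("difficulty scores must lie in [0, 1]", call. = FALSE)
  }
  expected <- sum(psxg_values)
  actual <- sum(as.logical(conceded_flags))
  structure(list(n_shots = n,
                 mean_psxg = mean(psxg_values),
                 expected_conceded = expected,
                 actual_conceded = as.integer(actual),
                 skill_differential = expected - actual),
            class = "session_score")
}

#' @export
print.session_score <- function(x, ...) {
  cat(sprintf(
    "Session of %d shots: expected %.2f conceded (mean difficulty %.3f), actual %d -> skill differential %+.2f\n",
    x$n_shots, x$expected_conceded, x$mean_psxg, x$actual_conceded,
    x$skill_differential))
  invisible(x)
}

#' Correlation between difficulty scores and observed concede proportions
#'
#' The model-validation statistic: Pearson correlation between predicted
#' difficulty and the proportion of goals actually conceded on the same
#' shots.
#'
#' @param psxg Difficulty scores.
#' @param goal_proportions Observed concede proportions, aligned.
#' @return The Pearson correlation (see [pearson_r()]).
#' @export
validation_correlation <- function(psxg, goal_proportions) {
  pearson_r(psxg, goal_proportions)
}
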