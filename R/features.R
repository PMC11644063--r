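#' Goal-mouth geometry
#'
#' Dimensions of the goal face and the reference point used as the "centre"
#' for gap-closure distances. The default is the full-size goal (7.32 m wide,
#' 2.44 m high) with the reference at x = 0, y = 1 m: the midriff height of
#' the mostly junior player base. Prior work on professional goalkeepers used
#' y = 1.3 m; pass `center = c(0, 1.3)` for that variant.
#'
#' @param width Goal width in metres.
#' @param height Goal height in metres.
#' @param center Length-2 numeric, the (x, y) gap reference point.
#' @return An object of class `goal_geometry`.
#' @export
goal_geometry <- function(width = 7.32, height = 2.44, center = c(0, 1)) {
  if (!is.numeric(width) || width <= 0 || !is.numeric(height) || height <= 0) {
    stop("goal width and height must be positive", call. = FALSE)
  }
  if (!is.numeric(center) || length(center) != 2 || !all(is.finite(center))) {
    stop("center must be a finite (x, y) pair", call. = FALSE)
  }
  if (center[2] < 0 || center[2] > height) {
    stop("center y must lie within [0, height]", call. = FALSE)
  }
  structure(list(width = width, height = height, center = as.numeric(center)),
            class = "goal_geometry")
}

#' @export
print.goal_geometry <- function(x, ...) {
  cat(sprintf("Goal mouth %.2f m x %.2f m, gap reference (%.2f, %.2f)\n",
              x$width, x$height, x$center[1], x$center[2]))
  invisible(x)
}

#' Euclidean distance from the goal-centre reference
#'
#' The size of the gap a goalkeeper's hand must close: the straight-line
#' distance from the reference point (default x = 0, y = 1) to the point
#' where the ball crosses the goal line.
#'
#' @param entry_x,entry_y Goal-line crossing coordinates (metres); vectorised.
#' @param geometry A [goal_geometry()].
#' @return Distances in metres.
#' @export
entry_distance_from_center <- function(entry_x, entry_y,
                                       geometry = goal_geometry()) {
  if (!all(is.finite(entry_x)) || !all(is.finite(entry_y))) {
    stop("entry coordinates must be finite", call. = FALSE)
  }
  sqrt((entry_x - geometry$center[1])^2 + (entry_y - geometry$center[2])^2)
}

#' Required rate of closure (RROC)
#'
#' Tau theory describes interception through the time-to-closure of a gap,
#' tau = gap / (rate of gap closure). For a goalkeeper the available time is
#' fixed by the ball's flight duration, so the roles invert: the *required*
#' rate of closure is the average hand speed needed to close the gap before
#' the ball arrives,
#' \deqn{RROC = \mathrm{distance\ from\ centre} / \tau,}
#' with tau the flight duration.
#'
#' @param distance Gap distance in metres (>= 0); vectorised.
#' @param flight_duration Flight duration in seconds (> 0); vectorised.
#' @return RROC in m/s.
#' @export
required_rate_of_closure <- function(distance, flight_duration) {
  if (!all(is.finite(flight_duration)) || any(flight_duration <= 0)) {
    stop("flight_duration must be > 0 (corrupt flight metadata?)",
         call. = FALSE)
  }
  if (!all(is.finite(distance)) || any(distance < 0)) {
    stop("distance must be finite and >= 0", call. = FALSE)
  }
  distance / flight_duration
}

#' Spin-free lateral entry coordinate
#'
#' Where the ball would cross the goal line if it carried no spin. Gravity
#' acts only vertically and spin is the sole lateral force, so the spin-free
#' lateral motion is uniform:
#' `x(T) = launch_x + vx * T`, with `T` the recorded flight duration (the
#' authoritative time of goal-line crossing).
#'
#' @param flights Ball-flight data frame (columns `launch_x`, `vx`,
#'   `flight_duration`).
#' @return Lateral coordinates (metres) at the goal line, one per flight.
#' @export
spin_free_entry_x <- function(flights) {
  flights$launch_x + flights$vx * flights$flight_duration
}

#' Spin-induced lateral deviation ("curvature")
#'
#' Lateral displacement at the goal line between where the ball actually
#' crossed and where the spin-free projection says it would have crossed.
#' Difficulty rises with the magnitude of the bend regardless of direction,
#' so the magnitude is the model feature; the signed value is available for
#' diagnostics.
#'
#' @param actual_entry_x Observed goal-line x coordinate(s), metres.
#' @param spin_free_x Spin-free projection from [spin_free_entry_x()].
#' @param signed If `TRUE`, return the signed difference
#'   `actual - spin_free` instead of the magnitude.
#' @return Deviation in metres.
#' @export
spin_deviation <- function(actual_entry_x, spin_free_x, signed = FALSE) {
  if (!all(is.finite(actual_entry_x)) || !all(is.finite(spin_free_x))) {
    stop("entry coordinates must be finite", call. = FALSE)
  }
  d <- actual_entry_x - spin_free_x
  if (signed) d else abs(d)
}

#' Lateral shot angle
#'
#' Angle between the goal-centre axis and the shot's origin on the pitch:
#' 0 degrees from straight in front of goal (e.g. the penalty spot) and 90
#' degrees from the goal line itself (e.g. the corner flag).
#'
#' @param launch_x Lateral launch coordinate(s), metres.
#' @param launch_z Distance(s) from the goal line, metres (>= 0).
#' @return Angle(s) in degrees, in `[0, 90]` for `launch_z >= 0`.
#' @export
shot_angle <- function(launch_x, launch_z) {
  if (any(launch_x == 0 & launch_z == 0)) {
    stop("shot angle undefined for a launch at the goal-mouth centre ",
         "(x = 0, z = 0)", call. = FALSE)
  }
  atan2(abs(launch_x), launch_z) * 180 / pi
}

# Feature columns shared by the whole model layer, in canonical order.
feature_names <- function() c("rroc", "curvature", "shot_angle")

#' Compute model features from ball flights
#'
#' @param flights Ball-flight data frame (see [read_ball_flights()]).
#' @param geometry A [goal_geometry()].
#' @return Data frame with `routine_id`, `rroc` (m/s), `curvature` (m,
#'   magnitude), `curvature_signed` (m) and `shot_angle` (degrees).
#' @export
compute_features <- function(flights, geometry = goal_geometry()) {
  bad <- which(!is.finite(flights$flight_duration) |
                 flights$flight_duration <= 0)
  if (length(bad) > 0) {
    stop("invalid flight_duration for routine(s): ",
         paste(flights$routine_id[bad], collapse = ", "), call. = FALSE)
  }
  bad <- which(flights$launch_x == 0 & flights$launch_z == 0)
  if (length(bad) > 0) {
    stop("undefined shot angle for routine(s): ",
         paste(flights$routine_id[bad], collapse = ", "), call. = FALSE)
  }
  gap <- entry_distance_from_center(flights$entry_x, flights$entry_y,
                                    geometry)
  sf <- spin_free_entry_x(flights)
  data.frame(
    routine_id = flights$routine_id,
    rroc = required_rate_of_closure(gap, flights$flight_duration),
    curvature = spin_deviation(flights$entry_x, sf),
    curvature_signed = spin_deviation(flights$entry_x, sf, signed = TRUE),
    shot_angle = shot_angle(flights$launch_x, flights$launch_z),
    stringsAsFactors = FALSE
  )
}

#' Build the modelling feature table
#'
#' Composes the three model features for every routine in a joined analysis
#' table and carries the goal proportion and play count through unchanged.
#'
#' @param table Analysis table from [join_flights_outcomes()].
#' @param geometry A [goal_geometry()].
#' @return Data frame with columns `routine_id`, `rroc`, `curvature`,
#'   `curvature_signed`, `shot_angle`, `goal_proportion`, `n_plays`.
#' @export
build_feature_table <- function(table, geometry = goal_geometry()) {
  if (nrow(table) == 0) {
    stop("analysis table is empty", call. = FALSE)
  }
  if (is.null(table$goal_proportion)) {
    stop("analysis table lacks goal_proportion; join outcomes first",
         call. = FALSE)
  }
  feats <- compute_features(table, geometry)
  feats$goal_proportion <- table$goal_proportion
  feats$n_plays <- table$n_plays
  feats
}

#' Flag IQR outliers
#'
#' Flags values outside `[Q1 - k*IQR, Q3 + k*IQR]` with quartiles computed by
#' linear interpolation (the usual type-7 quantile) and k = 1.5. Flagged
#' values are only reported, never removed: extreme shots are deliberately
#' part of the difficulty range.
#'
#' @param values Numeric vector, length >= 4.
#' @param multiplier Fence multiplier, default 1.5.
#' @return Logical vector, `TRUE` where the value lies outside the fences.
#' @export
iqr_outlier_flags <- function(values, multiplier = 1.5) {
  if (length(values) < 4) {
    stop("need at least 4 values to assess IQR outliers", call. = FALSE)
  }
  q <- quantile(values, probs = c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values < q[1] - multiplier * iqr | values > q[2] + multiplier * iqr
}

#' Pearson correlation with validity checks
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Sample Pearson product-moment correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  cor(x, y)
}

#' OLS significance screen of the features
#'
#' Fits an ordinary least-squares regression of the goal proportion on the
#' three features and reports each coefficient with its two-sided t-test
#' p-value. Used only as a screen for whether each feature carries signal;
#' it never transforms the data.
#'
#' @param features Data frame containing columns `rroc`, `curvature` and
#'   `shot_angle` (extra columns are ignored).
#' @param target Numeric goal proportions, one per row.
#' @return Data frame with columns `feature`, `coefficient`, `p_value`; the
#'   intercept estimate is attached as attribute `"intercept"`.
#' @export
ols_screen <- function(features, target) {
  X <- as.data.frame(features[, feature_names(), drop = FALSE])
  if (nrow(X) <= ncol(X) + 1) {
    stop("need more rows than features + 1 for the OLS screen",
         call. = FALSE)
  }
  dat <- cbind(X, .target = target)
  fit <- lm(.target ~ ., data = dat)
  if (anyNA(coef(fit))) {
    stop("collinear (rank-deficient) feature matrix in OLS screen",
         call. = FALSE)
  }
  tab <- summary(fit)$coefficients
  out <- data.frame(
    feature = feature_names(),
    coefficient = tab[feature_names(), "Estimate"],
    p_value = tab[feature_names(), "Pr(>|t|)"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "intercept") <- unname(tab["(Intercept)", "Estimate"])
  out
}
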