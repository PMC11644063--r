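#' Configuration for the synthetic shot generator
#'
#' Defines the generative scenario: how many routines, how often each is
#' played, the ground-truth difficulty parameters, and the physical ranges
#' of the simulated shots. The defaults describe the study conditions the
#' package is tested under: 600 routines played 200 times each, entry
#' points spanning the goal mouth with a corner-heavy tail, flight
#' durations of 0.4-1.2 s, spin deviations of a few decimetres, and true
#' parameters `(-3, 0.9, 0.8, -0.02)` chosen so that the standardized RROC
#' weight dominates the other two features roughly five-fold.
#'
#' @param n_routines Number of routines to generate.
#' @param plays_per_routine Plays per routine: a scalar, or a vector with
#'   one count per routine (see [sample_plays_longtail()] for a realistic
#'   long-tailed distribution).
#' @param true_params Ground-truth [psxg_params()] driving the outcomes.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param geometry A [goal_geometry()].
#' @param duration_range Flight-duration range in seconds; must lie within
#'   the physically sane (0.2, 2] s.
#' @param launch_z_range Launch distance from the goal line, metres.
#' @param launch_x_sd,launch_x_max Lateral launch spread (truncated normal).
#' @param entry_sd Length-2: sd of the central entry cluster in x and y.
#' @param corner_prob Probability a shot is aimed at the corner-heavy tail.
#' @param spin_sd Sd of the signed spin-induced lateral deviation, metres.
#' @param overdispersion Beta-binomial overdispersion rho in `[0, 1)`; 0
#'   (default) gives pure binomial play outcomes, larger values emulate
#'   unmodelled player heterogeneity.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_routines = 600,
                             plays_per_routine = 200,
                             true_params = psxg_params(-3, 0.9, 0.8, -0.02),
                             seed = 1,
                             geometry = goal_geometry(),
                             duration_range = c(0.4, 1.2),
                             launch_z_range = c(6, 20),
                             launch_x_sd = 6,
                             launch_x_max = 20,
                             entry_sd = c(1.5, 0.6),
                             corner_prob = 0.4,
                             spin_sd = 0.3,
                             overdispersion = 0) {
  if (n_routines < 1) stop("n_routines must be >= 1", call. = FALSE)
  if (any(plays_per_routine < 1)) {
    stop("plays_per_routine must be >= 1", call. = FALSE)
  }
  if (!(length(plays_per_routine) %in% c(1L, n_routines))) {
    stop("plays_per_routine must be a scalar or length n_routines",
         call. = FALSE)
  }
  if (length(duration_range) != 2 || duration_range[1] <= 0.2 ||
      duration_range[2] > 2 || duration_range[1] >= duration_range[2]) {
    stop("duration_range must be increasing and lie within (0.2, 2] s",
         call. = FALSE)
  }
  if (length(launch_z_range) != 2 || launch_z_range[1] <= 0 ||
      launch_z_range[1] >= launch_z_range[2]) {
    stop("launch_z_range must be increasing and positive", call. = FALSE)
  }
  if (overdispersion < 0 || overdispersion >= 1) {
    stop("overdispersion must lie in [0, 1)", call. = FALSE)
  }
  structure(list(
    n_routines = as.integer(n_routines),
    plays_per_routine = plays_per_routine,
    true_params = true_params,
    seed = as.integer(seed),
    geometry = geometry,
    duration_range = duration_range,
    launch_z_range = launch_z_range,
    launch_x_sd = launch_x_sd,
    launch_x_max = launch_x_max,
    entry_sd = entry_sd,
    corner_prob = corner_prob,
    spin_sd = spin_sd,
    overdispersion = overdispersion
  ), class = "generator_config")
}

#' Generate physically consistent synthetic ball flights
#'
#' Samples routines whose launch point, initial velocity, entry point,
#' flight duration and spin deviation are mutually consistent: the lateral
#' velocity is set so the spin-free projection `launch_x + vx * T` lands at
#' `entry_x` minus the sampled signed spin deviation; the vertical velocity
#' satisfies the ballistic relation under gravity (9.81 m/s^2); and the
#' closing velocity covers the launch distance in exactly the flight
#' duration. Entry points are a mixture of a central cluster around the
#' gap reference and a corner-heavy tail, so difficulty spans the full
#' range.
#'
#' @param config A [generator_config()].
#' @return Ball-flight data frame in the [read_ball_flights()] layout.
#' @export
generate_routines <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_routines
  geom <- config$geometry
  hw <- geom$width / 2
  h <- geom$height
  with_seed(config$seed, {
    corner <- runif(n) < config$corner_prob
    # central cluster around the gap reference
    ex <- rtrunc_norm(n, geom$center[1], config$entry_sd[1],
                      -hw + 1e-3, hw - 1e-3)
    ey <- rtrunc_norm(n, geom$center[2], config$entry_sd[2], 1e-3, h - 1e-3)
    # corner-heavy tail: wide x, low or high y
    n_c <- sum(corner)
    if (n_c > 0) {
      side <- sample(c(-1, 1), n_c, replace = TRUE)
      ex[corner] <- side * runif(n_c, 0.6 * hw, hw - 1e-3)
      high <- runif(n_c) < 0.5
      ey_c <- numeric(n_c)
      ey_c[high] <- runif(sum(high), h - 0.8, h - 1e-3)
      ey_c[!high] <- runif(sum(!high), 1e-3, 0.6)
      ey[corner] <- ey_c
    }
    dur <- runif(n, config$duration_range[1], config$duration_range[2])
    lz <- runif(n, config$launch_z_range[1], config$launch_z_range[2])
    lx <- rtrunc_norm(n, 0, config$launch_x_sd,
                      -config$launch_x_max, config$launch_x_max)
    ly <- runif(n, 0, 0.5)
    dev <- rnorm(n, 0, config$spin_sd)
    spin_free_x <- ex - dev
    vx <- (spin_free_x - lx) / dur
    vy <- (ey - ly) / dur + 0.5 * 9.81 * dur
    vz <- -lz / dur
    # angular velocity is metadata: backspin/sidespin loosely tied to the
    # lateral deviation, the rest small noise
    wy <- dev * 10 / dur
    wx <- rnorm(n, 0, 2)
    wz <- rnorm(n, 0, 0.5)
    data.frame(
      routine_id = sprintf("R%04d", seq_len(n)),
      launch_x = lx, launch_y = ly, launch_z = lz,
      vx = vx, vy = vy, vz = vz,
      entry_x = ex, entry_y = ey,
      flight_duration = dur,
      wx = wx, wy = wy, wz = wz,
      stringsAsFactors = FALSE)
  })
}

#' Simulate play outcomes from a known difficulty model
#'
#' For each routine, draws independent Bernoulli plays with concede
#' probability given by the ground-truth sigmoid model evaluated on that
#' routine's features. With `overdispersion > 0` each play's probability is
#' first drawn from a Beta distribution with the model probability as its
#' mean, emulating unmodelled heterogeneity between players.
#'
#' @param flights Ball-flight data frame.
#' @param true_params Ground-truth [psxg_params()].
#' @param plays Plays per routine: scalar or one count per routine.
#' @param seed Integer seed (independent of the flight-generation seed, so
#'   changing it never alters the flights).
#' @param geometry A [goal_geometry()].
#' @param overdispersion Beta-binomial rho in `[0, 1)`; default 0.
#' @return Outcome data frame in the [read_user_outcomes()] layout.
#' @export
simulate_outcomes <- function(flights, true_params, plays = 200, seed = 1,
                              geometry = goal_geometry(),
                              overdispersion = 0) {
  n <- nrow(flights)
  plays <- if (length(plays) == 1) rep(as.integer(plays), n) else
    as.integer(plays)
  if (length(plays) != n || any(plays < 1)) {
    stop("plays must be a scalar or one positive count per routine",
         call. = FALSE)
  }
  feats <- compute_features(flights, geometry)
  p <- psxg_score(feats, true_params)
  total <- sum(plays)
  p_rep <- rep(p, plays)
  conceded <- with_seed(seed, {
    if (overdispersion > 0) {
      s <- (1 - overdispersion) / overdispersion
      p_play <- rbeta(total, p_rep * s, (1 - p_rep) * s)
      runif(total) < p_play
    } else {
      runif(total) < p_rep
    }
  })
  data.frame(
    routine_id = rep(flights$routine_id, plays),
    conceded = conceded,
    play_id = paste0(rep(flights$routine_id, plays), "_p",
                     formatC(sequence(plays), width = 6, flag = "0")),
    stringsAsFactors = FALSE)
}

#' Simulate a cohort of players with distinct skill levels
#'
#' Each player's concede probability is the ground-truth difficulty shifted
#' on the log-odds scale by a per-player offset: negative offsets are more
#' skilled players, who concede less at every difficulty level. This is the
#' synthetic counterpart of a human validation cohort and is used to test
#' that the session skill differential recovers the true skill ordering.
#'
#' @param flights Ball-flight data frame (the validation shot set).
#' @param true_params Ground-truth [psxg_params()].
#' @param skill_offsets Named (or unnamed) numeric vector of per-player
#'   log-odds shifts.
#' @param plays Plays per routine per player.
#' @param seed Integer seed.
#' @param geometry A [goal_geometry()].
#' @return Named list of outcome data frames, one per player.
#' @export
simulate_skill_cohort <- function(flights, true_params, skill_offsets,
                                  plays = 30, seed = 1,
                                  geometry = goal_geometry()) {
  if (!all(is.finite(skill_offsets))) {
    stop("skill offsets must be finite", call. = FALSE)
  }
  nm <- names(skill_offsets)
  if (is.null(nm)) nm <- sprintf("player%d", seq_along(skill_offsets))
  feats <- compute_features(flights, geometry)
  p <- psxg_score(feats, true_params)
  lo <- qlogis(p)
  out <- vector("list", length(skill_offsets))
  names(out) <- nm
  for (k in seq_along(skill_offsets)) {
    p_k <- plogis(lo + skill_offsets[k])
    out[[k]] <- simulate_outcomes_from_p(flights$routine_id, p_k, plays,
                                         seed = seed + k)
  }
  out
}

# Bernoulli outcomes for given per-routine probabilities (internal).
simulate_outcomes_from_p <- function(routine_id, p, plays, seed) {
  n <- length(routine_id)
  plays <- if (length(plays) == 1) rep(as.integer(plays), n) else
    as.integer(plays)
  p_rep <- rep(p, plays)
  conceded <- with_seed(seed, runif(length(p_rep)) < p_rep)
  data.frame(
    routine_id = rep(routine_id, plays),
    conceded = conceded,
    play_id = paste0(rep(routine_id, plays), "_p",
                     formatC(sequence(plays), width = 6, flag = "0")),
    stringsAsFactors = FALSE)
}

#' Long-tailed plays-per-routine counts
#'
#' Real play logs are heavily long-tailed: a few routines are played tens
#' of thousands of times while many barely clear a hundred. This samples
#' log-normal counts (median about 250 plays) clipped to `[10, 50000]`.
#' Draws come from the current RNG state; wrap in a seed if determinism is
#' needed.
#'
#' @param n Number of routines.
#' @param meanlog,sdlog Log-normal parameters.
#' @param min,max Clipping bounds.
#' @return Integer vector of play counts.
#' @export
sample_plays_longtail <- function(n, meanlog = log(250), sdlog = 1.2,
                                  min = 10, max = 50000) {
  as.integer(round(pmin(pmax(rlnorm(n, meanlog, sdlog), min), max)))
}

#' Write a synthetic fixture to disk
#'
#' Writes `flights.json` and `outcomes.csv` exactly matching the ingest
#' interfaces ([read_ball_flights()], [read_user_outcomes()]), plus
#' `truth.json` with the ground-truth parameters when provided. Reading the
#' files back round-trips to the input collections.
#'
#' @param flights Ball-flight data frame.
#' @param outcomes Outcome data frame.
#' @param directory Output directory (created if needed).
#' @param true_params Optional ground-truth [psxg_params()] to record.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(flights, outcomes, directory, true_params = NULL) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop("cannot create fixture directory: ", directory, call. = FALSE)
  }
  fj <- file.path(directory, "flights.json")
  oc <- file.path(directory, "outcomes.csv")
  objs <- lapply(seq_len(nrow(flights)), function(i) {
    r <- flights[i, ]
    list(routine_id = r$routine_id,
         launch = c(r$launch_x, r$launch_y, r$launch_z),
         velocity0 = c(r$vx, r$vy, r$vz),
         entry = c(r$entry_x, r$entry_y),
         flight_duration = r$flight_duration,
         angular_velocity = c(r$wx, r$wy, r$wz))
  })
  jsonlite::write_json(objs, fj, auto_unbox = TRUE, digits = NA)
  oc_df <- data.frame(routine_id = outcomes$routine_id,
                      conceded = as.integer(outcomes$conceded),
                      play_id = outcomes$play_id,
                      stringsAsFactors = FALSE)
  utils::write.csv(oc_df, oc, row.names = FALSE, quote = FALSE)
  paths <- c(flights = fj, outcomes = oc)
  if (!is.null(true_params)) {
    tj <- file.path(directory, "truth.json")
    jsonlite::write_json(
      list(canonical = as.list(unclass(true_params)),
           classic_constants = legacy_constants(true_params),
           synthetic = TRUE),
      tj, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, truth = tj)
  }
  invisible(paths)
}
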