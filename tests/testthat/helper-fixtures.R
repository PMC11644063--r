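# Shared fixture builders. Everything is generated in code at test time.

# A tiny hand-specified flight table with known geometry.
make_flights_df <- function() {
  data.frame(
    routine_id = c("R1", "R2", "R3"),
    launch_x = c(0, 2, -6),
    launch_y = c(0.2, 0.1, 0.3),
    launch_z = c(11, 14, 9),
    vx = c(0.5, -1.5, 4),
    vy = c(4, 5, 3),
    vz = c(-16, -20, -12),
    entry_x = c(0.7, 0.3, -2.5),
    entry_y = c(1.4, 0.6, 2.0),
    flight_duration = c(0.7, 0.8, 0.75),
    wx = c(0, 1, -1), wy = c(5, -8, 2), wz = c(0, 0.2, 0),
    stringsAsFactors = FALSE)
}

# Write a list of routine objects as ball-flight JSON, independent of the
# package's own fixture writer.
write_flight_json <- function(objs, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  path
}

flight_obj <- function(id, launch = c(0, 0.2, 11), velocity0 = c(0.5, 4, -16),
                       entry = c(0.7, 1.4), flight_duration = 0.7,
                       angular_velocity = c(0, 5, 0)) {
  list(routine_id = id, launch = launch, velocity0 = velocity0,
       entry = entry, flight_duration = flight_duration,
       angular_velocity = angular_velocity)
}

write_outcome_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("routine_id,conceded,play_id", lines), path)
  path
}

# Default study-condition scenario used across model-level tests.
default_scenario <- function(seed, n_routines = 600, plays = 200,
                             outcome_seed = seed + 5000L) {
  cfg <- generator_config(n_routines = n_routines,
                          plays_per_routine = plays, seed = seed)
  flights <- generate_routines(cfg)
  outcomes <- simulate_outcomes(flights, cfg$true_params, plays = plays,
                                seed = outcome_seed)
  summaries <- summarize_routines(outcomes)
  table <- suppressMessages(join_flights_outcomes(flights, summaries))
  feats <- build_feature_table(table)
  list(config = cfg, flights = flights, outcomes = outcomes,
       features = feats)
}

# Forward-Euler integration of the lateral equation of motion with a zero
# lateral force: an independent numerical route to the spin-free entry x.
integrate_lateral <- function(x0, vx, duration, dt = 1e-4,
                              lateral_accel = function(t) 0) {
  t <- 0
  x <- x0
  v <- vx
  while (t < duration - 1e-12) {
    h <- min(dt, duration - t)
    x <- x + v * h
    v <- v + lateral_accel(t) * h
    t <- t + h
  }
  x
}
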