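#' Read ball-flight metadata from JSON
#'
#' Parses a JSON array of routine objects into a ball-flight table. Each
#' object must carry the keys `routine_id` (string), `launch` (x, y, z in
#' metres; z is the distance from the goal line), `velocity0` (initial
#' velocity in m/s), `entry` (x, y where the ball crosses the goal line at
#' z = 0), `flight_duration` (seconds) and `angular_velocity` (rad/s,
#' carried as metadata but unused by the difficulty features).
#'
#' @param path Path to the JSON file (a top-level array of routine objects).
#' @return A data frame with one row per routine and columns `routine_id`,
#'   `launch_x`, `launch_y`, `launch_z`, `vx`, `vy`, `vz`, `entry_x`,
#'   `entry_y`, `flight_duration`, `wx`, `wy`, `wz`. Units are preserved
#'   as read (SI).
#' @details Validation is strict: a missing or malformed key raises a schema
#'   error naming the routine and key, a duplicated `routine_id` is a hard
#'   error (routines define the analysis units), and non-positive flight
#'   durations, non-positive launch distances or below-ground entry heights
#'   are rejected.
#' @seealso [read_user_outcomes()], [join_flights_outcomes()]
#' @export
read_ball_flights <- function(path) {
  if (!file.exists(path)) {
    stop("ball-flight file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw)) {
    stop("ball-flight JSON must be a top-level array of routine objects",
         call. = FALSE)
  }
  if (length(raw) == 0) {
    return(empty_flights())
  }
  required <- c("routine_id", "launch", "velocity0", "entry",
                "flight_duration", "angular_velocity")
  lengths_req <- c(launch = 3L, velocity0 = 3L, entry = 2L,
                   angular_velocity = 3L)
  rows <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    obj <- raw[[i]]
    id <- if (!is.null(obj$routine_id)) as.character(obj$routine_id) else
      sprintf("<entry %d>", i)
    miss <- setdiff(required, names(obj))
    if (length(miss) > 0) {
      stop(sprintf("routine %s: missing key(s) %s", id,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    for (key in names(lengths_req)) {
      v <- unlist(obj[[key]])
      if (length(v) != lengths_req[[key]] || !is.numeric(v)) {
        stop(sprintf("routine %s: key '%s' must be a numeric %d-vector",
                     id, key, lengths_req[[key]]), call. = FALSE)
      }
    }
    dur <- unlist(obj$flight_duration)
    if (length(dur) != 1 || !is.numeric(dur)) {
      stop(sprintf("routine %s: key 'flight_duration' must be a number", id),
           call. = FALSE)
    }
    launch <- as.numeric(unlist(obj$launch))
    vel <- as.numeric(unlist(obj$velocity0))
    entry <- as.numeric(unlist(obj$entry))
    w <- as.numeric(unlist(obj$angular_velocity))
    rows[[i]] <- data.frame(
      routine_id = as.character(obj$routine_id),
      launch_x = launch[1], launch_y = launch[2], launch_z = launch[3],
      vx = vel[1], vy = vel[2], vz = vel[3],
      entry_x = entry[1], entry_y = entry[2],
      flight_duration = as.numeric(dur),
      wx = w[1], wy = w[2], wz = w[3],
      stringsAsFactors = FALSE
    )
  }
  flights <- do.call(rbind, rows)
  dup <- flights$routine_id[duplicated(flights$routine_id)]
  if (length(dup) > 0) {
    stop("duplicate routine_id in ball-flight file: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  validate_flights(flights)
  flights
}

empty_flights <- function() {
  data.frame(routine_id = character(0),
             launch_x = numeric(0), launch_y = numeric(0),
             launch_z = numeric(0),
             vx = numeric(0), vy = numeric(0), vz = numeric(0),
             entry_x = numeric(0), entry_y = numeric(0),
             flight_duration = numeric(0),
             wx = numeric(0), wy = numeric(0), wz = numeric(0),
             stringsAsFactors = FALSE)
}

validate_flights <- function(flights) {
  bad <- which(!is.finite(flights$flight_duration) |
                 flights$flight_duration <= 0)
  if (length(bad) > 0) {
    stop("non-positive flight_duration for routine(s): ",
         paste(flights$routine_id[bad], collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(flights$launch_z) | flights$launch_z <= 0)
  if (length(bad) > 0) {
    stop("launch distance from goal line (launch z) must be > 0 for ",
         "routine(s): ", paste(flights$routine_id[bad], collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(flights$entry_y) | flights$entry_y < 0)
  if (length(bad) > 0) {
    stop("entry height (entry y) must be >= 0 for routine(s): ",
         paste(flights$routine_id[bad], collapse = ", "), call. = FALSE)
  }
  invisible(flights)
}

#' Read per-shot user outcomes from CSV
#'
#' Reads a log of individual plays: one row per attempt at a routine, with a
#' flag recording whether the shot was conceded (goal) or saved.
#'
#' @param path Path to a UTF-8 CSV with header columns `routine_id`,
#'   `conceded`, `play_id`. `conceded` accepts `0`, `1`, `true` or `false`
#'   (case-insensitive).
#' @return Data frame with columns `routine_id` (character), `conceded`
#'   (logical; `TRUE` = goal) and `play_id` (character). A header-only file
#'   yields an empty (zero-row) data frame.
#' @details An unparseable `conceded` token is a row-level error citing the
#'   file line; duplicated (`routine_id`, `play_id`) pairs are kept but
#'   reported with a warning, since real play logs can repeat keys.
#' @export
read_user_outcomes <- function(path) {
  if (!file.exists(path)) {
    stop("outcome file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  required <- c("routine_id", "conceded", "play_id")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("outcome CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(data.frame(routine_id = character(0), conceded = logical(0),
                      play_id = character(0), stringsAsFactors = FALSE))
  }
  tok <- tolower(trimws(df$conceded))
  conceded <- rep(NA, length(tok))
  conceded[tok %in% c("1", "true")] <- TRUE
  conceded[tok %in% c("0", "false")] <- FALSE
  bad <- which(is.na(conceded))
  if (length(bad) > 0) {
    # +1 for the header row so the message points at the file line
    stop(sprintf("unparseable 'conceded' value %s at line %d of %s",
                 dQuote(df$conceded[bad[1]]), bad[1] + 1L, path),
         call. = FALSE)
  }
  if (any(df$routine_id == "")) {
    stop("empty routine_id in outcome CSV", call. = FALSE)
  }
  key <- paste(df$routine_id, df$play_id, sep = "\r")
  ndup <- sum(duplicated(key))
  if (ndup > 0) {
    warning(sprintf("%d duplicated (routine_id, play_id) pair(s) in %s",
                    ndup, path), call. = FALSE)
  }
  data.frame(routine_id = df$routine_id, conceded = as.logical(conceded),
             play_id = df$play_id, stringsAsFactors = FALSE)
}

#' Aggregate play outcomes into per-routine goal proportions
#'
#' Groups outcomes by routine and computes the goal proportion (mean of the
#' conceded flags) and the play count. A goal proportion of 0.8 means a goal
#' was conceded in 80% of that routine's plays.
#'
#' @param outcomes Data frame as returned by [read_user_outcomes()].
#' @return Data frame with columns `routine_id`, `goal_proportion`
#'   (in `[0, 1]`) and `n_plays`, one row per distinct routine in order of
#'   first appearance.
#' @export
summarize_routines <- function(outcomes) {
  if (nrow(outcomes) == 0) {
    return(data.frame(routine_id = character(0), goal_proportion = numeric(0),
                      n_plays = integer(0), stringsAsFactors = FALSE))
  }
  ids <- unique(outcomes$routine_id)
  f <- factor(outcomes$routine_id, levels = ids)
  n_plays <- as.integer(tabulate(f, nbins = length(ids)))
  goals <- as.integer(rowsum(as.integer(outcomes$conceded), f,
                             reorder = FALSE))
  data.frame(routine_id = ids,
             goal_proportion = goals / n_plays,
             n_plays = n_plays,
             stringsAsFactors = FALSE)
}

#' Filter routines by minimum play count
#'
#' Keeps only routines played at least `min_plays` times (inclusive), so
#' that the goal proportion is estimated from enough independent plays to
#' be trusted as a difficulty target.
#'
#' @param summaries Data frame from [summarize_routines()].
#' @param min_plays Minimum number of plays; default 100.
#' @return The retained rows in their original order.
#' @export
filter_min_plays <- function(summaries, min_plays = 100) {
  if (!is.numeric(min_plays) || length(min_plays) != 1 || min_plays < 1) {
    stop("min_plays must be a single integer >= 1", call. = FALSE)
  }
  out <- summaries[summaries$n_plays >= min_plays, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Join ball flights with routine outcome summaries
#'
#' Inner join on `routine_id`. Routines present in only one input are
#' dropped from the result but always reported via a message (and a warning
#' when nothing matches at all), never silently.
#'
#' @param flights Data frame from [read_ball_flights()].
#' @param summaries Data frame from [summarize_routines()] (optionally
#'   filtered by [filter_min_plays()]).
#' @return The joined analysis table, one row per routine present in both
#'   inputs, in the order of `flights`.
#' @export
join_flights_outcomes <- function(flights, summaries) {
  if (anyDuplicated(flights$routine_id) > 0) {
    stop("flights contain duplicated routine_id", call. = FALSE)
  }
  if (anyDuplicated(summaries$routine_id) > 0) {
    stop("summaries contain duplicated routine_id", call. = FALSE)
  }
  common <- intersect(flights$routine_id, summaries$routine_id)
  n_f <- sum(!(flights$routine_id %in% common))
  n_s <- sum(!(summaries$routine_id %in% common))
  message(sprintf(
    "join: %d routine(s) matched; %d flight(s) and %d summary(ies) unmatched",
    length(common), n_f, n_s))
  if (length(common) == 0 &&
      (nrow(flights) > 0 || nrow(summaries) > 0)) {
    warning(sprintf(
      "no routine_id overlap: %d flights, %d summaries, 0 matched",
      nrow(flights), nrow(summaries)), call. = FALSE)
  }
  merged <- merge(flights, summaries, by = "routine_id")
  merged <- merged[order(match(merged$routine_id, flights$routine_id)), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}
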