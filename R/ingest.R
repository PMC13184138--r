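#' Read and validate EMA sessions
#'
#' Expects the header written by \code{\link{write_cohort}}:
#' \code{participant_id, timestamp, phase, mood, <item columns...>}.
#' Rows are validated (parseable ISO-8601 timestamp, ratings within the scale
#' bounds, known phase label) and sorted by participant and timestamp;
#' malformed rows raise an error naming the offending row numbers.
#'
#' @param path CSV path.
#' @param rating_bounds integer rating scale bounds.
#' @param refractory_hours minimum allowed gap between a participant's
#'   consecutive sessions; violations raise an error.
#' @return data.frame of validated sessions with POSIXct \code{timestamp}.
#' @export
read_ema <- function(path, rating_bounds = c(1L, 7L), refractory_hours = 2) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("participant_id", "timestamp", "phase", "mood"),
                 "EMA file")
  if (nrow(df) == 0) {
    df$timestamp <- as.POSIXct(character(0), tz = "UTC")
    return(df)
  }
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad_ts <- which(is.na(ts))
  if (length(bad_ts)) {
    stop_config("unparseable timestamp(s) in EMA row(s): %s",
                paste(utils::head(bad_ts, 5), collapse = ", "))
  }
  bad_phase <- which(!df$phase %in% c("monitoring", "intervention"))
  if (length(bad_phase)) {
    stop_config("unknown phase label in EMA row(s): %s",
                paste(utils::head(bad_phase, 5), collapse = ", "))
  }
  rate_cols <- c("mood", setdiff(names(df),
                                 c("participant_id", "timestamp", "phase")))
  for (col in rate_cols) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < rating_bounds[1] | v > rating_bounds[2]))
    if (length(bad)) {
      stop_config("rating out of [%d, %d] bounds in column '%s', row(s): %s",
                  rating_bounds[1], rating_bounds[2], col,
                  paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  if (anyNA(df$mood)) {
    stop_config("missing mood (DV) in EMA row(s): %s",
                paste(utils::head(which(is.na(df$mood)), 5), collapse = ", "))
  }
  df$timestamp <- ts
  df <- df[order(df$participant_id, df$timestamp), , drop = FALSE]
  gaps <- stats::ave(as.numeric(df$timestamp), df$participant_id,
                     FUN = function(x) c(Inf, diff(x)))
  bad_gap <- which(gaps < refractory_hours * 3600)
  if (length(bad_gap)) {
    stop_config("inter-EMA gap below %.1f h at sorted row(s): %s",
                refractory_hours,
                paste(utils::head(bad_gap, 5), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Read and validate smartwatch samples
#'
#' @param path CSV path with columns \code{participant_id, timestamp, hr_bpm,
#'   steps, step_speed, distance_m, calories}.
#' @return data.frame sorted by participant and timestamp.
#' @export
read_watch <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("participant_id", "timestamp", "hr_bpm", "steps",
                       "step_speed", "distance_m", "calories"), "watch file")
  if (nrow(df) == 0) {
    df$timestamp <- as.POSIXct(character(0), tz = "UTC")
    return(df)
  }
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(ts)) {
    stop_config("unparseable timestamp(s) in watch row(s): %s",
                paste(utils::head(which(is.na(ts)), 5), collapse = ", "))
  }
  bad_hr <- which(!is.na(df$hr_bpm) & (df$hr_bpm <= 20 | df$hr_bpm >= 250))
  if (length(bad_hr)) {
    stop_config("heart rate outside (20, 250) bpm in row(s): %s",
                paste(utils::head(bad_hr, 5), collapse = ", "))
  }
  for (col in c("steps", "step_speed", "distance_m", "calories")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) {
      stop_config("negative %s in watch row(s): %s", col,
                  paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  df$timestamp <- ts
  df <- df[order(df$participant_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read and validate a clinical outcome table
#'
#' @param path CSV with columns \code{participant_id, instrument, timepoint,
#'   score}.
#' @return data.frame with \code{timepoint} as an ordered factor over the
#'   study grid (screening, pre, GS1, GS3, GS5, post, FU6, FU12).
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("participant_id", "instrument", "timepoint", "score"),
                 "outcomes file")
  bad_tp <- which(!df$timepoint %in% OUTCOME_TIMEPOINTS)
  if (length(bad_tp)) {
    stop_config("unknown timepoint(s) in outcome row(s): %s",
                paste(utils::head(bad_tp, 5), collapse = ", "))
  }
  bounds <- list(PHQ9 = c(0, 27), GAD7 = c(0, 21))
  for (instr in names(bounds)) {
    sel <- df$instrument == instr
    bad <- which(sel & !is.na(df$score) &
                   (df$score < bounds[[instr]][1] |
                      df$score > bounds[[instr]][2]))
    if (length(bad)) {
      stop_config("%s score outside [%d, %d] in row(s): %s", instr,
                  bounds[[instr]][1], bounds[[instr]][2],
                  paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  dup <- duplicated(df[c("participant_id", "instrument", "timepoint")])
  if (any(dup)) {
    stop_config("duplicate (participant, instrument, timepoint) in row(s): %s",
                paste(utils::head(which(dup), 5), collapse = ", "))
  }
  df$timepoint <- factor(df$timepoint, levels = OUTCOME_TIMEPOINTS,
                         ordered = TRUE)
  df[order(df$participant_id, df$instrument, df$timepoint), , drop = FALSE]
}
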