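#' @keywords internal
"_PACKAGE"

# Domain taxonomy used throughout: the four lifestyle intervention domains.
LIFESTYLE_DOMAINS <- c("sleep", "exercise", "diet", "social")

# Fixed tie-break order for domain assignment (most- to least-frequently
# assigned in practice): social > exercise > sleep > diet.
DOMAIN_TIEBREAK_ORDER <- c("social", "exercise", "sleep", "diet")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage / per-participant
#' sub-seeds, so that participant-level results do not depend on the order in
#' which participants are processed. Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param index nonnegative integer index (participant, stage, replicate...).
#' @return an integer seed.
#' @export
split_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  # LCG-style mix; constants are arbitrary odd primes
  for (k in c(as.numeric(index) + 1, 2654435761 %% m)) {
    s <- (s * 48271 + k * 9973 + 12345) %% m
  }
  as.integer(s)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Clip to the rating scale, then round to the nearest integer rating.
clip_round_rating <- function(x, bounds) {
  as.integer(round(clip(x, bounds[1], bounds[2])))
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# accept ISO-8601 strings or POSIXct
as_instant <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(out) && !anyNA(x)) {
    out2 <- as.POSIXct(x, tz = "UTC")
    out[is.na(out)] <- out2[is.na(out)]
  }
  out
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_config("%s is missing required column(s): %s", what,
                paste(missing, collapse = ", "))
  }
  invisible(df)
}
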