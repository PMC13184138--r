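#' Feature catalog: maps features to domains, sources and aggregation rules
#'
#' Each EMA item or smartwatch attribute used as a model feature is described
#' by one catalog entry: which lifestyle domain it belongs to, whether it
#' comes from the EMA stream or the watch stream, how it is aggregated or
#' extrapolated onto the mood sampling grid, and its health orientation
#' (+1 when a higher value means more of the healthy behavior, -1 otherwise).
#'
#' Aggregation rules:
#' \describe{
#'   \item{last_value}{the rating reported at the mood timestamp itself.}
#'   \item{carry_forward}{most recent report at or before the timestamp,
#'     up to a 36 h staleness horizon, after which the value is missing.}
#'   \item{mean_since_prev}{mean of watch samples in the half-open interval
#'     (previous mood timestamp, current timestamp].}
#'   \item{sum_since_prev}{sum of watch samples over the same interval.}
#' }
#'
#' @param entries data.frame with columns \code{feature}, \code{domain},
#'   \code{source}, \code{aggregation}, \code{orientation}. Defaults to
#'   \code{default_catalog()}.
#' @return an object of class \code{feature_catalog}.
#' @export
feature_catalog <- function(entries = default_catalog_entries()) {
  assert_columns(entries, c("feature", "domain", "source", "aggregation",
                            "orientation"), "feature catalog")
  if (anyDuplicated(entries$feature)) {
    stop_config("feature catalog has duplicated feature names")
  }
  ok_domain <- entries$domain %in% c(LIFESTYLE_DOMAINS, "watch", "other")
  if (!all(ok_domain)) {
    stop_config("unknown domain(s): %s",
                paste(unique(entries$domain[!ok_domain]), collapse = ", "))
  }
  stopifnot(all(entries$source %in% c("ema", "watch")),
            all(entries$aggregation %in%
                  c("last_value", "carry_forward", "mean_since_prev",
                    "sum_since_prev")),
            all(entries$orientation %in% c(-1, 1)))
  entries$feature <- as.character(entries$feature)
  structure(list(entries = entries), class = "feature_catalog")
}

#' Default feature catalog
#'
#' Ships 16 EMA lifestyle items (four per domain) plus 5 watch attributes.
#' Item wording follows the field's domain taxonomy; orientation encodes the
#' healthy direction (e.g. higher \code{sleep_quality} is healthy, higher
#' \code{sugar_intake} is not).
#'
#' @return a data.frame of catalog entries.
#' @export
default_catalog_entries <- function() {
  ema <- function(feature, domain, orientation, aggregation = "last_value") {
    data.frame(feature = feature, domain = domain, source = "ema",
               aggregation = aggregation, orientation = orientation,
               stringsAsFactors = FALSE)
  }
  watch <- function(feature, aggregation) {
    data.frame(feature = feature, domain = "watch", source = "watch",
               aggregation = aggregation, orientation = 1,
               stringsAsFactors = FALSE)
  }
  rbind(
    ema("sleep_quality",       "sleep",     +1, "carry_forward"),
    ema("sleep_duration",      "sleep",     +1, "carry_forward"),
    ema("sleep_restedness",    "sleep",     +1, "carry_forward"),
    ema("sleep_difficulty",    "sleep",     -1, "carry_forward"),
    ema("exercise_minutes",    "exercise",  +1),
    ema("exercise_intensity",  "exercise",  +1),
    ema("exercise_enjoyment",  "exercise",  +1),
    ema("sedentary_time",      "exercise",  -1),
    ema("diet_quality",        "diet",      +1),
    ema("fruit_veg_servings",  "diet",      +1),
    ema("sugar_intake",        "diet",      -1),
    ema("fat_intake",          "diet",      -1),
    ema("social_interactions", "social",    +1),
    ema("social_quality",      "social",    +1),
    ema("loneliness",          "social",    -1),
    ema("social_support",      "social",    +1),
    watch("hr_bpm",     "mean_since_prev"),
    watch("steps",      "sum_since_prev"),
    watch("step_speed", "mean_since_prev"),
    watch("distance_m", "sum_since_prev"),
    watch("calories",   "sum_since_prev")
  )
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat(sprintf("<feature_catalog> %d features (%s)\n",
              nrow(x$entries),
              paste(sprintf("%s: %d", names(table(x$entries$domain)),
                            as.integer(table(x$entries$domain))),
                    collapse = ", ")))
  invisible(x)
}

#' EMA item names of a catalog (source == "ema")
#' @param catalog a \code{feature_catalog}.
#' @return character vector of item names.
#' @export
catalog_ema_items <- function(catalog) {
  catalog$entries$feature[catalog$entries$source == "ema"]
}

#' Look up the domain of each feature
#'
#' Watch attributes count toward the exercise domain for decision scoring
#' (steps/heart rate reflect physical activity); "other" maps to no domain.
#'
#' @param catalog a \code{feature_catalog}.
#' @param features character vector of feature names.
#' @param for_scoring if TRUE, map watch to exercise and other to NA.
#' @return character vector of domains.
#' @export
catalog_domain <- function(catalog, features, for_scoring = FALSE) {
  idx <- match(features, catalog$entries$feature)
  d <- catalog$entries$domain[idx]
  if (for_scoring) {
    d[d == "watch"] <- "exercise"
    d[d == "other"] <- NA_character_
  }
  d
}

#' Read / write a feature catalog as YAML
#' @param path file path.
#' @return \code{read_catalog}: a \code{feature_catalog}.
#' @export
read_catalog <- function(path) {
  y <- yaml::read_yaml(path)
  feature_catalog(do.call(rbind, lapply(y$features, function(e) {
    data.frame(feature = e$feature, domain = e$domain, source = e$source,
               aggregation = e$aggregation, orientation = e$orientation,
               stringsAsFactors = FALSE)
  })))
}

#' @rdname read_catalog
#' @param catalog a \code{feature_catalog} to serialize.
#' @export
write_catalog <- function(catalog, path) {
  y <- list(features = lapply(seq_len(nrow(catalog$entries)), function(i) {
    as.list(catalog$entries[i, , drop = FALSE])
  }))
  yaml::write_yaml(y, path)
  invisible(path)
}
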