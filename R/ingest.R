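#' Read a detection log
#'
#' Reads a receiver-download style detection export with one row per
#' detection. Timestamps are parsed as ISO-8601 and converted to the analysis
#' timezone; rows with unparseable timestamps or blank identifiers are
#' collected into a reject log rather than silently dropped.
#'
#' @param path Path to a CSV with columns `timestamp`, `transmitter_id`,
#'   `receiver_id`.
#' @param tz Timezone used for all downstream day binning. Defaults to
#'   UTC+02:00 (South African Standard Time).
#' @param max_reject_frac Fatal error if more than this fraction of rows have
#'   unparseable timestamps (guards against a wrong column or format).
#'
#' @return A tibble of detections sorted by time, with columns `timestamp`
#'   (POSIXct), `transmitter_id`, `receiver_id`. The attribute `"rejects"`
#'   holds a tibble of per-reason reject counts.
#' @export
read_detections <- function(path, tz = .default_tz, max_reject_frac = 0.01) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  stop_missing_cols(raw, c("timestamp", "transmitter_id", "receiver_id"),
                    "detection log")
  n_in <- nrow(raw)
  ts <- rep(as.POSIXct(NA), nrow(raw))
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y/%m/%d %H:%M:%OS")) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(raw$timestamp[todo], fmt, tz = tz))
  }
  bad_ts <- is.na(ts) | is.na(raw$timestamp)
  if (n_in > 0 && mean(bad_ts) > max_reject_frac) {
    abort(sprintf("%d of %d detection rows (%.1f%%) have unparseable timestamps",
                  sum(bad_ts), n_in, 100 * mean(bad_ts)))
  }
  blank_id <- (is.na(raw$transmitter_id) | raw$transmitter_id == "" |
                 is.na(raw$receiver_id) | raw$receiver_id == "") & !bad_ts
  keep <- !bad_ts & !blank_id
  rejects <- tibble(
    reason = c("unparseable_timestamp", "blank_identifier"),
    n = c(sum(bad_ts), sum(blank_id))
  ) %>% filter(.data$n > 0)
  if (nrow(rejects) > 0) {
    inform(sprintf("read_detections: rejected %d of %d rows (%s)",
                   sum(rejects$n), n_in,
                   paste(sprintf("%s: %d", rejects$reason, rejects$n),
                         collapse = "; ")))
  }
  out <- tibble(
    timestamp = ts[keep],
    transmitter_id = raw$transmitter_id[keep],
    receiver_id = raw$receiver_id[keep]
  ) %>% arrange(.data$timestamp)
  attr(out, "rejects") <- rejects
  out
}

#' Read receiver deployment metadata
#'
#' Longitude breakpoints assign each receiver to the west, central or east
#' region of the bay with a half-open convention: `lon < breaks[1]` is west,
#' `breaks[1] <= lon < breaks[2]` is central, and the rest is east. The
#' default breakpoints split the bay's longitudinal extent into thirds; site
#' configurations should override them.
#'
#' @param path CSV with columns `receiver_id`, `longitude`, `latitude`,
#'   `depth_m`, `zone` (`marine`/`estuary`), `active_start`, `active_end`.
#' @param region_breaks Increasing pair of longitudes (degrees east).
#' @return Tibble with a `region` factor column added.
#' @export
read_receivers <- function(path, region_breaks = c(25.70, 25.95)) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    receiver_id = readr::col_character(),
    longitude = readr::col_double(),
    latitude = readr::col_double(),
    depth_m = readr::col_double(),
    zone = readr::col_character(),
    active_start = readr::col_date(),
    active_end = readr::col_date()
  ), progress = FALSE)
  stop_missing_cols(raw, c("receiver_id", "longitude", "latitude", "depth_m",
                           "zone", "active_start", "active_end"), "receiver table")
  validate_receivers(raw, region_breaks = region_breaks)
}

#' Validate a receiver table and assign regions
#'
#' @param receivers Data frame shaped as in [read_receivers()]. If a `region`
#'   column is absent it is derived from `longitude` and `region_breaks`.
#' @inheritParams read_receivers
#' @return Validated tibble.
#' @export
validate_receivers <- function(receivers, region_breaks = c(25.70, 25.95)) {
  receivers <- as_tibble(receivers)
  if (anyDuplicated(receivers$receiver_id)) {
    abort("duplicate receiver_id in receiver table")
  }
  check_enum(receivers$zone, .zone_levels, "zone")
  if (any(receivers$depth_m < 0, na.rm = TRUE)) abort("negative depth_m")
  if (any(receivers$active_start >= receivers$active_end, na.rm = TRUE)) {
    abort("active_start must precede active_end for every receiver")
  }
  if (length(region_breaks) != 2 || diff(region_breaks) <= 0) {
    abort("region_breaks must be an increasing pair of longitudes")
  }
  if (!"region" %in% names(receivers)) {
    receivers$region <- assign_region(receivers$longitude, region_breaks)
  } else {
    check_enum(receivers$region, .region_levels, "region")
  }
  receivers
}

#' Assign bay regions from longitude
#'
#' @param longitude Numeric vector, degrees east.
#' @param region_breaks Increasing pair of longitudes; half-open intervals,
#'   so a receiver exactly at the first break is `central`.
#' @return Character vector over `west`, `central`, `east`.
#' @export
assign_region <- function(longitude, region_breaks = c(25.70, 25.95)) {
  dplyr::case_when(
    longitude < region_breaks[1] ~ "west",
    longitude < region_breaks[2] ~ "central",
    TRUE ~ "east"
  )
}

#' Read tag deployment metadata
#'
#' @param path CSV with columns `transmitter_id`, `species`, `life_stage`,
#'   `length_mm`, `tag_date`, `tag_region`, `battery_expiry`, and optional
#'   `recapture_date`, `last_outside_detection`.
#' @param study_end Date at which monitoring windows are clamped (end of the
#'   study period).
#' @return Tibble with a derived `monitoring_end` column.
#' @export
read_tags <- function(path, study_end) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    transmitter_id = readr::col_character(),
    species = readr::col_character(),
    life_stage = readr::col_character(),
    length_mm = readr::col_double(),
    tag_date = readr::col_date(),
    tag_region = readr::col_character(),
    battery_expiry = readr::col_date(),
    recapture_date = readr::col_date(),
    last_outside_detection = readr::col_date()
  ), progress = FALSE)
  stop_missing_cols(raw, c("transmitter_id", "species", "life_stage",
                           "length_mm", "tag_date", "tag_region",
                           "battery_expiry"), "tag table")
  validate_tags(raw, study_end = study_end)
}

#' Validate a tag table and derive monitoring windows
#'
#' @param tags Data frame shaped as in [read_tags()].
#' @inheritParams read_tags
#' @return Validated tibble with `monitoring_end` added.
#' @export
validate_tags <- function(tags, study_end) {
  tags <- as_tibble(tags)
  study_end <- as.Date(study_end)
  if (anyDuplicated(tags$transmitter_id)) abort("duplicate transmitter_id in tag table")
  check_enum(tags$species, .species_levels, "species")
  check_enum(tags$life_stage, .stage_levels, "life_stage")
  check_enum(tags$tag_region, c("estuary", "coastal"), "tag_region")
  if (any(tags$length_mm <= 0, na.rm = TRUE)) abort("length_mm must be positive")
  if (any(tags$tag_date >= tags$battery_expiry, na.rm = TRUE)) {
    abort("tag_date must precede battery_expiry")
  }
  if (!"recapture_date" %in% names(tags)) tags$recapture_date <- as.Date(NA)
  if (!"last_outside_detection" %in% names(tags)) {
    tags$last_outside_detection <- as.Date(NA)
  }
  bad_recap <- !is.na(tags$recapture_date) & tags$recapture_date < tags$tag_date
  if (any(bad_recap)) abort("recapture_date precedes tag_date")
  tags$study_end <- study_end
  tags$monitoring_end <- monitoring_end(tags)
  tags
}

#' Monitoring-window endpoint for each individual
#'
#' The number of days an individual was monitored runs from its tagging date
#' to the earliest of: the end of the study period, its recapture date, its
#' tag battery expiry, or its last known detection outside the bay. Absent
#' candidates are ignored.
#'
#' @param tags Tibble with columns `tag_date`, `study_end`, `battery_expiry`
#'   and optional `recapture_date`, `last_outside_detection`.
#' @return Date vector, one endpoint per row.
#' @export
monitoring_end <- function(tags) {
  cand <- cbind(
    as.numeric(tags$study_end),
    as.numeric(tags$battery_expiry),
    if ("recapture_date" %in% names(tags)) as.numeric(tags$recapture_date) else NA_real_,
    if ("last_outside_detection" %in% names(tags)) {
      as.numeric(tags$last_outside_detection)
    } else NA_real_
  )
  out <- as.Date(apply(cand, 1, min, na.rm = TRUE), origin = "1970-01-01")
  if (any(out < tags$tag_date)) {
    abort("monitoring_end precedes tag_date for at least one individual")
  }
  out
}

#' Apply the study inclusion filters
#'
#' Produces the clean analysis dataset: estuary receivers and their
#' detections are removed first, detections from unknown transmitters are
#' dropped with a logged count, each individual's detections are clamped to
#' its monitoring window, and individuals detected on fewer than `min_days`
#' distinct days are excluded. Exclusions are recorded per individual with a
#' reason code.
#'
#' @param detections Detection tibble ([read_detections()] shape).
#' @param tags Validated tag tibble with `monitoring_end` ([validate_tags()]).
#' @param receivers Validated receiver tibble ([validate_receivers()]).
#' @param min_days Minimum number of distinct marine detection days for an
#'   individual to be retained; the boundary is inclusive (exactly
#'   `min_days` days is retained).
#' @param tz Analysis timezone used for day binning.
#'
#' @return An object of class `bay_dataset`: a list with tibbles
#'   `detections` (with `date` and `region` columns joined on), `tags`
#'   (retained individuals), `receivers` (marine only), and `exclusions`
#'   (one row per excluded individual with a `reason` in
#'   `never_detected` / `below_min_days`), plus the filter settings.
#' @export
filter_dataset <- function(detections, tags, receivers, min_days = 10,
                           tz = .default_tz) {
  detections <- as_tibble(detections)
  tags <- as_tibble(tags)
  receivers <- as_tibble(receivers)
  if (!"monitoring_end" %in% names(tags)) {
    abort("tags must carry a monitoring_end column; run validate_tags() first")
  }

  # derived columns are recomputed, so refiltering is idempotent
  detections <- detections %>%
    select(-dplyr::any_of(c("date", "region")))
  marine <- receivers %>% filter(.data$zone == "marine")
  n0 <- nrow(detections)
  det <- detections %>% semi_join(marine, by = "receiver_id")
  n_estuary <- n0 - nrow(det)

  known <- det$transmitter_id %in% tags$transmitter_id
  n_unknown <- sum(!known)
  if (n_unknown > 0) {
    inform(sprintf("filter_dataset: dropped %d detections from unknown transmitters",
                   n_unknown))
  }
  det <- det[known, , drop = FALSE]

  det <- det %>%
    mutate(date = detection_date(.data$timestamp, tz = tz)) %>%
    left_join(tags %>% select("transmitter_id", "tag_date", "monitoring_end"),
              by = "transmitter_id")
  in_window <- det$date >= det$tag_date & det$date <= det$monitoring_end
  n_outside <- sum(!in_window)
  det <- det %>%
    filter(in_window) %>%
    select(-"tag_date", -"monitoring_end") %>%
    left_join(marine %>% select("receiver_id", "region"), by = "receiver_id")

  day_counts <- det %>%
    distinct(.data$transmitter_id, .data$date) %>%
    count(.data$transmitter_id, name = "n_days")
  tags_days <- tags %>%
    left_join(day_counts, by = "transmitter_id") %>%
    mutate(n_days = dplyr::coalesce(.data$n_days, 0L))

  retained_ids <- tags_days %>% filter(.data$n_days >= min_days) %>%
    pull("transmitter_id")
  exclusions <- tags_days %>%
    filter(.data$n_days < min_days) %>%
    mutate(reason = if_else(.data$n_days == 0L, "never_detected",
                            "below_min_days")) %>%
    select("transmitter_id", "species", "life_stage", "n_days", "reason")

  if (length(retained_ids) == 0) {
    abort(sprintf(paste0("no individuals retained: all %d tagged individuals ",
                         "fall below the %d-day threshold"),
                  nrow(tags), min_days))
  }

  out <- list(
    detections = det %>% filter(.data$transmitter_id %in% retained_ids),
    tags = tags %>% filter(.data$transmitter_id %in% retained_ids),
    receivers = marine,
    exclusions = exclusions,
    counts = tibble(
      stage = c("input", "estuary_removed", "unknown_transmitter",
                "outside_window", "retained"),
      n = c(n0, n_estuary, n_unknown, n_outside,
            nrow(det %>% filter(.data$transmitter_id %in% retained_ids)))
    ),
    min_days = min_days,
    tz = tz
  )
  class(out) <- "bay_dataset"
  out
}

#' @export
print.bay_dataset <- function(x, ...) {
  cat(sprintf("<bay_dataset> %d detections | %d individuals | %d marine receivers\n",
              nrow(x$detections), nrow(x$tags), nrow(x$receivers)))
  cat(sprintf("  excluded: %d individuals (%s); min_days = %d, tz = %s\n",
              nrow(x$exclusions),
              if (nrow(x$exclusions) > 0) {
                paste(sprintf("%s: %d", names(table(x$exclusions$reason)),
                              as.integer(table(x$exclusions$reason))),
                      collapse = ", ")
              } else "none",
              x$min_days, x$tz))
  invisible(x)
}

#' Cohort bookkeeping by species and life stage
#'
#' Tabulates, per species-by-life-stage stratum, how many individuals were
#' tagged and how many survived the inclusion filters, with the retained
#' percentage rounded to the nearest integer, plus an overall row.
#'
#' @param dataset A `bay_dataset` from [filter_dataset()].
#' @param all_tags The full tag table before filtering (defines `n_tagged`).
#' @return Tibble with columns `species`, `life_stage`, `n_tagged`,
#'   `n_retained`, `pct_retained`. Declared strata with zero tagged
#'   individuals are omitted with a warning.
#' @export
cohort_summary <- function(dataset, all_tags) {
  stopifnot(inherits(dataset, "bay_dataset"))
  all_tags <- as_tibble(all_tags)
  retained <- dataset$tags %>% count(.data$species, .data$life_stage,
                                     name = "n_retained")
  tab <- all_tags %>%
    count(.data$species, .data$life_stage, name = "n_tagged") %>%
    left_join(retained, by = c("species", "life_stage")) %>%
    mutate(n_retained = dplyr::coalesce(.data$n_retained, 0L))
  zero <- tab %>% filter(.data$n_tagged == 0)
  if (nrow(zero) > 0) {
    warn(sprintf("omitting %d stratum/strata with no tagged individuals",
                 nrow(zero)))
    tab <- tab %>% filter(.data$n_tagged > 0)
  }
  overall <- tibble(
    species = "all", life_stage = "all",
    n_tagged = sum(tab$n_tagged), n_retained = sum(tab$n_retained)
  )
  bind_rows(tab, overall) %>%
    mutate(pct_retained = pct_round(.data$n_retained, .data$n_tagged))
}

#' Integer percentage, rounded to the nearest whole percent
#'
#' Shared by cohort tables so printed percentages follow one convention
#' (half-up, matching how cohort tables are usually typeset).
#'
#' @param numerator,denominator Integer vectors.
#' @return Integer percentage vector.
#' @export
pct_round <- function(numerator, denominator) {
  as.integer(floor(100 * numerator / denominator + 0.5))
}
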