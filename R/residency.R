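#' Distinct detection days per individual
#'
#' A detection day is a calendar date (in the analysis timezone) with at
#' least one marine detection.
#'
#' @param dataset A `bay_dataset`.
#' @param individual Optional transmitter ID; if given, only that
#'   individual's days are returned (unknown IDs error).
#' @return Tibble with columns `transmitter_id`, `date`.
#' @export
detection_days <- function(dataset, individual = NULL) {
  stopifnot(inherits(dataset, "bay_dataset"))
  days <- dataset$detections %>% distinct(.data$transmitter_id, .data$date)
  if (!is.null(individual)) {
    if (!individual %in% dataset$tags$transmitter_id) {
      abort(sprintf("unknown individual '%s'", individual))
    }
    days <- days %>% filter(.data$transmitter_id == individual)
  }
  days %>% arrange(.data$transmitter_id, .data$date)
}

#' Per-individual detection indices
#'
#' Two complementary residency measures. `di_total` is the number of
#' distinct detection days divided by the total days monitored (tagging date
#' to the monitoring endpoint); `di_bay` divides the same numerator by the
#' days at liberty up to the last in-bay detection, measuring residency
#' while the animal was demonstrably using the bay. Day counts are inclusive
#' of both endpoints by default, so an individual tagged and last detected
#' on the same day has a 1-day denominator.
#'
#' Because the `di_bay` denominator can never exceed the `di_total`
#' denominator, `di_total <= di_bay` holds for every individual.
#'
#' @param dataset A `bay_dataset`.
#' @param inclusive If `TRUE` (default) day spans count both endpoints
#'   (`end - start + 1`); if `FALSE`, only the start (`end - start`, with a
#'   1-day floor). The two conventions differ by at most one day.
#' @return Tibble with one row per retained individual: `transmitter_id`,
#'   `species`, `life_stage`, `tag_region`, `n_detection_days`,
#'   `days_monitored_total`, `days_to_last_bay_detection`, `di_total`,
#'   `di_bay`.
#' @export
detection_indices <- function(dataset, inclusive = TRUE) {
  stopifnot(inherits(dataset, "bay_dataset"))
  span_days <- function(start, end) {
    d <- as.integer(end - start) + if (inclusive) 1L else 0L
    pmax(d, 1L)
  }
  per_ind <- dataset$detections %>%
    group_by(.data$transmitter_id) %>%
    summarise(n_detection_days = n_distinct(.data$date),
              last_bay_detection = max(.data$date), .groups = "drop")
  out <- dataset$tags %>%
    select("transmitter_id", "species", "life_stage", "tag_region",
           "tag_date", "monitoring_end") %>%
    inner_join(per_ind, by = "transmitter_id") %>%
    mutate(
      days_monitored_total = span_days(.data$tag_date, .data$monitoring_end),
      days_to_last_bay_detection = span_days(.data$tag_date,
                                             .data$last_bay_detection),
      di_total = .data$n_detection_days / .data$days_monitored_total,
      di_bay = .data$n_detection_days / .data$days_to_last_bay_detection
    )
  if (any(out$days_monitored_total <= 0 |
            out$days_to_last_bay_detection <= 0)) {
    abort("nonpositive monitoring denominator; tag metadata is inconsistent")
  }
  out %>% select(-"tag_date", -"monitoring_end", -"last_bay_detection")
}

#' Monthly detection table
#'
#' One row per individual and calendar month overlapping its monitoring
#' window, with the number of distinct detection days in that month, the
#' calendar length of the month (the offset used by the seasonal model), and
#' their ratio (the monthly detection index).
#'
#' @param dataset A `bay_dataset`.
#' @return Tibble with columns `transmitter_id`, `species`, `life_stage`,
#'   `month_start`, `month` (1-12), `days_detected`, `days_in_month`,
#'   `monthly_di`.
#' @export
monthly_detection_table <- function(dataset) {
  stopifnot(inherits(dataset, "bay_dataset"))
  windows <- dataset$tags %>%
    select("transmitter_id", "species", "life_stage", "tag_date",
           "monitoring_end") %>%
    mutate(month_start = map2(.data$tag_date, .data$monitoring_end,
                              function(a, b) seq(month_start(a),
                                                 month_start(b),
                                                 by = "1 month"))) %>%
    select(-"tag_date", -"monitoring_end") %>%
    unnest("month_start")
  monthly_counts <- dataset$detections %>%
    distinct(.data$transmitter_id, .data$date) %>%
    mutate(month_start = month_start(.data$date)) %>%
    count(.data$transmitter_id, .data$month_start, name = "days_detected")
  windows %>%
    left_join(monthly_counts, by = c("transmitter_id", "month_start")) %>%
    mutate(days_detected = dplyr::coalesce(.data$days_detected, 0L),
           month = month_of(.data$month_start),
           days_in_month = days_in_month(.data$month_start),
           monthly_di = .data$days_detected / .data$days_in_month)
}

#' Daily detection matrix by bay region
#'
#' Long-format presence records for daily detection plots: one row per
#' individual, date and region with at least one detection that day. Dates
#' with no detections are absent; a date with detections in several regions
#' yields several rows.
#'
#' @param dataset A `bay_dataset`.
#' @return Tibble with columns `transmitter_id`, `species`, `life_stage`,
#'   `date`, `region`.
#' @export
daily_detection_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "bay_dataset"))
  dataset$detections %>%
    distinct(.data$transmitter_id, .data$date, .data$region) %>%
    left_join(dataset$tags %>% select("transmitter_id", "species",
                                      "life_stage"),
              by = "transmitter_id") %>%
    select("transmitter_id", "species", "life_stage", "date", "region") %>%
    arrange(.data$transmitter_id, .data$date, .data$region)
}
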