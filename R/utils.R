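#' Species and life-stage levels used throughout the package
#'
#' The four predator species monitored in the bay array (two mesopredatory
#' teleosts, two top-predatory sharks) and the life-stage classes used for
#' cohort stratification.
#'
#' @name levels
#' @keywords internal
NULL

.species_levels <- c("A_japonicus", "L_amia", "C_taurus", "C_carcharias")
.stage_levels <- c("juvenile", "subadult", "adult", "unknown")
.zone_levels <- c("marine", "estuary")
.region_levels <- c("west", "central", "east")

#' Default analysis timezone (UTC+02:00, South African Standard Time)
#' @keywords internal
.default_tz <- "Etc/GMT-2"

# calendar date of a timestamp in the analysis timezone
detection_date <- function(timestamp, tz = .default_tz) {
  as.Date(timestamp, tz = tz)
}

# month index 1..12 of a Date
month_of <- function(date) as.integer(format(date, "%m"))

# number of days in the calendar month containing `date` (vectorized)
days_in_month <- function(date) {
  first <- as.Date(format(date, "%Y-%m-01"))
  # day 1 plus 31 always lands inside the following month
  nxt <- as.Date(format(first + 31, "%Y-%m-01"))
  as.integer(nxt - first)
}

# first day of the calendar month containing `date`
month_start <- function(date) as.Date(format(date, "%Y-%m-01"))

stop_missing_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_enum <- function(x, levels, what) {
  bad <- setdiff(unique(as.character(x[!is.na(x)])), levels)
  if (length(bad) > 0) {
    abort(sprintf("invalid %s value(s): %s (allowed: %s)",
                  what, paste(bad, collapse = ", "),
                  paste(levels, collapse = ", ")))
  }
  invisible(x)
}
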