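#' Site configuration
#'
#' Bundles the geographic and calendar information needed to partition a
#' half-hourly flux record into day/night and growing/non-growing strata.
#' Defaults describe a mid-latitude site at UTC+8 where the growing season
#' spans May through September.
#'
#' @param latitude Degrees north (negative = south); must lie in \[-90, 90\].
#' @param longitude Degrees east (negative = west).
#' @param utc_offset Hours added to UTC to obtain local standard time.
#'   Timestamps in a flux table are interpreted as local standard time at this
#'   fixed offset (no daylight saving).
#' @param growing_months Integer months forming the growing season.
#' @param year Calendar year of the record.
#' @param timestamp_convention Whether a row's timestamp labels the `"end"`
#'   (EddyPro convention, default) or the `"start"` of its 30-minute
#'   averaging interval.
#'
#' @return An object of class `site_config` (a named list).
#' @export
#'
#' @examples
#' site_config()
site_config <- function(latitude = 44.618,
                        longitude = 83.5665,
                        utc_offset = 8,
                        growing_months = 5:9,
                        year = 2015,
                        timestamp_convention = c("end", "start")) {
  timestamp_convention <- match.arg(timestamp_convention)
  if (!is.numeric(latitude) || abs(latitude) > 90) {
    stop("`latitude` must lie in [-90, 90] degrees.", call. = FALSE)
  }
  growing_months <- as.integer(growing_months)
  if (!all(growing_months %in% 1:12)) {
    stop("`growing_months` must be a subset of 1..12.", call. = FALSE)
  }
  structure(
    list(
      latitude = latitude,
      longitude = longitude,
      utc_offset = utc_offset,
      growing_months = growing_months,
      year = as.integer(year),
      timestamp_convention = timestamp_convention
    ),
    class = "site_config"
  )
}

#' @export
print.site_config <- function(x, ...) {
  cat("<site_config>\n")
  cat(sprintf("  latitude:  %8.4f degN\n", x$latitude))
  cat(sprintf("  longitude: %8.4f degE\n", x$longitude))
  cat(sprintf("  utc offset: +%g h; year %d\n", x$utc_offset, x$year))
  cat(sprintf(
    "  growing months: %s; timestamps label interval %s\n",
    paste(x$growing_months, collapse = ","), x$timestamp_convention
  ))
  invisible(x)
}
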