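# Core half-hourly flux-table data model: construction, validation, CSV I/O,
# solar day/night partitioning, season labels, and unit conversion.

#' Columns a flux table may carry
#'
#' `flux_driver_cols()` returns the continuous meteorological/phenological
#' drivers used by the gap-filling models; `flux_binary_cols()` the 0/1
#' indicator columns passed through unscaled.
#'
#' @return Character vector of column names.
#' @export
flux_driver_cols <- function() {
  c(
    "t_air", "t_soil", "rh", "rd", "ru", "vpd", "e", "ndvi", "hdd",
    "hour_n", "hour_d"
  )
}

#' @rdname flux_driver_cols
#' @export
flux_binary_cols <- function() c("is_day", "is_growing")

flux_core_cols <- function() c("timestamp", "f_c", "qc_flag", "u_star", "wind")

#' Build an empty half-hourly timestamp grid for one calendar year
#'
#' Timestamps are local standard time (stored as POSIXct in UTC, interpreted
#' at the site's fixed `utc_offset`) and label the end of each 30-minute
#' averaging interval by default (EddyPro convention), so a full year runs
#' from 00:30 on Jan 1 to 00:00 on Jan 1 of the following year.
#'
#' @param site A [site_config()].
#' @return A tibble with a `timestamp` column of `48 * days in year` rows.
#' @export
#' @examples
#' nrow(halfhour_grid(site_config(year = 2015))) # 17520
halfhour_grid <- function(site = site_config()) {
  start <- as.POSIXct(sprintf("%d-01-01 00:00:00", site$year), tz = "UTC")
  n <- 48 * n_days_in_year(site$year)
  offset <- if (site$timestamp_convention == "end") 1800 else 0
  tibble::tibble(timestamp = start + offset + 1800 * (seq_len(n) - 1))
}

n_days_in_year <- function(year) {
  as.integer(as.Date(sprintf("%d-01-01", year + 1)) -
    as.Date(sprintf("%d-01-01", year)))
}

#' Validate a half-hourly flux table
#'
#' Checks the structural invariants every pipeline stage relies on: strictly
#' increasing, uniformly spaced 30-minute timestamps; `qc_flag` in {0, 1, 2};
#' non-negative friction velocity; and (when present) unit-circle time-of-day
#' encodings.
#'
#' @param table A data frame with at least a `timestamp` column.
#' @param full_year If `TRUE`, additionally require `48 * days-in-year` rows.
#' @param year Calendar year used for the `full_year` check (taken from the
#'   first timestamp when `NULL`).
#' @return The table, invisibly, as a tibble; errors describe the violation.
#' @export
validate_flux_table <- function(table, full_year = FALSE, year = NULL) {
  table <- tibble::as_tibble(table)
  if (!"timestamp" %in% names(table)) {
    stop("flux table must contain a `timestamp` column.", call. = FALSE)
  }
  ts <- table$timestamp
  if (!inherits(ts, "POSIXct")) {
    stop("`timestamp` must be POSIXct.", call. = FALSE)
  }
  if (anyDuplicated(ts) > 0) {
    stop("duplicated timestamps found; half-hourly slots must be unique.",
      call. = FALSE
    )
  }
  d <- diff(as.numeric(ts))
  if (any(d <= 0)) {
    stop("timestamps must be strictly increasing.", call. = FALSE)
  }
  if (length(d) && any(d != 1800)) {
    stop("timestamps must be uniformly spaced at 30 minutes.", call. = FALSE)
  }
  if ("qc_flag" %in% names(table)) {
    ok <- is.na(table$qc_flag) | table$qc_flag %in% c(0L, 1L, 2L)
    if (!all(ok)) stop("`qc_flag` must be 0, 1 or 2.", call. = FALSE)
  }
  if ("u_star" %in% names(table)) {
    if (any(table$u_star < 0, na.rm = TRUE)) {
      stop("`u_star` must be non-negative.", call. = FALSE)
    }
  }
  if (all(c("hour_n", "hour_d") %in% names(table))) {
    r <- table$hour_n^2 + table$hour_d^2
    if (any(abs(r - 1) > 1e-8, na.rm = TRUE)) {
      stop("hour_n^2 + hour_d^2 must equal 1.", call. = FALSE)
    }
  }
  if (full_year) {
    year <- year %||% as.integer(format(ts[1], "%Y"))
    want <- 48L * n_days_in_year(year)
    if (nrow(table) != want) {
      stop(sprintf(
        "full-year table for %d must have %d rows, got %d.",
        year, want, nrow(table)
      ), call. = FALSE)
    }
  }
  invisible(table)
}

#' Add cosine/sine encodings of time of day
#'
#' `hour_n = cos(2 pi h / 24)` and `hour_d = sin(2 pi h / 24)` where `h` is
#' the decimal hour of the row's timestamp, giving the models a continuous,
#' midnight-periodic clock.
#'
#' @param table A flux table.
#' @return The table with `hour_n`, `hour_d` columns (overwritten if present).
#' @export
add_time_encodings <- function(table) {
  h <- decimal_hour(table$timestamp)
  dplyr::mutate(
    tibble::as_tibble(table),
    hour_n = cos(2 * pi * h / 24),
    hour_d = sin(2 * pi * h / 24)
  )
}

decimal_hour <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Read / write a half-hourly flux table as CSV
#'
#' Plain CSV with a header and one row per half hour. Column names in the file
#' can be remapped through `schema`, a named character vector whose names are
#' the internal column names and whose values are the file's column names.
#' Missing flux must be an empty field or `NA`, never a sentinel number.
#'
#' @param path File path.
#' @param schema Named character vector mapping internal -> file column names;
#'   `NULL` keeps the internal names.
#' @return `read_flux_csv()` returns a validated flux tibble;
#'   `write_flux_csv()` returns `path` invisibly.
#' @export
read_flux_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    missing <- setdiff(unname(schema), names(raw))
    if (length(missing)) {
      stop(
        "column(s) required by schema missing from file: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    raw <- dplyr::rename(raw, !!!rlang::set_names(schema, names(schema)))
  }
  if (!"timestamp" %in% names(raw)) {
    stop("column(s) required by schema missing from file: timestamp",
      call. = FALSE
    )
  }
  if (is.character(raw$timestamp)) {
    raw$timestamp <- as.POSIXct(raw$timestamp,
      tz = "UTC",
      format = "%Y-%m-%dT%H:%M:%SZ"
    )
  } else {
    raw$timestamp <- lubridate_force_utc(raw$timestamp)
  }
  if (anyNA(raw$timestamp)) {
    stop("unparseable timestamps in ", path, call. = FALSE)
  }
  if ("qc_flag" %in% names(raw)) raw$qc_flag <- as.integer(raw$qc_flag)
  for (col in intersect(c("is_day", "is_growing"), names(raw))) {
    raw[[col]] <- as.logical(raw[[col]])
  }
  validate_flux_table(raw)
  tibble::as_tibble(raw)
}

# readr parses ISO timestamps as UTC already; normalize the tz attribute.
lubridate_force_utc <- function(ts) {
  attr(ts, "tzone") <- "UTC"
  ts
}

#' @rdname read_flux_csv
#' @param table A flux table to serialize.
#' @export
write_flux_csv <- function(table, path) {
  validate_flux_table(table)
  out <- tibble::as_tibble(table)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# ---- solar geometry (NOAA formulation) --------------------------------------

# Fractional-year angle, equation of time (minutes) and solar declination
# (radians) for a vector of days of year. Standard NOAA solar equations.
solar_parameters <- function(doy, hour = 12) {
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  list(eqtime = eqtime, decl = decl)
}

#' Sunrise and sunset in local standard time
#'
#' NOAA solar-geometry sunrise/sunset (zenith 90.833 degrees, i.e. including
#' standard refraction and the solar disc) for each date, returned as minutes
#' after local standard midnight. Polar day yields `sunrise = -Inf,
#' sunset = Inf`; polar night yields an empty daytime interval.
#'
#' @param dates A `Date` vector.
#' @param site A [site_config()].
#' @return A tibble with `date`, `sunrise_min`, `sunset_min`.
#' @export
solar_day_window <- function(dates, site = site_config()) {
  doy <- as.integer(format(dates, "%j"))
  sp <- solar_parameters(doy)
  lat <- site$latitude * pi / 180
  cos_ha <- (cos(90.833 * pi / 180) / (cos(lat) * cos(sp$decl))) -
    tan(lat) * tan(sp$decl)
  ha <- acos(pmin(pmax(cos_ha, -1), 1)) * 180 / pi
  sunrise <- 720 - 4 * (site$longitude + ha) - sp$eqtime + 60 * site$utc_offset
  sunset <- 720 - 4 * (site$longitude - ha) - sp$eqtime + 60 * site$utc_offset
  sunrise[cos_ha < -1] <- -Inf # polar day
  sunset[cos_ha < -1] <- Inf
  sunrise[cos_ha > 1] <- Inf # polar night: empty [sunrise, sunset)
  sunset[cos_ha > 1] <- -Inf
  tibble::tibble(date = dates, sunrise_min = sunrise, sunset_min = sunset)
}

#' Label each record day or night from site solar geometry
#'
#' A record is daytime iff its timestamp falls in `[sunrise, sunset)` for its
#' calendar date, with sunrise/sunset from the NOAA solar equations at the
#' site coordinates and fixed UTC offset.
#'
#' @param table A flux table.
#' @param site A [site_config()].
#' @return The table with a logical `is_day` column.
#' @export
compute_day_night <- function(table, site = site_config()) {
  table <- tibble::as_tibble(table)
  date <- as.Date(format(table$timestamp, "%Y-%m-%d"))
  minutes <- 60 * decimal_hour(table$timestamp)
  win <- solar_day_window(unique(date), site)
  idx <- match(date, win$date)
  dplyr::mutate(
    table,
    is_day = minutes >= win$sunrise_min[idx] & minutes < win$sunset_min[idx]
  )
}

#' Label growing-season records
#'
#' `is_growing` is `TRUE` iff the record's calendar month belongs to
#' `site$growing_months` (May-September by default).
#'
#' @inheritParams compute_day_night
#' @return The table with a logical `is_growing` column.
#' @export
assign_seasons <- function(table, site = site_config()) {
  month <- as.integer(format(table$timestamp, "%m"))
  dplyr::mutate(
    tibble::as_tibble(table),
    is_growing = month %in% site$growing_months
  )
}

#' Convert a half-hourly CO2 flux to grams of carbon
#'
#' One half hour of flux `f` (umol CO2 m^-2 s^-1) moves
#' `f * 1800 s * 12.011e-6 g umol^-1` grams of carbon per square metre.
#' Negative flux (uptake) yields negative grams, keeping the
#' micrometeorological sign convention.
#'
#' @param flux Numeric flux in umol m^-2 s^-1.
#' @return Numeric, g C m^-2 per half-hour slot.
#' @export
#' @examples
#' halfhour_to_gC(1) # ~0.02162
halfhour_to_gC <- function(flux) flux * 1800 * 12.011e-6

# ---- driver normalization ---------------------------------------------------

#' Min-max scale the model drivers
#'
#' Continuous drivers are linearly mapped to (0, 1) using the range of the
#' rows the scaler was fitted on; binary day/season indicators pass through as
#' 0/1. Rows outside the fitted range scale below 0 or above 1 — allowed
#' (linear extrapolation) and reported via a message.
#'
#' @param table A flux table carrying the driver columns.
#' @param cols Continuous driver columns to scale (default
#'   [flux_driver_cols()] intersected with what is present).
#' @param scaler A scaler returned by a previous call (stored in the
#'   `"scaler"` attribute of the result); `NULL` fits a new one on `table`.
#' @param quiet Suppress the out-of-range message.
#' @return A tibble of scaled drivers plus 0/1 indicator columns, with the
#'   fitted scaler in `attr(, "scaler")`.
#' @export
normalize_drivers <- function(table, cols = NULL, scaler = NULL, quiet = FALSE) {
  table <- tibble::as_tibble(table)
  cols <- cols %||% intersect(flux_driver_cols(), names(table))
  if (is.null(scaler)) {
    rng <- lapply(table[cols], range, na.rm = TRUE)
    widths <- vapply(rng, diff, numeric(1))
    if (any(widths == 0)) {
      stop(
        "driver column(s) with zero range cannot be scaled: ",
        paste(cols[widths == 0], collapse = ", "),
        call. = FALSE
      )
    }
    scaler <- list(cols = cols, range = rng)
  }
  out <- purrr::map2(
    scaler$cols, scaler$range,
    function(col, r) (table[[col]] - r[1]) / (r[2] - r[1])
  )
  names(out) <- scaler$cols
  out <- tibble::as_tibble(out)
  n_out <- sum(vapply(out, function(x) sum(x < 0 | x > 1, na.rm = TRUE), 0))
  if (n_out > 0 && !quiet) {
    message(n_out, " scaled driver value(s) fall outside (0, 1); ",
      "linear extrapolation of the stored transform applied."
    )
  }
  for (b in intersect(flux_binary_cols(), names(table))) {
    out[[b]] <- as.numeric(table[[b]])
  }
  attr(out, "scaler") <- scaler
  out
}

# Numeric design matrix for the regression gap fillers.
driver_design_matrix <- function(table, scaler = NULL, quiet = TRUE) {
  scaled <- normalize_drivers(table, scaler = scaler, quiet = quiet)
  x <- as.matrix(scaled)
  attr(x, "scaler") <- attr(scaled, "scaler")
  x
}
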