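# Data-cleaning chain for the half-hourly flux series. Stage order is fixed:
# QC-flag screening -> diurnal-quantile (distributional) cleaning -> median
# spike filtering -> (u* screening, in ustar.R). Each stage only sees the
# survivors of the previous one, and logs its per-season removal counts.

#' Spike-filter configuration
#'
#' Parameters of the 7-day median spike filter: for each window the
#' double-difference `D_i = (F_i - F_{i-1}) - (F_{i+1} - F_i)` over
#' consecutive valid records is compared against
#' `Md +/- z * MAD / 0.6745`, where `Md` and `MAD` are the window median and
#' median absolute deviation of `D`.
#'
#' @param z Sensitivity coefficient (default 5.5).
#' @param window_days Window length in days (default 7).
#' @param mad_scale Consistency constant relating MAD to a Gaussian SD.
#' @param split_day_night Process daytime and nighttime records separately.
#' @return A `spike_config` list.
#' @export
spike_config <- function(z = 5.5, window_days = 7, mad_scale = 0.6745,
                         split_day_night = TRUE) {
  stopifnot(z > 0, window_days >= 1, mad_scale > 0)
  structure(
    list(
      z = z, window_days = as.integer(window_days),
      mad_scale = mad_scale, split_day_night = isTRUE(split_day_night)
    ),
    class = "spike_config"
  )
}

# ---- removal bookkeeping ----------------------------------------------------

qc_log_append <- function(table, stage, removed_idx) {
  log <- attr(table, "qc_log") %||%
    tibble::tibble(
      stage = character(), growing = integer(), nongrowing = integer(),
      total = integer()
    )
  grow <- if ("is_growing" %in% names(table)) {
    table$is_growing[removed_idx]
  } else {
    rep(NA, length(removed_idx))
  }
  log <- dplyr::bind_rows(log, tibble::tibble(
    stage = stage,
    growing = sum(grow, na.rm = TRUE),
    nongrowing = sum(!grow, na.rm = TRUE),
    total = length(removed_idx)
  ))
  attr(table, "qc_log") <- log
  table
}

#' Per-stage, per-season removal counts
#'
#' @param table A flux table that has passed through one or more screens.
#' @return A tibble with columns `stage`, `growing`, `nongrowing`, `total`.
#' @export
qc_report <- function(table) {
  attr(table, "qc_log") %||%
    tibble::tibble(
      stage = character(), growing = integer(), nongrowing = integer(),
      total = integer()
    )
}

# Invalidate flux on `mask`, preserving the raw series in `f_c_raw`.
remove_flux <- function(table, mask, stage) {
  table <- tibble::as_tibble(table)
  if (!"f_c_raw" %in% names(table)) table$f_c_raw <- table$f_c
  removed <- which(mask & !is.na(table$f_c))
  table$f_c[removed] <- NA_real_
  qc_log_append(table, stage, removed)
}

#' Screen flux by EddyPro quality flag
#'
#' Retains flux only where `qc_flag == 0`; rows with flag 1 or 2 have their
#' flux invalidated (the flag itself is kept). Removal counts per season are
#' available via [qc_report()].
#'
#' @param table A flux table with `qc_flag`.
#' @return The table with low-quality flux set `NA` and the raw series kept
#'   in `f_c_raw`.
#' @export
screen_qc_flags <- function(table) {
  stopifnot("qc_flag" %in% names(table))
  remove_flux(table, table$qc_flag != 0L, "quality control")
}

#' Diurnal-quantile (distributional) outlier mask
#'
#' Splits the valid flux into 48 time-of-day bins and flags values outside
#' `[Q1 - k IQR, Q3 + k IQR]` within their bin (the boxplot rule). Bins with
#' fewer than `min_bin` valid values flag nothing.
#'
#' @param table A flux table.
#' @param k IQR multiplier (default 1.5).
#' @param min_bin Minimum valid values a bin needs before it can flag.
#' @return Logical vector, `TRUE` where the record is an outlier.
#' @export
diurnal_quantile_outliers <- function(table, k = 1.5, min_bin = 10) {
  slot <- floor(decimal_hour(table$timestamp) * 2) %% 48
  f <- table$f_c
  mask <- rep(FALSE, length(f))
  thin <- 0L
  for (s in unique(slot)) {
    idx <- which(slot == s & !is.na(f))
    if (length(idx) < min_bin) {
      if (length(idx)) thin <- thin + 1L
      next
    }
    q <- quantile(f[idx], c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    mask[idx] <- f[idx] < q[1] - k * iqr | f[idx] > q[2] + k * iqr
  }
  if (thin > 0L) {
    message(thin, " time-of-day bin(s) below the minimum occupancy of ",
      min_bin, "; no outliers flagged there."
    )
  }
  mask
}

#' Median spike-filter mask
#'
#' For each window of `cfg$window_days` days (daytime and nighttime records
#' processed separately when `cfg$split_day_night`), computes the
#' double-difference `D_i = (F_i - F_{i-1}) - (F_{i+1} - F_i)` over
#' consecutive valid flux triples and flags record `i` when `D_i` falls
#' outside `Md +/- z * MAD / 0.6745`, with `Md` and `MAD` the window median
#' and median absolute deviation of `D`. A triple is three consecutive
#' half-hour slots, all valid: records at window boundaries or beside missing
#' slots have no `D_i` and cannot be flagged. Exceedances are eliminated one
#' at a time (worst first) with the window statistics recomputed, so the
#' filter is idempotent on its own output. A window whose MAD is zero keeps
#' records with `D_i == Md` and flags the rest; a window with fewer than
#' three valid points flags nothing.
#'
#' @param table A time-ordered flux table (with `is_day` when splitting).
#' @param cfg A [spike_config()].
#' @return Logical vector, `TRUE` where the record is a spike.
#' @export
spike_filter <- function(table, cfg = spike_config()) {
  f <- table$f_c
  n <- length(f)
  date0 <- as.Date(format(table$timestamp[1], "%Y-%m-%d"))
  day_index <- as.integer(
    as.Date(format(table$timestamp, "%Y-%m-%d")) - date0
  )
  block <- day_index %/% cfg$window_days
  groups <- if (cfg$split_day_night && "is_day" %in% names(table)) {
    table$is_day
  } else {
    rep(TRUE, n)
  }
  mask <- rep(FALSE, n)
  for (g in unique(groups)) {
    for (b in unique(block)) {
      idx <- which(groups == g & block == b & !is.na(f))
      flagged <- spike_scan_window(f[idx], idx, cfg)
      mask[flagged] <- TRUE
    }
  }
  mask
}

# One window of the spike filter. D_i exists only for records whose previous
# and next half-hour slots are both valid in the same window ("consecutive
# valid triples"); records at holes or boundaries are unflaggable. The worst
# exceedance is dropped and the window statistics recomputed until clean, so
# removing a spike never manufactures exceedances at its neighbours.
spike_scan_window <- function(v, pos, cfg) {
  flagged <- integer(0)
  active <- rep(TRUE, length(v))
  repeat {
    keep <- which(active)
    if (length(keep) < 3) break
    left <- match(pos[keep] - 1L, pos[keep], nomatch = NA)
    right <- match(pos[keep] + 1L, pos[keep], nomatch = NA)
    has_d <- !is.na(left) & !is.na(right)
    if (sum(has_d) < 1) break
    j <- which(has_d)
    d <- (v[keep[j]] - v[keep[left[j]]]) - (v[keep[right[j]]] - v[keep[j]])
    md <- median(d)
    mad <- median(abs(d - md))
    dev <- abs(d - md)
    exceed <- if (mad == 0) dev > 0 else dev >= cfg$z * mad / cfg$mad_scale
    if (!any(exceed)) break
    worst <- j[which.max(ifelse(exceed, dev, -Inf))]
    flagged <- c(flagged, pos[keep[worst]])
    active[keep[worst]] <- FALSE
  }
  sort(flagged)
}

#' Flag and remove diurnal-quantile outliers
#'
#' @inheritParams diurnal_quantile_outliers
#' @return The table with flagged flux set `NA` (stage "distributional
#'   cleaning" in [qc_report()]).
#' @export
screen_diurnal_outliers <- function(table, k = 1.5, min_bin = 10) {
  remove_flux(
    table, diurnal_quantile_outliers(table, k, min_bin),
    "distributional cleaning"
  )
}

#' Flag and remove spikes
#'
#' @inheritParams spike_filter
#' @return The table with spikes set `NA` (stage "filtering" in
#'   [qc_report()]).
#' @export
screen_spikes <- function(table, cfg = spike_config()) {
  remove_flux(table, spike_filter(table, cfg), "filtering")
}

#' Summary statistics of the missing-data runs
#'
#' Identifies maximal runs of consecutive missing flux and reports their
#' count, total share, mean/maximum length, and the number of runs strictly
#' longer than 24 h.
#'
#' @param table A flux table.
#' @return A `gap_stats` list with `n_missing`, `missing_fraction`,
#'   `mean_gap_hours`, `n_gaps_gt_24h`, `max_gap_days`, `run_lengths`
#'   (half-hour slots).
#' @export
gap_statistics <- function(table) {
  miss <- is.na(table$f_c)
  r <- rle(miss)
  runs <- r$lengths[r$values]
  structure(
    list(
      n_missing = sum(miss),
      missing_fraction = mean(miss),
      mean_gap_hours = if (length(runs)) mean(runs) / 2 else 0,
      n_gaps_gt_24h = sum(runs / 2 > 24),
      max_gap_days = if (length(runs)) max(runs) / 48 else 0,
      run_lengths = as.integer(runs)
    ),
    class = "gap_stats"
  )
}

#' @export
print.gap_stats <- function(x, ...) {
  cat("<gap_stats>\n")
  cat(sprintf(
    "  %d missing half-hours (%.1f%%) in %d runs; mean %.1f h, max %.1f d; %d runs > 24 h\n",
    x$n_missing, 100 * x$missing_fraction, length(x$run_lengths),
    x$mean_gap_hours, x$max_gap_days, x$n_gaps_gt_24h
  ))
  invisible(x)
}

#' @export
tidy.gap_stats <- function(x, ...) {
  tibble::tibble(
    n_missing = x$n_missing,
    missing_fraction = x$missing_fraction,
    n_gaps = length(x$run_lengths),
    mean_gap_hours = x$mean_gap_hours,
    n_gaps_gt_24h = x$n_gaps_gt_24h,
    max_gap_days = x$max_gap_days
  )
}
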