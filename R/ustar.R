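# Seasonal nighttime friction-velocity threshold detection (45-level Wilcoxon
# scan), low-turbulence screening, and standardized-major-axis comparison of
# seasonal roughness.

#' Detect the nighttime u* threshold by a 45-level Wilcoxon scan
#'
#' Valid nighttime records are sorted by u* into `n_levels` equal-count
#' classes (sizes differ by at most one). Scanning upward, each class's flux
#' distribution is compared with the next higher class by a two-sample
#' Wilcoxon test; the threshold is the mean u* of the first class whose
#' comparison, and the `k_consecutive - 1` comparisons above it, are all
#' non-significant (`p >= alpha`). If no class qualifies the highest class
#' mean is returned with a warning.
#'
#' @param night A flux table subset of nighttime records with valid `f_c`
#'   and `u_star` (rows with either missing are dropped).
#' @param n_levels Number of u* classes (default 45).
#' @param alpha Significance level of each pairwise test (default 0.05).
#' @param k_consecutive Number of successive non-significant forward
#'   comparisons required (default 3).
#' @return A `ustar_result` list: `threshold` (m s^-1), `level_table`
#'   (per-class mean u*, mean flux, count, Wilcoxon p against the next
#'   class), `n_levels`, and the scan parameters.
#' @export
detect_ustar_threshold <- function(night, n_levels = 45, alpha = 0.05,
                                   k_consecutive = 3) {
  ok <- !is.na(night$f_c) & !is.na(night$u_star)
  u <- night$u_star[ok]
  f <- night$f_c[ok]
  if (length(u) < 2 * n_levels) {
    stop(sprintf(
      "insufficient data: %d valid nighttime records for %d u* levels.",
      length(u), n_levels
    ), call. = FALSE)
  }
  ord <- order(u)
  u <- u[ord]
  f <- f[ord]
  # equal-count classes whose sizes differ by at most one
  level <- as.integer(cut(seq_along(u), breaks = n_levels, labels = FALSE))
  mean_u <- as.numeric(tapply(u, level, mean))
  mean_f <- as.numeric(tapply(f, level, mean))
  n_lev <- as.integer(tapply(f, level, length))
  lt <- tibble::tibble(
    level = seq_len(n_levels),
    mean_ustar = mean_u,
    mean_flux = mean_f,
    n = n_lev,
    p_next = NA_real_
  )
  for (i in seq_len(n_levels - 1)) {
    lt$p_next[i] <- suppressWarnings(
      wilcox.test(f[level == i], f[level == i + 1], exact = NULL)$p.value
    )
  }
  nonsig <- lt$p_next >= alpha
  nonsig[is.na(nonsig)] <- TRUE
  k <- min(k_consecutive, n_levels - 1)
  run_ok <- vapply(seq_len(n_levels - k), function(i) {
    all(nonsig[i:(i + k - 1)])
  }, logical(1))
  if (any(run_ok)) {
    sel <- which(run_ok)[1]
    threshold <- lt$mean_ustar[sel]
  } else {
    sel <- n_levels
    threshold <- lt$mean_ustar[n_levels]
    warning(
      "no u* class passed ", k_consecutive,
      " consecutive non-significant comparisons; ",
      "returning the highest class mean.",
      call. = FALSE
    )
  }
  structure(
    list(
      threshold = threshold, selected_level = sel, level_table = lt,
      n_levels = n_levels, alpha = alpha, k_consecutive = k_consecutive,
      n_records = length(u)
    ),
    class = "ustar_result"
  )
}

#' @export
print.ustar_result <- function(x, ...) {
  cat("<ustar_result>\n")
  cat(sprintf(
    "  threshold %.3f m s-1 (class %d of %d; %d nighttime records)\n",
    x$threshold, x$selected_level, x$n_levels, x$n_records
  ))
  invisible(x)
}

#' @export
tidy.ustar_result <- function(x, ...) x$level_table

#' @export
glance.ustar_result <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold, selected_level = x$selected_level,
    n_levels = x$n_levels, n_records = x$n_records, alpha = x$alpha
  )
}

#' Detect seasonal u* thresholds (growing vs non-growing)
#'
#' Convenience wrapper running [detect_ustar_threshold()] independently on the
#' growing-season and non-growing-season nighttime records.
#'
#' @param table A flux table with `is_day` and `is_growing` labels.
#' @inheritParams detect_ustar_threshold
#' @return Named list of `ustar_result` (`growing`, `nongrowing`).
#' @export
detect_seasonal_ustar <- function(table, n_levels = 45, alpha = 0.05,
                                  k_consecutive = 3) {
  night <- dplyr::filter(table, !.data$is_day)
  list(
    growing = detect_ustar_threshold(
      dplyr::filter(night, .data$is_growing), n_levels, alpha, k_consecutive
    ),
    nongrowing = detect_ustar_threshold(
      dplyr::filter(night, !.data$is_growing), n_levels, alpha, k_consecutive
    )
  )
}

#' Invalidate nighttime flux below the seasonal u* threshold
#'
#' Nighttime records whose friction velocity falls below their season's
#' threshold have flux set `NA` (stage "u* screening" in [qc_report()]);
#' daytime records are untouched.
#'
#' @param table A flux table with `is_day` and `is_growing` labels.
#' @param thresholds Named numeric (`growing`, `nongrowing`) in m s^-1, or a
#'   list of `ustar_result` as returned by [detect_seasonal_ustar()].
#' @return The screened table.
#' @export
apply_ustar_filter <- function(table, thresholds) {
  if (is.list(thresholds) && !is.numeric(thresholds)) {
    thresholds <- vapply(thresholds, function(r) r$threshold, numeric(1))
  }
  thr <- ifelse(table$is_growing,
    thresholds[["growing"]], thresholds[["nongrowing"]]
  )
  mask <- !table$is_day & !is.na(table$u_star) & table$u_star < thr
  remove_flux(table, mask, "u* screening")
}

# ---- standardized major axis regression -------------------------------------

#' Standardized major axis (SMA) line fit
#'
#' Fits the SMA line, which treats both variables as subject to error:
#' `slope = sign(r) * SD(y) / SD(x)`, elevation through the means. The slope
#' confidence interval follows the standard SMA theory
#' (`B = F(1, n-2) * (1 - r^2) / (n - 2)`, CI `= slope * (sqrt(B + 1) +/-
#' sqrt(B))`); the correlation test is the usual Pearson t-test.
#'
#' @param x,y Paired numeric vectors (pairs with any `NA` are dropped).
#' @param alpha Confidence level complement for the intervals.
#' @return An `sma_fit` list: `slope`, `elevation`, `slope_ci`,
#'   `elevation_ci`, `r_squared`, `p_value` (H0: uncorrelated), `n`.
#' @export
sma_fit <- function(x, y, alpha = 0.05) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("SMA fit needs at least 3 paired values.", call. = FALSE)
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0) {
    stop("degenerate SMA fit: zero variance in x or y.", call. = FALSE)
  }
  r <- cor(x, y)
  slope <- sign2(r) * sy / sx
  elevation <- mean(y) - slope * mean(x)
  bstat <- stats::qf(1 - alpha, 1, n - 2) * (1 - r^2) / (n - 2)
  slope_ci <- slope * c(sqrt(bstat + 1) - sqrt(bstat), sqrt(bstat + 1) + sqrt(bstat))
  slope_ci <- sort(slope_ci)
  # elevation SE: residual variance of y - slope*x plus slope-uncertainty term
  resid_var <- var(y - slope * x)
  se_slope <- abs(slope) * sqrt((1 - r^2) / (n - 2))
  se_elev <- sqrt(resid_var / n + mean(x)^2 * se_slope^2)
  tcrit <- qt(1 - alpha / 2, n - 2)
  elevation_ci <- elevation + c(-1, 1) * tcrit * se_elev
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  structure(
    list(
      slope = slope, elevation = elevation,
      slope_ci = slope_ci, elevation_ci = elevation_ci,
      r_squared = r^2, p_value = p, n = n, alpha = alpha
    ),
    class = "sma_fit"
  )
}

sign2 <- function(r) if (r < 0) -1 else 1

#' @export
print.sma_fit <- function(x, ...) {
  cat("<sma_fit>\n")
  cat(sprintf(
    "  slope %.4g [%.4g, %.4g]; elevation %.4g [%.4g, %.4g]\n",
    x$slope, x$slope_ci[1], x$slope_ci[2],
    x$elevation, x$elevation_ci[1], x$elevation_ci[2]
  ))
  cat(sprintf("  r^2 = %.3f, p = %.3g, n = %d\n", x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.sma_fit <- function(x, ...) {
  tibble::tibble(
    term = c("elevation", "slope"),
    estimate = c(x$elevation, x$slope),
    conf.low = c(x$elevation_ci[1], x$slope_ci[1]),
    conf.high = c(x$elevation_ci[2], x$slope_ci[2])
  )
}

#' @export
glance.sma_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, p.value = x$p_value, nobs = x$n
  )
}

#' Likelihood-ratio test for a common SMA slope in two groups
#'
#' For SMA slope `b`, the residual axis `y - b x` and fitted axis `y + b x`
#' are uncorrelated exactly at the group's own SMA slope. The common-slope
#' estimate minimizes `-sum(n_g * log(1 - r_g(b)^2))` over `b`, where
#' `r_g(b)` is the residual/fitted-axis correlation in group `g`; the
#' minimized value is the likelihood-ratio statistic, compared against a
#' chi-squared distribution with one degree of freedom.
#'
#' @param xa,ya Paired series of the first group.
#' @param xb,yb Paired series of the second group.
#' @return A list with `statistic`, `df`, `p_value`, `common_slope`, and the
#'   two group slopes.
#' @export
sma_common_slope_test <- function(xa, ya, xb, yb) {
  fa <- sma_fit(xa, ya)
  fb <- sma_fit(xb, yb)
  groups <- list(
    list(x = xa[complete.cases(xa, ya)], y = ya[complete.cases(xa, ya)]),
    list(x = xb[complete.cases(xb, yb)], y = yb[complete.cases(xb, yb)])
  )
  negll <- function(b) {
    sum(vapply(groups, function(g) {
      r <- cor(g$y - b * g$x, g$y + b * g$x)
      -length(g$x) * log(max(1 - r^2, .Machine$double.eps))
    }, numeric(1)))
  }
  lo <- min(fa$slope, fb$slope)
  hi <- max(fa$slope, fb$slope)
  pad <- max(hi - lo, 1e-8) # the common slope lies between the group slopes
  opt <- optimize(negll, interval = c(lo - pad, hi + pad))
  stat <- opt$objective
  list(
    statistic = stat, df = 1L, p_value = pchisq(stat, 1, lower.tail = FALSE),
    common_slope = opt$minimum, slope_a = fa$slope, slope_b = fb$slope
  )
}
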