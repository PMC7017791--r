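# Random-uncertainty characterization of the gap-filled series (Laplace
# residual law, Kendall tau by stratum, heteroscedastic sigma model) and the
# stratified residual bootstrap of the annual/seasonal carbon sums with bias
# and 95% confidence intervals, plus multi-method fusion.

#' Six-way uncertainty stratum of each record
#'
#' Strata follow season x day/night, with daytime further split at incident
#' radiation 400 W m^-2 (`Rd <= 400` vs `Rd > 400`), giving six strata.
#'
#' @param table A flux table with `is_growing`, `is_day`, `rd`.
#' @return A factor with the six stratum labels.
#' @export
flux_strata <- function(table) {
  if (any(table$is_day & is.na(table$rd))) {
    stop("daytime rows with missing incident radiation cannot be stratified.",
      call. = FALSE
    )
  }
  season <- ifelse(table$is_growing, "growing", "nongrowing")
  part <- ifelse(!table$is_day, "night",
    ifelse(table$rd <= 400, "day_rd_le_400", "day_rd_gt_400")
  )
  factor(
    paste(season, part, sep = "."),
    levels = c(
      "growing.day_rd_le_400", "growing.day_rd_gt_400", "growing.night",
      "nongrowing.day_rd_le_400", "nongrowing.day_rd_gt_400",
      "nongrowing.night"
    )
  )
}

#' Prediction residuals with stratum labels
#'
#' `residual = prediction - observation` on rows with valid observed flux;
#' gap rows carry no residual.
#'
#' @param predictions Numeric predictions aligned with `table` rows.
#' @param observations Observed flux aligned with `table` rows (`NA` = gap).
#' @param table The flux table supplying `is_growing`, `is_day`, `rd`.
#' @return A `residual_set` tibble: `row`, `prediction`, `observed`,
#'   `residual`, `stratum`.
#' @export
compute_residuals <- function(predictions, observations, table) {
  stopifnot(
    length(predictions) == nrow(table),
    length(observations) == nrow(table)
  )
  valid <- which(!is.na(observations) & !is.na(predictions))
  out <- tibble::tibble(
    row = valid,
    prediction = predictions[valid],
    observed = observations[valid],
    residual = predictions[valid] - observations[valid],
    stratum = flux_strata(table[valid, ])
  )
  class(out) <- c("residual_set", class(out))
  out
}

#' Laplace (double-exponential) fit of the residuals
#'
#' Maximum-likelihood fit: location = sample median, scale = mean absolute
#' deviation from it. Reports the sample excess kurtosis (3 for an exact
#' Laplace) and a Wilcoxon rank-sum goodness-of-fit p-value against a seeded
#' fitted-Laplace reference sample of equal size.
#'
#' @param residuals Numeric vector, `n >= 10`.
#' @param seed Seed of the reference sample (reproducible test).
#' @return A `laplace_fit`: `location`, `scale`, `excess_kurtosis`,
#'   `gof_p_value`, `n`.
#' @export
fit_laplace <- function(residuals, seed = 1L) {
  residuals <- residuals[!is.na(residuals)]
  n <- length(residuals)
  if (n < 10) stop("Laplace fit needs at least 10 residuals.", call. = FALSE)
  if (sd(residuals) == 0) {
    stop("degenerate residuals: all values equal.", call. = FALSE)
  }
  mu <- median(residuals)
  b <- mean(abs(residuals - mu))
  set.seed(substream_seed(seed, 31L))
  ref <- rlaplace(n, mu, b)
  p <- suppressWarnings(wilcox.test(residuals, ref)$p.value)
  structure(
    list(
      location = mu, scale = b,
      excess_kurtosis = excess_kurtosis(residuals),
      gof_p_value = p, n = n, sample = residuals
    ),
    class = "laplace_fit"
  )
}

excess_kurtosis <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2 - 3
}

#' @export
print.laplace_fit <- function(x, ...) {
  cat("<laplace_fit>\n")
  cat(sprintf(
    "  location %.4g, scale %.4g, excess kurtosis %.2f, rank-sum GOF p = %.3f (n = %d)\n",
    x$location, x$scale, x$excess_kurtosis, x$gof_p_value, x$n
  ))
  invisible(x)
}

#' @export
glance.laplace_fit <- function(x, ...) {
  tibble::tibble(
    location = x$location, scale = x$scale,
    excess_kurtosis = x$excess_kurtosis, gof_p_value = x$gof_p_value,
    nobs = x$n
  )
}

#' Kendall's tau between predictions and residuals, per stratum
#'
#' Tau near zero means the residuals carry no structural signal from the
#' model; tie-corrected tau (tau-b) with a two-sided test per stratum.
#'
#' @param residual_set A [compute_residuals()] result.
#' @param min_n Strata with fewer pairs are omitted (with a message).
#' @return A tibble: `stratum`, `tau`, `p_value`, `n`.
#' @export
kendall_tau_by_stratum <- function(residual_set, min_n = 3) {
  split_rs <- split(residual_set, residual_set$stratum)
  out <- purrr::map(names(split_rs), function(s) {
    d <- split_rs[[s]]
    if (nrow(d) < min_n) {
      if (nrow(d) > 0) {
        message("stratum ", s, " has ", nrow(d), " < ", min_n,
          " pairs; omitted."
        )
      }
      return(NULL)
    }
    ct <- suppressWarnings(
      cor.test(d$prediction, d$residual, method = "kendall", exact = FALSE)
    )
    tibble::tibble(
      stratum = s, tau = unname(ct$estimate), p_value = ct$p.value,
      n = nrow(d)
    )
  })
  dplyr::bind_rows(out)
}

#' Heteroscedastic error law sigma(eps) = a + b |F_C|
#'
#' Partitions `|prediction|` into equal-count bins (default 20), computes the
#' residual SD within each bin, and regresses bin SD on the bin's mean
#' absolute flux by ordinary least squares.
#'
#' @param predictions,residuals Paired numeric vectors.
#' @param n_bins Number of equal-count bins.
#' @param min_bin Bins with fewer values are dropped.
#' @return A `sigma_model`: `a` (intercept, umol m^-2 s^-1), `b` (slope),
#'   `r_squared`, and the `bin_table` the fit is reproducible from.
#' @export
fit_sigma_model <- function(predictions, residuals, n_bins = 20, min_bin = 5) {
  keep <- complete.cases(predictions, residuals)
  af <- abs(predictions[keep])
  r <- residuals[keep]
  if (length(r) < 50) {
    stop("sigma model needs at least 50 residuals.", call. = FALSE)
  }
  br <- unique(quantile(af, seq(0, 1, length.out = n_bins + 1), names = FALSE))
  bin <- cut(af, br, include.lowest = TRUE, labels = FALSE)
  bt <- tibble::tibble(abs_flux = af, residual = r, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      center = mean(.data$abs_flux),
      sd_resid = sd(.data$residual),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= min_bin)
  if (nrow(bt) < 5) {
    stop("fewer than 5 usable |F_C| bins; cannot fit the sigma model.",
      call. = FALSE
    )
  }
  fit <- lm(sd_resid ~ center, data = bt)
  structure(
    list(
      a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
      r_squared = summary(fit)$r.squared,
      bin_table = bt, n = length(r), n_bins = n_bins
    ),
    class = "sigma_model"
  )
}

#' @export
print.sigma_model <- function(x, ...) {
  cat("<sigma_model>\n")
  cat(sprintf(
    "  sd(eps) = %.4f + %.4f |F_C| (r^2 = %.3f; %d bins, n = %d)\n",
    x$a, x$b, x$r_squared, nrow(x$bin_table), x$n
  ))
  invisible(x)
}

#' @export
tidy.sigma_model <- function(x, ...) x$bin_table

#' @export
glance.sigma_model <- function(x, ...) {
  tibble::tibble(
    a = x$a, b = x$b, r.squared = x$r_squared, nobs = x$n,
    n_bins = nrow(x$bin_table)
  )
}

#' Annual and seasonal carbon sums of a complete filled series
#'
#' Converts each half-hour flux to g C m^-2 and sums over the year and over
#' the growing / non-growing seasons (negative = net uptake).
#'
#' @param filled Complete numeric flux series, umol m^-2 s^-1 (no `NA`).
#' @param is_growing Logical season label per slot.
#' @return One-row tibble: `annual`, `growing`, `nongrowing` (g C m^-2).
#' @export
annual_sum <- function(filled, is_growing) {
  if (anyNA(filled)) {
    stop("filled series is incomplete: ", sum(is.na(filled)),
      " missing slot(s).",
      call. = FALSE
    )
  }
  stopifnot(length(filled) == length(is_growing))
  g <- halfhour_to_gC(filled)
  tibble::tibble(
    annual = sum(g),
    growing = sum(g[is_growing]),
    nongrowing = sum(g[!is_growing])
  )
}

#' Cumulative carbon-exchange trajectory
#'
#' @param filled Complete numeric flux series.
#' @param timestamp Matching timestamps.
#' @return Tibble `timestamp`, `cum_gC`; the final value equals the annual
#'   sum.
#' @export
cumulative_exchange <- function(filled, timestamp) {
  tibble::tibble(timestamp = timestamp, cum_gC = cumsum(halfhour_to_gC(filled)))
}

#' Stratified residual bootstrap of the annual-sum bias and spread
#'
#' For each of `n_reps` replicates, every slot of the year draws (with
#' replacement) a residual from its stratum's pool; the unit-converted draws
#' are summed into a replicate bias of the annual carbon sum. Reported are
#' the mean bias with its 2.5%/97.5% percentile interval (all slots resampled,
#' one extraction per half-hour of the year), and the annual/seasonal sums
#' with their mean, SD and 95% percentile interval taken over the replicate
#' distribution of (point sum + replicate bias applied to gap-filled slots
#' only). Observed slots contribute no gap-filling variance, so only the
#' filled slots are perturbed when describing the uncertainty of the sums
#' themselves; the all-slot bias replicates are reported separately as the
#' bias diagnostic.
#'
#' @param residual_set A [compute_residuals()] result (the pools).
#' @param table Full-year flux table supplying every slot's stratum and the
#'   gap mask (`is.na(f_c)`).
#' @param filled Complete filled flux series aligned with `table`.
#' @param n_reps Bootstrap replicates (default 1000).
#' @param seed Integer seed; identical seeds give identical summaries.
#' @param method Method name carried into the summary.
#' @return A `bootstrap_summary`.
#' @export
bootstrap_bias <- function(residual_set, table, filled, n_reps = 1000,
                           seed = 1L, method = "unknown") {
  strata_all <- flux_strata(table)
  pools <- split(residual_set$residual, residual_set$stratum)
  counts <- table(strata_all)
  empty <- names(counts)[counts > 0 &
    vapply(pools[names(counts)], length, 1L) == 0]
  if (length(empty)) {
    stop("no residuals available for stratum: ",
      paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  filled_mask <- is.na(table$f_c)
  grow <- table$is_growing
  set.seed(substream_seed(seed, 41L))

  bias_all <- numeric(n_reps)
  bias_filled <- numeric(n_reps)
  bias_grow_filled <- numeric(n_reps)
  bias_nongrow_filled <- numeric(n_reps)
  bias_grow_all <- numeric(n_reps)
  bias_nongrow_all <- numeric(n_reps)
  for (s in levels(strata_all)) {
    idx <- which(strata_all == s)
    if (!length(idx)) next
    pool <- halfhour_to_gC(pools[[s]])
    draws <- matrix(
      sample(pool, length(idx) * n_reps, replace = TRUE),
      nrow = length(idx)
    )
    tot <- colSums(draws)
    bias_all <- bias_all + tot
    gsel <- grow[idx]
    bias_grow_all <- bias_grow_all + colSums(draws[gsel, , drop = FALSE])
    bias_nongrow_all <- bias_nongrow_all + colSums(draws[!gsel, , drop = FALSE])
    fsel <- filled_mask[idx]
    bias_filled <- bias_filled + colSums(draws[fsel, , drop = FALSE])
    bias_grow_filled <- bias_grow_filled +
      colSums(draws[fsel & gsel, , drop = FALSE])
    bias_nongrow_filled <- bias_nongrow_filled +
      colSums(draws[fsel & !gsel, , drop = FALSE])
  }

  point <- annual_sum(filled, grow)
  qs <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  # the annual/seasonal sums are described by the replicate distribution of
  # (point sum + filled-slot bias): its mean, SD and percentile interval
  plus_q <- function(point_sum, bias) point_sum + qs(bias)
  seasonal <- tibble::tibble(
    season = c("growing", "nongrowing"),
    mean = c(
      point$growing + mean(bias_grow_filled),
      point$nongrowing + mean(bias_nongrow_filled)
    ),
    lower = c(
      plus_q(point$growing, bias_grow_filled)[1],
      plus_q(point$nongrowing, bias_nongrow_filled)[1]
    ),
    upper = c(
      plus_q(point$growing, bias_grow_filled)[2],
      plus_q(point$nongrowing, bias_nongrow_filled)[2]
    )
  )
  structure(
    list(
      method = method,
      point = point,
      annual_mean = point$annual + mean(bias_filled),
      annual_sd = sd(bias_filled),
      annual_ci = plus_q(point$annual, bias_filled),
      bias_mean = mean(bias_all),
      bias_ci = qs(bias_all),
      seasonal = seasonal,
      n_reps = n_reps, seed = as.integer(seed),
      modes = c(
        sums = "point sum + replicate bias over gap-filled slots only",
        bias = "all 17,520 slots resampled"
      )
    ),
    class = "bootstrap_summary"
  )
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap_summary: %s (%d reps)>\n", x$method, x$n_reps))
  cat(sprintf(
    "  annual sum %.2f +/- %.2f g C m-2; 95%% CI [%.2f, %.2f]\n",
    x$annual_mean, x$annual_sd, x$annual_ci[1], x$annual_ci[2]
  ))
  cat(sprintf(
    "  bias %.2f [%.2f, %.2f] g C m-2\n",
    x$bias_mean, x$bias_ci[1], x$bias_ci[2]
  ))
  invisible(x)
}

#' @export
glance.bootstrap_summary <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    annual_mean = x$annual_mean, annual_sd = x$annual_sd,
    annual_ci_lower = x$annual_ci[1], annual_ci_upper = x$annual_ci[2],
    bias_mean = x$bias_mean,
    bias_ci_lower = x$bias_ci[1], bias_ci_upper = x$bias_ci[2],
    n_reps = x$n_reps
  )
}

#' @export
tidy.bootstrap_summary <- function(x, ...) x$seasonal

#' Fuse annual sums across gap-filling methods
#'
#' The fused estimate is the arithmetic mean of the per-method annual sums;
#' its spread is the sample SD (n - 1 denominator) across methods.
#'
#' @param sums Numeric vector of per-method annual sums (>= 2), optionally
#'   named by method.
#' @return One-row tibble: `fused_mean`, `fused_sd`, `n_methods`.
#' @export
#' @examples
#' fuse_methods(c(
#'   ann = -159.91, gp = -178.25, rbf = -167.16,
#'   hlm = -156.95, mds = -155.21
#' ))
fuse_methods <- function(sums) {
  sums <- as.numeric(sums)
  if (length(sums) < 2) {
    stop("fusion needs at least 2 method sums.", call. = FALSE)
  }
  tibble::tibble(
    fused_mean = mean(sums), fused_sd = sd(sums), n_methods = length(sums)
  )
}
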