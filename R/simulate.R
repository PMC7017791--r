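# Synthetic full-year flux generator. Emulates the statistical structure the
# downstream analysis assumes: diurnal/seasonal NEE with growing-season daytime
# uptake and temperature-driven nighttime respiration, heteroscedastic Laplace
# noise sd(eps) = a + b|F_C|, heavy-tailed gap runs concentrated in the
# non-growing season, QC-flag contamination, and optional suppression of
# nighttime flux below a true u* threshold so threshold detection has signal.

#' Simulation parameters for a synthetic flux year
#'
#' Defaults are the package's reference study conditions: noise-law intercept
#' `sigma_a = 1.4` umol m^-2 s^-1 and slope `sigma_b = 0.08` (mid-range of the
#' per-method fits on real towers), 28% missing data in lognormal runs with a
#' mean of about 5.8 h and occasional multi-day windows in the non-growing
#' season, a third of surviving rows carrying non-zero QC flags, and true
#' nighttime u* thresholds of 0.12 (growing) / 0.10 (non-growing) m s^-1.
#'
#' @param seed Integer master seed; per-stage substreams are derived from it.
#' @param sigma_a,sigma_b Intercept (umol m^-2 s^-1) and slope of the
#'   heteroscedastic error law `sd(eps) = sigma_a + sigma_b * |F_C|`.
#' @param uptake_amplitude Peak gross daytime uptake, umol m^-2 s^-1.
#' @param respiration_base Respiration at 10 degC soil, umol m^-2 s^-1.
#' @param q10 Temperature sensitivity of respiration.
#' @param gap_fraction Target share of missing half-hours, in \[0, 1).
#' @param gap_length_law `list(meanlog, sdlog)` of the lognormal gap-run
#'   length distribution, in half-hour slots.
#' @param qc_bad_fraction Share of non-missing rows flagged 1 or 2.
#' @param ustar_threshold_true Named numeric, true nighttime u* thresholds
#'   (m s^-1) for `growing` and `nongrowing`.
#' @param roughness_inv Proportionality of u* to wind speed (inverse
#'   roughness index).
#' @param ustar_suppression Damp nighttime flux below the true threshold by
#'   `(u*/threshold)^suppression_exponent`, giving threshold detection signal.
#' @param suppression_exponent See `ustar_suppression`.
#' @return A `sim_params` list.
#' @export
sim_params <- function(seed = 1L,
                       sigma_a = 1.4,
                       sigma_b = 0.08,
                       uptake_amplitude = 12,
                       respiration_base = 0.8,
                       q10 = 1.9,
                       gap_fraction = 0.28,
                       gap_length_law = list(meanlog = 1.85, sdlog = 1.1),
                       qc_bad_fraction = 0.33,
                       ustar_threshold_true = c(growing = 0.12, nongrowing = 0.10),
                       roughness_inv = 0.10,
                       ustar_suppression = TRUE,
                       suppression_exponent = 1) {
  stopifnot(
    sigma_a > 0, sigma_b >= 0,
    gap_fraction >= 0, gap_fraction < 1,
    qc_bad_fraction >= 0, qc_bad_fraction <= 1,
    all(ustar_threshold_true >= 0), roughness_inv > 0
  )
  structure(
    list(
      seed = as.integer(seed), sigma_a = sigma_a, sigma_b = sigma_b,
      uptake_amplitude = uptake_amplitude,
      respiration_base = respiration_base, q10 = q10,
      gap_fraction = gap_fraction, gap_length_law = gap_length_law,
      qc_bad_fraction = qc_bad_fraction,
      ustar_threshold_true = ustar_threshold_true,
      roughness_inv = roughness_inv,
      ustar_suppression = isTRUE(ustar_suppression),
      suppression_exponent = suppression_exponent
    ),
    class = "sim_params"
  )
}

# Stage-specific substream: keeps the master seed below 2^31 while decoupling
# the random draws of the individual generator stages.
substream_seed <- function(seed, stage) {
  (as.integer(seed) * 131L + stage * 7919L) %% 2147483587L
}

#' Simulate half-hourly meteorological drivers for one year
#'
#' Produces a driver-only flux table: smooth seasonal plus diurnal air and
#' soil temperature with autocorrelated weather noise, incident radiation
#' consistent with the site solar geometry (shortwave component zero at
#' night) plus a thermal longwave floor, scattered radiation, humidity and
#' VPD anticorrelated with temperature, a 16-day NDVI course interpolated to
#' half-hours, heating degree days, and wind with u* proportional to it up to
#' multiplicative noise.
#'
#' @param site A [site_config()].
#' @param seed Integer seed.
#' @param params A [sim_params()] (roughness and threshold settings).
#' @return A flux table of drivers with `is_day`, `is_growing`, time
#'   encodings, `wind`, `u_star`, and an `sw` column holding the shortwave
#'   component of `rd` (used by the flux generator).
#' @export
simulate_drivers <- function(site = site_config(), seed = 1L,
                             params = sim_params(seed)) {
  set.seed(substream_seed(seed, 1L))
  tab <- halfhour_grid(site)
  tab <- add_time_encodings(tab)
  tab <- assign_seasons(tab, site)
  tab <- compute_day_night(tab, site)
  n <- nrow(tab)
  doy <- as.integer(format(tab$timestamp, "%j"))
  h <- decimal_hour(tab$timestamp)

  # potential shortwave from solar geometry: zero when the sun is down
  sp <- solar_parameters(doy, h)
  lat <- site$latitude * pi / 180
  tst_min <- 60 * h + sp$eqtime + 4 * site$longitude - 60 * site$utc_offset
  ha <- (tst_min / 4 - 180) * pi / 180
  cos_zen <- sin(lat) * sin(sp$decl) + cos(lat) * cos(sp$decl) * cos(ha)
  cloud <- 0.65 + 0.35 * stats::plogis(ar1_noise(n, 0.995, 1.2))
  sw <- 1000 * pmax(cos_zen, 0) * cloud

  seasonal <- -cos(2 * pi * (doy - 15) / 365)
  t_air <- 9 + 17 * seasonal + 7 * (-cos(2 * pi * (h - 14) / 24)) +
    ar1_noise(n, 0.98, 0.35)
  t_soil <- 9 + 15 * (-cos(2 * pi * (doy - 40) / 365)) +
    2.5 * (-cos(2 * pi * (h - 16) / 24)) + ar1_noise(n, 0.99, 0.12)
  rh <- pmin(pmax(78 - 1.6 * (t_air - 9) + ar1_noise(n, 0.97, 1.5), 10), 98)
  es <- 6.112 * exp(17.67 * t_air / (t_air + 243.5)) # hPa
  e <- es * rh / 100
  vpd <- es - e
  lw <- 250 + 3.5 * (t_air - 9) + ar1_noise(n, 0.98, 2)
  rd <- sw + lw
  ru <- 0.22 * rd + abs(ar1_noise(n, 0.9, 4))

  # 16-day NDVI knots, greening May-September, linearly interpolated
  knots <- seq(1, 380, by = 16)
  green <- exp(-((knots - 200) / 70)^2)
  ndvi_k <- 0.12 + 0.33 * green
  ndvi <- approx(knots, ndvi_k, xout = doy + h / 24, rule = 2)$y

  wind <- exp(0.75 - 0.1 * tab$is_growing + ar1_noise(n, 0.95, 0.16))
  u_star <- params$roughness_inv * wind * exp(rnorm(n, 0, 0.10))

  dplyr::mutate(tab,
    t_air = t_air, t_soil = t_soil, rh = rh, rd = rd, ru = ru,
    vpd = vpd, e = e, ndvi = ndvi, hdd = pmax(18 - t_air, 0),
    wind = wind, u_star = u_star, sw = sw
  )
}

ar1_noise <- function(n, phi, sd_innov) {
  as.numeric(stats::arima.sim(list(ar = phi), n, sd = sd_innov))
}

#' Noise-free NEE from simulated drivers
#'
#' Nighttime NEE is respiration `respiration_base * q10^((t_soil - 10) / 10)`
#' (always non-negative). Daytime NEE subtracts a gross-uptake term that
#' saturates in shortwave radiation and scales with an NDVI-derived canopy
#' factor, so growing-season middays are net uptake (negative).
#'
#' @param drivers Output of [simulate_drivers()].
#' @param params A [sim_params()].
#' @return Numeric vector of true NEE, umol m^-2 s^-1.
#' @export
simulate_nee <- function(drivers, params = sim_params()) {
  resp <- params$respiration_base * params$q10^((drivers$t_soil - 10) / 10)
  canopy <- pmin(pmax((drivers$ndvi - 0.10) / 0.35, 0), 1)
  sw <- drivers$sw %||% pmax(drivers$rd - 250, 0)
  uptake <- params$uptake_amplitude * canopy * sw / (sw + 250)
  resp - uptake
}

#' Heteroscedastic Laplace observation noise
#'
#' Draws independent Laplace noise per slot with standard deviation
#' `sigma_a + sigma_b * |truth|`; the Laplace scale is that SD divided by
#' sqrt(2), since the error law is stated for the standard deviation.
#'
#' @param truth Numeric vector of true flux.
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return `truth + eps`.
#' @export
add_noise <- function(truth, params = sim_params(), seed = 1L) {
  set.seed(substream_seed(seed, 2L))
  sd_eps <- params$sigma_a + params$sigma_b * abs(truth)
  truth + rlaplace(length(truth), 0, sd_eps / sqrt(2))
}

#' Laplace (double-exponential) random numbers
#'
#' @param n Count. @param mu Location. @param b Scale (> 0).
#' @return Numeric vector.
#' @export
rlaplace <- function(n, mu = 0, b = 1) {
  u <- runif(n) - 0.5
  mu - b * sign(u) * log(1 - 2 * abs(u))
}

#' Inject missing runs and QC-flag contamination
#'
#' Gap-run lengths are drawn from the configured lognormal law (heavy-tailed,
#' mean of order hours) until the target missing share is reached; runs longer
#' than 24 h are placed only in the non-growing season, shorter ones anywhere.
#' A further `qc_bad_fraction` of the surviving rows is flagged 1 or 2.
#'
#' @param table A flux table with an `f_c` column and `is_growing` labels.
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return The table with `f_c` set `NA` on gap rows and an integer `qc_flag`.
#' @export
inject_gaps <- function(table, params = sim_params(), seed = 1L) {
  if (params$gap_fraction >= 1) {
    stop("`gap_fraction` must be below 1.", call. = FALSE)
  }
  set.seed(substream_seed(seed, 3L))
  n <- nrow(table)
  target <- round(params$gap_fraction * n)
  missing <- rep(FALSE, n)
  if (target > 0) {
    law <- params$gap_length_law
    lengths <- integer(0)
    while (sum(lengths) < target) {
      draw <- pmax(1L, as.integer(round(
        stats::rlnorm(200, law$meanlog, law$sdlog)
      )))
      lengths <- c(lengths, draw)
    }
    lengths <- lengths[cumsum(lengths) <= target]
    short <- target - sum(lengths)
    if (short > 0) lengths <- c(lengths, as.integer(short))
    lengths <- sort(lengths, decreasing = TRUE)
    nongrow_ok <- !table$is_growing
    for (len in lengths) {
      allowed <- if (len > 48) nongrow_ok else rep(TRUE, n)
      placed <- FALSE
      for (try in 1:400) {
        s <- sample.int(n - len + 1L, 1L)
        span <- s:(s + len - 1L)
        if (allowed[s] && !any(missing[span])) {
          missing[span] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed) next
    }
  }
  qc <- integer(n)
  alive <- which(!missing)
  n_bad <- round(params$qc_bad_fraction * length(alive))
  if (n_bad > 0) {
    bad <- sample(alive, n_bad)
    qc[bad] <- sample(c(1L, 2L), n_bad, replace = TRUE)
  }
  out <- tibble::as_tibble(table)
  out$f_c[missing] <- NA_real_
  out$qc_flag <- qc
  out
}

#' Simulate one full synthetic flux year
#'
#' Runs the generator end to end: drivers, noise-free NEE (`truth`), optional
#' nighttime u*-suppression, heteroscedastic Laplace noise, gap injection and
#' QC flags (`observed`). Identical `seed` and `params` reproduce the year
#' bit for bit.
#'
#' @param site A [site_config()].
#' @param params A [sim_params()].
#' @return A `simulated_year` list with `truth`, `observed`, `params`, `site`.
#' @export
#' @examples
#' yr <- simulate_flux_year(site_config(), sim_params(seed = 7))
#' mean(is.na(yr$observed$f_c))
simulate_flux_year <- function(site = site_config(), params = sim_params()) {
  seed <- params$seed
  drivers <- simulate_drivers(site, seed, params)
  truth_fc <- simulate_nee(drivers, params)
  truth <- dplyr::mutate(drivers, f_c = truth_fc, qc_flag = 0L)

  signal <- truth_fc
  if (params$ustar_suppression) {
    thr <- ifelse(drivers$is_growing,
      params$ustar_threshold_true[["growing"]],
      params$ustar_threshold_true[["nongrowing"]]
    )
    damp <- pmin(drivers$u_star / thr, 1)^params$suppression_exponent
    signal <- ifelse(!drivers$is_day, signal * damp, signal)
  }
  observed <- dplyr::mutate(drivers, f_c = add_noise(signal, params, seed))
  observed <- inject_gaps(observed, params, seed)

  structure(
    list(truth = truth, observed = observed, params = params, site = site),
    class = "simulated_year"
  )
}

#' @export
print.simulated_year <- function(x, ...) {
  cat("<simulated_year>\n")
  cat(sprintf(
    "  %d half-hours of %d; %.1f%% missing; %.1f%% flagged > 0\n",
    nrow(x$observed), x$site$year,
    100 * mean(is.na(x$observed$f_c)),
    100 * mean(x$observed$qc_flag != 0, na.rm = TRUE)
  ))
  cat(sprintf(
    "  truth annual sum: %.1f g C m-2\n",
    sum(halfhour_to_gC(x$truth$f_c))
  ))
  invisible(x)
}
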