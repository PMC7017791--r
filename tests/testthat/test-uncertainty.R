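# Residual characterization, error law, annual sums, stratified bootstrap,
# fusion.

test_that("residual strata follow season x day/night x radiation", {
  g <- halfhour_grid(site_config())[1:6, ]
  tab <- dplyr::mutate(g,
    is_growing = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    is_day = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    rd = c(600, 400, 300, 100, 500, 250),
    f_c = 1:6
  )
  rs <- compute_residuals(rep(2, 6), tab$f_c, tab)
  expect_identical(
    as.character(rs$stratum),
    c(
      "growing.day_rd_gt_400", "growing.day_rd_le_400", "growing.night",
      "nongrowing.day_rd_le_400", "nongrowing.day_rd_gt_400",
      "nongrowing.night"
    )
  )
  expect_equal(rs$residual, 2 - (1:6))
  # perfect predictions give all-zero residuals
  expect_true(all(compute_residuals(tab$f_c, tab$f_c, tab)$residual == 0))
  # gap rows carry no residual
  tab$f_c[2] <- NA
  expect_equal(nrow(compute_residuals(rep(2, 6), tab$f_c, tab)), 5)
  # missing radiation on a daytime row is an error
  tab$rd[1] <- NA
  expect_error(compute_residuals(rep(2, 6), tab$f_c, tab), "radiation")
})

test_that("Laplace fit matches the closed-form MLE and kurtosis oracle", {
  f <- fit_laplace(c(-1, 0, 1, -1, 0, 1, -1, 0, 1, 0))
  expect_equal(f$location, 0)
  expect_equal(f$scale, 0.6)
  # for the 3-point sample the MLE is median 0, scale mean|x| = 2/3
  x3 <- rep(c(-1, 0, 1), 5)
  expect_equal(fit_laplace(x3)$scale, 2 / 3)
  # seeded Laplace sample: excess kurtosis ~ 3, GOF test passes
  big <- rlaplace(50000, 0, 1)
  fb <- fit_laplace(big, seed = 2)
  expect_equal(fb$excess_kurtosis, 3, tolerance = 0.15)
  expect_gt(fb$gof_p_value, 0.01)
  # a Gaussian sample is flat by comparison
  set.seed(3)
  fg <- fit_laplace(rnorm(50000), seed = 3)
  expect_equal(fg$excess_kurtosis, 0, tolerance = 0.1)
  expect_error(fit_laplace(rep(1, 20)), "degenerate")
})

test_that("Kendall tau per stratum matches brute-force pair counting", {
  brute_tau <- function(x, y) {
    s <- 0
    n <- length(x)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
      }
    }
    s / choose(n, 2)
  }
  g <- halfhour_grid(site_config())[1:4, ]
  tab <- dplyr::mutate(g,
    is_growing = TRUE, is_day = FALSE, rd = 0,
    f_c = c(2, 3.5, 2.5, 3) # tie-free residuals so tau-a equals tau-b
  )
  pred <- c(1, 2, 3, 4)
  rs <- compute_residuals(pred, tab$f_c, tab)
  # tau between prediction and residual, as tabulated
  kt <- kendall_tau_by_stratum(rs)
  expect_equal(kt$tau, brute_tau(rs$prediction, rs$residual))
  expect_equal(kt$tau, 2 / 3)
  # x = 1:4 vs y = (1,3,2,4): 5 concordant, 1 discordant -> 2/3
  expect_equal(brute_tau(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3)
  # identical and reversed orderings
  expect_equal(brute_tau(1:5, 1:5), 1)
  expect_equal(brute_tau(1:5, 5:1), -1)
})

test_that("sigma model recovers the generating error law", {
  set.seed(12)
  n <- 10000
  pred <- runif(n, 0, 20)
  # homoscedastic residuals: a ~ 1.5, b ~ 0
  r0 <- rnorm(n, 0, 1.5)
  s0 <- fit_sigma_model(pred, r0)
  expect_equal(s0$a, 1.5, tolerance = 0.07)
  expect_equal(s0$b, 0, tolerance = 0.02) # absolute via small expected slope
  # generated with a = 1.5, b = 0.1: recovery within 10%
  r1 <- rnorm(n, 0, 1.5 + 0.1 * pred)
  s1 <- fit_sigma_model(pred, r1)
  expect_equal(s1$a, 1.5, tolerance = 0.1)
  expect_equal(s1$b, 0.1, tolerance = 0.1)
  # linearity: scaling the residuals scales both coefficients
  s2 <- fit_sigma_model(pred, 2 * r1)
  expect_equal(s2$a, 2 * s1$a, tolerance = 1e-8)
  expect_equal(s2$b, 2 * s1$b, tolerance = 1e-8)
  # row-order invariance
  o <- sample.int(n)
  s3 <- fit_sigma_model(pred[o], r1[o])
  expect_equal(s3$a, s1$a)
  expect_error(fit_sigma_model(pred[1:20], r1[1:20]), "at least 50")
})

test_that("annual sums convert and partition exactly", {
  grow <- rep(c(TRUE, FALSE), length.out = 17520)
  expect_equal(annual_sum(rep(0, 17520), grow)$annual, 0)
  s <- annual_sum(rep(1, 17520), grow)
  expect_equal(s$annual, 378.78, tolerance = 1e-4)
  expect_equal(s$growing + s$nongrowing, s$annual)
  expect_error(annual_sum(c(1, NA), c(TRUE, FALSE)), "incomplete")
  # cumulative trajectory ends exactly at the annual sum
  ts <- halfhour_grid(site_config())$timestamp
  cum <- cumulative_exchange(rep(1, 17520), ts)
  expect_equal(dplyr::last(cum$cum_gC), s$annual)
})

test_that("stratified bootstrap matches its expectation oracle", {
  tab <- ref_year()$observed
  tab <- screen_qc_flags(tab)
  filled <- ifelse(is.na(tab$f_c), 0, tab$f_c)

  # all-zero residuals: zero bias with a degenerate CI
  rs0 <- compute_residuals(tab$f_c, tab$f_c, tab)
  b0 <- bootstrap_bias(rs0, tab, filled, n_reps = 50, seed = 1)
  expect_equal(b0$bias_mean, 0)
  expect_equal(b0$bias_ci, c(0, 0))
  expect_equal(b0$annual_sd, 0)

  # known stratum means: E[bias] = sum_s n_s * m_s (unit-converted)
  rs <- rs0
  strata <- levels(rs$stratum)
  m_s <- setNames(seq_along(strata) * 0.1, strata)
  rs$residual <- m_s[as.character(rs$stratum)] +
    rnorm(nrow(rs), 0, 0.3)
  n_s <- table(flux_strata(tab))
  # expectation oracle: each slot draws from its stratum pool, so
  # E[bias] = sum_s n_s * mean(pool_s), unit-converted
  pools <- split(halfhour_to_gC(rs$residual), rs$stratum)
  expected <- sum(vapply(
    names(n_s),
    function(s) as.numeric(n_s[s]) * mean(pools[[s]]),
    numeric(1)
  ))
  b1 <- bootstrap_bias(rs, tab, filled, n_reps = 400, seed = 2)
  # Monte-Carlo SE of the mean bias over replicates
  var_one <- sum(vapply(
    names(n_s),
    function(s) as.numeric(n_s[s]) * var(pools[[s]]) * (length(pools[[s]]) - 1) / length(pools[[s]]),
    numeric(1)
  ))
  mc_se <- sqrt(var_one / 400)
  expect_lt(abs(b1$bias_mean - expected), 3 * mc_se + 1e-9)

  # determinism and CI sanity
  b2 <- bootstrap_bias(rs, tab, filled, n_reps = 400, seed = 2)
  expect_identical(glance(b1), glance(b2))
  expect_true(b1$bias_ci[1] <= b1$bias_mean && b1$bias_mean <= b1$bias_ci[2])
  expect_true(all(b1$seasonal$lower <= b1$seasonal$mean &
    b1$seasonal$mean <= b1$seasonal$upper))
})

test_that("method fusion is the mean and n-1 SD of the inputs", {
  f <- fuse_methods(c(-159.91, -178.25, -167.16, -156.95, -155.21))
  expect_equal(f$fused_mean, -163.50, tolerance = 0.005 / 163.5)
  expect_equal(f$fused_sd, 9.43, tolerance = 0.005 / 9.43)
  expect_equal(fuse_methods(c(4, 4, 4))$fused_sd, 0)
  two <- fuse_methods(c(1, 5))
  expect_equal(two$fused_mean, 3)
  expect_equal(two$fused_sd, 4 / sqrt(2))
  expect_error(fuse_methods(-163.5), "at least 2")
})
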