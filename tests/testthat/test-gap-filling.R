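# The five gap fillers, the 80/20 protocol, and the skill metrics.

test_that("train/test split is a seeded partition with the right sizes", {
  idx <- 101:110
  p <- split_train_test(idx, 0.8, seed = 3)
  expect_length(p$train, 8)
  expect_length(p$test, 2)
  expect_setequal(c(p$train, p$test), idx)
  expect_length(intersect(p$train, p$test), 0)
  expect_identical(p, split_train_test(idx, 0.8, seed = 3))
  expect_error(split_train_test(idx, 1.2), "fraction")
})

test_that("skill metrics match their definitions", {
  obs <- c(1, 2, 3, 4)
  expect_equal(
    evaluate_fill(obs, obs),
    tibble::tibble(r2 = 1, rmse = 0, be = 0, n = 4L)
  )
  m <- evaluate_fill(obs + 1, obs)
  expect_equal(m$be, 1)
  expect_equal(m$rmse, 1)
  # hand-computed 4-pair example
  pred <- c(1.5, 1.8, 3.4, 3.9)
  ss_res <- sum((pred - obs)^2) # 0.25 + 0.04 + 0.16 + 0.01
  m2 <- evaluate_fill(pred, obs)
  expect_equal(m2$r2, 1 - 0.46 / 5)
  expect_equal(m2$rmse, sqrt(0.46 / 4))
  expect_equal(m2$be, mean(pred - obs))
  expect_error(evaluate_fill(c(1, 2), c(3, 3)), "zero variance")
})

test_that("MDS averages in-tolerance neighbours and falls back correctly", {
  tab <- small_table()
  cfg <- mds_config()
  # a gap with exactly two in-tolerance neighbours valued 2 and 4 fills as 3
  toy <- tab[1:240, ]
  toy$f_c <- NA_real_
  toy$rd <- 300
  toy$t_air <- 10
  toy$vpd <- 4
  toy$f_c[c(10, 20)] <- c(2, 4)
  toy$rd[30] <- 300.1
  toy$f_c[30] <- NA
  fill <- fit_predict_mds(toy, targets = 30, donors = c(10, 20), cfg)
  expect_equal(as.numeric(fill), 3)
  # identical drivers everywhere: every fill is the donor mean
  toy2 <- toy
  toy2$f_c[seq(1, 240, by = 3)] <- rnorm(80)
  donors <- which(!is.na(toy2$f_c))
  fills <- fit_predict_mds(toy2, targets = c(2, 50), donors = donors, cfg)
  expect_equal(as.numeric(fills), rep(mean(toy2$f_c[donors]), 2))
  # met conditions match nothing -> diurnal-course fallback: brute-force
  # lookup of same-slot donors over a 10-day toy table
  toy3 <- tab
  toy3$rd[100] <- toy3$rd[100] + 5000 # unmatched meteorology
  donors <- setdiff(seq_len(nrow(toy3)), 100)
  got <- fit_predict_mds(toy3, targets = 100, donors = donors, cfg)
  slot <- (floor(as.numeric(format(toy3$timestamp, "%H")) * 2 +
    as.numeric(format(toy3$timestamp, "%M")) / 30)) %% 48
  same_slot <- donors[
    pmin(abs(slot[donors] - slot[100]), 48 - abs(slot[donors] - slot[100])) <= 2 &
      abs(donors - 100) <= 7 * 48
  ]
  expect_equal(as.numeric(got), mean(toy3$f_c[same_slot]))
  expect_equal(attr(got, "window_used"), -7)
})

test_that("GP posterior behaves like an exact SE-ARD regression", {
  # kernel at zero distance equals the amplitude variance
  k0 <- fluxgap:::gp_kernel(
    matrix(0.3, 1, 1), matrix(0.3, 1, 1),
    theta = c(log(2.5), 0, log(0.1))
  )
  expect_equal(as.numeric(k0), 2.5)

  set.seed(2)
  x <- matrix(runif(50), ncol = 1)
  y <- sin(2 * pi * x[, 1])
  spec <- fit_gp(x, y, subset_size = Inf, restarts = 1, seed = 2)
  # near-interpolation at training inputs as the nugget is small
  at_train <- predict_gp(spec, x)
  expect_lt(sqrt(mean((at_train$mean - y)^2)), 0.05)
  # recovery of the underlying function on new inputs
  xn <- matrix(seq(0.02, 0.98, length.out = 200), ncol = 1)
  pr <- predict_gp(spec, xn)
  expect_lt(sqrt(mean((pr$mean - sin(2 * pi * xn[, 1]))^2)), 0.05)
  # posterior variance is non-negative and grows away from the data
  expect_true(all(pr$var >= 0))
  far <- predict_gp(spec, matrix(3, 1, 1))
  expect_gt(far$var, max(pr$var))
  expect_error(predict_gp(spec, matrix(0, 1, 2)), "dimension")
})

test_that("HLM reduces to OLS with a flat ridge prior and shrinks otherwise", {
  set.seed(9)
  n <- 300
  x <- cbind(a = runif(n), b = runif(n))
  y <- 1.5 + 2 * x[, 1] - 3 * x[, 2] + rnorm(n, 0, 0.4)
  g <- rep(1L, n)
  flat <- suppressMessages(
    fit_hlm(x, y, g, n_groups = 1, rho_alpha = 1e-9, rho_beta = 1e9)
  )
  ols <- coef(lm(y ~ x))
  expect_equal(unname(flat$beta), unname(ols[2:3]), tolerance = 1e-4)
  expect_equal(flat$gamma, unname(ols[1]), tolerance = 1e-4)
  # prior domination: beta shrinks to zero, predictions are group intercepts
  tight <- fit_hlm(x, y, g, n_groups = 1, rho_beta = 1e-12)
  expect_equal(unname(tight$beta), c(0, 0), tolerance = 1e-4)
  pr <- predict_hlm(tight, x, g)
  expect_equal(pr, rep(pr[1], n), tolerance = 1e-6)
})

test_that("HLM recovers known generative parameters", {
  # data drawn from the varying-intercept model itself
  inside <- vapply(1:50, function(s) {
    set.seed(300 + s)
    n <- 1500
    g <- sample.int(48, n, replace = TRUE)
    alpha <- rnorm(48, 1, 0.8)
    beta <- c(2, -1)
    x <- cbind(runif(n), runif(n))
    y <- alpha[g] + x %*% beta + rnorm(n, 0, 0.5)
    fit <- suppressMessages(fit_hlm(x, as.numeric(y), g, n_groups = 48))
    all(abs(fit$beta - beta) <= 2 * sqrt(fit$beta_var))
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("both networks recover a linear target and honour the seed", {
  set.seed(4)
  x <- cbind(x1 = runif(400), x2 = runif(400))
  y <- 2 * x[, 1]
  for (fitter in list(fit_ann, fit_rbf)) {
    spec <- fitter(x, y, seed = 6)
    expect_gt(evaluate_fill(predict_net(spec, x), y)$r2, 0.99)
    again <- fitter(x, y, seed = 6)
    expect_identical(predict_net(spec, x), predict_net(again, x))
  }
  # zero-variance target: constant prediction at the mean
  cst_ann <- fit_ann(x, rep(2.5, 400), seed = 1)
  cst_rbf <- fit_rbf(x, rep(2.5, 400), seed = 1)
  expect_equal(predict_net(cst_ann, x[1:5, ]), rep(2.5, 5))
  expect_equal(predict_net(cst_rbf, x[1:5, ]), rep(2.5, 5))
})

test_that("fill_gaps completes the series and preserves observations", {
  tab <- ref_screened()
  for (m in c("hlm", "mds")) {
    fr <- ref_fill(m)
    expect_false(anyNA(fr$data$filled))
    expect_equal(sum(fr$data$source == "filled"), sum(is.na(tab$f_c)))
    ok <- !is.na(tab$f_c)
    expect_identical(fr$data$filled[ok], tab$f_c[ok])
    expect_identical(fr$data$observed, tab$f_c)
  }
  # no gaps: filled series is identical to the observations
  full <- small_table()
  fr0 <- suppressMessages(fill_gaps(full, "hlm", seed = 2))
  expect_identical(fr0$data$filled, full$f_c)
  expect_error(fill_gaps(tab, "kriging"), "arg")
})

test_that("every method reaches plausible test skill on the simulated year", {
  methods <- c("mds", "hlm", "ann", "rbf", "gp")
  r2 <- vapply(methods, function(m) {
    fr <- ref_fill(m, config = if (m == "gp") {
      list(subset_size = 400, restarts = 1)
    })
    dplyr::filter(fr$metrics, set == "test")$r2
  }, numeric(1))
  expect_true(all(r2 >= 0.6 & r2 <= 0.95))
  # gap-filled diurnal fingerprint: growing-season midday medians negative
  fr <- ref_fill("rbf")
  d <- fr$data
  tab <- ref_screened()
  midday <- tab$is_growing & abs(fluxgap:::decimal_hour(d$timestamp) - 13) < 1.5
  expect_lt(median(d$filled[midday]), 0)
})
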