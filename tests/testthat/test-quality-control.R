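# QC chain: flag screening, diurnal-quantile outliers, median spike filter,
# gap statistics.

test_that("QC-flag screening removes exactly the non-zero flags", {
  tab <- small_table()[1:4, ]
  tab$qc_flag <- c(0L, 1L, 2L, 0L)
  out <- screen_qc_flags(tab)
  expect_identical(is.na(out$f_c), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(qc_report(out)$total, 2L)
  # nothing removed when all flags are zero
  clean <- small_table()[1:4, ]
  expect_false(anyNA(screen_qc_flags(clean)$f_c))
  # on the simulated year the removed share matches the configured rate
  yr <- ref_year()
  out <- screen_qc_flags(yr$observed)
  alive <- !is.na(yr$observed$f_c)
  expect_equal(
    sum(is.na(out$f_c) & alive) / sum(alive),
    yr$params$qc_bad_fraction,
    tolerance = 0.02
  )
})

test_that("diurnal-quantile screen implements the boxplot rule per bin", {
  tab <- small_table()
  # constant series: empty mask
  cst <- dplyr::mutate(tab, f_c = 1)
  expect_equal(sum(diurnal_quantile_outliers(cst)), 0)
  # a value far above Q3 + 10 IQR in its bin is flagged
  spiked <- tab
  bin_rows <- which(format(spiked$timestamp, "%H:%M") == "12:00")
  f <- spiked$f_c[bin_rows]
  q <- quantile(f, c(.25, .75))
  spiked$f_c[bin_rows[1]] <- q[2] + 10 * (q[2] - q[1]) + 10
  mask <- diurnal_quantile_outliers(spiked)
  expect_true(mask[bin_rows[1]])
  # Gaussian bins: flagged share near the 0.7% normal-tail rate
  set.seed(1)
  g <- halfhour_grid(site_config())
  g$f_c <- rnorm(nrow(g))
  share <- mean(diurnal_quantile_outliers(g))
  expect_equal(share, 2 * pnorm(-2.6975), tolerance = 0.5)
  # thin bins flag nothing
  tiny <- tab[1:96, ]
  expect_message(
    m <- diurnal_quantile_outliers(tiny, min_bin = 10),
    "minimum occupancy"
  )
  expect_equal(sum(m), 0)
})

test_that("spike filter reproduces the double-difference rule", {
  # D at a spike: F = [1, 1, 10, 1] -> (10-1) - (1-10) = 18
  v <- c(1, 1, 10, 1)
  d2 <- (v[3] - v[2]) - (v[4] - v[3])
  expect_equal(d2, 18)
  # constant series: MAD = 0, D == Md everywhere, no flags
  cst <- dplyr::mutate(small_table(), f_c = 2)
  expect_equal(sum(spike_filter(cst)), 0)
  # smooth sinusoid + one spike of 8x the local SD: exactly the spike flagged
  g <- halfhour_grid(site_config())[1:336, ]
  h <- seq_len(nrow(g))
  g$f_c <- sin(2 * pi * h / 48)
  spike_at <- 100
  g$f_c[spike_at] <- g$f_c[spike_at] + 8 * sd(g$f_c)
  mask <- spike_filter(g, spike_config(split_day_night = FALSE))
  expect_identical(which(mask), as.integer(spike_at))
})

test_that("spike filter matches a brute-force median oracle on one window", {
  # independent oracle: direct sort-based medians, D_i only where both
  # half-hour neighbours (original slots i - 1, i + 1) are still valid
  oracle_scan <- function(v, z = 5.5) {
    flagged <- integer(0)
    alive <- rep(TRUE, length(v))
    sort_median <- function(x) {
      s <- sort(x)
      m <- length(s)
      if (m %% 2) s[(m + 1) / 2] else mean(s[m / 2 + 0:1])
    }
    repeat {
      cand <- which(alive)
      cand <- cand[cand > 1 & cand < length(v)]
      cand <- cand[alive[cand - 1] & alive[cand + 1]]
      if (length(cand) < 1) break
      d <- (v[cand] - v[cand - 1]) - (v[cand + 1] - v[cand])
      md <- sort_median(d)
      mad <- sort_median(abs(d - md))
      dev <- abs(d - md)
      ex <- if (mad == 0) dev > 0 else dev >= z * mad / 0.6745
      if (!any(ex)) break
      worst <- which.max(ifelse(ex, dev, -Inf))
      flagged <- c(flagged, cand[worst])
      alive[cand[worst]] <- FALSE
    }
    sort(flagged)
  }
  set.seed(33)
  for (rep in 1:5) {
    v <- sin(seq(0, 6 * pi, length.out = 200)) + rnorm(200, 0, 0.1)
    v[sample(20:180, 3)] <- v[sample(20:180, 3)] + c(6, -7, 9)
    g <- halfhour_grid(site_config())[seq_along(v), ]
    g$f_c <- v
    g$is_day <- TRUE
    cfg <- spike_config(window_days = 5) # 200 slots < 5 days: one window
    expect_identical(which(spike_filter(g, cfg)), oracle_scan(v))
  }
})

test_that("spike filter is idempotent and quiet on clean simulations", {
  tab <- ref_year()$observed
  tab <- screen_qc_flags(tab)
  mask1 <- spike_filter(tab)
  # false-positive rate at z = 5.5 stays below 1% (no spikes were injected)
  expect_lt(sum(mask1) / sum(!is.na(tab$f_c)), 0.01)
  # survivors produce no new flags
  cleaned <- screen_spikes(tab)
  expect_equal(sum(spike_filter(cleaned)), 0)
})

test_that("screens run in the fixed order and only see survivors", {
  out <- ref_screened()
  log <- qc_report(out)
  expect_identical(
    log$stage,
    c(
      "quality control", "distributional cleaning", "filtering",
      "u* screening"
    )
  )
  # stages are disjoint by construction: totals add up to removed flux count
  yr <- ref_year()
  started <- sum(!is.na(yr$observed$f_c))
  expect_equal(started - sum(log$total), sum(!is.na(out$f_c)))
})

test_that("gap statistics enumerate missing runs correctly", {
  g <- halfhour_grid(site_config())[1:400, ]
  g$f_c <- 1
  gs <- gap_statistics(g)
  expect_equal(gs$n_missing, 0L)
  expect_length(gs$run_lengths, 0)

  g$f_c[11:13] <- NA # a single 3-slot gap
  gs <- gap_statistics(g)
  expect_equal(gs$mean_gap_hours, 1.5)
  expect_equal(gs$max_gap_days, 3 / 48)

  # runs of 2, 48 and 100 slots: only the 100-slot run exceeds 24 h
  g$f_c <- 1
  g$f_c[c(5:6, 21:68, 101:200)] <- NA
  gs <- gap_statistics(g)
  expect_identical(sort(gs$run_lengths), c(2L, 48L, 100L))
  expect_equal(gs$n_gaps_gt_24h, 1L)
  expect_equal(gs$n_missing, 150L)
})
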