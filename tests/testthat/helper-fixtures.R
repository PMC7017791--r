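# Shared fixtures, built once per test run and cached. All synthetic, all
# seeded.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# the reference simulated year used across modules
ref_year <- function(seed = 42) {
  fixture(paste0("year_", seed), function() {
    simulate_flux_year(site_config(), sim_params(seed = seed))
  })
}

# the reference year taken through the full cleaning chain
ref_screened <- function(seed = 42) {
  fixture(paste0("screened_", seed), function() {
    obs <- ref_year(seed)$observed
    obs <- screen_qc_flags(obs)
    obs <- suppressMessages(screen_diurnal_outliers(obs))
    obs <- screen_spikes(obs)
    thr <- detect_seasonal_ustar(obs)
    apply_ustar_filter(obs, thr)
  })
}

# one cached fill per method on the screened reference year
ref_fill <- function(method, seed = 42, config = NULL) {
  fixture(paste0("fill_", method, "_", seed), function() {
    suppressMessages(fill_gaps(ref_screened(seed), method,
      seed = seed, config = config
    ))
  })
}

# a small 10-day table with complete drivers, handy for MDS/QC unit tests
small_table <- function(seed = 5, days = 10) {
  fixture(paste0("small_", seed, "_", days), function() {
    site <- site_config()
    dr <- simulate_drivers(site, seed = seed)
    dr <- dr[seq_len(days * 48), ]
    dr$f_c <- simulate_nee(dr, sim_params(seed = seed))
    dr$qc_flag <- 0L
    dr
  })
}
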