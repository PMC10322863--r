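# Shared synthetic fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# one clean year: no noise, no gaps, no u* suppression
sim_clean_year <- function() fixture("clean_year", function() {
  simulate_halfhourly(sim_config(seed = 101, years = 2015, gap_fraction = 0,
                                 noise_sd_nee = 0,
                                 night_suppression_factor = 1))
})

# one year with u* suppression only (no noise, no gaps)
sim_suppressed_year <- function() fixture("suppressed_year", function() {
  simulate_halfhourly(sim_config(seed = 102, years = 2015, gap_fraction = 0,
                                 noise_sd_nee = 0))
})

# one realistic year: noise + gaps + suppression
sim_noisy_year <- function() fixture("noisy_year", function() {
  simulate_halfhourly(sim_config(seed = 103, years = 2015))
})

# long reference climate for SPEI standardization checks
climate_30y <- function() fixture("climate_30y", function() {
  simulate_daily_climate(sim_config(seed = 104, years = 1981:2012,
                                    drought_years = list()))
})
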