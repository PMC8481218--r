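test_that("scenario configs validate event ordering and presets match sizes", {
  expect_error(scenario_config(pulse_times = 20L, collapse_time = 15),
               "precede")
  expect_error(scenario_config(step_time = 16, collapse_time = 15), "precede")
  expect_error(scenario_config(phi0 = 0.9, phi1 = 0.2), "phi0")
  expect_error(scenario_config(pulse_dom_drop = 1.2), "pulse_dom_drop")

  expect_equal(preset_scenarios("kpg_like")$n_samples, 26)
  expect_equal(preset_scenarios("pe_like")$n_samples, 31)
  expect_equal(preset_scenarios("modern_like")$n_samples, 18)
  expect_equal(preset_scenarios("em_like")$n_samples, 33)
  expect_error(preset_scenarios("nope"), "kpg_like")

  # configs serialize and round-trip unchanged
  for (nm in c("kpg_like", "pe_like", "modern_like", "em_like")) {
    cfg <- preset_scenarios(nm)
    tmp <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
    back$pulse_times <- as.integer(back$pulse_times)
    cfg2 <- do.call(scenario_config, back[!vapply(back, is.null, logical(1))])
    expect_equal(cfg2, cfg)
  }
})

test_that("simulation is deterministic and compositionally closed", {
  cfg <- preset_scenarios("kpg_like", seed = 11)
  a <- simulate_community(cfg)
  b <- simulate_community(cfg)
  expect_identical(a, b)
  expect_true(all(abs(rowSums(a$series$rel_abund) - 100) < 1e-9))
  expect_true(all(a$series$counts >= 0))
})

test_that("expectation mode realizes the designed shapes exactly", {
  # no events, no collapse: constant composition and indicators
  calm <- simulate_community(scenario_config(seed = 1), mode = "expected")
  expect_equal(diff(range(cross_sd(calm$series)$value)), 0, tolerance = 1e-9)
  expect_equal(diff(range(species_richness(calm$series)$value)), 0)

  # pulse: dominant's pre-collapse minimum and indicator's maximum at t*
  cfg <- scenario_config(pulse_times = 10L, collapse_time = 16, seed = 1)
  sim <- simulate_community(cfg, mode = "expected")
  dom <- dominant_rel_abund(sim$series, "sp01")$value
  ind <- dominant_rel_abund(sim$series, "sp03")$value
  pre <- 1:15
  expect_equal(which.min(dom[pre]), 10L)
  expect_equal(which.max(ind), 10L)

  # pulse depresses total counts to the series minimum at t*
  ta <- total_abundance(sim$series)$value
  expect_equal(which.min(ta), 10L)

  # dominance turnover is real: successor strictly leads from collapse on
  succ <- dominant_rel_abund(sim$series, "sp02")$value
  expect_true(all(succ[16:30] > dom[16:30]))
  expect_true(all(dom[1:15] > succ[1:15]))
})

test_that("sampled pulses depress totals across seeds", {
  hit <- 0L
  for (seed in 1:50) {
    cfg <- scenario_config(pulse_times = 9L, collapse_time = 15, seed = seed)
    ta <- total_abundance(simulate_community(cfg)$series)$value
    hit <- hit + (which.min(ta) == 9L)
  }
  expect_equal(hit, 50L)    # the activity dip is deterministic
})

test_that("a csd ramp raises late rolling AR(1) relative to the control", {
  # collapse-free series so the autocorrelation ramp, not the collapse
  # trend, drives the contrast; window-10 estimates are noisy, so the
  # property is a clear separation of detection fractions, not certainty
  up <- function(csd, seeds) {
    mean(vapply(seeds, function(seed) {
      cfg <- scenario_config(n_samples = 60, csd = csd, seed = seed)
      s <- simulate_community(cfg)$series
      ar <- rolling_ar1(dominant_rel_abund(s, "sp01"), window = 10)
      v <- ar$value[ar$valid]
      mean(utils::tail(v, 5)) > mean(utils::head(v, 5))
    }, logical(1)))
  }
  on <- up(TRUE, 1:100)
  off <- up(FALSE, 1:100)
  expect_gte(on, 0.65)
  expect_lte(off, 0.65)
  expect_gt(on, off)
})

test_that("simulator output round-trips through the table dialect", {
  sim <- simulate_community(preset_scenarios("modern_like", seed = 2))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_community_table(sim$series, tmp)
  back <- read_community_table(tmp, axis_direction = "time")
  expect_equal(back$rel_abund, sim$series$rel_abund, tolerance = 1e-12)

  gt <- withr::local_tempfile(fileext = ".json")
  write_ground_truth_json(sim$truth, gt)
  j <- jsonlite::read_json(gt, simplifyVector = TRUE)
  expect_equal(j$collapse_sample, sim$truth$collapse_sample)
  expect_equal(j$events$kind, sim$truth$events$kind)
})
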