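ratio_series <- function(v) {
  structure(tibble::tibble(axis = seq_along(v), value = v,
                           valid = !is.na(v)),
            class = c("indicator_series", class(tibble::tibble())),
            indicator = "ratio")
}

test_that("ratio crossings: upward, strict, with persistence", {
  r1 <- ratio_threshold_crossings(ratio_series(c(0.2, 0.4, 0.6, 0.7)))
  expect_equal(r1$sample, 3L)
  expect_true(r1$sustained)

  r2 <- ratio_threshold_crossings(ratio_series(c(0.2, 0.6, 0.3, 0.7, 0.8)))
  expect_equal(r2$sample, c(2L, 4L))
  expect_equal(r2$sustained, c(FALSE, TRUE))

  expect_equal(nrow(ratio_threshold_crossings(ratio_series(rep(0.5, 5)))), 0)
  # crossing at the last sample counts as sustained (holds to series end)
  r3 <- ratio_threshold_crossings(ratio_series(c(0.1, 0.2, 0.9)))
  expect_true(r3$sustained)
  # masked samples are skipped entirely
  r4 <- ratio_threshold_crossings(ratio_series(c(0.2, NA, 0.6, 0.8)))
  expect_equal(r4$sample, 3L)
})

test_that("a single evidence flag never yields a pulse call", {
  # a one-sample outlier where the dominant RISES: the tree-outlier flag
  # fires, but there is neither a dominant trough nor a subordinate peak,
  # so the quorum of two is not met and no pulse is called
  m <- matrix(rep(c(60, 25, 15), each = 8), 8, 3,
              dimnames = list(NULL, c("t1", "t2", "t3")))
  m[5, ] <- c(85, 10, 5)
  x <- community_ts(1:8, rel_abund = m, axis_direction = "time")
  tr <- constrained_upgma(x)
  expect_true(5L %in% detect_tree_outliers(tr))
  ev <- detect_pulse_events(x, tr, dominant = "t1")
  expect_equal(nrow(ev), 0)
})

test_that("featureless series produce no event calls and no collapse flag", {
  # expectation mode: a genuinely featureless series (no events, no
  # collapse, no sampling noise)
  sim <- simulate_community(scenario_config(seed = 42), mode = "expected")
  rep <- run_pipeline(sim$series, quiet = TRUE)
  expect_equal(nrow(rep$events), 0)
  expect_false(rep$boundary$collapse_detected)
})

test_that("simulated pulses are called at the true sample", {
  hits <- 0L
  for (seed in 1:50) {
    rep <- run_pipeline(preset_scenarios("kpg_like", seed = seed),
                        quiet = TRUE)
    pt <- rep$truth$events$sample[rep$truth$events$kind == "pulse"]
    hits <- hits + all(pt %in% rep$events$sample[rep$events$kind == "pulse"])
  }
  expect_gte(hits, 45L)
})

test_that("simulated steps are called within one sample of the true onset", {
  hits <- 0L
  for (seed in 1:50) {
    rep <- run_pipeline(preset_scenarios("modern_like", seed = seed),
                        quiet = TRUE)
    st <- rep$truth$events$sample[rep$truth$events$kind == "step"]
    calls <- rep$events$sample[rep$events$kind == "step"]
    hits <- hits + (length(calls) > 0 && any(abs(calls - st) <= 1))
  }
  expect_gte(hits, 42L)
})

test_that("pulse and step kinds are distinguished when both occur", {
  ok <- 0L
  for (seed in 1:50) {
    rep <- run_pipeline(preset_scenarios("em_like", seed = seed),
                        quiet = TRUE)
    tt <- rep$truth$events
    pt <- tt$sample[tt$kind == "pulse"]
    st <- tt$sample[tt$kind == "step"]
    pulses <- rep$events$sample[rep$events$kind == "pulse"]
    steps <- rep$events$sample[rep$events$kind == "step"]
    good <- all(pt %in% pulses) &&
      any(abs(steps - st) <= 1) &&
      !any(steps == pt) &&
      !any(abs(pulses - st) <= 1)
    ok <- ok + good
  }
  expect_gte(ok, 40L)
})

test_that("event evidence flags are recomputable from the inputs", {
  rep <- run_pipeline(preset_scenarios("kpg_like", seed = 3), quiet = TRUE)
  ev <- dplyr::filter(rep$events, kind == "pulse")
  expect_gt(nrow(ev), 0)
  sim <- simulate_community(preset_scenarios("kpg_like", seed = 3))
  tr <- constrained_upgma(sim$series)
  outs <- detect_tree_outliers(tr)
  for (i in seq_len(nrow(ev))) {
    expect_equal(ev$tree_outlier[i], ev$sample[i] %in% outs)
  }
  # calls always reference samples present in the input
  expect_true(all(rep$events$sample %in% seq_len(rep$input_summary$n_samples)))
})

test_that("pulse calls adjacent to a step call yield to it", {
  ev <- tibble::tibble(
    sample = c(7L, 8L, 12L), axis = c(7, 8, 12),
    kind = c("pulse", "step", "pulse"),
    confidence = c(2/3, 2/3, 2/3))
  out <- reconcile_events(collapsescope:::new_event_calls(ev))
  expect_equal(out$kind, c("step", "pulse"))
  expect_equal(out$sample, c(8L, 12L))
})
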