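counts_series <- function(cnt) {
  colnames(cnt) <- paste0("t", seq_len(ncol(cnt)))
  to_relative(community_ts(seq_len(nrow(cnt)), counts = cnt,
                           axis_direction = "time"))
}

test_that("total abundance sums counts and requires counts", {
  x <- counts_series(rbind(c(2, 3), c(1, 1), c(5, 5)))
  expect_equal(total_abundance(x)$value, c(5, 2, 10))
  pct <- community_ts(1:3, rel_abund = percent_matrix(
    c(50, 50), c(40, 60), c(30, 70)), axis_direction = "time")
  expect_error(total_abundance(pct), "counts")
})

test_that("species richness counts taxa strictly above the threshold", {
  x <- community_ts(1:3, rel_abund = percent_matrix(
    c(10, 0, 90), c(0.05, 0.2, 99.75), c(33.4, 33.3, 33.3)),
    axis_direction = "time")
  expect_equal(species_richness(x)$value, c(2, 3, 3))
  expect_equal(species_richness(x, presence_threshold = 0.1)$value,
               c(2, 2, 3))
})

test_that("across-taxon sd matches closed forms and a two-pass oracle", {
  x <- community_ts(1:3, rel_abund = percent_matrix(
    c(50, 50), c(0, 100), c(30, 70)), axis_direction = "time")
  s <- cross_sd(x)
  expect_equal(s$value[1], 0)
  expect_equal(s$value[2], 70.710678, tolerance = 1e-6)

  y <- community_ts(1:3, rel_abund = rbind(c(10, 20, 30, 40),
                                           c(25, 25, 25, 25),
                                           c(40, 30, 20, 10)) |>
                      (\(m) {colnames(m) <- paste0("t", 1:4); m})(),
                    axis_direction = "time")
  expect_equal(cross_sd(y)$value[1], 12.909944, tolerance = 1e-6)

  # brute-force two-pass oracle on random fixtures, missing cells excluded
  for (seed in 1:10) {
    z <- random_percent_series(8, 5, seed = seed)
    z$missing[cbind(1:3, c(2, 4, 1))] <- TRUE
    got <- cross_sd(z)$value
    for (i in 1:8) {
      v <- z$rel_abund[i, !z$missing[i, ]]
      mu <- sum(v) / length(v)
      expect_equal(got[i], sqrt(sum((v - mu)^2) / (length(v) - 1)),
                   tolerance = 1e-10)
    }
  }
})

test_that("rows with fewer than two observed taxa are masked, not errors", {
  x <- random_percent_series(4, 3, seed = 1)
  x$missing[2, c(1, 2)] <- TRUE
  s <- cross_sd(x)
  expect_false(s$valid[2])
  expect_true(all(s$valid[-2]))
})

test_that("rolling AR(1): exact recurrence, degenerate windows, length guard", {
  n <- 60
  x <- numeric(n); x[1] <- 1
  for (t in 2:n) x[t] <- 0.9 * x[t - 1]
  est <- rolling_ar1(x, window = 20)
  expect_true(all(abs(est$value[est$valid] - 0.9) < 1e-9))
  expect_false(any(est$valid[1:19]))

  const <- rolling_ar1(rep(3, 30), window = 10)
  expect_false(any(const$valid))

  expect_warning(short <- rolling_ar1(rnorm(5), window = 20), "window")
  expect_false(any(short$valid))
})

test_that("rolling AR(1) matches an lm() oracle window by window", {
  set.seed(7)
  v <- as.numeric(arima.sim(list(ar = 0.5), 40))
  est <- rolling_ar1(v, window = 15)
  for (t in c(15, 22, 40)) {
    idx <- (t - 14):t
    o <- unname(coef(lm(v[idx][-1] ~ v[idx][-15]))[2])
    expect_equal(est$value[t], o, tolerance = 1e-10)
  }
})

test_that("rolling AR(1) recovers the coefficient of a simulated AR process", {
  ests <- vapply(1:50, function(seed) {
    set.seed(seed)
    v <- as.numeric(arima.sim(list(ar = 0.8), 500))
    s <- rolling_ar1(v, window = 200)
    mean(s$value[s$valid])
  }, numeric(1))
  expect_gt(mean(ests), 0.75)
  expect_lt(mean(ests), 0.82)
})

test_that("dominant series and taxon ratios are pure projections", {
  x <- counts_series(rbind(c(1, 1), c(3, 1), c(2, 2)))
  expect_equal(dominant_rel_abund(x, "t1")$value, c(50, 75, 50))
  expect_error(dominant_rel_abund(x, "nope"), "known taxa")

  y <- community_ts(1:3, rel_abund = percent_matrix(
    c(20, 40, 40), c(30, 30, 40), c(45, 30, 25)), axis_direction = "time")
  r <- species_ratio(y, "t1", "t2")
  expect_equal(r$value, c(0.5, 1.0, 1.5))
  expect_equal(species_ratio(y, "t1", "t1")$value, rep(1, 3))

  z <- community_ts(1:3, rel_abund = percent_matrix(
    c(20, 0, 80), c(30, 30, 40), c(45, 0, 55)), axis_direction = "time")
  rz <- species_ratio(z, "t1", "t2")
  expect_equal(rz$valid, c(FALSE, TRUE, FALSE))
  expect_error(species_ratio(z, "t1", "nope"), "unknown taxon")
})

test_that("indicator tables write axis plus value/validity columns", {
  x <- counts_series(rbind(c(2, 3), c(1, 1), c(5, 5)))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_indicator_tsv(list(total = total_abundance(x),
                           rich = species_richness(x)), tmp)
  tab <- read.delim(tmp)
  expect_equal(names(tab), c("axis", "total", "total_valid", "rich",
                             "rich_valid"))
  expect_equal(tab$total, c(5, 2, 10))
})
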