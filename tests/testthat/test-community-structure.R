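test_that("hand-checked constrained UPGMA: two tight blocks merge last", {
  # one informative taxon with values 0,0,10,10 (complement closes rows)
  m <- percent_matrix(c(0, 100), c(0, 100), c(10, 90), c(10, 90))
  tr <- constrained_upgma(community_ts(1:4, rel_abund = m,
                                       axis_direction = "time"))
  expect_equal(nrow(tr$merges), 3)
  expect_equal(tr$merges$height[1:2], c(0, 0))
  # all four cross-pair distances equal sqrt(10^2 + 10^2)
  expect_equal(tr$merges$height[3], sqrt(200))
  expect_equal(tr$merges$left_start[3], 1)
  expect_equal(tr$merges$right_start[3], 3)

  z <- cut_zones(tr, 2)
  expect_equal(z$start, c(1, 3))
  expect_equal(z$end, c(2, 4))
  expect_equal(cut_zones(tr, 1)$start, 1)
  expect_equal(nrow(cut_zones(tr, 4)), 4)
  expect_error(cut_zones(tr, 5), "k must be")
})

test_that("identical samples give an all-zero tree and no outliers", {
  m <- percent_matrix(c(30, 70), c(30, 70), c(30, 70), c(30, 70))
  tr <- constrained_upgma(community_ts(1:4, rel_abund = m,
                                       axis_direction = "time"))
  expect_equal(tr$merges$height, rep(0, 3))
  expect_length(detect_tree_outliers(tr), 0)
})

test_that("every merge joins temporally adjacent blocks (constraint property)", {
  for (seed in 1:20) {
    x <- random_percent_series(n = 10, m = 4, seed = seed)
    m <- constrained_upgma(x)$merges
    expect_equal(m$right_start, m$left_end + 1)
    expect_true(all(m$height >= 0))
  }
})

test_that("tree equals the exhaustive greedy full-averaging oracle", {
  for (seed in 1:100) {
    n <- sample(4:8, 1)
    x <- random_percent_series(n = n, m = 3, seed = seed)
    got <- as.data.frame(constrained_upgma(x)$merges)
    want <- oracle_constrained_upgma(x$rel_abund)
    expect_equal(got$left_start, want$left_start)
    expect_equal(got$right_start, want$right_start)
    expect_equal(got$height, want$height, tolerance = 1e-9)
  }
})

test_that("zone cuts are nested in k", {
  for (seed in 1:10) {
    x <- random_percent_series(n = 12, m = 4, seed = seed)
    tr <- constrained_upgma(x)
    for (k in 2:11) {
      coarse <- cut_zones(tr, k)$start
      fine <- cut_zones(tr, k + 1)$start
      expect_true(all(coarse %in% fine))
    }
  }
})

test_that("a one-sample spike is flagged as a dendrogram outlier", {
  v <- c(5, 6, 5, 50, 5, 6)   # small within-regime jitter keeps the median
  m <- cbind(v, 100 - v)      # merge height positive, so the scale-free
  colnames(m) <- c("a", "b")  # threshold is meaningful
  tr <- constrained_upgma(community_ts(1:6, rel_abund = m,
                                       axis_direction = "time"))
  expect_equal(detect_tree_outliers(tr), 4L)
  # with a huge factor nothing exceeds the threshold
  expect_length(detect_tree_outliers(tr, factor = 1e6), 0)
})

test_that("simulated pulses are recovered as tree outliers across seeds", {
  hit <- 0L
  for (seed in 1:100) {
    cfg <- scenario_config(n_samples = 20, pulse_times = 8L,
                           collapse_time = 14, seed = seed)
    sim <- simulate_community(cfg)
    out <- detect_tree_outliers(constrained_upgma(sim$series))
    hit <- hit + (8L %in% out)
  }
  expect_gte(hit, 90L)
})

test_that("covariance PCA matches the hand example and its invariants", {
  # two samples mirrored around 50/50: one axis of variation, total
  # variance var(±10) + var(±10) = 200 + 200 = 400 on the first component
  two <- structure(list(axis = c(1, 2), taxa = c("t1", "t2"),
                        counts = NULL,
                        rel_abund = percent_matrix(c(60, 40), c(40, 60)),
                        missing = matrix(FALSE, 2, 2),
                        axis_direction = "time"),
                   class = "community_ts")
  p <- pca_covariance(two)
  expect_equal(p$eigenvalues[1], 400)
  expect_equal(p$eigenvalues[2], 0, tolerance = 1e-9)

  for (seed in 1:10) {
    x <- random_percent_series(n = 9, m = 5, seed = seed)
    p <- pca_covariance(x)
    X <- x$rel_abund
    expect_true(all(p$eigenvalues > -1e-9))
    expect_equal(sum(p$eigenvalues), sum(diag(cov(X))), tolerance = 1e-6)
    # scores of distinct components are uncorrelated
    cc <- crossprod(p$scores) / (nrow(X) - 1)
    expect_equal(cc, diag(diag(cc)), tolerance = 1e-6, ignore_attr = TRUE)
    # eigenbasis reconstruction reproduces the centered matrix
    Xc <- scale(X, center = TRUE, scale = FALSE)
    expect_equal(unname(p$scores %*% t(p$loadings)), unname(Xc),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # sign convention: largest-magnitude loading positive
    for (j in seq_len(ncol(p$loadings))) {
      expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
    }
  }
})

test_that("constant matrices have all-zero eigenvalues", {
  x <- community_ts(1:4, rel_abund = percent_matrix(
    c(25, 75), c(25, 75), c(25, 75), c(25, 75)), axis_direction = "time")
  expect_equal(pca_covariance(x)$eigenvalues, c(0, 0), tolerance = 1e-12)
})

test_that("dominance: per-sample argmax with first-taxon ties, per-zone mean", {
  m <- percent_matrix(c(70, 30, 0), c(60, 40, 0), c(50, 50, 0),
                      c(20, 30, 50))
  x <- community_ts(1:4, rel_abund = m, axis_direction = "time")
  prof <- dominance_profile(x)
  expect_equal(prof$samples$dominant, c("t1", "t1", "t1", "t3"))
  tr <- constrained_upgma(x)
  z <- cut_zones(tr, 2)
  zd <- dominance_profile(x, z)$zones
  expect_equal(zd$dominant[1], "t1")
})

test_that("collapse boundary follows zone dominants, with turnover override", {
  # three clear regimes: dominants t1, t1, t2 -> boundary at regime 3
  m <- percent_matrix(c(80, 15, 5), c(78, 17, 5), c(79, 16, 5),
                      c(55, 15, 30), c(56, 14, 30), c(54, 16, 30),
                      c(10, 70, 20), c(12, 68, 20), c(11, 69, 20))
  x <- community_ts(1:9, rel_abund = m, axis_direction = "time")
  tr <- constrained_upgma(x)
  zl <- collapse_boundary(x, tr, k = 3)
  expect_true(attr(zl, "collapse_detected"))
  expect_equal(attr(zl, "boundary_sample"), 7L)
  expect_equal(zl$role, c("pre_collapse", "pre_collapse", "collapse"))

  # same dominant everywhere -> no collapse
  m2 <- percent_matrix(c(80, 20), c(60, 40), c(79, 21), c(61, 39))
  x2 <- community_ts(1:4, rel_abund = m2, axis_direction = "time")
  zl2 <- collapse_boundary(x2, constrained_upgma(x2), k = 2)
  expect_false(attr(zl2, "collapse_detected"))
  expect_true(all(zl2$role == "pre_collapse"))

  # per-sample turnover two samples before the cluster boundary pulls the
  # boundary earlier (abundance record outranks the dendrogram)
  m3 <- percent_matrix(c(80, 15, 5), c(78, 17, 5), c(77, 18, 5),
                       c(49, 46, 5), c(46, 49, 5), c(45, 50, 5),
                       c(10, 85, 5), c(11, 84, 5), c(12, 83, 5))
  x3 <- community_ts(1:9, rel_abund = m3, axis_direction = "time")
  tr3 <- constrained_upgma(x3)
  z3 <- cut_zones(tr3, 2)
  # clustering splits at the large compositional break (sample 7)
  expect_equal(z3$start[2], 7L)
  zl3 <- collapse_boundary(x3, tr3, k = 2)
  expect_equal(attr(zl3, "boundary_sample"), 5L)
})

test_that("simulator zone dominants and boundary recover the ground truth", {
  ok_dom <- 0L
  ok_bnd <- 0L
  for (seed in 1:100) {
    cfg <- scenario_config(seed = seed, pulse_times = 9L, collapse_time = 18)
    sim <- simulate_community(cfg)
    tr <- constrained_upgma(sim$series)
    zl <- collapse_boundary(sim$series, tr)
    pre <- zl$dominant[1]
    ok_dom <- ok_dom + (pre == sim$truth$dominants$taxon[1])
    b <- attr(zl, "boundary_sample")
    ok_bnd <- ok_bnd + (!is.na(b) && abs(b - sim$truth$collapse_sample) <= 1)
  }
  expect_equal(ok_dom, 100L)
  expect_gte(ok_bnd, 90L)
})

test_that("tree exports to hclust and Newick with matching structure", {
  x <- random_percent_series(8, 3, seed = 5)
  tr <- constrained_upgma(x)
  hc <- as.hclust(tr)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$height, tr$merges$height)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tr, tmp)
  phy <- ape::read.tree(tmp)
  expect_equal(ape::Ntip(phy), 8)
})
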