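test_that("sliding windows cover the series with the documented indexing", {
  w <- sliding_windows(225, 30, 1)
  expect_equal(nrow(w), 196)
  expect_equal(w$start[1], 0)
  expect_equal(w$end[1], 30)
  expect_equal(w$end[196], 225)

  expect_equal(nrow(sliding_windows(30, 30)), 1)
  expect_error(sliding_windows(29, 30), "insufficient")

  w2 <- sliding_windows(100, 20, 5)
  expect_equal(nrow(w2), floor((100 - 20) / 5) + 1)
  expect_true(all(diff(w2$start) == 5))
})

test_that("window correlations match hand-computed Pearson values", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_equal(window_correlation(x)["a", "b"], 1)

  x2 <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_equal(window_correlation(x2)["a", "b"], 0)

  x3 <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 5))
  expect_equal(window_correlation(x3)["a", "b"], 6.5 / sqrt(43.75),
               tolerance = 1e-12)

  # constant column: undefined entries flagged as NA
  x4 <- cbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4))
  expect_true(is.na(window_correlation(x4)["a", "b"]))
})

test_that("correlation p-values follow the exact-t reference", {
  expect_equal(correlation_pvalue(0, 10), 1)
  expect_equal(correlation_pvalue(1, 10), 0)
  expect_equal(correlation_pvalue(-1, 10), 0)
  expect_equal(correlation_pvalue(0.5, 30), 0.0049, tolerance = 1e-2)
  # t-CDF oracle at a few points
  for (r in c(0.2, -0.4, 0.8)) {
    n <- 25
    t <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(correlation_pvalue(r, n), 2 * stats::pt(-abs(t), n - 2),
                 tolerance = 1e-12)
  }
  expect_error(correlation_pvalue(0.5, 2), "insufficient")
})

test_that("bh_fdr implements the step-up rule", {
  r1 <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(r1$reject))

  expect_false(any(bh_fdr(0.5, 0.05)$reject))
  # 0.04 > 1 * 0.05 / 3: nothing rejected
  expect_false(any(bh_fdr(c(0.04, 0.5, 0.9), 0.05)$reject))

  expect_equal(bh_fdr(numeric(0))$reject, logical(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  # brute-force step-up oracle on random vectors
  for (seed in 1:25) {
    p <- withr::with_seed(seed, stats::runif(40)^2)
    expect_identical(bh_fdr(p, 0.05)$reject, bh_brute(p, 0.05))
  }
})

test_that("layer stacks retain planted edges and zero out noise", {
  # ROIs 1-2 share a strong common signal; 3-5 are independent noise
  ts <- withr::with_seed(42, {
    common <- stats::rnorm(30)
    cbind(n1 = common + stats::rnorm(30, sd = 0.3),
          n2 = common + stats::rnorm(30, sd = 0.3),
          n3 = stats::rnorm(30), n4 = stats::rnorm(30), n5 = stats::rnorm(30))
  })
  st <- build_layer_stack(ts, width = 30)
  expect_equal(dim(st$layers), c(5, 5, 1))
  expect_equal(st$n_pairs_tested, 10)
  expect_true(st$retained[1, 2, 1])

  # direct recomputation of r, p, BH on the same window
  ut <- upper.tri(matrix(0, 5, 5))
  rv <- window_correlation(ts)[ut]
  keep_ref <- bh_brute(correlation_pvalue(rv, 30), 0.05) & rv > 0
  expect_identical(st$retained[, , 1][ut], keep_ref)
  wt_ref <- ifelse(keep_ref, rv, 0)
  expect_equal(st$layers[, , 1][ut], wt_ref)
})

test_that("every layer is symmetric with zero diagonal and bounded weights", {
  cfg <- synth_config(
    n_per_group = c(tdc = 1, adhd_unmedicated = 0, adhd_medicated = 0),
    n_regions = 15, n_timepoints = 50, master_seed = 5)
  ts <- simulate_cohort(cfg)$timeseries[[1]]
  for (policy in c("zero", "retain")) {
    st <- build_layer_stack(ts, width = 30, negatives = policy)
    for (w in c(1, 10, 21)) {
      lay <- st$layers[, , w]
      expect_identical(lay, t(lay))
      expect_equal(diag(lay), rep(0, 15))
      expect_true(all(abs(lay) <= 1))
      expect_lte(sum(st$retained[, , w]) / 2, n_connections(15))
    }
  }
  # the zero policy leaves no negative weights
  expect_true(all(build_layer_stack(ts, negatives = "zero")$layers >= 0))
})

test_that("raising alpha never decreases the retained-edge count", {
  cfg <- synth_config(
    n_per_group = c(tdc = 1, adhd_unmedicated = 0, adhd_medicated = 0),
    n_regions = 12, n_timepoints = 45, master_seed = 6)
  ts <- simulate_cohort(cfg)$timeseries[[1]]
  counts <- vapply(c(0.01, 0.05, 0.2),
                   function(a) sum(build_layer_stack(ts, alpha = a)$retained),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("pure-noise input yields few retained edges (FDR control)", {
  fracs <- vapply(1:5, function(seed) {
    ts <- withr::with_seed(seed, matrix(stats::rnorm(40 * 12), 40, 12))
    st <- build_layer_stack(ts, width = 30, negatives = "retain")
    sum(st$retained) / 2 / (n_connections(12) * dim(st$layers)[3])
  }, numeric(1))
  # FDR controls the expected false-discovery fraction at 5% of discoveries;
  # with no true signal the retained fraction stays near zero
  expect_lt(mean(fracs), 0.05)
})

test_that("constant columns give non-retained edges, not failures", {
  ts <- withr::with_seed(8, cbind(matrix(stats::rnorm(90), 30, 3), flat = 1))
  st <- build_layer_stack(ts, width = 30)
  expect_true(all(!st$retained[4, , 1]))
  expect_true(all(st$layers[4, , 1] == 0))
})

test_that("tidy() lists exactly the retained edges", {
  ts <- withr::with_seed(42, {
    common <- stats::rnorm(35)
    cbind(n1 = common + stats::rnorm(35, sd = 0.3),
          n2 = common + stats::rnorm(35, sd = 0.3),
          n3 = stats::rnorm(35))
  })
  st <- build_layer_stack(ts, width = 30)
  ed <- tidy(st)
  expect_equal(nrow(ed), sum(st$retained) / 2)
  expect_true(all(ed$weight != 0))
})
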