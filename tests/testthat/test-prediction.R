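# planted-signal design: one informative feature among pure noise
planted_classification <- function(n = 200, p_noise = 19, seed = 1) {
  withr::with_seed(seed, {
    x1 <- stats::rnorm(n)
    X <- cbind(x1 = x1,
               matrix(stats::rnorm(n * p_noise), n,
                      dimnames = list(NULL, paste0("noise", 1:p_noise))))
    list(X = X, y = as.numeric(x1 > 0))
  })
}

test_that("importance ranking finds the planted feature first", {
  d <- planted_classification()
  rk <- rank_importance(d$X, d$y, "classify", seed = 5)
  expect_equal(rk$feature[1], "x1")
  expect_true(all(rk$importance >= 0))
  expect_equal(sum(rk$importance), 1, tolerance = 1e-6)
  expect_equal(nrow(rk), ncol(d$X))

  # regression flavor
  d2 <- withr::with_seed(2, {
    X <- matrix(stats::rnorm(150 * 10), 150,
                dimnames = list(NULL, paste0("f", 1:10)))
    list(X = X, y = X[, "f3"] + stats::rnorm(150, sd = 0.05))
  })
  rk2 <- rank_importance(d2$X, d2$y, "regress", seed = 5)
  expect_equal(rk2$feature[1], "f3")

  expect_error(rank_importance(d$X, rep(1, 200), "classify"), "degenerate")
})

test_that("top-N search selects the minimal perfect model", {
  d <- withr::with_seed(11, {
    flag <- rep(c(0, 1), each = 50)
    X <- cbind(sig = flag,
               matrix(stats::rnorm(100 * 8), 100,
                      dimnames = list(NULL, paste0("noise", 1:8))))
    list(X = X, y = flag)
  })
  ts <- top_n_search(d$X, d$y, "classify", n_folds = 5, n_repeats = 2,
                     seed = 3)
  expect_equal(ts$best_n, 1)
  expect_equal(ts$curve$metric[1], 1.0)
  expect_equal(ts$selected, "sig")
  expect_equal(ts$cv_metrics$accuracy, 1.0)
  # curve bookkeeping: one value per candidate N, maximum attained at best_n
  expect_equal(nrow(ts$curve), ncol(d$X))
  expect_equal(max(ts$curve$metric), ts$curve$metric[ts$curve$n == ts$best_n])
})

test_that("regression top-N recovers an exactly predictive feature", {
  d <- withr::with_seed(12, {
    x1 <- stats::rnorm(100)
    X <- cbind(x1 = x1,
               matrix(stats::rnorm(100 * 5), 100,
                      dimnames = list(NULL, paste0("noise", 1:5))))
    list(X = X, y = x1)
  })
  ts <- top_n_search(d$X, d$y, "regress", n_folds = 5, n_repeats = 2,
                     seed = 4, n_grid = c(1, 3, 6))
  expect_equal(ts$best_n, 1)
  expect_gt(ts$cv_metrics$r_squared, 0.9)
})

test_that("the search is deterministic given a seed", {
  d <- planted_classification(n = 60, p_noise = 5, seed = 21)
  a <- top_n_search(d$X, d$y, "classify", n_folds = 5, n_repeats = 2,
                    seed = 7, n_grid = c(1, 3))
  b <- top_n_search(d$X, d$y, "classify", n_folds = 5, n_repeats = 2,
                    seed = 7, n_grid = c(1, 3))
  expect_identical(a$curve, b$curve)
  expect_identical(a$cv_metrics, b$cv_metrics)
  expect_identical(a$ranking, b$ranking)
})

test_that("noise features beyond the signal do not inflate the CV metric", {
  d <- withr::with_seed(13, {
    flag <- rep(c(0, 1), each = 40)
    X <- cbind(sig = flag + stats::rnorm(80, sd = 0.2),
               matrix(stats::rnorm(80 * 10), 80,
                      dimnames = list(NULL, paste0("noise", 1:10))))
    list(X = X, y = flag)
  })
  ts <- top_n_search(d$X, d$y, "classify", n_folds = 5, n_repeats = 2,
                     seed = 5, n_grid = c(1, 6, 11))
  expect_lt(max(ts$curve$metric[-1]), ts$curve$metric[1] + 0.1)
})

test_that("classification metrics follow the confusion-count arithmetic", {
  # TP = 5, FN = 3, TN = 10, FP = 2
  y <- c(rep(1, 8), rep(0, 12))
  score <- c(rep(0.9, 5), rep(0.1, 3), rep(0.2, 10), rep(0.8, 2))
  m <- classification_metrics(y, score)
  expect_equal(m$sensitivity, 0.625)
  expect_equal(m$specificity, 10 / 12, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.75)

  # AUC by rank statistics, ties averaged: cross-check with the
  # Wilcoxon-Mann-Whitney statistic
  sc <- withr::with_seed(6, round(stats::runif(30), 1))  # forces ties
  yy <- withr::with_seed(7, sample(c(0, 1), 30, replace = TRUE))
  w <- stats::wilcox.test(sc[yy == 1], sc[yy == 0], exact = FALSE)$statistic
  expect_equal(classification_metrics(yy, sc)$auc,
               unname(w) / (sum(yy == 1) * sum(yy == 0)))

  expect_equal(classification_metrics(c(0, 1), c(0.1, 0.9))$auc, 1)
})

test_that("R-squared is 0 for the mean predictor and 1 for perfection", {
  y <- c(2, 4, 6, 8)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(y, y), 1)
  expect_lt(r_squared(y, rev(y)), 0)
})

test_that("independent-test evaluation fits on train only", {
  d <- withr::with_seed(14, {
    flag <- rep(c(0, 1), 60)
    X <- cbind(sig = flag,
               noise = stats::rnorm(120))
    list(X = X, y = flag)
  })
  tr <- 1:80
  te <- 81:120
  m <- evaluate_model(d$X[tr, ], d$y[tr], d$X[te, ], d$y[te],
                      features = "sig", task = "classify", seed = 2)
  expect_equal(m$accuracy, 1)
  expect_equal(m$auc, 1)

  expect_error(
    evaluate_model(d$X[tr, ], d$y[tr], d$X[te, , drop = FALSE][, 2,
                                                               drop = FALSE],
                   d$y[te], features = "sig", task = "classify"),
    "schema")
})

test_that("stratified folds refuse classes smaller than the fold count", {
  X <- matrix(stats::rnorm(24), 12, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(rep(0, 9), rep(1, 3))
  expect_error(top_n_search(X, y, "classify", n_folds = 5, n_repeats = 1),
               "stratification")
})

test_that("the nested variant runs and returns the same structure", {
  d <- planted_classification(n = 50, p_noise = 3, seed = 31)
  ts <- top_n_search(d$X, d$y, "classify", n_folds = 5, n_repeats = 1,
                     seed = 9, n_grid = c(1, 4), nested = TRUE)
  expect_equal(nrow(ts$curve), 2)
  expect_true(ts$best_n %in% c(1, 4))
  expect_true(all(c("accuracy", "auc") %in% names(ts$cv_metrics)))
})
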