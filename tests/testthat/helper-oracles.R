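# Independent oracles used by the unit and acceptance tests.  These stay
# deliberately naive (enumeration, brute-force definitions, normal
# equations) and share no code with the implementation they check.

# all set partitions of n items as restricted growth strings
enumerate_partitions <- function(n) {
  parts <- list()
  rec <- function(prefix, maxlab) {
    i <- length(prefix) + 1L
    if (i > n) {
      parts[[length(parts) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  parts
}

# exhaustive maximum of multilayer modularity over all partitions of the
# R x W node-layer copies (feasible up to ~6 copies; Bell(6) = 203)
exhaustive_best_quality <- function(net) {
  d <- dim(net$layers)
  n <- d[1] * d[3]
  best <- -Inf
  for (p in enumerate_partitions(n)) {
    q <- multilayer_modularity(net, matrix(p, d[1], d[3]))
    if (q > best) best <- q
  }
  best
}

# literal step-up definition of Benjamini-Hochberg rejection
bh_brute <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- 0L
  for (i in seq_len(m)) if (p[o[i]] <= i * alpha / m) k <- i
  reject <- logical(m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}

# normal-equations OLS; X must include the intercept column
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tt <- drop(b) / se
  list(beta = drop(b), se = se, t = tt, p = 2 * stats::pt(-abs(tt), df),
       df = df)
}

# two disconnected triangles (6 nodes, unit weights)
two_triangles <- function() {
  a <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    a[e[1], e[2]] <- 1
    a[e[2], e[1]] <- 1
  }
  a
}

# best-of-seeds generalized Louvain quality
louvain_best <- function(net, seeds = 1:5) {
  max(vapply(seeds, function(s) generalized_louvain(net, seed = s)$quality,
             numeric(1)))
}

# small random symmetric nonnegative weight matrix with zero diagonal
random_layer <- function(n, density = 0.6, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(0, n, n)
    ut <- which(upper.tri(a))
    on <- ut[stats::runif(length(ut)) < density]
    a[on] <- stats::runif(length(on), 0.2, 1)
    a + t(a)
  })
}
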