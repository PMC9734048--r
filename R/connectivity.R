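#' Sliding-window index ranges
#'
#' Windows are contiguous half-open index ranges `[start, start + width)` in
#' 0-based coordinates, advancing by `step` volumes. The defaults (width 30,
#' step 1) give `T - 30 + 1` maximally overlapping windows.
#'
#' @param n_timepoints Total number of volumes `T`.
#' @param width Window width in volumes (>= 2).
#' @param step Increment in volumes (>= 1).
#' @return Tibble with columns `window` (1-based counter), `start`, `end`
#'   (0-based half-open bounds).
#' @export
#' @examples
#' nrow(sliding_windows(225))  # 196
sliding_windows <- function(n_timepoints, width = 30, step = 1) {
  if (width < 2 || step < 1)
    abort("invalid configuration: need width >= 2 and step >= 1")
  if (n_timepoints < width)
    abort(sprintf(
      "insufficient data: %d timepoints < window width %d", n_timepoints, width))
  starts <- seq(0L, n_timepoints - width, by = step)
  tibble::tibble(window = seq_along(starts), start = as.integer(starts),
                 end = as.integer(starts + width))
}

#' Pearson correlation matrix of one window
#'
#' @param x Numeric matrix (window rows by R columns).
#' @return R x R symmetric correlation matrix, unit diagonal. Columns that
#'   are constant within the window yield `NA` entries for their pairs
#'   (flagged downstream as non-retained).
#' @export
window_correlation <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2)
    abort("insufficient data: window must be a matrix with >= 2 rows")
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  r
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact-t method: `t = r * sqrt((n - 2) / (1 - r^2))` referred to a
#' t distribution with `n - 2` degrees of freedom. `|r| = 1` maps to `p = 0`.
#'
#' @param r Correlation coefficient(s), `|r| <= 1` (vectorized).
#' @param n Number of observations per correlation (>= 3).
#' @return Two-sided p-value(s) in `[0, 1]`; `NA` in, `NA` out.
#' @export
#' @examples
#' correlation_pvalue(0.5, 30)  # ~0.0049
correlation_pvalue <- function(r, n) {
  if (any(n < 3)) abort("insufficient data: need n >= 3 for a correlation p-value")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) abort("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2))
  pmin(1, p)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Rejects the k smallest p-values where k is the largest i with
#' `p_(i) <= i * alpha / m`; adjusted q-values come from
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return List with `reject` (logical vector) and `q` (adjusted values).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(list(reject = logical(0), q = numeric(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(reject = !is.na(q) & q <= alpha, q = q)
}

# BH critical |r| sequence: the step-up rule "reject the k smallest p-values
# where k is the largest i with p_(i) <= i*alpha/m" is, for the exact-t
# p-value at fixed n, equivalent to "reject the k largest |r| where k is the
# largest i with |r|_(i) >= rcrit_i".  Precomputing rcrit once per stack
# avoids 2 t-CDF evaluations per pair per window.
bh_critical_r <- function(m, n, alpha) {
  tq <- stats::qt(1 - seq_len(m) * alpha / (2 * m), df = n - 2)
  tq <- pmax(tq, 0)
  tq / sqrt(n - 2 + tq^2)
}

#' Number of unique region pairs tested per window
#'
#' @param n_regions Number of ROIs.
#' @return `choose(n_regions, 2)`; 34716 for the 264-node parcellation.
#' @export
n_connections <- function(n_regions) choose(n_regions, 2)

#' Build an FDR-thresholded sliding-window layer stack
#'
#' For every sliding window: Pearson correlations for all
#' `choose(R, 2)` region pairs, exact-t p-values, Benjamini-Hochberg FDR
#' within the window across all pairs, and zeroing of non-retained entries.
#' Significant negative correlations are then either dropped (`negatives =
#' "zero"`, the default, keeping weights nonnegative for the modularity null
#' model) or kept with their sign (`"retain"`). Pairs involving a column that
#' is constant within a window are undefined and treated as non-retained.
#'
#' @param ts T x R numeric matrix (one subject's ROI time series), columns
#'   named by node id.
#' @param width,step Sliding-window width and increment in volumes.
#' @param alpha Within-window FDR level.
#' @param negatives Policy for significant negative correlations.
#' @param subject_id Optional subject identifier carried in the result.
#' @return A `layer_stack`: list with `layers` (R x R x W array of retained
#'   correlation weights, zero diagonal), `retained` (logical array of the
#'   same shape), `windows` (tibble from [sliding_windows()]), and the
#'   parameters used. `n_pairs_tested` records the per-window family size.
#' @export
build_layer_stack <- function(ts, width = 30, step = 1, alpha = 0.05,
                              negatives = c("zero", "retain"),
                              subject_id = NULL) {
  negatives <- match.arg(negatives)
  if (!is.matrix(ts)) ts <- as.matrix(ts)
  if (anyNA(ts)) abort("time series contains missing values")
  R <- ncol(ts)
  win <- sliding_windows(nrow(ts), width, step)
  W <- nrow(win)
  ut <- upper.tri(matrix(0, R, R))
  n_pairs <- sum(ut)
  rcrit <- bh_critical_r(n_pairs, width, alpha)
  layers <- array(0, dim = c(R, R, W))
  retained <- array(FALSE, dim = c(R, R, W))
  for (w in seq_len(W)) {
    rows <- (win$start[w] + 1):win$end[w]
    r <- window_correlation(ts[rows, , drop = FALSE])
    rv <- r[ut]
    av <- abs(rv)
    av[is.na(av)] <- -1  # constant-column pairs: undefined, never retained
    ord <- order(av, decreasing = TRUE)
    hit <- which(av[ord] >= rcrit)
    keep <- logical(n_pairs)
    if (length(hit) > 0) keep[ord[seq_len(max(hit))]] <- TRUE
    wt <- numeric(n_pairs)
    wt[keep] <- rv[keep]
    if (negatives == "zero") {
      keep <- keep & wt > 0
      wt[wt < 0] <- 0
    }
    m <- matrix(0, R, R)
    m[ut] <- wt
    m <- m + t(m)
    km <- matrix(FALSE, R, R)
    km[ut] <- keep
    km <- km | t(km)
    layers[, , w] <- m
    retained[, , w] <- km
  }
  ids <- colnames(ts)
  if (is.null(ids)) ids <- node_ids(R)
  structure(list(layers = layers, retained = retained, windows = win,
                 node_ids = ids, width = width, step = step, alpha = alpha,
                 negatives = negatives, n_pairs_tested = n_connections(R),
                 subject_id = subject_id),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  d <- dim(x$layers)
  cat(sprintf(
    "<layer_stack> %d nodes x %d windows (width %d, step %d, alpha %g, negatives '%s')\n",
    d[1], d[3], x$width, x$step, x$alpha, x$negatives))
  cat(sprintf("  %d pairs tested per window; mean retained edges/window: %.1f\n",
              x$n_pairs_tested, mean(apply(x$retained, 3, sum)) / 2))
  invisible(x)
}

#' @describeIn build_layer_stack Long tibble of retained edges
#'   (`window`, `from`, `to`, `weight`).
#' @param x A `layer_stack`.
#' @param ... Unused.
#' @export
tidy.layer_stack <- function(x, ...) {
  d <- dim(x$layers)
  ut <- which(upper.tri(matrix(0, d[1], d[1])), arr.ind = TRUE)
  purrr::map_dfr(seq_len(d[3]), function(w) {
    lay <- x$layers[, , w]
    keep <- x$retained[, , w][ut]
    tibble::tibble(window = w,
                   from = x$node_ids[ut[keep, 1]],
                   to = x$node_ids[ut[keep, 2]],
                   weight = lay[ut][keep])
  })
}
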