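#' Temporal multilayer network
#'
#' Stacks the windowed connectivity layers and couples each node to itself in
#' ordinally adjacent layers with weight `omega`. `gamma` scales the
#' intralayer configuration null model (`gamma` > 1 favors smaller
#' communities); `omega` controls temporal label persistence.
#'
#' @param layers A [build_layer_stack()] result, an R x R x W array, or a
#'   list of symmetric R x R matrices with zero diagonal.
#' @param gamma Intralayer resolution (> 0).
#' @param omega Interlayer coupling weight (>= 0).
#' @return A `multilayer_network` list: `layers` (R x R x W array), `gamma`,
#'   `omega`, `node_ids`.
#' @export
multilayer_network <- function(layers, gamma = 1, omega = 1) {
  if (gamma <= 0 || omega < 0)
    abort("invalid configuration: need gamma > 0 and omega >= 0")
  node_ids_ <- NULL
  if (inherits(layers, "layer_stack")) {
    node_ids_ <- layers$node_ids
    layers <- layers$layers
  } else if (is.list(layers)) {
    layers <- array(unlist(layers),
                    dim = c(nrow(layers[[1]]), ncol(layers[[1]]),
                            length(layers)))
  }
  stopifnot(is.array(layers), length(dim(layers)) == 3,
            dim(layers)[1] == dim(layers)[2])
  if (is.null(node_ids_)) node_ids_ <- node_ids(dim(layers)[1])
  structure(list(layers = layers, gamma = gamma, omega = omega,
                 node_ids = node_ids_),
            class = "multilayer_network")
}

#' Multilayer modularity of a community assignment
#'
#' Evaluates the temporal multilayer quality function
#' \deqn{Q = \frac{1}{2\mu} \sum_{ijsr} \left[ \left( A_{ijs} -
#'   \gamma \frac{k_{is} k_{js}}{2 m_s} \right) \delta_{sr} +
#'   \delta_{ij} C_{jsr} \right] \delta(g_{is}, g_{jr})}
#' where \eqn{C_{jsr} = \omega} for ordinally adjacent layers and
#' \eqn{2\mu} is the total node-layer strength including coupling. A layer
#' with zero total weight contributes no intralayer term but keeps its
#' coupling terms. With a single layer this reduces to Newman-Girvan
#' modularity.
#'
#' @param net A [multilayer_network()].
#' @param labels R x W integer matrix of community labels (columns = layers).
#' @return The modularity value; invariant under community relabeling.
#' @export
multilayer_modularity <- function(net, labels) {
  stopifnot(inherits(net, "multilayer_network"))
  d <- dim(net$layers)
  R <- d[1]; W <- d[3]
  labels <- as.matrix(labels)
  if (nrow(labels) != R || ncol(labels) != W)
    abort("labels must be an R x W matrix matching the network")
  twom <- apply(net$layers, 3, sum)
  twomu <- sum(twom) + 2 * net$omega * R * (W - 1)
  if (twomu <= 0)
    abort("undefined quality: all layers empty and omega = 0")
  qsum <- 0
  for (s in seq_len(W)) {
    if (twom[s] > 0) {
      A <- net$layers[, , s]
      k <- colSums(A)
      for (g in unique(labels[, s])) {
        idx <- labels[, s] == g
        qsum <- qsum + sum(A[idx, idx]) -
          net$gamma * sum(k[idx])^2 / twom[s]
      }
    }
    if (s < W)
      qsum <- qsum + 2 * net$omega * sum(labels[, s] == labels[, s + 1])
  }
  qsum / twomu
}

#' Generalized Louvain maximization of multilayer modularity
#'
#' Greedy two-phase optimization over all node-layer copies: repeated sweeps
#' (in seeded random order) moving each node-layer to the neighboring
#' community with the largest strictly positive modularity gain, followed by
#' aggregation of communities into super-nodes, cycling until quality stops
#' improving. Deterministic given `seed`.
#'
#' @param net A [multilayer_network()].
#' @param seed Integer seed for the sweep-order randomization.
#' @return A `community_assignment`: `labels` (R x W integer matrix, node
#'   ids as rownames), `quality` (its exact [multilayer_modularity()]),
#'   `n_communities`, `seed`.
#' @export
generalized_louvain <- function(net, seed = 1L) {
  stopifnot(inherits(net, "multilayer_network"))
  d <- dim(net$layers)
  twom <- apply(net$layers, 3, sum)
  if (sum(twom) + 2 * net$omega * d[1] * (d[3] - 1) <= 0)
    abort("undefined quality: all layers empty and omega = 0")
  res <- genlouvain_cpp(net$layers, d[1], d[3], net$gamma, net$omega,
                        as.integer(seed))
  labels <- res$labels
  rownames(labels) <- net$node_ids
  structure(list(labels = labels,
                 quality = res$quality,
                 n_communities = res$n_communities,
                 seed = as.integer(seed)),
            class = "community_assignment")
}

#' @export
print.community_assignment <- function(x, ...) {
  cat(sprintf("<community_assignment> %d nodes x %d layers, %d communities, Q = %.4f (seed %d)\n",
              nrow(x$labels), ncol(x$labels), x$n_communities, x$quality,
              x$seed))
  invisible(x)
}

#' Repeated community detection with independent seeds
#'
#' Runs [generalized_louvain()] `n_reps` times with run seeds derived
#' reproducibly from `master_seed`, to average out the pseudo-randomness of
#' the greedy optimizer. Downstream flexibility statistics are averaged over
#' these repetitions.
#'
#' @param net A [multilayer_network()].
#' @param n_reps Number of repetitions (the reference analysis uses 100).
#' @param master_seed Integer seed from which run seeds are drawn.
#' @return A `community_detection` list of `community_assignment`s with
#'   attributes `master_seed`, `gamma`, `omega`.
#' @export
detect_communities <- function(net, n_reps = 100, master_seed = 1L) {
  if (n_reps < 1) abort("invalid configuration: n_reps must be >= 1")
  run_seeds <- withr_seed(master_seed,
                          sample.int(.Machine$integer.max - 1L, n_reps))
  runs <- lapply(run_seeds, function(s) generalized_louvain(net, seed = s))
  structure(runs, class = "community_detection",
            master_seed = as.integer(master_seed),
            gamma = net$gamma, omega = net$omega)
}

#' @export
print.community_detection <- function(x, ...) {
  q <- vapply(x, `[[`, numeric(1), "quality")
  cat(sprintf("<community_detection> %d repetitions; Q in [%.4f, %.4f]\n",
              length(x), min(q), max(q)))
  invisible(x)
}

#' @describeIn detect_communities Long tibble of labels across repetitions
#'   (`rep`, `node_id`, `window`, `community`) plus a `quality` column.
#' @param x A `community_detection`.
#' @param ... Unused.
#' @export
tidy.community_detection <- function(x, ...) {
  purrr::map_dfr(seq_along(x), function(r) {
    lab <- x[[r]]$labels
    tibble::tibble(rep = r,
                   node_id = rep(rownames(lab), ncol(lab)),
                   window = rep(seq_len(ncol(lab)), each = nrow(lab)),
                   community = as.integer(lab),
                   quality = x[[r]]$quality)
  })
}

#' @describeIn detect_communities One-row summary (repetitions, mean and
#'   best quality, median community count).
#' @export
glance.community_detection <- function(x, ...) {
  q <- vapply(x, `[[`, numeric(1), "quality")
  k <- vapply(x, `[[`, numeric(1), "n_communities")
  tibble::tibble(n_reps = length(x), mean_quality = mean(q),
                 best_quality = max(q), median_communities = stats::median(k))
}
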