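#' Node flexibility of one community assignment
#'
#' Flexibility of node i is \eqn{f_i = n_i / N}: the number of times the
#' node changes its community label between consecutive windows, divided by
#' `N = W - 1`, the total number of possible changes.
#'
#' @param labels R x W integer matrix of community labels, or a
#'   `community_assignment`.
#' @return Named numeric vector of length R with values in `[0, 1]`.
#' @export
#' @examples
#' node_flexibility(matrix(c(1, 1, 1, 2, 2, 2, 1, 2), nrow = 2, byrow = TRUE))
node_flexibility <- function(labels) {
  if (inherits(labels, "community_assignment")) labels <- labels$labels
  labels <- as.matrix(labels)
  W <- ncol(labels)
  if (W < 2) abort("insufficient layers: flexibility needs >= 2 windows")
  changes <- labels[, -1, drop = FALSE] != labels[, -W, drop = FALSE]
  f <- rowSums(changes) / (W - 1)
  names(f) <- rownames(labels)
  f
}

#' Average per-node vectors over detection repetitions
#'
#' @param reps A `community_detection`, or a list of equal-length numeric
#'   vectors (e.g. per-repetition node flexibilities).
#' @return Elementwise arithmetic mean vector.
#' @export
mean_over_reps <- function(reps) {
  if (inherits(reps, "community_detection"))
    reps <- lapply(reps, node_flexibility)
  if (length(reps) == 0) abort("no repetitions to average")
  len <- lengths(reps)
  if (any(len != len[1])) abort("repetition vectors differ in length")
  Reduce(`+`, reps) / length(reps)
}

#' Aggregate node flexibility to functional systems and whole brain
#'
#' System flexibility is the unweighted mean over that system's nodes;
#' whole-brain flexibility is the mean over all nodes; stability is
#' `1 - flexibility` at every level.
#'
#' @param node_flex Named numeric vector of per-node flexibility (names =
#'   node ids), typically [mean_over_reps()] output.
#' @param atlas Tibble mapping `node_id` to `system` (see [make_atlas()]).
#' @param subject_id Optional subject identifier.
#' @param n_reps Number of repetitions averaged (recorded, not used).
#' @return A `flexibility_profile` tibble with columns `subject_id`, `level`
#'   (`"node"`, `"system"`, `"whole_brain"`), `unit` (node id, system label,
#'   or `"whole_brain"`), `flexibility`, `stability`.
#' @export
aggregate_flexibility <- function(node_flex, atlas, subject_id = NA_character_,
                                  n_reps = NA_integer_) {
  ids <- names(node_flex)
  if (is.null(ids)) ids <- node_ids(length(node_flex))
  missing <- setdiff(ids, atlas$node_id)
  if (length(missing) > 0)
    abort(sprintf("mapping error: nodes without a system label: %s",
                  paste(head(missing, 5), collapse = ", ")))
  node_tbl <- tibble::tibble(level = "node", unit = ids,
                             flexibility = unname(node_flex))
  sys_tbl <- tibble::tibble(unit = ids, flexibility = unname(node_flex)) |>
    dplyr::left_join(atlas, by = c(unit = "node_id")) |>
    dplyr::group_by(.data$system) |>
    dplyr::summarise(flexibility = mean(.data$flexibility), .groups = "drop") |>
    dplyr::transmute(level = "system", unit = .data$system, .data$flexibility)
  wb_tbl <- tibble::tibble(level = "whole_brain", unit = "whole_brain",
                           flexibility = mean(node_flex))
  out <- dplyr::bind_rows(node_tbl, sys_tbl, wb_tbl) |>
    dplyr::mutate(subject_id = subject_id, stability = 1 - .data$flexibility,
                  .before = 1) |>
    dplyr::relocate("subject_id", "level", "unit", "flexibility", "stability")
  attr(out, "n_reps") <- n_reps
  class(out) <- c("flexibility_profile", class(out))
  out
}

#' One subject's flexibility profile from repeated community detection
#'
#' Computes per-node flexibility for every repetition, averages at the node
#' level, then aggregates to systems and whole brain.
#'
#' @param detection A `community_detection` (see [detect_communities()]).
#' @param atlas Node-to-system mapping tibble.
#' @param subject_id Optional subject identifier.
#' @return A `flexibility_profile` tibble (see [aggregate_flexibility()]).
#' @export
flexibility_profile <- function(detection, atlas, subject_id = NA_character_) {
  aggregate_flexibility(mean_over_reps(detection), atlas,
                        subject_id = subject_id, n_reps = length(detection))
}
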