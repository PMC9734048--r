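#' Plot retained-edge density across windows
#'
#' @param object A [build_layer_stack()] result.
#' @param ... Unused.
#' @return A ggplot: fraction of retained region pairs per sliding window.
#' @export
autoplot.layer_stack <- function(object, ...) {
  d <- dim(object$layers)
  dens <- apply(object$retained, 3, sum) / 2 / object$n_pairs_tested
  ggplot2::ggplot(tibble::tibble(window = seq_len(d[3]), density = dens),
                  ggplot2::aes(x = .data$window, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window", y = "retained edge fraction",
                  title = sprintf("FDR-retained connectivity (alpha = %g)",
                                  object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a flexibility profile by functional system
#'
#' @param object A [flexibility_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot: system-level flexibility bars with the whole-brain mean
#'   as a reference line.
#' @export
autoplot.flexibility_profile <- function(object, ...) {
  sys <- dplyr::filter(object, .data$level == "system")
  wb <- dplyr::filter(object, .data$level == "whole_brain")$flexibility
  ggplot2::ggplot(sys, ggplot2::aes(x = stats::reorder(.data$unit,
                                                       -.data$flexibility),
                                    y = .data$flexibility)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = wb, linetype = "dashed") +
    ggplot2::labs(x = "functional system", y = "flexibility") +
    ggplot2::theme_minimal()
}

#' Plot the top-N cross-validation curve
#'
#' @param object A [top_n_search()] result.
#' @param ... Unused.
#' @return A ggplot: mean CV metric per candidate N, best N marked.
#' @export
autoplot.topn_search <- function(object, ...) {
  ylab <- if (object$task == "classify") "mean CV accuracy" else "mean CV R-squared"
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$n, y = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$best_n, linetype = "dashed") +
    ggplot2::labs(x = "top N features by importance", y = ylab) +
    ggplot2::theme_minimal()
}

#' Boxplot of whole-brain flexibility by group
#'
#' @param flex Stacked flexibility profiles for a cohort.
#' @param subjects Subject metadata tibble.
#' @param by Grouping: `"group"` (ADHD vs TDC) or `"medication"` (TDC /
#'   unmedicated / medicated ADHD).
#' @return A ggplot.
#' @export
plot_flexibility_groups <- function(flex, subjects,
                                    by = c("group", "medication")) {
  by <- match.arg(by)
  dat <- flex |>
    dplyr::filter(.data$level == "whole_brain") |>
    dplyr::inner_join(subjects, by = "subject_id")
  if (by == "medication")
    dat <- dat |>
      dplyr::mutate(grp = dplyr::case_when(
        .data$group == "TDC" ~ "TDC",
        .data$medication == "medicated" ~ "ADHD medicated",
        TRUE ~ "ADHD unmedicated"))
  else dat <- dplyr::mutate(dat, grp = .data$group)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$grp, y = .data$flexibility)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "whole-brain flexibility") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
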