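#' Covariate-adjusted group contrast by ordinary least squares
#'
#' Fits `y ~ group + covariates` by OLS and reports the group-indicator
#' coefficient with its two-sided t-test on residual degrees of freedom.
#' Covariates that are constant in the analysis subset are dropped (they
#' carry no information and would only render the design rank-deficient).
#'
#' @param y Numeric response (one feature value per subject).
#' @param group Binary indicator (0/1, logical, or 2-level factor); the
#'   reported effect is level-1 minus level-0.
#' @param covariates Optional data frame of covariates (factors become
#'   indicator columns via the model matrix).
#' @return One-row tibble: `beta`, `se`, `t`, `p`, `df`, `n`.
#' @export
#' @examples
#' fit_contrast(c(1, 2, 3, 4), c(0, 0, 1, 1))  # beta = 2, p ~ 0.106
fit_contrast <- function(y, group, covariates = NULL) {
  if (is.factor(group)) group <- as.numeric(group) - 1
  group <- as.numeric(group)
  if (length(unique(group)) != 2)
    abort("degenerate model: group indicator must take exactly two values")
  if (sd(y) == 0) abort("degenerate model: response has zero variance")
  dat <- data.frame(y = y, .group = group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- vapply(covariates, function(v) length(unique(v)) > 1, logical(1))
    dat <- cbind(dat, covariates[, keep, drop = FALSE])
  }
  if (nrow(dat) <= ncol(dat))
    abort("degenerate model: fewer subjects than design columns")
  fit <- stats::lm(y ~ ., data = dat)
  if (anyNA(coef(fit)))
    abort("degenerate model: rank-deficient design")
  if (fit$df.residual < 1 || summary(fit)$sigma < 1e-12)
    abort("degenerate model: zero residual variance")
  cf <- summary(fit)$coefficients[".group", ]
  tibble::tibble(beta = cf[["Estimate"]], se = cf[["Std. Error"]],
                 t = cf[["t value"]], p = cf[["Pr(>|t|)"]],
                 df = fit$df.residual, n = nrow(dat))
}

#' FDR-correct a declared family of contrasts
#'
#' Applies Benjamini-Hochberg step-up adjustment across exactly the rows of
#' `results` (e.g. the 14 functional systems, or the 3 medication
#' comparisons), filling column `q` and labeling the family.
#'
#' @param results Tibble of contrast results with a `p` column.
#' @param family Family label. If `results` already carries a `family`
#'   column with more than one value, mixing families is refused.
#' @return `results` with `q` and `family` columns.
#' @export
correct_family <- function(results, family = "family") {
  if (nrow(results) == 0) abort("empty contrast family")
  if ("family" %in% names(results) &&
      length(unique(results$family)) > 1)
    abort("configuration error: mixed families in one correction call")
  results$q <- bh_fdr(results$p)$q
  results$family <- family
  results
}

#' Group contrasts of flexibility at a chosen aggregation level
#'
#' Runs covariate-adjusted OLS contrasts of flexibility between groups and
#' applies FDR correction over the appropriate family:
#' \describe{
#'   \item{`adhd_vs_tdc`}{ADHD minus TDC (all ADHD in one group) for every
#'     unit at `level`. The single whole-brain comparison is reported at raw
#'     p (`q = p`); system- and node-level families are FDR-corrected across
#'     their units.}
#'   \item{`medication`}{Three pairwise whole-brain-style comparisons per
#'     unit — medicated vs unmedicated ADHD, unmedicated ADHD vs TDC,
#'     medicated ADHD vs TDC — FDR-corrected across the three.}
#' }
#'
#' @param flex Flexibility table: stacked [flexibility_profile()] rows for
#'   all subjects (columns `subject_id`, `level`, `unit`, `flexibility`).
#' @param subjects Subject metadata tibble (see [simulate_cohort()]).
#' @param comparison `"adhd_vs_tdc"` or `"medication"`.
#' @param level `"whole_brain"`, `"system"`, or `"node"`.
#' @param covariates Covariate column names in `subjects` entered into every
#'   model (age and mean FD continuous; sex and site as indicators).
#' @return A `group_contrasts` tibble: `level`, `unit`, `contrast`, `beta`,
#'   `se`, `t`, `p`, `q`, `df`, `n`, `family`.
#' @export
contrast_groups <- function(flex, subjects,
                            comparison = c("adhd_vs_tdc", "medication"),
                            level = c("whole_brain", "system", "node"),
                            covariates = c("age", "sex", "mean_fd", "site")) {
  comparison <- match.arg(comparison)
  level <- match.arg(level)
  dat <- flex |>
    dplyr::filter(.data$level == !!level) |>
    dplyr::inner_join(subjects, by = "subject_id",
                      suffix = c("", ".subj"))

  one_unit <- function(d, unit, sel1, sel0, contrast) {
    d1 <- d[sel1(d) | sel0(d), , drop = FALSE]
    ind <- as.numeric(sel1(d1))
    res <- tryCatch(
      fit_contrast(d1$flexibility, ind,
                   covariates = d1[, covariates, drop = FALSE]),
      error = function(e) {
        # degenerate unit (e.g. zero-variance feature): keep the row, NA stats
        tibble::tibble(beta = NA_real_, se = NA_real_, t = NA_real_,
                       p = NA_real_, df = NA_real_, n = nrow(d1))
      })
    dplyr::mutate(res, level = level, unit = unit, contrast = contrast,
                  .before = 1)
  }

  is_adhd <- function(d) d$group == "ADHD"
  is_tdc <- function(d) d$group == "TDC"
  is_med <- function(d)
    d$group == "ADHD" & !is.na(d$medication) & d$medication == "medicated"
  is_naive <- function(d)
    d$group == "ADHD" & !is.na(d$medication) & d$medication == "naive"

  units <- unique(dat$unit)
  if (comparison == "adhd_vs_tdc") {
    res <- purrr::map_dfr(units, function(u) {
      one_unit(dat[dat$unit == u, ], u, is_adhd, is_tdc, "ADHD-TDC")
    })
    fam <- switch(level, whole_brain = "whole_brain_raw",
                  system = sprintf("systems_%d", length(units)),
                  node = sprintf("nodes_%d", length(units)))
    if (level == "whole_brain") {
      res$q <- res$p  # single comparison reported at raw p
      res$family <- fam
    } else {
      res <- correct_family(res, fam)
    }
  } else {
    specs <- list(
      list(sel1 = is_med, sel0 = is_naive, lab = "medicated-naive"),
      list(sel1 = is_naive, sel0 = is_tdc, lab = "naive-TDC"),
      list(sel1 = is_med, sel0 = is_tdc, lab = "medicated-TDC"))
    res <- purrr::map_dfr(units, function(u) {
      du <- dat[dat$unit == u, ]
      three <- purrr::map_dfr(specs, function(sp)
        one_unit(du, u, sp$sel1, sp$sel0, sp$lab))
      correct_family(three, sprintf("medication_3_%s", u))
    })
  }
  class(res) <- c("group_contrasts", class(res))
  res
}

#' @describeIn contrast_groups One-row-per-family summary: number of tests
#'   and of FDR-significant ones at `alpha`.
#' @param x A `group_contrasts` tibble.
#' @param alpha Significance level applied to `q`.
#' @param ... Unused.
#' @export
glance.group_contrasts <- function(x, alpha = 0.05, ...) {
  x |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(n_tests = dplyr::n(),
                     n_significant = sum(.data$q < alpha),
                     min_p = min(.data$p), .groups = "drop")
}
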