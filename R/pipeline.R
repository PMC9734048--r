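#' Run the full neural-flexibility pipeline on a synthetic cohort
#'
#' Executes simulate -> sliding-window connectivity -> multilayer community
#' detection -> flexibility -> group statistics -> predictive models, and
#' optionally writes every stage's outputs plus a machine-readable manifest.
#'
#' The modeling recipe mirrors the reference analysis: classification
#' (ADHD vs TDC) and severity regression are trained on one site and
#' evaluated on the other as an independent test, with female and
#' medicated-ADHD subjects excluded from training by default (both
#' exclusions configurable). The severity model is trained on ADHD subjects
#' only.
#'
#' @param config A [synth_config()] describing the cohort.
#' @param width,step,alpha,negatives Connectivity-stage parameters (see
#'   [build_layer_stack()]).
#' @param gamma,omega Multilayer parameters (see [multilayer_network()]).
#' @param n_reps Community-detection repetitions per subject.
#' @param n_folds,n_repeats,n_grid Cross-validation shape and candidate-N
#'   grid for [top_n_search()].
#' @param exclude_female,exclude_medicated Training-cohort exclusions.
#' @param train_site,test_site Site labels for the independent-test split.
#' @param run_models Fit the predictive models (set `FALSE` for quick runs).
#' @param seed Master seed for everything downstream of the generator (the
#'   generator itself uses `config$master_seed`).
#' @param out_dir Optional output directory; when given, all stage outputs
#'   and `manifest.json` (config, seeds, per-file checksums) are written.
#' @return A `neuroflex_results` list: `cohort`, `flexibility` (all
#'   subjects' profiles), `contrasts` (whole-brain + system ADHD-TDC, and
#'   medication comparisons when a medicated group exists), `classification`
#'   and `severity` (each a list with `search` and `test` metrics), and
#'   `manifest`.
#' @export
run_pipeline <- function(config = synth_config(),
                         width = 30, step = 1, alpha = 0.05,
                         negatives = "zero",
                         gamma = 1, omega = 1, n_reps = 100,
                         n_folds = 10, n_repeats = 10, n_grid = NULL,
                         exclude_female = TRUE, exclude_medicated = TRUE,
                         train_site = "site1", test_site = "site2",
                         run_models = TRUE,
                         seed = config$master_seed, out_dir = NULL) {
  cohort <- simulate_cohort(config)
  n <- nrow(cohort$subjects)
  subj_seeds <- withr_seed(seed + 10L, sample.int(.Machine$integer.max - 1L, n))

  flex <- purrr::map_dfr(seq_len(n), function(i) {
    id <- cohort$subjects$subject_id[i]
    stack <- build_layer_stack(cohort$timeseries[[id]], width = width,
                               step = step, alpha = alpha,
                               negatives = negatives, subject_id = id)
    net <- multilayer_network(stack, gamma = gamma, omega = omega)
    det <- detect_communities(net, n_reps = n_reps,
                              master_seed = subj_seeds[i])
    flexibility_profile(det, cohort$atlas, subject_id = id)
  })

  contrasts <- list(
    whole_brain = contrast_groups(flex, cohort$subjects, "adhd_vs_tdc",
                                  "whole_brain"),
    system = contrast_groups(flex, cohort$subjects, "adhd_vs_tdc", "system"))
  if (config$n_per_group[["adhd_medicated"]] > 0 &&
      config$n_per_group[["adhd_unmedicated"]] > 0 &&
      config$n_per_group[["tdc"]] > 0)
    contrasts$medication <- contrast_groups(flex, cohort$subjects,
                                            "medication", "whole_brain")

  classification <- severity <- NULL
  if (run_models) {
    X <- flexibility_features(flex)
    meta <- cohort$subjects[match(rownames(X), cohort$subjects$subject_id), ]
    keep <- rep(TRUE, nrow(meta))
    if (exclude_female) keep <- keep & meta$sex == "M"
    if (exclude_medicated)
      keep <- keep & !(meta$group == "ADHD" &
                         !is.na(meta$medication) &
                         meta$medication == "medicated")
    tr <- keep & meta$site == train_site
    te <- keep & meta$site == test_site

    y_cls <- as.numeric(meta$group == "ADHD")
    cls_search <- top_n_search(X[tr, , drop = FALSE], y_cls[tr], "classify",
                               n_folds = n_folds, n_repeats = n_repeats,
                               n_grid = n_grid, seed = seed + 1L)
    cls_test <- evaluate_model(X[tr, , drop = FALSE], y_cls[tr],
                               X[te, , drop = FALSE], y_cls[te],
                               cls_search$selected, "classify",
                               seed = seed + 2L)
    classification <- list(search = cls_search, test = cls_test,
                           n_train = sum(tr), n_test = sum(te))

    adhd_tr <- tr & meta$group == "ADHD"
    adhd_te <- te & meta$group == "ADHD"
    reg_folds <- min(n_folds, sum(adhd_tr))
    sev_search <- top_n_search(X[adhd_tr, , drop = FALSE],
                               meta$severity[adhd_tr], "regress",
                               n_folds = reg_folds, n_repeats = n_repeats,
                               n_grid = n_grid, seed = seed + 3L)
    sev_test <- if (sum(adhd_te) >= 2) {
      evaluate_model(X[adhd_tr, , drop = FALSE], meta$severity[adhd_tr],
                     X[adhd_te, , drop = FALSE], meta$severity[adhd_te],
                     sev_search$selected, "regress", seed = seed + 4L)
    } else {
      # too few held-out subjects for a meaningful R^2
      tibble::tibble(r_squared = NA_real_)
    }
    severity <- list(search = sev_search, test = sev_test,
                     n_train = sum(adhd_tr), n_test = sum(adhd_te))
  }

  manifest <- list(
    package = "neuroflex",
    version = as.character(utils::packageVersion("neuroflex")),
    seed = seed,
    subject_seeds = subj_seeds,
    parameters = list(width = width, step = step, alpha = alpha,
                      negatives = negatives, gamma = gamma, omega = omega,
                      n_reps = n_reps, n_folds = n_folds,
                      n_repeats = n_repeats,
                      exclude_female = exclude_female,
                      exclude_medicated = exclude_medicated,
                      train_site = train_site, test_site = test_site),
    config = unclass_config(config))

  res <- structure(list(cohort = cohort, flexibility = flex,
                        contrasts = contrasts,
                        classification = classification,
                        severity = severity, manifest = manifest),
                   class = "neuroflex_results")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$n_per_group <- as.list(out$n_per_group)
  out$switch_rate <- as.list(out$switch_rate)
  out
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(res$cohort, file.path(out_dir, "cohort"))
  readr::write_csv(res$flexibility, file.path(out_dir, "flexibility.csv"))
  for (nm in names(res$contrasts))
    readr::write_csv(res$contrasts[[nm]],
                     file.path(out_dir, sprintf("contrasts_%s.csv", nm)))
  for (task in c("classification", "severity")) {
    if (is.null(res[[task]])) next
    readr::write_csv(res[[task]]$search$curve,
                     file.path(out_dir, sprintf("%s_curve.csv", task)))
    readr::write_csv(res[[task]]$search$ranking,
                     file.path(out_dir, sprintf("%s_ranking.csv", task)))
    jsonlite::write_json(
      list(cv = as.list(res[[task]]$search$cv_metrics),
           best_n = res[[task]]$search$best_n,
           test = as.list(res[[task]]$test)),
      file.path(out_dir, sprintf("%s_metrics.json", task)),
      auto_unbox = TRUE, digits = NA)
  }
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- res$manifest
  manifest$checksums <- as.list(setNames(unname(tools::md5sum(files)),
                                         sub(paste0(out_dir, "/"), "", files,
                                             fixed = TRUE)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.neuroflex_results <- function(x, ...) {
  cat(sprintf("<neuroflex_results> %d subjects\n", nrow(x$cohort$subjects)))
  wb <- x$contrasts$whole_brain
  cat(sprintf("  whole-brain ADHD-TDC: beta = %.4f, p = %.4g\n",
              wb$beta[1], wb$p[1]))
  if (!is.null(x$classification))
    cat(sprintf("  classification: best N = %d, CV accuracy = %.3f, test accuracy = %.3f\n",
                x$classification$search$best_n,
                x$classification$search$cv_metrics$accuracy,
                x$classification$test$accuracy))
  if (!is.null(x$severity))
    cat(sprintf("  severity: best N = %d, CV R^2 = %.3f, test R^2 = %.3f\n",
                x$severity$search$best_n,
                x$severity$search$cv_metrics$r_squared,
                x$severity$test$r_squared))
  invisible(x)
}
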