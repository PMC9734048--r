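#' Configuration for the synthetic resting-state cohort generator
#'
#' Defines a multi-subject generative model for parcellated ROI time series
#' with planted dynamic modular structure. Each subject's brain switches
#' between `n_states` discrete connectivity states; within a state, signal
#' rows are drawn from a zero-mean multivariate normal whose correlation
#' matrix has `rho_in` inside that state's modules, `rho_out` between
#' modules, and 1 on the diagonal. The probability of a state change at each
#' timepoint boundary (the switch rate) is group-dependent — lower for
#' unmedicated ADHD than for typically developing children (TDC), with the
#' medicated group close to TDC — so the planted switching propensity is the
#' ground truth that downstream flexibility estimates should recover.
#'
#' @param n_per_group Named integer vector of subject counts for groups
#'   `tdc`, `adhd_unmedicated`, `adhd_medicated`.
#' @param n_regions Number of ROIs (nodes) `R`.
#' @param n_timepoints Number of volumes `T` per subject.
#' @param n_states Number of discrete connectivity states `K`.
#' @param n_modules Modules per state partition (used when `state_partitions`
#'   is `NULL`; partitions are then drawn reproducibly from `master_seed`).
#' @param state_partitions Optional list of `n_states` integer vectors of
#'   length `n_regions`, mapping each node to a module within that state.
#' @param rho_in Within-module correlation, in `[0, 1)`.
#' @param rho_out Between-module correlation, in `[0, rho_in]`.
#' @param switch_rate Named numeric vector of per-group baseline state-switch
#'   probabilities (per timepoint boundary), each in `[0, 1]`.
#' @param switch_rate_sd Between-subject standard deviation of the switch
#'   rate around its group baseline (severity is a continuum, not a group
#'   constant); set to 0 for exactly identical rates within a group.
#' @param covariate_effects Named list of additive effects of `age` (per year,
#'   centered at 11), `sex` (male indicator), `motion` (per mm of mean FD,
#'   centered at 0.12), and `site` (site2 indicator) on the switch rate.
#' @param severity_slope,severity_noise_sd Severity score model: severity =
#'   `severity_slope * (-switch_rate) + N(0, severity_noise_sd)`, so higher
#'   severity accompanies lower switching.
#' @param n_sites Number of acquisition sites.
#' @param master_seed Integer seed; identical seeds give bit-identical cohorts.
#'
#' @return A `synth_config` list, validated (positive-definiteness of every
#'   state correlation matrix included).
#' @export
#' @examples
#' cfg <- synth_config(n_per_group = c(tdc = 3, adhd_unmedicated = 3,
#'                                     adhd_medicated = 0),
#'                     n_regions = 12, n_timepoints = 40, master_seed = 7)
#' cohort <- simulate_cohort(cfg)
#' cohort$subjects
synth_config <- function(n_per_group = c(tdc = 40, adhd_unmedicated = 40,
                                         adhd_medicated = 40),
                         n_regions = 50,
                         n_timepoints = 120,
                         n_states = 3,
                         n_modules = 5,
                         state_partitions = NULL,
                         rho_in = 0.6,
                         rho_out = 0.1,
                         switch_rate = c(tdc = 0.10, adhd_unmedicated = 0.04,
                                         adhd_medicated = 0.09),
                         switch_rate_sd = 0.02,
                         covariate_effects = list(age = 0, sex = 0,
                                                  motion = 0, site = 0),
                         severity_slope = 200,
                         severity_noise_sd = 3,
                         n_sites = 2,
                         master_seed = 1L) {
  groups <- c("tdc", "adhd_unmedicated", "adhd_medicated")
  if (!all(groups %in% names(n_per_group)))
    abort("`n_per_group` must name tdc, adhd_unmedicated, adhd_medicated")
  n_per_group <- n_per_group[groups]
  if (any(n_per_group < 0) || sum(n_per_group) < 1)
    abort("invalid configuration: subject counts must be >= 0, total >= 1")
  if (n_states < 1 || n_timepoints < 1 || n_regions < 2)
    abort("invalid configuration: need n_states >= 1, n_timepoints >= 1, n_regions >= 2")
  if (!(rho_out >= 0 && rho_out <= rho_in && rho_in < 1))
    abort("invalid configuration: need 0 <= rho_out <= rho_in < 1")
  if (!all(groups %in% names(switch_rate)))
    abort("`switch_rate` must name tdc, adhd_unmedicated, adhd_medicated")
  switch_rate <- switch_rate[groups]
  if (any(switch_rate < 0 | switch_rate > 1))
    abort("invalid configuration: switch rates must lie in [0, 1]")
  if (switch_rate_sd < 0)
    abort("invalid configuration: switch_rate_sd must be >= 0")

  if (is.null(state_partitions)) {
    m <- min(n_modules, n_regions)
    state_partitions <- withr_seed(master_seed + 1000L, {
      lapply(seq_len(n_states), function(k) sample(rep_len(seq_len(m), n_regions)))
    })
  }
  if (length(state_partitions) != n_states)
    abort("invalid configuration: one partition required per state")
  for (p in state_partitions) {
    if (length(p) != n_regions)
      abort("invalid configuration: each partition must map all nodes")
  }
  for (p in state_partitions) {
    sigma <- state_correlation(p, rho_in, rho_out)
    ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
    if (!ok)
      abort("invalid configuration: state correlation matrix is not positive definite")
  }

  structure(list(
    n_per_group = n_per_group, n_regions = n_regions,
    n_timepoints = n_timepoints, n_states = n_states,
    state_partitions = state_partitions, rho_in = rho_in, rho_out = rho_out,
    switch_rate = switch_rate, switch_rate_sd = switch_rate_sd,
    covariate_effects = covariate_effects,
    severity_slope = severity_slope, severity_noise_sd = severity_noise_sd,
    n_sites = n_sites, master_seed = as.integer(master_seed)
  ), class = "synth_config")
}

# evaluate `code` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) withr::with_seed(seed, code)

#' Block-structured correlation matrix for one connectivity state
#'
#' @param partition Integer vector mapping each node to a module.
#' @param rho_in Within-module correlation.
#' @param rho_out Between-module correlation.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
state_correlation <- function(partition, rho_in, rho_out) {
  same <- outer(partition, partition, `==`)
  sigma <- ifelse(same, rho_in, rho_out)
  diag(sigma) <- 1
  sigma
}

#' Sample a discrete connectivity-state sequence
#'
#' A first-order switching process: at each of the `n_timepoints - 1`
#' boundaries the state is, with probability `switch_rate`, redrawn uniformly
#' from the `n_states - 1` other states, and retained otherwise.
#'
#' @param n_timepoints Sequence length `T` (>= 1).
#' @param switch_rate Per-boundary switch probability in `[0, 1]`.
#' @param n_states Number of states `K` (>= 1).
#' @param seed Integer seed.
#' @return Integer vector of length `n_timepoints` with values in `1:n_states`.
#' @export
#' @examples
#' sample_state_sequence(10, 1, 2, seed = 1)  # strict alternation
sample_state_sequence <- function(n_timepoints, switch_rate, n_states, seed) {
  if (n_timepoints < 1 || n_states < 1)
    abort("invalid configuration: n_timepoints and n_states must be >= 1")
  if (switch_rate < 0 || switch_rate > 1)
    abort("invalid configuration: switch_rate must lie in [0, 1]")
  withr_seed(seed, {
    s <- integer(n_timepoints)
    s[1] <- sample.int(n_states, 1)
    if (n_timepoints > 1) {
      flips <- runif(n_timepoints - 1) < switch_rate
      for (t in 2:n_timepoints) {
        if (flips[t - 1] && n_states > 1) {
          others <- setdiff(seq_len(n_states), s[t - 1])
          s[t] <- others[sample.int(n_states - 1, 1)]
        } else s[t] <- s[t - 1]
      }
    }
    s
  })
}

#' Sample a T x R ROI time series given a state sequence
#'
#' Rows are independent draws from the multivariate normal with the current
#' state's block correlation matrix (unit variances, zero mean). Temporal
#' autocorrelation within a state is deliberately absent: downstream
#' statistics depend only on window correlation structure.
#'
#' @param states Integer state sequence (one entry per timepoint).
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return Numeric matrix, `length(states)` rows by `config$n_regions`
#'   columns; column names are node ids.
#' @export
sample_timeseries <- function(states, config, seed) {
  K <- config$n_states
  if (any(states < 1 | states > K))
    abort("invalid configuration: state labels outside 1..n_states")
  R <- config$n_regions
  chols <- lapply(config$state_partitions, function(p)
    chol(state_correlation(p, config$rho_in, config$rho_out)))
  tt <- length(states)
  withr_seed(seed, {
    z <- matrix(rnorm(tt * R), tt, R)
    x <- matrix(0, tt, R)
    for (k in unique(states)) {
      idx <- which(states == k)
      x[idx, ] <- z[idx, , drop = FALSE] %*% chols[[k]]
    }
    colnames(x) <- node_ids(R)
    x
  })
}

node_ids <- function(R) sprintf("n%03d", seq_len(R))

#' Generate a synthetic cohort: time series, subject table, atlas
#'
#' Per-subject switch rates are the group baseline plus the configured
#' additive covariate effects, clamped to `[0, 1]`; the severity score is
#' `severity_slope * (-switch_rate)` plus Gaussian noise, so severity and
#' switching are negatively related. All randomness is derived reproducibly
#' from `config$master_seed`.
#'
#' @param config A [synth_config()].
#' @return A `synthetic_cohort` list with elements `timeseries` (named list
#'   of T x R matrices), `subjects` (tibble: subject_id, group, medication,
#'   age, sex, mean_fd, site, severity, true_switch_rate), and `atlas`
#'   (tibble: node_id, system).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- sum(config$n_per_group)
  group_of <- rep(names(config$n_per_group), config$n_per_group)

  seeds <- withr_seed(config$master_seed, {
    matrix(sample.int(.Machine$integer.max - 1L, 2L * n), ncol = 2)
  })

  covs <- withr_seed(config$master_seed + 1L, {
    tibble::tibble(
      age = round(runif(n, 8, 14), 1),
      sex = ifelse(runif(n) < 0.7, "M", "F"),
      mean_fd = round(pmax(0.01, rnorm(n, 0.12, 0.04)), 3),
      site = paste0("site", sample.int(config$n_sites, n, replace = TRUE))
    )
  })

  eff <- config$covariate_effects
  base <- config$switch_rate[group_of]
  rate <- base +
    eff$age * (covs$age - 11) +
    eff$sex * (covs$sex == "M") +
    eff$motion * (covs$mean_fd - 0.12) +
    eff$site * (covs$site == "site2")
  if (config$switch_rate_sd > 0)
    rate <- rate + withr_seed(config$master_seed + 4L,
                              rnorm(n, 0, config$switch_rate_sd))
  rate <- pmin(1, pmax(0, rate))

  severity <- withr_seed(config$master_seed + 2L, {
    config$severity_slope * (-rate) + rnorm(n, 0, config$severity_noise_sd)
  })

  subjects <- tibble::tibble(
    subject_id = sprintf("sub%03d", seq_len(n)),
    group = ifelse(group_of == "tdc", "TDC", "ADHD"),
    medication = dplyr::case_when(
      group_of == "adhd_medicated" ~ "medicated",
      group_of == "adhd_unmedicated" ~ "naive",
      TRUE ~ NA_character_
    ),
    covs,
    severity = as.numeric(severity),
    true_switch_rate = as.numeric(rate)
  )

  ts <- lapply(seq_len(n), function(i) {
    st <- sample_state_sequence(config$n_timepoints, rate[i], config$n_states,
                                seed = seeds[i, 1])
    sample_timeseries(st, config, seed = seeds[i, 2])
  })
  names(ts) <- subjects$subject_id

  atlas <- make_atlas(config$n_regions, seed = config$master_seed + 3L)

  structure(list(timeseries = ts, subjects = subjects, atlas = atlas,
                 config = config),
            class = "synthetic_cohort")
}

#' Build a node-to-functional-system atlas mapping
#'
#' Assigns each node to one of up to 14 canonical functional system labels
#' (the systems of the 264-node functional parcellation: SH, SM, AUD, VIS,
#' CO, FP, DMN, MEM, SAL, SUB, VA, DA, CB, UC), in randomly shuffled but
#' reproducible fashion.
#'
#' @param n_regions Number of nodes.
#' @param n_systems Number of systems to use (capped at 14 and `n_regions`).
#' @param seed Integer seed for the node-to-system shuffle.
#' @return Tibble with columns `node_id`, `system`.
#' @export
make_atlas <- function(n_regions, n_systems = 14, seed = 1L) {
  labels <- c("SH", "SM", "AUD", "VIS", "CO", "FP", "DMN",
              "MEM", "SAL", "SUB", "VA", "DA", "CB", "UC")
  m <- min(n_systems, length(labels), n_regions)
  sys <- withr_seed(seed, sample(rep_len(labels[seq_len(m)], n_regions)))
  tibble::tibble(node_id = node_ids(n_regions), system = sys)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d regions x %d timepoints, %d states\n",
    nrow(x$subjects), x$config$n_regions, x$config$n_timepoints,
    x$config$n_states))
  print(dplyr::count(x$subjects, .data$group, .data$medication))
  invisible(x)
}
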