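# Minimal cohort -> whole-brain flexibility -> group contrast loop used by
# the replicate-cohort power and calibration studies.  Works at the level of
# node flexibility vectors (no tidy aggregation) to keep replicates cheap.

cohort_whole_brain_contrast <- function(config, n_reps, width = 30) {
  cohort <- simulate_cohort(config)
  n <- nrow(cohort$subjects)
  seeds <- withr::with_seed(config$master_seed + 77L,
                            sample.int(.Machine$integer.max - 1L, n))
  wb <- vapply(seq_len(n), function(i) {
    stack <- build_layer_stack(cohort$timeseries[[i]], width = width)
    det <- detect_communities(multilayer_network(stack), n_reps = n_reps,
                              master_seed = seeds[i])
    mean(mean_over_reps(det))
  }, numeric(1))
  s <- cohort$subjects
  fit_contrast(wb, as.numeric(s$group == "ADHD"),
               covariates = s[, c("age", "sex", "mean_fd", "site")])
}

# study conditions for the parameter-recovery power experiment
power_config <- function(seed) {
  synth_config(
    n_per_group = c(tdc = 40, adhd_unmedicated = 40, adhd_medicated = 0),
    n_regions = 50, n_timepoints = 120,
    switch_rate = c(tdc = 0.10, adhd_unmedicated = 0.04,
                    adhd_medicated = 0.09),
    switch_rate_sd = 0,  # exactly the stated planted rates
    master_seed = seed)
}

# scaled-down null conditions: equal planted switch rates in both groups
null_config <- function(seed) {
  synth_config(
    n_per_group = c(tdc = 20, adhd_unmedicated = 20, adhd_medicated = 0),
    n_regions = 30, n_timepoints = 80,
    switch_rate = c(tdc = 0.10, adhd_unmedicated = 0.10,
                    adhd_medicated = 0.10),
    switch_rate_sd = 0,  # identical planted rates under the null
    master_seed = seed)
}
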