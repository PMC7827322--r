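# Monte-Carlo runs shared by the benchmark-reproduction tests. Each
# condition is computed once per test session and cached; every run uses
# the same fixed base seed so results are reproducible.

study_cache <- new.env(parent = emptyenv())

study_reps <- 30L
study_seed <- 97L

cached_study <- function(scenario, strength, correlation, methods,
                         reps = study_reps) {
  key <- paste(scenario, strength, correlation,
               paste(sort(methods), collapse = "+"), reps, sep = "_")
  if (is.null(study_cache[[key]])) {
    cond <- data.frame(scenario = scenario, strength = strength,
                       correlation = correlation)
    study_cache[[key]] <- run_simulation_study(
      cond, methods = methods, reps = reps, base_seed = study_seed)
  }
  study_cache[[key]]
}

mean_or <- function(study, method, group) {
  reps <- study$replicates
  reps$odds_ratio[reps$method == method & reps$group == group]
}

# Tolerance for comparing a Monte-Carlo mean with a published Monte-Carlo
# value: 3 standard errors, accounting for both this run's R replicates
# and the published value's 100 replicates.
mc_tolerance <- function(values, published_reps = 100) {
  3 * sd(values) * sqrt(1 / length(values) + 1 / published_reps)
}
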