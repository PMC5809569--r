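# fixtures are built in code; the heavier study-scale objects are cached
# so several test files can share one simulation/fit

toy_attributes <- function(n_attr = 6L, K = 4L) {
  dce_attributes(paste0("attr", seq_len(n_attr)),
                 replicate(n_attr, paste0("L", seq_len(K)),
                           simplify = FALSE))
}

# random zero-sum segment utilities via the effects-coded parameterization
toy_utilities <- function(attributes, S = 2L, sd = 1, seed = 5L) {
  P <- nrow(effects_columns(attributes))
  B <- dcemix:::with_seed(seed, matrix(stats::rnorm(P * S, sd = sd), P, S))
  expand_utilities(B, attributes)
}

toy_synth_config <- function(n = 150L, S = 2L, sd = 1, scale = 1,
                             seed = 1L, n_versions = 5L,
                             tasks = 12L, holdouts = c(4L, 9L)) {
  at <- toy_attributes()
  shares <- if (S == 1L) 1 else c(0.3, rep(0.7 / (S - 1), S - 1))
  synthetic_config(
    attributes = at, segment_shares = shares,
    segment_utilities = toy_utilities(at, S = S, sd = sd),
    design = design_config(n_versions = n_versions, tasks_per_version = tasks,
                           alternatives_per_task = 3L,
                           attributes_per_task = 3L,
                           holdout_positions = holdouts, seed = seed),
    n_respondents = n, scale = scale, seed = seed
  )
}

toy_estimation_data <- function(...) {
  split_holdout(simulate_respondents(toy_synth_config(...))$dataset)$estimation
}

.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# full study-replica recovery run (simulate 563 respondents, fit 2 classes
# with 10 starts); shared by the acceptance checks
study_recovery <- function(seed) {
  cached(paste0("rec", seed), function() {
    recovery_experiment(study_config(seed = seed))
  })
}
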