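# Shared fixture builders: small designs and generator settings used across
# test files. Everything is generated in code at test time.

tiny_objects <- function(n = 12, experiment = 1, seed = 101) {
  assign_conditions(n, experiment, seed = seed)
}

# Small, fast generator settings; every knob overridable per test.
tiny_params <- function(..., experiment = 1, seed = 202) {
  args <- list(...)
  defaults <- list(experiment = experiment, n_participants = 4,
                   n_channels = 16, srate = 50, seed = seed)
  keep <- defaults[setdiff(names(defaults), names(args))]
  do.call(generator_params, c(keep, args))
}

# Directly simulated participant x condition x time null ERP matrix
# (Gaussian noise), bypassing the EEG generator, for permutation-test
# calibration checks where only the group-level structure matters.
null_erp_matrix <- function(n_participants, n_times, conditions = c("A", "B"),
                            sd = 1) {
  values <- array(rnorm(n_participants * length(conditions) * n_times, sd = sd),
                  dim = c(n_participants, length(conditions), n_times),
                  dimnames = list(NULL, conditions, NULL))
  structure(list(values = values,
                 times = seq(0, by = 20, length.out = n_times),
                 conditions = conditions, cluster = "Pz",
                 window = c(0, 20 * (n_times - 1))),
            class = "erp_matrix")
}

# Independent paired-t oracle used by several permutation-test checks.
oracle_t <- function(d) {
  n <- length(d)
  mean(d) / (sd(d) / sqrt(n))
}

# Independent max-cluster-size computation from a p-value vector.
oracle_max_cluster <- function(p, alpha = 0.05, min_len = 2) {
  sig <- p < alpha
  best <- 0L
  run <- 0L
  for (s in sig) {
    run <- if (s) run + 1L else 0L
    if (run >= min_len && run > best) best <- run
  }
  best
}
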