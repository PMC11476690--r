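# Small seeded fixtures shared across test files; everything is generated
# in code.

tiny_cubic <- function(n = 60, noise_sd = 1, seed = 3) {
  ds <- generate_dataset(experiment_spec("cubic", n_points = n,
                                         noise_sd = noise_sd, seed = seed))
  list(x = matrix(ds$replicates$x, ncol = 1), y = ds$replicates$y,
       truth = unname(ds$spec$params), data = ds)
}

random_params <- function(config, seed, scale = 0.4) {
  set.seed(seed)
  pinet_unpack(stats::rnorm(count_parameters(config), 0, scale), config)
}

# independent monomial design evaluation used as an expansion oracle
oracle_design <- function(X, exps) {
  out <- matrix(1, nrow(X), nrow(exps))
  for (k in seq_len(nrow(exps)))
    for (j in seq_len(ncol(exps)))
      out[, k] <- out[, k] * X[, j]^exps[k, j]
  out
}
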