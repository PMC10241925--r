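# Shared fixtures, all generated in code.

# Small numeric dataset with a known AND rule and mild label noise.
fixture_planted_and <- function(n = 300, d = 6, noise = 0, seed = 42) {
  make_planted_rule(synthetic_spec(
    n = n, d = d,
    rule = node_and(node_gt(1, 0.5), node_gt(2, -0.3)),
    label_noise = noise, seed = seed))
}

# Tiny deterministic dataset for exact-value tests.
fixture_tiny <- function() {
  x <- cbind(f1 = c(1, 2, 3, 4, 5, 6),
             f2 = c(0.5, -0.2, 1.5, -1, 2, 0.1))
  bf_dataset(x, labels = c(0, 0, 1, 1, 1, 0))
}

# A random valid Boolean representation over d columns (uses caller's RNG).
random_fixture_rep <- function(ds, max_dim = 3, max_depth = 3) {
  cfg <- evolution_config(pop_size = 4, generations = 0, max_dim = max_dim,
                          max_depth = max_depth)
  w <- rep(1 / ncol(ds$features), ncol(ds$features))
  pop <- init_population(ds, cfg, w)
  pop[[sample.int(length(pop), 1)]]
}

# Quick evolution config for plumbing tests.
quick_config <- function(...) {
  evolution_config(pop_size = 20, generations = 3, ...)
}
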