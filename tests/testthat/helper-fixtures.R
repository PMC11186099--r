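# Shared small fixtures, built in code at test time.

# Small planted dataset: 5 cell types + 1 activity program (6 ground-truth
# programs), sized so consensus factorization runs in seconds. Cached per
# session.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_counts(sim_config(
        n_cells = 600, n_genes = 1200, n_groups = 5,
        act_n_genes = 100, seed = 7))
    cache
  }
})

# Z-scored "catalog" weights derived from a simulation's ground-truth log
# factors plus a little seeded noise; a cheap stand-in for a full
# factorization when testing matching machinery.
truth_catalog_weights <- function(ds, noise_sd = 0.05, seed = 1) {
  lf <- log(ds$truth_factors)
  set.seed(seed)
  lf <- lf + matrix(rnorm(length(lf), 0, noise_sd), nrow(lf))
  zscore_weights(lf - min(lf) + 1e-9)
}

# Deterministic toy weight matrix with named genes.
toy_weights <- function(G = 50, k = 4, seed = 42) {
  set.seed(seed)
  W <- matrix(rexp(G * k), G,
              dimnames = list(sprintf("g%03d", seq_len(G)),
                              sprintf("p%02d", seq_len(k))))
  zscore_weights(W)
}
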