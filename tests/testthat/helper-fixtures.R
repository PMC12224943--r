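# Shared fixtures, built in code.

# 2-region connectome with a single edge A -> B of weight 1.
tiny_ab <- function() {
  as_connectome(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE), c("A", "B"))
}

# Small normalized synthetic bundle used by several fitting tests.
small_bundle <- function(n = 20, sigma = 0, seed = 42,
                         params = spread_params(0.3, 0.5, 0.2, 0.8)) {
  cfg <- synth_config(n_regions = n, noise_sigma = sigma,
                      detection_floor = 0, true_params = params,
                      rng_seed = seed)
  C <- synth_connectome(cfg)
  sp <- synth_pathology(C, params, rownames(C)[1], cfg$times,
                        sigma, cfg$detection_floor, rng_seed = seed + 1)
  list(C = C, data = sp$data, truth = sp$truth,
       seed_region = rownames(C)[1], params = params)
}

# Quick fit configuration for tests that loop over many fits.
quick_config <- function(n_starts = 20, seed = 1, maxit = 100,
                         n_refine = 2) {
  fit_config(n_starts = n_starts, n_refine = n_refine, rng_seed = seed,
             maxit = maxit)
}

rel_dev <- function(a, b) {
  scale <- pmax(abs(b), 1e-12 * max(abs(b)))
  max(abs(a - b) / scale)
}
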