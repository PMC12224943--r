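# Screens are exercised at desk scale (small regions/genes, few starts);
# the planted-gene construction mirrors how the generator produced the data.

make_screen_fixture <- function(n_regions = 15, n_decoys = 8, seed = 77,
                                mode = "outgoing") {
  cfg <- synth_config(n_regions = n_regions, n_genes = n_decoys,
                      noise_sigma = 0, detection_floor = 0, rng_seed = seed)
  synth_spread_bundle(cfg, planted_mode = mode)
}

test_that("a planted outgoing gene is recovered at rank 1", {
  fx <- make_screen_fixture()
  cfg <- quick_config(n_starts = 4, seed = 9)
  rec <- screen_genes(fx$data, fx$connectome, fx$seed_regions, fx$expr,
                      modes = "outgoing", config = cfg)
  expect_equal(rec$gene_id[rec$rank == 1 & rec$mode == "outgoing"],
               "planted1")
  expect_true(rec$improves_global[rec$gene_id == "planted1"])
  # select_candidates returns the planted gene first and is prefix-stable
  top1 <- select_candidates(rec, "outgoing", 1)
  expect_equal(top1, "planted1")
  top3 <- select_candidates(rec, "outgoing", 3)
  expect_equal(top3[1], top1)
})

test_that("a uniform gene reproduces the global model's Ave. CCC", {
  fx <- make_screen_fixture(n_decoys = 0)
  cfg <- quick_config(n_starts = 3, seed = 5)
  gfit <- fit_spread_model(fx$data, fx$connectome, fx$seed_regions, cfg)
  g <- rep(3, nrow(fx$connectome))
  for (mode in c("outgoing", "incoming")) {
    fit <- fit_spread_model(fx$data, fx$connectome, fx$seed_regions, cfg,
                            gene = g, mode = mode)
    expect_equal(fit$ave_ccc, gfit$ave_ccc, tolerance = 1e-4)
  }
})

test_that("a pathological expression vector fails its record, not the screen", {
  fx <- make_screen_fixture(n_decoys = 2)
  expr <- fx$expr[1:3, ]
  expr[2, ] <- c(1e308, rep(1e-308, ncol(expr) - 1))
  cfg <- quick_config(n_starts = 2, seed = 9)
  rec <- screen_genes(fx$data, fx$connectome, fx$seed_regions, expr,
                      modes = "outgoing", config = cfg,
                      gene_normalize = "none")
  failed <- rec[rec$gene_id == rownames(expr)[2], ]
  expect_equal(failed$status, "failed")
  expect_true(is.na(failed$rank))
  expect_true(any(rec$status == "ok"))
})

test_that("screen records reproduce from isolated fits with the same seed", {
  fx <- make_screen_fixture(n_decoys = 2)
  cfg <- quick_config(n_starts = 2, seed = 9)
  rec <- screen_genes(fx$data, fx$connectome, fx$seed_regions,
                      fx$expr[1:2, ], modes = "incoming", config = cfg)
  lone <- fit_spread_model(fx$data, fx$connectome, fx$seed_regions, cfg,
                           gene = fx$expr[1, ], mode = "incoming")
  expect_equal(rec$ave_ccc[rec$gene_id == rownames(fx$expr)[1]],
               lone$ave_ccc)
})

test_that("the permutation bootstrap counts nulls and flags degeneracy", {
  fx <- make_screen_fixture()
  cfg <- quick_config(n_starts = 2, seed = 9)
  bs <- permutation_bootstrap_gene(fx$data, fx$connectome, fx$seed_regions,
                                   fx$expr["planted1", ], mode = "outgoing",
                                   B = 5, config = cfg, rng_seed = 4)
  expect_length(bs$null_ave_ccc, 5 - bs$n_failed)
  expect_true(bs$percentile_of_actual >= 0 && bs$percentile_of_actual <= 100)

  const <- rep(2, nrow(fx$connectome))
  bsc <- permutation_bootstrap_gene(fx$data, fx$connectome, fx$seed_regions,
                                    const, mode = "outgoing", B = 3,
                                    config = cfg, rng_seed = 4)
  expect_true(bsc$degenerate)
})

test_that("gene-pathology Pearson correlations behave on the observed mask", {
  fx <- make_screen_fixture()
  obs <- fx$data$observed[, 1]
  mask <- obs > 0
  expr <- rbind(prop = obs * 2 + 0, neg = max(obs) - obs)
  expr[expr <= 0] <- 1e-9
  colnames(expr) <- rownames(fx$connectome)
  tab <- gene_pathology_correlation(expr, fx$data)
  r_prop <- tab$r[tab$gene_id == "prop" & tab$time_months == 3]
  expect_equal(r_prop, 1, tolerance = 1e-12)
  r_neg <- tab$r[tab$gene_id == "neg" & tab$time_months == 3]
  expect_equal(r_neg, -1, tolerance = 1e-12)
  # construct a vector exactly orthogonal (after centering) to the burdens
  x <- obs[mask] - mean(obs[mask])
  set.seed(1)
  w <- rnorm(sum(mask))
  w <- w - mean(w)
  w <- w - sum(w * x) / sum(x * x) * x
  g <- rep(1, length(obs))
  g[mask] <- w - min(w) + 1  # shift positive; correlation is shift-invariant
  gm <- rbind(orth = g)
  colnames(gm) <- names(obs)
  r <- gene_pathology_correlation(gm, fx$data)
  expect_lt(abs(r$r[r$time_months == 3]), 1e-10)
})
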