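test_that("seed vector places gamma at injected regions only", {
  expect_equal(build_seed_vector(c("A", "B", "C"), "B", 0.1),
               c(A = 0, B = 0.1, C = 0))
  expect_equal(build_seed_vector(c("A", "B", "C"), c("A", "C"), 0.5),
               c(A = 0.5, B = 0, C = 0.5))
  expect_error(build_seed_vector(c("A", "B"), "Z", 0.1), "Z")
  expect_error(build_seed_vector(c("A", "B"), "A", 0), "gamma")
})

test_that("gene modulation scales rows, columns, or both", {
  C <- matrix(c(0, 2, 3, 0), 2, 2, byrow = TRUE)
  g <- c(2, 1)
  expect_equal(gene_modulated_connectome(C, g, "outgoing"),
               matrix(c(0, 4, 3, 0), 2, 2, byrow = TRUE))
  expect_equal(gene_modulated_connectome(C, g, "incoming"),
               matrix(c(0, 2, 6, 0), 2, 2, byrow = TRUE))
  expect_equal(gene_modulated_connectome(C, g, "combined"),
               matrix(c(0, 4, 6, 0), 2, 2, byrow = TRUE))
  expect_error(gene_modulated_connectome(C, c(1, 2, 3), "outgoing"), "match")
  expect_error(gene_modulated_connectome(C, c(-1, 2), "outgoing"), ">= 0")
})

test_that("closed-form predictions match scalar and 2x2 hand solutions", {
  C <- tiny_ab()
  # beta = 0: pure exponential growth of the seed
  p <- predict_pathology(C, spread_params(0.33, 0, 0.1, 0.5), "A", 3)
  expect_equal(p$values["A", 1], 0.1 * exp(0.99), tolerance = 1e-10)
  expect_equal(p$values["B", 1], 0)
  # alpha = beta = 0: identity dynamics
  p0 <- predict_pathology(C, spread_params(0, 0, 0.4, 0.2), "B", c(1, 5))
  expect_equal(unname(p0$values), matrix(c(0, 0.4, 0, 0.4), 2))
  # fully retrograde transfer along A -> B moves mass B -> A
  p1 <- predict_pathology(C, spread_params(0, 1, 1, 1), "B", log(2))
  expect_equal(unname(p1$values[, 1]), c(0.5, 0.5), tolerance = 1e-10)
})

test_that("matrix exponential agrees with the ODE oracle on random instances", {
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(5:30, 1)
    cfg <- synth_config(n_regions = n, rng_seed = rep,
                        density = runif(1, 0.15, 0.6))
    C <- synth_connectome(cfg)
    params <- spread_params(runif(1, -1, 1), runif(1, 0.05, 2),
                            runif(1, 0.05, 1), runif(1))
    a <- predict_pathology(C, params, rownames(C)[1], c(3, 6))
    b <- ode_oracle(C, params, rownames(C)[1], c(3, 6))
    expect_equal(a$status, "ok")
    expect_lt(rel_dev(a$values, b$values), 1e-6)
  }
})

test_that("spread conserves, grows, and stays nonnegative as the generator dictates", {
  cfg <- synth_config(n_regions = 15, rng_seed = 3)
  C <- synth_connectome(cfg)
  seed <- rownames(C)[1]
  # alpha = 0: total mass conserved
  p <- predict_pathology(C, spread_params(0, 0.7, 0.3, 0.6), seed, c(2, 7))
  expect_equal(colSums(p$values), c(t2 = 0.3, t7 = 0.3), tolerance = 1e-8)
  # general alpha: total mass grows as exp(alpha * t)
  p2 <- predict_pathology(C, spread_params(0.4, 0.7, 0.3, 0.6), seed, c(3, 6))
  expect_equal(unname(colSums(p2$values)), 0.3 * exp(0.4 * c(3, 6)),
               tolerance = 1e-8)
  expect_true(all(p2$values >= 0))
})

test_that("predictions are symmetric under transpose + direction flip", {
  cfg <- synth_config(n_regions = 12, rng_seed = 8)
  C <- synth_connectome(cfg)
  seed <- rownames(C)[2]
  for (s in c(0, 0.3, 0.87)) {
    a <- predict_pathology(C, spread_params(0.2, 0.9, 0.5, s), seed, c(3, 6))
    b <- predict_pathology(t(C), spread_params(0.2, 0.9, 0.5, 1 - s),
                           seed, c(3, 6))
    expect_equal(a$values, b$values, tolerance = 1e-12)
  }
})

test_that("a uniform gene is absorbed into the diffusivity", {
  cfg <- synth_config(n_regions = 10, rng_seed = 12)
  C <- synth_connectome(cfg)
  seed <- rownames(C)[1]
  cc <- 2.5
  g <- rep(cc, 10)
  base <- function(beta) predict_pathology(
    C, spread_params(0.1, beta, 0.3, 0.7), seed, c(3, 6))
  for (mode in c("outgoing", "incoming")) {
    gm <- predict_pathology(C, spread_params(0.1, 0.4, 0.3, 0.7), seed,
                            c(3, 6), gene = g, mode = mode,
                            gene_normalize = "none")
    expect_equal(gm$values, base(0.4 * cc)$values, tolerance = 1e-9)
  }
  gmc <- predict_pathology(C, spread_params(0.1, 0.4, 0.3, 0.7), seed,
                           c(3, 6), gene = g, mode = "combined",
                           gene_normalize = "none")
  expect_equal(gmc$values, base(0.4 * cc^2)$values, tolerance = 1e-9)
  # with mean normalization any uniform gene reproduces the global model
  gm1 <- predict_pathology(C, spread_params(0.1, 0.4, 0.3, 0.7), seed,
                           c(3, 6), gene = g, mode = "combined",
                           gene_normalize = "mean")
  expect_equal(gm1$values, base(0.4)$values, tolerance = 1e-12)
})

test_that("the semigroup property holds for the propagator", {
  cfg <- synth_config(n_regions = 8, rng_seed = 21)
  C <- synth_connectome(cfg)
  params <- spread_params(0.25, 0.8, 0.2, 0.4)
  p36 <- predict_pathology(C, params, rownames(C)[1], c(3, 6))
  A <- spread_generator(C, params)
  E3 <- as.matrix(Matrix::expm(Matrix::Matrix(A * 3)))
  expect_equal(unname(p36$values[, 2]), unname(drop(E3 %*% p36$values[, 1])),
               tolerance = 1e-10)
})

test_that("non-finite dynamics yield a failed status, not a crash", {
  C <- as_connectome(matrix(c(0, 9, 0, 0), 2, 2, byrow = TRUE), c("A", "B"))
  g <- c(1e308, 1)  # 9 * 1e308 overflows the modulated weight to Inf
  p <- predict_pathology(C, spread_params(0, 5, 1, 1), "B", c(3, 6),
                         gene = g, mode = "outgoing", gene_normalize = "none")
  expect_equal(p$status, "failed")
})
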