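# Synthetic-data generators. Each generator is a pure function of its
# arguments and seed (bit-reproducible), and produces data with the
# statistical structure the analysis pipeline assumes: sparse nonnegative
# directed weights with heavy-tailed (log-normal) magnitudes, optional
# bilateral block structure, pathology spanning orders of magnitude with
# structural zeros, and gene vectors with planted outgoing/incoming/combined
# effects.

#' Synthetic study configuration
#'
#' Desk-scale defaults emulating the structure of a mesoscale tract-tracing
#' connectome and regional pathology quantified at 3 and 6 months post
#' injection: 40 regions, 25% edge density, and a two-tier weight structure:
#' a strong backbone occupying \code{backbone_frac} of the n^2 edge universe
#' carries almost all projection weight, while the remaining nonzero edges
#' sit \code{weak_scale} lower. Together with log-normal within-tier spread
#' this reproduces the ~5 orders of magnitude spanned by tract-tracing
#' projection strengths and the concentration of total weight in the
#' strongest few percent of connections — the "key subnetwork" property the
#' thresholding analyses probe. The backbone cell indices are recorded as
#' the generator's key edge set. true
#' parameters (alpha = 0.3, beta = 0.5, gamma = 0.2, s = 0.8), multiplicative
#' log-normal observation noise (sigma = 0.3 on the log10 scale) and a
#' detection floor of 1e-5 below which burdens are recorded as 0.
#'
#' @param n_regions number of regions.
#' @param bilateral pair regions L/R with weaker contralateral expected
#'   weights.
#' @param density fraction of nonzero off-diagonal edges.
#' @param weight_meanlog,weight_sdlog log-normal parameters of the
#'   within-tier weight spread.
#' @param backbone_frac fraction of the n^2 edge universe occupied by the
#'   strong backbone (the planted key subnetwork).
#' @param weak_scale multiplicative scale of non-backbone edges relative to
#'   backbone edges.
#' @param contra_scale contralateral weight scale (bilateral only).
#' @param normalize_strength rescale weights so the mean column strength is
#'   1. Tract-tracing weights come in arbitrary units; fixing the overall
#'   strength scale puts the diffusion time scale in the transient regime at
#'   the 3-6 month observation times (as in the real data, where pathology
#'   is still evolving between time points), which is what makes the
#'   diffusivity identifiable.
#' @param n_seed_regions number of injected regions.
#' @param true_params generating [spread_params()].
#' @param noise_sigma observation noise s.d. on the log10 scale.
#' @param detection_floor burdens below this observe as 0.
#' @param times months post injection.
#' @param n_genes decoy gene count for screens.
#' @param rng_seed master seed.
#' @return list of class \code{"synth_config"}.
#' @export
synth_config <- function(n_regions = 40, bilateral = FALSE, density = 0.25,
                         weight_meanlog = 0, weight_sdlog = 1,
                         backbone_frac = 0.05, weak_scale = 1e-4,
                         contra_scale = 0.3, normalize_strength = TRUE,
                         n_seed_regions = 1,
                         true_params = spread_params(0.3, 0.5, 0.2, 0.8),
                         noise_sigma = 0.3, detection_floor = 1e-5,
                         times = c(3, 6), n_genes = 50, rng_seed = 1) {
  stopifnot(density > 0, density <= 1, noise_sigma >= 0,
            detection_floor >= 0, n_regions >= 2,
            backbone_frac >= 0, backbone_frac <= density)
  structure(as.list(environment()), class = "synth_config")
}

synth_region_labels <- function(n, bilateral) {
  if (bilateral) {
    if (n %% 2 != 0) stop("bilateral atlas needs an even region count")
    m <- n / 2
    c(sprintf("L%02d", seq_len(m)), sprintf("R%02d", seq_len(m)))
  } else {
    sprintf("R%02d", seq_len(n))
  }
}

#' Generate a synthetic connectome
#'
#' Directed, nonnegative, zero-diagonal weights: each off-diagonal cell is
#' nonzero with probability \code{density}, with log-normal magnitude; a
#' random \code{backbone_frac} of the edge universe forms the strong
#' backbone and the remaining nonzero cells are scaled down by
#' \code{weak_scale}, so the backbone is exactly the strongest-edge
#' subnetwork. Under \code{bilateral = TRUE} regions are paired L/R and
#' contralateral (cross-hemisphere) expected weights are scaled down by
#' \code{contra_scale}, so the expectation structure commutes with the L/R
#' swap.
#'
#' @param config [synth_config()].
#' @return connectome matrix, with attribute \code{"key_edges"}: the linear
#'   indices of the backbone cells (the generator's key edge set).
#' @export
synth_connectome <- function(config = synth_config()) {
  n <- config$n_regions
  regions <- synth_region_labels(n, config$bilateral)
  gen <- local_seed(config$rng_seed, {
    mask <- matrix(stats::runif(n * n) < config$density, n, n)
    diag(mask) <- FALSE
    w <- matrix(stats::rlnorm(n * n, config$weight_meanlog,
                              config$weight_sdlog), n, n)
    # the backbone spans all regions (a directed cycle through a random
    # region order, as the strongest-edge subnetwork of a real connectome
    # spans the quantified regions), topped up with random strong cells
    n_bb <- max(n, ceiling(config$backbone_frac * n * n))
    ord <- sample(n)
    cycle <- cbind(ord, c(ord[-1], ord[1]))
    backbone <- unique(c(cycle[, 1] + (cycle[, 2] - 1) * n))
    pool <- setdiff(which(!diag(TRUE, n)), backbone)
    backbone <- sort(c(backbone, sample(pool, n_bb - length(backbone))))
    mask[backbone] <- TRUE
    weak <- setdiff(which(mask), backbone)
    w[weak] <- w[weak] * config$weak_scale
    list(weights = w * mask, backbone = backbone)
  })
  m <- gen$weights
  if (config$bilateral) {
    half <- n / 2
    hemi <- rep(c("L", "R"), each = half)
    contra <- outer(hemi, hemi, "!=")
    m[contra] <- m[contra] * config$contra_scale
  }
  diag(m) <- 0
  if (isTRUE(config$normalize_strength)) {
    m <- m / mean(colSums(m))
  }
  out <- as_connectome(m, regions)
  attr(out, "key_edges") <- gen$backbone
  out
}

#' Generate synthetic pathology observations
#'
#' Runs the forward spread model at the true parameters, then applies
#' multiplicative log-normal observation noise
#' (\code{observed = X * 10^(sigma * Z)}) and a detection floor below which
#' burdens are recorded as structural zeros.
#'
#' @param C connectome matrix.
#' @param true_params generating [spread_params()].
#' @param seed_regions injected region labels.
#' @param times months post injection.
#' @param noise_sigma log10-scale noise s.d.
#' @param detection_floor observation floor.
#' @param rng_seed seed for the noise draw.
#' @return list: \code{data} ([pathology_data()]), \code{truth} (list with
#'   the noiseless prediction matrix, true_params, seed_regions).
#' @export
synth_pathology <- function(C, true_params, seed_regions, times = c(3, 6),
                            noise_sigma = 0, detection_floor = 0,
                            rng_seed = 1) {
  pred <- predict_pathology(C, true_params, seed_regions, times)
  if (pred$status != "ok") stop("forward model failed at the true parameters")
  clean <- pred$values
  obs <- clean
  if (noise_sigma > 0) {
    z <- local_seed(rng_seed, matrix(stats::rnorm(length(clean)),
                                     nrow(clean), ncol(clean)))
    obs <- clean * 10^(noise_sigma * z)
  }
  obs[obs < detection_floor] <- 0
  list(data = pathology_data(obs, times, rownames(C)),
       truth = list(noiseless = clean, true_params = true_params,
                    seed_regions = seed_regions, noise_sigma = noise_sigma,
                    detection_floor = detection_floor, rng_seed = rng_seed))
}

#' Generate a synthetic gene-expression matrix with planted effects
#'
#' Decoy genes are i.i.d. log-normal across regions. Each planted gene gets
#' a higher-variance vector intended to be used (via its declared mode) to
#' modulate the connectome when generating an associated pathology dataset;
#' the returned ledger records the pairing.
#'
#' @param regions region labels (atlas order).
#' @param n_genes number of decoy genes.
#' @param planted named character vector: gene id -> effect mode.
#' @param decoy_sdlog,planted_sdlog log-normal sdlog for decoys / planted
#'   vectors.
#' @param rng_seed seed.
#' @return list: \code{expr} (genes x regions matrix; planted genes first),
#'   \code{planted} (the ledger, as given).
#' @export
synth_gene_matrix <- function(regions, n_genes = 50, planted = NULL,
                              decoy_sdlog = 0.5, planted_sdlog = 1,
                              rng_seed = 1) {
  n <- length(regions)
  local_seed(rng_seed, {
    ids <- sprintf("decoy%03d", seq_len(n_genes))
    expr <- matrix(stats::rlnorm(n_genes * n, 0, decoy_sdlog), n_genes, n,
                   dimnames = list(ids, regions))
    if (length(planted)) {
      pm <- matrix(stats::rlnorm(length(planted) * n, 0, planted_sdlog),
                   length(planted), n,
                   dimnames = list(names(planted), regions))
      expr <- rbind(pm, expr)
    }
    list(expr = expr, planted = planted)
  })
}

#' Generate a full synthetic screening bundle
#'
#' Convenience wrapper producing a connectome, a gene matrix with one
#' planted gene, and a pathology dataset generated from the planted gene's
#' modulated connectome (or the plain connectome when \code{planted_mode =
#' "global"}).
#'
#' @param config [synth_config()].
#' @param planted_mode \code{"global"} (no gene effect) or a gene effect
#'   mode.
#' @param gene_normalize normalization used when the planted gene enters the
#'   generator (matches the fitting default).
#' @return list: \code{connectome}, \code{expr}, \code{planted_gene},
#'   \code{data}, \code{truth}, \code{seed_regions}, \code{config}.
#' @export
synth_spread_bundle <- function(config = synth_config(),
                                planted_mode = "global",
                                gene_normalize = "mean") {
  C <- synth_connectome(config)
  regions <- rownames(C)
  seed_regions <- regions[seq_len(config$n_seed_regions)]
  planted_gene <- NULL
  Cgen <- C
  expr <- NULL
  if (planted_mode != "global") {
    gm <- synth_gene_matrix(regions, config$n_genes,
                            planted = stats::setNames(planted_mode,
                                                      "planted1"),
                            rng_seed = config$rng_seed + 1)
    expr <- gm$expr
    planted_gene <- "planted1"
    g <- normalize_gene_vector(expr[planted_gene, ], gene_normalize)
    Cgen <- gene_modulated_connectome(C, g, planted_mode)
  } else if (config$n_genes > 0) {
    expr <- synth_gene_matrix(regions, config$n_genes,
                              rng_seed = config$rng_seed + 1)$expr
  }
  sp <- synth_pathology(Cgen, config$true_params, seed_regions,
                        config$times, config$noise_sigma,
                        config$detection_floor,
                        rng_seed = config$rng_seed + 2)
  list(connectome = C, expr = expr, planted_gene = planted_gene,
       planted_mode = planted_mode, data = sp$data, truth = sp$truth,
       seed_regions = seed_regions, config = config)
}

#' Generate a synthetic regulatory network with planted hub drivers
#'
#' A directed preferential-attachment backbone over \code{n_nodes} genes,
#' plus \code{planted_hubs} hub nodes wired so their depth-1 neighborhoods
#' are over-represented for a designated candidate set.
#'
#' @param n_nodes number of genes.
#' @param n_candidates candidate-set size.
#' @param planted_hubs number of planted hubs.
#' @param hub_degree neighbors per planted hub.
#' @param hub_candidate_frac fraction of each hub's neighbors drawn from the
#'   candidate set.
#' @param rng_seed seed.
#' @return list: \code{network} (igraph), \code{candidates},
#'   \code{hubs} (ground truth).
#' @export
synth_network_and_sets <- function(n_nodes = 200, n_candidates = 30,
                                   planted_hubs = 3, hub_degree = 15,
                                   hub_candidate_frac = 0.8, rng_seed = 1) {
  stopifnot(planted_hubs <= n_nodes, n_candidates <= n_nodes)
  local_seed(rng_seed, {
    ids <- sprintf("G%03d", seq_len(n_nodes))
    g <- igraph::sample_pa(n_nodes, m = 2, directed = TRUE)
    igraph::V(g)$name <- ids
    candidates <- sample(ids, n_candidates)
    hubs <- sample(setdiff(ids, candidates), planted_hubs)
    extra <- list()
    for (h in hubs) {
      k_cand <- round(hub_candidate_frac * hub_degree)
      nb <- c(sample(candidates, min(k_cand, n_candidates)),
              sample(setdiff(ids, c(h, candidates)),
                     hub_degree - min(k_cand, n_candidates)))
      extra[[h]] <- data.frame(from = h, to = nb)
    }
    extra <- do.call(rbind, extra)
    old <- igraph::as_data_frame(g, what = "edges")
    edges <- unique(rbind(old[, c("from", "to")], extra))
    edges <- edges[edges$from != edges$to, ]
    net <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                         vertices = ids)
    list(network = net, candidates = candidates, hubs = hubs)
  })
}
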