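# Connectome perturbations: null models, edge removal, key-connectome
# extraction, and sweep orchestration.
#
# The edge universe for all fraction arithmetic is n^2 cells (including the
# dynamically inert diagonal): a 410-region connectome has 168100
# "connections", of which 2% is 3362. Retained counts use ceil(f * n^2);
# removal counts use n^2 - ceil((1 - f) * n^2) so that keeping f and removing
# 1 - f agree. Weight ties (and the ubiquitous zeros) are broken by
# (row, column) lexicographic order - stable and seed-independent.

# ceil(fraction * n^2) with a guard against floating-point noise in the
# product (0.02 * 168100 must give exactly 3362, and 0.08 * 13456 -> 1077).
ceil_count <- function(fraction, n2) {
  as.integer(ceiling(round(fraction * n2, 6)))
}

# Ordering of all n^2 cells: by weight, ties (row, col) lexicographic.
edge_order <- function(C, decreasing = FALSE) {
  n <- nrow(C)
  row <- rep(seq_len(n), times = n)
  col <- rep(seq_len(n), each = n)
  w <- as.vector(C)
  if (decreasing) order(-w, row, col) else order(w, row, col)
}

#' Uniform-random null connectome
#'
#' Off-diagonal entries i.i.d. uniform on \code{[0, 1]}, diagonal zero.
#'
#' @param n number of regions (>= 2).
#' @param rng_seed integer seed (reproducible).
#' @param regions optional labels.
#' @return connectome matrix.
#' @export
uniform_null_connectome <- function(n, rng_seed = 1, regions = NULL) {
  stopifnot(n >= 2)
  m <- local_seed(rng_seed, matrix(stats::runif(n * n), n, n))
  as_connectome(m, regions)
}

#' Weight-permutation null connectome
#'
#' Uniformly permutes the off-diagonal weights of \code{C} over the
#' off-diagonal positions; the multiset of weights (and hence the total
#' weight and weight histogram) is preserved exactly, the diagonal stays
#' zero.
#'
#' @param C connectome matrix.
#' @param rng_seed integer seed.
#' @return permuted connectome matrix.
#' @export
permuted_connectome <- function(C, rng_seed = 1) {
  off <- which(row(C) != col(C))
  w <- C[off]
  P <- C
  P[off] <- local_seed(rng_seed, sample(w))
  P
}

#' Remove a fraction of connectome edges
#'
#' Sets to zero \code{n^2 - ceiling((1 - fraction) * n^2)} cells, chosen at
#' random or by weight rank over the full n^2 edge universe (so zero cells
#' and the diagonal count as the weakest "connections", as the printed edge
#' totals imply).
#'
#' @param C connectome matrix.
#' @param fraction proportion of the edge universe to remove, in
#'   \code{[0, 1]}.
#' @param order \code{"random"}, \code{"weakest_first"} or
#'   \code{"strongest_first"}.
#' @param rng_seed seed (used only for \code{order = "random"}).
#' @return connectome matrix with the selected cells zeroed.
#' @export
remove_edges <- function(C, fraction,
                         order = c("random", "weakest_first",
                                   "strongest_first"),
                         rng_seed = 1) {
  order <- match.arg(order)
  stopifnot(fraction >= 0, fraction <= 1)
  n2 <- length(C)
  k <- n2 - ceil_count(1 - fraction, n2)
  if (k == 0) return(C)
  idx <- switch(order,
                random = local_seed(rng_seed, sample.int(n2, k)),
                weakest_first = edge_order(C, decreasing = FALSE)[seq_len(k)],
                strongest_first = edge_order(C, decreasing = TRUE)[seq_len(k)])
  C[idx] <- 0
  C
}

#' Extract the key connectome (strongest-edge subnetwork)
#'
#' Keeps the \code{ceiling(keep_fraction * n^2)} largest-weight cells and
#' zeroes the rest. For a 410-region connectome at 2% this retains 3362
#' cells; for a 116-region connectome at 8%, 1077.
#'
#' @param C connectome matrix.
#' @param keep_fraction proportion of the n^2 edge universe to keep,
#'   in \code{(0, 1]}.
#' @return list with \code{connectome} (thresholded matrix) and
#'   \code{retained_count}.
#' @export
key_connectome <- function(C, keep_fraction) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  n2 <- length(C)
  m <- ceil_count(keep_fraction, n2)
  if (m >= n2) return(list(connectome = C, retained_count = n2))
  drop_idx <- edge_order(C, decreasing = TRUE)[(m + 1):n2]
  K <- C
  K[drop_idx] <- 0
  list(connectome = K, retained_count = m)
}

#' Perturbation specification
#'
#' @param kind one of \code{"uniform_null"}, \code{"permutation_null"},
#'   \code{"random_removal"}, \code{"remove_weakest"},
#'   \code{"remove_strongest"}, \code{"keep_strongest"}.
#' @param fraction removal/keep fraction (required for removal/keep kinds).
#' @param replicates number of replicates (deterministic kinds collapse to
#'   identical replicates and default to 1).
#' @return list of class \code{"perturbation_spec"}.
#' @export
perturbation_spec <- function(kind = c("uniform_null", "permutation_null",
                                       "random_removal", "remove_weakest",
                                       "remove_strongest", "keep_strongest"),
                              fraction = NA_real_, replicates = 1) {
  kind <- match.arg(kind)
  needs_fraction <- kind %in% c("random_removal", "remove_weakest",
                                "remove_strongest", "keep_strongest")
  if (needs_fraction && !is.finite(fraction)) {
    stop("fraction required for kind ", kind)
  }
  stopifnot(replicates >= 1)
  structure(list(kind = kind, fraction = fraction, replicates = replicates),
            class = "perturbation_spec")
}

apply_perturbation <- function(C, spec, rng_seed) {
  switch(spec$kind,
         uniform_null = uniform_null_connectome(nrow(C), rng_seed,
                                                rownames(C)),
         permutation_null = permuted_connectome(C, rng_seed),
         random_removal = remove_edges(C, spec$fraction, "random", rng_seed),
         remove_weakest = remove_edges(C, spec$fraction, "weakest_first"),
         remove_strongest = remove_edges(C, spec$fraction, "strongest_first"),
         keep_strongest = key_connectome(C, spec$fraction)$connectome)
}

#' Fit the spread model across a grid of connectome perturbations
#'
#' For each spec and replicate, perturbs the connectome (replicate seeds are
#' \code{master_seed + replicate_index}, so every replicate is auditable) and
#' refits the global spread model. Percentiles are computed over successful
#' replicates only; failures are counted, not fatal.
#'
#' @inheritParams fit_spread_model
#' @param specs list of [perturbation_spec()] objects.
#' @param master_seed integer master seed for replicate derivation.
#' @return list with \code{per_replicate} (data.frame: kind, fraction,
#'   replicate, seed, ave_ccc, status) and \code{summary} (data.frame with
#'   percentiles 25/50/75/95 of Ave. CCC, range, n_failed).
#' @export
perturbation_sweep <- function(data, C, seed_regions, specs,
                               config = fit_config(), master_seed = 1) {
  if (inherits(specs, "perturbation_spec")) specs <- list(specs)
  per <- list()
  for (sp in specs) {
    for (r in seq_len(sp$replicates)) {
      seed_r <- master_seed + r
      Cp <- apply_perturbation(C, sp, seed_r)
      fit <- fit_spread_model(data, Cp, seed_regions, config)
      per[[length(per) + 1]] <- data.frame(
        kind = sp$kind, fraction = sp$fraction, replicate = r,
        seed = seed_r,
        ave_ccc = if (fit$status == "ok") fit$ave_ccc else NA_real_,
        status = fit$status)
    }
  }
  per <- do.call(rbind, per)
  grp <- paste(per$kind, ifelse(is.na(per$fraction), "", per$fraction))
  summary <- do.call(rbind, lapply(split(per, grp), function(d) {
    ok <- d$ave_ccc[d$status == "ok"]
    qs <- if (length(ok)) stats::quantile(ok, c(.25, .5, .75, .95),
                                          names = FALSE)
          else rep(NA_real_, 4)
    data.frame(kind = d$kind[1], fraction = d$fraction[1],
               n = nrow(d), n_failed = sum(d$status != "ok"),
               p25 = qs[1], p50 = qs[2], p75 = qs[3], p95 = qs[4],
               range = if (length(ok)) max(ok) - min(ok) else NA_real_)
  }))
  rownames(summary) <- NULL
  list(per_replicate = per, summary = summary)
}
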