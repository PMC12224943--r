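# Over-representation statistics for candidate gene sets, depth-1 key-driver
# analysis on regulatory networks, the chi-square same-effect edge test, and
# the relative-pathology score for the cell-culture validation assay.

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric test for over-representation of a
#' marker set within a candidate set, against a background gene universe
#' (the screened genes). Markers are intersected with the background before
#' testing; candidates outside the background are dropped with a warning.
#'
#' @param candidates character vector of candidate gene ids.
#' @param markers character vector of marker gene ids.
#' @param background character vector: the gene universe.
#' @return list: \code{overlap} (k), \code{candidate_size} (n),
#'   \code{marker_size_in_background} (K), \code{background_size} (N),
#'   \code{p_value} (P(X >= k)), \code{fold_enrichment} ((k/n)/(K/N)),
#'   \code{flagged} (TRUE when K = 0).
#' @export
hypergeometric_enrichment <- function(candidates, markers, background) {
  background <- unique(background)
  outside <- setdiff(candidates, background)
  if (length(outside)) {
    warning(length(outside), " candidate(s) outside the background dropped")
  }
  candidates <- unique(intersect(candidates, background))
  markers <- unique(intersect(markers, background))
  N <- length(background)
  K <- length(markers)
  n <- length(candidates)
  k <- length(intersect(candidates, markers))
  if (K == 0) {
    return(list(overlap = 0L, candidate_size = n,
                marker_size_in_background = 0L, background_size = N,
                p_value = 1, fold_enrichment = 0, flagged = TRUE))
  }
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (n > 0) (k / n) / (K / N) else 0
  list(overlap = k, candidate_size = n, marker_size_in_background = K,
       background_size = N, p_value = p, fold_enrichment = fold,
       flagged = FALSE)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni with an explicit family size \code{m} (which may exceed the
#' number of p-values supplied, e.g. m = 4 networks tested), or
#' Benjamini-Hochberg step-up.
#'
#' @param ps numeric vector of p-values in \code{[0, 1]}.
#' @param method \code{"bonferroni"} or \code{"BH"}.
#' @param m family size (defaults to \code{length(ps)}); must be >=
#'   \code{length(ps)}.
#' @return adjusted p-values, same order as input.
#' @export
adjust_pvalues <- function(ps, method = c("bonferroni", "BH"),
                           m = length(ps)) {
  method <- match.arg(method)
  stopifnot(all(ps >= 0 & ps <= 1, na.rm = TRUE))
  if (m < length(ps)) stop("family size m must be >= length(ps)")
  if (method == "bonferroni") pmin(1, ps * m)
  else stats::p.adjust(ps, method = "BH", n = m)
}

#' Load a directed regulatory network from an edge list
#'
#' Self-loops are dropped (with a warning) and parallel edges collapsed.
#'
#' @param edges data.frame (or TSV path) with columns regulator, target.
#' @return igraph directed graph.
#' @export
regulatory_network <- function(edges) {
  if (is.character(edges) && length(edges) == 1) {
    edges <- utils::read.table(edges, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges)[, 1:2]
  names(edges) <- c("regulator", "target")
  loops <- edges$regulator == edges$target
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  edges <- unique(edges)
  igraph::graph_from_data_frame(edges, directed = TRUE)
}

#' Depth-1 key-driver analysis
#'
#' For every network node with at least one neighbor, tests whether its
#' depth-1 neighborhood (union of in- and out-neighbors, direction ignored,
#' self excluded) is enriched for the candidate gene set, against the set of
#' all network nodes, using the exact hypergeometric upper tail. P-values
#' are BH-adjusted across nodes; key drivers are nodes with FDR below the
#' threshold.
#'
#' @param network igraph graph (see [regulatory_network()]) or an edge
#'   data.frame.
#' @param candidates character vector of candidate gene ids.
#' @param fdr_threshold FDR cutoff for calling key drivers (default 0.05).
#' @return data.frame: node, neighborhood_size, overlap, p_value, fdr,
#'   is_key_driver; sorted by fdr.
#' @export
key_driver_analysis <- function(network, candidates, fdr_threshold = 0.05) {
  if (!igraph::is_igraph(network)) network <- regulatory_network(network)
  nodes <- igraph::V(network)$name
  cand <- intersect(unique(candidates), nodes)
  if (length(cand) == 0) {
    warning("candidate set disjoint from network; no key drivers")
    return(data.frame(node = character(0), neighborhood_size = integer(0),
                      overlap = integer(0), p_value = numeric(0),
                      fdr = numeric(0), is_key_driver = logical(0)))
  }
  N <- length(nodes)
  K <- length(cand)
  adj <- igraph::as_adj_list(network, mode = "all")
  rows <- lapply(nodes, function(v) {
    nb <- setdiff(names(adj[[v]]), v)
    if (length(nb) == 0) return(NULL)
    k <- length(intersect(nb, cand))
    p <- stats::phyper(k - 1, K, N - K, length(nb), lower.tail = FALSE)
    data.frame(node = v, neighborhood_size = length(nb), overlap = k,
               p_value = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$is_key_driver <- out$fdr < fdr_threshold
  out[order(out$fdr, out$p_value, out$node), ]
}

#' Chi-square test of same-effect connectivity among key drivers
#'
#' Tests, per effect category, whether directed edges from that category's
#' key drivers preferentially target key drivers of the same category.
#' Observed: edges from source KDs of the effect to same-effect KDs, among
#' all their edges to any KD. Expected same-effect count under independent
#' target choice: \code{total * (|KD_effect| - 1) / (|KD_any| - 1)}
#' (the source cannot target itself). Two-cell goodness-of-fit, 1 df.
#'
#' @param network igraph directed graph or edge data.frame.
#' @param kd_sets named list: effect -> character vector of KD node names.
#' @return data.frame per effect: n_kd, total_edges_to_kd, observed_same,
#'   expected_same, statistic, p_value (NA with a note when |KD_any| <= 1 or
#'   no edges).
#' @export
kd_edge_chisquare <- function(network, kd_sets) {
  if (!igraph::is_igraph(network)) network <- regulatory_network(network)
  edges <- igraph::as_data_frame(network, what = "edges")
  kd_any <- unique(unlist(kd_sets))
  missing <- setdiff(kd_any, igraph::V(network)$name)
  if (length(missing)) stop("KD node(s) absent from network: ",
                            paste(missing, collapse = ", "))
  rows <- lapply(names(kd_sets), function(eff) {
    src <- kd_sets[[eff]]
    to_kd <- edges$from %in% src & edges$to %in% kd_any
    total <- sum(to_kd)
    obs_same <- sum(to_kd & edges$to %in% src)
    if (length(kd_any) <= 1 || total == 0) {
      return(data.frame(effect = eff, n_kd = length(src),
                        total_edges_to_kd = total, observed_same = obs_same,
                        expected_same = NA_real_, statistic = NA_real_,
                        p_value = NA_real_))
    }
    exp_same <- total * (length(src) - 1) / (length(kd_any) - 1)
    exp_other <- total - exp_same
    if (exp_same <= 0 || exp_other <= 0) {
      # a degenerate expected cell (all KDs share one effect, or none do)
      return(data.frame(effect = eff, n_kd = length(src),
                        total_edges_to_kd = total, observed_same = obs_same,
                        expected_same = exp_same, statistic = NA_real_,
                        p_value = NA_real_))
    }
    obs <- c(obs_same, total - obs_same)
    expd <- c(exp_same, exp_other)
    stat <- sum((obs - expd)^2 / expd)
    data.frame(effect = eff, n_kd = length(src),
               total_edges_to_kd = total, observed_same = obs_same,
               expected_same = exp_same, statistic = stat,
               p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

#' Relative pathology score from per-well quantifications
#'
#' Background-corrected pathology burden of the treated condition relative
#' to control, from summed pathology integrated densities normalised to the
#' neuron-marker area per condition:
#' \deqn{\frac{treated/area_t - bg/area_b}{control/area_c - bg/area_b}}
#' Invariant to rescaling all density measurements by a common factor.
#'
#' @param psyn_den named numeric vector with entries \code{treated},
#'   \code{control}, \code{background}: summed pathology integrated density.
#' @param map2_area named numeric vector, same names: neuron-marker area
#'   (all > 0).
#' @return scalar relative pathology (NA with a warning when the control
#'   signal does not exceed background).
#' @export
relative_pathology <- function(psyn_den, map2_area) {
  need <- c("treated", "control", "background")
  stopifnot(all(need %in% names(psyn_den)), all(need %in% names(map2_area)))
  if (any(map2_area[need] <= 0)) stop("map2_area must be > 0")
  if (any(psyn_den[need] < 0)) stop("psyn_den must be >= 0")
  ratio <- psyn_den[need] / map2_area[need]
  denom <- ratio[["control"]] - ratio[["background"]]
  if (denom <= 0) {
    warning("control signal does not exceed background; score undefined")
    return(NA_real_)
  }
  (ratio[["treated"]] - ratio[["background"]]) / denom
}
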