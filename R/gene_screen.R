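# Genome-wide per-gene model screening: each gene's regional expression
# vector modulates the connectome (outgoing / incoming / combined effect),
# the four spread parameters are refit, and genes are ranked by the averaged
# concordance of the resulting model.

#' Screen genes by refitting the gene-modulated spread model
#'
#' One fit per gene x mode. Genes whose Ave. CCC strictly exceeds the global
#' (gene-free) model's are flagged as improving; ranks run over successful
#' fits within each mode, descending Ave. CCC, ties broken by gene id.
#' Per-gene failures (e.g. overflow of the matrix exponential for extreme
#' vectors) are recorded with \code{status = "failed"} and excluded from
#' ranking; the screen never aborts.
#'
#' @inheritParams fit_spread_model
#' @param expr genes x regions numeric matrix (rownames = gene ids, columns
#'   aligned to the atlas).
#' @param modes subset of \code{c("outgoing", "incoming", "combined")}.
#' @param global_fit optional precomputed global-model [fit_spread_model()]
#'   result (computed once here otherwise).
#' @return data.frame: gene_id, mode, ave_ccc, alpha, beta, gamma, s,
#'   status, rank, improves_global; attribute \code{"global_ave_ccc"}.
#' @export
screen_genes <- function(data, C, seed_regions, expr,
                         modes = c("outgoing", "incoming", "combined"),
                         config = fit_config(), gene_normalize = "mean",
                         global_fit = NULL) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            ncol(expr) == nrow(C), !anyDuplicated(rownames(expr)))
  if (is.null(global_fit)) {
    global_fit <- fit_spread_model(data, C, seed_regions, config)
  }
  g0 <- if (global_fit$status == "ok") global_fit$ave_ccc else NA_real_
  rows <- list()
  for (mode in modes) {
    for (gid in rownames(expr)) {
      fit <- tryCatch(
        fit_spread_model(data, C, seed_regions, config,
                         gene = expr[gid, ], mode = mode,
                         gene_normalize = gene_normalize),
        error = function(e) NULL)
      ok <- !is.null(fit) && fit$status == "ok"
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gid, mode = mode,
        ave_ccc = if (ok) fit$ave_ccc else NA_real_,
        alpha = if (ok) fit$params[["alpha"]] else NA_real_,
        beta = if (ok) fit$params[["beta"]] else NA_real_,
        gamma = if (ok) fit$params[["gamma"]] else NA_real_,
        s = if (ok) fit$params[["s"]] else NA_real_,
        status = if (ok) "ok" else "failed")
    }
  }
  out <- do.call(rbind, rows)
  out$rank <- NA_integer_
  out$improves_global <- !is.na(out$ave_ccc) & !is.na(g0) & out$ave_ccc > g0
  for (mode in modes) {
    sel <- which(out$mode == mode & out$status == "ok")
    ord <- sel[order(-out$ave_ccc[sel], out$gene_id[sel])]
    out$rank[ord] <- seq_along(ord)
  }
  attr(out, "global_ave_ccc") <- g0
  out
}

#' Select top candidate genes from a screen
#'
#' Takes the top \code{n_top} genes, by Ave. CCC, among those that improve on
#' the global model in the given mode. Fewer are returned when fewer qualify;
#' exact ties order lexicographically by gene id. Larger \code{n_top} always
#' extends (never reorders) the selection.
#'
#' @param records [screen_genes()] output.
#' @param mode effect mode to select within.
#' @param n_top number of candidates (the screening design used 500).
#' @return character vector of gene ids, best first.
#' @export
select_candidates <- function(records, mode, n_top = 500) {
  sel <- records[records$mode == mode & records$status == "ok" &
                   records$improves_global, , drop = FALSE]
  sel <- sel[order(-sel$ave_ccc, sel$gene_id), , drop = FALSE]
  utils::head(sel$gene_id, n_top)
}

#' Permutation bootstrap for a single gene
#'
#' Refits the gene-modulated model \code{B} times with the elements of the
#' expression vector randomly permuted across regions (the multiset of
#' values is preserved, their regional assignment destroyed), and reports
#' the percentile of the actual Ave. CCC within that null (ties counted as
#' \code{<=}). Used on the marginal (e.g. 500th-ranked) candidate to verify
#' that its contribution is not a generic property of its value
#' distribution.
#'
#' @inheritParams fit_spread_model
#' @param gene expression vector for the gene under test.
#' @param B number of permutations.
#' @param rng_seed seed for the permutation stream.
#' @return list: \code{actual_ave_ccc}, \code{null_ave_ccc} (length <= B;
#'   failed refits excluded), \code{n_failed}, \code{percentile_of_actual},
#'   \code{degenerate} (TRUE when the null collapses to a single value,
#'   e.g. for a constant expression vector), \code{rng_seed}.
#' @export
permutation_bootstrap_gene <- function(data, C, seed_regions, gene,
                                       mode = "outgoing", B = 100,
                                       config = fit_config(),
                                       gene_normalize = "mean",
                                       rng_seed = 1) {
  stopifnot(B >= 1)
  actual <- fit_spread_model(data, C, seed_regions, config, gene = gene,
                             mode = mode, gene_normalize = gene_normalize)
  if (actual$status != "ok") stop("actual gene fit failed; nothing to test")
  perms <- local_seed(rng_seed,
                      replicate(B, sample(length(gene)), simplify = FALSE))
  null <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    fit <- tryCatch(
      fit_spread_model(data, C, seed_regions, config,
                       gene = gene[perms[[b]]], mode = mode,
                       gene_normalize = gene_normalize),
      error = function(e) NULL)
    if (!is.null(fit) && fit$status == "ok") null[b] <- fit$ave_ccc
  }
  ok <- null[!is.na(null)]
  pct <- if (length(ok)) 100 * mean(ok <= actual$ave_ccc) else NA_real_
  list(actual_ave_ccc = actual$ave_ccc, null_ave_ccc = ok,
       n_failed = B - length(ok), percentile_of_actual = pct,
       degenerate = length(unique(ok)) <= 1, rng_seed = rng_seed)
}

#' Pearson correlation between gene expression and pathology
#'
#' The direct (connectome-free) comparison model: for each gene and time
#' point, Pearson's r between the expression vector and the observed burden
#' over regions with positive observed burden (the same mask the model fit
#' uses).
#'
#' @param expr genes x regions matrix.
#' @param data [pathology_data()] object.
#' @return data.frame: gene_id, time_months, r (NA when either vector is
#'   constant on the mask).
#' @export
gene_pathology_correlation <- function(expr, data) {
  stopifnot(ncol(expr) == nrow(data$observed))
  rows <- list()
  for (i in seq_along(data$times)) {
    obs <- data$observed[, i]
    mask <- is.finite(obs) & obs > 0
    for (gid in rownames(expr)) {
      g <- expr[gid, mask]
      r <- if (stats::sd(g) == 0 || stats::sd(obs[mask]) == 0) NA_real_
           else stats::cor(g, obs[mask])
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gid, time_months = data$times[i], r = r)
    }
  }
  do.call(rbind, rows)
}
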