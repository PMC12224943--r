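# Tabular I/O: every pipeline input and output is plain TSV with a header
# row (dense connectome matrices, edge lists, long-format pathology tables,
# gene x region expression matrices, one-gene-per-line sets), plus JSON fit
# reports.

#' Write a connectome as a dense TSV matrix
#'
#' First column holds source-region labels; remaining columns are target
#' regions. Round-trips through [load_connectome()].
#'
#' @param C connectome matrix.
#' @param path output file.
#' @export
write_connectome_tsv <- function(C, path) {
  df <- data.frame(region = rownames(C), C, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write long-format pathology tables
#'
#' Long format: columns \code{region}, \code{time_months}, \code{burden}.
#'
#' @param path TSV file.
#' @param regions optional atlas order.
#' @return [pathology_data()] object.
#' @export
read_pathology_tsv <- function(path, regions = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  pathology_data(df, regions = regions)
}

#' @rdname read_pathology_tsv
#' @param data [pathology_data()] object (or a prediction's values matrix
#'   with a \code{times} attribute supplied via \code{times}).
#' @param times time points, when \code{data} is a bare matrix.
#' @export
write_pathology_tsv <- function(data, path, times = NULL) {
  if (inherits(data, "pathology_data")) {
    m <- data$observed; times <- data$times
  } else {
    m <- as.matrix(data)
    if (is.null(times)) stop("times required for a bare matrix")
  }
  df <- data.frame(region = rep(rownames(m), times = length(times)),
                   time_months = rep(times, each = nrow(m)),
                   burden = as.vector(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x region expression matrix from TSV
#'
#' Genes as rows (first column = gene id), regions as columns.
#'
#' @param path TSV file.
#' @param regions optional atlas order to align columns to.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path, regions = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (!is.null(regions)) {
    missing <- setdiff(regions, colnames(m))
    if (length(missing)) stop("regions absent from expression table: ",
                              paste(missing, collapse = ", "))
    m <- m[, regions, drop = FALSE]
  }
  m
}

#' @rdname read_expression_tsv
#' @param expr genes x regions matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write one-gene-per-line gene sets
#'
#' @param path text file, one gene id per line.
#' @return character vector.
#' @export
read_gene_set <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}

#' @rdname read_gene_set
#' @param genes character vector.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Write a fit report as JSON
#'
#' Structured key-value report of a [fit_spread_model()] result: parameters,
#' per-time CCC and Pearson r, mask sizes, status, and the configuration
#' (bounds, start count, seed) that produced it.
#'
#' @param fit \code{spread_fit} object.
#' @param path output file.
#' @export
write_fit_report <- function(fit, path) {
  rep <- list(status = fit$status)
  if (fit$status == "ok") {
    rep$parameters <- as.list(unclass(fit$params))
    rep$ave_ccc <- fit$ave_ccc
    rep$ccc_per_time <- fit$ccc_per_time
    rep$pearson_per_time <- fit$pearson_per_time
    rep$n_regions_used <- fit$n_regions_used
    rep$loss <- fit$loss
  }
  rep$config <- list(lower = as.list(fit$config$lower),
                     upper = as.list(fit$config$upper),
                     n_starts = fit$config$n_starts,
                     rng_seed = fit$config$rng_seed,
                     log_floor = fit$config$log_floor)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
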