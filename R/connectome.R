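#' Coerce a matrix to a validated connectome
#'
#' A connectome is represented as a plain numeric \code{n x n} matrix whose
#' rows are source regions and columns target regions: entry \code{(i, j)} is
#' the axonal projection strength from region \code{i} to region \code{j}.
#' Region labels are carried in \code{dimnames}. Self-projections play no role
#' in the spread dynamics (the rate equations sum over \code{j != i}), so the
#' diagonal is zeroed here once and for all; the edge universe used by the
#' thresholding analyses nevertheless counts all \code{n^2} cells.
#'
#' @param weights square numeric matrix of nonnegative, finite weights.
#' @param regions optional character vector of region labels; defaults to the
#'   matrix dimnames, or \code{R1..Rn} when absent.
#' @return a numeric matrix with both dimnames set and a zero diagonal.
#' @export
as_connectome <- function(weights, regions = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("connectome must be square, got ", nrow(weights), " x ", ncol(weights))
  }
  if (!is.numeric(weights)) stop("connectome weights must be numeric")
  if (any(!is.finite(weights))) stop("connectome contains non-finite weights")
  if (any(weights < 0)) {
    bad <- which(weights < 0, arr.ind = TRUE)[1, ]
    stop("negative weight at (", bad[1], ", ", bad[2], ")")
  }
  if (is.null(regions)) {
    regions <- rownames(weights)
    if (is.null(regions)) regions <- paste0("R", seq_len(nrow(weights)))
  }
  if (anyDuplicated(regions)) stop("region labels must be unique")
  if (length(regions) != nrow(weights)) {
    stop("length(regions) != nrow(weights)")
  }
  dimnames(weights) <- list(regions, regions)
  diag(weights) <- 0
  weights
}

#' Load a connectome from a tabular source
#'
#' Accepts either a dense region-by-region table (first column = source-region
#' labels, remaining column names = target-region labels) or a three-column
#' edge list (\code{source_region}, \code{target_region}, \code{weight}).
#'
#' @param x a file path (TSV/CSV, inferred from extension) or a data.frame.
#' @param format \code{"auto"}, \code{"dense"} or \code{"edges"}.
#' @param regions optional atlas (character vector) fixing region order; for
#'   edge lists it also defines the node universe. Unknown labels are an error.
#' @return connectome matrix (see [as_connectome()]).
#' @export
load_connectome <- function(x, format = c("auto", "dense", "edges"),
                            regions = NULL) {
  format <- match.arg(format)
  if (is.character(x) && length(x) == 1) {
    sep <- if (grepl("\\.csv$", x, ignore.case = TRUE)) "," else "\t"
    x <- utils::read.table(x, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x)
  if (format == "auto") {
    format <- if (ncol(x) == 3 && !is.numeric(x[[2]])) "edges" else "dense"
  }
  if (format == "dense") {
    labels <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- labels
    if (!identical(sort(labels), sort(colnames(m)))) {
      stop("dense connectome row and column labels disagree")
    }
    m <- m[, labels, drop = FALSE]
    if (!is.null(regions)) {
      missing <- setdiff(regions, labels)
      if (length(missing)) stop("regions absent from table: ",
                                paste(missing, collapse = ", "))
      m <- m[regions, regions, drop = FALSE]
    }
    return(as_connectome(m))
  }
  # edge list
  src <- as.character(x[[1]]); tgt <- as.character(x[[2]])
  w <- as.numeric(x[[3]])
  if (any(!is.finite(w))) stop("edge list contains non-finite weights")
  neg <- which(w < 0)
  if (length(neg)) {
    stop("negative weight on edge (", src[neg[1]], ", ", tgt[neg[1]], ")")
  }
  if (is.null(regions)) regions <- unique(c(src, tgt))
  unknown <- setdiff(unique(c(src, tgt)), regions)
  if (length(unknown)) stop("unknown region label(s) in edge list: ",
                            paste(unknown, collapse = ", "))
  m <- matrix(0, length(regions), length(regions),
              dimnames = list(regions, regions))
  m[cbind(match(src, regions), match(tgt, regions))] <- w
  as_connectome(m)
}

#' Validate a connectome and report anomalies
#'
#' Report-only check: negative entries, non-finite entries, nonzero diagonal
#' (zeroed with a warning in the returned matrix), and disconnected regions
#' (zero in- and out-strength).
#'
#' @param C square numeric weight matrix.
#' @return a list with elements \code{connectome} (diagonal-zeroed),
#'   \code{negative}, \code{nonfinite} (index matrices), \code{diagonal_nonzero}
#'   (region labels), \code{disconnected} (region labels), \code{ok} (logical).
#' @export
validate_connectome <- function(C) {
  C <- as.matrix(C)
  if (is.null(rownames(C))) rownames(C) <- paste0("R", seq_len(nrow(C)))
  if (is.null(colnames(C))) colnames(C) <- rownames(C)
  negative <- which(C < 0, arr.ind = TRUE)
  nonfinite <- which(!is.finite(C), arr.ind = TRUE)
  diag_nz <- rownames(C)[which(diag(C) != 0)]
  if (length(diag_nz)) {
    warning("nonzero diagonal zeroed for region(s): ",
            paste(diag_nz, collapse = ", "))
    diag(C) <- 0
  }
  strength <- rowSums(abs(C)) + colSums(abs(C))
  disconnected <- rownames(C)[strength == 0]
  list(connectome = C,
       negative = negative,
       nonfinite = nonfinite,
       diagonal_nonzero = diag_nz,
       disconnected = disconnected,
       ok = nrow(negative) == 0 && nrow(nonfinite) == 0)
}

#' Directionality mixture of a connectome
#'
#' Blends anterograde and retrograde transport into a single effective weight
#' matrix \eqn{\hat{C} = (1 - s) C' + s C}. With the convention that pathology
#' carried retrogradely along an axon from region \eqn{i} to \eqn{j} moves
#' mass \eqn{j \to i}, \code{s = 0} is fully anterograde spread, \code{s = 1}
#' fully retrograde, and \code{s = 0.5} unbiased.
#'
#' @param C connectome matrix (rows = sources, columns = targets).
#' @param s directionality in \code{[0, 1]}.
#' @return the mixed weight matrix \eqn{\hat{C}} with attribute \code{"s"}.
#' @export
directional_mixture <- function(C, s) {
  stopifnot(is.numeric(s), length(s) == 1)
  if (is.na(s) || s < 0 || s > 1) stop("s must lie in [0, 1], got ", s)
  Chat <- (1 - s) * t(C) + s * C
  attr(Chat, "s") <- s
  Chat
}

#' Graph Laplacian of a mixed connectome
#'
#' \eqn{\hat{L} = diag(columnsum(\hat{C})) - \hat{C}}. Every column of
#' \eqn{\hat{L}} sums to zero, so pure spread (\eqn{\alpha = 0}) conserves
#' total pathology; off-diagonal entries are \eqn{\le 0} and the diagonal
#' \eqn{\ge 0}, making \eqn{-\beta\hat{L}} a Metzler generator for
#' \eqn{\beta \ge 0} (solutions from nonnegative seeds stay nonnegative).
#'
#' @param Chat mixed (or plain) nonnegative weight matrix.
#' @return the Laplacian matrix, carrying over any \code{"s"} attribute.
#' @export
graph_laplacian <- function(Chat) {
  L <- diag(colSums(Chat), nrow(Chat)) - Chat
  dimnames(L) <- dimnames(Chat)
  attr(L, "s") <- attr(Chat, "s")
  L
}

#' Directionality-mixed graph Laplacian in one step
#'
#' @inheritParams directional_mixture
#' @return \code{graph_laplacian(directional_mixture(C, s))}.
#' @export
spread_laplacian <- function(C, s) {
  graph_laplacian(directional_mixture(C, s))
}
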