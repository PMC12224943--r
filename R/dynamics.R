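#' Spread-model parameters
#'
#' Bundles the four parameters of the global spread model: \code{alpha}, the
#' net amplification (+) / clearance (-) rate per month; \code{beta}, the
#' global diffusivity per month (\eqn{\ge 0}); \code{gamma}, the seed scaling
#' placed at the injected region(s) at time 0 (\eqn{0 < \gamma \le 1}); and
#' \code{s}, the anterograde/retrograde directionality in \code{[0, 1]}.
#'
#' @param alpha,beta,gamma,s scalar parameter values.
#' @return a named numeric vector of class \code{"spread_params"}.
#' @export
spread_params <- function(alpha, beta, gamma, s) {
  p <- c(alpha = alpha, beta = beta, gamma = gamma, s = s)
  if (any(!is.finite(p))) stop("spread parameters must be finite")
  if (beta < 0) stop("beta must be >= 0")
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]")
  if (s < 0 || s > 1) stop("s must lie in [0, 1]")
  class(p) <- "spread_params"
  p
}

#' Build the initial seed vector
#'
#' The seed vector holds \code{gamma} at each injected region and 0 elsewhere,
#' describing the amount of injected pathological seeds at time 0.
#'
#' @param regions character vector of atlas region labels.
#' @param seed_regions labels of the injected region(s).
#' @param gamma seed scaling in \code{(0, 1]}.
#' @return named numeric vector over \code{regions}.
#' @export
build_seed_vector <- function(regions, seed_regions, gamma) {
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]")
  if (length(seed_regions) < 1) stop("at least one seed region required")
  unknown <- setdiff(seed_regions, regions)
  if (length(unknown)) stop("unknown seed region(s): ",
                            paste(unknown, collapse = ", "))
  x0 <- stats::setNames(numeric(length(regions)), regions)
  x0[seed_regions] <- gamma
  x0
}

#' Gene-modulated connectome
#'
#' Scales connectome weights by a per-region expression vector \eqn{g}:
#' the \emph{outgoing} effect scales each row \eqn{i} by \eqn{g_i}
#' (\eqn{G C}, presynaptic modulation), the \emph{incoming} effect scales
#' each column \eqn{j} by \eqn{g_j} (\eqn{C G}, postsynaptic modulation),
#' and the \emph{combined} effect scales entry \eqn{(i, j)} by
#' \eqn{g_i g_j} (\eqn{G C G}).
#'
#' @param C connectome matrix.
#' @param g nonnegative expression vector, one value per region in atlas
#'   order.
#' @param mode one of \code{"outgoing"}, \code{"incoming"}, \code{"combined"}.
#' @return the modulated weight matrix.
#' @export
gene_modulated_connectome <- function(C, g,
                                      mode = c("outgoing", "incoming",
                                               "combined")) {
  mode <- match.arg(mode)
  g <- as.numeric(g)
  if (length(g) != nrow(C)) {
    stop("expression vector length ", length(g),
         " does not match ", nrow(C), " regions")
  }
  if (any(!is.finite(g)) || any(g < 0)) {
    stop("expression values must be finite and >= 0")
  }
  switch(mode,
         outgoing = g * C,           # row scaling: (G C)_{ij} = g_i c_ij
         incoming = C * rep(g, each = nrow(C)),  # column scaling
         combined = g * C * rep(g, each = nrow(C)))
}

# Rescale an expression vector before it enters the model. Only the shape of
# the vector matters for outgoing/incoming effects (beta absorbs the scale),
# but the combined effect is not scale-invariant, so a fixed convention keeps
# fitted betas comparable across genes.
normalize_gene_vector <- function(g, gene_normalize = c("mean", "none")) {
  gene_normalize <- match.arg(gene_normalize)
  if (gene_normalize == "mean") {
    m <- mean(g)
    if (m <= 0) stop("cannot mean-normalize an all-zero expression vector")
    g <- g / m
  }
  g
}

#' Generator matrix of the spread dynamics
#'
#' Assembles \eqn{A = \alpha I - \beta \hat{L}}, where \eqn{\hat{L}} is the
#' directionality-mixed Laplacian of the (optionally gene-modulated)
#' connectome. Gene modulation is applied \emph{before} directional mixing.
#'
#' @param C connectome matrix.
#' @param params [spread_params()] vector.
#' @param gene optional expression vector (required unless
#'   \code{mode = "global"}).
#' @param mode effect mode: \code{"global"} or one of the gene modes.
#' @param gene_normalize \code{"mean"} (default: divide the vector by its
#'   mean) or \code{"none"}.
#' @return the \eqn{n \times n} generator matrix.
#' @export
spread_generator <- function(C, params, gene = NULL, mode = "global",
                             gene_normalize = "mean") {
  if (mode != "global") {
    if (is.null(gene)) stop("gene expression vector required for mode ", mode)
    g <- normalize_gene_vector(as.numeric(gene), gene_normalize)
    C <- gene_modulated_connectome(C, g, mode)
  }
  L <- spread_laplacian(C, params[["s"]])
  A <- -params[["beta"]] * L
  diag(A) <- diag(A) + params[["alpha"]]
  A
}

# exp(A * t) %*% x via Matrix's scaling-and-squaring matrix exponential.
expm_action <- function(A, t, x) {
  E <- as.matrix(Matrix::expm(Matrix::Matrix(A * t)))
  drop(E %*% x)
}

#' Predict regional pathology with the analytical solution
#'
#' Solves the linear spread model in closed form,
#' \eqn{\hat{X}(t) = e^{(\alpha I - \beta \hat{L}) t} X_0}, at each requested
#' time. Times are evaluated incrementally (the semigroup property), so
#' repeated spacings share one matrix exponential.
#'
#' @inheritParams spread_generator
#' @param seed_regions labels of the injected region(s); \code{gamma} is taken
#'   from \code{params}.
#' @param times numeric vector of months post injection (\eqn{\ge 0}).
#' @return a list of class \code{"pathology_prediction"} with elements
#'   \code{times}, \code{values} (regions x times matrix), \code{params},
#'   \code{mode}, and \code{status} (\code{"ok"} or \code{"failed"} if the
#'   exponential overflowed to non-finite values).
#' @export
predict_pathology <- function(C, params, seed_regions, times,
                              gene = NULL, mode = "global",
                              gene_normalize = "mean") {
  stopifnot(length(times) >= 1, all(times >= 0))
  regions <- rownames(C)
  if (is.null(regions)) regions <- paste0("R", seq_len(nrow(C)))
  x0 <- build_seed_vector(regions, seed_regions, params[["gamma"]])
  values <- matrix(NA_real_, nrow(C), length(times),
                   dimnames = list(regions, paste0("t", times)))
  status <- "ok"
  A <- tryCatch(spread_generator(C, params, gene, mode, gene_normalize),
                error = function(e) NULL)
  if (is.null(A) || any(!is.finite(A))) {
    status <- "failed"
  } else {
    ord <- order(times)
    x <- x0
    t_prev <- 0
    cache_dt <- NA_real_
    E <- NULL
    for (i in ord) {
      dt <- times[i] - t_prev
      if (dt > 0) {
        if (!isTRUE(all.equal(dt, cache_dt))) {
          E <- tryCatch(as.matrix(Matrix::expm(Matrix::Matrix(A * dt))),
                        error = function(e) NULL)
          cache_dt <- dt
        }
        if (is.null(E) || any(!is.finite(E))) { status <- "failed"; break }
        x <- drop(E %*% x)
      }
      if (any(!is.finite(x))) { status <- "failed"; break }
      values[, i] <- x
      t_prev <- times[i]
    }
  }
  structure(list(times = times, values = values, params = params,
                 mode = mode, gene = attr(gene, "gene_id"), status = status),
            class = "pathology_prediction")
}

#' Numerically integrate the spread ODE (verification oracle)
#'
#' Integrates \eqn{dX/dt = (\alpha I - \beta \hat{L}) X} from the seed vector
#' with \code{deSolve::ode} (lsoda, tight tolerances). Serves as an
#' independent check on the matrix-exponential solution.
#'
#' @inheritParams predict_pathology
#' @param atol,rtol integrator tolerances.
#' @return same structure as [predict_pathology()].
#' @export
ode_oracle <- function(C, params, seed_regions, times,
                       gene = NULL, mode = "global", gene_normalize = "mean",
                       atol = 1e-12, rtol = 1e-10) {
  regions <- rownames(C)
  if (is.null(regions)) regions <- paste0("R", seq_len(nrow(C)))
  x0 <- build_seed_vector(regions, seed_regions, params[["gamma"]])
  A <- spread_generator(C, params, gene, mode, gene_normalize)
  rhs <- function(t, x, p) list(drop(A %*% x))
  tt <- sort(unique(c(0, times)))
  sol <- tryCatch(
    deSolve::ode(y = x0, times = tt, func = rhs, parms = NULL,
                 method = "lsoda", atol = atol, rtol = rtol),
    error = function(e) NULL)
  status <- "ok"
  values <- matrix(NA_real_, nrow(C), length(times),
                   dimnames = list(regions, paste0("t", times)))
  if (is.null(sol) || any(!is.finite(sol))) {
    status <- "failed"
  } else {
    for (i in seq_along(times)) {
      values[, i] <- sol[match(times[i], tt), -1]
    }
  }
  structure(list(times = times, values = values, params = params,
                 mode = mode, status = status),
            class = "pathology_prediction")
}

#' @export
print.pathology_prediction <- function(x, ...) {
  cat("Pathology prediction (", x$mode, " model), status: ", x$status, "\n",
      sep = "")
  cat("  regions:", nrow(x$values), " times:",
      paste(x$times, collapse = ", "), "\n")
  invisible(x)
}
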