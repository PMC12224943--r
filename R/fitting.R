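#' Lin's concordance correlation coefficient
#'
#' \deqn{CCC = \frac{2\,cov(x, y)}{var(x) + var(y) + (\bar{x} - \bar{y})^2}}
#' with population (1/n) moments. Unlike Pearson's r, the CCC penalises
#' differences in location and scale: it equals 1 only when \code{y == x}
#' elementwise, which is what lets it fit the seed scaling and amplification
#' parameters rather than just the trend.
#'
#' @param x,y numeric vectors of equal length (>= 2), finite.
#' @return a scalar in \code{[-1, 1]}, or \code{NA} if both vectors are
#'   constant (undefined).
#' @export
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("lin_ccc requires finite inputs")
  }
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(NA_real_)  # both constant and equal: undefined
  2 * mean((x - mx) * (y - my)) / denom
}

#' Mask and log10-transform an observed/predicted pair
#'
#' Regional burdens span several orders of magnitude, so model fit is judged
#' on the log10 scale, restricted to regions where the observed burden is
#' positive and finite (structural zeros carry no scale information).
#' Predicted values at masked-in regions are floored at \code{log_floor}
#' before the logarithm so that predicted zeros stay finite.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param log_floor floor applied to predicted values (default 1e-12).
#' @return list with \code{obs_log}, \code{pred_log}, \code{mask} (integer
#'   indices) and \code{status} (\code{"failed"} when the mask is empty).
#' @export
masked_log10 <- function(observed, predicted, log_floor = 1e-12) {
  stopifnot(length(observed) == length(predicted))
  mask <- which(is.finite(observed) & observed > 0)
  if (length(mask) == 0) {
    return(list(obs_log = numeric(0), pred_log = numeric(0),
                mask = integer(0), status = "failed"))
  }
  list(obs_log = log10(observed[mask]),
       pred_log = log10(pmax(predicted[mask], log_floor)),
       mask = mask, status = "ok")
}

#' Fitting configuration
#'
#' @param alpha_bounds,beta_bounds,gamma_bounds,s_bounds parameter boxes.
#'   The amplification rate is formally unbounded and the diffusivity only
#'   bounded below; practical boxes of \code{[-5, 5]} and \code{[0, 20]}
#'   (per month) cover the dynamics expressible at the 3-6 month horizon.
#' @param n_starts number of Latin-hypercube multistart points at which the
#'   loss is evaluated.
#' @param n_refine number of local optimisations, launched from the
#'   best-scoring start points (the loss surface has a long curved ridge
#'   where amplification and seed scaling trade off, so cheap pre-screening
#'   of many starts is far more robust than a few blind optimisations).
#' @param rng_seed seed making the multistart (and anything derived from the
#'   config) reproducible.
#' @param log_floor floor for predicted values on the log10 scale.
#' @param maxit L-BFGS-B iteration cap per start.
#' @return list of class \code{"fit_config"}.
#' @export
fit_config <- function(alpha_bounds = c(-5, 5), beta_bounds = c(0, 20),
                       gamma_bounds = c(1e-6, 1), s_bounds = c(0, 1),
                       n_starts = 30, n_refine = 4, rng_seed = 1,
                       log_floor = 1e-12, maxit = 200) {
  stopifnot(n_starts >= 1, n_refine >= 1, beta_bounds[1] >= 0,
            gamma_bounds[1] > 0, gamma_bounds[2] <= 1,
            s_bounds[1] >= 0, s_bounds[2] <= 1)
  structure(list(lower = c(alpha = alpha_bounds[1], beta = beta_bounds[1],
                           gamma = gamma_bounds[1], s = s_bounds[1]),
                 upper = c(alpha = alpha_bounds[2], beta = beta_bounds[2],
                           gamma = gamma_bounds[2], s = s_bounds[2]),
                 n_starts = n_starts, n_refine = min(n_refine, n_starts),
                 rng_seed = rng_seed, log_floor = log_floor, maxit = maxit),
            class = "fit_config")
}

#' Pathology dataset constructor
#'
#' @param observed regions x times numeric matrix of burden fractions
#'   (group-averaged), or a long data.frame with columns \code{region},
#'   \code{time_months}, \code{burden}.
#' @param times numeric time points (months post injection); inferred from
#'   long input.
#' @param regions region labels in atlas order; inferred when possible.
#' @return list of class \code{"pathology_data"} with \code{observed}
#'   (matrix), \code{times}, \code{regions}.
#' @export
pathology_data <- function(observed, times = NULL, regions = NULL) {
  if (is.data.frame(observed)) {
    stopifnot(all(c("region", "time_months", "burden") %in% names(observed)))
    if (is.null(times)) times <- sort(unique(observed$time_months))
    if (is.null(regions)) regions <- unique(observed$region)
    m <- matrix(0, length(regions), length(times),
                dimnames = list(regions, paste0("t", times)))
    idx <- cbind(match(observed$region, regions),
                 match(observed$time_months, times))
    m[idx] <- observed$burden
    observed <- m
  } else {
    observed <- as.matrix(observed)
    if (is.null(times)) {
      times <- as.numeric(sub("^t", "", colnames(observed)))
    }
    if (is.null(regions)) regions <- rownames(observed)
    dimnames(observed) <- list(regions, paste0("t", times))
  }
  if (any(observed < 0, na.rm = TRUE)) stop("burdens must be >= 0")
  if (length(times) < 1) stop("at least one time point required")
  structure(list(observed = observed, times = times, regions = regions),
            class = "pathology_data")
}

#' Spread-model loss (one minus concordance, summed over times)
#'
#' \deqn{loss(\theta) = \sum_t \big(1 - CCC(\log_{10} X(t),
#'   \log_{10} \hat{X}(t))\big)} over the masked (observed > 0) regions at
#' each time. A failed prediction (overflow) returns a worst-case sentinel of
#' 2 per time point so that screens and sweeps can continue.
#'
#' @param par numeric vector \code{c(alpha, beta, gamma, s)}.
#' @param data [pathology_data()] object.
#' @param C connectome matrix sharing the dataset's atlas.
#' @param seed_regions injected region labels.
#' @param gene,mode,gene_normalize see [predict_pathology()].
#' @param config [fit_config()].
#' @return scalar loss (attribute \code{"status"} records failures).
#' @export
spread_loss <- function(par, data, C, seed_regions, gene = NULL,
                        mode = "global", gene_normalize = "mean",
                        config = fit_config()) {
  params <- c(alpha = par[[1]], beta = par[[2]], gamma = par[[3]],
              s = par[[4]])
  worst <- 2 * length(data$times)
  pred <- predict_pathology(C, params, seed_regions, data$times,
                            gene = gene, mode = mode,
                            gene_normalize = gene_normalize)
  if (pred$status != "ok") {
    return(structure(worst, status = "failed"))
  }
  loss <- 0
  for (i in seq_along(data$times)) {
    ml <- masked_log10(data$observed[, i], pred$values[, i],
                       config$log_floor)
    if (ml$status != "ok" || length(ml$mask) < 2) {
      return(structure(worst, status = "failed"))
    }
    ccc <- lin_ccc(ml$obs_log, ml$pred_log)
    if (!is.finite(ccc)) ccc <- -1
    loss <- loss + (1 - ccc)
  }
  structure(loss, status = "ok")
}

# Latin-hypercube start points inside the box, deterministic per seed.
lhs_starts <- function(config, lower, upper) {
  k <- length(lower)
  pts <- local_seed(config$rng_seed, lhs::randomLHS(config$n_starts, k))
  sweep(sweep(pts, 2, upper - lower, "*"), 2, lower, "+")
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit the spread model by bounded multi-start optimisation
#'
#' Minimises [spread_loss()] over \code{(alpha, beta, gamma, s)} with
#' L-BFGS-B from \code{n_starts} Latin-hypercube initial points (seeded, so
#' the fit is bit-reproducible). The best start wins; ties break to the
#' earliest start index.
#'
#' @inheritParams spread_loss
#' @param fix_s optional fixed directionality; when given, only
#'   \code{(alpha, beta, gamma)} are optimised (used for the fully
#'   anterograde / unbiased / fully retrograde comparison fits).
#' @param extra_starts optional matrix (rows = \code{c(alpha, beta, gamma,
#'   s)}) of additional start points that are always refined, bypassing the
#'   pre-screen (used to warm-start nested models from restricted optima).
#' @return object of class \code{"spread_fit"}: \code{params}
#'   ([spread_params()]), \code{ave_ccc}, \code{ccc_per_time},
#'   \code{pearson_per_time}, \code{loss}, \code{n_regions_used},
#'   \code{status}, \code{starts} (per-start diagnostics), \code{config}.
#' @export
fit_spread_model <- function(data, C, seed_regions, config = fit_config(),
                             gene = NULL, mode = "global",
                             gene_normalize = "mean", fix_s = NULL,
                             extra_starts = NULL) {
  stopifnot(inherits(data, "pathology_data"))
  if (!is.null(data$regions) && !is.null(rownames(C)) &&
      !identical(data$regions, rownames(C))) {
    stop("pathology data and connectome use different atlases")
  }
  free <- if (is.null(fix_s)) c(1L, 2L, 3L, 4L) else c(1L, 2L, 3L)
  lower <- config$lower; upper <- config$upper
  obj <- function(p_free) {
    par <- numeric(4)
    par[free] <- p_free
    if (!is.null(fix_s)) par[4] <- fix_s
    as.numeric(spread_loss(par, data, C, seed_regions, gene, mode,
                           gene_normalize, config))
  }
  starts <- lhs_starts(config, lower, upper)
  if (!is.null(extra_starts)) {
    extra <- matrix(pmin(pmax(t(extra_starts), lower), upper),
                    ncol = 4, byrow = TRUE)
    starts <- rbind(starts, extra)
  }
  n_lhs <- config$n_starts
  n_all <- nrow(starts)
  # pre-screen: one loss evaluation per start, then refine the best few;
  # extra (warm) starts are always refined
  pre <- vapply(seq_len(n_all), function(i) obj(starts[i, free]), numeric(1))
  refine_idx <- union(order(pre[seq_len(n_lhs)])[
    seq_len(min(config$n_refine, n_lhs))],
    if (n_all > n_lhs) (n_lhs + 1):n_all else integer(0))
  best <- NULL
  diag_tab <- data.frame(start = seq_len(n_all), pre_loss = pre,
                         loss = NA_real_, convergence = NA_integer_)
  for (i in refine_idx) {
    p0 <- starts[i, free]
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B",
                   lower = lower[free], upper = upper[free],
                   control = list(maxit = config$maxit)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    diag_tab$loss[i] <- res$value
    diag_tab$convergence[i] <- res$convergence
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$start <- i
    }
  }
  worst <- 2 * length(data$times)
  if (is.null(best) || best$value >= worst) {
    return(structure(list(params = NULL, ave_ccc = NA_real_,
                          ccc_per_time = NULL, pearson_per_time = NULL,
                          loss = NA_real_, n_regions_used = NULL,
                          status = "failed", starts = diag_tab,
                          config = config),
                     class = "spread_fit"))
  }
  par <- numeric(4)
  par[free] <- best$par
  if (!is.null(fix_s)) par[4] <- fix_s
  params <- spread_params(par[1], par[2], max(par[3], config$lower[["gamma"]]),
                          min(max(par[4], 0), 1))
  pred <- predict_pathology(C, params, seed_regions, data$times,
                            gene = gene, mode = mode,
                            gene_normalize = gene_normalize)
  ccc <- pearson <- numeric(length(data$times))
  nused <- integer(length(data$times))
  for (i in seq_along(data$times)) {
    ml <- masked_log10(data$observed[, i], pred$values[, i], config$log_floor)
    ccc[i] <- lin_ccc(ml$obs_log, ml$pred_log)
    pearson[i] <- stats::cor(ml$obs_log, ml$pred_log)
    nused[i] <- length(ml$mask)
  }
  structure(list(params = params, ave_ccc = mean(ccc), ccc_per_time = ccc,
                 pearson_per_time = pearson, loss = best$value,
                 n_regions_used = nused, status = "ok",
                 best_start = best$start, starts = diag_tab,
                 config = config),
            class = "spread_fit")
}

#' @export
print.spread_fit <- function(x, digits = 4, ...) {
  cat("Spread-model fit (", x$status, ")\n", sep = "")
  if (x$status == "ok") {
    p <- x$params
    cat(sprintf("  alpha = %.*g, beta = %.*g, gamma = %.*g, s = %.*g\n",
                digits, p[["alpha"]], digits, p[["beta"]],
                digits, p[["gamma"]], digits, p[["s"]]))
    cat(sprintf("  Ave. CCC = %.*g  (per time: %s)\n", digits, x$ave_ccc,
                paste(signif(x$ccc_per_time, digits), collapse = ", ")))
    cat("  regions used per time:",
        paste(x$n_regions_used, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Free versus fixed directionality comparison table
#'
#' Fits the global spread model with free directionality and at the three
#' canonical fixed settings (fully anterograde \code{s = 0}, unbiased
#' \code{s = 0.5}, fully retrograde \code{s = 1}).
#'
#' @inheritParams fit_spread_model
#' @return data.frame with one row per condition: \code{condition}, \code{s},
#'   \code{alpha}, \code{beta}, \code{gamma}, \code{ave_ccc}, \code{status}.
#' @export
fit_directionality_table <- function(data, C, seed_regions,
                                     config = fit_config()) {
  conditions <- list(anterograde = 0, unbiased = 0.5, retrograde = 1,
                     free = NULL)
  fixed_optima <- list()
  rows <- lapply(names(conditions), function(nm) {
    if (nm == "free") {
      # the free model nests the fixed-s ones: warm-start from their optima
      warm <- do.call(rbind, fixed_optima)
      fit <- fit_spread_model(data, C, seed_regions, config,
                              extra_starts = warm)
    } else {
      fit <- fit_spread_model(data, C, seed_regions, config,
                              fix_s = conditions[[nm]])
      if (fit$status == "ok") {
        fixed_optima[[nm]] <<- unclass(fit$params)
      }
    }
    if (fit$status == "ok") {
      data.frame(condition = nm, s = fit$params[["s"]],
                 alpha = fit$params[["alpha"]], beta = fit$params[["beta"]],
                 gamma = fit$params[["gamma"]], ave_ccc = fit$ave_ccc,
                 status = fit$status)
    } else {
      data.frame(condition = nm, s = NA_real_, alpha = NA_real_,
                 beta = NA_real_, gamma = NA_real_, ave_ccc = NA_real_,
                 status = fit$status)
    }
  })
  tab <- do.call(rbind, rows)
  tab <- tab[match(c("free", "anterograde", "unbiased", "retrograde"),
                   tab$condition), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
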