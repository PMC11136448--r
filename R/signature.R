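# Per-marker expression-level calling. Each marker is modelled as a
# univariate Gaussian mixture p(x) = sum_i w_i N(x | mu_i, sigma_i) with
# G = 2 (negative/positive) or G = 3 (negative/medium/positive) components;
# cells are assigned the symbol of the maximum-a-posteriori component, with
# symbols ordered by the component means. Skewed markers can optionally be
# preconditioned by ranked-set-sampling tail selection before fitting.

#' Sample skewness
#'
#' Moment-based skewness `g1 = m3 / m2^(3/2)` with central sample moments
#' `m_k = mean((x - mean(x))^k)` (the convention of the classic moments
#' estimator). A zero-variance sample returns 0 by definition.
#'
#' @param values numeric vector, length >= 3.
#' @return skewness (single number).
#' @examples
#' compute_skewness(c(-1, 0, 1)) # 0
#' @export
compute_skewness <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) {
    stop("skewness needs at least 3 observations", call. = FALSE)
  }
  x <- values - mean(values)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^3) / m2^1.5
}

#' Ranked set sampling of the two tail strata
#'
#' Per cycle, four points are drawn uniformly (with replacement) from the
#' sample and arranged into two ranked sets of two; the first-ranked unit of
#' the first set goes to the leftmost stratum and the second-ranked unit of
#' the second set to the rightmost stratum. The strata are the lowest and
#' greatest order statistics of the marker distribution and give a sharper
#' view of its tails than simple random sampling.
#'
#' @param values numeric vector; with fewer than 4 values the sample itself
#'   is returned for both strata (with `fallback = TRUE` and a warning).
#' @param n_cycles number of cycles, i.e. the size of each output stratum.
#' @param seed optional integer seed.
#' @return list with numeric vectors `leftmost` and `rightmost` (each of
#'   length `n_cycles`) and the logical `fallback`.
#' @export
ranked_set_sample <- function(values, n_cycles, seed = NULL) {
  values <- as.numeric(values)
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L) {
    stop("'n_cycles' must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (length(values) < 4L) {
    warning("fewer than 4 values: returning the sample unchanged for both strata")
    return(list(leftmost = values, rightmost = values, fallback = TRUE))
  }
  draws <- matrix(sample(values, 4L * n_cycles, replace = TRUE), nrow = 4L)
  list(leftmost = pmin(draws[1L, ], draws[2L, ]),
       rightmost = pmax(draws[3L, ], draws[4L, ]),
       fallback = FALSE)
}

#' Select the tail stratum opposite a marker's skew
#'
#' Positively skewed markers (long right tail) keep the rightmost stratum,
#' emphasising the sparse high-expression tail; otherwise (including exactly
#' symmetric samples) the leftmost stratum is kept.
#'
#' @inheritParams ranked_set_sample
#' @return numeric vector of `n_cycles` values (or the input itself when the
#'   size fallback engages).
#' @export
select_tail_sample <- function(values, n_cycles, seed = NULL) {
  rss <- ranked_set_sample(values, n_cycles, seed)
  if (rss$fallback) return(rss$leftmost)
  if (compute_skewness(values) > 0) rss$rightmost else rss$leftmost
}

#' Fit a univariate Gaussian mixture by expectation-maximisation
#'
#' Components are initialised at the `(i - 0.5)/G` quantiles with uniform
#' weights and the pooled standard deviation, then updated by EM until the
#' relative log-likelihood change drops below `tol` (at most `max_iter`
#' iterations; the best iterate is returned with `converged = FALSE` if the
#' limit is hit). Under the equal-variance parameterisation (`"E"`) all
#' components share one standard deviation; under `"V"` each component owns
#' its own. Components are reported sorted by ascending mean. The fit is
#' deterministic: no random restarts are used.
#'
#' @param values numeric vector of marker intensities (length >= 10 G, not
#'   all identical).
#' @param G number of components, 2 or 3.
#' @param variance_mode `"E"` (equal) or `"V"` (variable) variance.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return object of class `gmm_fit`: `means`, `sds`, `weights` (each length
#'   `G`, mean-ascending), `G`, `variance_mode`, `loglik`, `converged`,
#'   `iterations`.
#' @export
fit_marker_gmm <- function(values, G = 2, variance_mode = c("E", "V"),
                           max_iter = 500L, tol = 1e-8) {
  variance_mode <- match.arg(variance_mode)
  G <- as.integer(G)
  if (!G %in% c(2L, 3L)) stop("'G' must be 2 or 3", call. = FALSE)
  x <- as.numeric(values)
  n <- length(x)
  if (n < 10L * G) {
    stop("need at least ", 10L * G, " observations to fit ", G, " components",
         call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("degenerate data: all values identical", call. = FALSE)
  }
  mu <- as.numeric(stats::quantile(x, probs = (seq_len(G) - 0.5) / G,
                                   names = FALSE))
  s0 <- stats::sd(x)
  if (anyDuplicated(mu)) {
    # heavily tied samples can collapse the quantile init; spread minimally
    mu <- mu + seq(0, s0 * 1e-3, length.out = G)
  }
  sig <- rep(s0, G)
  w <- rep(1 / G, G)
  sd_floor <- max(s0 * 1e-4, 1e-12)
  ll_old <- -Inf
  ll <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    logd <- vapply(seq_len(G),
                   function(i) log(w[i]) + stats::dnorm(x, mu[i], sig[i],
                                                        log = TRUE),
                   numeric(n))
    if (is.null(dim(logd))) logd <- matrix(logd, ncol = G)
    m <- logd[, 1L]
    for (i in 2:G) m <- pmax(m, logd[, i])
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    r <- exp(logd - lse)
    nk <- pmax(colSums(r), 1e-10)
    w <- nk / n
    mu <- colSums(r * x) / nk
    dev2 <- (matrix(x, n, G) - matrix(mu, n, G, byrow = TRUE))^2
    if (variance_mode == "V") {
      sig <- sqrt(colSums(r * dev2) / nk)
    } else {
      sig <- rep(sqrt(sum(r * dev2) / n), G)
    }
    sig <- pmax(sig, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll_old))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  ord <- order(mu)
  structure(list(means = mu[ord], sds = sig[ord], weights = w[ord],
                 G = G, variance_mode = variance_mode, loglik = ll,
                 converged = converged, iterations = iter),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: G=%d, variance mode %s, loglik %.3f (%s after %d iterations)\n",
              x$G, x$variance_mode, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(data.frame(mean = x$means, sd = x$sds, weight = x$weights))
  invisible(x)
}

#' Assign expression-level symbols from a mixture fit
#'
#' Each value is assigned to the component maximising the posterior
#' `w_i N(x | mu_i, sigma_i)`; the component of lowest mean maps to `-`,
#' the highest to `+`, and the middle one (three-component fits) to `m`.
#' Exact posterior ties resolve to the lower-mean component.
#'
#' @param values numeric vector.
#' @param fit a `gmm_fit`.
#' @return character vector of symbols in `{-, m, +}`.
#' @export
assign_expression_levels <- function(values, fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  x <- as.numeric(values)
  n <- length(x)
  logd <- vapply(seq_len(fit$G),
                 function(i) log(fit$weights[i]) +
                   stats::dnorm(x, fit$means[i], fit$sds[i], log = TRUE),
                 numeric(n))
  if (is.null(dim(logd))) logd <- matrix(logd, ncol = fit$G)
  comp <- max.col(logd, ties.method = "first")
  symbol_levels(fit$G)[comp]
}

#' Build the cell-signature matrix of a dataset
#'
#' Independently for each requested marker: optionally replace the fitting
#' sample by the skew-opposing tail stratum of [select_tail_sample()], fit
#' the marker's mixture, and assign level symbols to *all* cells of the
#' matrix under that fit. Markers absent from `levels_per_marker` are
#' skipped (no column emitted). Mixing weights estimated on the tail-biased
#' sample are applied as-is when assigning all cells.
#'
#' @param x expression matrix.
#' @param levels_per_marker named vector mapping markers to 2 or 3.
#' @param variance_mode `"E"` or `"V"` (see [fit_marker_gmm()]).
#' @param use_rss precondition each marker's fitting sample by ranked-set
#'   tail selection.
#' @param n_cycles RSS cycles; default `min(n_cells, 50000)`, which keeps
#'   the sampling linear in the dataset size.
#' @param seed integer seed for the RSS draws (a per-marker substream is
#'   derived from it); ignored when `use_rss = FALSE`, where the procedure
#'   is fully deterministic.
#' @return list with `levels` (character matrix, cells x selected markers)
#'   and `fits` (named list of `gmm_fit` objects).
#' @export
build_signature_matrix <- function(x, levels_per_marker,
                                   variance_mode = c("E", "V"),
                                   use_rss = FALSE, n_cycles = NULL,
                                   seed = NULL) {
  variance_mode <- match.arg(variance_mode)
  markers <- colnames(x)[colnames(x) %in% names(levels_per_marker)]
  if (!length(markers)) {
    stop("no marker of 'levels_per_marker' is present in the matrix",
         call. = FALSE)
  }
  absent <- setdiff(names(levels_per_marker), colnames(x))
  if (length(absent)) {
    stop("marker(s) not in the matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  lev <- matrix(NA_character_, nrow(x), length(markers),
                dimnames = list(rownames(x), markers))
  fits <- vector("list", length(markers))
  names(fits) <- markers
  failures <- character()
  for (j in seq_along(markers)) {
    mk <- markers[j]
    res <- tryCatch({
      xj <- x[, mk]
      fit_sample <- xj
      if (use_rss) {
        nc <- n_cycles %||% min(length(xj), 50000L)
        fit_sample <- select_tail_sample(xj, nc,
                                         seed = if (!is.null(seed)) seed + j)
      }
      fit <- fit_marker_gmm(fit_sample, G = levels_per_marker[[mk]],
                            variance_mode = variance_mode)
      list(fit = fit, symbols = assign_expression_levels(xj, fit))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(mk, ": ", conditionMessage(res)))
    } else {
      fits[[mk]] <- res$fit
      lev[, mk] <- res$symbols
    }
  }
  if (length(failures)) {
    stop("signature generation failed for marker(s):\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  list(levels = lev, fits = fits)
}

#' Dump per-marker mixture parameters as a data frame
#'
#' Diagnostic companion of [build_signature_matrix()]: one row per marker
#' and component, suitable for writing to CSV and eyeballing the fitted
#' gates.
#'
#' @param fits named list of `gmm_fit` objects.
#' @return data frame with columns `marker`, `component`, `mean`, `sd`,
#'   `weight`.
#' @export
gmm_parameter_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(mk) {
    f <- fits[[mk]]
    data.frame(marker = mk, component = seq_len(f$G), mean = f$means,
               sd = f$sds, weight = f$weights, stringsAsFactors = FALSE)
  }))
}
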