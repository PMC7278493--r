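# Diagonal-covariance Gaussian mixture emissions for the behavioral states.
# The per-state observation density p(z | s) over z = (x, y, L) is a mixture
# of axis-aligned Gaussians, fitted by EM from observer-labeled frames.

VARIANCE_FLOOR <- 1e-6  # squared length-units, applied to every diagonal entry

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

rowLogSumExp <- function(M) {
  m <- apply(M, 1L, max)
  m + log(rowSums(exp(M - m)))
}

# n x m matrix of log(w_j) + log N(z_i; mu_j, diag(var_j)), via one matrix
# product per term: the diagonal Gaussian exponent expands to
# -0.5 * (x^2/v - 2 x mu/v + mu^2/v) summed over coordinates
.componentLogDensity <- function(X, weights, means, variances) {
  d <- ncol(X)
  inv <- 1 / variances                              # m x d
  const <- log(weights) - 0.5 * d * log(2 * pi) -
    0.5 * rowSums(log(variances)) - 0.5 * rowSums(means^2 * inv)  # length m
  Q <- -0.5 * (X^2) %*% t(inv) + X %*% t(means * inv)             # n x m
  sweep(Q, 2L, const, `+`)
}

#' Fit a diagonal-covariance Gaussian mixture to state observations
#'
#' Fits an m-component mixture of axis-aligned 3-D Gaussians by
#' expectation-maximization, starting from a seeded k-means partition of the
#' data. Variances are floored at `1e-6` on every diagonal entry so the
#' density stays finite even for degenerate (constant-coordinate) data. The
#' AIC is computed with `p = 7m - 1` free parameters (3 means and 3 variances
#' per component, m - 1 free weights).
#'
#' @param obs numeric `n x 3` matrix of observation vectors from one state.
#' @param m number of mixture components, `m >= 1`, `m <= n`.
#' @param seed integer seed for the k-means initialization.
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @return An object of class `gmmEmission`: list with `m`, `weights`,
#'   `means` (`m x 3`), `variances` (`m x 3`), `loglik`, `aic`, `n`,
#'   `converged`.
#' @seealso [selectGMMComponentsAIC()], [gmmLogDensity()]
#' @export
fitStateGMM <- function(obs, m, seed = 1L, max_iter = 200L, tol = 1e-8) {
  obs <- as.matrix(obs)
  storage.mode(obs) <- "double"
  n <- nrow(obs); d <- ncol(obs)
  if (m < 1L) stop("m must be >= 1")
  if (n < m) stop(sprintf("need at least m = %d observations, got %d", m, n))

  if (m == 1L) {
    means <- matrix(colMeans(obs), 1L, d)
    variances <- matrix(pmax(apply(obs, 2L, function(v) mean((v - mean(v))^2)),
                             VARIANCE_FLOOR), 1L, d)
    weights <- 1
    ll <- sum(.componentLogDensity(obs, weights, means, variances))
    return(.newGMM(m, weights, means, variances, ll, n, TRUE))
  }

  # seeded k-means initialization; fall back to quantile split when k-means
  # cannot place m distinct centers
  assign <- local({
    set.seed(seed)
    ndistinct <- nrow(unique(obs))
    if (ndistinct >= m) {
      km <- suppressWarnings(stats::kmeans(obs, centers = m, nstart = 5L,
                                           iter.max = 50L))
      km$cluster
    } else {
      rep_len(seq_len(m), n)
    }
  })
  resp <- matrix(0, n, m)
  resp[cbind(seq_len(n), assign)] <- 1

  weights <- means <- variances <- NULL
  ll <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    # M-step
    nk <- pmax(colSums(resp), 1e-300)
    weights <- nk / n
    means <- t(resp) %*% obs / nk
    variances <- matrix(0, m, d)
    for (j in seq_len(m)) {
      dev2 <- sweep(obs, 2L, means[j, ])^2
      variances[j, ] <- pmax(colSums(resp[, j] * dev2) / nk[j],
                             VARIANCE_FLOOR)
    }
    # E-step
    lp <- .componentLogDensity(obs, weights, means, variances)
    lse <- rowLogSumExp(lp)
    ll_new <- sum(lse)
    resp <- exp(lp - lse)
    if (is.finite(ll) &&
        abs(ll_new - ll) <= tol * (abs(ll) + abs(ll_new) + 1e-12)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations (m = %d); ",
                    max_iter, m), "returning best iterate")
  .newGMM(m, weights, means, variances, ll, n, converged)
}

.newGMM <- function(m, weights, means, variances, loglik, n, converged) {
  p <- 7L * m - 1L
  structure(list(m = m, weights = as.numeric(weights),
                 means = means, variances = variances,
                 loglik = loglik, aic = -2 * loglik + 2 * p,
                 n = n, converged = converged),
            class = "gmmEmission")
}

#' @export
print.gmmEmission <- function(x, ...) {
  cat(sprintf(
    "Diagonal Gaussian mixture: m = %d, n = %d, loglik = %.3f, AIC = %.3f\n",
    x$m, x$n, x$loglik, x$aic))
  invisible(x)
}

#' Select the mixture component number by AIC
#'
#' Fits one mixture per candidate component count and keeps the fit with the
#' smallest AIC; ties go to the smaller m. Candidate counts that exceed the
#' number of observations are skipped with a warning.
#'
#' @inheritParams fitStateGMM
#' @param m_grid integer vector of candidate component counts.
#' @return The selected `gmmEmission` fit, with the searched grid and all AIC
#'   values attached as attribute `aic_trace`.
#' @export
selectGMMComponentsAIC <- function(obs, m_grid = 1:15, seed = 1L,
                                   max_iter = 200L, tol = 1e-8) {
  if (!length(m_grid)) stop("empty component grid")
  m_grid <- sort(unique(as.integer(m_grid)))
  n <- nrow(as.matrix(obs))
  feasible <- m_grid[m_grid <= n]
  if (length(feasible) < length(m_grid))
    warning("skipping infeasible component counts: ",
            paste(setdiff(m_grid, feasible), collapse = ", "))
  if (!length(feasible)) stop("no feasible component count in grid")
  fits <- lapply(feasible, function(m)
    fitStateGMM(obs, m, seed = seed, max_iter = max_iter, tol = tol))
  aics <- vapply(fits, `[[`, numeric(1L), "aic")
  best <- fits[[which.min(aics)]]  # which.min takes the first (smallest m) tie
  attr(best, "aic_trace") <- data.frame(m = feasible, aic = aics)
  best
}

#' Log-density of a Gaussian mixture emission
#'
#' @param em a `gmmEmission` object.
#' @param Z numeric 3-vector or `n x 3` matrix of observation vectors.
#' @return Numeric vector of log mixture densities, one per row of `Z`;
#'   finite for every finite observation (the variance floor guarantees a
#'   proper density).
#' @export
gmmLogDensity <- function(em, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, 1L)
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("non-finite observation value")
  if (ncol(Z) != ncol(em$means))
    stop("observation dimension mismatch")
  rowLogSumExp(.componentLogDensity(Z, em$weights, em$means, em$variances))
}
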