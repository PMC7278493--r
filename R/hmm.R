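# Supervised three-state hidden Markov model over the observables
# z_k = (x, y, L). Training is fully supervised: the transition matrix is
# counted from observer label sequences and the per-state emission densities
# are Gaussian mixtures fitted to the labeled frames. Decoding smooths the
# state posterior over the whole recording and takes the per-frame MAP state.

N_STATES <- 3L
TRANS_FLOOR <- 1e-10

#' Construct a transition model
#'
#' @param T_mat `3 x 3` row-stochastic matrix of state transition
#'   probabilities `p_ij = p(s_{k+1} = j | s_k = i)`, states 0..2.
#' @param pi initial state distribution (length 3, sums to 1).
#' @return An object of class `transitionModel` with elements `T` and `pi`.
#' @export
transitionModel <- function(T_mat, pi = NULL) {
  T_mat <- as.matrix(T_mat)
  if (!all(dim(T_mat) == N_STATES)) stop("transition matrix must be 3 x 3")
  if (any(T_mat < 0)) stop("transition probabilities must be non-negative")
  if (any(abs(rowSums(T_mat) - 1) > 1e-8))
    stop("transition matrix rows must sum to 1")
  T_mat <- T_mat / rowSums(T_mat)
  if (is.null(pi)) pi <- stationaryDistribution(T_mat)
  if (length(pi) != N_STATES || any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be a length-3 probability vector")
  dimnames(T_mat) <- list(from = 0:2, to = 0:2)
  structure(list(T = T_mat, pi = as.numeric(pi) / sum(pi)),
            class = "transitionModel")
}

#' @export
print.transitionModel <- function(x, ...) {
  cat("Markov transition matrix (rows: from-state 0..2):\n")
  print(round(x$T, 4L))
  cat("initial distribution pi:", paste(round(x$pi, 4L), collapse = " "), "\n")
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' The long-run state occupancy: the leading left eigenvector of `T`,
#' normalized to sum to 1.
#'
#' @param T_mat a `3 x 3` row-stochastic matrix (or `transitionModel`).
#' @return Numeric length-3 probability vector.
#' @export
stationaryDistribution <- function(T_mat) {
  if (inherits(T_mat, "transitionModel")) T_mat <- T_mat$T
  ev <- eigen(t(T_mat))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v / sum(v)
}

#' Estimate the transition matrix from labeled sequences
#'
#' Supervised estimation by transition counting, pooled over all supplied
#' observer label sequences: `p_ij = count(i -> j) / count(i -> .)`. A state
#' never left (zero outgoing count) receives a uniform row; zero cells are
#' floored at 1e-10 and rows renormalized so log-probabilities stay finite.
#' The initial distribution is the empirical distribution of first-frame
#' labels (floored and renormalized the same way).
#'
#' @param label_seqs list of integer vectors with values in `{0, 1, 2}`; at
#'   least one sequence of length >= 2.
#' @return A [transitionModel()].
#' @export
estimateTransitionMatrix <- function(label_seqs) {
  if (is.numeric(label_seqs)) label_seqs <- list(label_seqs)
  if (!length(label_seqs)) stop("no label sequences supplied")
  counts <- matrix(0, N_STATES, N_STATES)
  firsts <- numeric(N_STATES)
  any_pair <- FALSE
  for (s in label_seqs) {
    s <- as.integer(s)
    if (anyNA(s) || any(!s %in% 0:2)) stop("labels must lie in {0, 1, 2}")
    if (!length(s)) next
    firsts[s[1L] + 1L] <- firsts[s[1L] + 1L] + 1
    if (length(s) >= 2L) {
      any_pair <- TRUE
      from <- s[-length(s)] + 1L
      to <- s[-1L] + 1L
      for (k in seq_along(from))
        counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
    }
  }
  if (!any_pair) stop("need at least one sequence of length >= 2")
  T_mat <- matrix(0, N_STATES, N_STATES)
  for (i in seq_len(N_STATES)) {
    tot <- sum(counts[i, ])
    T_mat[i, ] <- if (tot > 0) counts[i, ] / tot else rep(1 / N_STATES, N_STATES)
  }
  T_mat <- pmax(T_mat, TRANS_FLOOR)
  T_mat <- T_mat / rowSums(T_mat)
  pi <- pmax(firsts / sum(firsts), TRANS_FLOOR)
  transitionModel(T_mat, pi / sum(pi))
}

#' Fit the full supervised HMM from labeled trajectories
#'
#' Pools the training animals (estrus and non-estrus together): counts the
#' transition matrix from their label sequences and fits one AIC-selected
#' Gaussian mixture emission density per state from the labeled observation
#' vectors.
#'
#' @param trajs list of labeled [trajectory()] objects (the training
#'   animals).
#' @param m_grid candidate mixture component counts per state (default 1:15).
#' @param seed integer seed for the emission EM initializations.
#' @param ... passed on to [selectGMMComponentsAIC()].
#' @return An object of class `estrusHMM`: list with `transition`
#'   (a [transitionModel()]) and `emissions` (list of three `gmmEmission`
#'   fits, states 0..2).
#' @export
fitHMM <- function(trajs, m_grid = 1:15, seed = 1L, ...) {
  if (!length(trajs)) stop("no training trajectories supplied")
  labels <- lapply(trajs, trajLabels)
  transition <- estimateTransitionMatrix(labels)
  pooled <- stackTrainingMatrix(trajs)
  emissions <- lapply(0:2, function(s) {
    rows <- pooled[, "label"] == s
    if (!any(rows))
      stop(sprintf("state %d absent from the training labels", s))
    selectGMMComponentsAIC(pooled[rows, c("x", "y", "L"), drop = FALSE],
                           m_grid = m_grid, seed = seed + s, ...)
  })
  structure(list(transition = transition, emissions = emissions),
            class = "estrusHMM")
}

#' @export
print.estrusHMM <- function(x, ...) {
  cat("Supervised 3-state estrus-behavior HMM\n")
  print(x$transition)
  for (s in 0:2)
    cat(sprintf("state %d emission: m = %d (AIC %.1f), n = %d\n",
                s, x$emissions[[s + 1L]]$m, x$emissions[[s + 1L]]$aic,
                x$emissions[[s + 1L]]$n))
  invisible(x)
}

#' Per-state emission log-densities
#'
#' @param model an `estrusHMM` model.
#' @param Z observation matrix (`K x 3`) or a single 3-vector.
#' @param state optional state in `{0, 1, 2}`; if given, returns the
#'   log-density under that state only.
#' @return `K x 3` matrix of log emission densities (columns = states), or a
#'   length-K vector when `state` is given.
#' @export
emissionLogDensity <- function(model, Z, state = NULL) {
  if (is.null(dim(Z))) Z <- matrix(Z, 1L)
  E <- vapply(model$emissions, function(em) gmmLogDensity(em, Z),
              numeric(nrow(Z)))
  E <- matrix(E, nrow = nrow(Z), ncol = N_STATES)
  if (!is.null(state)) return(E[, state + 1L])
  colnames(E) <- 0:2
  E
}

#' Forward filtering
#'
#' Runs the forward recursion: the one-step prediction
#' `p(s_k | Z_{k-1}) = sum_{s_{k-1}} p(s_k | s_{k-1}) p(s_{k-1} | Z_{k-1})`
#' followed by the measurement update
#' `p(s_k | Z_k) proportional to p(z_k | s_k) p(s_k | Z_{k-1})`,
#' initialized with `pi`. Emission weights are applied through their
#' log-densities with per-frame normalization, so no underflow occurs for
#' long recordings.
#'
#' @param model an `estrusHMM` model.
#' @param Z `K x 3` observation matrix (see [makeObservations()]).
#' @return List with `filtered` (`K x 3`, row k = `p(s_k | Z_k)`),
#'   `predicted` (`K x 3`, row k = `p(s_k | Z_{k-1})`, row 1 = `pi`) and
#'   `loglik` (total log marginal likelihood of the observations).
#' @export
forwardFilter <- function(model, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, 1L)
  K <- nrow(Z)
  if (K < 1L) stop("empty observation sequence")
  E <- emissionLogDensity(model, Z)
  T_mat <- model$transition$T
  filtered <- predicted <- matrix(0, K, N_STATES)
  loglik <- 0
  pred <- model$transition$pi
  for (k in seq_len(K)) {
    predicted[k, ] <- pred
    mx <- max(E[k, ])
    a <- pred * exp(E[k, ] - mx)
    tot <- sum(a)
    if (!is.finite(tot) || tot <= 0)
      stop(sprintf("degenerate filtering update at frame %d", k))
    filtered[k, ] <- a / tot
    loglik <- loglik + mx + log(tot)
    pred <- as.numeric(filtered[k, ] %*% T_mat)
  }
  list(filtered = filtered, predicted = predicted, loglik = loglik)
}

#' Backward smoothing
#'
#' Completes the fixed-interval (Rauch-style) smoother: starting from the
#' final filtered row, each earlier row is corrected by future evidence via
#' `p(s_k | Z_K) = p(s_k | Z_k) * sum_{s_{k+1}} p(s_{k+1} | Z_K)
#' p(s_{k+1} | s_k) / p(s_{k+1} | Z_k)`. Ratio terms with zero predictive
#' probability contribute zero (0/0 guard).
#'
#' @param model an `estrusHMM` model.
#' @param forward the output of [forwardFilter()] for the same observations.
#' @return `K x 3` matrix of smoothed posteriors `p(s_k | Z_K)`.
#' @export
backwardSmooth <- function(model, forward) {
  filtered <- forward$filtered
  predicted <- forward$predicted
  if (is.null(predicted) || !all(dim(filtered) == dim(predicted)))
    stop("filtered and predicted posteriors must match")
  K <- nrow(filtered)
  T_mat <- model$transition$T
  smoothed <- matrix(0, K, N_STATES)
  smoothed[K, ] <- filtered[K, ]
  if (K > 1L) {
    for (k in (K - 1L):1L) {
      r <- ifelse(predicted[k + 1L, ] > 0,
                  smoothed[k + 1L, ] / predicted[k + 1L, ], 0)
      row <- filtered[k, ] * as.numeric(T_mat %*% r)
      s <- sum(row)
      if (!is.finite(s) || s <= 0)
        stop(sprintf("degenerate smoothing update at frame %d", k))
      smoothed[k, ] <- row / s
    }
  }
  smoothed
}

#' MAP decoding of smoothed posteriors
#'
#' Assigns each frame the state maximizing its smoothed marginal posterior,
#' `s_k = argmax p(s_k | Z_K)`; ties break toward the smallest state index.
#'
#' @param smoothed `K x 3` matrix of (smoothed) posteriors.
#' @return Integer vector of decoded states in `{0, 1, 2}`.
#' @export
decodeMAP <- function(smoothed) {
  if (is.null(dim(smoothed))) smoothed <- matrix(smoothed, 1L)
  max.col(smoothed, ties.method = "first") - 1L
}

#' Decode the behavioral states of a trajectory
#'
#' Convenience wrapper: observation assembly, forward filtering, backward
#' smoothing and per-frame MAP state selection in one call.
#'
#' @param model an `estrusHMM` model.
#' @param traj a [trajectory()] object, or a `K x 3` observation matrix.
#' @return List with `states` (integer length-K), `smoothed`, `filtered`
#'   (`K x 3` posteriors) and `loglik`.
#' @export
decodeStates <- function(model, traj) {
  Z <- if (inherits(traj, "trajectory")) makeObservations(traj) else traj
  fw <- forwardFilter(model, Z)
  sm <- backwardSmooth(model, fw)
  list(states = decodeMAP(sm), smoothed = sm, filtered = fw$filtered,
       loglik = fw$loglik)
}

#' Exact smoothed posteriors by path enumeration
#'
#' Test oracle: computes `p(s_k | Z_K)` exactly by summing the joint
#' probability of every one of the `3^K` state paths. Refuses sequences
#' longer than 10 frames.
#'
#' @inheritParams forwardFilter
#' @return `K x 3` matrix of smoothed posteriors.
#' @export
bruteForcePosterior <- function(model, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, 1L)
  K <- nrow(Z)
  if (K > 10L) stop("path enumeration refused for K > 10")
  E <- emissionLogDensity(model, Z)
  logT <- log(model$transition$T)
  logpi <- log(model$transition$pi)
  paths <- as.matrix(expand.grid(rep(list(1:N_STATES), K)))
  logp <- logpi[paths[, 1L]] + E[cbind(1L, paths[, 1L])]
  if (K > 1L) {
    for (k in 2:K) {
      logp <- logp + logT[cbind(paths[, k - 1L], paths[, k])] +
        E[cbind(k, paths[, k])]
    }
  }
  w <- exp(logp - logSumExp(logp))
  post <- matrix(0, K, N_STATES)
  for (k in seq_len(K))
    for (s in seq_len(N_STATES))
      post[k, s] <- sum(w[paths[, k] == s])
  post / rowSums(post)
}

#' Serialize an HMM model to JSON
#'
#' All floating-point values are written at full precision so that a
#' write/read round trip reproduces the model bit-exactly.
#'
#' @param model an `estrusHMM` model.
#' @param path output JSON file path.
#' @return `path`, invisibly.
#' @export
writeHMMModel <- function(model, path) {
  obj <- list(
    transition = list(T = model$transition$T, pi = model$transition$pi),
    emissions = lapply(model$emissions, function(em)
      list(m = em$m, weights = em$weights, means = em$means,
           variances = em$variances, loglik = em$loglik, aic = em$aic,
           n = em$n, converged = em$converged))
  )
  # 17 significant digits: the shortest decimal precision that round-trips
  # every IEEE double exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeHMMModel
#' @return `readHMMModel()` returns the deserialized `estrusHMM` model.
#' @export
readHMMModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  asMat <- function(rows)
    do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  emissions <- lapply(obj$emissions, function(e) {
    structure(list(m = as.integer(e$m),
                   weights = as.numeric(unlist(e$weights)),
                   means = asMat(e$means),
                   variances = asMat(e$variances),
                   loglik = as.numeric(e$loglik), aic = as.numeric(e$aic),
                   n = as.integer(e$n), converged = isTRUE(e$converged)),
              class = "gmmEmission")
  })
  structure(list(transition = transitionModel(asMat(obj$transition$T),
                                              as.numeric(unlist(obj$transition$pi))),
                 emissions = emissions),
            class = "estrusHMM")
}
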