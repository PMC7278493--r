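# Frame-wise classifier baselines. Unlike the HMM, these predict the
# behavioral state of each frame from z_k = (x, y, L) alone, with no temporal
# structure: random forest (1 feature tried per split), RBF-kernel SVM with
# grid-searched kernel width and cost, and a single-hidden-layer neural
# network with 10 units. The fitting itself is delegated to the standard
# solvers (randomForest, kernlab, nnet).

#' Cross-validation fold count by Sturges' formula
#'
#' `k = floor(1 + log2(n))`. At the study's training size n = 9600
#' (8 animals x 1200 frames) this gives 14 folds.
#'
#' @param n sample count, `n >= 2`.
#' @return Integer fold count, `>= 2`.
#' @export
sturgesFolds <- function(n) {
  if (n < 2) stop("need n >= 2 for cross-validation")
  max(2L, as.integer(floor(1 + log2(n))))
}

#' Specify a frame-wise classifier
#'
#' @param method `"rf"` (random forest), `"svm"` (RBF-kernel support vector
#'   machine) or `"nn"` (single-hidden-layer neural network).
#' @param seed integer seed controlling all stochastic parts of the fit.
#' @param mtry rf: features tried per split (study value 1).
#' @param ntree rf: number of trees (randomForest default 500).
#' @param sigma_grid svm: candidate RBF kernel widths for the grid search.
#' @param cost_grid svm: candidate soft-margin costs.
#' @param folds svm: cross-validation folds for the grid search; `NULL`
#'   (default) uses [sturgesFolds()] on the training size.
#' @param size nn: hidden units in the single hidden layer (study value 10).
#' @param maxit nn: maximum optimizer iterations.
#' @return An object of class `classifierSpec`.
#' @export
classifierSpec <- function(method = c("rf", "svm", "nn"), seed = 1L,
                           mtry = 1L, ntree = 500L,
                           sigma_grid = 10^(-2:5), cost_grid = 10^(-1:3),
                           folds = NULL, size = 10L, maxit = 500L) {
  method <- match.arg(method)
  spec <- switch(method,
    rf = list(mtry = as.integer(mtry), ntree = as.integer(ntree)),
    svm = list(sigma_grid = as.numeric(sigma_grid),
               cost_grid = as.numeric(cost_grid), folds = folds),
    nn = list(size = as.integer(size), maxit = as.integer(maxit)))
  if (any(vapply(spec, function(v)
        is.numeric(v) && any(v <= 0), logical(1L))))
    stop("hyperparameters must be positive")
  structure(c(list(method = method, seed = as.integer(seed)), spec),
            class = "classifierSpec")
}

#' Train a frame-wise classifier
#'
#' @param spec a [classifierSpec()].
#' @param features numeric `n x 3` matrix of observation vectors
#'   (`x`, `y`, `L`).
#' @param labels integer state labels in `{0, 1, 2}`, aligned with
#'   `features`; at least two distinct classes.
#' @return An object of class `frameClassifier` wrapping the fitted model;
#'   for `"svm"`, the selected `(sigma, cost)` pair and its cross-validation
#'   error are recorded in the `tuning` element.
#' @export
trainFrameClassifier <- function(spec, features, labels) {
  features <- as.matrix(features)
  colnames(features) <- c("x", "y", "L")
  if (nrow(features) != length(labels))
    stop("features and labels must be aligned")
  y <- factor(as.integer(labels))  # levels = classes present in training
  if (nlevels(y) < 2L) stop("single-class training set")
  const <- apply(features, 2L, function(v) diff(range(v)) == 0)
  if (any(const))
    warning("constant feature column(s): ",
            paste(colnames(features)[const], collapse = ", "))
  tuning <- NULL
  set.seed(spec$seed)
  fit <- switch(spec$method,
    rf = randomForest::randomForest(x = features, y = y, mtry = spec$mtry,
                                    ntree = spec$ntree),
    svm = {
      folds <- if (is.null(spec$folds)) sturgesFolds(nrow(features))
               else as.integer(spec$folds)
      grid <- expand.grid(sigma = spec$sigma_grid, cost = spec$cost_grid)
      do_cv <- nrow(grid) > 1L
      grid$cv_error <- NA_real_
      best <- NULL; best_err <- Inf
      for (g in seq_len(nrow(grid))) {
        set.seed(spec$seed + g)
        m <- kernlab::ksvm(x = features, y = y, type = "C-svc",
                           kernel = "rbfdot",
                           kpar = list(sigma = grid$sigma[g]),
                           C = grid$cost[g],
                           cross = if (do_cv) folds else 0L)
        err <- if (do_cv) kernlab::cross(m) else kernlab::error(m)
        grid$cv_error[g] <- err
        if (err < best_err) { best <- m; best_err <- err }
      }
      sel <- which.min(grid$cv_error)
      tuning <- list(sigma = grid$sigma[sel], cost = grid$cost[sel],
                     cv_error = grid$cv_error[sel], folds = folds,
                     grid = grid)
      best
    },
    nn = {
      # standardized inputs help the single-layer optimizer; the scaling is
      # stored and re-applied at prediction time
      ctr <- colMeans(features)
      scl <- pmax(apply(features, 2L, stats::sd), 1e-12)
      Xs <- scale(features, center = ctr, scale = scl)
      net <- nnet::nnet(x = Xs, y = nnet::class.ind(y), size = spec$size,
                        softmax = TRUE, maxit = spec$maxit, trace = FALSE)
      list(net = net, center = ctr, scale = scl)
    })
  structure(list(method = spec$method, fit = fit, spec = spec,
                 tuning = tuning, levels = levels(y)),
            class = "frameClassifier")
}

#' @export
print.frameClassifier <- function(x, ...) {
  cat(sprintf("Frame-wise classifier: %s\n", x$method))
  if (!is.null(x$tuning))
    cat(sprintf("  selected sigma = %g, cost = %g (%d-fold CV error %.4f)\n",
                x$tuning$sigma, x$tuning$cost, x$tuning$folds,
                x$tuning$cv_error))
  invisible(x)
}

#' Predict states frame by frame
#'
#' Each frame is classified independently from its own observation vector;
#' predictions for a frame are unaffected by the other frames.
#'
#' @param classifier a trained [trainFrameClassifier()] handle.
#' @param Z `K x 3` observation matrix (see [makeObservations()]).
#' @return Integer vector of predicted states in `{0, 1, 2}`, length `K`
#'   (length 0 for an empty input).
#' @export
predictFrames <- function(classifier, Z) {
  Z <- as.matrix(Z)
  if (!nrow(Z)) return(integer(0L))
  if (ncol(Z) != 3L) stop("feature dimension mismatch: expected 3 columns")
  colnames(Z) <- c("x", "y", "L")
  pred <- switch(classifier$method,
    rf = stats::predict(classifier$fit, Z),
    svm = kernlab::predict(classifier$fit, Z),
    nn = {
      Xs <- scale(Z, center = classifier$fit$center,
                  scale = classifier$fit$scale)
      p <- stats::predict(classifier$fit$net, Xs)
      factor(classifier$levels[max.col(p, ties.method = "first")],
             levels = classifier$levels)
    })
  as.integer(as.character(pred))
}
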