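#' Per-frame step lengths
#'
#' The step length at frame k is the Euclidean displacement of the marker
#' between frames k and k+1,
#' `L(k) = sqrt((x(k+1)-x(k))^2 + (y(k+1)-y(k))^2)`. The final frame has no
#' successor; by default its step length carries the last defined value
#' forward (`L(K) = L(K-1)`) so that every frame has a complete observation
#' vector; `last = "drop"` returns only the K-1 defined values.
#'
#' @param traj a [trajectory()] object (or data frame with `x`, `y`).
#' @param last `"carry"` (default) or `"drop"`.
#' @return Numeric vector of step lengths, length `K` (`"carry"`) or
#'   `K - 1` (`"drop"`). All values are non-negative.
#' @export
stepLengths <- function(traj, last = c("carry", "drop")) {
  last <- match.arg(last)
  K <- nrow(traj)
  if (is.null(K) || K < 2L) stop("step length undefined for K < 2")
  L <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  if (last == "carry") L <- c(L, L[K - 1L])
  L
}

#' Assemble the observation sequence of a trajectory
#'
#' Builds the per-frame observable 3-vectors `z_k = (x(k), y(k), L(k))` used
#' by both the HMM emission model and the frame-wise classifiers.
#'
#' @param traj a [trajectory()] object.
#' @return A numeric `K x 3` matrix with columns `x`, `y`, `L`.
#' @export
makeObservations <- function(traj) {
  Z <- cbind(x = traj$x, y = traj$y, L = stepLengths(traj))
  rownames(Z) <- NULL
  Z
}

#' Stack labeled trajectories into a training matrix
#'
#' Pools several observer-labeled trajectories into the flat
#' `(K * n_animals) x 4` design matrix (three observables plus the observer
#' state) that supervised training consumes. Eight 1200-frame animals yield a
#' 9600 x 4 matrix, i.e. 38,400 entries.
#'
#' @param trajs list of labeled [trajectory()] objects.
#' @return Numeric matrix with columns `x`, `y`, `L`, `label`.
#' @export
stackTrainingMatrix <- function(trajs) {
  if (!length(trajs)) stop("no trajectories supplied")
  rows <- lapply(trajs, function(tr) {
    cbind(makeObservations(tr), label = trajLabels(tr))
  })
  do.call(rbind, rows)
}
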