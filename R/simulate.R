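# Synthetic goat-cohort generator. Emulates the structure of the study's
# tracking data: a square observation pen with the male paddock adjacent to
# the small-x side, three labeled behavioral states evolving by a Markov
# chain, and marker positions whose distribution depends on the active
# state. Two position mechanisms are provided: a state-attracted correlated
# walk (default; step length carries state information, positions are
# autocorrelated as in real tracks) and an iid Gaussian draw per frame
# (matching the HMM's own emission assumption exactly, for oracle-sharp
# tests).

#' Per-state position and movement profile
#'
#' Describes, for each behavioral state, where in the pen the animal tends
#' to be and how it moves. Defaults (pen = unit square, male side at x = 0):
#' state 0 roams away from the male with moderate steps, state 1 moves
#' toward the male side with large steps, state 2 stands at the male fence
#' with very small steps.
#'
#' @param means `3 x 2` matrix of state position-kernel centers (rows =
#'   states 0..2, columns = x, y), in pen units.
#' @param sds `3 x 2` matrix of kernel standard deviations.
#' @param attraction length-3 per-frame pull toward the active kernel
#'   center, in `[0, 1]` (walk mode only).
#' @param step_sd length-3 per-frame displacement noise sd (walk mode), also
#'   used to scale movement in Gaussian mode via the kernel sds.
#' @return An object of class `stateProfile`.
#' @export
stateProfile <- function(means = rbind(c(0.70, 0.50),
                                       c(0.30, 0.50),
                                       c(0.06, 0.35)),
                         sds = rbind(c(0.17, 0.17),
                                     c(0.13, 0.18),
                                     c(0.04, 0.12)),
                         attraction = c(0.10, 0.25, 0.35),
                         step_sd = c(0.030, 0.070, 0.006)) {
  means <- as.matrix(means); sds <- as.matrix(sds)
  if (!all(dim(means) == c(3L, 2L)) || !all(dim(sds) == c(3L, 2L)))
    stop("means and sds must be 3 x 2 matrices (states x coordinates)")
  if (any(sds <= 0) || any(step_sd <= 0)) stop("sds must be positive")
  if (any(attraction < 0 | attraction > 1))
    stop("attraction must lie in [0, 1]")
  structure(list(means = means, sds = sds,
                 attraction = as.numeric(attraction),
                 step_sd = as.numeric(step_sd)),
            class = "stateProfile")
}

#' A sharply separated state profile
#'
#' Tight position kernels and strongly distinct step scales, for parameter
#' recovery and decoding checks where the states must be identifiable from
#' the observables nearly without ambiguity.
#'
#' @return A [stateProfile()].
#' @export
separatedStateProfile <- function() {
  stateProfile(means = rbind(c(0.85, 0.80),
                             c(0.45, 0.40),
                             c(0.06, 0.15)),
               sds = rbind(c(0.04, 0.04),
                           c(0.05, 0.05),
                           c(0.02, 0.04)),
               attraction = c(0.30, 0.45, 0.55),
               step_sd = c(0.020, 0.080, 0.003))
}

#' Default group transition matrices
#'
#' Strongly diagonal (behavioral persistence) with group-specific occupancy:
#' estrus animals spend most frames approaching (1) or standing near the
#' male (2); non-estrus animals stay mostly in state 0.
#'
#' @return A [transitionModel()] with `pi` at the stationary distribution.
#' @export
defaultEstrusTransition <- function() {
  transitionModel(rbind(c(0.950, 0.040, 0.010),
                        c(0.030, 0.900, 0.070),
                        c(0.004, 0.016, 0.980)))
}

#' @rdname defaultEstrusTransition
#' @export
defaultNonestrusTransition <- function() {
  transitionModel(rbind(c(0.975, 0.020, 0.005),
                        c(0.080, 0.900, 0.020),
                        c(0.060, 0.040, 0.900)))
}

#' Synthetic cohort recipe
#'
#' @param pen_width,pen_height pen dimensions in length-units (default unit
#'   square; the study pen was 2.5 m x 2.5 m, selectable via these fields).
#' @param K frames per animal (default 1200 = 10 min at 0.5 s per frame).
#' @param n_estrus,n_nonestrus animals per group (default 8 each).
#' @param transition_estrus,transition_nonestrus group-specific true
#'   [transitionModel()]s.
#' @param profile shared [stateProfile()] giving the pen semantics of each
#'   state.
#' @param label_noise probability that an observer label is flipped to a
#'   uniformly chosen other state, in `[0, 1]`.
#' @param mode `"walk"` (state-attracted correlated walk, default) or
#'   `"gaussian"` (iid per-frame position draw from the state kernel).
#' @param seed cohort seed; animal i is simulated with `seed + i`.
#' @return An object of class `cohortConfig`.
#' @export
cohortConfig <- function(pen_width = 1, pen_height = 1, K = 1200L,
                         n_estrus = 8L, n_nonestrus = 8L,
                         transition_estrus = defaultEstrusTransition(),
                         transition_nonestrus = defaultNonestrusTransition(),
                         profile = stateProfile(),
                         label_noise = 0, mode = c("walk", "gaussian"),
                         seed = 1L) {
  mode <- match.arg(mode)
  if (K < 2L) stop("K must be >= 2")
  if (n_estrus < 0L || n_nonestrus < 0L) stop("animal counts must be >= 0")
  if (label_noise < 0 || label_noise > 1)
    stop("label_noise must lie in [0, 1]")
  structure(list(pen_width = pen_width, pen_height = pen_height,
                 K = as.integer(K), n_estrus = as.integer(n_estrus),
                 n_nonestrus = as.integer(n_nonestrus),
                 transition_estrus = transition_estrus,
                 transition_nonestrus = transition_nonestrus,
                 profile = profile, label_noise = label_noise,
                 mode = mode, seed = as.integer(seed)),
            class = "cohortConfig")
}

# simulate a state path of length K from a transitionModel
.simulateStates <- function(transition, K) {
  s <- integer(K)
  s[1L] <- sample.int(3L, 1L, prob = transition$pi)
  for (k in 2:K)
    s[k] <- sample.int(3L, 1L, prob = transition$T[s[k - 1L], ])
  s - 1L
}

#' Simulate one labeled trajectory
#'
#' States evolve by the transition model from its initial distribution.
#' Positions follow the profile: in walk mode an AR(1)-style walk pulled
#' toward the active state's kernel center with per-frame Gaussian
#' displacement noise, in Gaussian mode an independent draw from the state
#' kernel each frame. Positions are clipped to the pen. Labels equal the
#' generating states, then each is flipped to a uniformly chosen other state
#' with probability `label_noise`.
#'
#' @param profile a [stateProfile()].
#' @param transition a [transitionModel()].
#' @param K number of frames.
#' @param seed integer seed; the whole trajectory is reproducible from it.
#' @param pen_width,pen_height pen bounds.
#' @param label_noise label flip probability.
#' @param mode `"walk"` or `"gaussian"`.
#' @param animal_id,estrus metadata for the returned trajectory.
#' @return A labeled [trajectory()]; the generating states are attached as
#'   attribute `true_states`.
#' @export
simulateTrajectory <- function(profile, transition, K = 1200L, seed = 1L,
                               pen_width = 1, pen_height = 1,
                               label_noise = 0,
                               mode = c("walk", "gaussian"),
                               animal_id = "sim", estrus = NA) {
  mode <- match.arg(mode)
  if (!inherits(transition, "transitionModel"))
    stop("transition must be a transitionModel")
  if (K < 2L) stop("K must be >= 2")
  set.seed(as.integer(seed))
  s <- .simulateStates(transition, K)
  clip <- function(v, hi) pmin(pmax(v, 0), hi)
  if (mode == "gaussian") {
    x <- clip(stats::rnorm(K, profile$means[s + 1L, 1L],
                           profile$sds[s + 1L, 1L]), pen_width)
    y <- clip(stats::rnorm(K, profile$means[s + 1L, 2L],
                           profile$sds[s + 1L, 2L]), pen_height)
  } else {
    x <- y <- numeric(K)
    x[1L] <- clip(stats::rnorm(1L, profile$means[s[1L] + 1L, 1L],
                               profile$sds[s[1L] + 1L, 1L]), pen_width)
    y[1L] <- clip(stats::rnorm(1L, profile$means[s[1L] + 1L, 2L],
                               profile$sds[s[1L] + 1L, 2L]), pen_height)
    for (k in 2:K) {
      st <- s[k] + 1L
      a <- profile$attraction[st]
      x[k] <- clip(x[k - 1L] + a * (profile$means[st, 1L] - x[k - 1L]) +
                     stats::rnorm(1L, 0, profile$step_sd[st]), pen_width)
      y[k] <- clip(y[k - 1L] + a * (profile$means[st, 2L] - y[k - 1L]) +
                     stats::rnorm(1L, 0, profile$step_sd[st]), pen_height)
    }
  }
  labels <- s
  if (label_noise > 0) {
    flip <- stats::runif(K) < label_noise
    if (any(flip)) {
      shift <- sample.int(2L, sum(flip), replace = TRUE)
      labels[flip] <- (labels[flip] + shift) %% 3L
    }
  }
  traj <- trajectory(seq_len(K), x, y, label = labels,
                     animal_id = animal_id, estrus = estrus)
  attr(traj, "true_states") <- s
  traj
}

#' Simulate a full cohort
#'
#' Generates `n_estrus` animals under the estrus transition model and
#' `n_nonestrus` under the non-estrus one, all sharing the config's state
#' profile and pen. Animal i uses seed `config$seed + i`, so any animal can
#' be regenerated independently.
#'
#' @param config a [cohortConfig()].
#' @return An object of class `goatCohort`: list with `trajectories` (named
#'   list), `manifest` (data frame: `animal_id`, `estrus`, `seed`) and
#'   `config`.
#' @export
simulateCohort <- function(config) {
  n <- config$n_estrus + config$n_nonestrus
  if (n < 1L) stop("cohort must contain at least one animal")
  estrus_flags <- rep(c(TRUE, FALSE), c(config$n_estrus, config$n_nonestrus))
  ids <- c(sprintf("estrus_%02d", seq_len(config$n_estrus)),
           sprintf("nonestrus_%02d", seq_len(config$n_nonestrus)))
  trajs <- vector("list", n)
  names(trajs) <- ids
  for (i in seq_len(n)) {
    trans <- if (estrus_flags[i]) config$transition_estrus
             else config$transition_nonestrus
    trajs[[i]] <- simulateTrajectory(
      config$profile, trans, K = config$K, seed = config$seed + i,
      pen_width = config$pen_width, pen_height = config$pen_height,
      label_noise = config$label_noise, mode = config$mode,
      animal_id = ids[i], estrus = estrus_flags[i])
  }
  structure(list(trajectories = trajs,
                 manifest = data.frame(animal_id = ids,
                                       estrus = estrus_flags,
                                       seed = config$seed + seq_len(n)),
                 config = config),
            class = "goatCohort")
}

#' @export
print.goatCohort <- function(x, ...) {
  cat(sprintf("Synthetic goat cohort: %d estrus + %d non-estrus animals, %d frames each (%s mode, seed %d)\n",
              x$config$n_estrus, x$config$n_nonestrus, x$config$K,
              x$config$mode, x$config$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One tracking CSV per animal plus a `manifest.csv`
#' (`animal_id,estrus,path`) and a `truth.json` holding the generating
#' config (transition matrices, profile, seeds) at full precision.
#'
#' @param cohort a [simulateCohort()] result.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeCohortCsv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(cohort$manifest$animal_id, ".csv"))
  for (i in seq_along(paths))
    writeTrackingCsv(cohort$trajectories[[i]], paths[i])
  manifest <- cbind(cohort$manifest[c("animal_id", "estrus")],
                    path = basename(paths))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  truth <- list(pen_width = cfg$pen_width, pen_height = cfg$pen_height,
                K = cfg$K, n_estrus = cfg$n_estrus,
                n_nonestrus = cfg$n_nonestrus,
                transition_estrus = list(T = cfg$transition_estrus$T,
                                         pi = cfg$transition_estrus$pi),
                transition_nonestrus = list(T = cfg$transition_nonestrus$T,
                                            pi = cfg$transition_nonestrus$pi),
                profile = cfg$profile[c("means", "sds", "attraction",
                                        "step_sd")],
                label_noise = cfg$label_noise, mode = cfg$mode,
                seed = cfg$seed,
                animal_seeds = cohort$manifest$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = I(17), auto_unbox = TRUE)
  invisible(mpath)
}

#' Read a cohort from a manifest
#'
#' @param manifest_path path to a `manifest.csv` written by
#'   [writeCohortCsv()] (columns `animal_id,estrus,path`; relative paths are
#'   resolved against the manifest's directory).
#' @return Named list of [trajectory()] objects.
#' @export
readCohortCsv <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("animal_id", "estrus", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns animal_id, estrus, path")
  base <- dirname(manifest_path)
  trajs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    readTrackingCsv(p, animal_id = man$animal_id[i], estrus = man$estrus[i])
  })
  names(trajs) <- man$animal_id
  trajs
}
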