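# Shared fixtures: all synthetic, built in code at test time.

# a random but valid 3-state HMM (single- or two-component emissions fitted
# to random data, so all invariants hold by construction)
randomModel <- function(seed, m = 1L) {
  set.seed(seed)
  T_mat <- matrix(stats::rexp(9), 3L)
  T_mat <- T_mat / rowSums(T_mat)
  pi <- stats::rexp(3); pi <- pi / sum(pi)
  emissions <- lapply(1:3, function(s)
    fitStateGMM(matrix(stats::rnorm(60, mean = 3 * s, sd = s), 20L, 3L),
                m = m, seed = seed + s))
  structure(list(transition = transitionModel(T_mat, pi),
                 emissions = emissions),
            class = "estrusHMM")
}

# cohort with one shared true transition matrix and sharply separated
# emission profiles: the parameter-recovery reference conditions
recoveryConfig <- function(seed = 7, K = 1200L, mode = "gaussian") {
  Tshared <- defaultEstrusTransition()
  cohortConfig(transition_estrus = Tshared, transition_nonestrus = Tshared,
               profile = separatedStateProfile(), label_noise = 0,
               K = K, mode = mode, seed = seed)
}

firstTrainingIds <- function(cohort) {
  man <- cohort$manifest
  c(man$animal_id[man$estrus][1:4], man$animal_id[!man$estrus][1:4])
}

# draw n points from a d=3 diagonal-Gaussian mixture with component means
# spaced `gap` apart on every coordinate (gap = 10 means 10-sigma separation)
rmixture3d <- function(n, m, gap = 10, sd = 1) {
  comp <- sample.int(m, n, replace = TRUE)
  mu <- matrix(gap * (comp - 1L), n, 3L)
  mu + matrix(stats::rnorm(3L * n, sd = sd), n, 3L)
}
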