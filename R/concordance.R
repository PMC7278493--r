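# Percentage-concordance scoring of estimated behavior sequences against
# human observation, with a temporal tolerance window: a behavior frame
# counts as concordant when the other sequence shows the behavior within
# +/- `window` frames (one frame = 0.5 s; the default window of 1 allows the
# two-point tolerance between human and machine reaction to the video).

# dilate a logical sequence by `window` frames on each side (edge-truncated)
.dilate <- function(b, window) {
  if (window == 0L || !length(b)) return(b)
  K <- length(b)
  out <- b
  for (d in seq_len(window)) {
    out <- out | c(b[-seq_len(d)], rep(FALSE, d)) |
      c(rep(FALSE, d), b[seq_len(K - d)])
  }
  out
}

#' Windowed concordance counts for one behavior
#'
#' Frame-level counting against a +/- `window` frame tolerance: an
#' observed-behavior frame is a true positive (TP) if the prediction shows
#' the behavior anywhere in its window, otherwise a false negative (FN); a
#' predicted-behavior frame is a false positive (FP) if the observation
#' shows the behavior nowhere in its window. Windows are truncated at the
#' sequence edges.
#'
#' @param pred,obs equal-length label sequences (values in `{0, 1, 2}`).
#' @param behavior the target behavior state, 1 (approaching) or 2
#'   (standing).
#' @param window tolerance in frames, `>= 0` (default 1).
#' @return Named integer vector `c(TP, FN, FP)`.
#' @export
windowedConcordanceCounts <- function(pred, obs, behavior, window = 1L) {
  if (length(pred) != length(obs))
    stop("pred and obs must have equal length")
  if (window < 0L) stop("window must be >= 0")
  window <- as.integer(window)
  pred_b <- pred == behavior
  obs_b <- obs == behavior
  pred_d <- .dilate(pred_b, window)
  obs_d <- .dilate(obs_b, window)
  c(TP = sum(obs_b & pred_d),
    FN = sum(obs_b & !pred_d),
    FP = sum(pred_b & !obs_d))
}

#' Percentage concordance
#'
#' `PC = 100 * TP / (TP + FN + FP)`, with FP and FN likewise expressed as
#' percentages of `TP + FN + FP` (so the three shares sum to 100). When the
#' behavior occurs in neither sequence (`TP = FN = FP = 0`) the estimate is
#' in full agreement with the observer and PC is 100 by convention.
#'
#' @param TP,FN,FP non-negative frame counts, or a single named vector as
#'   returned by [windowedConcordanceCounts()] passed as `TP`.
#' @return Named numeric vector `c(PC, FP_pct, FN_pct)` in percent.
#' @export
percentageConcordance <- function(TP, FN = NULL, FP = NULL) {
  if (is.null(FN) && length(TP) == 3L) {
    FN <- TP[["FN"]]; FP <- TP[["FP"]]; TP <- TP[["TP"]]
  }
  counts <- c(TP, FN, FP)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- TP + FN + FP
  if (tot == 0) return(c(PC = 100, FP_pct = 0, FN_pct = 0))
  c(PC = 100 * TP / tot, FP_pct = 100 * FP / tot, FN_pct = 100 * FN / tot)
}

#' Per-animal, per-behavior concordance table
#'
#' Scores a set of predicted label sequences against the observer labels for
#' both estrus behaviors (approaching = 1, standing = 2).
#'
#' @param pred_list named list of predicted label sequences (names = animal
#'   ids).
#' @param obs_list named list of observer label sequences, same names.
#' @param window tolerance window in frames (default 1).
#' @param training_ids optional character vector of animal ids used for
#'   training; flagged in the output.
#' @return A data frame with one row per animal x behavior: `animal_id`,
#'   `behavior` (`"approaching"` or `"standing"`), `TP`, `FN`, `FP`, `PC`,
#'   `FP_pct`, `FN_pct`, `is_training`.
#' @export
concordanceTable <- function(pred_list, obs_list, window = 1L,
                             training_ids = character()) {
  ids <- names(obs_list)
  if (is.null(ids) || !setequal(ids, names(pred_list)))
    stop("pred_list and obs_list must be named lists over the same animals")
  rows <- list()
  for (id in ids) {
    for (b in c(1L, 2L)) {
      cts <- windowedConcordanceCounts(pred_list[[id]], obs_list[[id]],
                                       behavior = b, window = window)
      pcs <- percentageConcordance(cts)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = id,
        behavior = c("approaching", "standing")[b],
        TP = cts[["TP"]], FN = cts[["FN"]], FP = cts[["FP"]],
        PC = pcs[["PC"]], FP_pct = pcs[["FP_pct"]], FN_pct = pcs[["FN_pct"]],
        is_training = id %in% training_ids)
    }
  }
  do.call(rbind, rows)
}

#' Behavioral time budget of a label sequence
#'
#' Percentage of frames spent approaching the male (state 1) and standing
#' near the male (state 2).
#'
#' @param labels nonempty label sequence with values in `{0, 1, 2}`.
#' @return Named numeric vector `c(approaching, standing)` in percent.
#' @export
behaviorTimeBudget <- function(labels) {
  if (!length(labels)) stop("empty label sequence")
  c(approaching = 100 * mean(labels == 1),
    standing = 100 * mean(labels == 2))
}

#' Compare per-animal time budgets between observation and a method
#'
#' Paired two-sided t-test on the per-animal differences between observed
#' and estimated time budgets (each animal contributes one observation /
#' estimation pair). A Welch two-sample variant is available. Zero variance
#' of the differences (e.g. identical budgets) is flagged as degenerate
#' rather than raising an error.
#'
#' @param obs_budgets,method_budgets aligned numeric vectors of per-animal
#'   budget percentages, length >= 2.
#' @param paired paired t-test (default) or Welch two-sample.
#' @return List with `statistic`, `p_value`, `df`, `n`, `mean_difference`
#'   and `degenerate`.
#' @export
compareBudgetsTTest <- function(obs_budgets, method_budgets, paired = TRUE) {
  n <- length(obs_budgets)
  if (length(method_budgets) != n)
    stop("budget vectors must be aligned per animal")
  if (n < 2L)
    return(list(statistic = NA_real_, p_value = NA_real_, df = NA_real_,
                n = n, mean_difference = mean(obs_budgets - method_budgets),
                degenerate = TRUE))
  d <- obs_budgets - method_budgets
  if (paired && stats::sd(d) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, df = n - 1,
                n = n, mean_difference = mean(d), degenerate = TRUE))
  tt <- stats::t.test(obs_budgets, method_budgets, paired = paired)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), n = n,
       mean_difference = unname(if (paired) tt$estimate
                                else diff(rev(tt$estimate))),
       degenerate = FALSE)
}
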