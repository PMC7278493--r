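# End-to-end experiment: train every requested method on the designated
# training animals, decode/predict all animals (training animals included
# but flagged, mirroring the study's gray-cell reporting), score windowed
# concordance per animal and behavior, and compare behavioral time budgets
# between observation and each method with paired t-tests.

#' Configure an experiment run
#'
#' @param cohort a `goatCohort` (from [simulateCohort()]), a named list of
#'   labeled [trajectory()] objects, or a [cohortConfig()] to simulate.
#' @param training_ids animal ids used for supervised training; default: the
#'   first half of each estrus group (4 + 4 under the default cohort).
#' @param methods subset of `c("hmm", "rf", "svm", "nn")`.
#' @param window concordance tolerance window in frames (default 1).
#' @param m_grid HMM emission component grid (default 1:15).
#' @param rf_spec,svm_spec,nn_spec [classifierSpec()]s for the comparators;
#'   defaults use the study hyperparameters (rf mtry 1 / 500 trees, svm
#'   grid-searched RBF width and cost with Sturges-formula folds, nn 10
#'   hidden units).
#' @param seed master seed for the run.
#' @return An object of class `experimentConfig`.
#' @export
experimentConfig <- function(cohort, training_ids = NULL,
                             methods = c("hmm", "rf", "svm", "nn"),
                             window = 1L, m_grid = 1:15,
                             rf_spec = NULL, svm_spec = NULL, nn_spec = NULL,
                             seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!length(methods)) stop("at least one method must be requested")
  structure(list(cohort = cohort, training_ids = training_ids,
                 methods = methods, window = as.integer(window),
                 m_grid = m_grid, rf_spec = rf_spec, svm_spec = svm_spec,
                 nn_spec = nn_spec, seed = as.integer(seed)),
            class = "experimentConfig")
}

.resolveTrajectories <- function(cohort) {
  if (inherits(cohort, "cohortConfig")) cohort <- simulateCohort(cohort)
  if (inherits(cohort, "goatCohort")) return(cohort$trajectories)
  if (is.list(cohort) && all(vapply(cohort, inherits, logical(1L),
                                    "trajectory")))
    return(cohort)
  stop("cohort must be a goatCohort, cohortConfig or list of trajectories")
}

.defaultTrainingIds <- function(trajs) {
  est <- vapply(trajs, function(tr) isTRUE(isEstrus(tr)), logical(1L))
  pick <- function(ids) ids[seq_len(ceiling(length(ids) / 2))]
  c(pick(names(trajs)[est]), pick(names(trajs)[!est]))
}

#' Run the full benchmark experiment
#'
#' @param config an [experimentConfig()].
#' @param out_dir optional directory; when given, the concordance table,
#'   budget table, t-test table and a JSON run log (resolved
#'   hyperparameters, seeds, timings) are written there.
#' @return List with `concordance` (per animal x behavior x method),
#'   `budgets` (per animal x method time budgets, observation included),
#'   `ttests` (per method x behavior x group paired tests vs observation),
#'   `timings` (seconds per method, informational), `predictions`, `models`
#'   and `training_ids`.
#' @export
runExperiment <- function(config, out_dir = NULL) {
  trajs <- .resolveTrajectories(config$cohort)
  if (!all(vapply(trajs, hasLabels, logical(1L))))
    stop("every animal needs observer labels for scoring")
  training_ids <- config$training_ids
  if (is.null(training_ids)) training_ids <- .defaultTrainingIds(trajs)
  unknown <- setdiff(training_ids, names(trajs))
  if (length(unknown))
    stop("unknown training id(s): ", paste(unknown, collapse = ", "))
  train <- trajs[training_ids]
  obs_list <- lapply(trajs, trajLabels)
  Z_list <- lapply(trajs, makeObservations)
  train_mat <- stackTrainingMatrix(train)
  features <- train_mat[, c("x", "y", "L"), drop = FALSE]
  labels <- train_mat[, "label"]

  models <- list(); predictions <- list(); timings <- c(); failures <- list()
  for (method in config$methods) {
    elapsed <- system.time({
      res <- tryCatch({
        if (method == "hmm") {
          model <- fitHMM(train, m_grid = config$m_grid, seed = config$seed)
          preds <- lapply(Z_list, function(Z) decodeStates(model, Z)$states)
        } else {
          spec <- switch(method,
            rf = config$rf_spec %||% classifierSpec("rf", seed = config$seed),
            svm = config$svm_spec %||% classifierSpec("svm",
                                                      seed = config$seed),
            nn = config$nn_spec %||% classifierSpec("nn", seed = config$seed))
          model <- trainFrameClassifier(spec, features, labels)
          preds <- lapply(Z_list, function(Z) predictFrames(model, Z))
        }
        list(model = model, preds = preds)
      }, error = function(e) e)
    })[["elapsed"]]
    timings[method] <- elapsed
    if (inherits(res, "error")) {
      failures[[method]] <- conditionMessage(res)
      warning(sprintf("method '%s' failed: %s", method,
                      conditionMessage(res)))
      next
    }
    models[[method]] <- res$model
    predictions[[method]] <- res$preds
  }

  concordance <- do.call(rbind, lapply(names(predictions), function(m) {
    tab <- concordanceTable(predictions[[m]], obs_list,
                            window = config$window,
                            training_ids = training_ids)
    cbind(method = m, tab)
  }))

  budgets <- do.call(rbind, lapply(names(trajs), function(id) {
    rows <- list(data.frame(animal_id = id,
                            estrus = isEstrus(trajs[[id]]),
                            method = "observation",
                            t(behaviorTimeBudget(obs_list[[id]])),
                            is_training = id %in% training_ids))
    for (m in names(predictions))
      rows[[length(rows) + 1L]] <-
        data.frame(animal_id = id, estrus = isEstrus(trajs[[id]]),
                   method = m, t(behaviorTimeBudget(predictions[[m]][[id]])),
                   is_training = id %in% training_ids)
    do.call(rbind, rows)
  }))

  ttests <- do.call(rbind, lapply(names(predictions), function(m) {
    do.call(rbind, lapply(c(TRUE, FALSE), function(grp) {
      sel <- budgets$estrus == grp
      if (!any(sel)) return(NULL)
      do.call(rbind, lapply(c("approaching", "standing"), function(beh) {
        ob <- budgets[sel & budgets$method == "observation", beh]
        mb <- budgets[sel & budgets$method == m, beh]
        tt <- compareBudgetsTTest(ob, mb)
        data.frame(method = m, group = ifelse(grp, "estrus", "non-estrus"),
                   behavior = beh, n = tt$n, statistic = tt$statistic,
                   p_value = tt$p_value, mean_difference = tt$mean_difference,
                   degenerate = tt$degenerate)
      }))
    }))
  }))

  result <- list(concordance = concordance, budgets = budgets,
                 ttests = ttests, timings = timings,
                 predictions = predictions, models = models,
                 training_ids = training_ids, failures = failures)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(concordance, file.path(out_dir, "concordance.csv"),
                     row.names = FALSE)
    utils::write.csv(budgets, file.path(out_dir, "budgets.csv"),
                     row.names = FALSE)
    utils::write.csv(ttests, file.path(out_dir, "ttests.csv"),
                     row.names = FALSE)
    if (!is.null(models$hmm))
      writeHMMModel(models$hmm, file.path(out_dir, "hmm_model.json"))
    log <- list(methods = config$methods, training_ids = training_ids,
                window = config$window, m_grid = config$m_grid,
                seed = config$seed, timings = as.list(timings),
                svm_tuning = if (!is.null(models$svm))
                  models$svm$tuning[c("sigma", "cost", "cv_error", "folds")],
                hmm_components = if (!is.null(models$hmm))
                  vapply(models$hmm$emissions, `[[`, integer(1L), "m"),
                failures = failures)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a
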