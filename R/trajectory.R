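#' Construct a trajectory object
#'
#' A trajectory holds one animal's frame-indexed marker positions from
#' overhead video tracking, optionally with per-frame behavioral state labels
#' assigned by a human observer. Frames are recorded every 0.5 s, so a 10-min
#' recording yields 1200 frames. The three ethogram states are coded
#' 0 (behavior besides approaching/standing), 1 (approaching the male) and
#' 2 (standing near the male).
#'
#' @param frame integer vector of frame indices; must be consecutive and
#'   start at 1.
#' @param x,y numeric marker coordinates, in arbitrary but consistent
#'   length-units. By convention the male paddock is adjacent to the small-x
#'   side of the pen.
#' @param label optional integer vector of observer states in `{0, 1, 2}`,
#'   one per frame.
#' @param animal_id character scalar identifying the animal.
#' @param estrus logical scalar: is the animal in estrus?
#'
#' @return An object of class `trajectory`: a data frame with columns
#'   `frame`, `x`, `y` and optionally `label`, carrying `animal_id` and
#'   `estrus` attributes.
#' @seealso [readTrackingCsv()], [makeObservations()]
#' @export
trajectory <- function(frame, x, y, label = NULL, animal_id = "animal",
                       estrus = NA) {
  frame <- as.integer(frame)
  K <- length(frame)
  if (K < 2L) stop("a trajectory needs at least 2 frames")
  if (length(x) != K || length(y) != K)
    stop("frame, x and y must have equal length")
  bad <- which(frame != seq_len(K))
  if (length(bad))
    stop(sprintf("non-consecutive frame index at row %d", bad[1L]))
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y))
    stop("coordinates must be numeric and non-missing")
  df <- data.frame(frame = frame, x = as.numeric(x), y = as.numeric(y))
  if (!is.null(label)) {
    if (length(label) != K)
      stop("labels, when present, must cover every frame")
    label <- as.integer(label)
    if (anyNA(label) || any(!label %in% 0:2))
      stop("labels must all lie in {0, 1, 2}")
    df$label <- label
  }
  structure(df,
            animal_id = as.character(animal_id),
            estrus = as.logical(estrus),
            class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory '%s' (%s): %d frames%s\n",
              animalId(x),
              if (isTRUE(isEstrus(x))) "estrus"
              else if (isFALSE(isEstrus(x))) "non-estrus" else "status unknown",
              nrow(x),
              if (hasLabels(x)) ", observer-labeled" else ""))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("... %d more frames\n", nrow(x) - 4L))
  invisible(x)
}

#' Trajectory accessors
#'
#' @param traj a [trajectory()] object.
#' @return `animalId()` the animal identifier; `isEstrus()` the estrus flag;
#'   `hasLabels()` whether observer labels are present; `trajLabels()` the
#'   integer label vector (error if absent).
#' @export
animalId <- function(traj) attr(traj, "animal_id")

#' @rdname animalId
#' @export
isEstrus <- function(traj) attr(traj, "estrus")

#' @rdname animalId
#' @export
hasLabels <- function(traj) "label" %in% names(traj)

#' @rdname animalId
#' @export
trajLabels <- function(traj) {
  if (!hasLabels(traj)) stop("trajectory carries no observer labels")
  traj$label
}

#' Read a tracking table from CSV
#'
#' The expected dialect is comma-separated, header row `frame,x,y[,label]`,
#' UTF-8, `.` decimal separator.
#'
#' @param path path to a CSV file with columns `frame`, `x`, `y` and
#'   optionally `label`.
#' @param animal_id,estrus metadata attached to the trajectory (typically
#'   taken from a cohort manifest).
#' @return A [trajectory()] object.
#' @export
readTrackingCsv <- function(path, animal_id = basename(path), estrus = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in c("x", "y")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn))
        stop(sprintf("non-numeric %s coordinate at row %d", col,
                     which(is.na(vn))[1L]))
      df[[col]] <- vn
    }
  }
  fr <- df$frame
  if (anyNA(fr) || any(fr != as.integer(fr)))
    stop("frame indices must be integers")
  if (anyDuplicated(fr))
    stop(sprintf("duplicate frame index at row %d", anyDuplicated(fr)))
  bad <- which(as.integer(fr) != seq_len(nrow(df)))
  if (length(bad))
    stop(sprintf("non-consecutive frame index at row %d", bad[1L]))
  trajectory(df$frame, df$x, df$y,
             label = if ("label" %in% names(df)) df$label else NULL,
             animal_id = animal_id, estrus = estrus)
}

#' Write a trajectory to CSV
#'
#' @param traj a [trajectory()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrackingCsv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
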