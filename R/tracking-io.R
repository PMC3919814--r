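TRAJ_COLUMNS <- c("cell_id", "replicate", "condition", "frame", "time_s",
                  "x_um", "y_um")

#' Read and write trajectory tables
#'
#' The on-disk dialect is a CSV with header
#' `cell_id,replicate,condition,frame,time_s,x_um,y_um`, one row per cell
#' per frame. Reading validates each cell: at least two points, consecutive
#' frames and a uniform frame interval; violations raise errors naming the
#' offending cell.
#'
#' @param path CSV file path.
#' @return `readTrajectories()` an [ExperimentSet]; `writeTrajectories()`
#'   the path, invisibly.
#' @examples
#' es <- simulateExperiment(list(ctl = WalkParams()), nCells = 2,
#'                          nReplicates = 1, seed = 2)
#' f <- tempfile(fileext = ".csv")
#' writeTrajectories(es, f)
#' es2 <- readTrajectories(f)
#' @export
readTrajectories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRAJ_COLUMNS, names(df))
  if (length(missing)) {
    stop("trajectory CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  key <- paste(df$condition, df$replicate, df$cell_id, sep = "\r")
  trajs <- lapply(split(seq_len(nrow(df)), key), function(ix) {
    sub <- df[ix, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    id <- sub$cell_id[1]
    if (nrow(sub) < 2L) {
      stop("cell '", id, "' has fewer than 2 points")
    }
    if (any(diff(sub$frame) != 1L)) {
      stop("gap in frames for cell '", id, "'")
    }
    dt <- diff(sub$time_s)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * abs(dt[1])) {
      stop("non-uniform time steps for cell '", id, "'")
    }
    Trajectory(id, times = sub$time_s,
               positions = cbind(sub$x_um, sub$y_um),
               condition = sub$condition[1], replicate = sub$replicate[1])
  })
  names(trajs) <- NULL
  ExperimentSet(trajs)
}

#' @rdname readTrajectories
#' @param x an [ExperimentSet] or list of [Trajectory] objects.
#' @export
writeTrajectories <- function(x, path) {
  trajs <- if (is(x, "ExperimentSet")) trajectories(x) else x
  rows <- lapply(trajs, function(tr) {
    n <- nrow(tr@positions)
    data.frame(cell_id = rep(tr@cellId, n), replicate = tr@replicate,
               condition = tr@condition, frame = seq_len(n) - 1L,
               time_s = tr@times, x_um = tr@positions[, 1],
               y_um = tr@positions[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Link per-frame detections into trajectories
#'
#' Greedy globally-nearest-neighbour linking, a documented stand-in for the
#' commercial particle tracker used with low-density migration movies. Per
#' frame, all (open track end, detection) pairs within `maxDisp` are sorted
#' by ascending distance (ties broken by lower detection index, then lower
#' track index) and accepted greedily, each end and each detection used at
#' most once. Unmatched detections open new tracks; tracks unmatched in a
#' frame are closed — there is no gap closing and no merge/split handling.
#' Tracks shorter than `minTrackLen` frames are discarded.
#'
#' @param detections data.frame with columns `frame` (integer), `time_s`,
#'   `x_um`, `y_um`; frames may be empty (missing indices between min and
#'   max close all open tracks).
#' @param maxDisp numeric(1) > 0, maximum per-frame displacement in um. The
#'   default 2.5 um is four times the mean 15-s step of a 2.5 um/min cell.
#' @param minTrackLen integer or NULL; NULL keeps tracks spanning at least
#'   80% of the frame range (minimum 2).
#' @param maxGap integer >= 0; number of consecutive frames a track may
#'   survive without a detection. 0 (the default) closes a track the first
#'   frame it goes unmatched. With `maxGap > 0`, a track missing for `g`
#'   frames may reclaim a detection within `(g + 1) * maxDisp` and the
#'   skipped positions are filled by linear interpolation (needed for
#'   realistic missed-detection rates; 0 keeps the strict no-gap contract).
#' @return list of [Trajectory] sorted by cell id (`track_0001`, ...), with
#'   attribute `assignment`: a data.frame mapping every detection row to its
#'   track id before length filtering.
#' @examples
#' es <- simulateExperiment(list(ctl = WalkParams()), nCells = 3,
#'                          nReplicates = 1, seed = 4, originSpread = 200)
#' det <- renderDetections(es, seed = 4)
#' tracks <- linkDetections(det)
#' length(tracks)
#' @export
linkDetections <- function(detections, maxDisp = 2.5, minTrackLen = NULL,
                           maxGap = 0L) {
  stopifnot(is.data.frame(detections), maxDisp > 0, maxGap >= 0)
  need <- c("frame", "time_s", "x_um", "y_um")
  if (!all(need %in% names(detections))) {
    stop("detections must have columns frame, time_s, x_um, y_um")
  }
  if (nrow(detections) == 0L) stop("empty detection list")
  frames <- seq(min(detections$frame), max(detections$frame))
  nFrames <- length(frames)
  if (is.null(minTrackLen)) minTrackLen <- max(2L, ceiling(0.8 * nFrames))
  minTrackLen <- max(2L, as.integer(minTrackLen))
  dt <- if (nFrames > 1) {
    stats::median(diff(sort(unique(detections$time_s)))) } else 1
  byFrame <- split(seq_len(nrow(detections)), detections$frame)

  trackX <- numeric(0); trackY <- numeric(0)  # open track ends
  trackAge <- integer(0)                      # frames since last match
  openId <- integer(0); nTracks <- 0L
  store <- list()   # per track: detection rows and their frames
  assignment <- integer(nrow(detections))

  for (f in frames) {
    rows <- byFrame[[as.character(f)]]
    if (is.null(rows)) rows <- integer(0)
    dx <- detections$x_um[rows]; dy <- detections$y_um[rows]
    usedDet <- logical(length(rows))
    usedTrk <- logical(length(openId))
    if (length(rows) && length(openId)) {
      d2 <- outer(trackX, dx, "-")^2 + outer(trackY, dy, "-")^2
      lim2 <- ((trackAge + 1) * maxDisp)^2
      cand <- which(d2 <= lim2, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d2[cand], cand[, 2], cand[, 1])
        for (ci in ord) {
          ti <- cand[ci, 1]; di <- cand[ci, 2]
          if (!usedTrk[ti] && !usedDet[di]) {
            usedTrk[ti] <- TRUE; usedDet[di] <- TRUE
            id <- openId[ti]
            store[[id]]$rows <- c(store[[id]]$rows, rows[di])
            store[[id]]$frames <- c(store[[id]]$frames, f)
            assignment[rows[di]] <- id
            trackX[ti] <- dx[di]; trackY[ti] <- dy[di]
          }
        }
      }
    }
    # age unmatched tracks; close those beyond the gap allowance
    trackAge <- ifelse(usedTrk, 0L, trackAge + 1L)
    keep <- trackAge <= maxGap
    trackX <- trackX[keep]; trackY <- trackY[keep]
    trackAge <- trackAge[keep]; openId <- openId[keep]
    # unmatched detections open new tracks
    for (di in which(!usedDet)) {
      nTracks <- nTracks + 1L
      store[[nTracks]] <- list(rows = rows[di], frames = f)
      assignment[rows[di]] <- nTracks
      openId <- c(openId, nTracks)
      trackX <- c(trackX, dx[di]); trackY <- c(trackY, dy[di])
      trackAge <- c(trackAge, 0L)
    }
  }

  out <- list()
  for (id in seq_len(nTracks)) {
    ix <- store[[id]]$rows
    fr <- store[[id]]$frames
    if (length(ix) < minTrackLen) next
    full <- seq(fr[1], fr[length(fr)])
    x <- detections$x_um[ix]; y <- detections$y_um[ix]
    if (length(full) > length(fr)) {
      # fill gap-closed frames by linear interpolation
      x <- stats::approx(fr, x, xout = full)$y
      y <- stats::approx(fr, y, xout = full)$y
      times <- detections$time_s[ix][1] + (full - fr[1]) * dt
    } else {
      times <- detections$time_s[ix]
    }
    out[[length(out) + 1L]] <- Trajectory(
      sprintf("track_%04d", id), times = times,
      positions = cbind(x, y), condition = "tracked", replicate = "R1")
  }
  out <- out[order(vapply(out, cellId, character(1)))]
  attr(out, "assignment") <- data.frame(
    row = seq_len(nrow(detections)), frame = detections$frame,
    track = assignment)
  attr(out, "dt_s") <- dt
  out
}
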