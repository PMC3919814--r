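#' Simulate one cell trajectory as a biased persistent random walk
#'
#' The heading is updated each step by a fraction `biasStrength` of the
#' angular error to the target direction, plus wrapped Gaussian noise:
#' `theta <- theta + biasStrength * wrap(thetaTarget - theta) + eps`,
#' `eps ~ N(0, turnSd^2)`. With `targetMode = "none"` the correction term is
#' omitted (pure persistent random walk). The step length is
#' `meanSpeed * dt * (1 + stepCv * z)` truncated at zero, `z ~ N(0, 1)`.
#' For `targetMode = "point_source"` the target direction is recomputed each
#' step towards the source, with constant correction strength (no gradient
#' decay). The walk is deterministic given `params@seed`.
#'
#' @param params a [WalkParams] object.
#' @param origin numeric(2), starting position in um.
#' @param cellId,condition,replicate labels for the returned [Trajectory].
#' @return A [Trajectory] with `nSteps + 1` positions at times
#'   `0, dt, ..., nSteps * dt` seconds.
#' @examples
#' tr <- simulateTrajectory(WalkParams(turnSd = 0, stepCv = 0,
#'                                     initHeading = 0, nSteps = 10L,
#'                                     meanSpeed = 3, dt = 60))
#' netXDisplacement(tr)  # 30 um straight along +x
#' @seealso [simulateExperiment()] for whole studies.
#' @export
simulateTrajectory <- function(params, origin = c(0, 0),
                               cellId = "cell_1", condition = "unspecified",
                               replicate = "R1") {
  validObject(params)
  stopifnot(length(origin) == 2, all(is.finite(origin)))
  n <- params@nSteps
  stepMean <- params@meanSpeed * params@dt / 60 # um per frame
  pos <- matrix(NA_real_, n + 1L, 2L)
  pos[1L, ] <- origin

  withSeed(params@seed, {
    theta <- if (is.na(params@initHeading)) {
      stats::runif(1, -pi, pi)
    } else {
      params@initHeading
    }
    for (i in seq_len(n)) {
      if (params@targetMode != "none" && params@biasStrength > 0) {
        tdir <- if (params@targetMode == "fixed_direction") {
          atan2(params@target[2], params@target[1])
        } else {
          atan2(params@target[2] - pos[i, 2], params@target[1] - pos[i, 1])
        }
        theta <- theta + params@biasStrength * wrapAngle(tdir - theta)
      }
      theta <- wrapAngle(theta + stats::rnorm(1, 0, params@turnSd))
      len <- stepMean
      if (params@stepCv > 0) {
        len <- max(0, stepMean * (1 + params@stepCv * stats::rnorm(1)))
      }
      pos[i + 1L, ] <- pos[i, ] + len * c(cos(theta), sin(theta))
    }
  })

  Trajectory(cellId, times = params@dt * (0:n), positions = pos,
             condition = condition, replicate = replicate)
}

# evaluate expr under a local RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulate a multi-condition, multi-replicate migration study
#'
#' Emulates the experimental design of the rheotaxis assay: for each
#' condition, `nReplicates` independent replicate experiments of `nCells`
#' tracked cells. Replicate `r` and cell `c` of condition `k` use the
#' deterministic substream `childSeed(seed, k, r, c)`, so the same seed
#' always reproduces the identical study and any replicate can be
#' regenerated alone. Defaults elsewhere give 15 cells imaged every 15 s
#' for 10 min, 5 replicates per condition.
#'
#' @param paramsByCondition named list of [WalkParams], one per condition;
#'   names are the condition labels and must be unique.
#' @param nCells integer, cells per replicate (>= 1).
#' @param nReplicates integer, replicate experiments per condition (>= 1).
#' @param seed integer(1), top-level seed.
#' @param originSpread numeric(1), SD in um of the Gaussian scatter of
#'   starting positions around the field centre (0 starts all cells at the
#'   origin).
#' @return An [ExperimentSet]; trajectories carry condition and replicate
#'   labels, metadata records `dt_s`, `n_steps` and the seed.
#' @examples
#' ps <- list(flow = WalkParams(biasStrength = 0.3,
#'                              targetMode = "fixed_direction"),
#'            noflow = WalkParams())
#' es <- simulateExperiment(ps, nCells = 15, nReplicates = 5, seed = 7)
#' es
#' @export
simulateExperiment <- function(paramsByCondition, nCells = 15L,
                               nReplicates = 5L, seed = 1L,
                               originSpread = 50) {
  stopifnot(is.list(paramsByCondition), length(paramsByCondition) >= 1,
            nCells >= 1, nReplicates >= 1)
  labs <- names(paramsByCondition)
  if (is.null(labs) || any(labs == "")) {
    stop("paramsByCondition must be a fully named list of WalkParams")
  }
  if (anyDuplicated(labs)) stop("duplicate condition labels")
  trajs <- vector("list", length(labs) * nReplicates * nCells)
  idx <- 0L
  for (k in seq_along(labs)) {
    base <- paramsByCondition[[k]]
    validObject(base)
    for (r in seq_len(nReplicates)) {
      for (cc in seq_len(nCells)) {
        p <- base
        p@seed <- childSeed(seed, k, r, cc)
        origin <- if (originSpread > 0) {
          withSeed(childSeed(seed, k, r, cc, 999L),
                   stats::rnorm(2, 0, originSpread))
        } else c(0, 0)
        idx <- idx + 1L
        trajs[[idx]] <- simulateTrajectory(
          p, origin = origin,
          cellId = sprintf("%s_r%02d_c%03d", labs[k], r, cc),
          condition = labs[k], replicate = sprintf("R%d", r))
      }
    }
  }
  ExperimentSet(trajs, metadata = list(
    dt_s = paramsByCondition[[1]]@dt,
    n_steps = paramsByCondition[[1]]@nSteps,
    n_cells = as.integer(nCells), n_replicates = as.integer(nReplicates),
    seed = as.integer(seed)))
}

#' Degrade trajectories into per-frame detections
#'
#' Emits each true position with probability `1 - missRate`, jittered by
#' isotropic Gaussian localization noise; ground-truth cell ids are kept so
#' the detection linker can be scored against truth. All trajectories must
#' share the same frame times.
#'
#' @param x an [ExperimentSet] or list of [Trajectory] objects.
#' @param localizationSd numeric(1), localization noise SD in um (>= 0).
#' @param missRate numeric(1) in [0, 1), per-detection drop probability.
#' @param seed integer(1).
#' @return data.frame with columns `frame` (0-based, consecutive), `time_s`,
#'   `x_um`, `y_um` and `cell_id` (ground truth).
#' @examples
#' es <- simulateExperiment(list(ctl = WalkParams()), nCells = 2,
#'                          nReplicates = 1, seed = 3)
#' det <- renderDetections(es, localizationSd = 0.2, missRate = 0.05,
#'                         seed = 3)
#' head(det)
#' @export
renderDetections <- function(x, localizationSd = 0, missRate = 0, seed = 1L) {
  trajs <- if (is(x, "ExperimentSet")) trajectories(x) else x
  stopifnot(length(trajs) >= 1, localizationSd >= 0)
  if (missRate < 0 || missRate >= 1) {
    stop("missRate must lie in [0, 1)")
  }
  times <- trajs[[1]]@times
  for (tr in trajs) {
    if (length(tr@times) != length(times) ||
        max(abs(tr@times - times)) > 1e-6) {
      stop("all trajectories must share identical frame times")
    }
  }
  nF <- length(times)
  out <- withSeed(seed, {
    rows <- vector("list", length(trajs))
    for (j in seq_along(trajs)) {
      tr <- trajs[[j]]
      keep <- stats::runif(nF) >= missRate
      nk <- sum(keep)
      xy <- tr@positions[keep, , drop = FALSE]
      if (nk > 0 && localizationSd > 0) {
        xy <- xy + matrix(stats::rnorm(2 * nk, 0, localizationSd), nk, 2)
      }
      rows[[j]] <- data.frame(frame = which(keep) - 1L,
                              time_s = times[keep],
                              x_um = xy[, 1], y_um = xy[, 2],
                              cell_id = rep(tr@cellId, nk))
    }
    do.call(rbind, rows)
  })
  out <- out[order(out$frame, out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
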