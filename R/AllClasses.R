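#' @import methods
NULL

## ---------------------------------------------------------------------------
## Trajectory
## ---------------------------------------------------------------------------

#' Trajectory: one cell's time-ordered positions
#'
#' A `Trajectory` holds the path of a single tracked cell: positions in
#' micrometres sampled at a uniform frame interval. It is the atom on which
#' all motility metrics ([netXDisplacement()], [pathLength()],
#' [migrationSpeed()], [persistence()]) operate.
#'
#' @slot cellId character(1), cell identifier.
#' @slot condition character(1), experimental condition label
#'   (e.g. genotype x flow).
#' @slot replicate character(1), replicate experiment identifier.
#' @slot times numeric, acquisition times in seconds; strictly increasing
#'   with constant spacing (1e-6 relative tolerance).
#' @slot positions numeric matrix with columns `x`, `y` in micrometres,
#'   one row per frame; at least two rows.
#'
#' @param cellId,condition,replicate identity labels.
#' @param times numeric vector of times in seconds.
#' @param positions two-column numeric matrix (x, y) in micrometres.
#'
#' @return A `Trajectory` object.
#' @examples
#' tr <- Trajectory("c1", times = c(0, 15, 30),
#'                  positions = cbind(c(0, 1, 2), c(0, 0, 1)))
#' pathLength(tr)
#' @export Trajectory
#' @exportClass Trajectory
#' @aliases Trajectory-class
setClass("Trajectory",
  representation(
    cellId = "character",
    condition = "character",
    replicate = "character",
    times = "numeric",
    positions = "matrix"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character(0)
  n <- nrow(object@positions)
  if (length(object@cellId) != 1L) msg <- c(msg, "cellId must be length 1")
  if (n < 2L) {
    msg <- c(msg, sprintf("trajectory '%s' has fewer than 2 positions",
                          object@cellId))
  }
  if (ncol(object@positions) != 2L) {
    msg <- c(msg, "positions must have two columns (x, y)")
  }
  if (length(object@times) != n) {
    msg <- c(msg, "times and positions lengths differ")
  }
  if (!all(is.finite(object@positions))) {
    msg <- c(msg, sprintf("non-finite coordinates in trajectory '%s'",
                          object@cellId))
  }
  if (n >= 2L && length(object@times) == n) {
    dt <- diff(object@times)
    if (any(dt <= 0)) {
      msg <- c(msg, sprintf("times not strictly increasing for '%s'",
                            object@cellId))
    } else if (max(abs(dt - dt[1])) > 1e-6 * abs(dt[1])) {
      msg <- c(msg, sprintf("non-uniform frame interval for cell '%s'",
                            object@cellId))
    }
  }
  if (length(msg)) msg else TRUE
})

Trajectory <- function(cellId, times, positions,
                       condition = "unspecified", replicate = "R1") {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y")
  new("Trajectory", cellId = as.character(cellId),
      condition = as.character(condition),
      replicate = as.character(replicate),
      times = as.numeric(times), positions = positions)
}

## ---------------------------------------------------------------------------
## ExperimentSet
## ---------------------------------------------------------------------------

#' ExperimentSet: trajectories grouped by condition and replicate
#'
#' Container for a migration study: a list of [Trajectory] objects plus the
#' registry of conditions and replicate experiments. Replicate experiments
#' are the sampling units of the study's statistics (the `n` of figure
#' legends), so the registry is validated: every trajectory's condition and
#' replicate label must be registered.
#'
#' @slot trajectories list of [Trajectory] objects.
#' @slot conditions character, condition labels in display order.
#' @slot replicates named list; for each condition, the character vector of
#'   replicate identifiers.
#' @slot metadata list; free-form (frame interval `dt_s`, duration, seed...).
#'
#' @param trajectories list of [Trajectory] objects.
#' @param metadata optional list of metadata.
#'
#' @return An `ExperimentSet`.
#' @seealso [simulateExperiment()], [readTrajectories()], [cellMetrics()]
#' @export ExperimentSet
#' @exportClass ExperimentSet
#' @aliases ExperimentSet-class
setClass("ExperimentSet",
  representation(
    trajectories = "list",
    conditions = "character",
    replicates = "list",
    metadata = "list"
  )
)

setValidity("ExperimentSet", function(object) {
  msg <- character(0)
  for (tr in object@trajectories) {
    if (!is(tr, "Trajectory")) {
      msg <- c(msg, "all elements of trajectories must be Trajectory objects")
      break
    }
    if (!(tr@condition %in% object@conditions)) {
      msg <- c(msg, sprintf("condition '%s' of cell '%s' not registered",
                            tr@condition, tr@cellId))
    } else if (!(tr@replicate %in% object@replicates[[tr@condition]])) {
      msg <- c(msg, sprintf("replicate '%s' of cell '%s' not registered",
                            tr@replicate, tr@cellId))
    }
  }
  if (anyDuplicated(object@conditions)) {
    msg <- c(msg, "duplicate condition labels")
  }
  if (length(msg)) unique(msg) else TRUE
})

ExperimentSet <- function(trajectories, metadata = list()) {
  conds <- unique(vapply(trajectories, slot, character(1), "condition"))
  reps <- lapply(conds, function(cc) {
    unique(vapply(Filter(function(tr) tr@condition == cc, trajectories),
                  slot, character(1), "replicate"))
  })
  names(reps) <- conds
  new("ExperimentSet", trajectories = trajectories, conditions = conds,
      replicates = reps, metadata = metadata)
}

## ---------------------------------------------------------------------------
## WalkParams
## ---------------------------------------------------------------------------

#' WalkParams: biased persistent random-walk parameters
#'
#' Parameters of the synthetic motility model: a persistent random walk
#' whose heading is corrected each step by a fraction `biasStrength` of the
#' angular error towards the target (a fixed direction for flow experiments,
#' a point source for micropipette chemotaxis, or none for random motility).
#' Step lengths are `meanSpeed * dt` modulated by truncated multiplicative
#' Gaussian noise. Defaults emulate the acquisition protocol of the
#' rheotaxis assay: 15-s frames for 10 min and a mean random speed of
#' 2.5 um/min.
#'
#' @slot meanSpeed numeric(1), mean speed in um/min (> 0).
#' @slot dt numeric(1), frame interval in seconds (> 0).
#' @slot nSteps integer(1), number of steps; the walk has `nSteps + 1`
#'   positions.
#' @slot turnSd numeric(1), SD of per-step heading noise in radians (>= 0).
#' @slot biasStrength numeric(1) in [0, 1]; fraction of the angular error to
#'   the target direction corrected per step (0 = unbiased walk).
#' @slot targetMode one of `"none"`, `"fixed_direction"`, `"point_source"`.
#' @slot target numeric(2); unit direction vector (fixed_direction) or
#'   source position in um (point_source). The flow convention of the assay
#'   is `c(-1, 0)`: flow from right to left, so oriented cells have
#'   negative net X displacement.
#' @slot stepCv numeric(1) >= 0, coefficient of variation of step length.
#' @slot initHeading numeric(1), initial heading in radians, or `NA` to
#'   draw it uniformly.
#' @slot seed integer(1), RNG seed; walks are deterministic given the seed.
#'
#' @param meanSpeed,dt,nSteps,turnSd,biasStrength,targetMode,target,stepCv,initHeading,seed
#'   see slots.
#' @return A `WalkParams` object.
#' @examples
#' wp <- WalkParams(biasStrength = 0.3, targetMode = "fixed_direction",
#'                  target = c(-1, 0), seed = 1)
#' tr <- simulateTrajectory(wp)
#' netXDisplacement(tr)
#' @export WalkParams
#' @exportClass WalkParams
#' @aliases WalkParams-class
setClass("WalkParams",
  representation(
    meanSpeed = "numeric", dt = "numeric", nSteps = "integer",
    turnSd = "numeric", biasStrength = "numeric", targetMode = "character",
    target = "numeric", stepCv = "numeric", initHeading = "numeric",
    seed = "integer"
  ),
  prototype(
    meanSpeed = 2.5, dt = 15, nSteps = 40L, turnSd = 0.6,
    biasStrength = 0, targetMode = "none", target = c(-1, 0),
    stepCv = 0.3, initHeading = NA_real_, seed = 1L
  )
)

setValidity("WalkParams", function(object) {
  msg <- character(0)
  chk1 <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x)) c(sprintf("%s must be a finite scalar", nm)) else character(0)
  }
  msg <- c(msg, chk1(object@meanSpeed, "meanSpeed"), chk1(object@dt, "dt"),
           chk1(object@turnSd, "turnSd"), chk1(object@biasStrength, "biasStrength"),
           chk1(object@stepCv, "stepCv"))
  if (!length(msg)) {
    if (object@meanSpeed <= 0) msg <- c(msg, "meanSpeed must be > 0")
    if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
    if (object@turnSd < 0) msg <- c(msg, "turnSd must be >= 0")
    if (object@stepCv < 0) msg <- c(msg, "stepCv must be >= 0")
    if (object@biasStrength < 0 || object@biasStrength > 1) {
      msg <- c(msg, "biasStrength must lie in [0, 1]")
    }
  }
  if (object@nSteps < 1L) msg <- c(msg, "nSteps must be >= 1")
  if (!object@targetMode %in% c("none", "fixed_direction", "point_source")) {
    msg <- c(msg, "targetMode must be none, fixed_direction or point_source")
  }
  if (length(object@target) != 2L || !all(is.finite(object@target))) {
    msg <- c(msg, "target must be a finite length-2 vector")
  } else if (object@targetMode == "fixed_direction" &&
             sqrt(sum(object@target^2)) == 0) {
    msg <- c(msg, "fixed_direction target must be a non-zero vector")
  }
  if (length(msg)) msg else TRUE
})

WalkParams <- function(meanSpeed = 2.5, dt = 15, nSteps = 40L, turnSd = 0.6,
                       biasStrength = 0, targetMode = "none",
                       target = c(-1, 0), stepCv = 0.3,
                       initHeading = NA_real_, seed = 1L) {
  new("WalkParams", meanSpeed = as.numeric(meanSpeed), dt = as.numeric(dt),
      nSteps = as.integer(nSteps), turnSd = as.numeric(turnSd),
      biasStrength = as.numeric(biasStrength),
      targetMode = as.character(targetMode), target = as.numeric(target),
      stepCv = as.numeric(stepCv), initHeading = as.numeric(initHeading),
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## PatchSimParams
## ---------------------------------------------------------------------------

#' PatchSimParams: synthetic exocytic-patch image parameters
#'
#' Parameters for the labelled-cell image generator used to test the
#' exocytic-patch scoring pipeline. Cells are rendered as annular membrane
#' rings; with probability `p(t)` (see [prevalenceSchedule()]) a cell
#' carries a bright contiguous arc (the exocytic patch) whose intensity is
#' the ring intensity times `patchGain`. Defaults emulate the constitutive
#' wild-type prevalence of about 4.1% of cells with a patch and a transient
#' two-fold rise peaking 2 minutes after a calcium shift.
#'
#' @slot nCells integer(1), cells per image.
#' @slot basePrevalence numeric(1) in [0, 1]; constitutive patch fraction p0.
#' @slot foldPeak numeric(1) >= 1; peak fold-change A of the schedule
#'   (A = 1 gives the flat, knockout-like schedule).
#' @slot tPeak,peakWidth numeric(1), peak time and Gaussian width, minutes.
#' @slot timepoints numeric, minutes after the calcium shift.
#' @slot cellRadius numeric(1), um.
#' @slot membraneIntensity numeric(1), ring intensity on the [0, 1] image
#'   scale.
#' @slot patchGain numeric(1) > 1, patch/ring intensity ratio.
#' @slot patchArc numeric(1) in (0, 360), patch arc in degrees.
#' @slot noiseSd numeric(1), Gaussian pixel noise SD (image scale).
#' @slot pixelSize numeric(1), um per pixel.
#' @slot ringWidth numeric(1), membrane ring thickness, um.
#' @slot fieldSize numeric(1), image side in um; `NA` picks a side that
#'   keeps the rejection-sampling density comfortable.
#' @slot seed integer(1), RNG seed.
#'
#' @param nCells,basePrevalence,foldPeak,tPeak,peakWidth,timepoints,cellRadius,membraneIntensity,patchGain,patchArc,noiseSd,pixelSize,ringWidth,fieldSize,seed
#'   see slots.
#' @return A `PatchSimParams` object.
#' @export PatchSimParams
#' @exportClass PatchSimParams
#' @aliases PatchSimParams-class
setClass("PatchSimParams",
  representation(
    nCells = "integer", basePrevalence = "numeric", foldPeak = "numeric",
    tPeak = "numeric", peakWidth = "numeric", timepoints = "numeric",
    cellRadius = "numeric", membraneIntensity = "numeric",
    patchGain = "numeric", patchArc = "numeric", noiseSd = "numeric",
    pixelSize = "numeric", ringWidth = "numeric", fieldSize = "numeric",
    seed = "integer"
  ),
  prototype(
    nCells = 500L, basePrevalence = 0.041, foldPeak = 2, tPeak = 2,
    peakWidth = 1, timepoints = c(0, 1, 2, 4, 8), cellRadius = 5,
    membraneIntensity = 0.3, patchGain = 3, patchArc = 60, noiseSd = 0.03,
    pixelSize = 0.4, ringWidth = 2, fieldSize = NA_real_, seed = 1L
  )
)

setValidity("PatchSimParams", function(object) {
  msg <- character(0)
  if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
  if (object@basePrevalence < 0 || object@basePrevalence > 1) {
    msg <- c(msg, "basePrevalence must lie in [0, 1]")
  }
  if (object@foldPeak < 1) msg <- c(msg, "foldPeak must be >= 1")
  if (object@foldPeak * object@basePrevalence > 1) {
    msg <- c(msg, "prevalence schedule exceeds 1 at its peak")
  }
  if (object@patchArc <= 0 || object@patchArc >= 360) {
    msg <- c(msg, "patchArc must lie in (0, 360)")
  }
  if (object@peakWidth <= 0) msg <- c(msg, "peakWidth must be > 0")
  if (any(object@timepoints < 0)) msg <- c(msg, "timepoints must be >= 0")
  if (object@cellRadius <= 0 || object@pixelSize <= 0 ||
      object@ringWidth <= 0 || object@membraneIntensity <= 0) {
    msg <- c(msg, "geometry and intensity parameters must be > 0")
  }
  if (object@patchGain < 1) msg <- c(msg, "patchGain must be >= 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

PatchSimParams <- function(nCells = 500L, basePrevalence = 0.041,
                           foldPeak = 2, tPeak = 2, peakWidth = 1,
                           timepoints = c(0, 1, 2, 4, 8), cellRadius = 5,
                           membraneIntensity = 0.3, patchGain = 3,
                           patchArc = 60, noiseSd = 0.03, pixelSize = 0.4,
                           ringWidth = 2, fieldSize = NA_real_,
                           seed = 1L) {
  new("PatchSimParams", nCells = as.integer(nCells),
      basePrevalence = as.numeric(basePrevalence),
      foldPeak = as.numeric(foldPeak), tPeak = as.numeric(tPeak),
      peakWidth = as.numeric(peakWidth), timepoints = as.numeric(timepoints),
      cellRadius = as.numeric(cellRadius),
      membraneIntensity = as.numeric(membraneIntensity),
      patchGain = as.numeric(patchGain), patchArc = as.numeric(patchArc),
      noiseSd = as.numeric(noiseSd), pixelSize = as.numeric(pixelSize),
      ringWidth = as.numeric(ringWidth), fieldSize = as.numeric(fieldSize),
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## PatchImageSet
## ---------------------------------------------------------------------------

#' PatchImageSet: rendered labelled-cell images plus ground truth
#'
#' One synthetic image per timepoint of a calcium-shift experiment, with a
#' ground-truth table of per-cell patch status. Images are numeric matrices
#' on the [0, 1] scale indexed `[x, y]` (EBImage convention); the continuous
#' coordinate origin is the centre of the top-left pixel, x rightward,
#' y downward.
#'
#' @slot images named list of numeric matrices, one per timepoint, named
#'   `t<minutes>`.
#' @slot truth data.frame with columns `cell_id`, `time_min`, `x_um`,
#'   `y_um`, `has_patch`.
#' @slot params the generating [PatchSimParams].
#' @slot replicate character(1), replicate label.
#'
#' @seealso [renderPatchImages()], [scorePatchImages()]
#' @export
#' @aliases PatchImageSet-class
setClass("PatchImageSet",
  representation(images = "list", truth = "data.frame",
                 params = "PatchSimParams", replicate = "character")
)

setValidity("PatchImageSet", function(object) {
  msg <- character(0)
  need <- c("cell_id", "time_min", "x_um", "y_um", "has_patch")
  if (!all(need %in% names(object@truth))) {
    msg <- c(msg, "truth table must have columns cell_id, time_min, x_um, y_um, has_patch")
  }
  if (length(object@images) &&
      is.null(names(object@images))) {
    msg <- c(msg, "images must be named t<minutes>")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ChamberSpec
## ---------------------------------------------------------------------------

#' ChamberSpec: parallel-plate flow-chamber geometry and fluid
#'
#' Geometry and fluid parameters of a parallel-plate laminar flow chamber,
#' in the units in which such chambers are usually specified. The wall
#' shear stress follows from [shearStress()] as sigma = 6 D eta / (w h^2)
#' after SI conversion. Defaults are the operating point of the rheotaxis
#' assay: 14 ml/min of aqueous buffer (0.001 Pa s) through a 250-um-high,
#' 5.5-mm-wide chamber, i.e. a wall shear stress of about 4 Pa.
#'
#' @slot flowRate numeric(1), volumetric flow rate D in ml/min.
#' @slot viscosity numeric(1), dynamic viscosity eta in Pa s.
#' @slot height numeric(1), chamber height h in um.
#' @slot width numeric(1), chamber width w in mm.
#'
#' @param flowRate,viscosity,height,width see slots.
#' @return A `ChamberSpec`.
#' @examples
#' shearStress(ChamberSpec())  # ~4.07 Pa
#' @export ChamberSpec
#' @exportClass ChamberSpec
#' @aliases ChamberSpec-class
setClass("ChamberSpec",
  representation(flowRate = "numeric", viscosity = "numeric",
                 height = "numeric", width = "numeric"),
  prototype(flowRate = 14, viscosity = 0.001, height = 250, width = 5.5)
)

setValidity("ChamberSpec", function(object) {
  vals <- c(flowRate = object@flowRate, viscosity = object@viscosity,
            height = object@height, width = object@width)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    "flowRate, viscosity, height and width must all be finite and > 0"
  } else TRUE
})

ChamberSpec <- function(flowRate = 14, viscosity = 0.001, height = 250,
                        width = 5.5) {
  obj <- new("ChamberSpec", flowRate = as.numeric(flowRate),
             viscosity = as.numeric(viscosity), height = as.numeric(height),
             width = as.numeric(width))
  # parallel-plate formula assumes h << w
  if (obj@height * 1e-3 / obj@width > 0.2) {
    warning("chamber height is not small relative to width; ",
            "parallel-plate shear-stress formula may be inaccurate")
  }
  obj
}
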