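#' Accessors for rheotax objects
#'
#' Slot accessors for [Trajectory], [ExperimentSet] and [PatchImageSet]
#' objects; user code should use these rather than `@`.
#'
#' @param x a rheotax object.
#' @return The corresponding slot value: `trajectories()` a list of
#'   [Trajectory]; `conditions()` a character vector; `replicates()` a named
#'   list of replicate labels per condition; `positions()` a two-column
#'   matrix in um; `frameTimes()` times in seconds; `truthTable()` and
#'   `images()` the ground truth and image list of a [PatchImageSet].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("trajectories", "ExperimentSet", function(x) x@trajectories)

#' @rdname accessors
#' @export
setMethod("conditions", "ExperimentSet", function(x) x@conditions)

#' @rdname accessors
#' @export
setMethod("replicates", "ExperimentSet", function(x) x@replicates)

#' @rdname accessors
#' @export
setMethod("cellId", "Trajectory", function(x) x@cellId)

#' @rdname accessors
#' @export
setMethod("positions", "Trajectory", function(x) x@positions)

#' @rdname accessors
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("conditions", "Trajectory", function(x) x@condition)

#' @rdname accessors
#' @export
setMethod("replicates", "Trajectory", function(x) x@replicate)

#' @rdname accessors
#' @export
setMethod("truthTable", "PatchImageSet", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("images", "PatchImageSet", function(x) x@images)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory '%s' (%s / %s): %d frames, dt = %g s\n",
              object@cellId, object@condition, object@replicate,
              nrow(object@positions),
              if (length(object@times) > 1) diff(object@times)[1] else NA))
})

setMethod("show", "ExperimentSet", function(object) {
  cat(sprintf("ExperimentSet: %d trajectories, %d condition(s)\n",
              length(object@trajectories), length(object@conditions)))
  for (cc in object@conditions) {
    n <- sum(vapply(object@trajectories,
                    function(tr) tr@condition == cc, logical(1)))
    cat(sprintf("  %s: %d cells in %d replicate(s)\n", cc, n,
                length(object@replicates[[cc]])))
  }
})

setMethod("show", "ChamberSpec", function(object) {
  cat(sprintf(paste0("ChamberSpec: D = %g ml/min, eta = %g Pa.s, ",
                     "h = %g um, w = %g mm\n  wall shear stress = %.3f Pa ",
                     "(~%d Pa)\n"),
              object@flowRate, object@viscosity, object@height, object@width,
              shearStress(object), round(shearStress(object))))
})

setMethod("show", "PatchImageSet", function(object) {
  cat(sprintf("PatchImageSet (replicate %s): %d timepoint(s), %d cells each\n",
              object@replicate, length(object@images), object@params@nCells))
})

setMethod("show", "WalkParams", function(object) {
  cat(sprintf(paste0("WalkParams: %g um/min, dt = %g s, %d steps, turnSd = ",
                     "%g rad,\n  bias = %g (%s), stepCv = %g, seed = %d\n"),
              object@meanSpeed, object@dt, object@nSteps, object@turnSd,
              object@biasStrength, object@targetMode, object@stepCv,
              object@seed))
})
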