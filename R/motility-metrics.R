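#' Per-cell motility metrics
#'
#' The rheotaxis statistics of the migration assay, each defined on one
#' [Trajectory] (or a bare two-column position matrix, in which case
#' `migrationSpeed()` needs `times`):
#' \describe{
#'   \item{`netXDisplacement` (delta x, um)}{signed net displacement along
#'     the flow axis: the sum of all per-step x displacements, equal to
#'     `x_final - x_initial`. Negative values mean movement with the assay's
#'     right-to-left flow. Both forms are computed and asserted equal,
#'     guarding against non-finite steps.}
#'   \item{`pathLength` (um)}{total distance travelled, the sum of Euclidean
#'     step lengths.}
#'   \item{`netDistance` (um)}{Euclidean distance from first to last
#'     position.}
#'   \item{`migrationSpeed` (um/min)}{total distance divided by total time.}
#'   \item{`persistence` (dimensionless)}{net distance divided by total
#'     distance; 1 for straight motion, towards 0 for wandering. `NA` with a
#'     warning for a stationary cell (zero path length); such cells are
#'     excluded from aggregation by [cellMetrics()].}
#' }
#'
#' @param x a [Trajectory] or a numeric matrix of positions (columns x, y).
#' @param times numeric, times in seconds (matrix method of
#'   `migrationSpeed` only).
#' @param ... unused.
#' @return numeric(1) per trajectory.
#' @examples
#' tr <- Trajectory("c1", times = c(0, 60, 120),
#'                  positions = rbind(c(0, 0), c(3, 0), c(3, 4)))
#' netXDisplacement(tr)  # 3
#' pathLength(tr)        # 7
#' persistence(tr)       # 5/7
#' @name trajectory-metrics
NULL

#' @rdname trajectory-metrics
#' @export
setMethod("netXDisplacement", "matrix", function(x, ...) {
  dxs <- diff(x[, 1])
  bySum <- sum(dxs)
  byEnds <- x[nrow(x), 1] - x[1, 1]
  if (!isTRUE(all.equal(bySum, byEnds, tolerance = 1e-9,
                        check.attributes = FALSE))) {
    stop("inconsistent delta-x (non-finite step?): sum of steps ", bySum,
         " vs endpoint difference ", byEnds)
  }
  unname(byEnds)
})

#' @rdname trajectory-metrics
#' @export
setMethod("netXDisplacement", "Trajectory",
          function(x, ...) netXDisplacement(x@positions))

#' @rdname trajectory-metrics
#' @export
setMethod("pathLength", "matrix", function(x, ...) {
  sum(sqrt(diff(x[, 1])^2 + diff(x[, 2])^2))
})

#' @rdname trajectory-metrics
#' @export
setMethod("pathLength", "Trajectory", function(x, ...) pathLength(x@positions))

#' @rdname trajectory-metrics
#' @export
setMethod("netDistance", "matrix", function(x, ...) {
  n <- nrow(x)
  unname(sqrt((x[n, 1] - x[1, 1])^2 + (x[n, 2] - x[1, 2])^2))
})

#' @rdname trajectory-metrics
#' @export
setMethod("netDistance", "Trajectory",
          function(x, ...) netDistance(x@positions))

#' @rdname trajectory-metrics
#' @export
setMethod("migrationSpeed", "Trajectory", function(x, ...) {
  migrationSpeed(x@positions, times = x@times)
})

#' @rdname trajectory-metrics
#' @export
setMethod("migrationSpeed", "matrix", function(x, times, ...) {
  total <- times[length(times)] - times[1]
  if (total <= 0) stop("zero or negative total time")
  pathLength(x) / (total / 60)
})

#' @rdname trajectory-metrics
#' @export
setMethod("persistence", "matrix", function(x, ...) {
  pl <- pathLength(x)
  if (pl == 0) {
    warning("stationary cell: persistence undefined, returning NA")
    return(NA_real_)
  }
  netDistance(x) / pl
})

#' @rdname trajectory-metrics
#' @export
setMethod("persistence", "Trajectory", function(x, ...) {
  pl <- pathLength(x)
  if (pl == 0) {
    warning("stationary cell '", x@cellId,
            "': persistence undefined, returning NA")
    return(NA_real_)
  }
  netDistance(x) / pl
})

#' Per-cell metric table for a study
#'
#' Computes every motility metric for every trajectory of an
#' [ExperimentSet]. Stationary cells (zero path length) get `excluded =
#' TRUE` and `NA` persistence; downstream aggregation drops them and
#' reports the count.
#'
#' @param set an [ExperimentSet].
#' @return data.frame with one row per cell: `cell_id`, `condition`,
#'   `replicate`, `delta_x`, `path_length`, `net_distance`, `speed`,
#'   `persistence`, `excluded`.
#' @seealso [summarizeReplicates()]
#' @export
cellMetrics <- function(set) {
  stopifnot(is(set, "ExperimentSet"))
  trajs <- trajectories(set)
  n <- length(trajs)
  out <- data.frame(
    cell_id = vapply(trajs, cellId, character(1)),
    condition = vapply(trajs, slot, character(1), "condition"),
    replicate = vapply(trajs, slot, character(1), "replicate"),
    delta_x = vapply(trajs, netXDisplacement, numeric(1)),
    path_length = vapply(trajs, pathLength, numeric(1)),
    net_distance = vapply(trajs, netDistance, numeric(1)),
    speed = vapply(trajs, migrationSpeed, numeric(1)),
    persistence = rep(NA_real_, n),
    excluded = rep(FALSE, n))
  out$excluded <- out$path_length == 0
  ok <- !out$excluded
  out$persistence[ok] <- out$net_distance[ok] / out$path_length[ok]
  if (any(out$excluded)) {
    warning(sum(out$excluded),
            " stationary cell(s) excluded from aggregation")
  }
  rownames(out) <- NULL
  out
}

#' Replicate-level summaries (the study's sampling units)
#'
#' Averages per-cell metrics within each replicate experiment. Replicate
#' means — not pooled cells — are the sampling units passed to the
#' statistical comparisons, matching the convention that `n` is the number
#' of independent experiments. Warns when a replicate holds fewer than
#' `minCells` included cells (the assay tracks at least 15 cells per
#' experiment).
#'
#' @param set an [ExperimentSet] or a data.frame from [cellMetrics()].
#' @param minCells integer, threshold for the small-replicate warning.
#' @return data.frame with one row per condition x replicate: `n_cells`,
#'   `n_excluded`, and the mean of each per-cell metric.
#' @export
summarizeReplicates <- function(set, minCells = 15L) {
  cm <- if (is.data.frame(set)) set else cellMetrics(set)
  key <- interaction(cm$condition, cm$replicate, drop = TRUE, sep = "\r")
  pieces <- lapply(split(cm, key), function(sub) {
    inc <- sub[!sub$excluded, , drop = FALSE]
    if (nrow(inc) == 0L) {
      stop("all cells excluded in replicate '", sub$replicate[1],
           "' of condition '", sub$condition[1], "'")
    }
    if (nrow(inc) < minCells) {
      warning("replicate '", sub$replicate[1], "' of condition '",
              sub$condition[1], "' has only ", nrow(inc), " included cells")
    }
    data.frame(condition = sub$condition[1], replicate = sub$replicate[1],
               n_cells = nrow(inc), n_excluded = sum(sub$excluded),
               delta_x = mean(inc$delta_x),
               path_length = mean(inc$path_length),
               net_distance = mean(inc$net_distance),
               speed = mean(inc$speed),
               persistence = mean(inc$persistence))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$condition, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flow / no-flow persistence ratio
#'
#' Mean directional persistence under flow divided by the mean persistence
#' of the same strain migrating randomly. Oriented wild-type-like cells
#' roughly double their persistence under flow, so this ratio reads about 2
#' for the responsive phenotype and about 1 for a non-responding one. The
#' figure legend of the source assay words the ratio in the opposite
#' orientation to its running text; this function fixes the orientation as
#' flow over no-flow so that the responsive phenotype reads ~2.
#'
#' @param flow,noflow numeric vectors of per-replicate persistence means.
#' @return numeric(1).
#' @examples
#' persistenceRatio(c(0.6, 0.64), c(0.3, 0.32))  # ~2
#' @export
persistenceRatio <- function(flow, noflow) {
  stopifnot(length(flow) >= 1, length(noflow) >= 1,
            all(is.finite(flow)), all(is.finite(noflow)))
  mean(flow) / mean(noflow)
}

#' Wall shear stress of a parallel-plate flow chamber
#'
#' Evaluates sigma = 6 D eta / (w h^2) after converting the chamber
#' specification to SI units (D: ml/min to m^3/s; h: um to m; w: mm to m).
#' With the default chamber (14 ml/min, 0.001 Pa s, 250 um x 5.5 mm) this is
#' 4.0727... Pa — the assay's nominal "4 Pa" operating point at integer
#' rounding.
#'
#' @param chamber a [ChamberSpec].
#' @param ... unused.
#' @name shearStress
#' @aliases shearStress,ChamberSpec-method
#' @return numeric(1), wall shear stress in Pa (full precision; round for
#'   the nominal operating point).
#' @examples
#' shearStress(ChamberSpec(flowRate = 14, viscosity = 0.001,
#'                         height = 250, width = 5.5))
#' @export
setMethod("shearStress", "ChamberSpec", function(chamber, ...) {
  validObject(chamber)
  D <- chamber@flowRate * 1e-6 / 60   # ml/min -> m^3/s
  h <- chamber@height * 1e-6          # um -> m
  w <- chamber@width * 1e-3           # mm -> m
  6 * D * chamber@viscosity / (w * h^2)
})
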