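#' Net change in distance to a chemoattractant source
#'
#' Micropipette-assay statistic: the final Euclidean distance of the cell
#' to the pipette tip minus its initial distance (delta d, um). Cells moving
#' towards the source show negative values; randomly moving cells average
#' about zero.
#'
#' @param t a [Trajectory].
#' @param source numeric(2), tip position in um.
#' @return numeric(1), signed um.
#' @examples
#' tr <- Trajectory("c1", times = c(0, 20),
#'                  positions = rbind(c(100, 0), c(40, 0)))
#' deltaDistanceToSource(tr, c(0, 0))  # -60
#' @export
deltaDistanceToSource <- function(t, source) {
  stopifnot(is(t, "Trajectory"), length(source) == 2,
            all(is.finite(source)))
  p <- t@positions
  n <- nrow(p)
  dEnd <- sqrt(sum((p[n, ] - source)^2))
  dStart <- sqrt(sum((p[1, ] - source)^2))
  dEnd - dStart
}

#' Directional persistence in a gradient
#'
#' Identical contract to [persistence()] (net distance over total
#' distance), re-exported under the name used in the chemotaxis assay
#' report.
#'
#' @param t a [Trajectory].
#' @return numeric(1) in (0, 1], or NA for a stationary cell.
#' @export
gradientPersistence <- function(t) persistence(t)

#' Displacement of the cell front towards a chemoattractant
#'
#' Agar-spot assay statistic: the population "front" at a timepoint is the
#' `q`-th percentile of cell positions projected onto the source axis
#' (robust to single outlier cells; the assay itself gives no formal
#' definition of the front). Returns `front(t1) - front(t0)` in um along the
#' axis, positive towards the source. The default fixture geometry places
#' the folate well 4 mm from the spot centre.
#'
#' @param cloud0,cloud1 two-column matrices of cell positions (um) at the
#'   two timepoints (typically 0 and 5 h).
#' @param axis numeric(2), direction towards the source (normalized
#'   internally).
#' @param q percentile in (0, 1] defining the front (default 0.95).
#' @return numeric(1), um.
#' @examples
#' set.seed(1)
#' cloud <- matrix(rnorm(80, sd = 100), ncol = 2)
#' frontDisplacement(cloud, cloud + cbind(300, 0), axis = c(1, 0))  # 300
#' @export
frontDisplacement <- function(cloud0, cloud1, axis, q = 0.95) {
  cloud0 <- as.matrix(cloud0); cloud1 <- as.matrix(cloud1)
  if (nrow(cloud0) == 0L || nrow(cloud1) == 0L) {
    stop("empty cell cloud")
  }
  if (nrow(cloud0) < 20L || nrow(cloud1) < 20L) {
    warning("fewer than 20 cells in a cloud; front estimate will be noisy")
  }
  stopifnot(length(axis) == 2, all(is.finite(axis)), any(axis != 0),
            q > 0, q <= 1)
  u <- axis / sqrt(sum(axis^2))
  f0 <- stats::quantile(cloud0 %*% u, q, names = FALSE)
  f1 <- stats::quantile(cloud1 %*% u, q, names = FALSE)
  f1 - f0
}
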