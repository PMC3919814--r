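#' Patch-prevalence schedule after a calcium shift
#'
#' Gaussian-bump prevalence model: starting from the constitutive fraction
#' `p0` of cells bearing an exocytic patch, a sudden rise in extracellular
#' calcium transiently multiplies the prevalence, peaking at `foldPeak * p0`
#' at `tPeak` minutes and relaxing back to `p0`:
#' `p(t) = p0 * (1 + (A - 1) * exp(-(t - tPeak)^2 / (2 * peakWidth^2)))`.
#' `foldPeak = 1` gives the flat, knockout-like schedule. Defaults follow
#' the wild-type phenotype: p0 = 4.1%, two-fold peak at 2 min.
#'
#' @param params a [PatchSimParams].
#' @param t numeric, minutes after the calcium shift (>= 0).
#' @return numeric, prevalence fraction(s) in \[p0, A * p0\].
#' @examples
#' prevalenceSchedule(PatchSimParams(), t = c(0, 2, 8))
#' @export
prevalenceSchedule <- function(params, t) {
  validObject(params)
  stopifnot(all(t >= 0))
  p0 <- params@basePrevalence
  p0 * (1 + (params@foldPeak - 1) *
          exp(-(t - params@tPeak)^2 / (2 * params@peakWidth^2)))
}

#' Draw ground-truth patch status without rendering images
#'
#' Samples per-cell patch status at each timepoint (and replicate) from the
#' prevalence schedule. This is the image generator's sampling layer alone,
#' useful for statistical properties of the time course at scales where
#' rendering every image would be wasteful.
#'
#' @param params a [PatchSimParams].
#' @param nReplicates integer, replicate experiments.
#' @param seed integer(1); replicate r, timepoint i use
#'   `childSeed(seed, r, i)`.
#' @return data.frame with columns `replicate`, `time_min`, `cell_id`,
#'   `has_patch`.
#' @export
simulatePatchTruth <- function(params, nReplicates = 1L, seed = params@seed) {
  validObject(params)
  stopifnot(nReplicates >= 1)
  rows <- list()
  for (r in seq_len(nReplicates)) {
    for (i in seq_along(params@timepoints)) {
      t <- params@timepoints[i]
      p <- prevalenceSchedule(params, t)
      has <- withSeed(childSeed(seed, r, i),
                      stats::runif(params@nCells) < p)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = sprintf("R%d", r), time_min = t,
        cell_id = sprintf("cell_%03d", seq_len(params@nCells)),
        has_patch = has)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# place nCells centres >= minDist apart inside [margin, side - margin]^2 (um)
# by rejection sampling; error if the density is too high to place them.
placeCells <- function(nCells, side, minDist, margin, maxTries = 5000L) {
  lo <- margin
  hi <- side - margin
  if (hi <= lo) stop("field too small for the requested cell radius")
  xs <- numeric(nCells)
  ys <- numeric(nCells)
  for (i in seq_len(nCells)) {
    placed <- FALSE
    for (k in seq_len(maxTries)) {
      cx <- stats::runif(1, lo, hi)
      cy <- stats::runif(1, lo, hi)
      if (i == 1L || min((xs[seq_len(i - 1L)] - cx)^2 +
                         (ys[seq_len(i - 1L)] - cy)^2) >= minDist^2) {
        xs[i] <- cx; ys[i] <- cy
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("cell density too high: could not place ", nCells,
           " non-overlapping cells in a ", round(side), " um field")
    }
  }
  cbind(x = xs, y = ys)
}

# minimum centre-to-centre distance keeping rendered rings disjoint (um)
minCentreDist <- function(params) {
  2 * (params@cellRadius + params@ringWidth / 2) + 2
}

# default field side (um) giving a comfortable rejection-sampling density
defaultFieldSide <- function(params) {
  ceiling(sqrt(params@nCells * pi * minCentreDist(params)^2 / 0.25))
}

# compute the image tile of one annular ring (plus optional patch arc);
# the caller adds the tile into the image (avoids copying the full image
# per cell). Pixel centres sit at ((i-1)*px, (j-1)*px) um, image indexed
# [x, y].
drawRing <- function(npx, cx, cy, params, patchStart = NA_real_) {
  px <- params@pixelSize
  rOut <- params@cellRadius + params@ringWidth / 2
  rIn <- params@cellRadius - params@ringWidth / 2
  i0 <- max(1L, floor((cx - rOut) / px) + 1L)
  i1 <- min(npx, ceiling((cx + rOut) / px) + 1L)
  j0 <- max(1L, floor((cy - rOut) / px) + 1L)
  j1 <- min(npx, ceiling((cy + rOut) / px) + 1L)
  ii <- i0:i1
  jj <- j0:j1
  dx <- (ii - 1) * px - cx
  dy <- (jj - 1) * px - cy
  rr <- sqrt(outer(dx^2, dy^2, "+"))
  ring <- rr >= rIn & rr <= rOut
  val <- matrix(0, length(ii), length(jj))
  val[ring] <- params@membraneIntensity
  if (!is.na(patchStart)) {
    ang <- (atan2(outer(rep(1, length(dx)), dy), outer(dx, rep(1, length(dy)))) *
              180 / pi) %% 360
    inArc <- ((ang - patchStart) %% 360) <= params@patchArc
    val[ring & inArc] <- params@membraneIntensity * params@patchGain
  }
  list(ii = ii, jj = jj, val = val)
}

#' Render synthetic labelled-cell images with ground truth
#'
#' Renders one single-channel image per timepoint: `nCells` cells placed
#' without overlap by rejection sampling, each drawn as an annular membrane
#' ring of intensity `membraneIntensity`; with probability `p(t)` from
#' [prevalenceSchedule()] a contiguous arc of `patchArc` degrees at a
#' uniform random angle is multiplied by `patchGain` (the exocytic patch).
#' Gaussian pixel noise of SD `noiseSd` is added and the image clipped to
#' \[0, 1\]. Pixel origin is the centre of the top-left pixel, x rightward,
#' y downward.
#'
#' @param params a [PatchSimParams].
#' @param replicate character(1) replicate label; the RNG substream is
#'   derived from `params@seed` and `repIndex`.
#' @param repIndex integer(1), replicate index used for seed derivation.
#' @return A [PatchImageSet]: images named `t<minutes>` plus a truth table
#'   (`cell_id`, `time_min`, `x_um`, `y_um`, `has_patch`).
#' @examples
#' p <- PatchSimParams(nCells = 20L, timepoints = c(0, 2), seed = 5)
#' pis <- renderPatchImages(p)
#' dim(images(pis)[["t0"]])
#' @export
renderPatchImages <- function(params, replicate = "R1", repIndex = 1L) {
  validObject(params)
  side <- if (is.na(params@fieldSize)) defaultFieldSide(params) else
    params@fieldSize
  px <- params@pixelSize
  npx <- ceiling(side / px) + 1L
  margin <- params@cellRadius + params@ringWidth / 2 + 2 * px
  minDist <- minCentreDist(params)
  imgs <- vector("list", length(params@timepoints))
  names(imgs) <- sprintf("t%g", params@timepoints)
  truth <- list()
  for (i in seq_along(params@timepoints)) {
    t <- params@timepoints[i]
    p <- prevalenceSchedule(params, t)
    res <- withSeed(childSeed(params@seed, repIndex, i), {
      centres <- placeCells(params@nCells, side, minDist, margin)
      hasPatch <- stats::runif(params@nCells) < p
      patchStart <- stats::runif(params@nCells, 0, 360)
      img <- matrix(0, npx, npx)
      for (cc in seq_len(params@nCells)) {
        tile <- drawRing(npx, centres[cc, 1], centres[cc, 2], params,
                         patchStart = if (hasPatch[cc]) patchStart[cc]
                                      else NA_real_)
        img[tile$ii, tile$jj] <- img[tile$ii, tile$jj] + tile$val
      }
      if (params@noiseSd > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, params@noiseSd),
                            nrow(img))
      }
      list(img = pmin(pmax(img, 0), 1), centres = centres,
           hasPatch = hasPatch)
    })
    imgs[[i]] <- res$img
    truth[[i]] <- data.frame(
      cell_id = sprintf("cell_%03d", seq_len(params@nCells)),
      time_min = t, x_um = res$centres[, 1], y_um = res$centres[, 2],
      has_patch = res$hasPatch)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  new("PatchImageSet", images = imgs, truth = truth, params = params,
      replicate = as.character(replicate))
}

#' Write / read a PatchImageSet as 16-bit TIFFs plus a truth-table CSV
#'
#' One single-channel 16-bit TIFF per timepoint, named
#' `t<minutes>_rep<label>.tif`, with a sidecar CSV truth table
#' (`cell_id,time_min,x_um,y_um,has_patch`).
#'
#' @param x a [PatchImageSet].
#' @param dir output directory (created if needed).
#' @return `writePatchImages()` the directory, invisibly;
#'   `readPatchImages()` a list with `images` (named list of matrices, [0,1]
#'   scale) and `truth` (data.frame, or NULL when no sidecar is present).
#' @export
writePatchImages <- function(x, dir) {
  stopifnot(is(x, "PatchImageSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rep <- gsub("[^A-Za-z0-9]", "", x@replicate)
  for (nm in names(x@images)) {
    t <- sub("^t", "", nm)
    EBImage::writeImage(EBImage::Image(x@images[[nm]]),
                        file.path(dir, sprintf("t%s_rep%s.tif", t, rep)),
                        type = "tiff", bits.per.sample = 16L)
  }
  utils::write.csv(x@truth,
                   file.path(dir, sprintf("truth_rep%s.csv", rep)),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname writePatchImages
#' @param pattern regular expression with two groups (minutes, replicate)
#'   matching the image file names.
#' @export
readPatchImages <- function(dir, pattern = "^t([0-9.]+)_rep(.+)\\.tif$") {
  files <- list.files(dir, pattern = pattern)
  if (!length(files)) stop("no TIFF images matching the pattern in ", dir)
  t <- as.numeric(sub(pattern, "\\1", files))
  files <- files[order(t)]
  t <- sort(t)
  imgs <- lapply(file.path(dir, files), function(f) {
    EBImage::imageData(EBImage::readImage(f))
  })
  names(imgs) <- sprintf("t%g", t)
  truthFiles <- list.files(dir, pattern = "^truth_rep.*\\.csv$",
                           full.names = TRUE)
  truth <- if (length(truthFiles)) utils::read.csv(truthFiles[1]) else NULL
  list(images = imgs, truth = truth, time_min = t)
}
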