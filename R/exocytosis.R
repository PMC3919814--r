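#' Segment labelled cells in a fluorescence image
#'
#' Global Otsu threshold on a Gaussian-smoothed image, connected-component
#' labelling, and a size filter keeping components within `[0.25, 4]` times
#' the expected cell (membrane-ring) pixel area. Returns centroids in pixel
#' and um coordinates, sorted by centroid, plus each component's pixel
#' indices for profile extraction. Touching cells merge into a single
#' component — a documented limitation of global thresholding; the
#' synthetic generator avoids overlaps by construction.
#'
#' @param image numeric matrix on the [0, 1] scale, indexed `[x, y]`.
#' @param cellAreaPx numeric(1), expected component area in pixels (for the
#'   default ring rendering use [expectedRingAreaPx()]).
#' @param pixelSize numeric(1), um per pixel.
#' @param smoothSigma numeric(1), Gaussian blur sigma in pixels.
#' @param sizeRange numeric(2), multiples of `cellAreaPx` kept.
#' @return list with `centroids` (data.frame `label`, `x_px`, `y_px`,
#'   `x_um`, `y_um`, `area_px`) and `pixels` (list of pixel-index matrices,
#'   columns x, y, 1-based). Empty images yield zero rows, not an error.
#' @examples
#' p <- PatchSimParams(nCells = 5L, timepoints = 0, seed = 9)
#' pis <- renderPatchImages(p)
#' seg <- segmentCells(images(pis)[[1]], expectedRingAreaPx(p),
#'                     pixelSize = p@pixelSize)
#' nrow(seg$centroids)
#' @export
segmentCells <- function(image, cellAreaPx, pixelSize = 1,
                         smoothSigma = 1, sizeRange = c(0.25, 4)) {
  stopifnot(is.matrix(image), cellAreaPx > 0)
  img <- pmin(pmax(image, 0), 1)
  sm <- EBImage::gblur(EBImage::Image(img), sigma = smoothSigma)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  bin <- EBImage::imageData(sm) > thr
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin * 1)))
  nLab <- max(lab)
  if (nLab == 0) {
    return(list(centroids = data.frame(label = integer(0), x_px = numeric(0),
                                       y_px = numeric(0), x_um = numeric(0),
                                       y_um = numeric(0),
                                       area_px = integer(0)),
                pixels = list()))
  }
  idx <- which(lab > 0)
  labv <- lab[idx]
  xs <- ((idx - 1L) %% nrow(lab)) + 1L
  ys <- ((idx - 1L) %/% nrow(lab)) + 1L
  byLab <- split(seq_along(idx), labv)
  area <- lengths(byLab)
  keep <- area >= sizeRange[1] * cellAreaPx & area <= sizeRange[2] * cellAreaPx
  byLab <- byLab[keep]
  cx <- vapply(byLab, function(ii) mean(xs[ii]), numeric(1))
  cy <- vapply(byLab, function(ii) mean(ys[ii]), numeric(1))
  ord <- order(cx, cy)
  byLab <- byLab[ord]
  centroids <- data.frame(label = as.integer(names(byLab)),
                          x_px = cx[ord], y_px = cy[ord],
                          x_um = (cx[ord] - 1) * pixelSize,
                          y_um = (cy[ord] - 1) * pixelSize,
                          area_px = as.integer(lengths(byLab)))
  pixels <- lapply(byLab, function(ii) cbind(x = xs[ii], y = ys[ii]))
  rownames(centroids) <- NULL
  list(centroids = centroids, pixels = pixels)
}

#' Expected membrane-ring area in pixels
#'
#' Pixel count of the rendered annulus for a [PatchSimParams] geometry; the
#' reference area for [segmentCells()]'s size filter.
#'
#' @param params a [PatchSimParams].
#' @return numeric(1), pixels.
#' @export
expectedRingAreaPx <- function(params) {
  rOut <- params@cellRadius + params@ringWidth / 2
  rIn <- params@cellRadius - params@ringWidth / 2
  pi * (rOut^2 - rIn^2) / params@pixelSize^2
}

#' Angular membrane-intensity profile of one cell
#'
#' Mean image intensity in angular bins (default 5 degrees, 72 bins) over
#' the membrane ring band around the cell centroid. The band's radius and
#' half-width are estimated robustly from the annulus-like mask (median and
#' MAD of the mask pixels' radial distances — a global-threshold mask
#' dilates slightly around bright patches, so the band, not the raw mask,
#' defines the profile support). Angles are measured from +x towards +y
#' (downwards in image convention); only relative structure matters for
#' patch detection. Cells whose mask holds fewer than `minPixels` pixels
#' are skipped (returns NULL with a warning).
#'
#' @param image numeric matrix `[x, y]`.
#' @param pixels two-column matrix of 1-based pixel indices (from
#'   [segmentCells()]).
#' @param centroidPx numeric(2), centroid in pixel coordinates.
#' @param binDeg bin width in degrees; must divide 360.
#' @param minPixels minimum mask size.
#' @return numeric vector of `360 / binDeg` bin means (NA for empty bins),
#'   or NULL for a degenerate mask.
#' @export
membraneProfile <- function(image, pixels, centroidPx, binDeg = 5,
                            minPixels = 20L) {
  stopifnot(is.matrix(pixels), ncol(pixels) == 2, 360 %% binDeg == 0)
  if (nrow(pixels) < minPixels) {
    warning("degenerate mask (", nrow(pixels), " px): cell skipped")
    return(NULL)
  }
  # Kasa least-squares circle fit: the plain mask centroid is pulled towards
  # a bright (dilated) patch arc, the fitted centre is not.
  fit <- tryCatch({
    A <- cbind(2 * pixels[, 1], 2 * pixels[, 2], 1)
    sol <- qr.solve(A, pixels[, 1]^2 + pixels[, 2]^2)
    c(sol[1], sol[2])
  }, error = function(e) centroidPx)
  if (any(!is.finite(fit)) ||
      sqrt(sum((fit - centroidPx)^2)) > stats::median(
        sqrt((pixels[, 1] - centroidPx[1])^2 +
             (pixels[, 2] - centroidPx[2])^2))) {
    fit <- centroidPx  # fit wandered: not annulus-like, fall back
  }
  cx <- fit[1]; cy <- fit[2]
  radii <- sqrt((pixels[, 1] - cx)^2 + (pixels[, 2] - cy)^2)
  rMed <- stats::median(radii)
  # central half of the mask's radial extent: strictly interior to the
  # ring, so threshold dilation around bright arcs cannot leak background
  # pixels into the profile
  h <- max(1, stats::median(abs(radii - rMed)))
  ii <- max(1L, floor(cx - rMed - h)):min(nrow(image), ceiling(cx + rMed + h))
  jj <- max(1L, floor(cy - rMed - h)):min(ncol(image), ceiling(cy + rMed + h))
  dx <- ii - cx
  dy <- jj - cy
  rr <- sqrt(outer(dx^2, dy^2, "+"))
  sel <- which(rr >= rMed - h & rr <= rMed + h, arr.ind = TRUE)
  sx <- dx[sel[, 1]]
  sy <- dy[sel[, 2]]
  ang <- (atan2(sy, sx) * 180 / pi) %% 360
  nBins <- 360L %/% as.integer(binDeg)
  bin <- pmin(floor(ang / binDeg) + 1L, nBins)
  vals <- image[cbind(ii[sel[, 1]], jj[sel[, 2]])]
  out <- rep(NA_real_, nBins)
  means <- tapply(vals, bin, mean)
  out[as.integer(names(means))] <- means
  out
}

#' Call an exocytic patch from an angular profile
#'
#' A cell is scored patch-positive when a contiguous circular run of bins,
#' each at least `minContrast` times the median bin intensity, spans at
#' least `minArc` degrees. Runs wrap across 0 degrees. This operationalizes
#' the by-eye scoring of bright p80 membrane microdomains; both thresholds
#' are exposed and characterized by an ROC sweep in the test suite.
#'
#' @param profile numeric vector from [membraneProfile()].
#' @param minContrast numeric(1), intensity threshold as a multiple of the
#'   median bin (default 2.0).
#' @param minArc numeric(1), minimum arc in degrees (default 30).
#' @return list: `patch_present` (logical), `arc_extent` (degrees of the
#'   longest qualifying run, 0 if none), `arc_contrast` (mean run intensity
#'   over the median bin; NA if no hot bins).
#' @examples
#' prof <- rep(1, 72); prof[10:18] <- 3
#' detectPatch(prof)
#' @export
detectPatch <- function(profile, minContrast = 2.0, minArc = 30) {
  stopifnot(is.numeric(profile), length(profile) >= 2)
  binDeg <- 360 / length(profile)
  med <- stats::median(profile, na.rm = TRUE)
  hot <- !is.na(profile) & profile >= minContrast * med
  if (!any(hot)) {
    return(list(patch_present = FALSE, arc_extent = 0,
                arc_contrast = NA_real_))
  }
  if (all(hot)) {
    return(list(patch_present = 360 >= minArc, arc_extent = 360,
                arc_contrast = mean(profile, na.rm = TRUE) / med))
  }
  # longest circular run: double the vector, cap runs at one full turn
  r <- rle(c(hot, hot))
  hotRuns <- which(r$values)
  runLens <- pmin(r$lengths[hotRuns], length(profile))
  ends <- cumsum(r$lengths)
  bi <- hotRuns[which.max(runLens)]
  arcBins <- max(runLens)
  s <- ends[bi] - r$lengths[bi] + 1L
  binIdx <- ((seq(s, length.out = arcBins) - 1L) %% length(profile)) + 1L
  list(patch_present = arcBins * binDeg >= minArc,
       arc_extent = arcBins * binDeg,
       arc_contrast = mean(profile[binIdx], na.rm = TRUE) / med)
}

#' Score every cell of a PatchImageSet
#'
#' Runs the full chain — [segmentCells()], [membraneProfile()],
#' [detectPatch()] — on each timepoint image and returns one patch call per
#' segmented cell.
#'
#' @param x a [PatchImageSet], or a list with elements `images` (named
#'   `t<minutes>`) and optionally `truth` (as from [readPatchImages()]);
#'   when not a PatchImageSet, `params` must be given.
#' @param params [PatchSimParams] describing the rendering geometry (taken
#'   from `x` when it is a PatchImageSet).
#' @param replicate replicate label for the output.
#' @param minContrast,minArc detection thresholds, see [detectPatch()].
#' @param binDeg profile bin width, degrees.
#' @return data.frame: `replicate`, `time_min`, `cell`, `x_um`, `y_um`,
#'   `patch_present`, `arc_extent`, `arc_contrast`.
#' @export
scorePatchImages <- function(x, params = NULL, replicate = NULL,
                             minContrast = 2.0, minArc = 30, binDeg = 5) {
  if (is(x, "PatchImageSet")) {
    imgs <- x@images
    if (is.null(params)) params <- x@params
    if (is.null(replicate)) replicate <- x@replicate
  } else {
    imgs <- x$images
    if (is.null(params)) stop("params required when x is not a PatchImageSet")
    if (is.null(replicate)) replicate <- "R1"
  }
  areaPx <- expectedRingAreaPx(params)
  rows <- list()
  for (nm in names(imgs)) {
    t <- as.numeric(sub("^t", "", nm))
    img <- imgs[[nm]]
    seg <- segmentCells(img, areaPx, pixelSize = params@pixelSize)
    nSeg <- nrow(seg$centroids)
    for (i in seq_len(nSeg)) {
      prof <- membraneProfile(img, seg$pixels[[i]],
                              c(seg$centroids$x_px[i], seg$centroids$y_px[i]),
                              binDeg = binDeg)
      if (is.null(prof)) next
      call <- detectPatch(prof, minContrast = minContrast, minArc = minArc)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = replicate, time_min = t, cell = i,
        x_um = seg$centroids$x_um[i], y_um = seg$centroids$y_um[i],
        patch_present = call$patch_present, arc_extent = call$arc_extent,
        arc_contrast = call$arc_contrast)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Wilson score interval for a binomial proportion
wilsonCI <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lo = max(0, centre - hw), hi = min(1, centre + hw))
}

#' Patch-prevalence time course after a calcium shift
#'
#' Aggregates per-cell patch calls into per-timepoint prevalences with
#' Wilson 95% confidence intervals, and compares each timepoint to the
#' baseline (time 0) with a two-tailed unpaired t-test across replicate
#' prevalences — the replicate experiment, not the cell, is the sampling
#' unit. No multiple-testing correction is applied (a deliberate mirror of
#' the assay's reporting convention; treat the per-timepoint p-values
#' accordingly).
#'
#' @param calls data.frame with columns `time_min`, `replicate` and a
#'   logical patch column (`patch_present` or `has_patch`), e.g. from
#'   [scorePatchImages()] or [simulatePatchTruth()].
#' @param conf confidence level of the Wilson interval.
#' @return data.frame with one row per timepoint: `time_min`, `n_cells`,
#'   `n_patch`, `prevalence`, `ci_lo`, `ci_hi`, `p_vs_t0`, `stars`.
#' @export
prevalenceTimeCourse <- function(calls, conf = 0.95) {
  stopifnot(is.data.frame(calls),
            all(c("time_min", "replicate") %in% names(calls)))
  patchCol <- intersect(c("patch_present", "has_patch"), names(calls))[1]
  if (is.na(patchCol)) stop("no patch status column in calls")
  if (!any(calls$time_min == 0)) {
    stop("time 0 must be present as the baseline")
  }
  times <- sort(unique(calls$time_min))
  repPrev <- function(t) {
    sub <- calls[calls$time_min == t, , drop = FALSE]
    vapply(split(sub[[patchCol]], sub$replicate), mean, numeric(1))
  }
  base <- repPrev(0)
  rows <- lapply(times, function(t) {
    sub <- calls[calls$time_min == t, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0L) stop("timepoint ", t, " has 0 cells")
    k <- sum(sub[[patchCol]])
    ci <- wilsonCI(k, n, conf)
    p <- NA_real_
    if (t != 0 && length(base) >= 2) {
      p <- tTestUnpaired(repPrev(t), base)$p
    }
    data.frame(time_min = t, n_cells = n, n_patch = k, prevalence = k / n,
               ci_lo = ci["lo"], ci_hi = ci["hi"], p_vs_t0 = p,
               stars = pStars(p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
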