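#' Construct a 4D dynamic image volume
#'
#' @param data 4D numeric array indexed (frame, z, y, x), MBq/mL.
#' @param voxelSize numeric(3), voxel edge lengths (z, y, x) in mm.
#' @param schedule a [FrameSchedule-class] matching the frame axis.
#' @return an [ImageVolume4D-class].
#' @export
imageVolume4D <- function(data, voxelSize, schedule) {
  new("ImageVolume4D", data = data, voxelSize = as.numeric(voxelSize),
      schedule = schedule)
}

#' @rdname dynFDG-accessors
#' @export
setMethod("imageData", "ImageVolume4D", function(object) object@data)

#' @rdname dynFDG-accessors
#' @export
setMethod("voxelSize", "ImageVolume4D", function(object) object@voxelSize)

#' @rdname dynFDG-accessors
#' @export
setMethod("schedule", "ImageVolume4D", function(object) object@schedule)

#' @rdname dynFDG-accessors
#' @export
setMethod("nFrames", "ImageVolume4D", function(object) dim(object@data)[1L])

setMethod("show", "ImageVolume4D", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume4D: %d frames, %d x %d x %d voxels (z,y,x), %s mm\n",
              d[1L], d[2L], d[3L], d[4L],
              paste(object@voxelSize, collapse = " x ")))
})

#' Construct an ROI mask from voxel coordinates
#'
#' @param coords n x 3 matrix of 1-based voxel indices, columns (z, y, x);
#'   rows are sorted lexicographically and deduplicated.
#' @param spatialDim integer(3), spatial (z, y, x) dimensions of the parent
#'   volume.
#' @return an [ROIMask-class].
#' @export
roiMask <- function(coords, spatialDim) {
  m <- matrix(as.integer(round(coords)), ncol = 3L,
              dimnames = list(NULL, c("z", "y", "x")))
  m <- unique(m)
  m <- m[order(m[, 1L], m[, 2L], m[, 3L]), , drop = FALSE]
  new("ROIMask", coords = m, spatialDim = as.integer(spatialDim))
}

#' @rdname dynFDG-accessors
#' @export
setMethod("maskCoords", "ROIMask", function(object) object@coords)

#' Number of voxels in an ROI
#' @param roi an [ROIMask-class].
#' @return integer.
#' @export
roiSize <- function(roi) nrow(roi@coords)

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask: %d voxels in a %s grid (z,y,x)\n", nrow(object@coords),
              paste(object@spatialDim, collapse = " x ")))
})

# 1-based (z,y,x) coords -> linear index into the spatial grid
.linIndex <- function(coords, dims) {
  (coords[, 3L] - 1L) * dims[1L] * dims[2L] +
    (coords[, 2L] - 1L) * dims[1L] + coords[, 1L]
}

.coordsFromLin <- function(idx, dims) {
  idx0 <- idx - 1L
  z <- idx0 %% dims[1L] + 1L
  y <- (idx0 %/% dims[1L]) %% dims[2L] + 1L
  x <- idx0 %/% (dims[1L] * dims[2L]) + 1L
  cbind(z = z, y = y, x = x)
}

#' Ellipsoid region of interest
#'
#' Selects all voxels whose physical centers satisfy the ellipsoid
#' inequality.  Voxel i (1-based) is centered at (i - 0.5) * voxelSize mm
#' along each axis; `center` is given in (possibly fractional) voxel
#' coordinates and `semiAxes` in mm.
#'
#' @param volume an [ImageVolume4D-class].
#' @param center numeric(3), ellipsoid center in voxel coordinates (z, y, x).
#' @param semiAxes numeric(3), semi-axis lengths (z, y, x), mm.
#' @return an [ROIMask-class]; error if no voxel center falls inside.
#' @export
ellipsoidROI <- function(volume, center, semiAxes) {
  stopifnot(is(volume, "ImageVolume4D"), length(center) == 3L,
            length(semiAxes) == 3L, all(semiAxes > 0))
  dims <- dim(volume@data)[2:4]
  vs <- volume@voxelSize
  cmm <- (center - 0.5) * vs
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - 0.5) * vs[a] - cmm[a]) /
                 semiAxes[a])
  g <- expand.grid(z = ax[[1L]], y = ax[[2L]], x = ax[[3L]])
  keep <- g$z^2 + g$y^2 + g$x^2 <= 1
  if (!any(keep)) stop("ellipsoid does not intersect any voxel center")
  idx <- expand.grid(z = seq_len(dims[1L]), y = seq_len(dims[2L]),
                     x = seq_len(dims[3L]))
  roiMask(as.matrix(idx[keep, , drop = FALSE]), dims)
}

# duration-weighted time-average image over a frame window
.timeAveragedImage <- function(volume, frameWindow = NULL) {
  nf <- nFrames(volume)
  frames <- if (is.null(frameWindow)) nf else frameWindow
  frames <- as.integer(frames)
  stopifnot(all(frames >= 1L), all(frames <= nf))
  w <- frameDurations(volume@schedule)[frames]
  d <- dim(volume@data)
  img <- array(0, d[2:4])
  for (i in seq_along(frames))
    img <- img + w[i] * array(volume@data[frames[i], , , ], d[2:4])
  img / sum(w)
}

#' Region-growing refinement of a manual ROI
#'
#' Replaces a manually drawn ROI by a region grown from its hottest voxel,
#' accepting only voxels whose intensity (on a duration-weighted
#' time-averaged image over `frameWindow`, by default the last frame) lies
#' within +/- 40 % of the initial ROI's mean intensity.  The band
#' \code{[(1-band)*m, (1+band)*m]} is fixed at the start (not recomputed
#' during growth) and growth uses 6-neighbour face connectivity.
#'
#' @param volume an [ImageVolume4D-class].
#' @param initialROI an [ROIMask-class], the manual ROI.
#' @param frameWindow integer vector of frame indices to average over;
#'   default the final frame.
#' @param band half-width of the acceptance band as a fraction of the
#'   initial-ROI mean (default 0.4).
#' @return an [ROIMask-class].  If the hottest seed voxel itself falls
#'   outside the band the seed alone is returned with a warning.
#' @export
regionGrowRefine <- function(volume, initialROI, frameWindow = NULL,
                             band = 0.4) {
  stopifnot(is(volume, "ImageVolume4D"), is(initialROI, "ROIMask"))
  dims <- dim(volume@data)[2:4]
  stopifnot(all(initialROI@spatialDim == dims))
  img <- .timeAveragedImage(volume, frameWindow)
  lin <- .linIndex(initialROI@coords, dims)
  m <- mean(img[lin])
  lo <- (1 - band) * m; hi <- (1 + band) * m
  seed <- lin[which.max(img[lin])]
  if (img[seed] < lo || img[seed] > hi) {
    warning("seed voxel outside the intensity band; returning the seed only")
    return(roiMask(.coordsFromLin(seed, dims), dims))
  }
  inBand <- img >= lo & img <= hi
  nz <- dims[1L]; nzy <- dims[1L] * dims[2L]
  visited <- logical(length(img))
  visited[seed] <- TRUE
  frontier <- seed
  zc <- function(i) (i - 1L) %% nz + 1L
  yc <- function(i) ((i - 1L) %/% nz) %% dims[2L] + 1L
  xc <- function(i) (i - 1L) %/% nzy + 1L
  while (length(frontier)) {
    nb <- c(frontier[zc(frontier) > 1L] - 1L,
            frontier[zc(frontier) < nz] + 1L,
            frontier[yc(frontier) > 1L] - nz,
            frontier[yc(frontier) < dims[2L]] + nz,
            frontier[xc(frontier) > 1L] - nzy,
            frontier[xc(frontier) < dims[3L]] + nzy)
    nb <- unique(nb)
    nb <- nb[!visited[nb] & inBand[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  roiMask(.coordsFromLin(which(visited), dims), dims)
}

#' Extract the time-activity curve of an ROI
#'
#' Per-frame arithmetic mean over the ROI voxels, paired with the volume's
#' frame schedule.
#'
#' @param volume an [ImageVolume4D-class].
#' @param roi an [ROIMask-class].
#' @return a [TimeActivityCurve-class].
#' @export
extractTAC <- function(volume, roi) {
  stopifnot(is(volume, "ImageVolume4D"), is(roi, "ROIMask"))
  dims <- dim(volume@data)[2:4]
  stopifnot(all(roi@spatialDim == dims))
  lin <- .linIndex(roi@coords, dims)
  nf <- nFrames(volume)
  flat <- matrix(volume@data, nrow = nf)
  vals <- rowMeans(flat[, lin, drop = FALSE])
  timeActivityCurve(volume@schedule, vals)
}

#' Standardized uptake value
#'
#' SUV = concentration / (injected dose / body weight); dimensionless when
#' concentration is in MBq/mL, dose in MBq and weight in g (1 g tissue ~ 1 mL).
#'
#' @param concentration activity concentration, MBq/mL (vectorized).
#' @param injectedDose injected activity, MBq (> 0).
#' @param bodyWeight animal weight, g (> 0).
#' @return numeric SUV.
#' @examples
#' computeSUV(0.5, injectedDose = 5.55, bodyWeight = 21.1)
#' @export
computeSUV <- function(concentration, injectedDose, bodyWeight) {
  if (injectedDose <= 0 || bodyWeight <= 0)
    stop("injectedDose and bodyWeight must be positive")
  concentration / (injectedDose / bodyWeight)
}

#' Static SUV analysis of the last frame
#'
#' Converts every ROI voxel of the final frame to SUV and records the mean
#' and the maximum (SUVmax), the conventional static-analysis metric.
#'
#' @param volume an [ImageVolume4D-class].
#' @param roi an [ROIMask-class].
#' @param injectedDose injected activity, MBq.
#' @param bodyWeight animal weight, g.
#' @return an [SUVRecord-class].
#' @export
suvmaxStatic <- function(volume, roi, injectedDose, bodyWeight) {
  stopifnot(is(volume, "ImageVolume4D"), is(roi, "ROIMask"))
  dims <- dim(volume@data)[2:4]
  stopifnot(all(roi@spatialDim == dims))
  nf <- nFrames(volume)
  lin <- .linIndex(roi@coords, dims)
  last <- matrix(volume@data, nrow = nf)[nf, lin]
  suv <- computeSUV(last, injectedDose, bodyWeight)
  st <- frameStarts(volume@schedule)[nf]
  new("SUVRecord", suvMean = mean(suv), suvMax = max(suv),
      injectedDose = injectedDose, bodyWeight = bodyWeight,
      frameWindow = c(st, st + frameDurations(volume@schedule)[nf]))
}

setMethod("show", "SUVRecord", function(object) {
  cat(sprintf(
    "SUVRecord: SUVmax=%.3f SUVmean=%.3f (dose %.3g MBq, weight %.3g g, frame %g-%g s)\n",
    object@suvMax, object@suvMean, object@injectedDose, object@bodyWeight,
    object@frameWindow[1L], object@frameWindow[2L]))
})
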