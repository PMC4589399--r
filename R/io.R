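#' Read and write time-activity curves
#'
#' TACs are stored as delimited text with a required header line and the
#' columns `frame_start_s`, `frame_duration_s`, `concentration_MBq_per_mL`;
#' lines starting with `#` are comments.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return [readTAC()] returns a [TimeActivityCurve-class].
#' @export
readTAC <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#")
  need <- c("frame_start_s", "frame_duration_s", "concentration_MBq_per_mL")
  if (!all(need %in% names(df)))
    stop("TAC file needs columns: ", paste(need, collapse = ", "))
  timeActivityCurve(frameSchedule(df$frame_start_s, df$frame_duration_s),
                    df$concentration_MBq_per_mL)
}

#' @rdname readTAC
#' @param tac a [TimeActivityCurve-class].
#' @export
writeTAC <- function(tac, path, sep = "\t") {
  stopifnot(is(tac, "TimeActivityCurve"))
  utils::write.table(as.data.frame(tac), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write kinetic parameter sets as JSON
#'
#' Flat key-value JSON with entries K1, k2, k3, k4, VB (units: K1 and the
#' derived ki in mL/s/g, rates in 1/s).
#'
#' @param path file path.
#' @return [readKineticParams()] returns a [KineticParams-class].
#' @export
readKineticParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kineticParams(x$K1, x$k2, x$k3, x$k4, x$VB %||% 0)
}

#' @rdname readKineticParams
#' @param params a [KineticParams-class].
#' @export
writeKineticParams <- function(params, path) {
  stopifnot(is(params, "KineticParams"))
  x <- as.list(kineticVector(params))
  x$ki <- influxConstant(params)
  x$units <- list(K1 = "mL/s/g", k2 = "1/s", k3 = "1/s", k4 = "1/s",
                  VB = "fraction", ki = "mL/s/g")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a fit result as JSON
#'
#' All [FitResult-class] fields with units, as a machine-readable record.
#'
#' @param fit a [FitResult-class].
#' @param path file path.
#' @export
writeFitResult <- function(fit, path) {
  stopifnot(is(fit, "FitResult"))
  x <- list(params = as.list(kineticVector(fit@params)),
            ki = fit@ki, rss = fit@rss, n_frames_used = fit@nFramesUsed,
            converged = fit@converged, se = as.list(fit@se),
            units = list(K1 = "mL/s/g", k2 = "1/s", k3 = "1/s", k4 = "1/s",
                         VB = "fraction", ki = "mL/s/g"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and write 4D image volumes as NIfTI plus a JSON sidecar
#'
#' The voxel data are stored in NIfTI (x, y, z, t axis order); the frame
#' schedule, which NIfTI cannot carry natively, goes to a sidecar JSON
#' (same path with extension .json) holding `frame_starts_s`,
#' `frame_durations_s` and `voxel_size_mm`.
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @return [readVolume4D()] returns an [ImageVolume4D-class].
#' @export
readVolume4D <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  arr <- aperm(unclass(img)[, , , , drop = FALSE], c(4L, 3L, 2L, 1L))
  imageVolume4D(arr, rev(side$voxel_size_mm),
                frameSchedule(side$frame_starts_s, side$frame_durations_s))
}

.sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' @rdname readVolume4D
#' @param volume an [ImageVolume4D-class].
#' @export
writeVolume4D <- function(volume, path) {
  stopifnot(is(volume, "ImageVolume4D"))
  arr <- aperm(volume@data, c(4L, 3L, 2L, 1L))    # (x, y, z, frame)
  img <- RNifti::asNifti(arr, pixdim = c(rev(volume@voxelSize), 1))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(frame_starts_s = frameStarts(volume@schedule),
         frame_durations_s = frameDurations(volume@schedule),
         voxel_size_mm = rev(volume@voxelSize)),
    .sidecarPath(path), digits = NA)
  invisible(path)
}

#' Read and write ROI masks as sorted-index TSV
#'
#' One voxel per line, tab-separated 1-based (z, y, x) indices, sorted
#' lexicographically; a comment header records the volume dimensions.
#'
#' @param path file path.
#' @return [readROIMask()] returns an [ROIMask-class].
#' @export
readROIMask <- function(path) {
  first <- readLines(path, n = 1L)
  dims <- as.integer(strsplit(sub("^#\\s*dim\\s*", "", first), "\\s+")[[1L]])
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  roiMask(as.matrix(df[, c("z", "y", "x")]), dims)
}

#' @rdname readROIMask
#' @param roi an [ROIMask-class].
#' @export
writeROIMask <- function(roi, path) {
  stopifnot(is(roi, "ROIMask"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# dim", paste(roi@spatialDim, collapse = " ")), con)
  writeLines("# 1-based voxel indices (z, y, x)", con)
  utils::write.table(as.data.frame(roi@coords), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write measurement tables
#'
#' Tab-separated tables with columns subject, group, metric, value.
#'
#' @param path file path.
#' @return [readMeasurementTable()] returns a validated data.frame.
#' @export
readMeasurementTable <- function(path) {
  measurementTable(utils::read.table(path, header = TRUE, sep = "\t",
                                     comment.char = "#"))
}

#' @rdname readMeasurementTable
#' @param table a [measurementTable()] data.frame.
#' @export
writeMeasurementTable <- function(table, path) {
  utils::write.table(measurementTable(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a group-analysis report as JSON
#'
#' Machine-readable version of [runGroupAnalysis()] output: per metric and
#' contrast the group summaries, omnibus H/df/p/method, and any post-hoc
#' pairwise table.
#'
#' @param analysis an object from [runGroupAnalysis()].
#' @param path file path.
#' @export
writeGroupAnalysis <- function(analysis, path) {
  stopifnot(inherits(analysis, "fdgGroupAnalysis"))
  enc <- lapply(analysis$results, function(met) lapply(met, function(res) {
    omni <- res$omnibus
    list(summary = res$summary,
         omnibus = list(H = omni@H, p_value = omni@pValue, df = omni@df,
                        method = omni@method),
         pairwise = if (nrow(omni@pairwise)) omni@pairwise else NULL)
  }))
  jsonlite::write_json(list(alpha = analysis$alpha, results = enc), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
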