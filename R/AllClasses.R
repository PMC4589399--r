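#' @useDynLib dynFDG, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' FrameSchedule: the dynamic acquisition time grid
#'
#' Frame start times and durations (seconds).  Frames must be contiguous and
#' non-overlapping: \code{starts[i+1] == starts[i] + durations[i]}.
#'
#' @slot starts numeric, frame start times in seconds (first frame at 0).
#' @slot durations numeric, frame lengths in seconds (all > 0).
#' @seealso [frameSchedule()], [mouseDynamicSchedule()]
#' @exportClass FrameSchedule
setClass("FrameSchedule",
  representation(starts = "numeric", durations = "numeric"))

setValidity("FrameSchedule", function(object) {
  s <- object@starts; d <- object@durations
  if (length(s) == 0L) return("schedule must contain at least one frame")
  if (length(s) != length(d)) return("starts and durations differ in length")
  if (any(!is.finite(s)) || any(!is.finite(d))) return("non-finite frame times")
  if (any(d <= 0)) return("frame durations must be positive")
  if (is.unsorted(s, strictly = TRUE)) return("frame starts must be strictly increasing")
  if (length(s) > 1L &&
      max(abs(s[-1L] - (s[-length(s)] + d[-length(d)]))) > 1e-9)
    return("frames must be contiguous (start[i+1] == start[i] + duration[i])")
  TRUE
})

#' TimeActivityCurve: frame-averaged activity over a FrameSchedule
#'
#' @slot schedule a [FrameSchedule-class].
#' @slot activity numeric, activity concentration per frame (MBq/mL).
#' @exportClass TimeActivityCurve
setClass("TimeActivityCurve",
  representation(schedule = "FrameSchedule", activity = "numeric"))

setValidity("TimeActivityCurve", function(object) {
  if (length(object@activity) != length(object@schedule@starts))
    return("activity length must equal the number of frames")
  if (any(!is.finite(object@activity))) return("non-finite activity values")
  TRUE
})

#' KineticParams: rate constants of the two-tissue FDG model
#'
#' The irreversible/reversible two-tissue compartment model for FDG:
#' plasma -> free tissue tracer (K1 in, k2 out) -> phosphorylated tracer
#' (k3 in, k4 out), plus a fractional vascular volume VB contributing
#' \code{VB * Cp(t)} to the measured tissue signal.
#'
#' @slot K1 forward transfer constant, mL/s/g.
#' @slot k2 efflux rate constant, 1/s.
#' @slot k3 phosphorylation rate constant, 1/s.
#' @slot k4 dephosphorylation rate constant, 1/s.
#' @slot VB fractional vascular volume, dimensionless, in [0, 1).
#' @seealso [kineticParams()], [influxConstant()], [computeAlphas()]
#' @exportClass KineticParams
setClass("KineticParams",
  representation(K1 = "numeric", k2 = "numeric", k3 = "numeric",
                 k4 = "numeric", VB = "numeric"))

setValidity("KineticParams", function(object) {
  v <- c(object@K1, object@k2, object@k3, object@k4, object@VB)
  if (length(v) != 5L || any(!is.finite(v))) return("all parameters must be finite scalars")
  if (any(v[1:4] < 0)) return("K1, k2, k3, k4 must be nonnegative")
  if (object@VB < 0 || object@VB >= 1) return("VB must lie in [0, 1)")
  TRUE
})

#' AlphaPair: eigenrates of the tissue ODE system
#'
#' The two exponential rates of the analytic model solution,
#' \code{alpha_{1,2} = ((k2+k3+k4) -/+ sqrt((k2+k3+k4)^2 - 4 k2 k4)) / 2}.
#' Always real and nonnegative for valid rate constants; they satisfy
#' \code{alpha1 + alpha2 == k2 + k3 + k4} and \code{alpha1 * alpha2 == k2 * k4}.
#'
#' @slot alpha1 slow eigenrate, 1/s.
#' @slot alpha2 fast eigenrate, 1/s.
#' @exportClass AlphaPair
setClass("AlphaPair", representation(alpha1 = "numeric", alpha2 = "numeric"))

setValidity("AlphaPair", function(object) {
  if (!is.finite(object@alpha1) || !is.finite(object@alpha2))
    return("eigenrates must be finite")
  if (object@alpha1 < 0 || object@alpha2 < object@alpha1)
    return("require 0 <= alpha1 <= alpha2")
  TRUE
})

#' ImageVolume4D: a dynamic (4D) PET image
#'
#' Voxel values are activity concentrations (MBq/mL) indexed
#' \code{[frame, z, y, x]}; the frame axis matches the attached schedule.
#'
#' @slot data 4D numeric array indexed (frame, z, y, x).
#' @slot voxelSize numeric(3), voxel edge lengths in mm for (z, y, x).
#' @slot schedule a [FrameSchedule-class] with one entry per frame.
#' @seealso [imageVolume4D()], [extractTAC()], [ellipsoidROI()]
#' @exportClass ImageVolume4D
setClass("ImageVolume4D",
  representation(data = "array", voxelSize = "numeric",
                 schedule = "FrameSchedule"))

setValidity("ImageVolume4D", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array (frame, z, y, x)")
  if (d[1L] != length(object@schedule@starts))
    return("frame count must equal the schedule length")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be three positive lengths (mm)")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    return("all voxel values must be finite")
  TRUE
})

#' ROIMask: a set of voxels within an ImageVolume4D
#'
#' Voxel indices are 1-based (z, y, x) triples, stored lexicographically
#' sorted for determinism.
#'
#' @slot coords integer matrix, n x 3, columns (z, y, x), sorted.
#' @slot spatialDim integer(3), spatial dimensions (z, y, x) of the parent volume.
#' @exportClass ROIMask
setClass("ROIMask",
  representation(coords = "matrix", spatialDim = "integer"))

setValidity("ROIMask", function(object) {
  m <- object@coords
  if (!is.numeric(m) || ncol(m) != 3L) return("coords must be an n x 3 matrix")
  if (nrow(m) == 0L) return("ROI must be non-empty")
  if (any(m != round(m))) return("coords must be integer voxel indices")
  if (length(object@spatialDim) != 3L) return("spatialDim must have length 3")
  if (any(m < 1L) || any(t(m) > object@spatialDim))
    return("coords out of volume bounds")
  o <- order(m[, 1L], m[, 2L], m[, 3L])
  if (is.unsorted(o, strictly = TRUE)) return("coords must be sorted (z, y, x)")
  if (anyDuplicated(m) > 0L) return("duplicate voxels in ROI")
  TRUE
})

#' SUVRecord: static-analysis SUV summary of an ROI
#'
#' @slot suvMean mean SUV over the ROI on the analysis frame.
#' @slot suvMax maximum voxel SUV in the ROI on the analysis frame.
#' @slot injectedDose injected activity, MBq.
#' @slot bodyWeight animal weight, g.
#' @slot frameWindow numeric(2), (start, end) of the analysed frame, s.
#' @exportClass SUVRecord
setClass("SUVRecord",
  representation(suvMean = "numeric", suvMax = "numeric",
                 injectedDose = "numeric", bodyWeight = "numeric",
                 frameWindow = "numeric"))

setValidity("SUVRecord", function(object) {
  if (object@suvMean < 0 || object@suvMax < object@suvMean)
    return("require suvMax >= suvMean >= 0")
  TRUE
})

#' FitResult: a fitted two-tissue compartment model
#'
#' @slot params the estimated [KineticParams-class].
#' @slot ki net influx constant K1*k3/(k2+k3), mL/s/g (always recomputed
#'   from \code{params}).
#' @slot rss weighted residual sum of squares of the best restart.
#' @slot nFramesUsed number of frames entering the fit.
#' @slot converged logical, TRUE when the optimizer met its tolerance.
#' @slot se approximate standard errors (K1, k2, k3, k4, VB) from the final
#'   Jacobian; NA where the information matrix is singular.
#' @exportClass FitResult
setClass("FitResult",
  representation(params = "KineticParams", ki = "numeric", rss = "numeric",
                 nFramesUsed = "integer", converged = "logical",
                 se = "numeric"))

#' PatlakResult: Patlak graphical analysis of an irreversibly trapped tracer
#'
#' @slot slope asymptotic slope (estimates Ki for k4 = 0), mL/s/g.
#' @slot intercept dimensionless intercept.
#' @slot rSquared goodness of the linear fit, in [0, 1].
#' @slot tStar start of the linear phase used, s.
#' @slot nFramesUsed frames with mid-time >= tStar.
#' @exportClass PatlakResult
setClass("PatlakResult",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", tStar = "numeric",
                 nFramesUsed = "integer"))

#' GroupComparisonResult: Kruskal-Wallis omnibus plus optional post-hoc table
#'
#' @slot H Kruskal-Wallis statistic (tie-corrected).
#' @slot pValue omnibus p-value.
#' @slot df degrees of freedom (groups - 1).
#' @slot method "chi-square" or "exact permutation".
#' @slot pairwise data.frame of Dunn pairwise comparisons (possibly empty).
#' @exportClass GroupComparisonResult
setClass("GroupComparisonResult",
  representation(H = "numeric", pValue = "numeric", df = "integer",
                 method = "character", pairwise = "data.frame"))

#' GroupPreset: a simulated experimental group
#'
#' @slot name group label.
#' @slot params group-mean [KineticParams-class].
#' @slot nSubjects animals per group in the emulated study design.
#' @slot betweenSubjectCV log-normal between-subject coefficient of variation
#'   applied per rate constant.
#' @seealso [groupPresets()]
#' @exportClass GroupPreset
setClass("GroupPreset",
  representation(name = "character", params = "KineticParams",
                 nSubjects = "integer", betweenSubjectCV = "numeric"))

#' NoiseModel: measurement noise for simulated TACs and phantoms
#'
#' Gaussian noise with standard deviation
#' \code{proportionalSD * value / sqrt(duration / durationRef) + floorSD}
#' when \code{durationScaling} is on (longer frames average more counts and
#' are quieter), else \code{proportionalSD * value + floorSD}.  Values are
#' clipped at zero after noise addition.
#'
#' @slot proportionalSD fractional noise level (e.g. 0.05 for 5 %).
#' @slot floorSD additive noise floor, MBq/mL.
#' @slot durationScaling logical, scale noise with 1/sqrt(frame duration).
#' @slot durationRef reference frame duration for the scaling, s.
#' @seealso [noiseModel()]
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(proportionalSD = "numeric", floorSD = "numeric",
                 durationScaling = "logical", durationRef = "numeric"))

setValidity("NoiseModel", function(object) {
  if (object@proportionalSD < 0 || object@floorSD < 0)
    return("noise levels must be nonnegative")
  if (object@durationRef <= 0) return("durationRef must be positive")
  TRUE
})
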