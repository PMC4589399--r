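#' Construct a noise model
#'
#' @param proportionalSD fractional noise level (0.05 = 5 %).
#' @param floorSD additive noise floor, MBq/mL.
#' @param durationScaling logical; scale the noise with
#'   1/sqrt(duration/durationRef) so longer frames are quieter.
#' @param durationRef reference frame duration, s (default 5 s, the median
#'   frame length of [mouseDynamicSchedule()]).
#' @return a [NoiseModel-class].
#' @export
noiseModel <- function(proportionalSD = 0.05, floorSD = 0,
                       durationScaling = TRUE, durationRef = 5) {
  new("NoiseModel", proportionalSD = proportionalSD, floorSD = floorSD,
      durationScaling = durationScaling, durationRef = durationRef)
}

.noiseSD <- function(noise, value, duration) {
  s <- noise@proportionalSD * abs(value)
  if (noise@durationScaling) s <- s / sqrt(duration / noise@durationRef)
  s + noise@floorSD
}

#' Construct a group preset
#'
#' @param name group label.
#' @param params group-mean [KineticParams-class].
#' @param nSubjects animals per group.
#' @param betweenSubjectCV per-parameter log-normal coefficient of variation.
#' @return a [GroupPreset-class].
#' @export
groupPreset <- function(name, params, nSubjects, betweenSubjectCV = 0.3) {
  new("GroupPreset", name = name, params = params,
      nSubjects = as.integer(nSubjects), betweenSubjectCV = betweenSubjectCV)
}

#' @describeIn influxConstant of a preset's group-mean parameters.
#' @export
setMethod("influxConstant", "GroupPreset",
          function(object) influxConstant(object@params))

setMethod("show", "GroupPreset", function(object) {
  cat(sprintf("GroupPreset \"%s\": n=%d, CV=%.0f%%\n", object@name,
              object@nSubjects, 100 * object@betweenSubjectCV))
  show(object@params)
})

#' The six emulated experimental groups
#'
#' Group-mean rate constants and group sizes of the emulated mouse study:
#' tumor and/or inflammation lesions placed subcutaneously, in the lung
#' (in situ), or arising spontaneously in the liver.  All presets use a
#' fractional blood volume VB = 0.05 (a typical lesion vascular fraction;
#' the group tables report no VB) and a default between-subject CV of 30 %.
#'
#' @param betweenSubjectCV log-normal per-parameter CV applied when
#'   simulating subjects.
#' @return named list of six [GroupPreset-class] objects.
#' @examples
#' sapply(groupPresets(), influxConstant)
#' @export
groupPresets <- function(betweenSubjectCV = 0.3) {
  vb <- 0.05
  defs <- list(
    subcutaneous_tumor =
      list(kineticParams(0.00229, 0.042, 0.0104, 0.00177, vb), 5L),
    in_situ_tumor =
      list(kineticParams(0.185, 0.459, 0.00166, 0.00499, vb), 5L),
    subcutaneous_inflammation_with_tumor =
      list(kineticParams(0.00326, 0.0124, 0.00119, 0.000706, vb), 4L),
    subcutaneous_inflammation_without_tumor =
      list(kineticParams(0.00531, 0.0578, 0.19, 0.00993, vb), 4L),
    in_situ_inflammation =
      list(kineticParams(0.0241, 0.674, 0.148, 0.56, vb), 9L),
    spontaneous_liver_inflammation =
      list(kineticParams(0.00817, 0.00982, 0.109, 0.418, vb), 6L))
  out <- lapply(names(defs), function(nm)
    groupPreset(nm, defs[[nm]][[1L]], defs[[nm]][[2L]], betweenSubjectCV))
  names(out) <- names(defs)
  out
}

# mean-preserving log-normal jitter of the rate constants (VB kept fixed)
.jitterParams <- function(params, cv) {
  if (cv <= 0) return(params)
  sig <- sqrt(log(1 + cv^2))
  v <- kineticVector(params)
  j <- v[1:4] * exp(stats::rnorm(4L, 0, sig) - sig^2 / 2)
  kineticParams(j[1L], j[2L], j[3L], j[4L], v[5L])
}

.addNoise <- function(tac, noise) {
  d <- frameDurations(tac@schedule)
  sd <- .noiseSD(noise, tac@activity, d)
  vals <- pmax(tac@activity + stats::rnorm(length(sd), 0, sd), 0)
  timeActivityCurve(tac@schedule, vals)
}

#' Simulate one subject's plasma and tissue TACs
#'
#' Draws subject-level parameters by mean-preserving log-normal jitter of
#' the preset's rate constants, frame-averages the bolus into the measured
#' plasma TAC, drives the analytic forward model with that frame-sampled
#' input (the same piecewise-linear representation the estimator uses, so
#' the generator is an exact oracle for the fit), and adds seeded Gaussian
#' noise to the tissue curve (clipped at zero).  The plasma TAC is returned
#' noiseless: blood-pool ROIs pool many voxels, so input-function noise is
#' negligible next to lesion-ROI noise.  Input-sampling bias (continuous
#' physiology vs frame-sampled input) is exercised separately by the 4D
#' phantom pipeline, whose regions are painted from the continuous bolus.
#'
#' @param preset a [GroupPreset-class].
#' @param bolus plasma input function of time (s), e.g. [defaultBolus()].
#' @param schedule a [FrameSchedule-class].
#' @param noise a [NoiseModel-class].
#' @param seed integer; identical seeds give identical output.
#' @return list with `cp` and `tissue` ([TimeActivityCurve-class]) and
#'   `truth` (the subject's [KineticParams-class]).
#' @export
simulateSubjectTACs <- function(preset, bolus = defaultBolus(),
                                schedule = mouseDynamicSchedule(),
                                noise = noiseModel(), seed = 1L) {
  stopifnot(is(preset, "GroupPreset"), is.function(bolus),
            is(schedule, "FrameSchedule"), is(noise, "NoiseModel"))
  cp <- frameAverage(bolus, schedule)
  .withSeed(seed, {
    truth <- .jitterParams(preset@params, preset@betweenSubjectCV)
    tissue <- .addNoise(modelFrameTAC(truth, cp), noise)
    list(cp = cp, tissue = tissue, truth = truth)
  })
}

#' Simulate a multi-group kinetic study
#'
#' Simulates every subject of every preset, fits the compartment model to
#' each, and returns a measurement table with the fitted Ki (plus the
#' subject's true Ki for validation).
#'
#' @param presets list of [GroupPreset-class] objects.
#' @param bolus plasma input function.
#' @param schedule a [FrameSchedule-class].
#' @param noise a [NoiseModel-class].
#' @param seed integer master seed; subject seeds are derived from it.
#' @param control fitting control, see [kineticFitControl()].
#' @return data.frame with columns subject, group, metric ("Ki"), value,
#'   trueValue.
#' @export
simulateStudy <- function(presets = groupPresets(), bolus = defaultBolus(),
                          schedule = mouseDynamicSchedule(),
                          noise = noiseModel(), seed = 1L,
                          control = kineticFitControl()) {
  rows <- list()
  sid <- 0L
  for (g in seq_along(presets)) {
    preset <- presets[[g]]
    for (i in seq_len(preset@nSubjects)) {
      sid <- sid + 1L
      sseed <- (seed * 10007L + sid * 101L) %% .Machine$integer.max
      sim <- simulateSubjectTACs(preset, bolus, schedule, noise, seed = sseed)
      fit <- fitCompartmentModel(sim$cp, sim$tissue, seed = sseed,
                                 control = control)
      rows[[sid]] <- data.frame(
        subject = sprintf("S%03d", sid), group = preset@name, metric = "Ki",
        value = fit@ki, trueValue = influxConstant(sim$truth))
    }
  }
  do.call(rbind, rows)
}

#' Build a 4D digital phantom
#'
#' Paints disjoint ellipsoidal regions of a voxel grid with frame-averaged
#' model TACs: the blood pool carries the whole-blood curve (plasma bolus
#' divided by the plasma-to-whole-blood ratio, so the plasma calibration
#' step is exercised non-trivially), each lesion carries the analytic
#' tissue curve of its kinetic parameters, and the background a low-uptake
#' tissue curve.  Optional voxel-level Gaussian noise is seeded.
#'
#' @param bloodPool list(center = voxel (z,y,x), semiAxes = mm).
#' @param lesions named list; each element list(center, semiAxes, params =
#'   [KineticParams-class]).
#' @param bolus plasma input function of time (s).
#' @param schedule a [FrameSchedule-class].
#' @param noise a [NoiseModel-class] or NULL for a noiseless phantom.
#' @param seed integer seed for the voxel noise.
#' @param dim integer(3), grid size (z, y, x).
#' @param voxelSizeMM numeric(3) or scalar, voxel size in mm.
#' @param backgroundParams [KineticParams-class] for non-lesion tissue.
#' @param ratioParams plasma-to-whole-blood [plasmaRatioParams()].
#' @return list with `volume` ([ImageVolume4D-class]), `masks` (named list
#'   of ground-truth [ROIMask-class]: bloodPool, lesions, background), and
#'   `regionTACs` (named list of noiseless painted [TimeActivityCurve-class]).
#' @export
buildPhantom <- function(bloodPool = list(center = c(32, 32, 20),
                                          semiAxes = c(3, 3, 3)),
                         lesions = list(
                           lesion = list(center = c(32, 32, 44),
                                         semiAxes = c(4, 4, 4),
                                         params = kineticParams(
                                           0.005, 0.05, 0.01, 0.001, 0.05))),
                         bolus = defaultBolus(),
                         schedule = mouseDynamicSchedule(),
                         noise = NULL, seed = 1L,
                         dim = c(64L, 64L, 64L), voxelSizeMM = 0.5,
                         backgroundParams = kineticParams(2e-4, 0.01, 1e-4,
                                                          0, 0.02),
                         ratioParams = plasmaRatioParams()) {
  dim <- as.integer(dim)
  voxelSizeMM <- rep(as.numeric(voxelSizeMM), length.out = 3L)
  nf <- nFrames(schedule)
  shell <- imageVolume4D(array(0, c(nf, dim)), voxelSizeMM, schedule)

  # whole blood = frame-averaged plasma divided by the ratio at frame
  # mid-times (the ratio varies negligibly within a frame), so the
  # calibration step inverts the painting exactly
  cpFrames <- frameAverage(bolus, schedule)
  wholeBlood <- timeActivityCurve(
    schedule, activity(cpFrames) / plasmaRatio(frameMids(schedule),
                                               ratioParams))
  lesionTAC <- function(p) .modelFramesFromFunction(p, bolus, schedule)

  masks <- list(bloodPool = ellipsoidROI(shell, bloodPool$center,
                                         bloodPool$semiAxes))
  tacs <- list(bloodPool = wholeBlood)
  for (nm in names(lesions)) {
    masks[[nm]] <- ellipsoidROI(shell, lesions[[nm]]$center,
                                lesions[[nm]]$semiAxes)
    tacs[[nm]] <- lesionTAC(lesions[[nm]]$params)
  }
  lins <- lapply(masks, function(m) .linIndex(maskCoords(m), dim))
  all <- unlist(lins)
  if (anyDuplicated(all) > 0L) stop("phantom regions must be disjoint")

  bg <- lesionTAC(backgroundParams)
  nvox <- prod(dim)
  flat <- matrix(rep(bg@activity, nvox), nrow = nf)
  for (nm in names(lins))
    flat[, lins[[nm]]] <- tacs[[nm]]@activity
  if (!is.null(noise)) {
    stopifnot(is(noise, "NoiseModel"))
    sdm <- .noiseSD(noise, flat, frameDurations(schedule))
    flat <- .withSeed(seed,
      pmax(flat + stats::rnorm(length(flat), 0, as.numeric(sdm)), 0))
  }
  bgLin <- setdiff(seq_len(nvox), all)
  masks$background <- roiMask(.coordsFromLin(bgLin, dim), dim)
  tacs$background <- bg
  vol <- imageVolume4D(array(flat, c(nf, dim)), voxelSizeMM, schedule)
  list(volume = vol, masks = masks, regionTACs = tacs)
}
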