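#' Feng-type bolus plasma input model
#'
#' A tracer bolus of the classic gamma-ramp-plus-biexponential form
#' \deqn{C_p(t) = (A_1 (t-d) - A_2 - A_3) e^{-\lambda_1 (t-d)} +
#'   A_2 e^{-\lambda_2 (t-d)} + A_3 e^{-\lambda_3 (t-d)},\quad t \ge d,}
#' zero before the injection delay d.  Used to drive simulations in place of
#' a measured left-ventricle curve.
#'
#' @param A1 ramp amplitude, MBq/mL/s.
#' @param A2,A3 amplitudes, MBq/mL.
#' @param lambda1,lambda2,lambda3 decay rates, 1/s; require
#'   lambda1 > lambda2 > lambda3 >= 0.
#' @param delay injection delay, s.
#' @param tEnd domain end used for the non-negativity check, s.
#' @return vectorized function(t) -> MBq/mL (zero for t < delay).
#' @seealso [defaultBolus()] for study-scale defaults.
#' @export
fengBolus <- function(A1, A2, A3, lambda1, lambda2, lambda3, delay = 0,
                      tEnd = 3600) {
  stopifnot(lambda1 > lambda2, lambda2 > lambda3, lambda3 >= 0, delay >= 0)
  f <- function(t) {
    u <- t - delay
    ifelse(u <= 0, 0,
           (A1 * u - A2 - A3) * exp(-lambda1 * u) +
             A2 * exp(-lambda2 * u) + A3 * exp(-lambda3 * u))
  }
  chk <- f(seq(0, tEnd, length.out = 4097))
  if (any(chk < -1e-9 * max(abs(chk))))
    stop("bolus parameters yield a negative curve on [0, tEnd]")
  f
}

#' Default simulation bolus at mouse study scale
#'
#' A [fengBolus()] with a 5 s injection delay and shape rates
#' lambda = (1, 0.01, 1.7e-4) /s — a sharp (about 2 s wide) tail-vein bolus
#' whose peak, at roughly delay + 1 s, falls inside the rapid 0.5 s framing
#' window of [mouseDynamicSchedule()], as that protocol intends — rescaled
#' so the plasma peak equals `dose / peakVolume`: by default 5.55 MBq (the
#' emulated mean injected activity) distributed over 1.7 mL (mouse blood
#' volume scale), i.e. a peak of about 3.3 MBq/mL.
#'
#' @param dose injected activity, MBq.
#' @param peakVolume effective distribution volume setting the peak, mL.
#' @param delay injection delay, s.
#' @return vectorized function(t) -> MBq/mL.
#' @export
defaultBolus <- function(dose = 5.55, peakVolume = 1.7, delay = 5) {
  shape <- fengBolus(A1 = 1, A2 = 0.25, A3 = 0.15,
                     lambda1 = 1, lambda2 = 0.01, lambda3 = 1.7e-4,
                     delay = delay)
  pk <- max(shape(seq(delay, delay + 60, by = 0.01)))
  scl <- (dose / peakVolume) / pk
  function(t) scl * shape(t)
}

#' Plasma-to-whole-blood ratio parameters
#'
#' The calibrated time-dependent concentration ratio between plasma and
#' whole blood, \eqn{R_{PB}(t) = a e^{-b t} + c} with t in minutes;
#' defaults a = 0.432, b = 0.168 /min, c = 1.158.
#'
#' @param a amplitude (dimensionless).
#' @param b decay rate, 1/min.
#' @param c asymptote (dimensionless); must be positive so the ratio stays
#'   above 1 at all times for the default values.
#' @return list with class "PlasmaRatioParams".
#' @export
plasmaRatioParams <- function(a = 0.432, b = 0.168, c = 1.158) {
  stopifnot(b >= 0, a + c > 0, c > 0)
  structure(list(a = a, b = b, c = c), class = "PlasmaRatioParams")
}

#' Plasma-to-whole-blood concentration ratio
#'
#' Evaluates R_PB at time `t` given in seconds (the ratio's rate constant is
#' per minute; the conversion is confined to this function).
#'
#' @param t time since injection, seconds; must be nonnegative.
#' @param params a [plasmaRatioParams()] object.
#' @return dimensionless ratio, strictly decreasing in t, bounded in
#'   (c, a + c].
#' @examples
#' plasmaRatio(0)     # 1.590
#' plasmaRatio(60)    # about 1.5233
#' @export
plasmaRatio <- function(t, params = plasmaRatioParams()) {
  if (any(t < 0)) stop("t must be nonnegative")
  params$a * exp(-params$b * t / 60) + params$c
}

#' Image-derived input function (whole blood)
#'
#' Per-frame mean concentration over a blood-pool ROI (e.g. the left
#' ventricle), yielding the whole-blood TAC that
#' [calibrateToPlasma()] converts to a plasma input.
#'
#' @param volume an [ImageVolume4D-class].
#' @param bloodROI an [ROIMask-class] inside the volume.
#' @return a [TimeActivityCurve-class].
#' @export
imageDerivedInput <- function(volume, bloodROI) {
  extractTAC(volume, bloodROI)
}

#' Calibrate a whole-blood TAC to plasma
#'
#' Multiplies each frame value by the plasma-to-whole-blood ratio evaluated
#' at the frame mid-time (start + duration/2), so results are
#' bit-reproducible.
#'
#' @param wholeBlood a [TimeActivityCurve-class] of whole-blood activity.
#' @param params a [plasmaRatioParams()] object.
#' @return the plasma [TimeActivityCurve-class].
#' @export
calibrateToPlasma <- function(wholeBlood, params = plasmaRatioParams()) {
  stopifnot(is(wholeBlood, "TimeActivityCurve"))
  r <- plasmaRatio(frameMids(wholeBlood@schedule), params)
  timeActivityCurve(wholeBlood@schedule, wholeBlood@activity * r)
}
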