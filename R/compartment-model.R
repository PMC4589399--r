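#' Construct kinetic parameters for the two-tissue FDG model
#'
#' @param K1 forward transfer constant, mL/s/g.
#' @param k2,k3,k4 rate constants, 1/s.
#' @param VB fractional vascular volume in [0, 1).
#' @return a [KineticParams-class].
#' @examples
#' kineticParams(K1 = 0.005, k2 = 0.05, k3 = 0.01, k4 = 0.001, VB = 0.05)
#' @export
kineticParams <- function(K1, k2, k3, k4, VB = 0) {
  new("KineticParams", K1 = as.numeric(K1), k2 = as.numeric(k2),
      k3 = as.numeric(k3), k4 = as.numeric(k4), VB = as.numeric(VB))
}

#' @rdname dynFDG-accessors
#' @export
setMethod("kineticVector", "KineticParams", function(object)
  c(K1 = object@K1, k2 = object@k2, k3 = object@k3, k4 = object@k4,
    VB = object@VB))

setMethod("show", "KineticParams", function(object) {
  cat(sprintf(
    "KineticParams: K1=%.4g mL/s/g  k2=%.4g  k3=%.4g  k4=%.4g /s  VB=%.3g\n",
    object@K1, object@k2, object@k3, object@k4, object@VB))
  cat(sprintf("  Ki = K1*k3/(k2+k3) = %.4g mL/s/g\n", influxConstant(object)))
})

#' @describeIn influxConstant from a parameter set.
#' @export
setMethod("influxConstant", "KineticParams", function(object) {
  s <- object@k2 + object@k3
  if (s == 0) return(0)
  object@K1 * object@k3 / s
})

# stable quadratic roots: alpha1*alpha2 == k2*k4 holds to machine precision
.alphas <- function(k2, k3, k4) {
  s <- k2 + k3 + k4
  disc <- s * s - 4 * k2 * k4          # = (k2-k4)^2 + k3^2 + 2 k3 (k2+k4) >= 0
  r <- sqrt(max(disc, 0))
  a2 <- (s + r) / 2
  a1 <- if (a2 > 0) min((k2 * k4) / a2, a2) else 0
  c(a1, a2)
}

#' Eigenrates of the two-tissue model
#'
#' Computes the two exponential rates alpha1 <= alpha2 of the analytic
#' tissue solution.  They are always real for nonnegative rate constants
#' and satisfy alpha1+alpha2 = k2+k3+k4 and alpha1*alpha2 = k2*k4.
#'
#' @param params a [KineticParams-class].
#' @return an [AlphaPair-class].
#' @examples
#' computeAlphas(kineticParams(0.005, 0.1, 0.05, 0))
#' @export
computeAlphas <- function(params) {
  stopifnot(is(params, "KineticParams"))
  a <- .alphas(params@k2, params@k3, params@k4)
  new("AlphaPair", alpha1 = a[1L], alpha2 = a[2L])
}

setMethod("show", "AlphaPair", function(object) {
  cat(sprintf("AlphaPair: alpha1=%.6g /s, alpha2=%.6g /s\n",
              object@alpha1, object@alpha2))
})

.asCpFunction <- function(cp) {
  if (is(cp, "TimeActivityCurve")) return(tacInterpolant(cp))
  if (is.function(cp)) return(cp)
  stop("cp must be a function of time (s) or a TimeActivityCurve")
}

#' Numerically integrate the tissue compartment ODEs
#'
#' Integrates the free (Ce) and phosphorylated (Cm) tissue compartments
#'   dCe/dt = K1*Cp(t) - (k2+k3)*Ce + k4*Cm
#'   dCm/dt = k3*Ce - k4*Cm
#' with fixed-step 4th-order Runge-Kutta (via \pkg{deSolve}) and assembles
#' the measured signal CT = (Ce + Cm) + VB*Cp.  The integration grid uses a
#' 0.05 s step while the bolus varies fast (t < 120 s) and 0.5 s thereafter.
#' This is the package's independent numerical oracle for
#' [analyticTissueCurve()].
#'
#' @param params a [KineticParams-class].
#' @param cp plasma input: a vectorized function of time (s) or a
#'   [TimeActivityCurve-class] (interpolated piecewise-linearly).
#' @param tGrid strictly increasing sample times starting at 0, s.
#' @return data.frame with columns time, Ce, Cm, CT.
#' @examples
#' solveTissueODE(kineticParams(0.01, 0, 0, 0, VB = 0.2),
#'                function(t) rep(1, length(t)), tGrid = c(0, 10, 20))
#' @export
solveTissueODE <- function(params, cp, tGrid) {
  stopifnot(is(params, "KineticParams"))
  tGrid <- as.numeric(tGrid)
  if (length(tGrid) < 1L || tGrid[1L] != 0 || is.unsorted(tGrid, strictly = TRUE))
    stop("tGrid must be strictly increasing and start at 0")
  cpf <- .asCpFunction(cp)
  tEnd <- max(tGrid)
  fine <- seq(0, min(120, tEnd), by = 0.05)
  if (tEnd > 120) fine <- c(fine, seq(120.5, tEnd, by = 0.5))
  times <- sort(unique(c(fine, tGrid)))
  p <- kineticVector(params)
  rhs <- function(t, y, parms) {
    cpt <- cpf(t)
    list(c(parms[["K1"]] * cpt - (parms[["k2"]] + parms[["k3"]]) * y[1L] +
             parms[["k4"]] * y[2L],
           parms[["k3"]] * y[1L] - parms[["k4"]] * y[2L]))
  }
  sol <- deSolve::ode(y = c(Ce = 0, Cm = 0), times = times, func = rhs,
                      parms = p, method = "rk4")
  idx <- match(tGrid, times)
  ce <- sol[idx, "Ce"]; cm <- sol[idx, "Cm"]
  data.frame(time = tGrid, Ce = ce, Cm = cm,
             CT = (ce + cm) + params@VB * cpf(tGrid))
}

# Convolution states of the analytic solution for cp sampled on knots `tk`
# (piecewise linear).  Returns the kernel convolution contribution to CT
# (without the VB*Cp term) as point values `ct` and running integral `CT`.
.analyticStates <- function(K1, k2, k3, k4, tk, cpk) {
  k34 <- k3 + k4
  a <- .alphas(k2, k3, k4)
  if ((a[2L] - a[1L]) > 1e-12 * max(1, a[2L])) {
    s1 <- .cppExpConv(tk, cpk, a[1L], 0L)
    s2 <- .cppExpConv(tk, cpk, a[2L], 0L)
    c1 <- K1 * (k34 - a[1L]) / (a[2L] - a[1L])
    c2 <- K1 * (a[2L] - k34) / (a[2L] - a[1L])
    list(ct = c1 * s1$y + c2 * s2$y, CT = c1 * s1$Y + c2 * s2$Y)
  } else {
    # confluent limit alpha1 == alpha2: kernel K1*((k34-alpha)*t + 1)*e^(-alpha t)
    s <- .cppExpConv(tk, cpk, a[1L], 1L)
    list(ct = K1 * ((k34 - a[1L]) * s$z + s$y),
         CT = K1 * ((k34 - a[1L]) * s$Z + s$Y))
  }
}

#' Analytic solution of the two-tissue model
#'
#' Evaluates
#' \deqn{C_T(t) = \frac{K_1}{\alpha_2-\alpha_1}\left[(k_3+k_4-\alpha_1)
#'   e^{-\alpha_1 t} + (\alpha_2-k_3-k_4) e^{-\alpha_2 t}\right] \otimes
#'   C_p(t) + V_B C_p(t)}
#' with the convolution carried out exactly for a piecewise-linear
#' representation of Cp on a fine uniform grid (default 0.02 s, which keeps
#' the representation error of a sharp ~1/s bolus below 1e-4 relative)
#' merged with `tGrid`.  When alpha1 == alpha2 (within 1e-12 relative) the confluent
#' kernel \eqn{K_1[(k_3+k_4-\alpha)t + 1]e^{-\alpha t}} is used.
#'
#' @inheritParams solveTissueODE
#' @param dt fine-grid spacing for the piecewise-linear Cp representation, s.
#' @return numeric vector, CT sampled on `tGrid` (MBq/mL).
#' @seealso [solveTissueODE()] for the numerical oracle.
#' @export
analyticTissueCurve <- function(params, cp, tGrid, dt = 0.02) {
  stopifnot(is(params, "KineticParams"))
  tGrid <- as.numeric(tGrid)
  if (length(tGrid) < 1L || any(tGrid < 0) || is.unsorted(tGrid, strictly = TRUE))
    stop("tGrid must be strictly increasing and nonnegative")
  cpf <- .asCpFunction(cp)
  tk <- sort(unique(c(seq(0, max(tGrid), by = dt), max(tGrid), tGrid)))
  cpk <- cpf(tk)
  st <- .analyticStates(params@K1, params@k2, params@k3, params@k4, tk, cpk)
  (st$ct + params@VB * cpk)[match(tGrid, tk)]
}

# Frame-averaged analytic model output for a *continuous* plasma input:
# the input is represented piecewise-linearly on a fine grid (default
# 0.1 s) merged with the frame boundaries, and the convolution plus its
# frame integrals are evaluated in closed form on that grid.
.modelFramesFromFunction <- function(params, cpFun, schedule, dt = 0.1) {
  starts <- frameStarts(schedule)
  ends <- starts + frameDurations(schedule)
  tk <- sort(unique(c(seq(0, max(ends), by = dt), starts, ends)))
  cpk <- cpFun(tk)
  st <- .analyticStates(params@K1, params@k2, params@k3, params@k4, tk, cpk)
  dtk <- diff(tk)
  cpInt <- c(0, cumsum(dtk * (cpk[-length(cpk)] + cpk[-1L]) / 2))
  i0 <- match(starts, tk); i1 <- match(ends, tk)
  vals <- ((st$CT[i1] - st$CT[i0]) + params@VB * (cpInt[i1] - cpInt[i0])) /
    frameDurations(schedule)
  timeActivityCurve(schedule, vals)
}

#' Frame-average a continuous curve over a schedule
#'
#' PET measures the time-average of the activity over each frame; this
#' computes those averages by composite Simpson quadrature (step <= 0.05 s).
#'
#' @param curve vectorized function of time (s) -> MBq/mL.
#' @param schedule a [FrameSchedule-class]; frames must lie inside the
#'   curve's domain.
#' @return a [TimeActivityCurve-class].
#' @examples
#' frameAverage(function(t) exp(-t), frameSchedule(durations = c(1, 1)))
#' @export
frameAverage <- function(curve, schedule) {
  stopifnot(is.function(curve), is(schedule, "FrameSchedule"))
  vals <- mapply(function(s, d) {
    n <- max(8L, 2L * ceiling(d / 0.1))        # even number of intervals
    x <- seq(s, s + d, length.out = n + 1L)
    y <- curve(x)
    if (any(!is.finite(y))) stop("curve not finite over frame")
    h <- d / n
    w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
    sum(w * y) * h / 3 / d
  }, schedule@starts, schedule@durations)
  timeActivityCurve(schedule, vals)
}
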