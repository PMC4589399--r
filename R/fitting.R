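# run expr with a temporary RNG state seeded by `seed` (restores global state)
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Precompute the fitting geometry for a plasma TAC: knot grid holding the
# piecewise-linear input (0 + frame mid-times + frame boundaries), cp values
# on the knots, cumulative integral of cp, and frame boundary indices.
#
# The input knot values are refined so that the interpolant's own frame
# averages reproduce the measured frame values (a PET frame value is a
# time-average, not a point sample; naive interpolation through mid-times
# underestimates a sharp bolus).  The refinement solves the small linear
# system mapping knot values to frame averages and clamps at zero; where
# the nonnegative piecewise-linear family cannot represent the averages
# exactly (the bolus arrival frames) the residual mismatch is confined to
# near-zero frames.
.fitPrep <- function(cp, refine = TRUE) {
  sched <- cp@schedule
  mids <- frameMids(sched)
  starts <- frameStarts(sched)
  ends <- starts + frameDurations(sched)
  dur <- frameDurations(sched)
  tk <- sort(unique(c(0, mids, starts, ends)))
  i0 <- match(starts, tk); i1 <- match(ends, tk)
  vals <- cp@activity
  if (refine && length(mids) >= 2L) {
    avgOf <- function(v) {
      ck <- stats::approx(c(0, mids), c(0, v), xout = tk, rule = 2)$y
      dtk <- diff(tk)
      ci <- c(0, cumsum(dtk * (ck[-length(ck)] + ck[-1L]) / 2))
      (ci[i1] - ci[i0]) / dur
    }
    n <- length(mids)
    A <- vapply(seq_len(n), function(j) avgOf(replace(numeric(n), j, 1)),
                numeric(n))
    v <- tryCatch(solve(A, vals), error = function(e) NULL)
    if (!is.null(v) && all(is.finite(v))) vals <- pmax(v, 0)
  }
  cpk <- stats::approx(c(0, mids), c(0, vals), xout = tk, rule = 2)$y
  dtk <- diff(tk)
  cpInt <- c(0, cumsum(dtk * (cpk[-length(cpk)] + cpk[-1L]) / 2))
  list(tk = tk, cpk = cpk, cpInt = cpInt, i0 = i0, i1 = i1, dur = dur)
}

# Exact model frame averages for parameter vector p = (K1,k2,k3,k4,VB)
.modelFrames <- function(p, prep) {
  st <- .analyticStates(p[1L], p[2L], p[3L], p[4L], prep$tk, prep$cpk)
  ((st$CT[prep$i1] - st$CT[prep$i0]) +
     p[5L] * (prep$cpInt[prep$i1] - prep$cpInt[prep$i0])) / prep$dur
}

#' Model-predicted frame averages
#'
#' Frame-averaged tissue curve predicted by the analytic two-tissue model
#' for a plasma input given as a TAC.  The input is represented piecewise
#' linearly with knot values refined so the interpolant's frame averages
#' reproduce the measured frame values; the convolution and the frame
#' integrals are then evaluated in closed form on the knots, so the result
#' is exact for that input representation (this is the forward model the
#' fit minimizes against).
#'
#' @param params a [KineticParams-class].
#' @param cp plasma input [TimeActivityCurve-class].
#' @param refineInput logical; refine the input knots to be
#'   frame-average-consistent (disable to interpolate the raw frame values
#'   through the mid-times).
#' @return a [TimeActivityCurve-class] on the same schedule.
#' @export
modelFrameTAC <- function(params, cp, refineInput = TRUE) {
  stopifnot(is(params, "KineticParams"), is(cp, "TimeActivityCurve"))
  prep <- .fitPrep(cp, refine = refineInput)
  timeActivityCurve(cp@schedule, .modelFrames(kineticVector(params), prep))
}

#' Control settings for the compartment-model fit
#'
#' The optimizer works on (log K1, log k2, log k3, log k4, VB): the group
#' estimates span four orders of magnitude, and the log scale keeps the
#' Levenberg-Marquardt steps well conditioned across that range.
#'
#' @param nStarts total number of starting points: four fixed
#'   literature-scale FDG regime starts (slow lesion, high-flow lesion,
#'   fast-turnover lesion, avid trapping) plus seeded Latin-hypercube draws
#'   with K1 in [1e-5,1], k2,k3,k4 in [1e-6,2], VB in [0,0.5].
#' @param screenIter Levenberg-Marquardt iterations allotted to every start
#'   during the screening stage.
#' @param polishTop number of best screened starts refined to convergence.
#' @param maxIter iteration cap for the refinement stage.
#' @param ftol relative reduction tolerance on the weighted residual sum of
#'   squares declaring convergence.
#' @param upper upper parameter bounds (K1, k2, k3, k4, VB); the lower
#'   bound of the rates is a floor of 1e-8, snapped to 0 in the result.
#' @return list of class "kineticFitControl".
#' @export
kineticFitControl <- function(nStarts = 10L, screenIter = 30L, polishTop = 3L,
                              maxIter = 500L, ftol = 1e-8,
                              upper = c(5, 5, 5, 5, 0.999)) {
  structure(list(nStarts = as.integer(nStarts),
                 screenIter = as.integer(screenIter),
                 polishTop = as.integer(polishTop),
                 maxIter = as.integer(maxIter), ftol = ftol, upper = upper),
            class = "kineticFitControl")
}

# typical FDG kinetic regimes used as fixed starting points (natural units)
.regimeStarts <- matrix(c(
  0.003, 0.04, 0.01, 0.002, 0.05,    # slow exchange, slow trapping
  0.1,   0.5,  0.005, 0.005, 0.1,    # high flow, weak trapping
  0.02,  0.5,  0.15,  0.5,   0.05,   # fast turnover, strong dephosphorylation
  0.005, 0.05, 0.15,  0.01,  0.05),  # avid trapping
  ncol = 5L, byrow = TRUE)

.lmStarts <- function(n, fixK4) {
  p <- .regimeStarts
  nr <- n - nrow(p)
  if (nr > 0) {
    lo <- log10(c(1e-5, 1e-6, 1e-6, 1e-6))
    hi <- log10(c(1, 2, 2, 2))
    u <- lhs::randomLHS(nr, 5L)
    p <- rbind(p, cbind(10^(sweep(sweep(u[, 1:4, drop = FALSE], 2L, hi - lo,
                                        "*"), 2L, lo, "+")),
                        0.5 * u[, 5L]))
  } else {
    p <- p[seq_len(n), , drop = FALSE]
  }
  if (fixK4) p[, 4L] <- 0
  p
}

#' Fit the two-tissue compartment model to a tissue TAC
#'
#' Weighted nonlinear least squares
#' \deqn{\min \sum_f w_f (C_T^{model}(f) - tissue_f)^2,\quad w_f =
#'   \mathrm{duration}_f,}
#' over (K1, k2, k3, k4, VB) with nonnegativity bounds and VB in [0, 1),
#' using the Levenberg-Marquardt algorithm (\pkg{minpack.lm}).  Model frames
#' come from the analytic solution convolved with the piecewise-linearly
#' interpolated plasma TAC and averaged exactly over each frame.  Restarts
#' from `nStarts` seeded quasi-random points are screened with a few LM
#' iterations and the best candidates refined; ties between restarts are
#' broken by lowest weighted RSS, then by the lexicographically smallest
#' parameter vector.
#'
#' @param cp plasma input [TimeActivityCurve-class].
#' @param tissue tissue [TimeActivityCurve-class] on the same schedule.
#' @param fixK4 logical; fix k4 = 0 (the irreversible, Patlak-comparable
#'   model) instead of fitting it.
#' @param seed integer seed controlling the multi-start draw (the fit is
#'   deterministic given data, control and seed).
#' @param control a [kineticFitControl()].
#' @param refineInput see [modelFrameTAC()].
#' @return a [FitResult-class].  An all-zero tissue TAC yields a flagged
#'   non-converged result with zero parameters.
#' @examples
#' sched <- mouseDynamicSchedule()
#' cp <- frameAverage(defaultBolus(), sched)
#' truth <- kineticParams(0.005, 0.05, 0.01, 0.001, VB = 0.05)
#' tissue <- modelFrameTAC(truth, cp)
#' fit <- fitCompartmentModel(cp, tissue, seed = 1)
#' @export
fitCompartmentModel <- function(cp, tissue, fixK4 = FALSE, seed = 1L,
                                control = kineticFitControl(),
                                refineInput = TRUE) {
  stopifnot(is(cp, "TimeActivityCurve"), is(tissue, "TimeActivityCurve"))
  if (!isTRUE(all.equal(frameStarts(cp@schedule), frameStarts(tissue@schedule))) ||
      !isTRUE(all.equal(frameDurations(cp@schedule), frameDurations(tissue@schedule))))
    stop("cp and tissue must share the same frame schedule")
  nf <- nFrames(tissue)
  if (nf < 6L) stop("need at least 6 frames to fit 5 parameters")
  if (all(tissue@activity == 0)) {
    return(new("FitResult", params = kineticParams(0, 0, 0, 0, 0), ki = 0,
               rss = 0, nFramesUsed = nf, converged = FALSE,
               se = rep(NA_real_, 5L)))
  }
  prep <- .fitPrep(cp, refine = refineInput)
  w <- sqrt(frameDurations(tissue@schedule))
  obs <- tissue@activity
  rateFloor <- 1e-8
  free <- if (fixK4) c(1:3, 5L) else 1:5
  nfree <- length(free)
  # optimize theta = (log rates, VB); a fixed k4 stays exactly 0
  toTheta <- function(p) c(log(pmax(p[setdiff(free, 5L)], rateFloor)), p[5L])
  toParams <- function(th) {
    v <- numeric(5L)
    v[setdiff(free, 5L)] <- exp(th[-nfree])
    v[5L] <- th[nfree]
    v
  }
  resid <- function(th) w * (.modelFrames(toParams(th), prep) - obs)
  lower <- c(rep(log(rateFloor), nfree - 1L), 0)
  upper <- c(log(control$upper[setdiff(free, 5L)]), control$upper[5L])
  starts <- .withSeed(seed, .lmStarts(control$nStarts, fixK4))
  runLM <- function(th0, iters) {
    tryCatch(suppressWarnings(minpack.lm::nls.lm(
      par = pmin(pmax(th0, lower), upper), fn = resid,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = iters,
                                           ftol = control$ftol))),
      error = function(e) NULL)
  }
  screened <- lapply(seq_len(nrow(starts)),
                     function(i) runLM(toTheta(starts[i, ]),
                                       control$screenIter))
  rssOf <- function(f) if (is.null(f)) Inf else sum(f$fvec^2)
  ord <- order(vapply(screened, rssOf, 0))
  top <- ord[seq_len(min(control$polishTop, length(ord)))]
  fits <- lapply(screened[top], function(f) {
    if (is.null(f)) return(NULL)
    runLM(coef(f), control$maxIter)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all restarts failed")
  rss <- vapply(fits, rssOf, 0)
  best <- which(rss == min(rss))
  if (length(best) > 1L) {            # lexicographic tie-break
    pm <- do.call(rbind, lapply(fits[best], function(f) toParams(coef(f))))
    best <- best[do.call(order, as.data.frame(pm))[1L]]
  }
  fit <- fits[[best]]
  pfull <- toParams(coef(fit))
  pfull[1:4][pfull[1:4] <= 2 * rateFloor] <- 0    # snap floor-bound rates
  params <- kineticParams(pfull[1L], pfull[2L], pfull[3L], pfull[4L], pfull[5L])
  finalRss <- sum(resid(toTheta(pfull))^2)
  se <- rep(NA_real_, 5L)
  dof <- nf - nfree
  if (dof > 0) {
    covm <- tryCatch(solve(fit$hessian) * finalRss / dof,
                     error = function(e) NULL)
    if (!is.null(covm)) {
      d <- diag(covm); d[d < 0] <- NA_real_
      seth <- sqrt(d)
      se[setdiff(free, 5L)] <- seth[-nfree] * pfull[setdiff(free, 5L)]
      se[5L] <- seth[nfree]
    }
  }
  names(se) <- c("K1", "k2", "k3", "k4", "VB")
  new("FitResult", params = params, ki = influxConstant(params),
      rss = finalRss, nFramesUsed = nf,
      converged = fit$info %in% 1:3, se = se)
}

#' @describeIn influxConstant from a fit.
#' @export
setMethod("influxConstant", "FitResult", function(object) object@ki)

setMethod("show", "FitResult", function(object) {
  p <- kineticVector(object@params)
  cat("FitResult (two-tissue compartment model)\n")
  cat(sprintf("  K1=%.4g mL/s/g  k2=%.4g  k3=%.4g  k4=%.4g /s  VB=%.3g\n",
              p[1L], p[2L], p[3L], p[4L], p[5L]))
  cat(sprintf("  Ki=%.4g mL/s/g  weighted RSS=%.4g  frames=%d  converged=%s\n",
              object@ki, object@rss, object@nFramesUsed, object@converged))
})

#' Patlak graphical analysis
#'
#' Ordinary least squares of y(t) = CT(t)/Cp(t) against
#' x(t) = (int_0^t Cp du)/Cp(t) over frames with mid-time >= `tStar`; for an
#' irreversibly trapped tracer (k4 = 0) the asymptotic slope equals
#' Ki = K1*k3/(k2+k3).  Cp and its running integral (with Cp(0) = 0) are
#' evaluated at the frame mid-times from the same frame-average-consistent
#' piecewise-linear input representation the compartment fit uses.
#'
#' @param cp plasma input [TimeActivityCurve-class] (positive over the
#'   linear window).
#' @param tissue tissue [TimeActivityCurve-class], same schedule.
#' @param tStar start of the assumed linear phase, s.
#' @param refineInput see [modelFrameTAC()].
#' @return a [PatlakResult-class].
#' @export
patlakFit <- function(cp, tissue, tStar = 600, refineInput = TRUE) {
  stopifnot(is(cp, "TimeActivityCurve"), is(tissue, "TimeActivityCurve"))
  if (!isTRUE(all.equal(frameStarts(cp@schedule), frameStarts(tissue@schedule))))
    stop("cp and tissue must share the same frame schedule")
  mids <- frameMids(cp@schedule)
  prep <- .fitPrep(cp, refine = refineInput)
  im <- match(mids, prep$tk)
  cpv <- prep$cpk[im]
  cpInt <- prep$cpInt[im]
  use <- mids >= tStar
  if (sum(use) < 3L) stop("need at least 3 frames after tStar")
  if (any(cpv[use] <= 0)) stop("cp must be positive over the linear window")
  x <- cpInt[use] / cpv[use]
  y <- tissue@activity[use] / cpv[use]
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  r2 <- if (stats::var(y) > 0) max(0, 1 - sum(res^2) / sum((y - mean(y))^2)) else 1
  new("PatlakResult", slope = unname(fit$coefficients[2L]),
      intercept = unname(fit$coefficients[1L]), rSquared = r2,
      tStar = tStar, nFramesUsed = as.integer(sum(use)))
}

setMethod("show", "PatlakResult", function(object) {
  cat(sprintf(
    "PatlakResult: slope=%.4g mL/s/g  intercept=%.4g  R^2=%.4f  (t*=%g s, %d frames)\n",
    object@slope, object@intercept, object@rSquared, object@tStar,
    object@nFramesUsed))
})

#' Fit diagnostics
#'
#' Per-frame residuals (model - data, unweighted) and an AIC-style score
#' \code{n*log(RSSw/n) + 2p} based on the weighted residual sum of squares,
#' for comparing e.g. the full model against a k4-frozen one.
#'
#' @param result a [FitResult-class].
#' @param cp plasma input [TimeActivityCurve-class] used in the fit.
#' @param tissue the fitted tissue [TimeActivityCurve-class].
#' @param nParams number of free parameters the fit estimated (5, or 4 for a
#'   k4-frozen fit).
#' @return list with `residuals` (numeric per frame), `rss` (weighted),
#'   `aic`, and `nParams`.
#' @export
goodnessOfFit <- function(result, cp, tissue, nParams = 5L) {
  stopifnot(is(result, "FitResult"))
  pred <- modelFrameTAC(result@params, cp)
  res <- pred@activity - tissue@activity
  w <- frameDurations(tissue@schedule)
  rssw <- sum(w * res^2)
  n <- nFrames(tissue)
  list(residuals = res, rss = rssw, aic = n * log(rssw / n) + 2 * nParams,
       nParams = as.integer(nParams))
}
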