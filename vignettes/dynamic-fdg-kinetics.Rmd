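---
title: "Kinetic analysis of dynamic FDG-PET: models, estimators and validation"
author: "dynFDG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of dynamic FDG-PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynFDG)
```

# The problem

Static FDG-PET reads out a single late-time uptake value (SUV), which is
elevated both in malignant lesions and in inflammatory tissue; inflammatory
false positives are a recognized weakness of SUV-based reading, especially
for lung lesions.  Dynamic acquisition of the full time course of tracer
concentration, together with compartmental modeling against the plasma
input function, yields the net influx constant

$$K_i = \frac{K_1 k_3}{k_2 + k_3} \quad [\mathrm{mL\,s^{-1}\,g^{-1}}],$$

which quantifies the trapping flux of FDG and can separate lesion classes
that SUV cannot.  `dynFDG` implements this analysis end to end for mouse
dynamic PET — forward model, estimators, image operations, statistics — and
ships a synthetic-data generator that emulates a six-group tumor/
inflammation study so the entire pipeline is testable without any
acquisition.

# The two-tissue compartment model

Plasma tracer $C_p(t)$ exchanges with free tissue tracer $C_e(t)$
(rates $K_1$ in, $k_2$ out); hexokinase phosphorylates free tracer into a
trapped pool $C_m(t)$ at rate $k_3$, and glucose-6-phosphatase releases it
at rate $k_4$:

$$\frac{dC_e}{dt} = K_1 C_p - (k_2 + k_3)\,C_e + k_4 C_m, \qquad
\frac{dC_m}{dt} = k_3 C_e - k_4 C_m.$$

The measured tissue signal includes a fractional vascular volume $V_B$:

$$C_T(t) = \bigl[C_e(t) + C_m(t)\bigr] + V_B\,C_p(t).$$

This formulation keeps the tissue term unscaled (no $(1-V_B)$ factor on
$C_e + C_m$); `dynFDG` implements it exactly in this form.  Note that some
of the literature writes the influx constant with $k_2$ in the numerator
due to a typesetting slip; the standard form $K_1 k_3/(k_2+k_3)$ is what
`influxConstant()` computes, with the convention $K_i = 0$ when
$k_2 + k_3 = 0$ (no exchange means no trapping flux).

## Analytic solution

The system is linear, so $C_T$ is a convolution of $C_p$ with a
two-exponential kernel whose rates are

$$\alpha_{1,2} = \frac{(k_2+k_3+k_4) \mp
  \sqrt{(k_2+k_3+k_4)^2 - 4k_2k_4}}{2},$$

real and nonnegative for any nonnegative rate constants (the discriminant
equals $(k_2-k_4)^2 + k_3^2 + 2k_3(k_2+k_4) \ge 0$), and satisfying
$\alpha_1+\alpha_2 = k_2+k_3+k_4$ and $\alpha_1\alpha_2 = k_2k_4$ — two
identities the test suite checks to $10^{-12}$ over $10^4$ random draws.
`computeAlphas()` evaluates the roots in the numerically stable form
$\alpha_1 = k_2k_4/\alpha_2$, which preserves the product identity to
machine precision even when the roots are far apart.

`analyticTissueCurve()` evaluates the convolution *exactly* for a
piecewise-linear representation of $C_p$: on every segment, linear input
times exponential kernel has a closed-form integral (implemented in C++
with `expm1`-based formulas and series fallbacks for small $\alpha\Delta t$,
which also cover $\alpha = 0$, the common irreversible case $k_4 = 0$).
When $\alpha_1 = \alpha_2$ within $10^{-12}$ relative, the confluent-limit
kernel $K_1[(k_3+k_4-\alpha)t + 1]e^{-\alpha t}$ is used.  The same
machinery also propagates the *running time-integral* of the solution, so
frame averages (what PET actually measures) are computed in closed form
rather than by quadrature.

`solveTissueODE()` provides an independent numerical oracle: fixed-step
4th-order Runge-Kutta (via **deSolve**) with a 0.05 s step while the bolus
varies fast ($t < 120$ s) and 0.5 s thereafter.  Analytic and RK4 routes
agree to $10^{-4}$ relative over $[0, 3600]$ s across random parameter
sets — one of the standing acceptance checks.

# Acquisition grid and input function

The default `mouseDynamicSchedule()` is a 29-frame bolus-chasing protocol
(2×1.5 s, 10×0.5 s, 8×5 s, then 20, 30, 75, 120, 150, 400, 600, 750,
900 s) totalling 3093 s.  Two bookkeeping quirks are worth noting: the
protocol is nominally a 60 min acquisition although the printed frames sum
to ~51.5 min, and the "last frame" used for static analysis spans
~36.5–51.5 min rather than a nominal 45–60 min window.  The implementation
trusts the schedule object it is given; the final scheduled frame defines
the static-analysis window.

The plasma input is obtained image-derived: `imageDerivedInput()` averages
a blood-pool (left-ventricle) ROI per frame, and `calibrateToPlasma()`
multiplies each frame by the time-dependent plasma-to-whole-blood ratio

$$R_{PB}(t) = 0.432\,e^{-0.168 t_{\min}} + 1.158,$$

evaluated at the frame mid-time (so results are bit-reproducible); $t$ is
in minutes in this one formula — everywhere else the package works in
seconds.  The ratio was calibrated on blood samples in a different species
context; its validity for mouse plasma is an assumption inherited with the
formula.  No partial-volume or spill-over correction is applied to the
left-ventricle curve.

For simulation, `fengBolus()` provides the standard ramp-plus-
triexponential bolus model.  The defaults in `defaultBolus()` were chosen
once to emulate the study conditions: injection delay 5 s; decay rates
$\lambda = (1, 0.01, 1.7\times 10^{-4})\ \mathrm{s^{-1}}$, i.e. a sharp
(~2 s) tail-vein bolus whose peak at ~6 s falls inside the protocol's
0.5 s-frame window (that is what the rapid early framing is designed to
sample), a minute-scale clearance phase, and a slow washout; and the peak
plasma concentration `dose/peakVolume` with 5.55 MBq distributed over
1.7 mL (mouse blood volume scale), about 3.3 MBq/mL.

# Estimators

## Weighted nonlinear least squares

`fitCompartmentModel()` minimizes
$\sum_f w_f\,(C_T^{\mathrm{model}}(f) - \mathrm{tissue}_f)^2$ with
$w_f = \mathrm{duration}_f$ (longer frames average more counts and carry
lower variance) using Levenberg-Marquardt (**minpack.lm**) on
$(\log K_1, \log k_2, \log k_3, \log k_4, V_B)$.  The log scale matters:
group-level rate constants span four orders of magnitude, and
linear-scale steps condition badly across that range.  Bounds are a
$10^{-8}$ floor on the rates (snapped to exact zero in the result) with
upper bounds $(5,5,5,5,0.999)$.

Model frame values are computed exactly: the plasma TAC is represented
piecewise-linearly with knot values *refined* so that the interpolant's
own frame averages reproduce the measured frame values (a PET frame value
is a time average, not a point sample — naive interpolation through frame
mid-times systematically underestimates a sharp bolus).  The refinement
solves the small linear system mapping knot values to frame averages and
clamps at zero; the residual mismatch is confined to the near-zero bolus
arrival frames, where the nonnegative piecewise-linear family cannot
represent the averages exactly.

Because the surface is multimodal, the fit is multi-start: four fixed
starts at typical FDG kinetic regimes (slow exchange, high flow,
fast turnover, avid trapping) plus seeded Latin-hypercube draws in
log-parameter space, screened with a few LM iterations, the best
candidates polished to convergence (`kineticFitControl()` exposes all of
this).  Ties between restarts break by lowest weighted RSS, then by the
lexicographically smallest parameter vector; the fit is deterministic
given data, control settings and seed.  $k_4$ is always fitted by default —
the emulated study observed significantly non-zero dephosphorylation — and
`fixK4 = TRUE` gives the irreversible, Patlak-comparable variant.

Approximate standard errors come from the final Jacobian
($J^TJ$ scaled by $\mathrm{RSS}/(n-p)$, delta-method-transformed from the
log scale).  `goodnessOfFit()` reports per-frame residuals and an
AIC-style score $n\log(\mathrm{RSS}_w/n) + 2p$ for comparing the free-$k_4$
and frozen-$k_4$ models.

## Patlak graphical analysis

`patlakFit()` regresses $C_T(t)/C_p(t)$ on
$\int_0^t C_p\,du \,/\, C_p(t)$ over frames with mid-time $\ge t^*$
(default 600 s; by then the transient $e^{-(k_2+k_3)t}$ has decayed for
every shipped preset, the slowest having $k_2+k_3 = 0.0136\ \mathrm{s^{-1}}$).
$C_p$ and its running integral are evaluated from the same
frame-average-consistent input representation the compartment fit uses.
For $k_4 = 0$ the slope estimates $K_i$ (validated to 1 % against
$K_1k_3/(k_2+k_3)$ for all six presets); for $k_4 > 0$ Patlak
systematically underestimates it, which the tests assert rather than hide.

# Image operations

Volumes are dense 4D arrays (frame, z, y, x) of MBq/mL with mm voxel
sizes; NIfTI I/O carries the frame schedule in a JSON sidecar since NIfTI
has no native frame-timing field.  Voxel indices are 1-based in R; a voxel
center sits at $(i - 0.5)\cdot\mathrm{voxelSize}$.

`ellipsoidROI()` emulates a manually drawn 3D ellipsoid ROI (all voxels
whose centers satisfy the ellipsoid inequality in mm space).
`regionGrowRefine()` implements the refinement used before TAC extraction:
on a duration-weighted time-averaged image (window = last frame by
default), take the mean $m$ over the manual ROI, fix the acceptance band
$[0.6m, 1.4m]$ (±40 %), and grow by 6-neighbor face connectivity from the
ROI's hottest voxel.  The band is deliberately *not* recomputed during
growth: the iterative variant has no published recurrence and is unstable.
Whether the ±40 % band should reference the manual or the refined ROI mean
is ambiguous in the source procedure; the manual-ROI mean is used, and the
choice is configurable via the `band` argument.  A seed falling outside
its own band returns the seed alone with a warning.

`computeSUV()` is concentration divided by injected dose per body weight;
`suvmaxStatic()` evaluates it voxelwise on the final frame and records the
ROI mean and maximum (SUVmax).

# The synthetic-data generator

`groupPresets()` ships six groups with the emulated study's group-mean
rate constants and sizes (n = 5, 5, 4, 4, 9, 6): subcutaneous tumor,
in-situ (lung) tumor, subcutaneous inflammation with/without tumor,
in-situ inflammation, spontaneous liver inflammation.  $V_B = 0.05$ for
all presets (a typical lesion vascular fraction; the group tables report
no $V_B$ value).  One inherited inconsistency is documented rather than
resolved: applying $K_1k_3/(k_2+k_3)$ to the group-mean rate constants
does not reproduce the published group-mean $K_i$ (per-animal values were
averaged, and those are unpublished), so printed group-mean $K_i$ values
are never used as numeric oracles; similarly the spontaneous-liver mean
$K_i$ is printed inconsistently between table and text (0.0033 vs 0.033).

Between-subject variability is mean-preserving log-normal jitter per rate
constant with CV 30 % — rate constants are positive, only group means are
published, and log-normal is the minimal positive-support choice; the CV
is configurable.  Measurement noise is Gaussian, proportional to the
signal, scaled by $1/\sqrt{\mathrm{duration}/5\,\mathrm{s}}$ (5 s is the
protocol's median frame length), clipped at zero.  All randomness flows
from one explicit seed through `set.seed`-scoped blocks; the global RNG
stream is left untouched.

`simulateSubjectTACs()` drives the forward model with the *frame-sampled*
plasma input — the same representation the estimator uses — so the
generator is an exact oracle for the fit: at zero noise and zero jitter
the tissue TAC equals `modelFrameTAC()` bit for bit, and noisy-recovery
studies isolate estimation error from input-representation error.  What
this deliberately does **not** emulate is the bias from sampling a
continuous physiological input on frames; that effect is exercised
separately by `buildPhantom()`, whose regions are painted from the
continuous bolus (lesions via the analytic model; the blood pool with the
whole-blood curve, i.e. plasma divided by $R_{PB}$ at frame mid-times, so
the calibration step is non-trivially inverted), plus a low-uptake
background ($K_1 = 2\times10^{-4}$, $k_2 = 0.01$, $k_3 = 10^{-4}$,
$k_4 = 0$, $V_B = 0.02$).  The default phantom is a 64³ grid of 0.5 mm
voxels.  Real-scanner physics — attenuation, scatter, randoms, decay,
reconstruction artifacts, motion — is out of scope, so passing tests
validate the analysis chain, not scanner robustness.

# Statistics

`kruskalWallis()` is the omnibus comparison (tie-corrected H; chi-square
p via `stats::kruskal.test`, or an exact permutation p enumerating all
label assignments for pooled $N \le 10$).  `posthocPairwise()` implements
Dunn's z from pooled mid-ranks with tie correction; Holm adjustment by
default, Bonferroni and unadjusted as options — the emulated study cites
only "post-hoc multiple pairwise comparisons", so the concrete choice is
this package's, not an inference about the original procedure.  Alpha is
0.05.  `metricCorrelation()` gives Pearson $R^2$ with a two-sided p for
metric pairs such as SUVmax vs $K_i$.  `runGroupAnalysis()` assembles the
study's comparison layout (lesions within a location; a lesion type across
locations) with group summaries, omnibus tests, and post-hoc tables when
the omnibus is significant.

# Validation problem sizes

The shipped acceptance checks use: 100 random parameter sets for the
analytic/RK4 equivalence; $10^4$ draws for the eigenrate identities; all
six presets for Patlak consistency (1 % tolerance); 200 simulated subjects
per preset per noise level (5 %, 2 %, 0.5 %) for $K_i$ recovery; one 64³
zero-noise phantom for the full image pipeline round trip (1 % tolerance
on $K_i$); 2000 null simulations at the study's group sizes for the
omnibus type-I error; and 100 seeded study replicates for the in-situ
contrast rates.

# Known limitations

* **$K_i$ identifiability collapses for second-scale $k_4$.**  Two of the
  shipped presets (in-situ inflammation, $k_4 = 0.56\ \mathrm{s^{-1}}$;
  spontaneous liver, $k_4 = 0.418\ \mathrm{s^{-1}}$) have their slowest
  tissue eigenmode at seconds ($\alpha_1 = k_2k_4/\alpha_2 \approx
  0.27\ \mathrm{s^{-1}}$ for the former): the model is effectively fully
  reversible on the scan timescale and the trapping flux leaves almost no
  imprint on the curve.  Quantitatively, forcing $k_3 = 0$ ($K_i = 0$) on
  a *noiseless* in-situ-inflammation subject costs only $\Delta\chi^2
  \approx 0.11$ at the 5 % noise level — the whole scan carries well under
  one standard deviation of information about $K_i$.  Consequently fitted
  $K_i$ for such groups scatters over orders of magnitude at realistic
  noise regardless of optimizer, weighting or starts, per-group recovery
  medians do not shrink with noise there, and the in-situ
  tumor-vs-inflammation contrast on *fitted* $K_i$ is usually
  non-significant even though the contrast on the *true* subject $K_i$
  values separates almost surely.  (Biologically, dephosphorylation
  half-lives of ~1-2 s are implausible — literature $k_4$ is of order
  $10^{-4}\ \mathrm{s^{-1}}$ — but the preset values are used verbatim as
  the emulated study conditions.)  The package reports what the data
  support; it does not regularize $K_i$ toward identifiability.
* The $\pm 40\%$ region-growing band uses a fixed band from the manual
  ROI; lesions with strong internal gradients may be truncated.
* The exact-permutation omnibus enumerates label assignments and is
  limited to small pooled samples (default $N \le 10$).
* The input-knot refinement is a deconvolution-type step; on very noisy
  measured input curves it can amplify noise (simulated inputs here are
  noiseless; for real data inspect the refined curve or disable
  refinement).
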