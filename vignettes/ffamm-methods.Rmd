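---
title: "Methods: glucose/FFA minimal models across IM-FSIGT and meal tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glucose/FFA minimal models across IM-FSIGT and meal tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the modelling, numerical and design choices
behind `ffamm`: what the models assume, how the weighted fitting is
set up, what the synthetic-subject generator does and does not
emulate, and where the package had to make a call that the underlying
methodology leaves open.

## Models and assumptions

All three model variants treat measured plasma insulin as an external
input rather than a state: insulin secretion, glucagon and hepatic
glucose output are deliberately absorbed into a handful of
phenomenological parameters, which is what makes per-subject fitting
tractable.  Between samples the insulin record is interpolated
linearly; outside the sampled window it is clamped to the nearest
sample value.  Clamping matters because MOD 3 looks up insulin at
delayed times `t − t_Delay`, which can precede the first sample; a
shifted lookup into the measured record (rather than a
delay-differential state) keeps integration ordinary.

MOD 1 and MOD 2 share the minimal-model glucose equation and the
remote insulin-action compartment `X`, which lags plasma insulin with
rate `C_x` and acts on glucose disposal (`S_I`), on lipolysis
suppression (Hill function with half-point `X_2`) and — in MOD 1 only —
on FFA clearance activation (half-point `K_Cl`).  The MOD 1 clearance
factor is bounded between `C_f` and `2 C_f` by construction, encoding
the assumption that insulin can at most double basal FFA removal.
`I_bx` is the action-threshold insulin: it is fitted, and need not
equal measured basal insulin.  Hill exponents are fixed at 2
(`A_lipo`, `A_Cl`) in MOD 1; MOD 2 frees its lipolysis exponent.
Model outputs are insensitive to these exponents, which is why fixing
them is harmless and why, when freed, they are expected to be flagged
by the identifiability guard (below).

Units throughout: glucose mg/dL, insulin uU/mL, time min.  FFA units
are whatever the assay reports; mmol/L is assumed in the
documentation.  Ra functions return concentration/min and are added
directly to the derivatives — the magnitude factors `Delta_G`,
`Delta_F`, `phi_G` are phenomenological and absorb any
distribution-volume scaling.

The Type I (log-normal-like) Ra is zero at `t = 0` (and up to the
60-min chylomicron lag for FFA) and continuous there, so no smoothing
is applied at the breakpoints.  Its total area is `Delta * sqrt(2*pi)`
and its peak sits at `m * exp(-sigma^2)`; the Type II form integrates
to `phi_G` exactly and peaks at `tau_G`.  These closed forms are the
oracles for the quadrature tests.  Hill terms clamp their argument at
zero before exponentiation: adaptive solvers probe transient states
where `X` dips infinitesimally below zero, and non-integer exponents
would otherwise produce complex values.

## Protocols, initial conditions, integration

The IM-FSIGT is fitted over [10, 180] min only.  The initial glucose
and FFA are the averages of the 0–8 min samples — the [0, 10) window
is used, not [0, 10], so the t = 10 sample remains an ordinary fitted
datum rather than entering twice.  The −10 and −1 min draws feed only
basal summaries (e.g. the AIRg basal level).  The meal test is fitted
over the whole [0, 360] window with initial values taken directly
from the t = 0 samples.  Insulin action starts at zero in both
protocols.

Integration uses `deSolve::lsoda` (stiff-capable, adaptive) with
relative and absolute tolerances `1e-8`, with the right-hand sides
compiled in C and insulin supplied as a forcing function; a pure-R
reference implementation of each right-hand side is exported and the
test suite checks that the two engines agree to `1e-6` relative.
Trajectories are reported on a 1-min grid (or at caller-supplied
times, e.g. the protocol sample times during fitting — the output grid
does not affect solver accuracy).

## Weighted objective and variance estimation

Residuals are summed over the glucose and FFA channels of each active
protocol at the fitted sample times and weighted by one variance per
(protocol, channel) pair.  That variance is estimated from the raw
series alone: the series is smoothed by singular spectrum analysis
with only the leading eigentriple retained (Hankel embedding, SVD,
anti-diagonal averaging) and the plain mean squared deviation from
that trend — no degrees-of-freedom correction — is the variance.  The
SSA window length is not prescribed by the methodology; the package
default is `floor(n/2)`, standard practice for trend extraction, and
it is configurable.  A floor of `(0.01 * channel mean)^2` keeps
noiseless synthetic channels from receiving infinite weight.

## Optimisation

`fit_subject()` minimises the weighted residuals with bounded
Levenberg-Marquardt (`minpack.lm::nls.lm`, objective tolerance
`1e-10`), which exploits the least-squares structure and converges in
tens of iterations where a generic quasi-Newton method needs
thousands of function evaluations.  Three numerical choices matter:

* **Scaling.**  Parameters span six orders of magnitude (`S_I ~ 1e-4`
  vs `G_b ~ 1e2`), so optimisation runs on parameters divided by their
  reference group means.
* **Finite-difference step.**  The default Jacobian step
  (`sqrt(machine eps)`) sits at the ODE solver's noise floor and
  produces garbage gradients that stall the optimiser far from the
  optimum.  The package sets `epsfcn = 1e-6` (relative steps around
  `1e-3`), well above solver noise and well below parameter scale.
* **Bounds.**  Lower bounds are zero for magnitude parameters; scale
  parameters that appear in denominators (`X_2`, `K_Cl`, `sigma_G`,
  `tau_G`, `m_G`, `K_Lip`, `K_Rem`, `sigma_F`) are bounded below at
  `1e-3` of their reference mean, because an exact zero produces `0/0`
  in the Hill terms when the optimiser probes the boundary.  Upper
  bounds are five times the reference group means (configurable), with
  insulin delays additionally capped at 180 min.

Starts default to the reference means plus 0.5x and 1.5x
perturbations; the original single-start procedure is not reproducible
from its description, so a small deterministic multi-start is the
documented substitute (explicit start vectors and seeded jitter are
available).  Integration failures inside the objective return a large
finite penalty (`1e12`) so the optimiser can retreat.  After
convergence, an identifiability guard perturbs each parameter by
±10 % and flags those that change the objective by less than `1e-6`
rather than silently reporting them.

A known behaviour worth stating: on a noiseless joint FSIGT+MT subject
fitted with *unit* variances, glucose residuals (mg/dL scale) dominate
FFA residuals (mmol/L scale) by five orders of magnitude in the sum of
squares.  Glucose-side parameters and the Ra parameters are then
recovered essentially exactly, while FFA-side parameters (`l_0`,
`X_2`, `C_f`, `K_Cl`) can settle in a flat valley and be recovered
only approximately; the guard flags them.  With SSA-estimated (or
true-noise) variances the channels are weighted comparably and this
asymmetry disappears.

## Model comparison and indices

The methodology behind the BIC/RMSE comparison tables does not state
its exact formulas, so the package documents its own: BIC is the
weighted residual sum (a Gaussian deviance with known variances) plus
`k log n` over free parameters only, and RMSE is
`sqrt(mean(resid^2/sigma2))` per (protocol, channel), so that the
objective decomposes exactly into `sum n * RMSE^2`.  These are
internally consistent but not necessarily numerically identical to
published tables, which is why no published BIC/RMSE value is used as
a test oracle.  AIRg is the trapezoidal incremental insulin area over
[0, 10] min above the mean of the −10/−1 min samples, clipped at zero;
the disposition index is `AIRg * S_I`.

## Ra back-calculation

Rearranging the glucose equation gives the appearance flux from data:
`Ra(t) = dG/dt − S_G G_b + (S_G + S_I X(t)) G(t)`, with `G` and
`dG/dt` from a cubic spline through the 13 meal samples on a 1-min
grid and `X` from a model simulation.  The derivative is taken
analytically from the spline, not by differencing.  End conditions
were a genuinely open choice: natural boundaries force zero curvature
at t = 0, precisely where the meal Ra ramps fastest, and roughly
double the boundary error; the package therefore uses
Forsythe–Malcolm–Moler end conditions (the exact cubic through the
four points nearest each end, R's `splinefun` default).  In the
closed-loop test — simulate the AA-C3 fixture, sample at the 13 meal
times, back-calculate — the maximum error stays within 15 % of the
true Ra peak and the AUC within 10 %.  No positivity constraint is
applied: negative excursions around 30–60 min are a known artifact of
30-min sampling and are reported as-is.

## Synthetic subjects

The generator exists so that every pipeline stage is testable without
subject data.  It emulates: the exact sampling schedules; an FSIGT
insulin excursion with basal level, endogenous first-phase peak
(default 10x basal, peaking ~3 min) and a larger exogenous spike after
the 20-min bolus; a monophasic meal insulin excursion (default 5x
basal, peaking ~40 min, relaxed by 360 min); glucose and FFA generated
by the fixture's own model; and independent multiplicative Gaussian
noise (default assay-like CVs of a few percent) applied only at sample
times, never inside the integration.  Shape defaults were chosen once
on physiological grounds (insulin assays put basal near 5 uU/mL;
first-phase FSIGT peaks are an order of magnitude above basal; meal
insulin is a few-fold above basal).

It does *not* emulate: endogenous insulin-glucose feedback (insulin is
an open-loop input); multiphasic meal glucose responses; assay
artifacts beyond i.i.d. multiplicative noise; demographic covariates.
Passing round-trip tests therefore shows that the estimator inverts
the model correctly under the stated noise model — not that the model
is adequate for any particular real population.

Two details keep the round trip exact.  The FSIGT trajectory is
generated from t = 10 with `X(10) = 0` and the 0–8 min samples are
reported at the initial values (a post-bolus mixing plateau), so the
protocol's averaging convention returns exactly the generating state.
And the generator drives the model with the insulin series *sampled at
the protocol times* (then interpolated), exactly as the fitter does —
driving it with a continuous shape would leave an interpolation
mismatch that no parameter set could close.  The FSIGT post-bolus
glucose starts at 250 mg/dL, a typical value after a 0.3 g/kg dextrose
bolus.  Fixture steady-state FFA ((l_0 + l_2)/C_f = 2.7 mmol/L for
AA-C3) is higher than typical fasting FFA because group-mean
parameters do not satisfy group-mean steady states; the fixtures are
used as self-consistent generating values, not as physiological
claims.

When noise is added, the stored per-channel variances are the true
mean noise variances `mean((cv * y_true)^2)` — one scalar per channel,
consistent with the scalar-variance weighting; with `noise_cv = 0`
they are unit.

## Problem sizes in the test suite

The suite favours a few deep checks over many shallow ones: the SSA
noise-recovery Monte Carlo uses 200 draws of length-32 series; the
noise-CV calibration check uses 200 replicate subjects; the stochastic
robustness experiment fits 20 replicate subjects at 5 % noise
(median relative error of `S_I` is the summary, since single noisy
subjects scatter); the recovery experiments use one noiseless subject
per fixture.  These sizes give stable medians while keeping the whole
suite in a few minutes of CPU.

## Known limitations

* The Type I Ra is monophasic by construction and cannot represent
  multiphasic meal glucose responses; fits to such subjects push the
  Ra parameters toward degenerate shapes.
* `sigma2` is a single scalar per channel; heteroscedastic noise within
  a channel (e.g. proportional error) is only captured on average.
* BIC comparisons across models are only meaningful when the fitted
  channels coincide: MOD 3 fits FFA alone and its BIC is not
  comparable with MOD 1/2.
* Bounded Levenberg-Marquardt gives local optima; the multi-start set
  mitigates but does not remove this, and `fit_subject()` reports
  which start won so users can widen the set when results look
  start-dependent.
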