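---
title: "Models and methods behind chitkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chitkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chitkin)
```

chitkin analyses plate-reader kinetics of chitinases measured on two very
different substrate classes: soluble fluorogenic oligomers
(4-methylumbelliferyl chitobioside/chitotrioside) and insoluble colloidal
chitin read out by scattering, an endpoint ferricyanide reduction, or a
one-pot chitooligosaccharide-oxidase/peroxidase (chitO) coupled
fluorescence assay. All four assay chemistries funnel into one statistical
pipeline: calibrate, fit progress curves, extract initial rates, fit the
Michaelis–Menten curve, and propagate uncertainty into $k_{cat}/K_m$.

## The relaxation model for progress curves

A progress curve is modelled as a sum of exponential approaches to an
asymptote plus an optional linear term and a background:

$$\mathrm{signal}(t) \;=\; \sum_i A_i\,\bigl(1 - e^{-k_{1,i} t}\bigr)
\;+\; m\,t \;+\; B,$$

where $A_i$ is an asymptotic amplitude (negative for loss-of-signal
assays — scattering and absorbance fall as substrate clears; one code path
handles both directions), $k_{1,i}$ a relaxation rate constant
($k_{1,i} > 0$ enforced by bounds), $m$ a drift/pseudo-zeroth-order slope
and $B$ the background. The initial rate is the model derivative at
$t = 0$,

$$v_0 = \sum_i A_i k_{1,i} + m,$$

which is converted to concentration per second through the standard-curve
slope alone (the intercept cancels under $d/dt$).

This is a phenomenological description, not a mechanistic one: a single
exponential is exact only in the pseudo-first-order limit
$S_0 \ll K_m$. Its virtue is that $v_0$ is read from the fitted model at
$t = 0$ rather than from a hand-chosen "linear window", which matters when
curvature sets in early at low substrate. On noiseless simulated
integrated-Michaelis–Menten curves with $S_0 \le K_m/10$ the fitted $v_0$
is within 5% of the analytic $V_{max} S_0/(K_m + S_0)$ (asserted in the
test suite).

### Fitting and numerical choices

* **Optimizer.** Levenberg–Marquardt (`minpack.lm::nls.lm`) with analytic
  Jacobians, `ftol = 1e-12`, `ptol = 1e-10`.
* **Initialization.** $B_0$ = first signal, $A_0$ = last − first,
  $k_{1,0} = 2/t_{1/2}$ where $t_{1/2}$ is the time the signal crosses
  the midpoint; a deterministic multi-start over
  $k_{1,0} \times \{0.2, 1, 5\}$ takes the lowest SSE, so fits are
  reproducible from data alone. Exponential fits are
  initialization-sensitive; this rule plus the multi-start removed that
  sensitivity in practice.
* **Ridge plateaus.** A nearly linear curve drives the single-exponential
  fit along the benign ridge $k_1 \to 0$, $A \to \infty$ with $A k_1$
  (the quantity of interest) fixed. LM then exhausts its iteration budget
  without meeting `ftol`/`ptol`. Runs whose SSE trace has plateaued
  (relative improvement below $10^{-6}$ over the last five iterations)
  are accepted as converged; anything else is flagged `nonconvergence`.
* **Covariance.** $s^2 (J^\top J)^{-1}$ computed through the SVD of $J$;
  near-null directions (singular values below $10^{-10}$ of the largest)
  are dropped pseudo-inverse style and the fit flagged
  `singular_covariance`. Along the degenerate directions of extended
  models the well-determined combination — $v_0$ — keeps a finite,
  meaningful standard error.
* **Rate-indeterminate wells.** If $|v_0| \le 3\,\mathrm{SE}(v_0)$ (or the
  SE is unavailable) the well is flagged `rate_indeterminate`: flat wells
  (no enzyme, dead mutants) land here by construction.

### Residual structure and automatic model extension

A single relaxation step is usually enough. Lack of fit is diagnosed with
a one-sided Wald–Wolfowitz runs test on residual signs: too few runs means
blocked residuals, i.e. systematic misfit. The null distribution is
computed exactly (conditional on the numbers of positive and negative
residuals) up to 30 signed residuals and by a continuity-corrected normal
approximation above; fewer than 8 signed residuals is inconclusive and
reported unstructured. The default threshold $p < 0.01$ is a package
choice, exposed as `p_threshold`. Worth knowing: short blocked patterns
are *not* significant under the exact null — three runs in twelve signs
has $p = 12/495 \approx 0.024$ — so the diagnostic is deliberately
conservative on short reads, while 1000-point overnight reads make it
sensitive to small real misfit.

`auto_fit()` starts with one component and, while residuals are
structured, extends the model: a linear term is tried first when the tail
of the curve is still rising steadily with low curvature (the
pseudo-zeroth-order regime of substrate excess — a judgement call, since
"pseudo-first-order" extensions could equally be read as additional
exponentials; we treat near-constant-velocity segments as the linear
case), otherwise a second exponential is added. The first unstructured fit
wins. If nothing resolves the structure, the best-AICc fit is returned
flagged, with a parsimony tie-break: the smallest model within 2 AICc
units of the minimum. The tie-break exists because on long reads an
overparameterized extension can shave AICc marginally while splitting the
initial slope between degenerate terms and corrupting $v_0$.

## Calibration

Standards are fit by unweighted OLS of signal on concentration,
restricted to each assay's linear range: 50 µM (free 4MU), 0.5 % w/v
(OD680 scattering), 250 µM (ferricyanide A420), 30 µM (chitO). The
boundary is inclusive — "below X" with X printed to one or two significant
figures cannot distinguish inclusive from exclusive, so the inclusive
convention is fixed and documented. The intercept is left free (whether
the source protocols pinned it to the blank is unstated); rates use the
slope only, so the choice does not propagate into kinetics.

## Michaelis–Menten estimation and error propagation

Initial rates across the substrate dilution are pooled — replicate wells
enter as individual points, never pre-averaged — and fit by unweighted
nonlinear least squares to $v = V_{max} S/(K_m + S)$ with positivity
bounds, again profile-started LM with a deterministic multi-start on
$K_m$. Rates are first normalized per enzyme: each well's rate is divided
by its own enzyme concentration (expressed in the product-concentration
unit), so $V_{max}$ of the normalized fit *is* $k_{cat}$ and
mixed-enzyme-concentration plates need no special casing.

The catalytic efficiency carries a delta-method SD that keeps the
$(V_{max}, K_m)$ covariance:

$$\frac{\mathrm{Var}(k_{cat}/K_m)}{(k_{cat}/K_m)^2} =
\frac{\mathrm{Var}(V_{max})}{V_{max}^2} +
\frac{\mathrm{Var}(K_m)}{K_m^2} -
\frac{2\,\mathrm{Cov}(V_{max}, K_m)}{V_{max} K_m}.$$

The covariance term matters: $V_{max}$ and $K_m$ estimates from a
saturation curve are strongly positively correlated, and ignoring the
cross term would overstate the efficiency error; in the perfect-correlation
limit with equal relative errors the ratio is error-free and the formula
returns exactly zero. The delta-method SD agrees with $10^6$-draw
Monte-Carlo propagation within 5% for coefficients of variation up to
about 20% (tested); beyond that the ratio distribution grows skewed and a
single SD is a blunt summary regardless of how it is computed.

When every measured concentration sits far below the fitted $K_m$
(max $S < K_m/5$), $V_{max}$ and $K_m$ are only jointly identified; the
fit is flagged `km_unidentifiable` and only the slope $V_{max}/K_m$ should
be quoted.

Construct comparisons use ratios reported to 2 significant figures with a
two-sided $z$ test on the difference,
$z = (m - w)/\sqrt{se_m^2 + se_w^2}$ — the source tables report $p$-values
without naming a test, so this is an interpretation, documented as such.

## Units

Oligomer kinetics use µM (or mM); bulk chitin uses % w/v, a suspension
mass concentration. The two meet through the infinite-polymer
approximation of one binding site per N-acetylglucosamine unit
(203.21 g/mol): `percent_wv_to_monomer_mM()` maps 1 % w/v to
$10/0.20321 \approx 49.2$ mM monomer. Pipelines carry a substrate unit
(the $K_m$ axis) and a product unit (the calibrated signal axis)
separately, because the coupled and ferricyanide assays calibrate product
in µM of chitobioside equivalents while the substrate axis stays in
% w/v; $k_{cat} = V_{max}/[E]$ is formed with $[E]$ expressed in the
product unit.

## The simulator: what it emulates, and what it does not

The generator produces whole synthetic plates from known
$(k_{cat}, K_m)$: substrate depletion follows the integrated
Michaelis–Menten equation

$$K_m \ln(S_0/S) + (S_0 - S) = V_{max}\,t,$$

solved in closed form as $S(t) = K_m\,W\!\bigl((S_0/K_m)\,
e^{(S_0 - V_{max} t)/K_m}\bigr)$ with the Lambert $W$ principal branch.
$W(e^y)$ is evaluated on the log-scale argument $y$ (Newton on
$w + \ln w = y$, with $W(e^y) = e^y$ for $y \le -36$), which stays finite
where $e^y$ overflows ($S_0 \gg K_m$). The closed form agrees with stiff
ODE integration to $10^{-9}$ relative across $S_0 \in [K_m/100,\,
100\,K_m]$ (tested against `deSolve`).

Product $P = S_0 - S$ maps to signal per assay mode: gain
($\mathrm{gain}\cdot P + B$), loss ($B + \mathrm{gain}\cdot S$), or
coupled gain with a linear background drift emulating the slowly rising
chitinase-free signal of washed colloidal chitin. Noise is additive
i.i.d. Gaussian applied last — the simplest model consistent with the
unweighted least squares used downstream; real reader noise is partly
multiplicative and correlated, so passing recovery tests here demonstrates
correctness of the estimators under the stated model, not robustness to
every instrument pathology. No attempt is made to model chitin
crystallinity, decrystallization, processivity, enzyme clustering,
photobleaching or inner-filter effects; % w/v is treated as a well-mixed
pseudo-concentration obeying Michaelis–Menten kinetics, which is exactly
the approximation under which the bulk assays are analysed.

### Canonical scenarios (the simulated study conditions)

`simulate_assay_plate()` fixes one set of operating conditions per assay:

| assay | enzyme | substrate series | reads | reference truth |
|---|---|---|---|---|
| four_mu | 10 nM | 480…3.75 µM (halving, 8) | 30 s × 30 min | 1.5 /s, 33 µM |
| clearance | 100 nM | 2…0.0156 % w/v | 20 min × 72 h | 0.0014 /s, 0.09 % w/v |
| ferricyanide | 10 nM | 0.4…0.0031 % w/v | 10 min reads, 18 h incubation | 0.454 /s, 0.046 % w/v |
| chito | 2 nM | 2…0.0156 % w/v | 1 min × 16 h | 1.0 /s, 0.032 % w/v |

Three replicate wells per concentration (screens were confirmed in
triplicate; per-condition replicate counts are otherwise unreported, so 3
is the package default, exposed as `n_replicates`). `noise_frac` anchors
the noise SD to the enzyme-dependent amplitude of the $S_0 = K_m$ curve;
0.05 is the "5% noise" condition used by the recovery tests. These sizes
keep a full four-assay validation run in tens of seconds on one core
while leaving each fit comfortably overdetermined.

## Known limitations

* **Endpoint noise floor.** The ferricyanide rate is
  $(\max - \min)/t_{inc}$ over the read window. The range of a noisy
  series never falls below the noise range, so low-substrate rates are
  inflated at high noise and the fitted $K_m$ is dragged *down*; at
  instrument-realistic A420 noise (∼5 mAU) the bias is negligible, and
  the test suite asserts both the good-noise recovery and the direction
  of the high-noise bias. Progress-curve analysis of the ferricyanide
  read window is deliberately not attempted (the endpoint difference is
  the prescribed, more robust measure).
* **Pseudo-first-order approximation.** At $S_0 = K_m/10$ the
  single-exponential surrogate for the integrated MM curve deviates from
  the true product curve by up to ≈2.5% of $S_0$ (oracle-computed); the
  deviation shrinks another order of magnitude by $S_0 = K_m/100$.
* **Coverage.** Unweighted-fit standard errors are honest but
  approximate: across seeded replicates the 1-SE interval for $K_m$
  covers the truth at roughly the Gaussian 68% (tested to lie between
  55% and 80%).
* **Dead-well rates.** The $t=0$ derivative of an exponential fit to
  flat noise can be wild; screen activities therefore fall back to the
  linear-model slope whenever a well is rate-indeterminate.
* **Fit window.** All time points are used by default (whether source
  analyses truncated long reads is unstated); pass a truncated
  `progress_curve` to impose a window.

## Screen normalization

Screening wells report the product of specific activity, expression and
secretion, and drift between plates; scores are therefore normalized
strictly per plate against on-plate controls:
$\mathrm{score} = (a - \overline{a}_{neg})/(\overline{a}_{pos} -
\overline{a}_{neg})$, mapping the catalytically dead control to 0 and
wild type to 1. A mutant with 5× wild-type specific activity at equal
expression scores ≈5 at the screening substrate concentration (simulated
and tested end to end).

Screen scores are rate *ratios*, so they are only meaningful while every
well is still in its initial-rate regime. The simulated screen therefore
uses 2 nM secreted enzyme with 10-s reads over 30 min: wild type turns
over ~12% of the 10.8 µM screening substrate and a 5× hit ~48%, keeping
the fitted $v_0$ of both within ~1% of truth. At several-fold higher
enzyme a strong hit exhausts the substrate mid-read, its progress curve
degenerates to a ramp-then-plateau for which the single-exponential
$v_0$ is biased upward (of order +10% under noise in our simulations),
and hit scores inflate — a screen-design caveat, not a property of the
normalization.
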