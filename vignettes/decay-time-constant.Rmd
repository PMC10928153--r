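---
title: "Methods: the diastolic decay time constant from pressure features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the diastolic decay time constant from pressure features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wktau)
```

## The model

The package works in the two-element Windkessel (WK2) world: the whole
arterial tree is lumped into one compliance $C$ (mL/mmHg) storing volume in
parallel with one resistance $R$ (mmHg·s/mL) draining it, driven by the
ventricular outflow $Q(t)$:

$$C\,\frac{dP}{dt} = Q(t) - \frac{P}{R}.$$

Once ejection ends ($Q = 0$), pressure relaxes exponentially with the time
constant $\tau = RC$ — in WK2 this is not an approximation but the exact
diastolic solution, which is what makes the model the natural ground-truth
generator for studying $\tau$ estimators.

Three standard relations connect $\tau$ to routine pressure features. The
total compliance is approximately proportional to the stroke volume per
unit central pulse pressure, $C = k\,SV/cPP$; resistance is mean pressure
over cardiac output, $R = MBP/CO$; and $CO = SV/T$ with $T$ the heart
period in seconds. Chaining them, the stroke volume cancels:

$$\tau = k'\,T\,\frac{MBP}{cPP},$$

and subject-by-subject the dimensionless coefficient is exactly
$k' = C\,cPP/SV$ (when heart rate in beats/min replaces $T$, tabulated
coefficients are 60-fold larger). The package's central empirical question
is how stable a *single* population-level $k'$ is, and how well the fixed
coefficient predicts $\tau$ out of sample.

Because $dP/dt \le Q/C$ pointwise, the pulse pressure can never exceed
$SV/C$, so $k' \le 1$ always, with equality only in the limit of an
instantaneous (bolus) ejection. Physiological ejection times put $k'$ in
the 0.45–0.75 range; the origin-constrained fit over the default cohort
lands near 0.67.

## Assumptions, and what a green test does not establish

The synthetic cohorts are WK2 subjects with parametric (half-sine or
triangular) ejection waves. The generator deliberately omits:

- wave propagation and reflection (no pulse-wave velocity, no augmentation
  of central pressure by reflected waves);
- arterial geometry (no segment lengths or diameters; the brachial pulse
  pressure is a scalar amplification of the central one);
- pressure-dependent (nonlinear) compliance and a characteristic impedance
  (no three-element Windkessel).

Two visible consequences, both left red in the acceptance suite rather than
tuned away:

1. **Goodness of fit is too good.** In the WK2 world $\tau = RC$ holds
   exactly and the only per-subject scatter in $k' = C\,cPP/SV$ comes from
   the ratio of ejection time to $\tau$. The centered $R^2$ of the pooled
   origin fit is therefore ≈ 0.99, noticeably above what distributed
   (wave-propagating) virtual populations or human cohorts show (≈ 0.85–0.9),
   where reflection timing spreads $k'$ much more.
2. **The heart-rate trend reverses.** The generator draws the ejection
   *fraction* $t_s/T$ independently of $T$, so slower hearts eject longer,
   lose more volume to peripheral run-off during systole, and end up with a
   smaller $cPP$ relative to $SV$ — i.e. $k'$ *rises* with heart rate.
   Distributed models and in vivo data show the opposite, mild decline,
   driven by reflection physics the lumped model does not contain. The
   subgroup machinery is exercised and tested for its algebra (sizes,
   pooling bounds, scale equivariance); the *direction* of the HR trend is a
   property of the generator, not of the fitting code.

So a green suite establishes the correctness of the solvers, estimators,
fitting algebra and statistics — not that the WK2 stand-in reproduces every
population-level feature of wave-propagating arterial trees.

## The virtual population

Defaults describe a middle-aged adult population and are chosen once:

| parameter | distribution | default | rationale |
|---|---|---|---|
| $R$ | trunc. normal | 1 ± 0.2 (0.4–1.8) mmHg·s/mL | normal adult peripheral resistance |
| $C$ | trunc. normal | 1.1 ± 0.5 (0.2–2.8) mL/mmHg | wide compliance spread spanning stiff to compliant trees |
| $T$ | trunc. normal | 0.7 ± 0.1 (0.4–1.1) s | resting heart rates ~55–150 bpm tail-truncated |
| $t_s/T$ | uniform | 0.30–0.40 | physiological systolic fraction of the cycle |
| $SV$ | trunc. normal | 70 ± 14 (25–130) mL | from cardiac output 6 ± 1.2 L/min at $T$ = 0.7 s |
| age | uniform | 35–55 y | middle-aged screening population |
| brachial amplification | normal | 57/45 ± 0.05 | typical central→brachial PP amplification |

Truncation keeps every draw physiologically positive; draws use the inverse
CDF so a seed reproduces the cohort bit-identically. With these defaults the
cohort means land near MBP ≈ 100 mmHg and cPP ≈ 45–50 mmHg, consistent
with the adult population the defaults emulate. Age–hemodynamics coupling is
off by default (`age_c_slope = 0`) because the coefficient is treated as
age- and gender-independent; a negative slope can be switched on to emulate
stiffening with age.

The measurement-noise model tiles the clean cycle into a ~20 s recording
with per-beat period jitter (sd 2 % of $T$), adds white noise (sd 1 mmHg)
and a slow linear drift (2 mmHg over the recording), and perturbs the
diastolic/mean calibration anchors (sd 3 mmHg each — typical cuff error).
Note the calibration-gain sensitivity this implies: the gain is
$(MBP_{ref}-DBP_{ref})/(\overline{p}-\min p)$, so subjects whose mean-to-
minimum pressure distance is small can see large relative pulse-pressure
errors from modest anchor noise. That is a faithful property of
diastolic/mean calibration, not an artifact.

## Numerical choices

- **Period-commensurate sampling.** Waves hold $n = \mathrm{round}(f_s T)$
  samples at $t_k = kT/n$ (effective rate $n/T$). On this grid the sample
  mean *is* the periodic trapezoidal time-average; with a fixed $1/f_s$
  step the mean pressure would be off by up to ~5·10⁻⁴ relative whenever
  $f_s T$ is not an integer, violating the 10⁻⁶ conservation contract
  ($\overline{P} = R\,SV/T$).
- **Closed-form periodic solver.** Systole is solved by integrating factor
  (sinusoidal or piecewise-linear forcing); because the systolic end value
  is affine in the unknown initial pressure, the periodicity condition
  $P(0)=P(T)$ is solved linearly. No ODE stepping, so oracle tests carry no
  discretization error and the diastolic branch is exponential to machine
  precision. A Fourier-domain path ($\hat P = \hat Q R/(1+i\omega\tau)$)
  serves as an independent cross-check and handles band-limited flows.
- **Decay fit.** Log-linear least squares over a window starting 5 % of
  $T$ after ejection end (skipping notch-like transients) — deterministic
  and exact on exponential data; `nonlinear_ls` (port algorithm) is the
  fallback for signals that cross zero.
- **Pulse pressure method.** Predicted pulse pressure is strictly
  decreasing in $C$, so the compliance is bracketed in [10⁻³, 100] mL/mmHg
  and root-found (tolerance 10⁻¹³ on $C$, giving |ΔPP| ≲ 10⁻¹⁰ mmHg). An
  optional 5-harmonic low-pass of the flow mirrors the classical
  low-frequency variant; it is off by default since no truncation rule is
  canonical.
- **Origin fit.** $k' = \sum x\tau / \sum x^2$ (no intercept, since the
  relation has none); $R^2$ uses the centered total sum of squares so it is
  comparable with with-intercept conventions, with the uncentered variant
  behind a flag. The slope equals the $x^2$-weighted mean of per-subject
  ratios $\tau/x$ — the brute-force oracle used in tests.
- **Tertile rule.** HR/MBP subgroups are equal thirds after sorting;
  remainder subjects go to the outer groups (3818 → 1273/1272/1273).
- **ICC variant.** Two-way, absolute-agreement, single measures
  (ICC(2,1)): method agreement, not consistency, is the question; ICC(3,1)
  is selectable. Mean squares come from explicit sum-of-squares
  decomposition and are oracle-checked against an ANOVA fit.
- **Savitzky–Golay defaults.** Window 51 samples (51 ms at 1 kHz), order 3
  — gentle enough to leave the systolic upstroke intact, exact on cubic
  segments. No canonical parameters exist for tonometry post-processing, so
  these are declared, not inferred.
- **Cycle detection.** Period from the zero-padded FFT autocorrelation,
  upstrokes as local maxima of the derivative, feet as the preceding
  pressure minima — robust under drift, and consistent with the convention
  that cycles start at ejection onset.

## Degenerate inputs and tie-breaks

Zero stroke volume yields the identically-zero periodic solution (and is
the documented lower boundary, not an error). Flat waves cannot be
calibrated (the gain is undefined) and a constant reference makes $r$ and
nRMSE undefined; both raise errors. The `dbp_third_pp_plus5` MBP formula
keeps its +5 mmHg offset at zero pulse pressure — the one formula that does
not coincide with the others in that degenerate limit. Fits require at
least two points, subgroups at least two subjects, agreement reports at
least three pairs.

## Known limitations

Beyond the generator caveats above: the brachial surrogate is a scalar, so
brachial-predictor refits are exact scale copies of the central fit (slope
× amplification), with none of the frequency-dependent amplification real
arms show; the decay-fit window assumes the cycle starts at ejection onset;
and the pulse pressure method inherits WK2's bias when applied to data from
wave-propagating systems — here it is evaluated only on data the same model
generated, where it is exact by construction.
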