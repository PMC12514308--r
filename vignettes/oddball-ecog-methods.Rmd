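---
title: "Event-related ECoG analysis with nonlinear network connectivity: models and methods"
author: "ncreann package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-related ECoG analysis with nonlinear network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ncreann` implements an end-to-end analysis of event-related
electrocorticography (ECoG) recorded from a 3 x 3 epidural electrode grid
over rodent medial prefrontal cortex during a passive two-tone auditory
oddball paradigm, together with a synthetic-data generator that emulates
every input the analysis needs. The pipeline covers FIR preprocessing,
epoching and artifact rejection, ERP and event-related spectral
perturbation (ERSP) feature extraction, directed linear and nonlinear
connectivity estimation by a neural-network nonlinear multivariate
autoregressive (nMVAR) model with time-shifted surrogate significance
testing, and the group and drinking-behaviour statistics of an
alcohol-deprivation-effect (ADE) study design.

Because no public recordings exist for this paradigm, the package treats
the simulator as a first-class module: all validation is against planted
ground truth, analytic oracles, and statistical calibration.

# The synthetic-data generator

## Stimulus sequences

A session consists of `nBlocks` blocks (default 6) of `blockDuration`
seconds (default 300 s) of tones at a fixed stimulus-onset asynchrony of
ISI + tone duration (1 s + 50 ms = 1.05 s; the stated interstimulus
interval is read as offset-to-onset). `round(fraction * total)` deviants
(default 13%) are placed uniformly at random under the constraint that
no two deviants are adjacent, sampled exactly (not by rejection) through
the standard bijection between non-adjacent k-subsets of 1..n and
unrestricted k-subsets of 1..(n-k+1). The default session has 1716
events, exceeding the 1600-stimulus habituation-control threshold of the
protocol.

## Session signals

Each channel is the sum of

* **1/f^chi background** (chi = 1, SD 12 uV), generated by spectral
  shaping of white noise, plus white sensor noise (SD 3 uV);
* **phase-locked evoked components**: Gaussian-windowed deflections
  P1 (45 ms), N1 (85 ms), P2 (180 ms), N2 (260 ms), P3 (400 ms), with
  deviant amplitudes larger than standard (ratio 1/0.6). Latencies and
  widths were chosen so that each component - rather than a neighbour's
  tail - is the extremum of its own detection window on the
  deviant-minus-standard difference wave; this matters because the
  detection windows overlap (N1 60-150 ms vs P2 70-250 ms, etc.);
* **induced oscillatory bursts**: Gaussian-windowed sinusoids per band
  (delta 2.5 Hz to gamma 38 Hz) with a random phase per trial. Random
  phase makes the bursts cancel in the trial-averaged ERP while fully
  driving the event-related spectral power, cleanly separating the two
  feature families. Group and stimulation effects on the bursts scale the
  deviant response only: the ERSP is a deviant-vs-standard dB contrast
  relative to a common baseline, so any scaling applied to both
  conditions cancels exactly and would be invisible by construction;
* optional **artifact injections**: 800 uV peak-to-peak biphasic
  transients at known event indices, used to validate the rejection
  stage.

The four presets (`control_pre`, `control_post`, `alcohol_pre`,
`alcohol_post`) encode the qualitative effect directions of the study
design: chronic alcohol reduces P1/N1 (hence the P1N1 and N1P2 spans),
deepens N2 (larger P2N2), weakens delta-alpha and beta burst power,
strengthens gamma, and shifts the beta burst carrier from 14 to 19 Hz;
stimulation scales amplitudes and burst powers up, less in the alcohol
group and there concentrated at the frontocentral (FC) electrode. Effect
magnitudes are calibration knobs of the generator, not measured
quantities. One caveat is documented rather than "fixed": with the
400-point (133 ms) analysis window the spectral mainlobe is about
+/- 15 Hz wide, so the beta carrier shift, while present in the signal,
is smeared below reliable detectability in the extracted beta-band
maximum frequency; tests therefore do not assert it.

The default test sampling rate is 600 Hz (all windows are specified in
ms, so the rate is free); the full-protocol configuration uses 3 kHz.

## Ground-truth nMVAR series and drinking tables

`simulateNmvar()` runs the forward nonlinear MVAR model: a linear
coefficient tensor `A` (target x source x lag; the companion-matrix
spectral radius must be below 1) plus nonlinear terms (`square`,
`scaled_tanh`, `cross_product`) and Gaussian innovations. It provides
planted ground truth for the connectivity estimator.

`simulateDrinking()` draws daily intakes of 5/10/20% ethanol solutions
around baseline means 1.02/1.25/1.16 g/kg/day (total 3.43) with
rat-level random effects (SD 0.33 per concentration, giving the reported
cohort SD of about 0.57 for the total) and day noise (SD 0.25); the
first day after each deprivation phase is elevated by configured ADE
increments (defaults reproduce ADE-day totals of about 4.66 g/kg/day).

# Preprocessing

## FIR design and filtering

The band-pass filter is a Kaiser-window FIR: attenuation
`A = -20 log10(ripple)`, shape `beta = 0.1102 (A - 8.7)` for A > 50, and
order `N = (A - 8) / (2.285 * dw)` with `dw = 2 pi transition / fs`,
rounded up to the next even integer so the group delay N/2 is an integer
number of samples. At 3 kHz with a 0.1-45 Hz band, ripple 0.001 and a
0.2 Hz transition this yields the protocol's order of 54,330
(beta = 5.653). Because the low cutoff sits within a transition width of
DC, leakage from the +/- 0.1 Hz edges adds about 2 x ripple at 0 Hz; the
taps are therefore normalised to an exactly zero sum (exact DC
rejection), perturbing the passband by a negligible Dirichlet-kernel
term.

Filtering is a single-pass FFT convolution with symmetric group-delay
compensation (not forward-backward filtering, preserving the one-pass
design); the N/2 samples at each edge are flagged as unreliable in the
recording metadata.

## Epoching, artifact rejection, interpolation

Epochs span the half-open window [-100, 700) ms relative to stimulus
onset (2400 samples at 3 kHz); the per-trial, per-channel mean over
[-100, 0) ms is subtracted. Trials whose window does not fit in the
recording are dropped and logged. A trial is rejected when its
within-epoch peak-to-peak range strictly exceeds the delta criterion
(500 uV) on any retained channel; a channel whose own exceedance rate
exceeds 50% is first marked bad and excluded from the trial decision.
The interactive visual-inspection step of the original workflow is
deliberately replaced by this fully quantitative rule. Bad channels are
replaced by inverse-distance-weighted (power 2) averages of the good
channels on the planar grid - planar weighting rather than spherical
splines, because the array is a flat 3 x 3 grid; the centre channel of
any planar linear gradient field is recovered exactly by symmetry.

## Feature imputation

Missing feature cells (from rejected channels) are filled by a
round-robin iterative imputer: initialise with column medians, then
repeatedly regress each incomplete column on all others with a random
forest and refresh the imputed cells until the relative change falls
below 1e-3 or 10 rounds. Because the feature tables are small and the
columns strongly inter-correlated, the forests consider all predictors
at every split (bagging) with leaf size 3. A structural limitation of
any tree ensemble applies: predictions cannot extrapolate beyond the
observed range, so recovery error at the sample extremes is bounded away
from zero no matter how predictable a column is (about 0.15-0.19
sd-normalised RMSE for Gaussian columns at n = 50). Tests therefore
assert bounds that reflect this floor plus a large margin over naive
median filling.

# ERP and ERSP features

Component peaks are detected on the deviant-minus-standard difference
wave (per-condition detection is available): P components are window
maxima and N components window minima within P1 20-80, N1 60-150,
P2 70-250, N2 100-330, P3 130-600 ms, ties broken by the earliest time.
Peak-to-peak spans follow the positive-minus-negative convention
(P1N1 = amp(P1) - amp(N1), N1P2 = amp(P2) - amp(N1),
P2N2 = amp(P2) - amp(N2), N2P3 = amp(P3) - amp(N2)).

The ERSP uses a sliding Hann-tapered FFT (400 samples at 3 kHz, scaled
with the sampling rate; zero-padding ratio 64), per-trial power averaged
within condition and expressed as `10 log10` of the ratio to the mean
pre-stimulus baseline power per frequency (windows whose centre lies at
or before 0 ms). Output is cropped to 1-45 Hz; the gamma upper edge is
the filter's 45 Hz passband edge. Frequencies below the window's native
resolution (7.5 Hz) come from the zero-padded grid and are spectrally
smoothed - delta-band values are therefore interpolated, which is
documented rather than corrected. Band maxima (delta through gamma, the
three beta subranges, and the whole 1-45 Hz range) are restricted to
post-stimulus times, ties broken by earliest time then lowest frequency.

# Directed connectivity (nCREANN)

## Model and training

The estimator models the single-trial contrast signals (each kept
deviant trial minus the mean kept standard trial, on the full analysis
window) as a nonlinear MVAR process of order p: each channel's current
sample is a function of the previous p samples of all channels. Subjects
need at least 8 usable electrodes; a missing ninth channel is
interpolated first. Channels are z-scored with the statistics of the
concatenated contrast series; lagged input rows are built strictly
within trials. The model order is selectable by AIC/BIC curves of a
least-squares linear MVAR (the default pipeline order is fixed at 8).

The function is decomposed as `f = f_lin + f_nonlin` in two explicit
stages:

1. **Linear stage**: least-squares multivariate regression of the
   targets on the lagged inputs.
2. **Nonlinear stage**: a one-hidden-layer perceptron (10 tanh units,
   affine output) trained on the stage-1 residuals by incremental
   (per-presentation) error back-propagation with momentum (0.9) and an
   adaptive learning rate (initial 0.01; grown by 1.05 after an epoch
   whose training MSE decreased, shrunk by 0.7 with the epoch rolled
   back when it rose by more than 4%), with early stopping on a
   validation split (patience 6, maximum 200 epochs) and restoration of
   the best-validation weights. Ten independently permuted 80/10/10
   train/validation/test splits are fitted; per-repetition MSE and
   pooled R-squared on train and test data document validity (a healthy
   fit has test error within the range of the training error), and
   connectivity is averaged across repetitions.

Why the explicit two-stage split: a tanh network fitted directly to data
with strong *linear* cross-channel coupling represents that coupling
with partially saturated units, so its learned function acquires genuine
curvature even though the target is linear - the nonlinear sensitivity
of such a net is a coupling detector, not a nonlinearity detector.
Training the network on linear-stage residuals means that on a purely
linear system the network faces the same structureless target as under
the surrogate null, which is exactly what makes the nonlinear test
specific (verified: on linear VAR systems the nonlinear connectivity
stays below the surrogate 95th percentile essentially always, while a
planted quadratic coupling is detected with near-complete power).

## Connectivity measures

* `lC[i -> j]` (linear connectivity): the sum over lags of the absolute
  linear coefficients mapping lagged channel i into target j, combining
  the least-squares stage with the network's data-averaged Jacobian
  (for standardised, near-Gaussian inputs the averaged Jacobian is the
  least-squares linear component of the learned function, by Stein's
  lemma).
* `NC[i -> j]` (nonlinear connectivity): the mean absolute change of the
  network's nonlinear remainder `f_j(u) - Jbar_j u` when channel i's
  lagged inputs are ablated to their (zero) mean. A value-based ablation
  is used rather than a Jacobian deviation because derivative-based
  measures scale with the learned cross-weights (first-order in linear
  coupling), whereas the nonlinear-remainder values of a well-fitted
  linear map are second-order small.

Matrices are oriented from-row to-column; self-connections are computed
but excluded from testing and group reporting.

## Surrogate significance

Significance uses a randomisation test with time-shifted surrogates:
circular shifts by a random offset uniform in [0.1 L, 0.9 L] preserve a
channel's spectrum and dynamics while destroying its causal alignment.
The null for the connections out of source channel i shifts channel i's
*predictor (lagged-input) copy only*, leaving all targets and other
channels aligned - the conditional-independence null "the past of
channel i carries no information about the present given the other
channels". This choice (rather than shifting all channels at once)
matters in two ways: it keeps genuine structure not involving channel i
present under the null, so the weak curvature spillover that a
shared-hidden-layer network spreads across all connections is matched
between observed and null fits; and it remains a pure time-shift
surrogate. Each surrogate reruns the full two-stage estimate with the
same configuration (a reduced epoch budget is available for surrogates;
the default is the full budget, and all calibration studies in the test
suite use identical budgets for observed and surrogate fits, which is
what makes the permutation p-value exchangeable).

P-values use the add-one rule
`(1 + #{surrogate >= observed}) / (1 + n_surrogates)` (never exactly
zero) on a *studentised* statistic: each connection is divided by the
mean off-diagonal connectivity of the same estimate computed over all
rows other than the tested source. This removes the estimate-level
noise/curvature component shared by all connections of one fit, which
otherwise makes the per-run false-positive count overdispersed (measured
run-level SD of the white-noise false-positive rate drops about
five-fold, with the mean at the theoretical 1/21 = 4.8% for 20
surrogates). Raw lC/NC values are retained for reporting and group
comparisons; 100 surrogates is the default.

Band-restricted variants (low 12-15, mid 15-18, high 18-30 Hz beta)
band-pass the concatenated contrast series before estimation.

## Learning-rate choices in the validation studies

The pipeline default (eta0 = 0.01) suits the strong nonlinear structure
of real contrast signals. The desk-scale validation studies fix their
own rates once: 0.002 for linear-oracle studies, because the asymptotic
SGD fluctuation at larger rates noise-fits correlated inputs and masks
weak linear signal; 0.003 for nonlinear-recovery and calibration
studies, because 0.002 cannot escape the initial plateau when learning a
quadratic from residuals. These are analysis-configuration choices of
the studies, documented here and fixed in the test suite and acceptance
script.

# Statistics

* **Mixed-design ANOVA** per feature: between-subject factor group,
  within-subject factors treatment and channel, subject as the repeated
  unit (`aov` Error strata). Greenhouse-Geisser-corrected p-values are
  reported alongside uncorrected ones for effects involving the channel
  factor (uncorrected is the default inference). Single-level factors
  are dropped so the collapsed two-level design reduces exactly to the
  paired t-test (F = t^2). All-equal data reports F = 0, p = 1 by
  convention (the raw ratio is 0/0).
* **Channelwise paired t-tests** between treatments with
  Benjamini-Hochberg FDR across channels; zero-variance differences are
  flagged (p = 1 if all differences are zero, p = 0 with infinite t for
  a constant non-zero difference).
* **Mann-Whitney U** for group comparisons of connectivity, exact for
  small untied samples and normal-approximated with tie correction
  otherwise, with the rank-biserial correlation
  `r = 1 - 2U/(n_a n_b)` as effect size.
* **Partial Spearman correlation**: rank-transform all three variables,
  residualise the ranked x and y on the ranked covariate, correlate the
  residuals; p from the t approximation with n - 3 degrees of freedom.
* **Drinking measures** per rat and concentration: BL is the mean intake
  over the final 7 free-access days of each drinking phase, averaged
  across phases (phase-averaging adopted; the alternative reading -
  final phase only - is available by subsetting); ADE is the first
  post-deprivation day, averaged over cycles; relapse is the per-cycle
  ADE minus the immediately preceding BL. Totals are sums over
  concentrations. A phase-by-concentration repeated-measures ANOVA and
  one-sample t-tests of relapse against zero accompany the measures.

One mathematical note: step-up FDR adjustment is monotone and
conservative but not idempotent on arbitrary already-adjusted vectors
(re-adjustment multiplies by m/rank again); fully tied adjusted vectors
are fixed points.

# Problem sizes and what the tests show

The validation studies run at desk scale: the linear oracle uses
four-channel order-2 systems of 20,000 samples over 20 seeds; nonlinear
recovery uses two-channel quadratic systems of 8,000 samples over 20
seeds; surrogate calibration uses nine independent noise channels of
3,000 samples over 20 runs; statistical calibration uses 2,000 null
simulations; all surrogate tests in these studies use 20 surrogates with
budgets identical between observed and surrogate fits. The end-to-end
smoke profile runs at 600 Hz with 2 blocks, 2 subjects per group, 16
contrast trials per subject and 20 surrogates, and is checked for
byte-identical outputs across reruns with the same seed.

Passing these tests shows that the implementation recovers planted
effects under its own generative model and that its tests are
statistically calibrated. It does not show that the generator's effect
magnitudes match real recordings (they are uncalibrated knobs), nor that
real ECoG noise - movement artifacts with complex morphology, volume
conduction, electrode drift - behaves like the simulated 1/f background.

# Known limitations

* The exact functional definitions of the linear/nonlinear connectivity
  measures in the literature this estimator follows are not fully
  published; the package's two-stage decomposition and ablation measure
  are its own, selected to satisfy the testable properties above, and
  are documented accordingly.
* The nonlinear test's per-connection null is a conditional-independence
  null for the tested source channel; simultaneous inference across
  connections relies on per-connection level control plus FDR, not on a
  joint null.
* The multivariate omnibus (MANOVA) of the original workflow is replaced
  by per-measure univariate mixed ANOVAs with FDR across measures.
* Interactive artifact screening is not reproduced; only the
  quantitative delta criterion is implemented.
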