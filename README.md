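# ncreann

Event-related ECoG analysis for a rodent auditory oddball paradigm, with
directed linear and nonlinear connectivity estimated by a
neural-network nonlinear multivariate autoregressive (nMVAR) model.

## The scientific problem

Chronic alcohol exposure alters prefrontal event-related potentials
(ERPs), event-related oscillations, and the directed communication
between cortical sites; epidural electrical stimulation can partially
restore them. Quantifying these effects from electrocorticography
(ECoG) recorded over a 3 x 3 electrode grid during a two-tone oddball
paradigm requires a long chain of processing - band-pass FIR filtering,
epoching, artifact rejection, deviant-minus-standard ERP and
event-related spectral perturbation (ERSP) feature extraction, directed
connectivity with surrogate-based significance, and mixed-design group
statistics plus alcohol-deprivation-effect (ADE) drinking measures.
`ncreann` implements that chain as a tested, reusable R package for
electrophysiologists and methods researchers, together with a
synthetic-data generator that emulates every input (oddball sessions
with known planted effects, ground-truth nMVAR series, drinking
tables), so the whole pipeline runs and validates itself with no data
download.

## The model at the core

The connectivity estimator models the single-trial contrast signals
(each deviant trial minus the mean standard trial) as a nonlinear MVAR
process of order *p*:

    x(n) = f(x_p) + e(n),    x_p = [x_1(n-1), ..., x_M(n-p)]

with `f = f_lin + f_nonlin`. The linear part is estimated by least
squares combined with the data-averaged Jacobian of a one-hidden-layer
perceptron (10 tanh units) trained on the linear-stage residuals by
incremental back-propagation with momentum, adaptive learning rate and
early stopping over ten permuted 80/10/10 cross-validation splits.
Linear connectivity `lC[i -> j]` sums the absolute linear coefficients
from lagged channel *i* to target *j*; nonlinear connectivity
`NC[i -> j]` is the mean absolute change of the network's nonlinear
remainder when channel *i*'s lagged inputs are ablated. Significance
comes from a randomisation test with time-shifted surrogates (circular
shifts of the tested source channel's predictor copy), with add-one
permutation p-values on studentised statistics. Matrices are oriented
from-row to-column; self-connections are excluded. The methods
vignette (`vignettes/oddball-ecog-methods.Rmd`) derives and motivates
every choice.

## Worked example

```r
library(ncreann)

## the protocol band-pass filter: 0.1-45 Hz Kaiser FIR at 3 kHz
designBandpassFir(3000, 0.1, 45)
#> Kaiser FIR bandpass 0.1-45 Hz at 3000 Hz: order 54330 (54331 taps), beta 5.653, 60 dB

## a default oddball session: 6 blocks x 5 min, 1-s ISI, 13% deviants
ev <- makeStimulusSequence(seed = 1)
nrow(ev); sum(ev$tone_type == "deviant")
#> [1] 1716
#> [1] 223

## simulate, filter, epoch and reject a (reduced, 2-block) session
rec <- simulateSession(makeStimulusSequence(nBlocks = 2, seed = 1),
                       "alcohol_pre", fs = 600, seed = 2)
ep <- rejectArtifacts(epochAndBaseline(
  applyFilter(rec, designBandpassFir(600, 0.1, 45, transitionWidth = 1))))
ep
#> EpochSet: 571 trials x 9 channels x 480 samples [-100, 698.333] ms at 600 Hz
#>   kept 571/571 | standard 497, deviant 74 | bad channels: none

## ERP peak-to-peak spans on the deviant-minus-standard difference wave
pk <- peakToPeak(detectPeaks(averageAndDifference(ep)$difference))
subset(pk, channel == "FC" & is.na(latency_ms))
#>  component channel latency_ms amplitude_uV
#>       P1N1      FC         NA     11.27766
#>       N1P2      FC         NA     10.55221
#>       P2N2      FC         NA     14.49513
#>       N2P3      FC         NA     15.10246

## ERSP band maxima of the deviant-vs-standard contrast (dB)
bf <- bandFeatures(computeErsp(ep, nTimes = 60)$contrast)
subset(bf, channel == "FC" & band %in% c("beta", "gamma"))
#>  channel  band   max_db latency_ms  freq_hz
#>       FC  beta 4.791626   55.83333 12.07031
#>       FC gamma 6.307888   90.83333 41.71875
```

The `alcohol_pre` preset encodes the study's effect directions: the
P1N1/N1P2 spans above are smaller and the gamma contrast larger than a
`control_pre` session analysed identically. Per-subject connectivity is
`estimateConnectivity(ep, connectivityConfig(), seed = 1)`, and
`runPipeline(pipelineConfig("smoke"), seed = 1, outDir = "out")` runs
the full cohort simulation, preprocessing, features, imputation, group
statistics, connectivity and drinking analysis end-to-end, writing CSV
result tables and a JSON run log. A thin command-line wrapper lives at
`inst/scripts/run-pipeline.R`.

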