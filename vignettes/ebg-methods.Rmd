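---
title: "Electrobulbogram time-frequency analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrobulbogram time-frequency analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scientific problem

The electrobulbogram (EBG) records human olfactory bulb activity from four
forehead electrodes. In a two-group design (Parkinson's disease patients
versus healthy controls), each participant receives interleaved odor and
odorless-sniff trials. The analysis asks three questions:

1. Where in time-frequency space does odor-induced (non-phase-locked)
   oscillatory power differ between groups?
2. Are the resulting components reliable within participants, and can they
   classify diagnostic group?
3. Do component magnitudes track clinical parameters (levodopa-equivalent
   daily dose, disease duration, Hoehn & Yahr stage, odor identification)?

`ebgtools` implements the full path — preprocessing, frequency-adaptive
multitaper decomposition, induced-power contrasts, cluster-based Monte Carlo
permutation statistics, component scoring with ICC(2,k) reliability, and
mixed-effect classification/association models — plus a seeded synthetic
generator that emulates the recording and cohort structure so every stage can
be validated against ground truth.

# Pipeline model and procedure

## Preprocessing

Continuous recordings are epoched with a half-open sample convention
(`N = round(fs * duration)` samples at `t0 + k/fs`, `k = 0..N-1`, t = 0 at
stimulus onset), re-referenced to the average of the two mastoids, notch
filtered at 50 Hz (second-order IIR, quality factor 30, applied
forward-backward for zero phase), and shifted by the olfactometer
trigger-to-nose delay (`round-half-up(delay * fs)` samples; the epoch is
re-cropped at the end so the time origin marks odor arrival).

Artifact screening band-passes each trial (0.5–4 Hz on the vertical EOG
channels for blinks, 20–45 Hz on the EBG channels for muscle), takes the
Hilbert envelope (analytic signal via the frequency domain), and z-scores the
envelope against the distribution pooled over all trials per channel and
band. A trial whose envelope exceeds z = 4 (blink) or z = 8 (muscle) anywhere
is flagged; blink takes precedence when both trip. Remaining ocular influence
is removed from the EBG channels by ordinary least-squares regression on the
two EOG channels, with coefficients estimated on the pooled clean trials.

## Frequency-adaptive multitaper decomposition

At each analysis frequency `f` the window length is `T(f) = min(2/f, epoch)`
seconds (at least two cycles of `f`), the half-bandwidth is `W(f) = 0.8 f`,
and `K = max(1, floor(2 T W - 1)) = 2` DPSS tapers are used — a constant
relative smoothing of ±80% of the bin frequency. The default analysis grid is
0.5–100 Hz in 0.5 Hz steps by −2 to 2 s in 10 ms steps. Window centres snap
to the nearest sample (round-half-up); bins whose window exceeds the epoch
support are `NaN` rather than zero-padded.

DPSS tapers are computed from the symmetric tridiagonal eigenproblem of the
commuting operator (Percival & Walden 1993, ch. 8) and validated in the test
suite against the defining dense sinc-kernel concentration eigenproblem to
1e−8. The implementation assembles, per frequency, a banded kernel matrix
(taper × complex exponential at every valid output time) and applies it to
all trials/channels with two real matrix products, which keeps the
permutation-scale simulations tractable on one CPU.

## Induced power: a deliberate design decision

"Induced" (non-phase-locked) power must remove the evoked (phase-locked)
response. Two conventions exist:

* **ERP subtraction (package default, `method = "power"`):** subtract the
  trial-average waveform from each trial, compute per-trial multitaper power
  of the residual, average, then baseline-normalize to dB.
* **dB subtraction (`method = "db"`):** baseline-normalize total and evoked
  power separately and subtract the dB maps.

The dB-subtraction convention fails a basic sanity property: for a fully
phase-locked response the evoked map's *own baseline* is the trial-averaged
noise floor (≈ noise/n), so its dB values are inflated by ≈ 10·log10(n) and
the difference does not cancel to ~0 dB. ERP subtraction satisfies both
limits — a fully phase-locked burst leaves |induced| ≪ 1 dB, and a fully
random-phase burst leaves induced ≈ total — and is therefore the default;
the dB convention is retained as an option for comparability. The
power/baseline ratio is clipped below at 1e−2 (−20 dB) before the logarithm
as a numerical guard.

The subject-level map is the odor-minus-sniff difference of induced dB maps,
averaged over the four EBG electrodes, using a pre-stimulus baseline
(default −1.5 to −0.5 s, chosen inside the valid part of the map).

## Cluster-based permutation statistics

Per bin, a pooled-variance two-sample t (Control − PD, df = n1 + n2 − 2) is
thresholded at p < 0.05; supra-threshold bins of equal sign are grouped under
4-connectivity on the frequency × time lattice and kept when strictly larger
than `minSize` bins (100 on the full grid; scaled proportionally to the grid
in reduced runs). Family-wise correction uses the max-statistic over cluster
mass (sum of member t values): each of `nPerm = 1000` random relabellings of
participants contributes its maximum absolute candidate-cluster mass to the
null distribution, and an observed cluster gets
`p = (1 + #{null >= |mass|}) / (nPerm + 1)`. Clusters with p < 0.05 are
retained. The permutation t maps are computed for whole chunks of
relabellings at once via indicator-matrix products.

## Components, reliability, classification, associations

Retained clusters become "Component 1..k", ordered by earliest member time
bin (ties: lower minimum frequency). A participant's score on a component is
the mean contrast dB over the component's bins; trial scores use single-trial
contrast maps; scores are z-scored pooled across both groups. Reliability is
ICC(2,k) — two-way random effects, average measures — on participants ×
random trial-splits (k = 4).

Classification fits a mixed-effect logistic model (group on z-scored trial
scores with a by-participant random intercept); participant-level predicted
probability is the mean of the trial-level population predictions (random
effects excluded, threshold 0.5, PD positive). Models are compared by AIC;
forward stepwise selection adds the component that maximizes subject-level
accuracy (ties broken by AIC) and stops at the first accuracy maximum.
Hyposmia is labelled from the 16-item odor identification score (< 11).

Clinical associations regress an outcome on component trial scores. Because
clinical outcomes are constant within participant, the literal trial-level
mixed model is degenerate — the within-participant observations carry zero
outcome variance and drive the slope estimate to zero — so the model reduces
to its between-participant component: OLS of the outcome on the
participant-mean score. (Outcomes that genuinely vary across trials are fit
with `lmerTest::lmer`, Satterthwaite df.) Associations are validated by a
subsample bootstrap: 1000 draws of 80% of each group's participants without
replacement, two-sided `p = 2 min(frac > 0, frac < 0)`, floored at
`1/nBoot`.

# Synthetic generator and its realism

`generateDataset()` emulates the study: 20 PD + 18 control participants, 72
odor + 24 sniff epochs at 512 Hz on EBG1–4, two mastoids and two vertical EOG
channels. Background activity is 1/f pink noise (SD 10 µV) plus a white
floor (1 µV); a coherent 50 Hz line component (2 µV) is added per channel.
Group-differential activity is injected as Gabor bursts (Gaussian-windowed
cosines) on the EBG channels of odor trials: control-dominant bursts in gamma
(65 Hz, 460 ms), beta (20 Hz, 620 ms) and theta (6 Hz, 680 ms), and
PD-dominant bursts in alpha/beta (12 Hz, near onset) and gamma (65 Hz, 660
and 980 ms). Per-participant amplitudes are truncated-normal around the group
mean; burst phase is random per trial by default (`phaseLockedFraction`
configurable). Blink artifacts are derivative-of-Gaussian deflections (σ =
0.15 s; full amplitude on EOG, ×0.3 on EBG); muscle artifacts are
Gaussian-windowed 20–45 Hz noise bursts; counts are Poisson per epoch.
Clinical covariates are drawn from truncated/discretized distributions
matching the cohort description, optionally coupled to per-participant burst
amplitudes with a configured correlation while preserving the marginals.

The default burst amplitude (8 µV peak) is chosen for *testability* — it
yields subject-level effect sizes of roughly d ≈ 2–3.5 on footprint scores
under the default noise model, comfortably detectable at the study's n — not
to match any empirical effect size. Known departures from realism: bursts
are independent across trials and components, the 1/f field is spatially
white apart from the shared line component, volume conduction between EBG
electrodes is not modelled (all four receive the same burst), and artifact
waveforms are stylized.

# Numerical choices

* **Sample snapping** uses round-half-up everywhere (window centres, trigger
  delays), documented and tested; base R `round()` is banker's rounding and
  is deliberately not used.
* **DPSS sign convention:** the first element above 1e−7 of the maximum
  modulus is positive — an unambiguous rule even for antisymmetric tapers,
  whose two extrema tie in magnitude.
* **Determinism:** every stochastic stage takes an integer seed; the
  pipeline derives stage seeds from one master seed. Identical
  (configuration, seed) reproduce outputs bit-identically.
* **Permutation p floor** is `1/(nPerm + 1)`; bootstrap p floor `1/nBoot`.
* **Zero-variance guards:** envelope z-scores define z = 0 for constant
  envelopes; the EOG regression is skipped (with a warning) when the EOG
  covariance is numerically singular; baselines must be strictly positive.

# Problem sizes in the test suite

Simulation-heavy validations keep the prescribed replication counts at full
size (100 null-calibration runs × 1000 permutations; 50 recovery runs × 500
permutations; 50 stepwise seeds; 1000 ICC seeds; 200 + 100 association
seeds) but run on reduced data dimensions chosen for a single-CPU budget:
lower sampling rates (128–200 Hz), shorter epochs, 6–12 trials per
condition, two EBG channels, coarser analysis grids (4 Hz × 50 ms), and a
cluster-size threshold of 10 bins scaled to the reduced grid. Pure-noise ICC
matrices are 200 × 4 so that the sampling spread of ICC(2,k) under the null
(driven by `1/df1 + 1/df2` of the between/within F) keeps |ICC| < 0.3 with
~99% probability. These reductions were fixed before the assertions were
first run.

# Limitations

* The generator validates the *pipeline*, not the biology; effect sizes,
  burst shapes and artifact morphology are stylized.
* The frequency-adaptive bandwidth W = 0.8f smears energy across a wide band
  at high frequencies by construction; neighbouring components of opposite
  sign can partially cancel in overlap regions.
* The cluster permutation test controls family-wise error at the cluster
  level only; bin-level inference inside a cluster is not supported.
* With participant-constant outcomes the association model is effectively a
  between-participant regression at n = cohort size; trial counts do not add
  power there beyond stabilizing the participant means.

# Worked example

```{r example}
library(ebgtools)
res <- runPipeline(seed = 3) # demo scale, ~30 s
res$components
res$classification$confusion
res$associations$table
```
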