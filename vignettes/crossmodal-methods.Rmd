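---
title: "Methods: cross-modal response analysis in gustatory cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-modal response analysis in gustatory cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmodal)
```

This vignette documents the scientific model behind each stage of the
pipeline, the parameters that matter, the numerical choices made where
the procedure was genuinely open, and what the synthetic-data generator
does and does not emulate.

## The experimental structure being modeled

Extracellular single units are recorded in the gustatory cortex (GC) of
alert rats under two conditions: *untrained* animals receive four
tastants (sucrose, NaCl, citric acid, quinine, delivered intraorally)
and four cross-modal stimuli (an air puff to the whiskers, an odor, a
tone, a light) in random order; *trained* animals have first learned,
over 14 daily sessions, that each cross-modal cue predicts sucrose
delivered 2.5 s after cue onset. Every stimulus is presented on 8–14
trials per session. Spike times are stored relative to stimulus onset
(time 0) and analyzed from 1 s before onset to 2 s (cross-modal) or
2.5 s (taste) after it. Cross-modal stimuli always last 2 s; in trained
sessions the analysis window for cues extends to 2.5 s so that the
500 ms delay between cue offset and sucrose is included.

Binned analyses use 200 ms half-open bins `[t, t + 0.2)`, so a spike at
exactly 0 s is post-stimulus. The 2.5 s taste window is not a multiple
of the bin width; binned analyses therefore use the 12 complete bins
covering 0–2.4 s, while the change-point analysis, which works in
continuous time, uses the full 2.5 s. The decoder uses a wider grid,
`[-1, 2.8)` s, so that both the onset window (0–0.2 s) and the
post-offset window (2.5–2.7 s) are resolvable; bins are assigned to
those windows by their midpoints.

## Change-point analysis

Firing-rate changes are detected from the cumulative count of spike
times pooled across a stimulus' trials. Under a constant rate this
function grows linearly; an evoked change bends its slope. The scan is
forward-recursive: within the current segment, the candidate change
point is the spike time maximizing the absolute deviation between the
cumulative count and the straight line joining the segment's endpoints;
if significant, it is recorded and the scan restarts from it.

**Significance.** The candidate is found by maximization, so evaluating
an ordinary binomial test only at the candidate position is strongly
anti-conservative: measured on constant-rate pooled trains (10 Hz x 10
trials), the naive version declares a spurious post-onset change point
in about a third of windows. The test used here is the exact null
distribution of the maximal deviation itself — a Kolmogorov–Smirnov
uniformity test of the segment's spike times — which is the calibrated
version of the same before/after count comparison. Measured on the same
null trains the per-window false-positive rate is ~4%, and a 5→20 Hz
step at 0.5 s (10 trials) is localized within ±0.1 s in ~98% of runs. A
Bonferroni correction of the binomial test over candidate positions was
also evaluated and rejected as over-conservative (measured type-I
~0.3%).

Defaults, all exposed as arguments: `alpha = 0.05`, at most 10 change
points per window, at least 5 spikes per scanned segment, candidates
restricted to observed spike times, no multiple-testing correction
across neurons or stimuli (none is applied at this stage in this kind of
analysis). Change points before onset are detected (they keep the
recursion honest) but ignored for responsiveness. The response sign
compares the mean rate between the first post-onset change point and the
next one (or the window end) against the baseline mean rate; the
modulation count is the number of post-onset change points.

## Taste selectivity, sharpness, convergence

*Taste selectivity* is a two-factor fixed-effects ANOVA on per-trial
per-bin rates (taste x bin, 12 post-delivery bins), with type-II sums of
squares (`car::Anova`) because trial counts differ across tastes. The
neuron is selective when the taste main effect or the interaction is
significant at `alpha = 0.05` (the observation unit and the error term
are not dictated by the procedure's description; trial-level rates are
the natural choice). With two chances at 0.05 the realized null rate is
~5–10%.

*Sharpness* uses mean firing rates over the 2.5 s following onset for
all 8 stimuli regardless of modality. It is scale-invariant, equals 1
iff exactly one rate is nonzero, 0 iff all rates are equal, and is
undefined (flagged) for an all-zero profile.

*Convergence* is counted on the boolean responsiveness matrix, and its
significance is assessed by simulating populations with independent
Bernoulli responses at the observed marginal probabilities (default
10,000 simulations). The p-value is two-sided (doubled smaller tail)
because both excess and deficit of convergence are of interest. Because
the statistic is integer-valued, the tail fraction uses the mid-p
convention (ties counted half, smoothed by +0.5/(n+1)): the plain
"at least as extreme" fraction is visibly conservative for discrete
statistics and fails a uniformity check that the mid-p version passes
(null KS p = 0.57 over 200 runs at 1,000 simulations each).

## auROC normalization and the cue-similarity index

Each post-stimulus bin of a peristimulus histogram is normalized against
baseline firing by the probability that a randomly drawn evoked
per-trial count exceeds a randomly drawn baseline count, ties counted
half — the Mann–Whitney statistic over all cross pairs, computed via
ranks. The baseline distribution pools the per-trial counts of the five
200 ms baseline bins; pooling across baseline bins and trials gives the
comparison a stable reference at 8–14 trials.

The cue-similarity index for one neuron-bin quadruple (O, S, T, L =
auROC for odor, air puff, tone, light) is

CI = 0.25(|ln O/T| + |ln O/L| + |ln S/T| + |ln S/L|)
   − 0.5(|ln O/S| + |ln T/L|),

positive when cues of similar associability (odor/air-puff; tone/light)
evoke more similar normalized responses than cues across pairs. Values
are clipped to `[0.001, 0.999]` before logs since auROC values of
exactly 0 or 1 occur at finite trial counts. The index is exactly
invariant to swaps within a pair and to swapping the two pairs, and its
expectation is 0 for exchangeable quadruples.

The population time course averages CI over neurons responsive to at
least one cue. The null band re-pairs the cues in the two alternative
ways ({O,T}/{S,L} and {O,L}/{S,T}) — under the null hypothesis that the
similar/dissimilar partition is arbitrary — over bootstrap resamples of
neurons (default 1,000, both pairings pooled symmetrically); bins whose
observed CI exceeds the 97.5th percentile are flagged. Fewer than 5
neurons is refused.

## Population decoding

Units from different sessions are collected into a pseudo-population;
only units with at least 8 trials per cross-modal stimulus qualify, and
trial counts are truncated to the common minimum K after an independent
seeded shuffle of each unit's trials (the pairing of trials across
units is arbitrary, so it is randomized rather than fixed by recording
order). Firing rates are used raw, not z-scored (a normalization flag
exists but defaults off).

Classification is per 200 ms bin, leave-one-pseudo-trial-out: a
pseudo-trial spans all four stimuli, and holding out index j removes it
from every class's template. This symmetry matters: excluding the
held-out trial only from its own class's template leaves that template
with K−1 trials against K for the others, and the extra template noise
biases null accuracy measurably below the 0.25 chance level (measured
0.20 at 50 neurons, K = 8); the symmetric version is unbiased (0.25
across regenerated null populations). Distance ties are broken uniformly
at random with the caller's RNG state.

The confidence band resamples ⌈0.8R⌉ neurons with replacement (default
100 runs); a bin decodes significantly when the band's lower bound
exceeds 0.25. The correct-hit / false-hit analysis averages confusion
matrices over the bins of the onset (0–0.2 s) and post-offset
(2.5–2.7 s) windows; per stimulus the correct hit is the diagonal and
the false hit the largest off-diagonal row entry, compared across the
four stimuli by a pooled-variance t-test (df = 6). Note that accuracy
conditional on one fixed population is offset by that population's
realized spikes; chance-level measurements therefore average over
regenerated populations.

## Orofacial movement analysis

Movement is the absolute frame-to-frame difference of mean pixel
intensity in a mouth ROI, normalized by the mean intensity of a
background ROI taken from the earlier frame of each pair (either frame
would do; the earlier one is fixed for determinism). The trace is
sampled at 30 Hz. Epoch means are taken over the spontaneous (−1–0 s),
cue (0.5–1.5 s) and taste (2.7–3.7 s) windows; traces can be normalized
per trial to the taste-epoch maximum (refused when that maximum is 0).
Trials flagged invalid, or whose spontaneous-epoch mean exceeds 3x the
session median (the mouth already in motion), are excluded with a
message.

Learning is assessed per cue by a day x epoch ANOVA on trial-level epoch
means and a Tukey HSD on the day factor within the cue epoch; the first
learned day is the earliest day whose cue-epoch mean exceeds day 1 with
corrected p < 0.05.

## The synthetic generator

`generate_session()` draws, per neuron: a log-normal baseline rate
(median 4 Hz, sigma 0.6 on the log scale — chosen to give realistic
spike counts at 8–14 trials); independent Bernoulli responses per
stimulus at the observed marginal probabilities (untrained: air puff
0.15, odor 0.16, tone 0.04, light 0.03; trained: 0.34/0.33/0.16/0.11;
tastes ~0.39–0.41); a per-response modulation count 1 + Poisson(mean −
1) matched to the observed means (1.22 untrained, 1.44 trained); change
times uniform in the post window; excitatory amplitudes of 50–200% of
baseline (evoked magnitudes are not reported, so these are the package's
choice) and inhibitory responses as multiplicative rate reductions
floored at 0.1 Hz, with the observed inhibited fractions (0.296 /
0.477). Spikes are drawn from the resulting piecewise-constant rate as
an inhomogeneous Poisson process. One global seed splits into
per-neuron substreams so that adding neurons leaves existing ones
untouched.

Neurons that respond to a taste but are not selected as taste-selective
(observed fractions 0.64 / 0.57) respond to all four tastants with one
shared profile, which is what makes them non-selective in the ANOVA; as
a side effect the realized taste marginals sit slightly above their
configured values. The `similarity_coupling` weight makes the
odor/air-puff and tone/light pairs share responsiveness and response
profiles with that probability; it defaults to 0 in both conditions
because the observed convergence statistics are consistent with
independent responses, and coupling is switched on explicitly when a
correlated population is needed (similarity and convergence power
checks).

`generate_orofacial()` produces Δ-intensity traces whose cue-epoch
amplitude follows a sigmoid in day centered on the cue's learning day
(defaults 3 for odor/air puff, 7 for tone/light, the observed learning
schedule) with day-scale 0.35, asymptotic cue amplitude 0.3 and constant
taste amplitude 0.5 (normalized units), multiplicative per-trial gain
(log-SD 0.2) and additive sample noise (SD 0.03). The steep sigmoid
reflects the abrupt appearance of conditioned responding and makes the
learning day a well-defined recovery target: at these defaults the
analysis recovers days 3/3/7/7 in >90% of seeded runs.

What the generator does **not** emulate: refractoriness, spike-count
correlations between simultaneously recorded neurons, electrode drift,
session-to-session nonstationarity, rhythmic (6–10 Hz) licking/whisking
units, and real video frames (traces are generated directly; the
frame-difference path is exercised by synthetic frame stacks in tests).
Passing tests therefore validate the statistical machinery, not the
biological claims: conclusions about real recordings still require real
recordings.

## Rhythmic-unit exclusion

Units dominated by 6–10 Hz rhythmicity (licking/whisking-locked) are
excluded from stimulus analyses. The criterion — spectral maximum over
1–50 Hz inside [6, 10] Hz and at least 2x the median band power, from a
Welch-averaged periodogram of the 10 ms-binned spike train — is this
package's operationalization of "a large spectral peak", and both the
band and the ratio are exposed as arguments. Units with fewer than 500
spikes and under 60 s of data give an indeterminate verdict and are
retained with a warning.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed or documents that it
uses the caller's RNG state, and identical seeds give byte-identical
written outputs. The test suite runs the full pipeline on reduced
populations (24 neurons per condition, 8 trials per stimulus, 25–500
bootstrap/simulation replicates) and the calibration checks at the sizes
stated above (e.g. 200 step-recovery simulations, 500 null windows, 200
uniformity runs at 1,000 simulations, 50 learning-recovery runs); these
sizes are the package's choices for stable Monte-Carlo estimates at
interactive run times.

## Known limitations

- The change-point significance calibration is exact only for the first
  segment; segments that start at a previously detected change point
  inherit a small conditioning effect, measured as a ~4% (slightly
  conservative) realized type-I rate.
- The ANOVA on per-trial-per-bin rates treats bins as independent
  observations; serial correlation within trials makes the interaction
  test mildly liberal, which is inherent to this standard procedure.
- Published figure-level values that depend on the recorded data (peak
  decoding accuracies, CI time-course magnitudes, absolute movement
  amplitudes) are out of scope by design; the pipeline reproduces the
  procedures and the closed-form/count-based statistics.
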