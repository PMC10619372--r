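---
title: "Dominant coupling modes: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant coupling modes: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(docm)
```

## The model

Resting-state electrophysiological activity couples across regions through
more than one mechanism at once: oscillations of the same frequency phase-lock
(within-frequency coupling), and the phase of a slow rhythm modulates the
amplitude envelope of a faster one (phase-to-amplitude coupling, PAC). `docm`
treats the two families as a single multiplex alphabet of 36 coupling modes —
8 within-frequency modes over the canonical bands (delta 1–4, theta 4–8,
alpha1 8–10, alpha2 10–13, beta1 13–20, beta2 20–30, gamma1 30–45, gamma2
55–90 Hz) and the 28 ordered (slow, fast) cross-frequency pairs — and asks, for
every region pair and every sliding window: *which single mode, if any,
dominates the interaction right now?*

The per-window answer is an integer label in 0–36 (0 = no statistically
significant coupling). The label sequence of a region pair over time — its
dominant-coupling-mode (DoCM) sequence — is the package's central observable:
its marginal distribution gives the comodulogram, its switching rate the
flexibility index, and its temporal structure, modelled with a discrete hidden
Markov model (dHMM) per connection, carries enough individual signature to
identify a person across recording sessions and across cohorts.

### Estimators

Within-frequency coupling is measured with the imaginary part of the
phase-locking value,
$$\mathrm{iPLV} = \left|\,\mathrm{Im}\;\tfrac1T\sum_t
e^{i(\varphi_x(t)-\varphi_y(t))}\right| ,$$
where the phases are analytic-signal phases of zero-phase Butterworth
band-passed series. Taking only the imaginary part makes the estimator blind
to zero-lag locking, the signature of volume conduction and spatial leakage;
the price is that genuinely zero-lag physiological coupling is also invisible,
which the synthetic generator respects by planting quarter-cycle lags.

PAC is estimated by an envelope-phase-locking chain: band-pass the modulated
signal at the fast band, take the analytic amplitude envelope, band-pass that
envelope at the slow band, and compute the iPLV between the modulating
signal's slow phase and the envelope's slow-band phase. The construction is
directed (phase of $x$ to amplitude of $y$), so both orientations of every
pair are evaluated and reconciled later.

Band-pass filtering is a 3rd-order Butterworth applied forward and backward
(zero phase; effective 6th-order magnitude). Inside `compute_dfcg()` the
identical response is applied spectrally — the FFT of each channel is
multiplied by the filter's squared digital magnitude response together with
the analytic-signal mask — which fuses filtering and Hilbert transform into a
handful of batched FFTs per session. The periodic boundary this implies
affects only the outermost fraction of a second of a recording; the
user-facing `bandpass()` keeps the literal forward–backward implementation.

Filtering and phase extraction happen once on the full recording; windows
(default 1 s width, 100 ms step, so a 300-s session yields 2991 windows) are
cut afterwards, avoiding per-window filter transients. One second holds fewer
than three delta cycles, so delta-involved modes at the default width are
flagged with a reliability warning rather than silently trusted.

## Statistical filtering

A coupling value means little without a null. The null is built from
single-cut surrogates: a series is cut once at a random point and the two
segments exchanged — a circular rotation that preserves the amplitude
distribution, spectrum and autocorrelation while destroying the alignment
between the two signals. Inside the pipeline the rotation is applied to the
phase sample sequence of one signal (for iPLV, either signal at random; for
PAC, the amplitude-bearing envelope-phase series), over the *full recording*,
keeping rotations at least one window width away from zero: a rotated window
of a genuinely coupled pair is then decorrelated rather than a near-copy of
the observed alignment.

Two design choices matter here:

* **Pooled nulls.** Drawing a separate null per (pair, window, mode) is both
  unaffordable (it multiplies the estimator cost by the surrogate count for
  every cell of a 36 × windows × R × R array) and statistically fragile — 200
  rotations of one pair at one window share most of their samples, leaving an
  effective null sample of roughly the recording length divided by the window
  width, whose noisy quantiles make per-pair p-values anti-conservative
  (measured false-positive rate near 0.07 at a nominal 0.05). `docm` instead
  pools, per coupling mode, `n_null` surrogate values drawn over random pairs,
  windows and cut points. Pairs are exchangeable under the null, the pooled
  draws are nearly independent, and the measured per-test false-positive rate
  is indistinguishable from nominal. Pooling also buys p-resolution: the
  smallest attainable one-sided p is $1/(n_{\mathrm{null}}+1)$, which must lie
  below the Bonferroni threshold $\alpha/36$ for any coupling to ever be
  declared dominant. The default configuration (`n_null = 5000`,
  `alpha = 0.05`) resolves its own threshold of $1.39\times10^{-3}$; the
  full-scale preset (`surrogate_config_fullscale()`: 10,000 surrogates,
  `alpha = 0.001`) is provided for completeness but warns that
  $1/10001 > 0.001/36$ — that combination cannot label anything and is kept
  only as a historical reference point.

* **One-sided add-one p-values.** $p = (1 + \#\{s \ge \mathrm{obs}\})/(1+n)$,
  so $p > 0$ always and the null p-distribution is discrete-uniform.

Selection then proceeds per window and ordered pair: modes with
$p < \alpha/36$ form the survivor set; one survivor wins outright; several
survivors are reduced to the highest strength (ties: lower p, then lower mode
index); none leaves the pair unlabelled. The two orientations of each pair are
reconciled by the lower p-value (ties: higher strength), after which the graph
is undirected. Finally a Benjamini–Hochberg filter at `fdr_q` (default 0.05)
runs per window across all pairs' dominant-mode p-values; because those
p-values are minima over 36 modes they are strongly sub-uniform under the
null, so BH prunes chance survivors aggressively while planted couplings,
whose p sits at the resolution floor, pass easily. Labels and strengths are
zeroed together; `labels == 0` exactly where `strengths == 0`.

## Chronnectomic descriptors

The **comodulogram** of a label sequence is the 8 × 8 probability table of its
nonzero labels (diagonal: within-frequency; row = modulating band, column =
modulated band). Zero labels mean "no coupling", not a 37th mode, so the
table is normalized over labelled windows only and sums to 1 whenever any
coupling exists.

The **flexibility index** of a pair is the fraction of consecutive-window
transitions at which the label changes,
$FI = \tfrac{1}{T-1}\sum_{t} \mathbf{1}[\ell_t \ne \ell_{t+1}] \in [0,1]$,
and the global FI averages over the $R(R-1)/2$ pairs. (A literal reading of
the usual printed prefactor $1/(1-T)$ would be negative; the positive
normalization with a change indicator is the only choice consistent with a
fraction-of-switches interpretation.) FI counts changes, not identities, so it
is invariant under any relabelling bijection of the nonzero modes.

Window width and step are tunable; `optimize_window_params()` scores each
grid point (defaults: widths 0.5–3 s in 0.25-s steps, steps 50–500 ms — 110
points) by the between-session Pearson correlation of pooled pairwise FI,
with ICC(2,1) reported alongside. Within a grid point the surrogate draws are
seeded identically for both sessions of a subject, which makes the surface
deterministic given the cohort and gives copied sessions a repeatability of
exactly 1.

## Fingerprinting with discrete HMMs

Each connection's label sequence from the first session is modelled by a
discrete-emission HMM over the 37-symbol alphabet, trained with Baum–Welch
(scaled forward–backward; tolerance 1e-4, up to 200 iterations, 2 random
restarts) with the state count chosen by BIC over a small grid (default 2–3).
The epoch-wise probability-distribution feature matrix (6 × 36) is retained as
a descriptor; the HMM itself is trained on the raw label sequence, the only
object on which discrete Baum–Welch is well defined. For classification the
stored emission matrix is lightly smoothed toward uniform (weight 1e-3) so a
test sequence containing symbols unseen in training keeps a finite
log-likelihood; BIC and the monotone EM trace use the raw fit.

Identification proceeds in the classical closed-set way: subject $m$'s
second-session sequence on edge $e$ is scored under every subject's model for
that edge, and the predicted identity is the argmax of the (summed)
log-likelihood. Edges are ranked by single-edge accuracy, then greedily
accumulated in rank order, keeping an edge only when the summed-log-likelihood
accuracy strictly improves, and stopping at 100% or after five consecutive
non-improving candidates — so the retained accuracy curve is non-decreasing by
construction.

For external matching against a second cohort, the training similarity matrix
(models × second-session sequences over the selected edges) yields two score
populations: the diagonal (self) and the off-diagonal (cross). Both are
summarized as mean ± sd, but the decision cutoff is placed halfway between the
*largest off-diagonal* and the *smallest diagonal* score: cross-subject
log-likelihoods are strongly left-skewed (a wrong model can be arbitrarily
unlikely), so an SD-buffered rule routinely declares cleanly separated cohorts
non-separable while the facing extremes define the actual gap. Matching uses
at least the five top-ranked connections even when the greedy accuracy set is
smaller: the greedy set optimizes identification accuracy, whereas threshold
stability improves with more log-likelihood summands. A cohort-1
subject is declared present in cohort 2 when its best summed log-likelihood
there exceeds the cutoff; the match is the argmax. The differentiability score
of a subject is the z-score of its self (or best) match against its
cross-subject scores.

The subnetwork analysis partitions the edge universe by a user-supplied
5-network ROI map into 5 within- and 10 between-network groups (15 runs) and
repeats the summed-log-likelihood identification per group.

## Baselines

Four reference methods calibrate how much of the identification performance
the DoCM dynamics actually carry: (i) Welch power-spectral profiles per ROI
(2-s Hann segments, 50% overlap, constant detrend, 0–90 Hz at 0.5-Hz bins)
matched by maximum absolute correlation; (ii) static per-band iPLV connectomes
(vectorized upper triangle) matched the same way; (iii) the dynamic
coupling-strength stack matched by minimum Euclidean distance; and (iv) random
edge subsets of the same size as the selected set, scored with the same
summed-log-likelihood classifier.

## The synthetic cohort generator

No public recordings accompany this problem, so the package ships a generator
whose defaults define the validation conditions. Each region is a sum of
eight band-limited Gaussian-noise oscillations with a $1/f^{1/4}$ amplitude
profile plus 1/f background noise (`noise_level = 0.2` relative to the
unit-variance oscillatory mixture). Band-passed noise rather than sinusoids
keeps phases non-degenerate, so surrogate nulls behave as on real data.

A subject's identity is their `coupling_plan`: a common set of driven region
pairs (default 6 disjoint edges on 20 regions, shared by the whole cohort, as
befits anatomically conserved hubs) on which each subject has private mode
sets (two modes per edge, drawn from modes whose slow band is theta or above
so every planted mode is resolvable in 1-s windows) and private sticky Markov
dynamics (0.5-s ticks, stay probability 0.6–0.9, geometric dwell times of
roughly 1.3–5 s). Sessions are fresh realizations of the same plan: the plan,
not any waveform, is what repeats across sessions.

Coupling episodes are realized as coherent bursts. For a within-frequency
mode the target region's band component is cross-faded (50-ms raised-cosine
ramps) to an exact quarter-cycle Hilbert-shifted copy of the source's band
component at `snr = 4` times the baseline band amplitude, with the source
component amplified by the same factor; sharing the source envelope keeps the
planted signal inside the band so the pipeline's re-filtering does not jitter
its phase. For PAC the target's fast band becomes a constant-modulus FM
carrier whose envelope is $(1 + d\cos(\varphi_{\mathrm{slow}} - \pi/2))$
modulated (depth $d = 0.9$): a noisy-envelope carrier would mask its own
modulation, and the quarter-cycle modulation lag is required because the
estimator's final stage is an imaginary-part locking. These amplitudes were
fixed once, from estimator-level pilot runs of the planted constructions
against independent-pair nulls, so that a full-strength planted mode is
recovered as the per-window label in well over 70% of windows — the operating
point the generator is meant to emulate: strong, burst-like, clearly
resolvable coupling episodes.

What the generator does *not* emulate: spatial leakage and volume conduction
(regions are uncorrelated unless driven), realistic head geometry,
non-stationary background spectra, artifacts, or amplitude–amplitude
coupling. Passing the suite therefore shows the statistical machinery is
correct and calibrated under its stated model, not that any particular
identification rate will hold on real recordings.

## Numerical choices and degenerate inputs

* Artifact screening standardizes per-window kurtosis, order-2 Rényi entropy
  (16-bin histogram over ±4 SD) and skewness with median/MAD by default: a
  contaminated window cluster of fraction $p$ can sit at most
  $\sqrt{(1-p)/p}$ plain SDs from the mean — below 2 for $p > 0.2$ — so plain
  z-scores can never flag more than 20% of windows and the component criterion
  (>20% of windows with all three scores outside ±2) would be unreachable;
  robust scales restore it. `robust = FALSE` gives the literal z-score
  variant. Constant components are flagged as degenerate.
* The ROI representative weights voxels by the sum of absolute Pearson
  correlations to the other voxels of the region (self-correlations excluded —
  they only add a constant), normalized to sum to 1; weights are computed once
  per session (per-window weights at 1-s windows are dominated by estimation
  noise). A single voxel gets weight 1; any NaN is an error.
* Epochs for the PD feature matrix are `10 * ceiling(T/60)` windows wide
  (500 at the full scale of 2991 windows, last epoch shorter), falling back to
  an even six-way split for very short sequences.
* Argmax classification breaks ties toward the lower subject index; exact
  ties have probability zero in floating point.
* Empty sequences score log-likelihood 0 (empty product); single-symbol
  sequences yield a 1-state model with a warning; all-zero label sequences
  produce a zero comodulogram and an all-zero feature matrix, both flagged.
* Cohort containers are serialized as RDS with schema validation on load
  (rate present, equal ROI counts, finite values); matrices and reports are
  written as CSV/JSON. Every pipeline run records a configuration hash and the
  seed.

## Problem sizes

The shipped tests and the acceptance script exercise the full machinery at
desk scale, chosen as the package's validation conditions: a two-session
cohort of 10 subjects, 20 regions and 60 s at 600 Hz for within-study
identification and baselines (591 windows, 190 edges, 36 modes); a 12-region,
60-s pair of cohorts (10 and 20 subjects, 6 hidden overlaps) for external
matching; 4-region micro-networks for planted-mode recovery; and enumerable
instances (2 states, length 6) for the exhaustive HMM oracle. Full-scale
settings (90 regions, 300 s, 10,000 surrogates) are configuration presets,
not requirements.

## Known limitations

* A 1-s window holds under three delta cycles; delta-involved modes at the
  default width carry a reliability warning and are excluded from the
  generator's planted-mode palette.
* The pooled null assumes pairs are exchangeable under the null; strong
  heterogeneity of spectra across regions would call for stratified pooling.
* The iPLV family is blind to genuine zero-lag coupling by construction.
* Greedy edge selection is not optimal; it mirrors the step-wise aggregation
  it is meant to study.
* The external-match cutoff depends on two order statistics of the training
  similarity matrix and inherits their sampling noise in small cohorts.
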