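---
title: "Microstate dynamics and band-power analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate dynamics and band-power analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`microdyn` implements a complete group-analysis pipeline for resting-state
EEG: microstate segmentation and dynamics features, frequency-band power
with a group ICA decomposition, a two-stage statistical battery, and
SVM-RFE classification. Because clinical EEG datasets are rarely shareable,
the package also ships a synthetic-cohort generator with fully known ground
truth; every stage of the pipeline is validated against quantities that the
generator plants. This vignette explains the models, the tunable parameters
and the choices made where the methodology left room for judgement.

## Microstates

Resting EEG topographies do not vary continuously: the scalp potential
field stays quasi-stable for roughly 60-120 ms and then switches to a new
configuration. These discrete states, four of which (labeled A-D)
reappear across studies with characteristic geometries, are extracted as
follows.

**Global field power.** For an average-referenced sample
$V(t) \in \mathbb{R}^{n}$ over $n$ electrodes,
$$\mathrm{GFP}(t) = \sqrt{\tfrac{1}{n}\sum_{i=1}^{n}\left(V_i(t) - \bar V(t)\right)^2},$$
the spatial standard deviation (population divisor). Topographies at GFP
peaks have the highest signal-to-noise ratio, so only peak samples enter
clustering. A peak is an interior sample with a strict rise and non-strict
fall (`gfp[t-1] < gfp[t] >= gfp[t+1]`); a flat plateau contributes its
first sample. This deterministic rule matters only for ties that are
measure-zero in real data but must be reproducible.

**Modified k-means.** Resting-state topographies are polarity-ambiguous
(the sources' sign flips with the oscillatory phase), so clustering must
identify $v$ with $-v$. Assignment uses the squared spatial correlation;
the centroid update is the dominant eigenvector of the assigned maps'
channel covariance, the natural polarity-invariant analogue of the mean.
Iteration runs to an assignment fixpoint (cap 100). Because the objective
is non-convex, the procedure restarts from random map initialisations
(`n_restarts`, default 100) and keeps the solution with the highest GEV. A
restart count in the hundreds is conventional; the default is configurable
and the chosen solution's GEV is non-decreasing in the number of restarts
by construction.

**Global explained variance.** With maps $a_k$ and per-sample labels
$L(t)$,
$$\mathrm{GEV} = \frac{\sum_t \mathrm{GFP}(t)^2\, r^2\!\left(V(t), a_{L(t)}\right)}{\sum_t \mathrm{GFP}(t)^2},$$
where $r$ is the polarity-invariant spatial correlation. Zero-GFP samples
contribute to neither sum.

**Two-level clustering and A-D labelling.** Clustering runs per subject
first; each subject's $K$ maps are then pooled within a group and
re-clustered to give the group model. Group models are aligned to their
grand mean and labeled A-D by the permutation of the four maps (exhaustive
over all $4! = 24$) that maximises the summed absolute correlation with
reference templates. The built-in references are synthesized canonical
gradients — two mirrored diagonals, an anterior-posterior gradient, and a
fronto-central focus — since the classical normative maps are not
redistributable; users can supply their own reference matrix.

**Back-fitting and features.** Every sample (not only peaks) is labeled
with the map of maximal absolute correlation; ties and zero-variance
samples inherit the previous label (lowest index at the start). No
minimum-duration smoothing is applied by default — smoothing changes dwell
statistics and the default keeps the estimator unbiased with respect to
the generator's Markov dynamics. Run-length encoding then yields, per
state: mean duration (ms), occurrence (segments/s) and coverage (fraction
of samples), plus the $K \times K$ segment transition matrix normalized
per source state (row-stochastic, zero diagonal). Row-normalizing by
segments-with-a-successor is the only convention that makes the 12
off-diagonal entries independent of recording length. Boundary segments
(first/last, possibly truncated) are included in duration statistics;
their effect is a small negative bias that vanishes with recording length
and applies equally to all groups. At $K = 4$ the flattened vector has
$4 + 4 + 4 + 12 = 24$ features.

## Band power and group ICA

Absolute band power uses a Welch estimate: 2-s Hamming windows (matching
the preprocessing epoch length), 50% overlap, per-segment mean removal,
one-sided density in µV²/Hz. Band power integrates the density over the
FFT bins in $[f_{low}, f_{high})$ by bin-mass (Riemann) summation.
Riemann rather than trapezoid integration is deliberate: a spectral line
falling on a band's edge bin keeps its full mass in exactly one band, and
the six-band total respects Parseval. The bands are delta 1-4, theta 4-8,
low alpha 8-10, high alpha 10-12, beta 12-30 and gamma 30-45 Hz; the
theta/beta ratio (TBR) is computed channel-wise so that it forms a
subjects-by-channels matrix like the six power bands.

Each of the seven subjects-by-channels matrices is decomposed with ICA:
the matrix is column-centered, PCA-whitened to $M$ components and unmixed
by extended Infomax (natural-gradient entropy maximisation with a
kurtosis-sign switch so sub-Gaussian sources are handled). The learning
schedule follows the classic EEG practice: annealing when the update
direction swings by more than 60 degrees, plus a slow unconditional decay
so that flat directions spanned by near-Gaussian trailing components
cannot drift indefinitely; convergence is declared when the realized
relative weight change drops below $10^{-5}$, a point at which planted
sources are recovered to $|r| \approx 0.999$ in validation. The
decomposition sweep covers $M \in \{5,\dots,10\}$; which $M$ is featured
per band is a reporting choice, not hard-coded.

Components are oriented so the reference group's mean loading is the
larger (a pure sign convention), tested for group differences with
pooled-variance t-tests at the Bonferroni level $\alpha/M$, and their
spatial maps are channel-standardized; channels with $|Z| > 2$ are
reported as the component's top contributors.

## Statistics

The two-stage battery mirrors the study design: stage 1 contrasts
patients with controls using models clustered across everyone; stage 2
re-clusters within the two patient subtypes and contrasts them. Per
feature family (duration, occurrence, coverage, transitions) a two-way
fixed-effects ANOVA on the long format tests the group-by-state
interaction. State is in truth a within-subject factor; the fixed-effects
layout treats observations as independent, which is flagged in the report
rather than silently repaired, because the emulated design did not specify
a repeated-measures model. Post-hoc pooled-variance t-tests per feature
use the Bonferroni threshold $0.05/24$.

Demographic comparisons use the Pearson chi-square *without* continuity
correction — the convention is pinned down by the emulated cohort table,
whose printed values (0.73, 0.34, 4.17) reproduce exactly without the
correction and not with it. Likewise pooled-variance (Student) rather than
Welch t-tests reproduce the printed age comparison; Welch is available via
the raw-data interface if wanted.

The topography comparison ranks, per state, a scalar per subject: the
absolute spatial correlation between the subject's individual map
(optimally permuted and signed against the grand-mean model) and the
grand-mean map of that state, compared across groups by tie-corrected
Kruskal-Wallis. The ranked quantity is this package's operationalization;
any monotone measure of map similarity would serve.

## Classification

SVM-RFE runs inside stratified (class-ratio preserving) five-fold
cross-validation. Within each training fold, features are z-scored on
training statistics only, a linear SVM ($C = 1$) is fitted, and the
feature with the smallest squared weight is eliminated, one per step,
until a full ranking exists. Every nested prefix of the ranking is
evaluated on the held-out fold; the fold's best subset maximises held-out
accuracy with ties resolved toward fewer features. Reported accuracy,
sensitivity (patient recall) and specificity (control recall) are fold
means at the per-fold best subsets, and `selection_counts` records how
many folds retained each feature — the feature-stability ranking.
"Balanced" folds are interpreted as stratified; with a 2:1 class ratio an
optional subsampling interpretation would discard data, so stratification
is the default.

## The synthetic cohort

The generator is an emulation contract, not a claim about real EEG. Each
subject's label sequence is a semi-Markov chain: geometric dwell times
(memoryless, the simplest model consistent with Markov dynamics and the
reported 60-120 ms quasi-stability) with group-specific mean durations,
and group-specific zero-diagonal transition matrices. The planted group
structure mirrors the direction of the emulated findings: patients have
fewer A-C transitions, more B-D transitions, less state C and longer
state D; the combined subtype additionally shortens state A, routes more
transitions into state B, and carries stronger posterior-occipital gamma;
patients carry stronger fronto-central delta and fronto-temporal theta
(raising TBR).

The signal model is
$$V(t) = s_{\mathrm{seg}} \cdot a(t) \cdot A \cdot T_{L(t)} + \text{band sinusoids} + \varepsilon(t),$$
with $T_k$ unit-norm mean-zero templates on a synthetic disc montage,
$s_{\mathrm{seg}} \in \{-1,+1\}$ a random per-segment polarity (forcing
polarity-invariant analysis), and $a(t)$ a rectified 10 Hz envelope
*with a positive floor*, $(0.3 + |\sin 2\pi \cdot 10 t|)$ rescaled to
mean one. The floor is a deliberate design choice: a strictly rectified
envelope has exact zeros every 50 ms, at which the signal is pure noise,
back-fitted sequences fragment, and dwell statistics become unrecoverable
at any noise level — an artifact of the envelope, not of the method under
test. The floor preserves the waxing-waning GFP that makes peak-picking
meaningful while keeping every sample identifiable.

Scale choices ($A = 100$ µV on the unit-norm map, i.e. about 10 µV
per-channel RMS; sensor noise 2 µV) follow from signal-to-noise
reasoning: at the envelope floor, the correlation margin between the true
template and its closest competitor exceeds four standard deviations of
the noise projection, so mislabelling is rare, while peak voltages stay
well below the 100 µV artifact-rejection threshold. The rectified
envelope also gives the source broadband harmonic content (20 Hz
fundamental and overtones spread by the random segment polarity), which
acts as a crude stand-in for the broadband background of real EEG.

What the generator does *not* emulate: no volume-conduction forward
model, no 1/f spectral background, no ocular/muscle artifacts, no
electrode-position realism (channels are points on a disc; region masks
are disc sectors). Passing recovery tests therefore demonstrates the
estimators' correctness under the stated model, not robustness to real
recording pathology. Metadata (sex, age, handedness, rating-scale scores)
are sampled per group from the emulated cohort's margins so the
demographic statistics exercise realistic tables.

## Numerical choices and degenerate inputs

* Preprocessing order is select → band-pass → resample → average
  reference → epoch rejection → trim, recorded in the recording's
  history. Filtering precedes resampling so the 45 Hz edge cannot alias.
* The band-pass is a linear-phase FIR applied once with exact group-delay
  compensation and anti-symmetric edge reflection — zero-phase without
  the fragility of forward-backward filtering when the kernel is long
  relative to the recording; order ≈ 3·fs/f_low, capped by the recording
  length.
* Epoch rejection: a 2-s window dies if any channel exceeds ±100 µV
  anywhere in it; shorter-than-requested survivors proceed with a warning
  (exploratory practice) and the retained duration is logged.
* `cluster_microstates` reseeds a dead cluster from the currently
  worst-fit map; all-equal peak maps are rejected as having fewer than K
  distinct maps.
* `backfit` on an all-zero leading segment assigns the lowest map index;
  `compute_gev` refuses an all-zero recording.
* All generators save and restore the caller's RNG state; every
  stochastic function takes an explicit seed, and the pipeline derives
  stage seeds from one master seed, so identical configurations produce
  byte-identical artifacts.

## Problem sizes in the validation suite

The test suite and the acceptance script run reduced-scale versions of
the study conditions, chosen to keep full validation runs convenient on a
single core: parameter-recovery cohorts use 10-20 subjects at the study's
91-channel, 250 Hz geometry with 60-120 s recordings over 5-20 seeds;
ICA effect-recovery cohorts use 16 subjects per group at 20 s; null
calibrations use 200-500 replicates at n = 12 per group; end-to-end
pipeline checks use 15-30 subjects at 24-48 channels. The study-scale
defaults (161 subjects, 120 s) remain the package defaults and run in
tens of minutes.

## Known limitations

* The fixed-effects interaction ANOVA ignores the within-subject
  correlation across states; its null calibration is verified by
  simulation under exchangeable errors, but a repeated-measures model
  would be more efficient on real data.
* The ICA's component count per band is a reporting choice; no automatic
  model-order selection is provided.
* K is fixed at 4; no cluster-number criteria (cross-validation,
  Krzanowski-Lai) are implemented.
* EDF I/O is not provided; the plain-text matrix format is the
  interchange format, chosen for exactness and auditability.
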