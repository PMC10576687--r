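# microdyn

Resting-state EEG group analysis: microstate dynamics, band power with
group ICA, two-stage statistics, and SVM-RFE classification — with a
synthetic-cohort generator that makes every stage testable against known
ground truth.

## The problem

Resting EEG alternates between quasi-stable scalp topographies
("microstates", ~60–120 ms each, canonically labeled A–D). How long each
state lasts, how often it occurs, how much time it covers, and how states
transition into one another are compact descriptors of large-scale brain
dynamics, and band-limited spectral power (delta through gamma, plus the
theta/beta ratio) complements them in the frequency domain. Group studies
— for example contrasting children with ADHD against controls, or ADHD
subtypes against each other — need these features extracted reproducibly,
tested with appropriate corrections, and fed into a classifier whose
feature selection is auditable. `microdyn` packages that entire path for
R users working with multichannel resting EEG.

## The method

* **GFP**: per-sample spatial standard deviation
  `GFP(t) = sqrt(mean_i (V_i(t) − V̄(t))²)`; topographies at GFP peaks
  enter clustering.
* **Modified k-means**: polarity-invariant clustering of peak maps
  (assignment by squared spatial correlation, centroids as dominant
  eigenvectors), restarted many times, best solution by **GEV**
  `= Σ_t GFP(t)² r²(V(t), map_L(t)) / Σ_t GFP(t)²`.
* **Two-level models**: subject-level maps pooled and re-clustered per
  group; group maps labeled A–D against canonical reference gradients by
  exhaustive permutation matching; every sample back-fitted to the most
  correlated map.
* **24 features** at K = 4: per-state mean duration, occurrence and
  coverage (4 + 4 + 4) plus the 12 off-diagonal segment-transition
  probabilities.
* **Spectral ICA**: Welch absolute power per channel in six bands plus
  channel-wise TBR, arranged as subjects × channels matrices and unmixed
  with extended Infomax; components oriented by group mean, tested at
  Bonferroni α/M, localized by |Z| > 2 channels.
* **Statistics**: two-way group×state interaction ANOVA per feature
  family, Bonferroni post-hoc pooled t-tests (0.05/24), Pearson χ²
  (no continuity correction) for demographics, Kruskal–Wallis for
  topography similarity.
* **Classification**: linear SVM-RFE inside stratified five-fold CV with
  per-fold nested-subset evaluation and fold-wise feature-selection
  counts.

The methods vignette (`vignettes/microdyn-methods.Rmd`) documents the
models, parameter defaults and design choices in detail.

## Worked example

Simulate a small labeled cohort, run the full two-stage pipeline, and
look at what it finds:

```r
library(microdyn)

cfg <- default_config(
  seed = 11,
  simulate = list(n_hc = 8, n_adhd_c = 8, n_adhd_i = 8,
                  n_channels = 32, fs = 250, duration_s = 20,
                  amplitude = 80),
  microstates = list(K = 4, n_restarts = 6),
  classify = list(n_folds = 3)
)
res <- run_pipeline(cfg)

round(res$stage1$group_gev, 3)
#>  ADHD    HC
#> 0.996 0.998

res$stage1$anova$transitions
#> <two-way ANOVA interaction> statistic=22.73, df=11,264, p=1.89e-32 *

res$classification$stage1
#> <microdyn_clf> 3-fold SVM-RFE: accuracy 100.0%, sensitivity 100.0%, specificity 100.0%
#> top selected: tp_B_D (2/3), occ_D (1/3), tp_D_B (1/3), delta_IC5 (1/3)
```

The four microstate maps explain ≈99% of the global variance of this
synthetic cohort (the generator's maps are exactly four), the
group-by-state interaction on transition probabilities is strongly
significant because the generator plants fewer A↔C and more B↔D
transitions in the patient group, and the classifier's most-selected
features are exactly the planted signatures: the B↔D transition
probabilities, state-D occurrence, and a significant delta-band ICA
component — the kind of closed-loop check the package is built for. On real data the same call
chain applies, starting from `read_recording()` /
`preprocess()` instead of the simulator.

Single stages are available as plain functions (`compute_gfp`,
`cluster_microstates`, `backfit`, `extract_features`, `band_power`,
`ica_decompose`, `svm_rfe_cv`, ...), and a thin command line lives at
`inst/cli/microdyn.R` (`simulate`, `preprocess`, `run-all`).

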