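---
title: "Ensemble hard-voting biomarker discovery from small RNA counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble hard-voting biomarker discovery from small RNA counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sncvote)
```

## The problem

In assisted reproduction, the medium an embryo was cultured in (spent
blastocyst medium, SBM) carries small non-coding RNAs — miRNAs and
piRNAs — secreted by the embryo. Profiles of these molecules differ between
embryos that later implanted successfully and embryos that did not, which
makes SBM sequencing a candidate non-invasive test of embryo quality.
`sncvote` implements the full analysis such a study needs: from a
feature-by-sample count matrix (or record-level read fixtures) through
normalization, ensemble feature selection, leave-one-out classification and
evaluation. Because no public SBM sequencing dataset accompanies this
problem, the package ships a first-class synthetic generator that emulates
the study design and provides ground truth for every downstream stage.

## The synthetic study

`make_scenario()` fixes the design: 32 implantation-success and 28
implantation-failure embryo samples plus 3 background medium controls
(63 libraries), 1000 sncRNA features of which 7 are planted markers, and a
stratified 80/20 exploratory/validation split of the 60 embryo samples
(26 success + 22 failure exploratory, 12 validation). Counts follow the
standard RNA-seq model: a negative binomial with mean $\mu$ and variance
$\mu + \phi\mu^2$, per-feature baseline means drawn log-uniformly from
[5, 500] expected counts, and per-sample library sizes log-normal with mean
$10^6$ reads and coefficient of variation 0.3. Markers multiply the
success-group mean by $2^{\pm\Delta}$ (5 up, 2 down in success). The three
presets differ only in effect size and dispersion: `default`
($\Delta = 2.5$, $\phi = 0.3$), `strong` ($\Delta = 3.0$, $\phi = 0.1$) and
`moderate_noise` ($\Delta = 1.5$, $\phi = 0.4$).

Background controls are not empty: culture medium has its own RNA content,
so they are generated as embryo profiles attenuated by a factor 0.05. They
are excluded from normalization reference choice and from all modelling.

What the generator does *not* emulate: sequencing error, adapter artifacts,
the true catalogue size (a real run annotates on the order of $10^5$
molecules against miRBase/piRBase; 1000 features keep every test
desk-scale), compositional correlation between features, or batch
structure. Passing tests therefore demonstrate that the pipeline recovers
the structure it assumes — planted NB markers under honest
cross-validation — not that it would perform identically on real SBM
libraries.

```{r scenario}
cfg <- make_scenario("strong")
cfg
ds <- generate_dataset(cfg, seed = 1)
ds
```

## Counting rules

Record-level inputs (read length plus the set of mapped references) are
reduced to counts by two rules. Size filtering keeps 19–25 nt reads for
miRNA references and 24–32 nt for piRNA references, bounds inclusive; the
24–25 nt overlap belongs to both classes, so class membership is decided by
the reference catalogue a read maps to, not by length alone. Multi-mapped
reads are divided equally over their references: a read with $k$ hits
contributes $1/k$ to each, so total counted mass is conserved exactly.
Alignment itself (trimming, contaminant removal, mapping) is performed by
published tools and is out of scope; an optional per-record `overlap`
column is thresholded at 19 nt when present.

## Normalization

Between-sample normalization is a from-scratch trimmed mean of M-values
(TMM). For sample $s$ against reference $r$ with library sizes $N$, over
features nonzero in both,

$$M_g = \log_2\frac{y_{gs}/N_s}{y_{gr}/N_r}, \qquad
  A_g = \tfrac12\log_2\left(\frac{y_{gs}}{N_s}\cdot\frac{y_{gr}}{N_r}\right),$$

the top and bottom 30% by $M$ and 5% by $A$ are discarded (the canonical
trim fractions), and the factor is $2$ to the weighted mean of the
surviving $M_g$ with inverse asymptotic binomial variance weights
$1/v_g$, $v_g = \frac{N_s-y_{gs}}{N_s y_{gs}} + \frac{N_r-y_{gr}}{N_r y_{gr}}$.
The reference sample is the one whose 75th percentile of nonzero scaled
counts is closest to the cross-sample mean. Factors are constrained to a
geometric mean of 1 over the embryo samples; background controls receive
factors but do not influence the constraint, and normalization is computed
after the matrix is assembled but with the controls excluded from the
reference choice. The unit tests verify the implementation against an
independent step-through of the formulas on a toy and against
`edgeR::calcNormFactors` (agreement to numerical precision). Expression
values downstream are $\log_2(\mathrm{CPM} + 1)$ on the TMM-effective
library sizes. An optional per-batch median centering of log-CPM is
available (`batch_center()`) but off by default: the canonical TMM path is
the tested configuration.

One numerical nuance: with inverse-variance weighting, multiplying one
column's counts and library size by a constant changes that sample's
weights non-proportionally, so its factor is invariant only approximately
(well below 2% at realistic depths); the unweighted trimmed mean is exactly
invariant.

## Feature selection

Selection runs on exploratory samples only, in five stages.

1. **Pre-filter.** Constant features (including all-zero) are removed,
   then the bottom 10% of variances.
2. **Three rankers**, each on standardized log-CPM features:
   gradient-boosted trees ranked by gain; L1-regularized logistic
   regression ranked by $|\hat\beta|$; extremely randomized trees ranked by
   impurity importance. Ties are broken by feature id and every ranker is
   deterministic given its seed.
3. **Hard vote.** The consensus is the intersection of the three top-15
   lists (a `min_votes` knob relaxes this to "at least m of 3"), ordered by
   mean rank.
4. **ANOVA arbitration.** A Shapiro–Wilk gate (α = 0.05) on within-group-
   centered log-CPM of the consensus features selects plain one-way ANOVA
   or ANOVA on rank-transformed values; every surviving feature gets an F
   and p at df = (1, n−2), and the consensus is reported ordered by F.
5. **Volcano flags.** A feature is "deregulated" when $|\log_2 FC| \ge 1$
   and $p \le 0.05$ (boundaries inclusive), with the fold change computed
   on group-mean CPM with pseudocount 1. The raw-p gate is deliberate; no
   multiplicity correction is applied at this step.

Two ranker choices deserve explanation because the defaults a classifier
user would pick are wrong for *ranking*:

* **Boosting.** With greedy boosting and no subsampling, one member of a
  set of redundant strong predictors absorbs all the gain and the others
  never enter the ranking. The boosted ranker therefore uses 500 depth-3
  trees with shrinkage 0.05, row subsampling 0.5, per-node column
  subsampling 0.1 and L2 penalty 10, which spreads gain across redundant
  markers while leaving noise features far down the list.
* **L1 penalty.** The penalty is chosen by 5-fold cross-validated binomial
  deviance under the one-standard-error rule, with the CV curve averaged
  over five fold assignments. The plain `lambda.min` choice frequently
  admits a handful of chance-associated features on label-uninformative
  data; because all three rankers see the same data, those same features
  top every list and contaminate the consensus. The averaged 1-SE rule
  selects the empty model on null data almost always, which is what keeps
  the false-positive control tight (consensus of ≤1 feature in ≥90% of
  null-scenario replicates) while leaving true markers untouched.

## Classification

`fit_voting_classifier()` is the package's model object: an RBF support
vector machine (cost 1, γ = 1/(d·var)), a 500-tree random forest, and a
hinge-loss linear classifier trained by stochastic gradient descent
(pegasos-style, λ = 10⁻⁴, 1000 epochs) — all on standardized features,
combined by majority vote, so three voters never tie. The returned
`snc_voter` object has `print`, `summary` and `predict` methods; `predict`
reports per-model votes and the fraction of success votes as a score.

Leave-one-out evaluation re-runs the entire feature-selection stage inside
each fold by default (`nested = TRUE`), which is the leakage-safe
procedure; `nested = FALSE` reuses the global consensus, mimicking a
selection-then-CV workflow. A fold whose training labels degenerate falls
back to the majority class with a logged message; a nested fold with an
empty consensus falls back to the top features by F (at most 7).

Projections: `pca_project()` (mean-centered SVD, explained-variance
fractions) and `lda_project()`, a Fisher discriminant written directly from
the scatter matrices so that a singular within-class scatter can be
ridge-regularized (ε = 10⁻⁶ of the mean diagonal) instead of failing; the
unit tests check it against `MASS::lda` on well-conditioned data.
`detect_anomalies()` cuts a Ward-linkage dendrogram (Euclidean distance on
standardized features) into two clusters and flags samples carrying the
minority label of their cluster — the unsupervised cross-check for samples
whose label disagrees with their expression neighborhood.

## Evaluation

Implantation success is the positive class everywhere. `confusion_metrics()`
reports accuracy, sensitivity, specificity, F1, MSE of the voting score
against 0/1 truth, and the error count; `roc_auc()` uses the rank
(Mann–Whitney) formulation with ties counted ½, cross-checked against
`pROC`; `accuracy_vs_k()` traces leave-one-out accuracy as a function of
the number of top-ranked features, the curve used to confirm that seven
markers suffice (it plateaus at or before k = 7 on the planted scenarios).
`run_pipeline()` chains every stage, writes all tables plus a provenance
manifest, and is byte-reproducible for a fixed config.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed: dataset generation is fully
determined by `(config, seed)`, the three rankers receive consecutive
seeds, and leave-one-out folds derive per-fold seeds by offset. The test
suite runs the full presets (1000 features, 48 exploratory samples) for the
recovery and threshold checks, a 50-replicate Monte-Carlo check of the
generator's planted effect sizes, a 20-seed null-scenario false-positive
control, and desk-scale toys (≤ 200 features) elsewhere; the
accuracy-vs-k curve is evaluated at k ∈ {7, 11, 20} on the fixed consensus
ranking.

## Known limitations

* The consensus can be empty on weak-signal data; the pipeline then falls
  back to the top-F features rather than failing, and says so.
* ANOVA arbitration uses log-CPM values (or their ranks); arbitration on
  model residuals is not implemented.
* The generator draws features independently; correlated co-regulation and
  compositional effects are not modelled, so the false-positive control
  speaks to chance associations, not to confounded ones.
* Reported sensitivities/specificities on synthetic scenarios are
  properties of the planted signal strength; they are upper bounds on, not
  estimates of, real-data performance.
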