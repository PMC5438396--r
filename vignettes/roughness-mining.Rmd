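---
title: "Mining cortical roughness for case-control diagnosis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining cortical roughness for case-control diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the pipeline

Essential tremor (ET) is a common movement disorder whose clinical
diagnosis is error-prone. Structural MRI morphometry offers candidate
biomarkers: regional volumes, mean cortical thickness, and — the measure
this package is organized around — **roughness**, the standard deviation
of cortical thickness across the vertices of a region. Thinning of a
sub-area raises the SD of the region it sits in before it moves the
regional mean, which is why roughness can outperform mean thickness as a
discriminative feature at early disease stages.

`etminer` implements the full data-mining pipeline around that idea:

1. **Feature extraction** (`parse_stats_table()`, `assemble_features()`,
   `extract_subject()`): FreeSurfer-style parcellation/segmentation stats
   tables are parsed into a fixed 281-feature schema — 129 volume-typed
   features (cortical gray volumes, subcortical segmentation volumes,
   cerebral white matter, total gray, and intracranial-volume ratios),
   76 regional/lobar mean-thickness features, and 76 roughness features,
   following the Desikan-Killiany parcellation (34 regions per
   hemisphere) plus four lobar composites per hemisphere.
2. **Univariate statistics** (`compare_groups()`, `summary_t_test()`,
   `chi_square_test()`, `pairwise_letter_groups()`).
3. **Ensemble feature ranking** (`rank_features()`): six univariate
   measures, min-max normalized and averaged.
4. **Classification sweep** (`run_sweep()`): five classifiers evaluated
   on nested top-*n*% fragments of the ranking under stratified 10-fold
   cross-validation.
5. **Rule induction** (`induce_rules()`, `apply_rules()`): an ordered
   decision list grown by sequential covering, used both as one of the
   classifiers and as a descriptive subgrouping device; the published
   five-rule diagnostic model ships as `printed_rule_model()`.
6. **Synthetic cohorts** (`generate_cohort()`): a seeded generator that
   emulates the 36-subject study population so every downstream stage is
   testable without access to the original MRI data.

## Roughness

For a region with per-vertex thickness $t_1, \dots, t_n$ (mm), roughness
is the sample SD with the $n-1$ denominator — the same convention as the
`ThickStd` column of parcellation stats tables, which is where the
feature comes from in practice. A mean-normalized variant (the
coefficient of variation) is available via
`compute_roughness(x, normalized = TRUE)` because the measure is
occasionally described that way; it is never the default, since the
plain SD is what the stats-table convention defines. Lobar composite
features aggregate member regions: vertex-count-weighted means for
thickness, pooled SDs ($\sqrt{\sum_i (n_i - 1) s_i^2 / (\sum_i n_i - k)}$)
for roughness. The lobar member lists (frontal 11, temporal 9, parietal
5, occipital 4 regions) are packaged; cingulate regions and the insula
belong to no lobe.

## The six-measure ensemble ranking

Each feature is scored by six measures against the binary class label.
The frequency-based measures operate on an equal-frequency
discretization (default `n_bins = 3`, leaving at least 12 subjects per
bin at $n = 36$; ties at a bin edge go to the lower bin):

* **chi-squared**: $\sum (O - E)^2 / E$ over the bins-by-class table;
* **information gain** (bits): $H(\mathrm{class}) - \sum_b p(b)\,
  H(\mathrm{class} \mid b)$;
* **gain ratio**: information gain divided by the entropy of the bin
  partition (0 when that entropy is 0);
* **Gini gain**: the same decomposition with Gini impurity;
* **symmetrical uncertainty**: $2\,IG / (H(\mathrm{class}) +
  H(\mathrm{bins}))$;
* **one-rule accuracy**: the training accuracy of the best single
  threshold rule over all midpoints and both orientations, computed on
  the raw values.

Scores are min-max normalized to $[0,1]$ *within the feature subset
being ranked* (so a volume-only ranking is self-normalized), averaged
with equal weights, and sorted in descending order with a lexicographic
name tie-break. All six measures depend only on the ordering of the
feature values, so the ranking is invariant under strictly monotone
transformations — a property the test suite asserts.

Two formula-level decisions deserve a note. The source material prints
its chi-squared expression with a "$\times 2$" where the surrounding
prose describes *squared* discrepancies; the squared form is
implemented. Its uncertainty expression as printed can leave $[0,1]$
and under-specifies its conditional probability; the measure is named
"symmetrical uncertainty" in the text, so standard SU is implemented,
with the literal printed expression available as
`score_uncertainty(..., variant = "literal")` for comparison only.

## Classifiers

Five classifiers sit behind one `train_classifier()` / `predict()`
contract, with the stated hyperparameters as defaults
(`classifier_spec()`):

| kind | model | key defaults |
|------|-------|--------------|
| `nb` | Gaussian naive Bayes | Laplace-smoothed class priors (add 1); per-class variance floored at $10^{-9}$ of the pooled feature variance |
| `svm` | C-SVC, RBF kernel | convergence tolerance $10^{-3}$; $C = 1$, $\gamma = 1/p$ (conventional library defaults, configurable) |
| `rule` | sequential-covering decision list | pureness 0.99, information-gain scoring, min coverage 2 |
| `knn` | k-nearest neighbours | $k = 3$, Manhattan (L1) distance, inverse-distance vote weights; a query at distance zero short-circuits to the training labels at that point |
| `ann` | multilayer perceptron | 1 hidden layer of 20 sigmoid units, 10,000 full-batch epochs, learning rate 0.2, momentum 0.15, squared-error loss, weights initialized Uniform(−0.5, 0.5) from the run seed |

Inputs to `svm`, `knn` and `ann` are z-scored with center/scale fit on
the training split only; `nb` and `rule` operate on raw values. Whether
the original analysis standardized is unknown and materially affects
accuracy — the choice here is the common practice for distance- and
gradient-based learners, and it is prominently configurable in the
source. The ANN trains full-batch, so its fit is invariant to
training-row order given the seed.

## The fragment sweep

Within each feature-type subset (`all` 281, `thickness` 76, `roughness`
76, `volume` 129), features are ranked and classifiers evaluated on the
top-$n\%$ fragment for $n \in \{5, 7, \dots, 99, 100\}$ (the 2-point
grid starting at 5 never lands on 100, which is appended). Fragment
size is round-half-up$(n/100 \times$ subset size$)$ with a minimum of
one feature — the rounding rule consistent with most of the published
argmax feature counts (10/76 at 13%, 36/76 at 47%, 23/152 at 15%,
19/129 at 15%, 6/129 at 5%, and 62/281 at 22%, though 22 itself is not
on the odd grid). Cross-validation is stratified 10-fold with a shared
fold assignment per cohort; fold sizes differ by at most one and each
fold keeps both classes.

By default the ranking is computed **once on the full dataset** and the
fragments are fixed across folds (`mode = "rank-once"`). This mirrors
the descriptive design the pipeline reproduces, and it is optimistically
biased: the ranking has seen the validation subjects. The leakage-safe
alternative re-ranks inside every training split
(`mode = "rank-per-fold"`) and is the recommended setting for any new
study; the test suite includes a canary check that the per-fold ranking
cannot see test rows. Because a label permutation with *fixed* features
is the cleanest leakage guard, the suite also verifies that every
classifier's CV accuracy on permuted labels is statistically
indistinguishable from 0.5.

`compare_subsets()` compares feature types per classifier by pairwise
pooled t-tests on the per-fragment accuracy vectors,
Bonferroni-corrected over the subset pairs, summarized as a compact
letter display (insert-and-absorb; groups sharing no letter differ
significantly).

## Rule induction and the printed model

`induce_rules()` grows one rule at a time: repeatedly add the (feature,
orientation, midpoint-threshold) condition with the highest information
gain on the currently covered subjects, keeping the purer side, until
the covered set reaches **pureness** (the fraction of covered subjects
in their majority class, default 0.99) or no condition improves; commit
the rule, remove covered subjects, repeat; finish with an unconditional
default rule. Ties break lexicographically by feature name, then by
smaller threshold, making induction deterministic. `min_coverage`
(default 2) keeps singleton rules out except the default. Rules are
applied with first-match semantics.

Because the first-split information gain of a perfectly balanced XOR
arrangement is zero, a greedy gain-driven coverer cannot enter such a
configuration; it solves XOR-like structure as soon as the corner
counts are unbalanced. This is a known property of the greedy scheme,
not a defect of the implementation, and the tests exercise it
explicitly.

The published five-rule diagnostic model (thresholds 0.666, 0.609,
0.696, 0.841, 0.558, 0.514 on six roughness features) ships as a JSON
fixture; its per-rule coverage counts describe the original cohort and
are stored as metadata only — they are never asserted against synthetic
data.

## The synthetic cohort generator

`study_cohort_spec()` encodes the study conditions: 36 subjects in five
rule-defined subgroups — 9 + 8 + 1 controls and 12 + 6 cases — with
covariates (age, sex proportion, education) per subgroup. Every schema
feature draws from exactly one of three Gaussian tiers, with subgroup
parameters taking precedence over group parameters over the background:

* **subgroup tier** — the eight cortical features published with
  subgroup-level means/SDs, plus the four roughness features the printed
  rules test but whose subgroup distributions were not published
  (lateral occipital, medial orbitofrontal, frontal lobe, pars
  triangularis). For those four, parameters were chosen once so that
  each subgroup predominantly follows its printed rule path (e.g.
  control subgroup 1 sits below the 0.609 lateral-occipital threshold,
  the case subgroups sit above 0.514 on pars triangularis); with these
  choices the printed model recovers the generating group label for
  roughly 85–90% of subjects, satisfying the design requirement of
  rule-separability without making the cohort trivially separable.
* **group tier** — the nineteen further features published with
  case-control means/SDs (one of them an ICV-ratio).
* **background tier** — everything else: thickness ~ N(2.6, 0.15) mm,
  roughness ~ N(0.65, 0.08) mm, volumes ~ N(structure-specific packaged
  mean, 10% CV), ICV ~ N(1.5 × 10⁶, 10% CV) mm³; magnitudes consistent
  with the published tables and standard adult morphometry.

Draws are truncated at zero. Ratio features with explicit parameters
are drawn directly and their raw volume back-derived as ratio × ICV;
all other ratios are derived as volume / ICV, so the identity
ratio = volume/ICV holds throughout every generated table. One master
seed drives counter-based per-subject streams, so generation is
bit-reproducible and growing a cohort never reshuffles earlier
subjects.

**What the generator does and does not emulate.** Features are drawn
independently (an optional correlation matrix hook exists for
sensitivity studies): real morphometry is strongly spatially
correlated, and only group/subgroup means and SDs were published, so
any correlation structure would be invented. Consequently the synthetic
cohorts are *more* separable than real data — many independent features
each carry a little signal, where in reality they would share it. Tests
passing on synthetic cohorts therefore demonstrate the pipeline's
correctness and its behavior under the published effect sizes, not the
field accuracy of the method on new MRI data. The published headline
(~81% with roughness features) is reproduced as a *lower bound* on the
synthetic analogue for the same reason. Two further emulation notes:
the published subgroup table shows the right-inferior-parietal
roughness of one *control* subgroup as high as the case subgroups, so
at whole-group level that feature separates weakly here, exactly as it
is absent from the published group-level table; and "posterior
temporal" (a published row, not a Desikan-Killiany region) is mapped to
the banks of the superior temporal sulcus.

## Numerical choices and degenerate inputs

* Normality gate for `compare_groups()`: Shapiro-Wilk at α = 0.05 per
  group (the original analysis names no test); configurable.
* Chi-squared without continuity correction — the published sex-table
  value (1.001) is only consistent with an uncorrected statistic;
  recomputation from the printed counts gives 1.003, a discrepancy
  reported as-is.
* Bonferroni family = number of features tested in the call; raw and
  adjusted p are always both reported, because the published
  group-comparison p-values appear unadjusted despite their caption.
* Published t(34) = 2.455 for right superior frontal thickness is
  inconsistent with its own printed means/SDs (recomputation ≈ 3.15);
  treated as a typo and excluded from checks.
* Constant features are skipped (statistics) or zero-scored (ranking)
  with flags, never fatal; a failed sweep cell records `NA` rather than
  a fabricated value; subjects missing a model feature are flagged and
  skipped by `apply_rules()`.
* Equal-frequency bins collapse gracefully under heavy ties; a single
  surviving bin marks the feature degenerate.

## Problem sizes used by the shipped checks

The package's own verification runs at deliberately chosen sizes: the
headline-accuracy check generates ten 36-subject cohorts (seeds 1–10)
and sweeps the roughness and thickness subsets with the naive Bayes,
rule and kNN classifiers over the full 49-point fragment grid under
10-fold CV — the three classifiers that dominate the published
roughness/thickness results; the ANN is exercised in the unit and
permutation tests at reduced epoch counts (its epoch budget is an
ordinary hyperparameter) rather than in the sweep, where its 10,000
full-batch epochs add hours without changing the best cell. Oracle
comparisons run on 1,000 random small contingency tables; permutation
checks use 12 label permutations per classifier under 10-fold CV.

## Known limitations

* The synthetic generator cannot validate diagnostic accuracy on real
  cohorts; it validates the machinery and the published effect sizes.
* `rank-once` mode is optimistically biased by construction; use
  `rank-per-fold` for honest generalization estimates in new studies.
* The rule learner is deliberately overfit-capable (pureness up to 1.0
  with unlimited rules); it is a descriptive device as much as a
  classifier.
* Binary labels only; no covariate adjustment, no probability
  calibration, no metrics beyond accuracy (AUC is available from class
  scores but is not used in summaries).
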