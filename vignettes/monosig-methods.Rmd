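---
title: "Methods: signature scoring, subtyping and outcome association in monosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature scoring, subtyping and outcome association in monosig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Severe tissue injury reprograms circulating monocytes: a set of
inflammatory and emergency-myelopoiesis programs is induced within hours,
while steady-state programs (interferon response, MHC class II antigen
presentation, and others) are suppressed. The magnitude of this deviation
differs sharply between patients and tracks with how quickly they recover.
`monosig` implements the computational road from that observation to a
patient classifier:

1. derive disjoint gene modules from cluster-labeled single-cell data
   (`pairwise_degs()`, `cluster_gene_modules()`);
2. score the six canonical modules C1–C6 in bulk patient transcriptomes
   (`signature_scores()`, `intrinsic_scores()`, `ids()`);
3. stratify patients into a high-deviation subtype SG1 and a low-deviation
   subtype SG2 (`cluster_subtypes()`, `score_pca()`);
4. train a transferable random-forest classifier on the intrinsic scores
   (`train_subtype_classifier()`, `predict_subtype()`);
5. associate subtypes with time-to-recovery (`km_estimate()`,
   `logrank_test()`, `cox_fit()`).

Everything is validated against a synthetic cohort generator
(`generate_cohort()`, `generate_cell_matrix()`) whose ground truth is known
by construction.

## Two normalizations, two uses

**Cross-patient signature scores.** Each signature gene is z-scored across
the patients of one cohort (sample SD, $n-1$ denominator); the score of
signature $k$ in a patient is the mean of its member genes' z-scores. These
scores are ideal for clustering *within* a cohort, but they are
cohort-relative: adding or removing patients changes everyone's scores.

**Intrinsic signature scores.** For each patient *independently*, the log2
expression values of all signature genes are z-scored across genes within
that patient, then averaged per signature, giving IC1..IC6. Because only
the patient's own profile enters, intrinsic scores transfer across cohorts
and platforms, which is what makes the subtype classifier portable. Two
identities follow directly from the construction and are pinned by tests:
the gene-count-weighted sum $\sum_k n_k \mathrm{IC}_k$ is exactly zero for
every patient, and IC values are invariant to any positive affine
transform ($a x + b$, $a > 0$) of a patient's log2 profile — so arbitrary
per-array scaling and offset drop out.

**IDS.** The Intrinsic Deviation Score is the signed combination
$\mathrm{IDS} = \sum_{k=1}^{6} s_k \, \mathrm{IC}_k$ with $s_k = +1$ for
the induced signatures C1–C3 and $s_k = -1$ for the suppressed C4–C6. We
use the unweighted signed *sum*; a signed mean differs only by the
constant factor $1/6$ and preserves every patient ordering, so the choice
affects absolute values but nothing downstream. `ids(..., normalize =
"mean")` exposes the alternative.

### Conventions worth stating

* z-scores use the sample SD ($n-1$). For the two-sample worked example
  with values $(1, 3)$ this gives $\mp 1/\sqrt{2} \approx \mp 0.7071$,
  frozen in a golden test.
* a zero-variance gene contributes z = 0 to cross-patient scores; a
  patient whose entire signature-gene vector is constant has undefined
  intrinsic scores and is excluded with a report.
* signature genes missing from a matrix are dropped and coverage is
  reported; coverage below 50% for any signature is an error rather than a
  silent partial score (a conservative threshold of our choosing).
* `log2_transform()` defaults to offset 1 for counts and refuses to
  transform data already tagged log2.

## Subtyping and the classifier

Patients are clustered on the 6-column cross-patient score matrix by
agglomerative Ward clustering on Euclidean distance (`hclust` method
`ward.D2`, the algorithm that implements Ward's criterion on raw
distances), cut at $k = 2$. The cluster with the higher mean signed score
$\sum_k s_k\,\mathrm{score}_k$ — stronger induced programs, weaker
steady-state programs — is labeled SG1. The clustering algorithm for the
patient split is a design choice (hierarchical presentations of such score
matrices motivate it), and the tree cut is the only split rule
implemented; no manual post-hoc reassignment of borderline patients.

`score_pca()` summarizes score-space structure; the "separation PC" is
identified programmatically as the component whose loading pattern aligns
best with the sign vector, and its coordinates correlate near-perfectly
with IDS on synthetic cohorts.

The classifier is a random forest (500 trees, $\sqrt{p}$ candidate
features per split, no depth cap — standard defaults, exposed as
arguments) on the six intrinsic scores, evaluated by *stratified* k-fold
cross-validation (default 5 folds; stratification protects the smaller
subtype). We report per-fold misclassification error and the AUC of the
pooled out-of-fold SG1 probabilities — pooling, rather than averaging
per-fold AUCs, uses every patient exactly once and is stable for small
folds. The final model is refit on all data. All randomness (fold deal,
forests) is derived from one integer seed.

## Enrichment statistics

For two gene sets within a universe of $N$ genes (in single-cell work, the
genes expressed in at least 0.5% of cells), with $a$ shared genes, $b$
only in set 2 and $c$ only in set 1:

$$\mathrm{FE} = \frac{a\,N}{(a+b)(a+c)},$$

the observed overlap over its expectation under independence — symmetric
in the two sets, with mean 1 for random sets. Significance is the
upper-tail hypergeometric $P(X \ge a)$, Benjamini–Hochberg adjusted across
set pairs. Report-level filters (FE ≥ 2 with ≥ 15 or ≥ 5 overlapping
genes, depending on context) are arguments of `set_enrichment()`, not
hard-coded.

For cluster-by-time composition, each (cluster, time) pair forms a 2×2
table tested by Pearson's chi-square (two-sided, no Yates correction — the
tables are large) with the odds ratio given a Haldane–Anscombe 0.5
correction when any cell is zero, so clusters confined to one time point
get a large finite OR rather than infinity. A cluster whose largest OR is
≤ 2.5 is spread evenly over time and labeled **pan**; otherwise it takes
the time label of its maximal OR (earliest wins on exact ties).

## Module discovery

`pairwise_degs()` tests every unordered cluster pair per gene, either by
Wilcoxon rank-sum on depth-normalized log2 expression or by logistic
regression of cluster membership on expression with an optional batch
covariate (likelihood-ratio test) — the two conventions used for
droplet-based mouse and human data respectively. P values are Bonferroni
adjusted over genes; the DEG union takes genes passing adjusted P < 0.05
and fold change ≥ 2 in at least one pair. Fold change is computed on
de-logged per-cluster means with a 0.01 pseudocount, since no canonical
single-cell FC definition exists. Constant genes get P = 1; clusters with
fewer than 3 cells are excluded with a warning.

The DEG union's per-cluster mean profile is row z-scored and clustered
with Ward linkage; the tree is cut at a caller-chosen $k$ (different
analyses legitimately use different $k$; there is no automatic selection).
Modules are renumbered so that injury-induced modules come first,
by a caller-supplied contrast over profile columns (default: first column
minus last). Genes are sorted lexicographically before clustering, making
the assignment invariant to input order. Pseudotime estimation is out of
scope: any external ordering or binning can be supplied as the profile.

## Outcomes

Time-to-event analysis treats **recovery** as the event for injured
cohorts: in-hospital deaths are rare, and nonsurvivors enter with their
length of stay and event = 0. This is censoring-by-death, not a
competing-risks analysis; with mortality of a few percent the practical
difference is small, but `event_type` is kept so a Fine–Gray analysis
could be bolted on. Kaplan–Meier curves are truncated at a 28-day horizon
(administrative censoring); the log-rank test compares subtypes; the Cox
model (Efron tie handling — day-resolution stays guarantee ties) adjusts
for age, sex, maximal serum lactate within 6 hours, and injury severity,
with SG2 as the reference level so the reported HR reads "SG1 vs SG2".

`binned_group_test()` compares score trajectories between outcome strata
within time bins centered at 0.5, 1, 4, 7, 14, 21 and 28 days; samples are
assigned to the nearest bin center (half-open intervals with midpoint
boundaries — the edge rule is ours, as only the centers are canonical),
and bins with fewer than 2 samples in either stratum are skipped.

## The synthetic cohort generator

`generate_cohort()` draws a gene universe of 871 background genes plus 129
module genes (sizes 25/25/25/25/21/8 — the total is canonical, the split
configurable; C6 = 8 is an option we default to, not an assertion), a
healthy baseline per gene (log2 intensities, mean 8, SD 1.5,
microarray-like), and two patient subtypes. At time $t$ hours a patient's
module genes sit at
`baseline + sign * effect[subtype] * 2^(-t/halflife) + noise` with
defaults: SG1 effect 2.0 and SG2 effect 0.7 log2 units, noise SD 0.5,
half-life 96 h, sampling at 12/24/96/168 h. Recovery times are exponential
with a SG2:SG1 hazard ratio of 3 (SG1 median stay ~12 days), rounded up to
whole days to emulate day-resolution annotation; deaths (8% SG1, 1.5% SG2)
are censored at length of stay. Covariates are independent of subtype
unless the `confounding` knob shifts SG1 severity, giving
Cox-adjustment tests a known truth. `generate_cell_matrix()` produces
negative-binomial counts in which cluster $k \le 6$ over-expresses module
$k$ eight-fold, so discovery has a planted answer.

The generator emulates the *statistical structure* the analysis assumes —
disjoint signed modules, subtype-dependent effect magnitude, exponential
return to baseline, subtype-dependent hazards. It does **not** emulate
probe-level microarray artifacts, batch effects, dropout or doublets in
droplet data, correlated gene-gene noise, or informative censoring.
Passing tests therefore demonstrate correctness of the machinery and
recoverability under the stated model, not performance on any real cohort.

## Problem sizes and numerical choices in the test suite

Tests run the default 200-patient cohort over 20 seeds for subtype and
classifier recovery; 1000 patient samples for the intrinsic-score
conservation property (tolerance 1e-9); a 1000-patient confounded cohort
for Cox parameter recovery (15% relative tolerance); 1000 null
simulations at n = 200 for log-rank size; and reduced gene/cell counts
(192 genes, 7×40 cells) for discovery fixtures — sizes chosen to exercise
the asymptotics each check needs while keeping the suite quick. Exact
oracles (hypergeometric enumeration for N ≤ 12, rank-sum enumeration for
group sizes ≤ 6, hand product-limit for ≤ 5 subjects, a reference BH
step-up, grid-search Cox partial likelihood) are implemented independently
in the test helpers.

## Known limitations

* The subtype split is a hard tree cut; borderline patients get no
  uncertainty from the clustering itself (the classifier's probabilities
  are the practical substitute).
* Recovery analysis censors deaths rather than modeling competing risks.
* Probe-to-gene collapsing for microarray inputs is the caller's
  responsibility; matrices are assumed gene-level.
* IDS absolute values depend on the signed-sum convention; only orderings
  are convention-free.
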