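# monosig

Monocyte gene-signature scoring and subtyping for critical illness.

## What this is for

After severe injury (trauma, burns, sepsis), circulating monocytes shift
away from their steady-state program: emergency inflammatory modules are
induced while interferon and antigen-presentation modules are suppressed.
The *magnitude* of that shift varies widely between patients and predicts
how fast they recover. `monosig` implements the complete computational
pipeline for exploiting this:

* **Module discovery** — pairwise differential expression between cell
  clusters (Wilcoxon or batch-aware logistic regression, Bonferroni),
  Ward hierarchical clustering of the DEG profile into gene modules, and
  correlation-based selection of PC-associated genes.
* **Scoring** — for six signed signatures C1–C6 (C1–C3 injury-induced,
  C4–C6 suppressed):
  * *cross-patient signature scores*: mean of member-gene z-scores taken
    across the patients of a cohort;
  * *intrinsic signature scores* IC1–IC6: z-scoring across the signature
    genes **within** each patient, making scores transferable across
    cohorts and platforms;
  * the **Intrinsic Deviation Score**
    `IDS = Σ_k s_k · IC_k`, with sign `s_k = +1` for induced and `−1` for
    suppressed signatures — one number per patient summarizing deviation
    from steady state.
* **Stratification** — Ward clustering of the score matrix into subtypes
  SG1 (high deviation, slow recovery) and SG2, PCA of score space, and a
  stratified cross-validated random-forest classifier on IC1–IC6 with
  out-of-fold AUC.
* **Enrichment** — gene-set overlap fold enrichment
  `FE = a·N / ((a+b)(a+c))` with upper-tail hypergeometric P and BH
  adjustment; cluster-by-time χ²/odds-ratio enrichment with the "pan"
  rule (max OR ≤ 2.5 ⇒ evenly spread over time).
* **Outcomes** — 28-day Kaplan–Meier curves, log-rank tests, and Cox
  models (Efron ties) of recovery adjusted for age, sex, lactate and
  injury severity; time-binned Wilcoxon trajectory comparison.
* **Synthetic cohorts** — `generate_cohort()` / `generate_cell_matrix()`
  produce expression, metadata, survival and ground-truth subtype labels
  under a known generative model, so every stage is testable without any
  external data.

See the methods vignette (`vignettes/monosig-methods.Rmd`) for the model,
conventions and design decisions.

## Worked example

```r
library(monosig)

co  <- generate_cohort(cohort_spec(seed = 7))
co
#> SyntheticCohort: 200 patients x 4 timepoints + 20 controls, 1000 genes (129 in modules)

run <- run_classification(co$expression, co$signatures, co$metadata,
                          co$survival, folds = 5, seed = 7)
run
#> ClassificationRun: 200 patients; CV error 0.000, AUC 1.000
#>   log-rank p = 2.45e-11 (SG1 vs SG2 recovery)
run$subtypes
#> SubtypeAssignment: SG1=87, SG2=113

round(head(cbind(run$intrinsic$ic, IDS = run$ids), 3), 3)
#>                C1    C2    C3     C4     C5     C6   IDS
#> P0001_T012h 0.828 0.573 0.575 -0.980 -0.927 -0.682 4.566
#> P0002_T012h 0.797 0.527 0.660 -1.047 -0.883 -0.607 4.521
#> P0003_T012h 0.624 0.227 0.328 -0.692 -0.462 -0.309 2.641

run$cox
#> Cox proportional hazards (Efron ties), 192 events
#>            term        hr      lo95      hi95            p
#>      subtypeSG1 0.3641503 0.2680339 0.4947338 1.041500e-10
#>             age 0.9957584 0.9856057 1.0060158 4.162698e-01
#>            sexM 1.0819048 0.8120303 1.4414708 5.907686e-01
#>  severity_score 0.9807655 0.9619415 0.9999579 4.950495e-02
#>  lactate_max_6h 0.9646665 0.8709778 1.0684331 4.901270e-01
```

Reading the output: the pipeline took each patient's first sampled time
point, scored the six signatures, split the cohort into SG1/SG2, and
cross-validated the random-forest classifier on the intrinsic scores
(error 0, AUC 1 at the default effect sizes — the subtypes are well
separated in this simulation). The first three patients are SG1-like:
induced signatures C1–C3 positive, suppressed C4–C6 negative, hence large
IDS. In the Cox model the subtype hazard ratio of 0.36 (SG2 is the
reference; the event is *recovery*) says SG1 patients recover roughly
three times more slowly — matching the generative hazard ratio of 3 —
while age, sex, severity and lactate carry no independent effect, as
simulated.

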