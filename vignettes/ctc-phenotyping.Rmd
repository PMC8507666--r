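---
title: "Phenotyping circulating tumor cells from single-cell TPM profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping circulating tumor cells from single-cell TPM profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcpheno)
```

## The problem

Marker-free CTC enrichment (filtration plus CD45/CD50 immunomagnetic
depletion) recovers circulating tumor cells of every phenotype — epithelial,
epithelial–mesenchymal transition (EMT), stem-like — at the price of
residual leukocyte and endothelial contamination that immunofluorescence
alone cannot resolve. After plate-based scRNA-seq of the candidate cells,
the analysis problem is: decide transcriptionally which candidates are
CTCs, place each CTC on the epithelial and EMT/stem axes, and ask whether
the resulting phenotype burden predicts outcome. `ctcpheno` implements
that analysis as a deterministic, testable pipeline over a gene × cell TPM
matrix, per-cell metadata (patient, uniquely mapped reads, cluster flag)
and a per-patient clinical table.

## Marker panels and scores

Five fixed panels drive everything (`marker_panels()`): 12 epithelial
genes (*CDH1*, *EPCAM*, claudins, keratins, *VIL1*), *PTPRC* for
leukocytes, *PECAM1* for endothelium, 11 stem-cell genes (*LGR5*,
*ALDH2*, *CD44*, ..., *POU5F1*) and 7 EMT genes (*VIM*, *SPARC*, *ITGB1*,
...). Panel membership is part of the method, not a tunable: the gene
lists are reproduced exactly as published, including *ABCB2* in the stem
panel even though *ABCG2* is the canonical stem transporter — we
implement the printed panel rather than silently "correcting" it.

No published definition pins down the "gene expression score" such panels
are summarized by, so the package adopts the simplest reading consistent
with a log-scale heatmap: the score of cell $j$ for panel $G$ is
$\sum_{g \in G} \log_{10}(\mathrm{TPM}_{gj} + 1)$. The pseudocount keeps
zeros at zero; summation (rather than averaging) weights broader panel
coverage upward, which is what distinguishes "high" from "middle"
epithelial cells that share a core of markers. A mean variant is
available (`score_method: mean`) and changes nothing qualitatively, since
group naming only uses within-clustering score *ranks*. Gene symbols are
matched case-insensitively; a panel gene missing from the matrix scores 0
and is warned about once, so partial matrices remain scorable.

One unit caveat: the upstream quantification is described as TPM while
the corresponding heatmaps are labelled log10(FPM). The pipeline assumes
TPM throughout; since both are within-cell normalizations and all
decisions are rank- or threshold-based on the log scale, the distinction
does not move group boundaries in practice.

## Quality control

Two gates, in order, neither of which drops cells silently
(`qc_filter()` returns the full per-cell verdict):

* **Read floor** — a cell passes with *strictly more than* `min_reads`
  (default 100,000) uniquely mapped reads. The strict inequality follows
  the stated inclusion criterion verbatim. A second, purely descriptive
  tier at 400,000 reads is reported (`reads_tier_pct`) because cohort
  summaries conventionally quote it.
* **Contaminant elimination** — a non-cluster cell with *PTPRC* ≥
  `positivity_tpm` is a leukocyte; a cluster object with *PTPRC* positive
  is a CTC cluster with mixed leukocytes (always excluded — the assay
  cannot distinguish a conjugated cluster from a stray leukocyte, so we
  take the conservative side); *PECAM1*-positive cells without *PTPRC*
  are endothelial. The positivity floor defaults to 1 TPM, the
  conventional detection threshold; no cutoff was published. When both
  markers are positive in a single cell, the leukocyte call wins —
  leukocytes are the dominant contaminant in this protocol by an order of
  magnitude, so the tie should default to the likelier class. Both the
  threshold and the precedence are configurable.

Retention percentages are rounded half-up to integers, matching how such
rates are conventionally printed (59/110 → 54%, 109/110 → 99%).

## Phenotype groups

Retained cells are clustered twice with Ward linkage (`ward.D2`) on
Euclidean distances of $\log_{10}(\mathrm{TPM}+1)$ submatrices:

* epithelial axis: the 12 epithelial genes plus *PTPRC* and *PECAM1*
  (14 genes), tree cut at exactly $k = 3$;
* EMT/stem axis: the 11 + 7 stem and EMT genes (18 genes), cut at
  $k = 4$.

Neither the linkage nor the distance nor the cut rule was published;
Ward/Euclidean with a fixed-$k$ cut is the standard heatmap default and
is deterministic under a fixed cell order (merge ties resolve to the
lowest-index pair, `hclust`'s convention). Clusters are then *named by
their empirical mean scores*, not by dendrogram order: ascending mean
epithelial score → Low / Middle / High; the cluster with the highest mean
stem score → HighStem_LowEMT, the remaining three by descending mean EMT
score → LowStem_{High,Middle,Low}EMT. Naming by score rank rather than by
cluster letter is a deliberate design choice: letter conventions in the
source material contradict themselves between text and table, whereas the
score ordering is unambiguous. Exact ties in cluster means (possible on
degenerate data) are broken by cluster size, larger cluster first, with a
logged message.

Between-group score differences are tested with the two-sided
Mann–Whitney U test (`compare_group_scores()`), the natural choice for
small, skewed score samples; no test was named in the source. For small
untied samples the exact distribution is used, otherwise the normal
approximation with tie correction — so tiny-cohort p-values coincide with
the exhaustive permutation answer.

The four group pairs found to be significantly enriched define CTC
Categories 1–4 (high-epi/high-stem, low-epi/middle-EMT,
middle-epi/low-EMT, low-epi/high-EMT); every other pair is "other". This
fixed mapping is applied verbatim by `assign_categories()`.

## Contingency statistics

`cross_tabulate()` builds the 3 × 4 table; `chi_square_test()` is the
Pearson test without continuity correction (df = 6 for the full grid),
with a logged warning whenever an expected count is below 5 — which is
the norm at n = 59, so the χ² p-value is understood as approximate.
"Residual analysis" is implemented as Haberman adjusted standardized
residuals,

$$ r_{ij} = \frac{O_{ij} - E_{ij}}
  {\sqrt{E_{ij}\,(1 - R_i/n)\,(1 - C_j/n)}}, $$

coded five ways by sign against the two-sided 1.96 / 2.58 cutpoints.
This is the standard post-hoc procedure implied by arrow-and-asterisk
table annotations; no multiple-testing correction is applied across the
12 cells, matching the source analysis. Degenerate margins (an empty row
or column) raise an error rather than returning NaNs; `run_pipeline()`
catches this and marks the test not computable when a simulated cohort
happens to produce one.

Detection rates treat a patient as positive for a CTC type given ≥ 1
cell of it (epithelial = Middle or High epithelial group; EMT = Middle or
High EMT group); patients with no retained cells are negatives, and rates
are percentages of the *full* cohort. Rate comparisons use the exact
two-sided Fisher test on independent 2 × 2 tables — enumerating
hypergeometric probabilities of all tables with the observed margins and
summing those no more probable than the observed one (with the
conventional $1 + 10^{-7}$ tie tolerance). Treating the two rates as
independent groups mirrors the source analysis even though each patient
contributes to both; the paired McNemar analysis is provided as
`detection_mcnemar()` for sensitivity checks and is, as expected,
somewhat more powerful on discordant-heavy cohorts.

## Survival

`km_estimate()` wraps the product-limit estimator. The median is defined
as the smallest observed time with $S(t) \le 0.5$ — note that
`quantile.survfit()` midpoint-averages across an exact-0.5 plateau, which
is *not* the convention used here. Confidence intervals for the median
come from the survfit log-scale confidence bands (Brookmeyer–Crowley
style). Events precede censorings at tied times.

The "Generalized Wilcoxon" test is implemented as Gehan–Breslow:
score $U_i$ = (observations definitely later than $i$) − (definitely
earlier), where an observed event is definitely earlier than anything
strictly later and than a censoring tied with it; censored times are
never definitely earlier than anything. $W = \sum_{i \in a} U_i$,
$\mathrm{Var}(W) = n_a n_b \sum U_i^2 / (N(N-1))$ (the permutation
variance). For total $N \le 20$ the p-value is computed exactly by
enumerating all $\binom{N}{n_a}$ score reassignments — at the cohort
sizes this pipeline targets (a few dozen patients split unevenly), the
normal approximation is visibly off, and the enumeration is instant;
larger cohorts use the normal approximation. When the variance is zero
(identical degenerate strata) the test returns $p = 1$. Gehan weights
early differences more than the log-rank test, which is the appropriate
emphasis when early progression is the clinically meaningful signal; the
Peto–Peto variant is available behind `gehan_variant: "peto"`.

Stratification rules (`stratify()`) restrict to treatment line ≥ 2 by
default — mixing first-line patients into an exploratory survival
analysis confounds CTC phenotype with treatment-line benefit — and split
on a CTC-type count threshold, optionally *exclusive* (the positive
stratum may have no other CTC type detectable). Both readings of an
"only EMT CTCs, ≥ 2" rule are expressible via the `exclusive` flag; the
default rule set uses the exclusive form for EMT. The median CI method
behind published negative CI bounds (e.g. −20 days) is not recoverable
and is deliberately not imitated.

## The synthetic-data generator

`generate_cells()` draws each cell from one of eight archetypes
(`archetype_specs()`): on-genes log-normal on the log10 scale
(`10^N(μ, σ)`), zeroed with a dropout probability; all other genes in a
500-gene universe (32 panel genes + 468 background genes) expressed with
probability 0.05 at a background level of ~3 TPM. Defaults: on-mean
2.0 log10-TPM (≈ 100 TPM), σ = 0.5, dropout 0.2 — magnitudes that make
marker-positive calls unambiguous in expectation while forcing the
clustering to cope with real sparsity. The archetype gene programs follow
the published phenotype descriptions: middle-epithelial cells express
*EPCAM*/*CLDN4*/keratins; high-epithelial cells add *CLDN3*/*CLDN7* at
higher level; EMT cells the full mesenchymal panel; intermediate-EMT
cells *VIM*/*SPARC*/*ITGB1* weakly plus moderate *CD44*/*KLF4*/*MYC*;
stem-like clusters strong *CD44*/*ALDH2*/*MYC* on a high-epithelial
background (and carry the cluster flag). Leukocyte/endothelial/mixed
archetypes use dropout 0.02 rather than 0.2: *PTPRC* and *PECAM1* are
abundant lineage transcripts, and dropout probability falls steeply with
expression, so a 20% technical-zero rate for them would be biologically
unreasonable (and would make transcriptional contaminant removal
impossible for any method).

`generate_cohort()` layers patients on top: candidate counts per patient
Poisson(3) (sparse counts with median ~2, and occasional CTC-negative
patients, as observed in small CTC cohorts); archetypes drawn from a
mixture putting ~46% of candidates in contaminant classes; PFS
exponential with baseline hazard $\ln 2 / 76$ per day and OS at a quarter
of that hazard (medians ~76 and ~300 days); the hazard of both endpoints
multiplied by `hazard_ratio_emt` (default 2) for patients whose *true*
EMT-CTC count is ≥ 2; independent uniform censoring on [100, 800] days.
No generative survival model was published — this module is the stand-in
that makes the survival stage testable at all.

What the generator does *not* emulate: transcriptome-wide covariance,
batch and plate effects, ambient RNA, doublets beyond the labelled
cluster archetypes, library-size variation, or any dependence between a
cell's expression and its patient's outcome other than through archetype
counts. Passing recovery tests therefore demonstrates that the pipeline's
decision rules are correct and robust to dropout-style noise — not that
they would achieve the same accuracy on real scRNA-seq data.

## Verification strategy and problem sizes

Every statistical routine is tested against an independent brute-force
oracle: Fisher p-values against direct binomial-coefficient enumeration
(agreement to 1e−12 for margins ≤ 30), the χ² statistic against naive
double-loop summation (1e−9), adjusted residuals against
`chisq.test()$stdres`, Mann–Whitney and Gehan p-values against exhaustive
permutation, and the KM curve against a hand product-limit computation.
Calibration and power of the Gehan test are checked by simulation at
sizes chosen to keep the full suite under a minute: 100 null replicates
(two exponential samples of 20, uniform censoring) must give a type-I
error in [0.01, 0.10] at α = 0.05, and 200 cohort replicates (100
patients, hazard ratio 3 on truth strata) must give power ≥ 0.8.
Archetype recovery runs on a 500-cell simulation at default noise
(requiring ≥ 90% CTC classification accuracy and ≥ 95% contaminant
removal) and without dropout (requiring 100% of both). A built-in 59-cell
label fixture (`reference_ctc_labels()`) encodes the reference cohort's
group structure — cross-tab (7,0,1,0 / 0,0,7,3 / 0,9,4,28), detection
rates 30/74/89%, 13 multi-category patients — and anchors the
end-to-end expectations; its patient-level survival times were never
published, so the clinical companion (`synthetic_reference_clinical()`)
is explicitly synthetic and survival outputs on it are plumbing checks,
not reproductions.

## Known limitations

* Fixed $k$ (3 and 4) is assumed, not selected; cohorts genuinely lacking
  a phenotype will still be split into that many groups, and group
  *names* are always relative to the cohort at hand.
* The marker panels are literature-derived and unvalidated as a
  combination; the pipeline inherits that limitation.
* Chi-square and residual p-values are asymptotic despite small expected
  counts; the residual analysis is descriptive, not confirmatory.
* Detection-rate Fisher tests ignore the pairing across CTC types
  (McNemar variant provided).
* The survival analysis is exploratory two-group testing; no covariate
  adjustment (Cox or otherwise) is attempted, and first-line patients are
  excluded rather than modelled.
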