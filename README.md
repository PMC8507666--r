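# ctcpheno

Phenotyping and prognostic stratification of circulating tumor cells
(CTCs) from single-cell TPM expression profiles.

CTCs are tumor cells shed into peripheral blood. Marker-free enrichment
captures the full phenotypic spectrum — epithelial CTCs, CTCs undergoing
epithelial–mesenchymal transition (EMT), and stem-like CTC clusters — but
also leukocytes and endothelial cells that slip through depletion.
`ctcpheno` implements the downstream analysis for such experiments, for
researchers working with per-cell TPM matrices from plate-based scRNA-seq
(SMART-Seq-style) of enriched CTC candidates:

1. **Quality control** — cells must exceed a uniquely-mapped-read floor
   (default: strictly more than 100,000 reads); cells expressing the
   leukocyte marker *PTPRC* (CD45) or the endothelial marker *PECAM1*
   (CD31) at ≥ 1 TPM are eliminated as leukocytes, endothelial cells, or
   CTC clusters with mixed leukocytes.
2. **Phenotyping** — retained cells are clustered twice in log marker
   space (Ward linkage, Euclidean distance, on log10(TPM+1)): once on 12
   epithelial markers plus *PTPRC*/*PECAM1* (cut at k = 3 → Low / Middle /
   High epithelial), once on 11 stem-cell and 7 EMT markers (cut at k = 4 →
   HighStem_LowEMT, LowStem_MiddleEMT, LowStem_LowEMT, LowStem_HighEMT).
   Clusters are named by their mean panel scores, where the score of cell
   *j* for panel *G* is

   `score_G(j) = Σ_{g ∈ G} log10(TPM_gj + 1)`

3. **Cross-classification** — the 3 × 4 contingency table of group pairs
   is tested for independence (Pearson χ², df = 6) and dissected cell-wise
   with Haberman adjusted standardized residuals
   `(O − E) / √(E (1 − r/n)(1 − c/n))`, coded against ±1.96 / ±2.58. Four
   enriched group pairs define CTC Categories 1–4; all others are "other".
4. **Detection rates** — per-patient positivity (≥ 1 CTC of a type) for
   epithelial, EMT, and combined CTC types, with exact two-sided Fisher
   tests between rates.
5. **Survival** — Kaplan–Meier estimates (median = smallest *t* with
   S(t) ≤ 0.5) and the Gehan generalized Wilcoxon test comparing
   progression-free and overall survival between strata defined by CTC
   burden rules such as "only EMT CTCs detectable, count ≥ 2", restricted
   to second- or later-line patients. The Gehan statistic uses
   censoring-aware pairwise scores with permutation variance; p-values are
   exact (full enumeration) for small strata.

A synthetic-data module (`generate_cells()`, `generate_cohort()`)
simulates candidate cells from eight archetypes (epithelial mid/high, EMT
strong/intermediate, stem-like cluster, leukocyte, endothelial, mixed
cluster) with log-normal expression, dropout and sparse background noise,
plus cohorts whose survival hazard depends on true EMT-CTC burden — so the
whole pipeline is testable with no sequencing data.

## Worked example

```r
library(ctcpheno)

sim <- generate_cohort(cohort_spec(seed = 1))          # 27 patients
report <- run_pipeline(sim$expr, sim$clinical)
print(report)
```

```
CTC phenotyping report: 84 candidates, 48 retained (57%)
contingency (epithelial x EMT/stem):
          emt_stem
epithelial HighStem_LowEMT LowStem_MiddleEMT LowStem_LowEMT LowStem_HighEMT
    High                 4                 0              4               0
    Middle               5                 0              4               0
    Low                  0                 9              3              19
chi-square 38.59 on 6 df, p = 8.62e-07
detection rates:
          ctc_type positive negative rate_pct
        epithelial        9       18       33
               emt       19        8       70
 epithelial_or_emt       22        5       81
```

Of 84 simulated CTC candidates, 48 survive QC (36 were leukocyte or
endothelial contaminants or failed the read floor). The contingency table
shows the simulated structure the statistics then quantify: stem-like
cluster cells sit in the high-epithelial/high-stem corner, EMT cells in
the low-epithelial/high-EMT corner, and the χ² test rejects independence.
Detection rates mirror the clinical observation the pipeline is built
around: EMT CTCs are found in far more patients (70%) than epithelial
CTCs (33%). The survival table (`report$survival`) then compares, e.g.,
patients with ≥ 2 exclusively-EMT CTCs against the rest:

```r
subset(report$survival, ctc_type == "emt" & min_count == 2 & endpoint == "pfs")
```

```
  stratum  n n_events   median   ci_low  ci_high   p_value
 positive  4        4 44.65482 11.54598       NA 0.6421048
 negative 20       20 49.23028 42.34412 135.2789 0.6421048
```

(The default simulated hazard ratio of 2 is rarely detectable at n = 24 —
exactly the situation the power analysis in the vignette quantifies.)

The built-in reference fixture reproduces the structure of a published
27-patient metastatic colorectal cancer cohort with 59 retained
CTCs/CTC clusters:

```r
ann <- reference_ctc_labels()
cross_tabulate(ann)                    # 3 x 4 table, total 59
adjusted_residuals(cross_tabulate(ann))  # 4 enriched / 3 depleted / 5 ns cells
patient_positivity(ann, data.frame(patient_id = reference_cohort_patients()))
#> epithelial 30%, EMT 74%, either 89%
```

A command-line front end with `simulate`, `classify`, `crosstab`,
`survival` and `run-all` subcommands is installed at
`inst/scripts/ctcpheno`.

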