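# mdnlr

Immunomethylomic analysis of whole-blood DNA methylation: estimate
leukocyte composition from Illumina 450K-style beta values, derive the
methylation-based neutrophil-to-lymphocyte ratio (mdNLR), discover
single-CpG myeloid surrogates of it, and relate both to patient survival.

## Why

The blood neutrophil-to-lymphocyte ratio is a replicated marker of
cancer-associated inflammation: elevated NLR predicts shorter survival in
glioma and many other solid tumors. Cell counts are rarely available for
archival samples, but whole-blood DNA methylation is a weighted average of
cell-type-specific profiles, so the counts can be recovered. This package
is for epigenetics and biostatistics researchers who have a normalized
beta-value matrix plus clinical follow-up and want the full chain from
methylation to survival inference, with every step testable against a
synthetic cohort carrying planted ground truth.

## The model

With reference profiles `X` (L-DMR CpGs × 6 cell types: CD4T, CD8T, B, NK,
Mono, Gran), each sample's composition is the constrained projection

    omega-hat = argmin || y − X·omega ||²   s.t.  omega ≥ 0,  sum(omega) ≤ 1

solved by a deterministic active-set (Lawson–Hanson) iteration. The score

    mdNLR = omega-hat(Gran) / [ omega-hat(CD4T) + omega-hat(CD8T) + omega-hat(B) + omega-hat(NK) ]

is dichotomized at 4 (boundary to the high group; a strict variant is a
flag). Myeloid-lineage CpGs are found from sorted-cell samples by per-CpG
regression of M values on a myeloid/lymphoid indicator adjusted for
flow-measured blood proportions; the top loci are screened as polynomial
(degree ≤ 3) surrogates of the mdNLR by adjusted R², requiring ≥ 0.80 in
every evaluated dataset. Survival uses Cox proportional hazards (Efron
ties) with Schoenfeld diagnostics, likelihood-ratio model comparisons,
Harrell's c, IPCW Brier score and time-dependent AUROC.

## Worked example

```r
library(mdnlr)

## a synthetic reference with planted structure
truth <- generate_reference_profiles(n_cpgs = 1000, n_ldmr_per_type = 50,
                                     n_surrogates = 5, seed = 42)
#> Synthetic leukocyte reference: 1000 CpGs x 6 cell types
#>   L-DMRs: 300  surrogates: 5  seed: 42

## a 50-sample cohort spanning NLR ~0.5-12, deconvolved against the truth
fc <- simulate_fidelity_cohort(truth, n_samples = 50, seed = 43)
round(head(fc$props$proportions, 3), 3)
#>        CD4T  CD8T     B    NK  Mono  Gran
#> S0001 0.201 0.195 0.106 0.025 0.195 0.277
#> S0002 0.135 0.002 0.000 0.006 0.213 0.643
#> S0003 0.201 0.030 0.016 0.000 0.048 0.705
head(fc$mdnlr, 3)
#>   sample_id     mdnlr floored
#> 1     S0001 0.5250217   FALSE
#> 2     S0002 4.4645582   FALSE
#> 3     S0003 2.8581060   FALSE
cor(fc$mdnlr$mdnlr, fc$composition$true_nlr)
#> [1] 0.9670697
```

The estimated fractions track the planted truth (mean absolute error well
below 0.02 per cell type at array noise sd 0.02), and dichotomization at 4
reproduces the true high/low split exactly in this cohort.

The one-call pipeline runs generation → QC → deconvolution → mdNLR →
surrogate screen → survival, writing every intermediate table to
`out_dir`:

```r
report <- run_pipeline(default_config(n_samples = 300, seed = 7,
                                      out_dir = "run1"))
report
#> Cohort: n=300, 147 events, median survival 16.7 months
#> mdNLR >= 4.0: 44% of samples
#>
#> Model performance:
#>            model c_index brier_integrated tauroc lr_p_vs_baseline
#> 1       baseline   0.694            0.170  0.741               NA
#> 2 baseline+mdNLR   0.704            0.165  0.766          0.00234
report$km_median
#>     high      low
#> 11.57385 19.50051
```

Read: adding the mdNLR group to the clinical baseline model (age, sex,
grade, mutation subtype) raises the concordance from 0.694 to 0.704,
lowers the integrated Brier score, and is supported by a likelihood-ratio
p of 0.002 — the planted high-NLR hazard ratio of 2 is being detected. The
Kaplan–Meier median survival is 11.6 months in the high-mdNLR group versus
19.5 months in the low group. `run1/` contains the cell proportions, mdNLR
scores, QC removal log, lineage statistics, surrogate screen, per-locus
group summaries, Cox tables and KM curves as TSV/CSV.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/mdnlr-pipeline.R", package="mdnlr"))')" \
    --synthetic 300 --seed 7 --out-dir run1
```

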