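# menimm

Location-resolved immune microenvironment analysis of meningioma
transcriptomes.

Skull base and convexity meningiomas differ in clinical behaviour, and part
of that difference may be immunological. `menimm` implements, as a tested R
pipeline, a systems-biology analysis that links tumour location to the
immune microenvironment from bulk expression data: multi-study
preprocessing, weighted gene co-expression modules with location testing,
reference-based immune cell deconvolution, and a bipartite cell–cytokine
correlation network with a per-cell connectivity statistic and eigenvector
centrality ranking. It is aimed at computational biologists who want each
stage of such an analysis as an explicit, unit-tested function rather than
a chain of opaque tool calls — and at anyone who needs a synthetic
multi-study cohort with planted ground truth to validate this class of
method end to end.

## The methods in brief

* **Preprocessing.** Per study: quantile normalisation and
  log2(x + 1); across studies: gene intersection and merging, per-study
  scaling to global mean 0 / SD 1, and parametric empirical-Bayes batch
  correction (ComBat, via `sva`).
* **Co-expression network.** Soft-thresholded correlations
  (a<sub>ij</sub> = |cor(x<sub>i</sub>, x<sub>j</sub>)|<sup>β</sup>, β = 20),
  topological overlap
  TOM<sub>ij</sub> = (Σ<sub>u</sub> a<sub>iu</sub>a<sub>uj</sub> + a<sub>ij</sub>) /
  (min(k<sub>i</sub>, k<sub>j</sub>) + 1 − a<sub>ij</sub>),
  average-linkage clustering of 1 − TOM with a minimum module size of 30,
  module eigengenes (first PC), Mann–Whitney and covariate-adjusted
  (grade, age, sex) location tests, cytokine labelling at r > 0.6 /
  p < 0.05, and a top-kME-gene logistic classifier scored by ROC AUC.
* **Deconvolution.** CIBERSORT-style estimation of 22 immune cell
  fractions per sample against an LM22-format signature, with NNLS
  (default) and linear ν-SVR engines; outputs are simplex-constrained.
* **Immune network.** Per location, Pearson edges between cell fractions
  and a 35-gene cytokine panel; *connectivity* = the sum of all
  significant (p < 0.05) correlations per cell; unweighted eigenvector
  centrality of the significance-defined adjacency (power iteration, unit
  Euclidean norm); convexity − skull base difference tables.
* **Enrichment.** Hypergeometric over-representation of module genes
  against GMT gene sets, Bonferroni-corrected.
* **Synthetic cohorts.** `sim_config()` / `generate_cohort()` emulate
  three studies (12/84/11 samples, 71 of 107 skull base), batch effects,
  partially overlapping gene sets, location-specific Dirichlet immune
  fractions, planted co-expression modules and location-specific
  cell–cytokine couplings — every stage of the pipeline can be checked
  against this planted truth.

See `vignettes/menimm-methods.Rmd` for the models, assumptions, parameter
choices and limitations.

## Worked example

```r
library(menimm)

report <- run_pipeline(run_config(seed = 1))
print(report)
#> <run_report> seed 1 | 3 modules (1 significant) | AUC 0.888

tidy(report$coexpress)
#> # A tibble: 3 × 6
#>   module n_genes variance_explained mann_whitney_p  adjusted_p n_cytokine_labels
#> 1 ME1         80              0.971  0.00000000950 0.000000494                 0
#> 2 ME2         51              0.982  0.908         0.670                       0
#> 3 ME3         39              0.978  0.754         0.571                       0

head(report$network$differences, 4)
#> # A tibble: 4 × 3
#>   cell_type            delta_connectivity delta_centrality
#> 1 Mast cells activated              4.58             0.251
#> 2 Neutrophils                       1.62             0.197
#> 3 Eosinophils                       0.879           -0.102
#> 4 B cells memory                    0.721            0.191

tail(report$network$differences, 3)
#>   cell_type           delta_connectivity delta_centrality
#> 1 Monocytes                        -1.26           0.0762
#> 2 T cells CD4 naive                -2.13          -0.0500
#> 3 T cells gamma delta              -2.74          -0.540
```

Reading the output: of the modules detected in the merged simulated cohort,
exactly one (ME1 — the planted location-shifted module) separates skull
base from convexity (Mann–Whitney p ≈ 1e-8, preserved after adjusting for
grade, age and sex), and a logistic model on its top-10 kME genes separates
locations with AUC 0.888. In the cell–cytokine networks, activated mast
cells and neutrophils are more cytokine-connected in convexity tumours
(positive Δconnectivity) while gamma-delta T cells dominate skull base
(most negative Δ) — the planted, and biologically expected, pattern.
`autoplot(report$network)` draws the diverging Δconnectivity bar chart;
`autoplot(report$fractions)` the per-sample composition.

A thin command-line wrapper is provided at
`inst/scripts/run_pipeline.R` (`Rscript run_pipeline.R --seed 1 --out report`),
for simulated or on-disk cohorts.

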