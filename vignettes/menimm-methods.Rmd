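---
title: "Methods: location-resolved immune network analysis of meningioma transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: location-resolved immune network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

Skull base and convexity meningiomas differ in clinical behaviour, and one
candidate explanation is a different immune microenvironment. `menimm`
implements a systems-level analysis that links tumour location to immune
composition from bulk expression data, in five stages:

1. **Preprocessing** — per-study quantile normalisation and log2 transform,
   cross-study gene intersection and merging, per-study global scaling, and
   parametric empirical-Bayes batch correction.
2. **Co-expression modules** — a weighted gene co-expression network
   (soft-thresholded correlations, topological overlap, hierarchical
   clustering), module eigengenes, and per-module location tests.
3. **Deconvolution** — reference-based estimation of 22 immune cell
   fractions per sample from the linear-scale bulk signal.
4. **Cell–cytokine networks** — per-location bipartite correlation networks
   between estimated cell fractions and a 35-gene cytokine panel, with a
   per-cell *connectivity* statistic and unweighted eigenvector centrality.
5. **Enrichment** — hypergeometric over-representation of module genes
   against user-supplied gene sets with Bonferroni correction, as an
   offline substitute for web-based annotation services.

A synthetic multi-study cohort generator with planted ground truth stands in
for the original GEO cohorts, so that every stage can be validated against a
known answer.

## Preprocessing

Each study's matrix is quantile normalised (all samples mapped onto the mean
of the per-sample sorted value vectors; ties receive the mean of their
reference quantiles, the midrank rule) and log2 transformed with a
pseudo-count of 1, so that a linear value of 0 maps to 0. The offset is not
dictated by the data; +1 is the common convention and it makes the transform
invertible for the deconvolution path, which requires linear-scale input.

Studies are merged on the intersection of their gene sets, in sorted order.
Scaling to a global mean of 0 and SD of 1 is applied **per study** before
batch correction: pooled scaling would fold the between-study location/scale
differences into the standardised values — exactly the structure the batch
correction is supposed to remove — whereas per-study scaling leaves the
residual, gene-level batch structure for the empirical-Bayes step. Pooled
scaling remains available (`pooled_scale = TRUE`) since the order of these
two operations is a genuine interpretation choice.

Batch correction is the parametric Johnson empirical-Bayes adjustment
(per-gene standardisation; per-batch location and scale estimates shrunk by
a normal prior on the location effect and an inverse-gamma prior on the
scale effect, hyperparameters by method of moments), with no covariate
design, delegated to the canonical `sva::ComBat` implementation. A single
batch is returned unchanged; batches of one sample are rejected; only the
parametric mode is exposed.

## Co-expression network

Pairwise gene correlations are soft-thresholded with exponent
$\beta = 20$ (the default; `pick_soft_threshold()` reports the scale-free
fit $R^2$ across candidate powers for data-driven selection). The default
network is **unsigned**, $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$; a signed
variant $((1+\mathrm{cor})/2)^\beta$ is available. Adjacency is transformed
into the topological overlap matrix

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}},$$

which rewards shared neighbourhoods and stabilises clustering at modest
sample sizes.

Modules are obtained by average-linkage hierarchical clustering of
$1-\mathrm{TOM}$, cutting the dendrogram at a fixed fraction (default 0.99)
of the tallest merge height, and discarding clusters below the minimum size
of 30 genes into the grey/background label 0. This static-height cut with a
size filter is a deliberate simplification of dynamic branch cutting: under
soft thresholding at $\beta=20$, background gene pairs have dissimilarity
essentially 1 while module members merge far below the cut, so the adaptive
part of branch cutting adds little for data of this structure, and the
static rule is exactly reproducible. Module labels are renumbered by
descending size with ties broken by the lexicographically smallest member
gene, making labels invariant to gene order.

Each module is summarised by its eigengene: the first right-singular vector
(over samples) of the row-standardised module submatrix, sign-aligned so
that its correlation with the module's mean profile is non-negative, with
the share of variance explained reported. Location association is tested
two ways: a Mann–Whitney comparison of eigengene scores between skull base
and convexity, and a Wald test of the eigengene coefficient in a logistic
regression of location on eigengene + WHO grade (ordinal numeric) + age +
sex — the covariate-adjusted confirmation. Cytokines label a module when
their expression correlates with the eigengene at Pearson $r > 0.6$ and
$p < 0.05$, positive correlations only.

The robustness check trains a logistic regression on the expression of the
10 highest-kME genes from each location-significant module and reports the
ROC AUC via the rank (Mann–Whitney) formula. In-sample evaluation is the
default; a k-fold scheme is provided because in-sample AUC over ten
predictors is overfit-inflated — under label permutation it sits well above
1/2, so null calibration is only meaningful out-of-sample. Numerically
separated fits (fitted probabilities at the boundary) fall back to an
L2-ridge fit rather than failing.

## Deconvolution

`estimate_fractions()` intersects the mixture with the signature on shared
genes (at least 50 required) and normalises each gene by the **signature's
per-gene SD, without centering**, applied identically to both sides. A
shared per-gene affine map preserves convex mixtures exactly; the centering
half of a z-score, however, projects the data onto the complement of the
all-ones direction, and for signatures with balanced row sums (equal
marker/background structure per gene — true of the simulator's block
signatures and approximately of LM22-style references) that direction *is*
the simplex direction, making the fractions unidentifiable. Variance-only
normalisation keeps the weighting benefit of the z-score while preserving
identifiability; the exact-mixture unit tests (a pure signature column must
return fraction 1; a 50/50 blend must return 0.5/0.5) fail under any shared
centering.

Engines: non-negative least squares (`pracma::lsqnonneg`; deterministic,
the default) and a linear $\nu$-SVR ensemble over
$\nu \in \{0.25, 0.5, 0.75\}$ keeping the lowest-RMSE fit with negative
coefficients clamped. Coefficients are normalised to the unit simplex;
an all-zero solution returns uniform fractions with a warning.

The upstream global z-scoring of the mixture ("scaled to a global mean and
standard deviation of 0 and 1") is implemented in `prepare_mixture()` but
**off by default in the pipeline** (`scale_mixture = FALSE`): global
centring shifts every gene by a constant, which an intercept-free
non-negative fit cannot absorb — against a balanced signature the NNLS
solution collapses to zero. The switch exists for fidelity experiments.

## Cell–cytokine networks

Within each location, every (cell type, cytokine) pair receives a Pearson
correlation with the two-sided p-value from the
$t = r\sqrt{(n-2)/(1-r^2)}$ transform. Cell fractions constant across a
location's samples yield degenerate rows ($r=0$, $p=1$, flagged) rather
than errors. The displayed network keeps edges with $r > 0.6$ and
$p < 0.05$ (one-sided on positive correlations, as the effect-size cut-off
is stated; `two_sided = TRUE` uses $|r|$).

Two node statistics are computed from the *unthresholded-by-effect-size*
edge set:

- **Connectivity**: per cell, the sum of all significant ($p < 0.05$)
  correlations with the panel. The default is the signed sum — the
  statistic as literally defined — with an absolute-value mode available
  because summary histograms of correlation distributions do not
  disambiguate the two; the mode used is recorded in the output.
- **Eigenvector centrality**: the principal eigenvector of the binary
  adjacency (1 iff $p < 0.05$) over all cell and cytokine nodes, computed
  by power iteration to a $10^{-12}$ tolerance. Iteration runs on
  $A + I$, which has the same eigenvectors but a strictly dominant
  eigenvalue even on bipartite components, whose $\pm\lambda$ symmetric
  spectrum would otherwise make plain power iteration oscillate. The vector
  is non-negative, scaled to unit Euclidean norm; nodes outside the
  dominant connected component, and isolated nodes, score 0. Unit-norm
  scaling (rather than max-normalisation) keeps printed maxima below 1 for
  non-trivial graphs.

The location comparison reports, per cell, the convexity-minus-skull-base
difference in connectivity and centrality; positive values mark cells more
cytokine-active in convexity tumours. No multiple-testing correction is
applied to edge p-values by default (raw $p<0.05$ adjacency is the
definition of the statistic); a Benjamini–Hochberg option can be applied to
the edge table by the user before summarising.

## The synthetic cohort generator

`sim_config()` defaults encode the study conditions of the real cohort:
three studies of 12, 84 and 11 samples with skull-base fractions 7/12,
53/84 and 11/11 (counts assigned deterministically as
`round(fraction * n)`, giving 71 of 107 skull base), WHO grade ≈95% grade 1
with grade 2 enriched in convexity, ages $\mathcal{N}(56.4, 12.6^2)$, and
30% male (female predominance is the norm for meningioma cohorts).

Ground truth is planted at four levels:

- **Fractions**: per-sample Dirichlet draws with location-specific
  concentrations — skull base boosts gamma-delta T cells, monocytes and
  plasma cells; convexity boosts activated mast cells and neutrophils.
- **Signature/markers**: disjoint marker blocks per cell type (markers at
  `marker_fold` × base level); marker-gene expression is the signature
  mixed by the true fractions.
- **Modules**: each module is a latent factor per sample times per-gene
  loadings, applied **multiplicatively on the linear scale** (i.e.
  additively on log2): this keeps linear values non-negative for the
  deconvolution path and produces exactly the log-scale co-expression the
  network stage consumes. One module's factor is shifted between locations
  (default 1.5 SD) — the "immune response" module the location tests must
  find.
- **Couplings**: within one location, a coupled cytokine gene is
  $\mu + a\,(f - \bar f) + e$ with $a$ and $\mathrm{var}(e)$ solved so the
  *emitted* values carry the target population correlation — the known
  variance contributed by the downstream multiplicative lognormal
  measurement noise is subtracted from the noise budget (infeasible
  combinations raise an error). The other location receives independent
  noise at the same marginal scale.

The default coupling set plants a **block** of cytokines per active cell
(mast cells: IL6 at 0.69 plus five further couplings at 0.45–0.60;
gamma-delta T cells: CCL3 at 0.70 plus five more; neutrophils, plasma cells
and monocytes weaker). The block design is deliberate: connectivity is a
*sum* of significant correlations, and at ~36 samples per location the null
per-cell signed sum has a standard deviation near 0.5, so its maximum over
~21 inactive cells routinely exceeds any single edge of 0.7 — a cell that
is genuinely cytokine-active in the sense the statistic measures correlates
with many panel genes, which is also what the real networks show. A single
planted pair is therefore detectable as an *edge* but cannot, even in
principle, dominate the connectivity *ranking*.

After assembly, all values receive multiplicative lognormal noise (default
5% log-scale SD), per-study affine batch effects (shift/scale with
gene-level shift jitter), and each study drops a disjoint random 5% of
non-marker, non-panel genes so that cross-study intersection is exercised.
Identical configs and seeds give byte-identical cohorts.

**What the generator does not emulate**: probe-level microarray physics,
correlated cytokine co-regulation beyond the planted couplings,
cell-fraction measurement error in the "true" fractions, missing values,
and any coupling between module structure and immune fractions. Passing
tests therefore demonstrate correctness of the pipeline's statistical
machinery under its own assumptions, not robustness to everything real
cohorts do.

## Problem sizes and numerical choices

The validation suite runs at desk scale: module recovery uses 1,500 genes ×
60 samples (four planted modules of 100–300 genes plus a 10-gene cluster
that must fall to grey under the 30-gene minimum); deconvolution recovery
uses 6 cell types × 40 samples at 5% noise; the location-network recovery
runs 20 seeded replicates at 36 samples per location and **1,000 genes**.
The gene count in the last scenario matters for an interesting reason:
quantile normalisation maps each gene through its within-sample rank, and
when fraction-driven marker genes are a large share of the distribution
(16% at 400 genes) the remapping couples *every* gene's profile to the
sample's immune composition, audibly distorting planted correlations. At
1,000 genes (markers 6.6%) the artifact is minor, and at real cohort scale
(~19,000 genes) it is negligible — so the validation scale is chosen to be
small enough to run in seconds yet large enough not to manufacture a
desk-scale artifact.

Other numerical choices: correlations are clamped to $[-1, 1]$ before the
t transform and $|r| = 1$ returns $p = 0$; the Mann–Whitney test uses exact
enumeration when $n_a + n_b \le 20$ without ties, otherwise the normal
approximation with tie and continuity correction, and the fully tied case
returns $p = 1$; TOM is symmetrised against accumulation-order rounding;
kME ties break lexicographically; the all-tied AUC uses midranks. Module
eigengene extraction warns on single-gene modules and returns the
standardised profile.

## Known limitations

- The static dendrogram cut can split or lump modules whose merge heights
  straddle the cut fraction; real-data use may warrant tuning
  `cut_fraction` or an external dynamic-cut implementation.
- The $\nu$-SVR engine is less accurate than NNLS on the simulator's block
  signatures and is provided for methodological fidelity, not as the
  default.
- Connectivity's signed/absolute ambiguity is inherited from its verbal
  definition; both modes are first-class and reported with the output.
- Reference signatures are not bundled; real-data runs must supply an
  LM22-format TSV and their own cytokine panel.
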