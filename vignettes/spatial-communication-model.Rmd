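---
title: "Modeling neighbor-type regulation of highly variable genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling neighbor-type regulation of highly variable genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacomm)
```

## The model

`spacomm` treats a tissue as a multiple-input multiple-output system: the
expression of each cell type's highly variable genes (HVGs) is the
output, and the spatial presence of every cell type in the neighborhood
is the input. For cell $c$ and cell type $b$ the raw neighbor score is

$$f'_{c,b} = \sum_{m \ne c,\; d_m = b} \log_{10}\!\left(\frac{\mathrm{dist}(c,m)}{\mathrm{dist}_0}\right),$$

with $\mathrm{dist}_0$ the minimum pairwise distance in the dataset.
Scores are z-scored per column. For each cell type $a$ (its cells only),
the z-scored expression $u^{(a)}_{c,h}$ of its HVGs is modeled linearly:

$$u^{(a)}_{c,h} = \sum_b f^{(a)}_{c,b}\, w^{(a)}_{b,h} + \varepsilon_{c,h}.$$

The coefficients $w_{b,h}$ — direction and magnitude of neighbor type
$b$'s regulation of gene $h$ — are the object of inference, estimated by
multi-response partial least squares (PLS2) and decomposed per latent
component, $w_{b,h} = \sum_c w_{b,h,c}$.

Two modeling caveats are worth stating plainly. First, the score
$\log_{10}(\mathrm{dist}/\mathrm{dist}_0)$ *increases* with distance:
far-away cells of a type contribute more than adjacent ones, and the
nearest pair contributes exactly 0. We implement this form as the
method's definition; users who want a decaying influence can set
`kernel = "exp_decay"` ($e^{-\mathrm{dist}/\mathrm{dist}_0}$) in
`neighbor_score_matrix()` or `fit_communication()`. Because the z-scoring
absorbs any monotone rescaling common to all cells, the two kernels often
give similar fits on strongly stratified tissue, but they are not
equivalent. Second, the regression is associational: spatial
stratification of cell types induces collinearity between neighbor
scores, and the filtered coefficients should be read as evidence of
spatially structured co-variation, not causal signaling.

## Fitting

`fit_pls2()` is a standard NIPALS PLS2: both blocks are mean-centered
(a no-op on z-scored inputs, kept as a numerical guard), components are
extracted iteratively with deflation of both blocks by the x-score, and
coefficients are $B = R\,Q^\top$ with rotation
$R = W_x (P^\top W_x)^{-1}$. Slice $c$ of the coefficient tensor is
$r_c q_c^\top$, so the slices sum to $B$ exactly (a telescoping identity
asserted in the tests to $10^{-10}$), and with as many components as the
rank of the centered predictor block $B$ equals the OLS solution (tested
to $10^{-8}$ against the normal equations). PLS rather than OLS matters
in the small-$n$, collinear-predictor regime typical of per-type slices.

The component count $C$ is selected by 10-fold cross-validation:
cells are shuffled with a fixed seed, split into contiguous near-equal
folds, and the $C \in [1, \min(A, Z_a - 1, 10)]$ minimizing the mean
out-of-fold RMSEP is chosen, ties going to the smaller $C$ (preferring
the simpler model when the curve is flat, as it is for pure noise).

## Filtering, with its ambiguities resolved

Stage 1 tests, for every component $c$, the Pearson correlation of each
predictor column with the x-score $t_c$ and of each gene with the
y-score $l_c$, via $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of
freedom. The two p-value families (predictors × components and genes ×
components) are Benjamini–Hochberg adjusted separately, and
$w_{b,h,c}$ is kept only if **both** FDR values fall below
$\delta = 0.05$. Stage 2 sums the surviving tensor over components and
retests each surviving $(b,h)$ pair by the direct correlation between
the neighbor score and the gene's expression, BH-adjusted over all
tested pairs within the cell type. Filtering only zeroes entries; it
never alters a retained value.

Design choices that were genuinely open: the BH families are scoped per
cell type and per family as above (the finest scope that keeps each test
family homogeneous); degenerate correlations (zero variance) receive
$p = 1$; the stored (undeflated) score vectors are used in stage 1; and
$\delta$ is a configuration parameter with default 0.05. Under a seeded
global-null simulation (200 replicates of 100 cells × 3 types × 50
genes) the retained fraction is ~0.002, comfortably below
$\delta$ + 3 binomial sd — the acceptance script recomputes this.

## Clustering and the communication graph

Genes whose entire coefficient row is zero are dropped; the remaining
genes × $A$ coefficient vectors are clustered by seeded k-means
(10 random restarts, Euclidean distance; base R's `kmeans` with random
restarts stands in for k-means++ initialization, which changes only the
initialization heuristic, not the objective). $k$ ranges over
$[2, \min(15, n_{\mathrm{genes}} - 1)]$ and the mean silhouette
$(b - a)/\max(a, b)$ — singleton clusters and 0/0 cases contributing 0 —
selects $k$, ties to the smaller value.

For the cell-type graph, each receiver $a$'s cluster-level coefficient
matrix (per-cluster means) is reduced to the $k_{\min}$ clusters with the
largest L2 norms, where $k_{\min}$ is the minimum cluster count over
types — this standardization keeps $w_{a,b}$ comparable across cell
types with different cluster counts. Then
$w_{a,b} = \sqrt{\sum_m w_{m,b}^2}$, stored as the directed edge
$b \to a$. Entries below the mean of the off-diagonal entries are
zeroed, as is the diagonal (self-communication is outside the graph
semantics). The same mean is the attenuation constant: each simple
directed path (no repeated nodes, at most $A - 1$ edges) contributes
$\sum_s (\mathrm{weight}(e_s) - \mathrm{mean}\cdot 10^{1-s})$, summed
over all paths into $R[\mathrm{src}, \mathrm{dst}]$. Thresholding
guarantees every per-edge term is nonnegative, so no clamping is needed;
restricting to simple paths makes the sum finite. An exhaustive
recursive enumerator in the tests confirms the igraph-based
implementation exactly on all random graphs with up to 6 types. The
mean (not the median mentioned as an alternative for the decay base) is
used throughout so thresholding and attenuation share one constant.

## HVG selection and the overlap statistic

HVGs are selected **per cell type** (each type's slice drops genes that
are all-zero within the type, then ranks the rest), because the method's
premise is that each type has its own characteristic HVG set; a single
global selection is available by passing the full dataset to
`select_hvgs_vst()`. The ranking is the variance-stabilizing standard:
loess (span 0.3, degree 2) of $\log_{10}$ variance on $\log_{10}$ mean,
standardization by the fitted sd, clipping at $\sqrt{n}$, ranking by the
variance of the clipped values. `hvg_overlap_ratio()` summarizes
between-type HVG similarity as the mean over ordered pairs of
$|H_i \cap H_j| / |H_i|$; since the literature also uses
$|H_i \cap H_j| / \min(|H_i|,|H_j|)$, that variant is available via
`mode = "min_fraction"`.

## Gene classification

Annotation text is matched offline against fixed keyword lists — strong
("receptor", "ligand", "receptors", "ligands", "cell–cell adhesion",
"intercellular interaction"; hyphen, en-dash and space between the
"cell" tokens are equivalent) and weak ("surfaces of many cells and
extracellular matrices", "Participates in cellular", "Pathway",
"regulation", "signal transduction"). A gene is positive iff a strong
keyword matches, making labeling deterministic and reproducible without
web access. Features are the gene's filtered coefficient vector averaged
over the cell types where it is an HVG, plus mean expression, log1p
variance and dropout fraction — the coefficients are the method's own
measure of communication involvement, and the three summaries let the
classifier exploit expression-level regularities. The classifier is a
single-hidden-layer perceptron (`nnet`, 64 logistic hidden units,
entropy loss, weight decay $10^{-3}$, at most 500 epochs) under
stratified seeded 10-fold cross-validation; weight decay plays the
regularizing role that early stopping would otherwise play.

## The synthetic generator: what it does and does not emulate

`simulate_dataset()` places each type in a contiguous 100-unit spatial
stripe (so neighbor scores differ strongly across space), computes true
neighbor scores with the package's own scorer (tests cross-check it
against an independent double-loop implementation to break the
circularity), and draws responsive genes as
$f_z \beta + \mathcal{N}(0, \sigma^2)$ with per-gene shifts to
nonnegativity. The standard study conditions are 600 cells, 3 types,
200 genes, 20% responsive, $|\beta| = 2$, $\sigma = 0.5$ — sizes at
which every pipeline stage is exercised in seconds while leaving clear
signal-to-noise margins ($|\beta|/\sigma = 4$ is a strong but not
trivial effect for a spatial regression at $n = 200$ cells per type).
The generator emulates spatially clustered cell types, per-type HVG
structure and linear neighbor-score effects. It does **not** emulate
count noise (negative binomial, library-size variation), spatial
expression gradients unrelated to cell type, within-type substructure,
or segmentation errors — so passing recovery tests demonstrate
correctness of the estimation machinery, not robustness to every
property of real data.

Recovery is measured by `evaluate_recovery()`: for each planted
(sender type, gene) pair, surviving coefficients are de-standardized
(multiplied by the gene's within-type expression sd, undoing the
response z-scoring) and averaged over receiver types before comparing
sign and Pearson correlation with the planted $\beta$. On the standard
conditions all 40 planted pairs survive with the correct sign and
$r \approx 0.96$.

## Numerical choices and degenerate inputs

- Coincident cells make $\mathrm{dist}_0 = 0$ and are a hard error;
  an optional seeded jitter (≤ $10^{-6}$ of the bounding-box diagonal)
  resolves duplicated coordinates deterministically.
- Constant columns z-score to all zeros; degenerate correlations are
  non-significant by convention.
- NIPALS stops with an informative error if the response block deflates
  to zero before the requested component count.
- All seeds (CV shuffle, k-means, MLP, generator, jitter) are explicit
  arguments recorded in the pipeline manifest; two runs with the same
  config agree bit-for-bit.
- Cell and gene identity are string-keyed throughout; the canonical cell
  order is the expression file's order. Expression may be raw counts or
  normalized values — no normalization is applied beyond the stated
  z-scoring, so the coefficient scale follows the input scale.

## Known limitations

The neighbor score sums over *all* cells ($O(Z^2)$ distances), which is
exact but memory-bound around $10^4$–$10^5$ cells. Simple-path
enumeration is exponential in the number of cell types; it is intended
for the tens of types typical of annotated spatial datasets, not for
hundreds. The two overlap-ratio reference values for the public
Seq-Scope colon and seqFISH+ cortex datasets require those external
downloads and are checked by the test suite only when the data are
placed under `external_data/`.
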