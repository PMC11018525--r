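---
title: "Methods: tile-level regression models for enhancer-gene linking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tile-level regression models for enhancer-gene linking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilelink)
```

## The model

tilelink treats each gene as its own prediction problem: given the
chromatin accessibility of a genomic context around the gene, measured in
the same single cells as the gene's expression (multi-ome data), learn
which parts of that context predict expression. The context is split
into non-overlapping 500 bp tiles covering 250 kb upstream, the gene
body, and 250 kb downstream (both defaults are adjustable). Tiles are
anchored at `gene start - flank`, so the tile count depends only on gene
length: `2 * flank/tile_size + ceiling(length/tile_size)`. An 11,703 bp
gene yields 1,024 tiles; a 140,502 bp gene yields 1,282.

For one gene with tile matrix $X$ (cells $\times$ tiles, scaled as
described below) and depth-normalized expression $y$, the model is a
regularized Poisson regression with a log link,

$$
\min_{w \ge 0,\ \epsilon} \quad
\frac{1}{N}\sum_{i=1}^{N}\left(e^{X_i w + \epsilon} - y_i\,(X_i w + \epsilon)\right)
+ \alpha \lVert w \rVert_2^2 ,
$$

with three structural choices that shape everything downstream:

* **Non-negative coefficients.** Only positive regulators are learned;
  a tile with $w_t > 0$ is a candidate enhancer. Repressive elements are
  invisible to the model by construction.
* **L2 (ridge) penalty.** The model keeps all tiles and shrinks, rather
  than selects; interpretation happens afterwards via attribution and
  significance testing, not via the sparsity pattern. An L1 penalty is
  deliberately not offered.
* **Poisson loss on normalized (non-integer) expression.** The loss is
  applied to counts-per-10,000 values exactly as written; no
  integerization. These values are overdispersed relative to Poisson,
  which is tolerated: the loss acts as a robust link-appropriate fitting
  criterion, and inference about tiles never relies on Poisson standard
  errors.

## Preprocessing

* Expression: counts per `scale_factor` (default 10,000). A counts-per-million
  convention is available through the same argument; the default follows
  the dominant convention in this class of pipeline.
* Accessibility: each cell's tile counts are divided by its ReadsInTSS
  (insertions near transcription start sites, a depth-and-quality
  normalizer) and multiplied by the median ReadsInTSS; the rescaling
  constant keeps magnitudes familiar and cancels in the min-max scaling.
  When metadata lacks ReadsInTSS, a fallback counts insertions within
  ±2 kb of supplied TSSs, floored at 1.
* Gene selection: top-5,000 genes by dispersion (variance/mean of
  log1p-normalized expression; constant-in-raw-counts genes excluded),
  then a sparsity filter keeping genes with at most 90% zero-count cells
  (the boundary value is kept).
* Per-tile min-max scaling is fitted on training cells only and the same
  affine rule is applied to test cells without clipping, so test values
  may leave $[0, 1]$; clipping would silently change predictions.
* Cells are split 3:1 into train and test; the regularization weight
  $\alpha$ is chosen by fourfold cross-validation on the training cells,
  scored by unpenalized held-out Poisson deviance
  $\mathrm{mean}(e^{\eta} - y\,\eta)$, ties resolving to the larger
  $\alpha$. The default grid is $\{0.01, 0.1, 1, 10, 100\}$.

## Optimization

The loss is minimized by full-batch Adam (learning rate 0.01, at most
5,000 iterations) with projection of $w$ onto the non-negative orthant
after every step, stopping when the relative loss change falls below
1e-6. $\epsilon$ is initialized at $\log(\bar y + 10^{-8})$, $w$ at zero,
and $\epsilon$ is floored at $\log(10^{-8})$ so an all-zero target
degrades to the flat model instead of diverging. Because a first-order
stopping rule on the loss cannot guarantee tight first-order optimality,
an active-set projected Newton polish runs afterwards: coordinates that
are positive, or at zero with an inward-pointing gradient, take damped
Newton steps (with backtracking line search) until the KKT residual —
$|g_t|$ on free coordinates, $\max(0, -g_t)$ on bound ones — falls below
1e-9. The polish is what makes exact zeros meaningful and lets tests
assert KKT conditions at tolerance rather than hoping Adam landed close.
The problem is convex, so the two phases are a globalization strategy
plus a fast local method, not two different estimators.

Prediction is $\hat y = e^{Xw + \epsilon}$ and performance is the
Spearman correlation between $\hat y$ and $y$ on held-out cells
(average-rank ties; a constant vector yields $\rho = 0$ with a
degeneracy flag).

## Cell-type-specific attribution

For a linear predictor, the Shapley value of tile $t$ on a profile $x$
reduces to $w_t\,(x_t - \overline{X_{\cdot t}})$, with the background
mean taken over **all** training cells (not per type), matching the
single global mean in the attribution formula. Scores are made
cell-type-specific by pseudobulking: 500 iterations, each sampling 50
training cells of the type without replacement and scoring the averaged
profile; the per-tile means are then z-scored across tiles within each
(gene, cell type). Only cell types with at least 100 cells are scored.
Standardization is per (gene, cell type): that is the unit in which the
scores are displayed and thresholded, and it makes z-scores comparable
across genes whose raw coefficient scales differ.

Tile importance is ranked by a second, prediction-based route: for each
tile with $w_t > 0$, predictions "without the tile" are formed by zeroing
$w_t$ (scaler and intercept untouched), and a one-sided paired Wilcoxon
signed-rank test compares $|\hat y - y|$ with versus without the tile on
held-out cells, per cell type. The paired quantity is a design choice —
the underlying test is stated abstractly in the field — and absolute
prediction error makes "the tile helps" a one-sided hypothesis. Zeroing
the coefficient rather than the accessibility column keeps the scaler
fixed and makes the null exact when $w_t = 0$ ($p = 1$ by convention).
P-values are BH-adjusted across all (gene, tile, cell type) tests in a
run.

A **gene-linked tile** for a cell type passes all three filters: model
test correlation > 0.1, Shapley z > 0.5, and FDR < 0.001. Linked tiles
are ranked by the signed-rank p-value for enrichment-recall analysis.

## Variant enrichment with matched backgrounds

Fine-mapped GWAS variants (PIP > 0.2), fine-mapped eQTLs (PIP > 0.5) and
curated regulatory variants are compared against common variants matched
on three keys: MAF bin (<0.01, 0.01–0.1, >0.1), LD block, and a
distance-based annotation. Distance classes per gene window: gene-body
tiles; the 20 flank tiles immediately upstream of the gene
(promoter-proximal, 10 kb), resolved by strand; the 20 immediately
downstream; all else distal. With non-default flanks the proximal band
shrinks to `min(20, flank_tiles)`.

Within each unit (trait for GWAS, gene for eQTL, the match group itself
for regulatory databases) and each match group $g$:

$$
\mathrm{enrichment}_g =
\frac{\#\text{positive in linked} / \#\text{common in linked}}
     {\#\text{positive in } g \text{ overall} / \#\text{common in } g \text{ overall}} .
$$

Groups with a zero denominator are excluded from the unweighted group
average (the formulas are averaged exactly as written, without variant
count weighting); units with no valid group are dropped with a message,
and an empty linked set reports enrichment 0. Uncertainty is a
percentile bootstrap (1,000 iterations) over units, with the two-sided
comparison p-value $2\min(P(\Delta \le 0), P(\Delta \ge 0))$ floored at
$1/n_{\text{boot}}$.

A practical caveat surfaced by the coverage simulations: per-unit
enrichments share the common-variant denominators, so with a small
common-variant universe the trait bootstrap understates variance and the
95% interval undercovers. Coverage reaches its nominal range once the
common background is large relative to the per-trait counts, which is
the regime the method is meant for (genome-scale backgrounds); the
acceptance simulations use 20,000 common variants against 80 traits of
20 causal variants each.

## Chromatin potential

The trajectory field asks, for each cell, "which cells' observed
expression looks like this cell's chromatin-predicted expression?" —
under the hypothesis that chromatin opens before transcription follows.
Predicted and observed expression are smoothed over a kNN graph (k = 50,
self included) built on an LSI embedding of accessibility (TF-IDF,
log1p, truncated SVD with deterministic sign fixing), genes with
non-positive Spearman correlation between smoothed predicted and
observed values are dropped (strictly positive required), and both
matrices are min-max scaled per gene over all cells (no train/test split
here). Target cells are the k = 10 with the highest Pearson correlation
between their observed vector and the source cell's predicted vector —
the correlation reading of "nearest neighbours", which is the operative
phrasing; self-matches are allowed so terminal states produce near-zero
arrows. The arrow runs from the source cell's 2D layout position to the
mean position of its targets, and arrows are averaged over a 30×30 grid
for display (the grid resolution is a display choice). Degenerate
(constant) predicted vectors yield flagged zero arrows, and at least two
genes are required. Smoothing precedes the positive-correlation filter,
following the natural order of the computation.

## The synthetic-data generator

The generator exists so every stage is testable against known truth
without external downloads. It draws per-cell depth factors
$\mathrm{LogNormal}(0, 0.3)$ shared by ATAC and RNA (ReadsInTSS
proportional to depth), background tile rates uniform on
[0.02, 0.15] insertions/cell, and plants `n_active = 5` enhancer tiles
per gene. Planted tiles are closed (rate 0.05) outside the expressing
cell type; inside it, each (cell, tile) is independently open with
probability 0.5, and open tiles have rate 2.5. This stochastic per-cell
enhancer state mirrors the strongly bimodal accessibility of real
scATAC data, and it matters statistically: if planted tiles were
deterministic cell-type markers they would be mutually redundant proxies
of the type label, the ridge solution could shift weight freely among
them, and "recovery of the planted tiles" would not be a well-posed
claim. With independent per-cell states each tile carries its own
within-type association with expression, so the planted coefficient
vector is identifiable. Expression is drawn
$y \sim \mathrm{Poisson}(e^{X_s w^* + \epsilon^*})$ with
$w^* \sim U(2, 3)$ on planted tiles and $\epsilon^* = \log 2$, the model
family's own generative form; an overdispersion knob (Gamma-mixed rates)
exists for robustness checks. Fifty log-normal background genes pad the
RNA matrix so per-cell totals are realistic.

Variant simulation places common variants uniformly over the window and
causal variants with a configurable placement weight on the planted
enhancer tiles (weight 1 = exchangeable), draws MAF to populate all
three matching bins, assigns PIP in (0.5, 1] and cyclic trait labels,
and tiles the window with LD blocks (25 tiles each).

The trajectory generator orders cells on a pseudotime, switches each
driver gene along a sigmoid at a gene-specific time — half the genes
activate and half deactivate, as in real differentiation where
early-state markers turn off — with chromatin at the switch time and
expression delayed by `delta` (default 0.15). The deactivating half is
essential: with monotone activation only, terminal cells have
near-constant profiles, correlation matching degenerates to noise, and
arrows regress toward the trajectory centre; mixed directions keep
profiles informative along the entire path. The 2D layout is a noisy
curve in pseudotime whose tangent provides the true direction for cosine
comparisons.

What the generator does **not** emulate: doublets, batch effects,
ambient contamination, DNA sequence content, negative regulation, or
linked (haplotype-correlated) variant placement. Passing tests on this
generator therefore demonstrate correctness of the computations and
recoverability under the model's own assumptions, not robustness to the
full messiness of real multi-ome data.

## Problem sizes in the test and acceptance suites

The recovery protocol fits 20 independent simulations at 2,000 cells ×
200 tiles × 5 planted enhancers with full cross-validation (the package's
documented study conditions); unit tests use a shared 600-cell fixture.
Bootstrap coverage is assessed over 500 simulated variant universes with
1,000 bootstrap iterations each; the chromatin potential check runs 10
seeded 400-cell trajectories. At these sizes the whole suite completes
in a couple of minutes on one core. The acceptance script
(`scripts/acceptance.R`) re-runs the same computations at 10 simulations
and 100 coverage universes, which reproduces every quantity comfortably.

## Known limitations

* Only positive regulation is modelled; repressors are invisible.
* The Poisson loss on normalized counts ignores overdispersion; the
  package leans on rank-based evaluation and resampling-based
  uncertainty rather than likelihood-based standard errors.
* Enhancers shared identically by all cells of a type are subject to the
  redundancy ambiguity discussed above; coefficients then spread
  arbitrarily among correlated tiles even though predictions are stable.
* The signed-rank tile test needs enough expressing held-out cells per
  cell type; rare cell types yield weak p-values at any effect size.
* Enrichment estimates assume the common-variant background is large;
  small backgrounds correlate the per-unit estimates and narrow the
  bootstrap intervals.
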