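---
title: "Methods: spatial cytokine milieus, neighborhoods and crosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial cytokine milieus, neighborhoods and crosstalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`spatmilieu` analyzes per-cell tables from multiplexed tissue imaging (IMC
with RNAscope probe panels) of tumor immune microenvironments, contrasting
exhausted (IE1, rich in PD-1^high^ T cells) and non-exhausted (IE2) immune
environments. The package covers six analyses that share one data model —
cells as disks (centroid + radius, in micrometers, 1 px = 1 µm, origin
top-left) inside 1 mm × 1 mm images, grouped into patients — plus a
synthetic-data generator that plants known structure so every stage can be
scored against ground truth.

# Cytokine expression calling

Each cell carries raw counts for cytokine mRNA probes and for *DapB*, a
bacterial transcript absent from human tissue that measures per-cell probe
background. For cytokine *k* and cell *i* the statistic is the difference
`d_ik = count_ik − count_i,DapB`. Under exchangeable probe noise a
non-expressing cell has `d` symmetric about zero, so the null is estimated
per cytokine from the empirical differences by **symmetrizing the
non-positive tail**: the null sample is `{d ≤ 0} ∪ {−d : d ≤ 0}` (a
multiset; zeros count twice). This is assumption-light — it needs no
parametric noise model and is insensitive to contamination by true
expressers, which essentially never produce `d ≤ 0`. The p-value is the
upper-tail empirical probability with add-one smoothing, so the smallest
attainable p is `1/(n_null + 1)` and p is never zero.
Benjamini–Hochberg correction is applied **per cytokine across all cells of
the dataset** (prevalences differ by probe; a high-prevalence probe must not
relax the threshold of a rare one), and `q < 0.01` defines an expressing
cell. Pooling across images is the default because the probe background is
a property of the staining run, not of one image; `per_image = TRUE` is
available for batch-suspect data.

**Operating characteristics.** With a Poisson background (mean λ₀) and an
additive expression boost Δ, the difference for a non-expresser is
Skellam(λ₀, λ₀) and for an expresser Skellam(λ₀+Δ, λ₀). BH at q < 0.01
self-calibrates to a rejection threshold around `d ≥ 6–8` (prevalence
dependent), so at λ₀ = 1, Δ = 5 per-cell sensitivity is the Skellam upper
tail P(d ≥ threshold) ≈ 0.4 while the false-call rate stays below 10⁻³.
Single-cell counting noise, not the estimator, sets this ceiling: a
detector that called more of the planted expressers at these parameters
would necessarily violate the FDR target. Aggregate quantities (per-image
expressing fractions, IE ratios) are unbiased by the shared threshold, which
is why the planted 5:1 IE contrast is recovered even at ~0.4 per-cell
sensitivity.

# Neighbor structures

Three image-scoped neighbor definitions drive all spatial statistics:

* **Contact graph** (default expansion 8 µm): cells touch when
  `dist ≤ r_i + r_j + 2·8` µm. Both disks are expanded, mirroring
  segmentation-mask expansion of *every* cell's circumference before overlap
  testing; `combined = FALSE` switches to single-sided slack for sensitivity
  analyses, since a disk model cannot settle which reading matches mask
  geometry.
* **Radius graph** (default 25 µm): centroid distance, boundary inclusive.
* **kNN lists** (default k = 10): exact, ties broken by ascending
  `cell_id` for bit-reproducibility; optional candidate-type restriction and
  exclusion (e.g. "ten closest T cells excluding T~regs~").

All three are computed exactly (uniform-grid indexing or blocked distance
evaluation) and the test suite checks set/list equality against all-pairs
brute force up to 2000 cells. No edge correction is applied at image
borders: border cells simply have truncated neighborhoods, matching
per-image analysis of real regions of interest.

# Cytokine patches and milieus

A **patch** is a connected component — chains allowed, not mutual cliques —
of the 25 µm radius graph restricted to qualifying cells (expressing any
cytokine for *general* patches, a named cytokine for *specific* ones), with
at least 3 members. The component reading is deliberate: a clique reading
would make large patches geometrically impossible. A **milieu** adds every
cell within 30 µm (centroid-to-centroid; mask borders are unavailable in a
table-based model) of a patch member. Per image, milieus of one kind are
merged before testing so each cell counts once per (image, kind); cell-type
enrichment uses the two-sided Fisher exact test on the 2×2 in/out × type
table at p < 0.01, with direction assigned post hoc by the sample odds
ratio — one test reports both enrichment and depletion. Only images
containing both the cell type and the milieu kind enter the cross-image
summary (percentage of images enriched minus depleted). Degenerate margins
give p = 1 and an `ns` call.

# Pairwise neighborhood permutation test

For each ordered type pair (A, B) the statistic is the mean over A cells of
their B-neighbor count in the contact graph, including A cells with zero
neighbors (excluding them would bias toward interaction). The null permutes
cell-type labels over the image with the graph fixed — this conditions on
type counts and *is* the correction for relative cell-type frequency. One
seeded permutation stream is shared by all pairs of an image (joint
reproducibility; 1000 permutations by default), p-values use add-one
smoothing, and the observed/permuted comparison is done on integer link
totals, so no floating-point tolerance enters. Raw p < 0.01 thresholds the
calls, uncorrected across pairs and images, which matches how such
interaction heat maps are conventionally reported; a total-count statistic
variant is available and gives identical p-values (the denominator is
permutation-invariant).

# Signature scoring and ligand–receptor crosstalk

Gene-signature scores are `Σ_g log(1 + 10⁴·count_g/total)` — counts
per 10k, natural log, pseudocount 1. The scale and pseudocount are the
package's concrete choice for "normalize by total and log-transform"; the
score is invariant to uniform per-cell scaling and strictly monotone in any
signature gene. The four shipped lists (T-cell attraction, T-cell
suppression, M1, M2) are literature-role placeholders in editable text
files; real analyses should substitute curated lists. A random control
signature is drawn from genes *disjoint* from the functional lists — drawing
from the functional genes themselves would trivially correlate. Spearman
correlations use `stats::cor.test`.

LR scores are the regularized geometric mean
`sqrt(l·r)/(µ + sqrt(l·r))` of mean normalized ligand (sender) and receptor
(receiver) expression, bounded in [0, 1); µ defaults to the global mean of
the expression matrix so 0.5 marks typical intensity. Scores ≥ 0.4 count as
"true" interactions; pair-specific interactions are the five highest
coefficients of variation among each type pair's top-100 scores (ties by
pair name; a constant matrix degenerates to name order and is flagged).
Per-patient scoring skips types with fewer than 10 cells in a patient.
IE enrichment compares per-patient scores with the exact two-sided Wilcoxon
rank-sum test at p < 0.05, *uncorrected* (a screening analysis by design),
retaining rows whose overall mean score exceeds 0.4. Autocrine vs paracrine
is labeled purely by sender == receiver.

# Exact rank tests

IE comparisons run on small per-patient summaries (typically 7 vs 7) that
often contain ties, where `stats::wilcox.test` abandons exactness. The
package therefore computes exact conditional null distributions given the
observed (tie-averaged) ranks by dynamic programming over the generating
function, for both the rank-sum and the signed-rank test; average ranks are
doubled to keep all sums integral. Two-sided p doubles the smaller tail,
capped at 1; zero paired differences are dropped (all-zero input reports
p = 1 with a warning); beyond 200 (rank-sum) / 100 (signed-rank) units a
tie-corrected normal approximation takes over. Full-enumeration oracles
verify both tests in the suite. The first-choice comparison between immune
environments in the reporting pipeline is the **sample-averaged Wilcoxon**:
per-image values averaged per patient, then rank-sum between IE groups.
Mixed-effects modeling of per-image values is intentionally out of scope.

# The synthetic-data generator

`simulate_tme()` emulates the statistical and spatial structure the
analyses assume, with every planted feature returned as ground truth:

* **Geometry**: 1000 µm square images, 4000 cells each (defaults:
  7 patients per IE × 4 images); radii log-normal, median 5 µm, clipped to
  [2, 15] µm — only the contact rule consumes them.
* **Types**: i.i.d. per-IE frequencies; IE1 carries ~8% PD-1^high^ T cells
  and 2% NKT, IE2 ~1% and 0.5% — the defining compositional contrast.
* **Attraction** (Thomas-type shared parents): a strength-θ fraction of both
  pair members is re-placed around common Gaussian parents (σ = 25 µm).
  Defaults plant migDC–PD-1^high^CD8 (θ = 0.8) and
  fibroblast–endothelial (θ = 0.6). O(n) to sample, and strength maps
  directly onto permutation-test power.
* **Avoidance**: tumor–B (strength 0.8): B proposals within 40 µm of a tumor
  cell are repeatedly resampled.
* **TLS**: per-IE status probabilities (mature more frequent in IE2,
  immature in IE1); mature = dense B-cell disc of radius 80 µm, immature =
  loose σ = 120 µm aggregate. Centers prefer tumor-poor candidate positions
  (TLS are stromal structures); CXCL13 expresser clusters anchor at mature
  TLS and are absent (dispersed only) in immature ones, reproducing the
  patch-membership contrast by TLS status.
* **Probes**: `cy_DapB ~ Pois(1)`; cytokines `Pois(1)` or `Pois(1+5)` for
  planted expressers (per-cytokine fractions 0.02 in IE1 vs 0.004 in IE2 —
  the planted 5:1). Part of each quota is laid down as spatial clusters
  (seed cell + Gaussian-weighted neighbors, σ = 15 µm, size 3 + Pois(5),
  ~1 cluster/image/cytokine) so that detectable patches exist; cluster cells
  count against the quota, preserving the planted fractions.
* **Genes** (optional): a compact panel (signature genes, ~50 LR genes, 20
  filler genes), Poisson counts with per-type structure (ligands up in
  myeloid lineages, receptors in T/NK), lognormal per-patient-per-gene
  factors, per-cell library factors, 6× elevation of attraction+suppression
  genes in a designated 30% of myeloid cells (which also get high PD-L1/IDO1
  marker intensity), and 4× boosts of designated checkpoint/chemokine/
  cytokine LR pairs in IE1 patients (FLT3LG–FLT3 in IE2).

**What it does not emulate**: segmentation artifacts and signal spillover
between neighboring cells, probe-specific background differences,
transcriptome-wide expression (only the panel genes exist, so totals are
panel totals), spatial gradients within cell types, and patient-level
covariates such as grade effects. Passing tests therefore demonstrate
correctness of the computations and recoverability of planted structure
under idealized noise — not performance on real tissue.

# Problem sizes and numerical choices

The validation suite and the acceptance script run at reduced sizes chosen
to keep Monte-Carlo error small relative to each tolerance: permutation
calibration on 8 structureless images × 1500 cells (1800 evaluable
pair-image combinations), planted-pair recovery on 32 images × 2000 cells,
the IE contrast on 14 patients × 2 images × 2000 cells (10 seeds in the
suite), and calling characteristics on 20 000 cells with 10% planted
expressers. Determinism is enforced end to end: one root seed feeds named
substreams (stage-name hash, kept below 2³¹), all tie-breaks are by
`cell_id`, and identical configurations produce byte-identical output
bundles.

Degenerate inputs are defined, not errored, wherever a convention exists:
empty candidate sets give empty kNN lists; images lacking a target type
flag distances as missing; all-zero 2×2 tables and all-tied rank tests give
p = 1; zero-variance cytokine differences warn and give p = 1; zero-total
cells are excluded from scoring with a warning.

# Known limitations

* Per-cell calling sensitivity is bounded by counting noise (see operating
  characteristics above); analyses should treat per-cell calls as
  conservative and rely on aggregate statistics.
* The disk model approximates mask geometry; the contact rule's combined
  16 µm slack is a convention, exposed as a parameter.
* Fisher enrichment treats cells as independent within an image; spatial
  autocorrelation makes these p-values anti-conservative, which is why only
  image-level percentages (not pooled p-values) are summarized across the
  cohort.
* The LR stage scores mean expression; it does not model subunit complexes,
  ligand diffusion, or pathway activity.
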