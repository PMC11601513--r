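---
title: "Methods: from spatially barcoded reads to perturbation clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from spatially barcoded reads to perturbation clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbitscreen)
```

## The measurement

Deterministic barcoding in tissue (DBiT) delivers two orthogonal sets of 50
or 100 barcoded microfluidic channels across a fixed tissue section. The
intersection of an A-channel and a B-channel defines a *pixel*, the spatial
unit of every matrix in this package. When the tissue carries a pooled
CRISPR knockout screen, each captured guide RNA molecule yields a read pair
encoding, behind constant flanking sequences: two spatial barcodes (8-mers),
a unique molecular identifier (UMI, 10-mer), and the sgRNA spacer (the
15-30 nt sequence identifying the guide). `dbitscreen` turns such read
pairs into a pixel x sgRNA UMI count matrix, labels pixels by their
perturbation, derives perturbation signatures and clusters from a companion
expression matrix, and benchmarks spatial detection against a pooled
(non-spatial) screen readout.

Everything downstream of sequencing is covered; everything upstream (the
chemistry itself) is emulated by a simulator so each stage can be validated
against ground truth without any external data.

## Chemistry dialects

Four read chemistries are built in (`chemistry_preset()`): polyadenylated
capture (`polyA_enrichment`), two size-selection capture variants
(`capture_v1`, `capture_v2`), and a 100x100-channel layout (`pixel100`).
A dialect is a set of per-element extraction rules: which mate carries the
element, the constant flank(s) anchoring it, a length window, and the error
tolerance used to locate the flank. Three dialect quirks worth knowing:

* `capture_v1` anchors barcode B by a flank *after* the element (a 3'
  adapter); the 8-mer preceding the flank is extracted.
* `pixel100` reads run linker, UMI (10 nt), then barcode B; barcode B's
  anchor is therefore encoded as the linker plus ten `N` wildcard
  positions, requiring at least 13 anchor bases.
* The spacer is extracted between a linked 5'...3' flank pair, with at
  least 6 flank bases required at read ends, and must fall in 15-30 nt.

Flank location allows `ceiling(error_rate * flank_length)` substitutions
(default rate 0.1), with `N` in a flank matching any base. Matching is
substitution-only: the trimmed element boundaries are then exact, which
keeps barcode coordinates unambiguous. Indels in flanks are not modeled —
a deliberate trade against the error model of the simulator, which is also
substitution-only. Rules serialize to a YAML config
(`write_schema()`/`load_schema()`) that round-trips field-identically.

## Demultiplexing rules

Each element is matched with the tolerances conventional for its reference
size:

| element  | reference              | max mismatches | max hits |
|----------|------------------------|----------------|----------|
| barcodes | channel whitelist      | 1              | 2        |
| UMI      | data-derived whitelist | 0 (exact)      | 4        |
| spacer   | guide library          | 2              | 2        |

`match_with_tolerance()` implements one deterministic post-condition: among
references within the mismatch budget, the unique one at minimal Hamming
distance wins; a tie at the minimal distance, or more candidates than
`max_hits`, rejects the read as ambiguous. Where an aligner asked for the
"best" hit would report an arbitrary tie member, this package prefers a
conservative, reproducible rejection — for barcode correction a wrong
pixel is worse than a lost read.

The UMI whitelist is built from the data itself (`build_umi_whitelist()`):
the distinct, N-free 10-mers extracted by the UMI rule. UMI matching is
exact membership; deduplication is exact-sequence within each
(pixel, sgRNA) pair, with no directional-graph collapse. An empty
whitelist degrades to pass-through with a warning rather than rejecting
everything.

A read pair is assigned only when all four elements resolve; otherwise it
carries the *first* failing element's reason (barcode A, barcode B, UMI,
spacer order), so reasons partition the rejected reads. Pixels are
identified as `"AxB"` (1-based); orientation to microscope images is
metadata and never computed. Guide *area* — the number of pixels where a
guide is detected at least once — is the detection unit used downstream,
computed on raw detection (count >= 1) rather than any additional QC
state.

## The simulator

`simulate_tissue()` emulates what the analysis needs to be tested against,
not the full biology: disc-shaped clonal patches (non-overlapping by
default) on the pixel grid, one guide per clone; `Poisson(umi_rate)`
molecules per clone pixel; `Poisson(ambient_rate)` ambient molecules of
uniformly random guides on every on-tissue pixel; random 10-mer UMIs.
`emit_reads()` inverts the extraction rules exactly — reads are literal
concatenations of the dialect's template — then applies i.i.d. base
substitutions. `emit_gex()` draws negative-binomial counts with a
per-gene baseline mean and multiplies target-gene means by `2^effect` in
clone pixels.

Defaults mirror the study conditions used throughout the tests: a 50x50
grid, 4 clones of 25 pixels (radius 2.9), 5 UMIs per clone pixel, ambient
rate 0.05, substitution rate 0 or 0.005. Synthetic whitelists use random
distinct 8-mers at pairwise Hamming distance >= 3 (so one substitution is
always correctable uniquely) and spacer libraries use 20-mers at distance
>= 5 (so two substitutions cannot collide); production barcode sets are
instrument-specific and not shipped, and every fixture file is named
`synthetic_*`. What the simulator does *not* model: PCR duplication and
chimeras, indels, base-quality variation (constant Q40 is emitted), cell
segmentation, and diffusion between pixels. Tests passing on this
generator therefore validate the algorithmic contracts, not robustness to
those artifacts.

## Perturbation analysis

**Labeling** (`label_pixels()`): a pixel with no guide is `non_perturbed`
(NP); exactly one, `unique`; several, `resolved` in favor of the top guide
iff the top has >= 10 UMIs and every other guide has <= 1, else
`ambiguous`. The rule is a pure function of the count vector and is tested
exhaustively against a brute-force predicate.

**Normalization** (`normalize_gex()`): counts are scaled per pixel to the
median pixel depth, `log1p`-transformed, then centered and unit-scaled per
gene. This is a deliberate, documented substitution for variance-
stabilizing transforms used in production single-cell stacks: it is
dependency-free, monotone, and sufficient for the rank-based statistics
used here. Note one consequence: depth scaling is compositional, so a
strong perturbation of many genes deflects the normalized values of
untouched genes slightly in the opposite direction. Zero-variance genes
are dropped with a warning; an all-zero matrix is an error.

**Signatures** (`perturbation_signature()`): each eligible pixel's
signature is its normalized expression minus the mean of its k = 20
nearest NP pixels in PC space (NP pixels use their k nearest NP neighbors
excluding themselves). k = 20 is the common default for nearest-control
signature constructions; the PC count comes from `select_pcs()`, which
takes the variance-elbow (maximal perpendicular distance to the chord
through the first and last variance points, ties to the smallest index),
floored at 10 and capped at 50. Guides enter the signature assay when
detected with area >= 4; screens with fewer than 100 distinct guides skip
the gate entirely. Note that a k-nearest-control signature is *not*
exactly mean-zero on null data: selecting the nearest controls couples the
reference to local point density, leaving a small residual bias relative
to the signature's spread. It vanishes only when
the control pool is averaged uniformly (k equal to the pool size), a
degenerate case the unit tests use to pin the construction down.

**Scores** (`perturbation_score()`): a guide's class vector is the mean
signature of its pixels; a pixel's score is the Pearson correlation of its
signature with its class vector (NP pixels score against the mean of all
class vectors). Correlation puts the published +/-0.2 thresholds on a
fixed, scale-free [-1, 1] axis. `filter_by_score()` keeps labeled pixels
with score > 0.2 as perturbed and NP pixels with score < -0.2 as controls.
With many genes, null correlations concentrate tightly around zero, so the
score-selected control set can be small or empty (a warning, not an
error); differential expression therefore uses the NP-labeled pixel set as
its reference group.

**Clustering** (`cluster_pixels()`): PCA, then a shared-nearest-neighbor
graph (k = 20, Jaccard edge weights, edges below 1/15 pruned), then
modularity communities at each candidate resolution (0.2 to 2). Among
solutions with more than 3 clusters, the resolution with the best average
silhouette width (in PC space) wins; ties break to the smaller
within-cluster sum of squares, then the smaller resolution; if nothing
exceeds 3 clusters the best silhouette overall is used with a warning.
Pixels are ordered canonically by name before graph construction so
results do not depend on input row order; all stochastic steps take an
explicit seed (default 0). A 2-D UMAP (min_dist 0.01) is attached for
visualization only and never feeds the clustering.

**Naming** (`name_clusters()`): perturbations covering more than 20% of a
cluster's pixels are its majors, joined by `_` in decreasing frequency;
clusters with no major are named `NP+n`, with n the number of distinct
perturbations present.

**Differential expression** (`de_wilcoxon()`): genes detected in more than
20% of group A are tested with a two-sided Wilcoxon rank-sum test — exact
when both groups have at most 10 pixels and the data are tie-free, normal
approximation with tie and continuity correction otherwise — with
Benjamini-Hochberg adjustment across tested genes. Fold-changes are log2
ratios of group means on the depth-scaled scale with a pseudocount of 1.

## Benchmarking

`roc_auc()` computes the AUC as the Mann-Whitney statistic with midranks,
which equals the trapezoidal area under the returned curve and handles
ties exactly; it is verified against brute-force pairwise concordance.
`pooled_vs_spatial()` benchmarks a pooled screen's per-guide detection
fraction (continuous predictor) against spatial detection (area > 2,
binary response); guides absent from one side count as zero there. The
conventional 25% pooled cut is reported as an operating point with its
contingency table rather than binarizing the predictor, which would
degenerate the AUC. The area gates differ by use: >= 4 for the signature
gate, > 2 for the benchmark response; both are parameters with these
defaults. `demux_recovery()` scores assignments against simulator truth:
precision and recall on (pixel, guide) per read, an exact-triple fraction
that additionally requires the UMI, and per-guide area errors.

## Problem sizes and budgets

The shipped tests and the acceptance script run, per configuration: about
600-700 read pairs for round-trip checks (50x50 grid), three seeds at
substitution rate 0.005 (~1,900 pairs), 10,000 random queries against a
100-entry whitelist for the matcher oracle, a 400-pixel / 300-gene null
simulation, and a 34x34 / 400-gene two-clone recovery with ~200 pixels per
class. These sizes were chosen so every distributional check has
comfortable power while the whole suite completes in well under a minute
on one core; all of them scale linearly if larger runs are wanted.

## Known limitations

* Substitution-only matching everywhere; indel-containing reads are lost
  (by design, matched by the simulator's error model).
* The normalization is a simple log/median-depth scheme, not a fitted
  variance-stabilizing model; its compositional coupling is documented
  above.
* The k-nearest-control signature carries the small density bias discussed
  above; treat per-gene mean signatures near zero as approximate, not
  exact.
* mRNA alignment and gene counting are out of scope: the expression matrix
  is an input. Modality routing relies on spacer matches (or, for
  direct-capture layouts, separate barcode sets); reads from the mRNA
  library are simply not assigned by this package.
* "Resolved"/"ambiguous" labeling thresholds (10 and 1) are the published
  convention and are exposed as parameters, not re-derived.
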