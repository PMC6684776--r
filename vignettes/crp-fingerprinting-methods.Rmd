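---
title: "Methods: CRP fingerprint preprocessing, classification and marker analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRP fingerprint preprocessing, classification and marker analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpfp)
```

## The problem

Closely related medicinal roots — here Radix Astragali (RA, *Astragalus
membranaceus*) and Radix Hedysarum (RH, *Hedysarum polybotrys*) — are
hard to tell apart morphologically and are frequent substitution
partners in commerce. Cysteine-rich peptides (CRPs) between 2 and 6 kDa
are hyperstable, survive decoction and processing, and differ between
species, so a MALDI-TOF MS fingerprint of the 2–6 kDa region is a fast,
robust authentication signal: RA carries the astratides aM1 (3811.8 Da)
and bM1 (4724.4 Da), RH the hedytides hP1 (3944.3 Da) and hP2
(4780.1 Da). `crpfp` implements the full chemometric workflow around
such fingerprints — alignment, preprocessing, exploration, supervised
classification, performance metrics — plus the peptide-level analytics
(motifs, masses, digests) used to characterize the markers themselves.

## Fingerprint containers

A `crp_spectrum` is a tibble (`axis`, `intensity`) with sample metadata
in attributes. A `crp_matrix` holds samples × points; at study scale
that is 91 samples × 30935 m/z points, which is why the numeric block
stays a base matrix inside the container while `tidy()`/`as_tibble()`
offer data-frame views. Intensities are never clamped at I/O: negative
values can legitimately arise from instrument baseline export and are
the business of preprocessing, not parsing. All samples are placed on a
common axis by linear interpolation (`resample_to_grid()`), the minimal
assumption given that vendor software fixes only the number of exported
points, not the grid; points outside a spectrum's range fill with 0.
Triplicate acquisitions are averaged point-wise (`average_replicates()`)
before matrix assembly.

## Correlation optimized warping

Retention-time and m/z drift misalign peaks across samples.
`cow_align_pair()` partitions both query and reference into
`floor((n-1)/L)` fixed-length segments (the last absorbs the
remainder), lets every interior boundary of the query shift by at most
the slack `s`, linearly stretches or compresses each query segment onto
its reference segment, and maximizes the summed per-segment Pearson
correlation by dynamic programming. This summed correlation is the
canonical COW objective. Numerical choices:

* Zero-variance segments (flat baseline) contribute correlation 0, not
  `NaN`, so the total stays finite.
* Endpoints never move, and the warped signal keeps the input length.
* Ties prefer the smaller boundary displacement, so warping a signal
  onto itself is exactly the identity.
* Defaults are segment 150, slack 5 — the combination that aligns
  study-scale MALDI fingerprint matrices well.

The reference is the row with maximal total correlation to all others
(`choose_reference()`); constant rows are excluded, ties go to the
lowest index. `optimize_cow()` grid-searches (segment, slack) scoring
each candidate by *simplicity* (`sum(sv^4)/sum(sv^2)^2` over singular
values of the aligned, row-normalized matrix — alignment concentrates
variance into fewer components) plus a *peak factor* penalizing area
distortion (`1 - mean(min(1, |Δarea|/area))`, areas as sums of absolute
intensities). The exact constants of this score are our choice; the
tie-break (smaller segment, then smaller slack) keeps it deterministic.
The DP is verified against exhaustive enumeration of all boundary
placements on every instance with ≤ 3 interior boundaries and slack
≤ 2.

Published per-class optima differ slightly between classes (segment
148–151, slack 1–22), implying per-class alignment before pooling. The
toolkit supports both styles: align a whole matrix to one reference, or
run `cow_align()` per class and then align class references to each
other.

## Preprocessing recipes

`crp_recipe()` composes `cow`, `blank_subtract`, `snv`,
`normalize_sum`, `mean_center` in an explicit order. SNV
(per-row standardization) followed by mean centering is the shipped
default — the combination that yields the fewest PLS-DA latent
variables with the smallest calibration/prediction error on CRP
matrices. Two leakage guards are deliberate design choices rather than
published prescriptions: column means for centering are learned on
calibration rows only (`prep()`) and reapplied verbatim to validation
rows (`bake()`), and a `cow` step inside a recipe stores the
calibration reference signal at `prep()` time so validation rows warp
onto it. `mean_center` may appear at most once, and only last — any
row-wise step after column centering would silently destroy the
centering.

## PCA, outliers, clustering

`fit_pca()` is a centered SVD with a deterministic sign convention
(largest-magnitude loading element positive). Outlier screening uses
the conjunctive Hotelling's T² / Q-residual rule: T² is the
Mahalanobis distance in score space with the limit
`k(n-1)/(n-k) F(conf; k, n-k)`, Q is the squared reconstruction
residual with the Jackson–Mudholkar limit from the residual-space
eigenvalues, and a sample is flagged only when **both** exceed their
95% limits. The published workflow removed four outliers in a single
pass and proceeded with 38 RH + 49 RA samples; `run_pipeline()`
likewise performs at most one removal pass (off by default). Because
the exact limit constants of commercial toolboxes are unpublished,
flagged-sample identity on real data is not a contract of this package;
the planted-outlier recovery test on synthetic data is.

`hca_ward()` delegates to `stats::hclust(method = "ward.D")` on
squared Euclidean distances — the classic Ward/Lance–Williams
formulation, whose merge heights are provably monotone. `cut_dendrogram()`
cuts by cluster count or height, and `dendrogram_newick()` exports the
tree for external viewers.

## Kennard–Stone splitting

Calibration samples should span the fingerprint space.
`kennard_stone_split()` seeds each class with its two most distant
samples and greedily adds the sample with the greatest minimum distance
to the selected set, stopping at `ceiling(fraction * n)` per class.
Per-class ⌈0.6·n⌉ sizing is the only rule consistent with the published
23/38 + 30/49 split. Ties break to the lowest row index, making the
split fully deterministic.

## The five classifiers

All classifiers share `fit_*(X, y)` / `predict()` returning class
labels; only SIMCA may return `"unassigned"`.

* **PLS-DA** — NIPALS PLS1 regression of the 0/1 class code on the
  matrix; prediction thresholds the response at 0.5, the symmetric
  point between the codes (the published account says only "close to
  0/close to 1"). With as many latent variables as the rank, PLS
  reproduces ordinary least squares — a property the tests exploit as
  an oracle. Default 2 latent variables for MALDI matrices, 1 for UPLC.
* **KNN** — Euclidean majority vote, `k = 3` default for both matrix
  types, `k` selectable by leave-one-out CV (ties to smaller `k`). A
  tied vote resolves to the nearest neighbor's class.
* **SIMCA** — one PCA model per class (5 PCs default for MALDI, 1 for
  UPLC); a query's residual variance is F-compared to the class's
  calibration residual variance at `1 - alpha`. Sole acceptor wins;
  both-accept resolves to the smaller F-ratio; both-reject is
  `"unassigned"` — published NA counts imply the refusal outcome is
  rejected-by-both, not ambiguous-accept.
* **CART** — Gini-impurity binary splits grown to purity without
  pruning (tree size deliberately left undetermined), tie-breaking by
  lowest feature index then lowest threshold so the tree is unique.
* **SVM-DA** — soft-margin SVM via libsvm (`e1071`), linear kernel,
  `C = 1`, no internal rescaling; probability estimation optional and
  seeded.

## Performance metrics

`confusion_summary()` implements the two-class rates with an explicit
convention for `"unassigned"`: an unassigned positive counts against
sensitivity (it is a missed positive), while an unassigned negative is
excluded from specificity (no false claim was made). This asymmetric
rule is the only one consistent with published confusion tables that
report sensitivity 17/19 alongside specificity 13/13 when two samples
of each class go unassigned. The non-error rate is reported as the
class-size-weighted mean of sensitivity and specificity — the fraction
of non-errors over all samples those two rates cover — because the
weighted form reproduces published NER/ER pairs exactly at two
decimals, where the unweighted macro mean does not; the macro mean is
also exposed (`ner_macro`). `ER = 1 - NER` holds exactly at full
precision. Rates are rounded only at report time (two decimals in
`glance()`; four for RMSE-type quantities).

Venetian-blinds CV assigns sample *i* to block `i mod k` (default ten
blocks). Method-validation helpers implement the analytical formulas:
RSD% with the n−1 sample standard deviation (verified against
published intra-day precision tables), recovery accuracy %, and linear
calibration with `LOD = 3.3σ/slope` and `LOQ = 10σ/slope`. The LOQ
factor is the conventional 10 — published LOD/LOQ value pairs have a
ratio near 3 ≈ 10/3.3, confirming 10 was used even where the printed
formula duplicates the LOD expression.

## Peptide marker analytics

Marker peptides are characterized by cysteine-spacing motifs rendered
in C-Xn notation (`"C-X3-C-X7-C-X4-C-X-C-X9-C"` for aM1/hP1; single
residues render as plain `X`, adjacent cysteines as `C-C`), ungapped
positional identity for equal-length pairs (bM1 vs hP2: 28/45 =
62.2%; unequal lengths are an error directing users to a real
aligner), and neutral masses from the standard residue-mass table
(monoisotopic and average, with water). Cysteine chemistry is explicit:
each disulfide removes two hydrogens; reduction plus
carbamidomethylation adds 58 Da nominal (58.0293 monoisotopic) per
cysteine — the mass-increment rule used to count cysteines from intact
masses. Published similarity figures computed with unstated similarity
matrices (e.g. 65.7% for aM1 vs hP1, where positional identity gives
19/37 = 51.4%) are deliberately not reproduced.

In-silico digestion uses the Keil rules: trypsin cleaves C-terminal to
K/R, chymotrypsin (high specificity) to F/W/Y — never before proline;
the low-specificity chymotrypsin set F/W/Y/L/M sits behind a flag.
Fragments carry 1-based inclusive spans and both mass kinds; complete
digests tile the parent exactly and conserve mass up to one water per
cut (both fuzz-tested). The hP1 digest yields C-terminal fragment
CSTPSG at 550 Da monoisotopic, and hP2 with one missed cleavage yields
fragment 1–13 (CEKGSEFFVGACR) at 1433 Da average — the two observed
digest peaks that recompute cleanly; other published digest masses
likely involve partially modified species and are not asserted.

## The synthetic benchmark

`simulate_spectrum()` builds each replicate as
`baseline + Σ Gaussian(center + shift + warp, width, amplitude·(1+ε)) + noise`.
Gaussian peak shapes are a good approximation to reflector-mode MALDI
peaks at this resolution. One integer seed drives everything;
per-sample/replicate substreams are derived by counter, so generation
order cannot change the data. What the simulator does **not** emulate:
isotope envelopes, detector saturation, chemical noise, intensity-
dependent mass error. Passing tests on synthetic data therefore
demonstrate algorithmic correctness and the qualitative behavior of the
workflow, not instrument-level performance on real spectra (the real
deposited spectra are not shipped or downloaded).

`simulate_benchmark()` fixes the study conditions: 38 RH + 49 RA
samples, triplicates averaged, the four marker masses above, 5%
amplitude noise, additive noise 0.5, baseline 1, 2 Da global shift and
1 Da local warp — our one-time choice of a realistic moderate-noise
regime. The default benchmark grid is 4001 points over 2–6 kDa (1 Da
spacing): wide enough to resolve the 6 Da-wide peaks, small enough
that the entire pipeline runs in seconds; the generator's grid width
is configurable up to the full 30935-point study width, and unit tests
use a range of smaller grids. On this benchmark KNN, PLS-DA and SVM-DA
classify the 34 validation samples perfectly while SIMCA leaves
samples unassigned and CART sits in between — the same qualitative
ordering reported for the real data.

```{r benchmark, eval = FALSE}
res <- run_pipeline(model = "knn", seed = 7, positive_class = "RA")
res$metrics
```

## Known limitations

* Two classes only; the multiclass generalizations of PLS-DA/SIMCA
  coding are out of scope.
* COW is the only warping family; DTW/PTW/icoshift are not provided.
* T²/Q limit constants may differ from proprietary toolboxes, so
  real-data outlier identities can differ even when the rule agrees.
* Identity is ungapped; alignment-based identity belongs to external
  aligners.
* The CV-accuracy percentages printed in some published model tables
  are not exactly derivable from their own confusion counts; only the
  metric rows that recompute exactly are treated as reference values.
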