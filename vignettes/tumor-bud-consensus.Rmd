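---
title: "Methods: tumor-bud candidate detection and multi-observer consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-bud candidate detection and multi-observer consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budconsensus)
```

# The problem

Tumor budding — single tumor cells or clusters of up to four cells at the
invasive front — predicts outcome in colorectal cancer, but its assessment
is notoriously observer-dependent. Pan-cytokeratin immunohistochemistry
(IHC) highlights every keratin-expressing object in brown (DAB), which
makes candidate buds easy to find automatically but does not settle what
each object *is*: a tumor bud (TB), a poorly differentiated cluster (PDC,
five or more cells), or neither (debris, vessel fragments, "pseudo buds").
`budconsensus` implements the computational side of a multi-observer study
design on exactly this question: automated candidate detection, stratified
sampling into review sets, patch-based presentation, fusion of categorical
ratings into gold-standard labels, and chance-corrected agreement
statistics.

# Image model and detection

## Forward model

Brightfield transmitted intensity follows the Beer–Lambert law per RGB
channel $c$:

$$ I_c = I_{0,c} \cdot 10^{-(c_H M_{H,c} + c_D M_{D,c})} + \varepsilon_{\text{noise}}, $$

where $M_H, M_D$ are unit optical-density (OD) vectors for hematoxylin and
DAB, $c_H, c_D$ the per-pixel stain concentrations, and $I_0$ the
blank-field intensity (255 per channel by default). The synthetic tile
generator (`generate_tile()`) uses this model directly; noise, when
enabled, is additive Gaussian on transmitted intensity, applied *after*
the exponential and clipped to $[0, I_0]$, matching the camera-noise
convention and keeping the OD inversion well defined.

The stain vectors are not something a pipeline should guess per image at
this scale; the defaults are the standard published H-DAB pair
(hematoxylin $(0.650, 0.704, 0.286)$, DAB $(0.268, 0.570, 0.776)$,
renormalized), configurable through `stain_model()`.

## Deconvolution

`rgb_to_od()` computes $OD_c = -\log_{10}((I_c + \epsilon)/I_{0,c})$,
clipped at 0. The offset $\epsilon$ exists to guard the logarithm for
quantized 8-bit counts and defaults to 1; on unquantized synthetic tiles
$\epsilon = 0$ makes the transform an exact inverse of the forward model,
which is how the round-trip tests verify deconvolution to $10^{-6}$
relative error. `deconvolve()` solves, per pixel, the least-squares
projection of the OD 3-vector onto the two stain vectors; the residual
direction orthogonal to both stains is discarded and negative solutions
are clipped to zero. Near-collinear stain pairs are rejected at
construction.

## Segmentation and grouping

DAB-positive pixels are `c_DAB >= threshold`. The study this design
follows does not print its threshold; the package default is a fixed
concentration threshold of 0.15 OD units — fixed thresholds are the
reproducible choice, and an Otsu mode (`threshold = "otsu"`) is available
when adaptivity is wanted. Whether the original thresholding operated in
OD-concentration or RGB space is likewise unstated; this implementation
commits to concentration space and exposes the value as configuration.

Positive pixels are grouped under **8-connectivity** (diagonal contact
joins objects — the more inclusive convention for few-pixel objects;
`EBImage::bwlabel()`'s 4-connected labels are merged across diagonal
adjacencies). Optional morphological closing with a disc of configurable
physical radius (default 0 µm = off, since no gap bridging is part of the
detection contract) can bridge 1–2 px gaps before grouping.

## Area filter and measurements

Objects with surface area in $[25, 5000]$ µm² are retained — both bounds
**inclusive**, one convention fixed and tested. Area is pixel count times
the pixel area ($0.24^2 = 0.0576$ µm² at the study's scanner resolution).
Centroids are unweighted binary-mask centroids ("center of mass" of the
candidate object, not intensity-weighted), reported in micrometres in a
frame with origin at the tile's top-left pixel corner and $x$ along
columns; pixel indices are 0-based.

# Sampling, patches, coordinate transfer

`stratify_sample()` splits the pool at 1000 µm²; the study describes the
strata as "<1000" and ">1000", leaving 1000 exactly unassigned — here it
belongs to the **large** stratum. Defaults are 1900 small + 300 large.
`split_groups()` partitions the sample uniformly into groups of exactly
the configured sizes (1500/1500 by default). Both are seeded, sample
without replacement, and never duplicate or drop an object.

`extract_patch()` crops a square of side 256 µm (the abstract-level figure;
"0.25 × 0.25 mm" elsewhere in the source design is treated as the same
quantity rounded) centered on the center of mass — the patch start index is
`round(com_px − side_px/2)`, which keeps the CoM within half a pixel of the
patch center for either side parity — padding out-of-tile regions with
background intensity. The marker is an outline-only square (never filled,
so the candidate stays visible), 2 px thick, of area 0.03 mm². That marker
area implies a side of √0.03 mm ≈ 173 µm, i.e. most of a 256 µm patch;
this is an internal inconsistency of the source design, and both values
are deliberately plain configuration defaults rather than something the
package silently "fixes".

`transfer_coordinates()` applies a supplied 2×3 µm→µm affine transform to
centroids (for tracing IHC candidates into co-registered restained H&E
images). No registration is performed; fidelity of the transform is the
caller's responsibility.

# Consensus under the 70% rule

`vote_threshold(n, f)` returns the smallest integer $t$ with $t/n \ge f$,
implemented with an explicit floating-point guard around the ceiling; at
$f = 0.7$ this reproduces 5-of-7 and 8-of-11. Fractions $\le 0.5$ are
rejected because uniqueness of the winning class requires a strict
majority — with $f > 0.5$, at most one class can reach the threshold
(pigeonhole; the tests verify this exhaustively over all vote triples up
to $n = 12$). Objects are tiered *uniform* (count $= n$), *majority*
(threshold reached, not unanimous) or *no agreement* (fused label `NONE`).
Incomplete panels are rejected rather than imputed: the study design
guarantees a constant rating count per object.

`per_rater_counts()` reports per-rater class counts with group means and
standard deviations; the sd is the **sample** sd ($n-1$ denominator, the
convention for small observer groups), with a population option, and a
single-rater group reports sd 0 with a degeneracy flag.

# Agreement statistics

`fleiss_kappa()` follows the textbook formula chain
($P_i$, $\bar P$, $p_j$, $\bar P_e$, $\kappa$); perfect agreement returns
exactly 1 even where the chance term saturates, and an all-one-class panel
— where the statistic is uninformative — returns 1 with a warning.
`cohen_kappa()` is the unweighted nominal statistic (no weighting scheme
applies to an unordered 3-class alphabet). Pairwise kappas between raters
who shared no objects are `NA`, not 0: absence of data is not agreement.

Landis–Koch bands are implemented as upper-inclusive half-open intervals,
poor $(-\infty, 0.20]$, fair $(0.20, 0.40]$, moderate $(0.40, 0.60]$,
good $(0.60, 0.80]$, very good $(0.80, 1]$ — the conventional verbal scale
is ambiguous at the boundaries, and this choice is consistent with group
kappas of 0.42 and 0.51 being read as moderate.

A note on scope: the raw per-observer ratings behind the published group
kappas are not public, so those exact values cannot be recomputed from
data. The package's correctness claims for the kappa statistics therefore
rest on independent-oracle tests (direct-formula and contingency-table
evaluations), exact recovery ($\kappa = 1$) under identity rater
confusions, and convergence to 0 under uninformative raters.

# The synthetic-data module

`generate_tile()` emulates: two-stain brightfield appearance via the
forward model above; a uniform hematoxylin counterstain background (0.3 OD
by default); keratin-positive objects as randomly oriented elliptical
blobs with uniform per-object DAB concentration (0.4–1.2 OD), spanning
four size classes — artifact 5–20 µm², bud 30–600 µm², PDC 1100–3000 µm²,
cluster 5500–6500 µm². The class ranges stay at least one pixel-area clear
of the 25/5000 µm² filter bounds so that every planted object's
in-range/out-of-range status is unambiguous after rasterization. Objects
are rasterized as the $N$ pixel centers with smallest rotated-ellipse
quadratic form, $N = \mathrm{round}(\text{area}/\text{px}^2)$, giving
exact pixel-count control (ground-truth area within half a pixel-area of
the request). Placement is rejection sampling, largest object first, with
a one-pixel clear halo (objects stay distinct 8-connected components) and
a bounded retry count (default 1000) that fails loudly.

What it does **not** emulate: nuclei (the human "visible nucleus" rule is
representable only as a latent class in the rating simulator, not as an
image feature), inflammation, tissue texture, stain gradients, scanner
artifacts, or H&E appearance (the H&E study arm is exercised purely at the
rating-panel level). Passing detection tests on these tiles therefore
demonstrates correctness of the deconvolution/segmentation/measurement
chain, not robustness to real-tissue confounders.

`generate_rating_panel()` draws a latent class per object from a
prevalence vector (default 45% TB / 5% PDC / 50% NEITHER, reflecting a
bud-enriched candidate stream where roughly half of candidates are
ultimately neither) and each rater's report from a per-rater 3×3
row-stochastic confusion matrix. Identity confusions give a panel where
every downstream consensus label equals the latent truth and both kappas
are exactly 1; uniform rows give chance-level agreement. All randomness in
the package flows from a single integer seed per call, with the caller's
RNG state untouched.

# Pipeline and interfaces

`run_pipeline()` chains simulate → detect → filter → sample → split →
patches → ratings → consensus → agreement into an artifact directory:
8-bit PNG tiles with 16-bit label TIFFs and ground-truth CSVs, candidate
and sample tables, patch PNGs with a manifest, panel/consensus/agreement
CSVs and a JSON-lines run manifest echoing the configuration and seeds.
Detection inside the pipeline reads the written 8-bit tiles back (with
$\epsilon = 1$), so running stages manually from the files on disk gives
identical results. Stage failures leave a `FAILURE` marker naming the
stage and preserve earlier outputs. In the simulated-ratings path the
latent class of a sampled candidate is set by its stratum (small = TB,
large = PDC), mirroring the strata's intended composition.

The exported functions and per-stage readers/writers *are* the tool's
interface; the package deliberately ships no shell wrapper, since every
stage is a one-line R call and the artifact directory layout is the
machine-facing contract. Category tokens are serialized as exactly `TB`,
`PDC`, `NEITHER`; parsers are strict (unknown tokens, duplicate ids and
ragged rows are errors with line numbers) rather than coercing.

# Numerical choices and problem sizes

Tolerances: deconvolution round trips are asserted to $10^{-6}$ relative
error; kappa implementations to $10^{-12}$ against independent oracles;
affine round trips to $10^{-9}$ µm. Chance-level kappa is asserted as
$|\kappa| < 0.05$ on panels of $10^4$ objects across 20 seeds, which is
comfortably above the Monte-Carlo sd at that size.

Test problem sizes are scaled to what the properties need, not to the
study's full scale: detection fidelity uses twenty 1024×1024 px tiles
(≈ 246 µm square at 0.24 µm/px, 12 planted objects each); consensus
reconstructions use the full 3000×7 and 150×11 vote-pattern panels (cheap,
since they are categorical); end-to-end pipeline tests use two 512 px
tiles with 11 sampled candidates and 64 µm patches. The study-scale
numbers (1900 + 300 samples, 1500/1500 groups, 256 µm patches) remain the
configuration defaults.

# Known limitations

* The DAB threshold, being unpublished, is a convention; real-slide use
  should calibrate it (or use the Otsu mode) per staining batch.
* The simulator's blobs are convex and uniformly stained; fragmented or
  halo-stained buds, overlapping objects, and pseudo-bud morphology are
  out of scope, so detector performance on real WSIs cannot be inferred
  from these tests.
* Kappa values carry no confidence intervals (none are part of the
  design this follows).
* The 800 externally contributed candidates of the original design enter
  only as a pass-through candidate list; their upstream detection is not
  modeled.
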