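---
title: "Measuring fibroblast-to-neuron conversion: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fibroblast-to-neuron conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`morphotrace` quantifies chemically induced conversion of mouse embryonic
fibroblasts (MEFs) into neuron-like cells from hourly live-cell movies,
and scores the accompanying epithelial–mesenchymal transition (EMT) in
expression data. This vignette is the package's account of the underlying
models: what is computed, under which assumptions, which knobs matter, and
where the design was genuinely open.

## The morphology model

A movie frame is a label image: every cell is a connected region with a
distinct positive integer (a matching nucleus label image is optional but
needed by two of the three class rules). Working from label images is a
deliberate scope decision — segmentation of light-field microscopy is a
separate, hard problem that typically needs manual correction, and none of
the quantities this package is about depend on how segmentation was
obtained. `detect_cells()` also accepts binary images and labels
8-connected components itself.

Per cell the package computes:

* **Gravity centre** — the unweighted mean of member pixel coordinates,
  0-based, in (row, col) order.
* **Perimeter** — the number of mask/background transitions over
  4-neighbour pairs. This estimator is simple, deterministic and
  consistent across scales (halving `perimeter/area` under 2× upscaling,
  which the tests assert); absolute values depend on the estimator
  convention, so only ratios of like quantities should be compared.
* **Length and width** — `4 * sqrt(eigenvalue)` of the pixel-coordinate
  covariance (ellipse-equivalent axes). A `+1/12` diagonal term accounts
  for the unit extent of a pixel; it makes a 3×30 bar measure exactly
  `L/W = 10` and keeps one-pixel-wide shapes at positive width. A
  single-pixel mask uses the convention length = width = 1.
* **Neurite count** — the mask is thinned to a one-pixel skeleton
  (Zhang–Suen), the soma is defined as the largest inscribed disc (centre
  and radius from the Euclidean distance transform), and a neurite is a
  skeleton endpoint whose along-skeleton distance from the soma exceeds
  `min_neurite_len` (default 5 px). The published rule ("neurite
  outgrowths around the cell body") does not specify a measurement
  procedure for light-field images; the skeleton-endpoint/inscribed-disc
  construction is this package's operational definition, chosen because it
  is parameter-light and exactly testable (a disc with *k* drawn rays
  measures *k*).
* **Nucleus-to-cytosol ratio** — `nucleus_area / (area − nucleus_area)`.

Classification applies three rules in fixed order with first match
winning — neuron-like (`L/W > 5` and ≥ 2 neurites), shrunken (small,
`L/W < 1.5`, `N:C > 1:5` i.e. 0.2), MEF-like (large, `N:C < 1:10` i.e.
0.1) — and everything else is unclassified. The ordering mirrors how the
rules are stated and keeps the classes disjoint. Missing nucleus features
simply disable the two rules that need them.

The "small"/"large" size thresholds have no published pixel values (no
µm/pixel scale is stated anywhere), so they are exposed as
`area_small`/`area_large` with defaults 400/800 px², calibrated once
against the synthetic archetype area distributions (shrunken ≈ 120 px²,
neuron-like ≈ 250–350 px², MEF-like ≈ 1200 px²) and recorded in the run
configuration. On data with a different magnification these two values are
the first thing to adjust.

## Tracking and lineages

Frame-to-frame linking is greedy mutual nearest neighbour on gravity-centre
distance within a gate (default 5× the largest per-frame step SD when the
generator configuration is known, else 50 px), with ties broken by
(distance, lower label) so results are independent of input order. This
matches the "closest cell" logic of manual tracing and is provably exact
when every displacement is less than half the minimum inter-cell distance;
a brute-force minimum-cost assignment over all permutations serves as the
test oracle on small frames.

Divisions are recognised two ways: an unmatched source cell with at least
two unmatched next-frame cells inside the division radius (default 2× the
mean major-axis length) splits to the two nearest; and — the geometry a
splitting region actually produces — an unmatched next-frame cell whose
nearest linked source has both it and its link target inside the division
radius upgrades that link to a division. Remaining unmatched source cells
are disappearances, split into `death` (no next-frame cell within the
gate) and `untraceable` (a candidate existed but was not linked); the
published procedure never defines "untraceable", so this operational
definition is ours. Unmatched next-frame cells are appearances and open
new lineage roots.

Migration follows the stated rule exactly: the distance between the cell
on hour *n* and hour *n + 1*; a divided cell uses the nearer daughter, an
untraceable cell uses the globally closest next-frame observation with an
`imputed` flag, and the last frame has no value (absent, not zero).

## Kinetics

* **Doubling time**: `Td = 24 / log2(N_{t+24} / N_t)`; undefined (NA) when
  the count does not grow. For a per-frame division probability *p* with
  negligible death, counts grow by `(1 + p)` per frame, so census growth
  and `Td` are two views of the same parameter — the parameter-recovery
  tests exploit this.
* **Days** are hours `[24 d, 24 (d + 1))`; frame 1 is hour 0, the moment
  induction medium replaced serum medium.
* **Conversion events**: a lineage branch converts when its class switches
  into the target and persists for ≥ `persistence` frames (default 3 —
  hourly frames make single-frame switches indistinguishable from
  classification flicker; a run cut off by the end of the movie counts).
  When both daughters of a division are born converted, the division
  itself is the event: one founder, both subtrees as descendants.
* **Mode**: high-mitosis when at least `mitosis_threshold` (default 1)
  divisions occurred in the 24 h preceding conversion — the operational
  reading of "immediately after one particular round of mitosis" — else
  low-mitosis. No numeric cutoff is published; the default is exposed in
  configuration.
* **Grid sampling** divides the field into k×k (default 5×5 = 25) equal
  rectangles and picks the cell nearest each rectangle's centre, ties to
  the lower label, empty rectangles contributing nothing. An exhaustive
  per-field search is the test oracle.

## Expression scores

All scores share one formula on log2 changes versus control:
`(Σ up − Σ down) / n`. The denominator counts the signature genes *used* —
genes absent from the data are excluded from numerator and denominator
alike, which is how "overall number of genes used for calculation" is read
here; a fixed-denominator mode (`denominator = "all"`) is provided because
the alternative reading cannot be ruled out. Scores are linear in the
changes, antisymmetric under swapping the up/down lists, and unchanged by
removing a gene whose change equals the score — all asserted as
properties.

The qPCR variant fixes the panel (up: Cdh2, Fn1, Slug, Zeb1; down: Epcam,
Ocln) and resolves aliases first (Snai2 is the official symbol of Slug).
The metabolism score contrasts oxidative-phosphorylation members
(KEGG00190) against glycolysis members (KEGG00010); the shipped GMT is a
curated ~20-gene subset of each pathway and is configuration, not code —
any GMT can be substituted. The 130-gene EMT signature itself is external
to this package; a structurally equivalent stand-in ships as
`emt_signature_synthetic.gmt` (the file name marks it synthetic) so the
machinery is fully exercised. Raw-count inputs are converted with a
pseudocount of 1 (`log2((x + 1) / (control + 1))`); no published
pseudocount exists, and 1 is the field's default.

## Meta-analysis

Each dataset's biological replicates are averaged on the linear scale,
divided by the mean of the control samples (all treatments of one dataset
share that single control mean), and log2-transformed; a dataset declared
as already log2-versus-control passes through untouched (idempotence is a
tested invariant). Datasets merge on official symbols after alias
resolution; genes missing from a dataset stay missing — never zero — and
every reported fraction carries its basis count. Duplicate symbols within
one dataset collapse by mean with a warning.

"Up-regulated" needs a threshold the source never states numerically; the
default is 1.5× (log2 change > 0.585), chosen because the Stat3 effect
this analysis targets is described as a low but universal 150–200%
up-regulation, and it is configurable. "Strongly induced EMT" is likewise
defined here as the top quartile of the per-column EMT score.

## The synthetic generators

The movie generator emulates a Cell Observer acquisition: hourly frames,
an initial MEF population, isotropic Gaussian random-walk motion with
reflecting boundaries, per-frame division and death probabilities per
archetype, and a conversion schedule assigning lineage fractions to
with-mitosis conversions (the converting cell divides; both daughters are
born converted) or without-mitosis conversions (in-place archetype
switch) inside a frame window. Rendered archetypes are verified against
their own class rules at draw time — parameters that cannot satisfy the
contract raise an error rather than silently emitting off-contract masks —
which is what closes the oracle loop: on noise-free renders the classifier
must recover the generator's archetype for every cell.

Placement uses a conservative bounding-circle test with a pixel-accurate
fallback inside contact-dense clusters; when even that finds no room for a
division's daughters, the division is postponed to a later frame — a
contact-inhibition behaviour that also means realised division rates fall
below the nominal probability in crowded fields. The parameter-recovery
analyses therefore use sparse configurations where the effect is
negligible. Marker positivity (the TuJ stand-in) flags exactly the cells
whose archetype is neuron-like at the final frame.

What the generator deliberately does **not** emulate: photorealistic
microscopy, phase-contrast artifacts, segmentation errors, touching-cell
merging, focus drift, or cells entering the field. Passing tests therefore
demonstrate the correctness of the measurement and tracking logic on
faithful label images, not robustness to segmentation noise on real
light-field data.

The compendium generator emulates a collection of EMT-induction
microarray datasets: each dataset carries an EMT strength *s* ~
Exponential(mean 1); up/down signature genes respond with log2 changes
Normal(±*a·s*, σ) (*a* = 1, σ = 0.3); Stat3 responds universally and
modestly, Normal(*b* = 0.8, σ_b = 0.2) independent of *s* (2^0.8 ≈ 1.74,
i.e. ~174%, inside the 150–200% band the analysis is designed around);
Sox2 and the neuron projection markers (Map1b, Reln, Robo1, Tubb3) respond
only above a strength threshold, Normal(*c*·max(0, *s* − *s₀*), σ_c) with
*c* = 1.2, *s₀* = 1.5. Raw linear intensities with replicate noise
(σ_rep = 0.05 log2 units, 3 replicates plus 3 controls) are emitted so the
meta-analysis module has real work to do. The closed-form Normal tail
(including replicate-noise variance `σ_rep²·(1/n_t + 1/n_c)`) is the
oracle for the Stat3 up-regulation fraction.

## Problem sizes and numerical choices

The shipped demo movie runs 48 hourly frames on a 1500×1500 px field from
110 initial MEFs, converting 25% of lineages with mitosis and 25% without
to neuron-like plus 15% to shrunken, reaching roughly 380 cells at the
final frame — large enough for stable percentages while a full
simulate-and-analyse cycle stays around two minutes on one CPU. Recovery
analyses use 220-cell fields; the compendium uses 30 datasets. These sizes
are the package's validation scale, chosen to make the whole suite cheap
to re-run.

Every stochastic step flows from one master seed through a documented
splitting scheme (`derive_seed()`: stream 1 for movies, stream 2 for
compendia), so identical configurations are bit-reproducible; output
tables carry the configuration hash and seed in a header comment. All
tie-breaks (linking, grid sampling, division daughter choice) resolve by
(distance, lower label). Degenerate inputs have defined behaviour: empty
frames yield empty observation tables, a one-pixel mask has length =
width = 1, doubling time without growth is absent rather than infinite,
and two empty sets overlap vacuously at 100% with a flag.

## Known limitations

* Classification quality on real data depends entirely on upstream
  segmentation, which is out of scope here.
* The tracker closes no gaps: a cell missing for one frame re-enters as a
  new lineage root. Long occlusions need manual correction, as in the
  original tracing workflow.
* `area_small`/`area_large` are calibrated to the synthetic archetype
  scale and must be re-set for real magnifications.
* The high/low-mitosis dichotomy depends on `mitosis_threshold` and the
  24 h window; published exemplars motivate but do not fix these values.
* Realised division rates fall below nominal probabilities in crowded
  fields (contact inhibition by construction); census-based estimates
  inherit this property of the simulation, not a defect of the estimator.
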