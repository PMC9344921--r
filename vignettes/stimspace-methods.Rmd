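---
title: "Methods: spot-level analysis of stimulation effects around cortical implants"
author: "stimspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spot-level analysis of stimulation effects around cortical implants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`stimspace` analyses Visium-style spatial transcriptomics of transverse rat
cortex sections that contain an implanted (and usually stimulated)
microelectrode tract, together with the IHC channels imaged on the same
section. The unit of measurement is the *spot*: a barcoded ~55 µm disc on a
hexagonal lattice (100 µm pitch) with a physical (x, y) position in
micrometres and a gene-count column. One capture area (one section) is a
`SpatialStimSample`, an S4 class extending `SummarizedExperiment`: the
`"counts"` assay holds the sparse gene × spot matrix, `colData` the spot
geometry and the tissue/artifact flags, and dedicated slots the optional
registered section image and the confidently-mapped read total.

Coordinates follow one convention everywhere: array indices 0-based,
physical micrometres with the origin at the capture-area top-left, physical
positions derived from pixel coordinates times the microns-per-pixel scale
factor. Image pixel `(r, c)` has its centre at `((c-1)/s, (r-1)/s)` µm. We
assume the section image is already registered to the spot frame, which is
how the on-disk dialect supplies it.

## The analysis chain

### Depth equalization (aggregation)

Capture areas are sequenced to different depths. Before any cross-sample
comparison, deeper samples are down-sampled to the shallowest sample's
confidently-mapped read total: sample *s* is thinned at rate
$r_s = \min_t(\text{mapped}_t)/\text{mapped}_s$, replacing each count by an
independent $\mathrm{Binomial}(c, r_s)$ draw. We thin UMI counts rather
than raw reads — read-level data are out of scope — which preserves the
defining properties (zeros stay zero, counts never increase, expected totals
equalize) and is the closest count-level analogue. For synthetic data the
mapped-read total is defined as the matrix grand total.

### Spot filtering

A spot enters a comparison iff it has tissue over it and is not under a
cryosectioning artifact (roll, fold, bubble). Artifact regions are supplied
as polygons in a sidecar table — the scriptable equivalent of manual GUI
curation — and a spot is flagged when its centre falls inside any polygon.
The filter is deterministic and idempotent.

### Size-factor normalization

The size factor of spot *i* is its total count divided by the mean total
over *the spots of the comparison at hand*:
$sf_i = T_i / \overline{T}$, and normalized counts are $c_{gi}/sf_i$. By
construction `mean(sf) == 1` (asserted to 1e-12 in tests). Size factors are
deliberately comparison-specific, not global, matching the definition of
the normalization they implement. Spots with zero total have no defined
size factor and are excluded with a warning rather than assigned zero.

One consequence worth knowing: with total-count size factors, a strongly
induced gene inflates the totals of the spots it occupies and thereby
deflates its own normalized fold change (a compositional effect). On
transcriptome-wide panels a single gene's induction is a negligible share
of any spot's total and the effect is immaterial; on toy panels of a few
dozen genes it is visible, which is why the package's test fixtures embed
planted genes in a null background of 20–60 genes.

### Differential expression

For two disjoint spot clusters A and B (each member passing the filter),
the log2 fold change of gene *g* is
$\mathrm{LFC}_g = \log_2\frac{\bar n_{gA} + c}{\bar n_{gB} + c}$ with
pseudocount $c = 1$ normalized count. The pseudocount keeps LFCs finite for
genes absent from one condition (e.g. an inflammatory chemokine that a
control section simply does not express); it also compresses fold changes
of genes whose means are well below 1, so whole-section LFCs of low-count
genes are conservative relative to pipelines that floor or skip the
pseudocount. Genes with zero counts in both clusters get LFC 0, p 1, and
are never called significant.

P-values come from a conditional negative-binomial exact test on the
cluster sums. With per-spot size factors $s_i$, the sum of cluster *g* is
modelled as NB with mean $q S_g$ (where $S_g = \sum_{i \in g} s_i$ and *q*
is the pooled per-unit-size expression) and effective dispersion
$\phi \sum s_i^2 / S_g^2$ — the exact second moment of a sum of independent
NB counts with common $\phi$. Conditional on the total, the two-sided
p-value sums the probabilities of all splits no more likely than the
observed one. With $\phi = 0$ and equal size factors this reduces to the
classical conditional-binomial two-sample Poisson test (10 vs 0 gives
$2 \cdot 2^{-10} \approx 0.00195$), which the tests assert against
`binom.test`. The original analyses were run in a point-and-click browser
whose test is undocumented; exact reproduction of those p-values is not a
goal, and a Welch t-test on log1p-normalized counts is exposed as a
cross-check (`test = "welch"`).

Dispersions are method-of-moments estimates on normalized counts, pooled
within clusters (residuals about each cluster mean, so a real expression
difference does not masquerade as dispersion), floored at zero and shrunk
toward the across-gene mean with weight 0.5. The strong shrinkage is the
point: per-gene moment estimates at 50–100 spots are noisy, and pulling
them halfway to the common value is what keeps the exact test calibrated
(null type-I ≈ 0.03–0.06 at α = 0.05 in the seeded simulations; KS distance
from uniform < 0.05 at 500 genes).

Significance uses the raw rule *p* < 0.05 ∧ |LFC| > 0.6 for fidelity with
the source analyses (whose threshold sentence contains an obvious sign typo
for the p-value; the volcano-plot context makes *p* < 0.05 the only
coherent reading). BH q-values are reported alongside for anyone who wants
rigor over fidelity. Genes averaging under one raw read per spot are
retained by default and flagged `low_count`: implant effects are spatially
confined, and dropping locally expressed genes would mask exactly the
signal of interest.

### Implant-site localization

Sections often lack the focal GFAP signal that traditionally marks a tract,
so the site is estimated from two pieces of evidence: the stereotaxic
insertion coordinate (e.g. 3.5 mm lateral of midline, mapped into the
section frame) as a prior, and prototypic device-response markers (default
Ccl3, Ccl4, Gfap). Within a 1.5 mm search disc around the prior, the site
is the centroid of spot centres weighted by each spot's *marker excess*:
summed normalized marker counts minus the section background (median plus
two MADs over included spots), floored at zero. How prior and marker
evidence should be combined was genuinely open; we chose excess-weighted
centroid with fallback because raw-count weights are biased — markers like
Gfap are expressed at baseline everywhere, and that baseline drags a raw
centroid toward the middle of the search disc rather than the implant.
Background subtraction removes the bias and makes the estimator
translation-equivariant (asserted exactly in tests). If the total excess
in the disc falls below a threshold — by default the 99th percentile of
the in-disc mass over 100 label-shuffled nulls, since no criterion for
marker "presence" exists — the marker evidence is deemed absent and the
prior is returned, flagged `prior_only`. With planted implants (amplitude
7, σ = 200 µm) at full 65 × 65 capture-area geometry the estimator lands
within one spot pitch (100 µm) of the truth in 20/20 seeded simulations;
on much smaller grids the search disc covers most of the section and the
shuffle null loses power, so tests run at the realistic geometry.

### Radial profiles

All radial statistics share one binning: half-open annuli
$[k w, (k+1) w)$ of distance from the site, distances measured spot-centre
(or pixel-centre, or nucleus-centroid) to site, bins 0-based. Empty bins
are reported as missing, never zero — a bin with no spots carries no
information, and zero would fake a depletion. Gene profiles default to
100 µm bins (configurable; the bin width used for the published expression
profiles is unstated, and 100 µm matches the neuronal-density convention).
The first bin at a 100 µm width contains at most one lattice spot, so
single-section peak estimates are noisy; shape-sensitive tests use 150 µm
bins (tract spot plus its six neighbours) or average replicate sections.

### IHC quantification

Nuclei are segmented by Gaussian smoothing (σ = 1 µm), Otsu thresholding,
connected components and an area filter (10–400 µm²) — the scripts behind
the original quantification are unpublished, so a standard deterministic
pipeline stands in, with every threshold a configurable, logged parameter.
Touching-nuclei watershed splitting is off by default (the synthetic
fixtures are non-overlapping). NeuN positivity applies a single global
per-section threshold (Otsu over per-nucleus mean intensities) to the mean
NeuN intensity within each nucleus mask. NeuN+ density per 100 µm annulus
is counted over the annulus area *on the pixel grid intersected with the
tissue mask* — not the analytic ring area — so annuli clipped by the
section edge are handled correctly; units are nuclei/mm². GFAP intensity
per 10 µm annulus is the mean over tissue pixels divided by the
whole-section tissue mean (the normalizer was unstated in the source; we
use the tissue-only mean and document it), so a constant image gives
exactly 1 everywhere and the pixel-weighted profile mean is 1 by
construction.

### Enrichment

Over-representation of a significant-gene list against GMT collections uses
the hypergeometric upper tail over the universe of genes measured in the
comparison (not the whole annotation — the DE list can only contain
measured genes). The ranked-list minimum-hypergeometric algorithm of
GO-browser tools is intentionally not reimplemented; fixed-threshold ORA on
the significant list is the scriptable equivalent and is labelled as such.
The `enriched` flag uses BH q < α. Per-spot module means
(`moduleMeanExpression`) feed the same radial profiling to map an enriched
process spatially.

### Stimulation safety arithmetic

Charge per phase $Q = I t$ (µA × µs → nC), charge density $D = Q/A$ over
the *geometric* electrode area (nC/µm² × 100 = mC/cm²), Shannon
$k = \log_{10} D_{\mu C/cm^2} + \log_{10} Q_{\mu C}$, with strict
inequalities at both classification boundaries (exactly 4 nC is not above
the 4 nC rule). Geometric rather than electrochemically effective area
matches how the device areas are quoted; the k limit defaults to 1.85 (the
common literature value) and is configurable because the framework is cited
without fixing k. Device presets: a 50 µm PtIr microwire at its stated
round 2000 µm², and a 6.8 µm carbon-fiber cone with 140 µm exposed
(lateral area ≈ 1496 µm²). The acute protocol's quoted charge density
implies an effective area near 1440 µm² while the text says ≈ 1500 µm²;
both are accepted via `explicit_area`, and the discrepancy is left
unresolved on purpose.

## The synthetic generator: what it emulates, and what it does not

The generator reproduces the *structure* of the deposited study data:
~6.5 × 6.5 mm capture areas (65 × 65 spots at 100 µm pitch, bounding box
6.45 × 5.54 mm), library-size variation across spots (log-normal,
σ = 0.35), unequal depth across samples, an implant site with radially
decaying induction of inflammatory genes (Ccl3, Ccl4, Gfap, Cxcl13, C3)
and local depletion of the neuron marker Rbfox3. Effects are Gaussian in
distance, $f(d) = 1 \pm A e^{-d^2/2\sigma^2}$, with σ defaulting to
300 µm so that profiles flatten by roughly 700 µm — the distance at which
reactive-astrocyte expression was observed to plateau; no quantitative
decay lengths were published, so this calibration is loose and qualitative.
Counts are NB with per-gene dispersion (variance $\mu + \phi\mu^2$),
default φ around 0.1–0.3. The paired image generator plants Poisson
nuclei (thinned near the implant for neurons), renders them as Gaussian
blobs, and lays an exponentially decaying GFAP field with additive noise;
ground-truth centroids, labels, library sizes, kernels and the implant
position are always emitted alongside.

What it does **not** emulate: cell-level structure, tissue morphology,
layer anatomy, section-shape irregularity, image registration error, or
any read-level process. Passing tests therefore demonstrate that the
pipeline recovers known spatial-expression and image structure under
realistic count noise — not that it is robust to every failure mode of
real slides (registration drift and segmentation of dense, overlapping
nuclei being the obvious gaps).

## Numerical and design notes

- Determinism: every stochastic operation takes an explicit seed;
  identical config + seed gives bit-identical counts, images and ground
  truth. The pipeline driver expands one global seed into per-stage seeds
  (`seed * 1000 + stage index`) so stages are independently reproducible.
- The exact test enumerates the conditional distribution over the total;
  computations are in log space and the observed-probability comparison
  uses a 1e-8 relative slack to absorb rounding ties.
- Zero-total spots, empty bins, blank images, empty gene lists and empty
  matrices are all defined, tested cases (excluded-with-warning, missing,
  empty set, error, header-only files respectively).
- Problem sizes in tests and the acceptance script — 25–65 grids, 500-gene
  null panels, 400 µm benchmark images, 10–20 seeded replicates — were
  chosen as the smallest sizes at which the statistical properties under
  test are stable.
- Known limitations: the pseudocount compresses whole-section LFCs of
  low-expression genes relative to the published magnitudes; p-values are
  not expected to match the original GUI tool numerically; localization
  assumes a single implant per section; no spatial autocorrelation is
  modelled in DE (spots are treated as independent replicates within
  clusters, as in the source analyses).
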