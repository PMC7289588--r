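---
title: "Methods: single-cell SIP quantification from NanoSIMS ion images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell SIP quantification from NanoSIMS ion images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosip)
```

## The measurement model

NanoSIMS rasters a Cs⁺ primary beam over the sample and counts secondary
ions per pixel per plane. For stable-isotope probing of a biofilm fed
H¹³CO₃⁻ and ¹⁵N-labeled nitrogen sources, six channels are detected
simultaneously: ¹⁶O⁻, the dicarbon pair ¹²C¹²C⁻/¹²C¹³C⁻, the cyanide pair
¹²C¹⁴N⁻/¹²C¹⁵N⁻, and ³¹P⁻. Counts are Poisson to good approximation; we sum
all planes before any ratio is formed, because a ratio of sums is the
maximum-likelihood estimate under Poisson statistics whereas a mean of
per-plane ratios is biased (the package asserts the distinction on a
two-plane counterexample in its tests).

Enrichment is reported in delta notation,
$\delta = (R_{sample}/R_{standard} - 1) \times 1000$‰, against VPDB
($R = 0.0112372$) for carbon and AIR ($R = 0.003676$) for nitrogen.

**The C₂⁻ pairing factor.** If carbon atoms pair randomly into dicarbon
ions at atom fraction $x$, the isotopologue proportions are
$(1-x)^2 : 2x(1-x) : x^2$, so the observable count ratio
¹²C¹³C⁻/¹²C¹²C⁻ has expectation $2x/(1-x)$ — twice the atom ratio. The
default conversion therefore halves the count ratio
(`c2_correction = "half"`), which is exact under random pairing with the
doubly-heavy ¹³C¹³C⁻ neglected. Because conventions differ between
laboratories, `c2_correction = "none"` is available; reports record which
ran. The neglected isotopologue is second order: its share of dicarbon
pairs is $x^2$, under 1% up to $x = 0.02$ and about 0.5% at the most
enriched default class in this package ($x \approx 0.068$). The CN⁻ pair
carries a single nitrogen, so ¹²C¹⁵N⁻/¹²C¹⁴N⁻ estimates ¹⁵N/¹⁴N directly.

**Validity masking.** A pixel's delta is only as good as its denominator
counts: the Poisson relative SE of the ratio is roughly
$1/\sqrt{n_{heavy}}$ + $1/\sqrt{n_{light}}$ in quadrature. The default
`min_counts = 100` on the denominator isotopologue keeps the single-pixel
delta SE near or below ~100‰ at natural abundance; pixels below it are
flagged invalid and excluded from every downstream statistic rather than
imputed.

## Segmentation

The class masks derive from the ¹⁶O, ¹²C¹⁴N and ³¹P channels only — not
from the enrichment maps, so segmentation never sees the quantity being
compared between classes. Each channel is `log1p`-transformed (admitting
zero counts) and thresholded. The automatic threshold maximizes
between-class variance over 256 candidates on the log histogram; manual
values are accepted and echoed into provenance, since published workflows
often threshold by eye with unpublished values but reproducible tests need
automation.

The default boolean recipe treats the cyanide mask as biomass, splits it by
the phosphate mask (cyanobacterial filaments carry polyphosphate-rich
granules and a higher ³¹P background than the small heterotrophs), and
calls everything outside both the cyanide and oxygen masks background:

* autotroph = cn ∧ p
* heterotroph = cn ∧ ¬p
* background = ¬(cn ∨ o)
* phosphate_high = p ∧ ¬cn

This recipe is a documented assumption, not a claim about any particular
instrument session; it is a plain expression string the user can override,
and whatever ran is stored in the output provenance. The phosphate_high
region is excluded from all per-cell and population statistics.

Cleanup is a binary opening followed by removal of small components.
Connectivity is 8-connected throughout, and the opening uses a square
(Chebyshev-ball) structuring element of the given radius: consistent with
8-connectivity, idempotent, and exactly shape-preserving on axis-aligned
rectangles, which makes its contract easy to state and test. Components
below `min_object_px` (default 10 px, well under the ~50 px of a default
coccus) are discarded.

**Overlap exclusion.** Heterotrophs sitting on top of a filament measure a
mixed voxel column and are not analyzable; cells attached to a filament's
side are. Each 8-connected heterotroph component whose pixel overlap with
the autotroph mask exceeds `overlap_fraction_cutoff` (default 0.5) is
deleted; kept components donate their overlapping pixels back to the
autotroph mask. The three boundary behaviors (fully covered → deleted,
touching with zero overlap → kept intact, partial overlap below cutoff →
kept minus overlap) are asserted in the tests.

**Per-filament records.** Filaments are deliberately labeled as single
components: the biological unit of the autotroph here is the filament, not
the individual trichome cell, and nothing in the ion images delimits cell
septa reliably.

## Statistics

Population summaries report arithmetic mean ± sample SD (n−1) with
histograms (default 50 bins), per pixel or per cell; per-cell deltas are
ratios of summed counts over the cell, so large cells are not averages of
noisy pixel deltas. The two-population comparison defaults to the unpaired
Wilcoxon rank-sum test: pixel or cell populations from different classes or
images are unpaired, so the paired signed-rank variant — which is offered
behind `variant = "signed_rank"` for genuinely paired designs — cannot
apply to them as a default. Reports state which variant ran. P values are
exact by enumeration for combined n ≤ 25 without ties and otherwise use the
normal approximation with tie correction; values below 10⁻³ are formatted
as "p < 1e-3", never as a literal zero. Confidence ellipses scale the
sample covariance eigendecomposition by the 0.95 chi-square quantile with
2 df (semi-axis $\sqrt{5.9915\,\lambda_i}$); collinear point sets are an
error rather than a degenerate ellipse.

## Rendering

Rendering is pure: identical inputs produce byte-identical PNGs. Intensity
bounds are either fixed (e.g. −200 to 9000‰ for a δ¹³C panel) or
percentile-based; "bottom 5% and upper 95%" is implemented as winsorizing
at the 5th/95th percentiles of the valid pixels — the only self-consistent
reading — using the linear-interpolation percentile definition. Colors come
from the cividis colormap; background is black. Foreground pixels within 2
pixels (Euclidean distance) of background fade toward black by scaling
perceptual lightness J′ in CAM02-UCS by $d/(band+1)$, linearly in distance
(the interpolation curve is otherwise unconstrained; linear is assumed and
recorded), leaving the chroma coordinates untouched. The CIECAM02 model and
its UCS transform are implemented in full (sRGB viewing conditions: D65
white, average surround, background luminance factor 20) and verified
against the standard published worked examples; out-of-gamut results after
fading are clipped to [0, 1].

## Bulk assays

**IRMS two-point calibration.** Standards of assigned δ −26.39‰ (USGS 40)
and +37.63‰ (USGS 41) anchor an affine map from measured to assigned delta,
fitted through the two anchor means and exact at them. Standards that
directly follow a highly labeled sample are screened for carryover: one is
flagged when it deviates from the mean of its anchor's clean standards by
more than `tolerance` (default 2‰ — no published value exists, and 2‰ is
far beyond instrument precision yet far below real carryover from
thousands-of-permil samples). A lone post-label standard with no clean
groupmates is compared against its assigned value directly, which assumes
measurements are already near the assigned scale. Flagged standards are
excluded from the fit but always reported. Correction is per run; nitrogen
calibration reuses the same machinery with AIR-referenced anchors.

**qPCR.** Cq is fitted against log₁₀(copies) over the standard series
(3×10¹ … 3×10⁶ copies), averaging technical triplicates per level before
fitting — the aggregation level is not dictated by the assay design, and
level means keep the fit balanced. Efficiency is $10^{-1/slope} - 1$
(perfect doubling: slope −3.3219, efficiency 1.00); quantification inverts
the fit. Relative abundances normalize genome copies within each replicate;
Welch's unequal-variance t test compares members across two conditions when
both have ≥ 2 replicates.

**Peptides.** A protein's peptide count is divided by the total peptide
count of its organism in that sample, removing organism-abundance
differences from protein-level comparisons; organisms with zero totals get
flagged-missing fractions, and each organism's share of community-wide
counts is reported alongside.

## The synthetic-scene generator

The generator is first-class, tested code: it draws filaments as
constant-width tubes along smooth random spline curves spanning a
256 × 256 px field (40 µm, 13 planes by default — the standard acquisition
geometry), places coccoid heterotrophs half side-attached and half distal,
embeds phosphate granules inside filaments, and renders Poisson counts per
plane with the isotopologue splits described above. Class enrichment
defaults come from the published population statistics for the two labeling
regimes where such values exist (heterotrophs: δ¹³C 1328.39‰ / δ¹⁵N
1814.13‰ under NO₃⁻-only; δ¹³C 121.38‰ / δ¹⁵N 6351.97‰ under NH₄⁺
amendment); autotroph deltas are not published, so the defaults (3000/9000‰
and 5500/16000‰) encode the qualitative finding that autotrophs co-enrich
under both regimes and more strongly with NH₄⁺. Channel count rates are
invented — no per-class instrument rates are published — and are chosen so
biomass cyanide signal exceeds background by well over 10×, making
thresholding well-posed; they are labeled as synthetic defaults wherever
they appear. Randomness is split into one stream per operation (seeded from
the scene seed plus an operation tag), so adding cocci does not perturb the
filament draw.

What the generator does **not** emulate: detector dead time and
quasi-simultaneous-arrival effects, beam drift and plane misalignment
(no alignment is performed — real drifting stacks should be registered
upstream), instrumental mass fractionation, topography, and continuous
intra-cell enrichment gradients. Passing recovery tests therefore shows the
estimator chain is correct and unbiased at realistic count levels, not that
instrument systematics are handled.

## Numerical and testing choices

Counts are stored as exact integers in doubles (sufficient below 2⁵³);
deltas and ratios are double precision. TIFF interchange stores counts
scaled by their recorded maximum with a JSON sidecar, giving bit-exact
round trips. Degenerate inputs have defined behavior: constant images are
an error for automatic thresholding (with a pointer to manual mode) and map
to zero after normalization; a single-value population reports SD 0 with an
explicit flag; empty populations are errors naming the class and basis.

Test problem sizes are chosen for tight statistical power at desk scale:
full-geometry 256 × 256 scenes for the recovery and segmentation
guarantees (recovered class means within 3 SE of the configured deltas;
Jaccard ≥ 0.8 per class; exact cell counts for non-touching cocci), 1000
null simulations for the rank test's type-I error (0.05 ± 0.02), and 10⁴
bivariate normal points for ellipse coverage (0.95 ± 0.01). Smaller 96 × 96
scenes back the per-module tests.

## Known limitations

Filament-level (not trichome-cell) autotroph records; no 3-D
reconstruction across planes; no machine-learned segmentation; the default
boolean recipe presumes the ³¹P channel separates autotrophs, which should
be re-examined on instruments or organisms where it may not; Cameca's
proprietary .im format is not read — stacks must arrive as TIFF + JSON or
be generated synthetically.
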