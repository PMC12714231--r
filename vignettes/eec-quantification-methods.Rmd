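---
title: "Methods: quantifying enteroendocrine cells and mapping their peptides"
author: "eecquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying enteroendocrine cells and mapping their peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eecquant)
```

## The problem

Enteroendocrine cells (EECs) are hormone-secreting epithelial cells
scattered along the intestine. In larval zebrafish they are imaged with
fluorescent reporters (e.g., *neurod1* and *neurog3* drivers), and
questions about lineage and ablation phenotypes reduce to counting
labeled cells per fish, classifying them by reporter co-expression, and
asking where along the gut they sit. On the peptidomic side, the hormones
these cells secrete are processed from prohormone precursors, and mapping
identified peptides back onto precursors shows which products are
actually made. This package implements both quantification pipelines and
a synthetic-data module that generates inputs with known ground truth, so
every stage can be validated exactly.

## Automated counting

Counting works on maximum-intensity projections. `maxProject()` collapses
the z dimension per pixel and channel. For dual-reporter images,
`compositeChannels()` rescales each channel to [0, 1] by its own maximum
and takes the per-pixel maximum, so objects visible in either channel are
segmented once and their per-channel intensities extracted afterwards.

`segmentObjects()` binarizes at a threshold and labels connected
components with **8-connectivity** — the ImageJ particle-analysis
default, which this pipeline mirrors — discarding components below a
minimum object size of 10 px². The default threshold is Otsu's method on
the image histogram; the exact automated threshold used in practice by
ImageJ varies by variant, so a fixed absolute threshold can be supplied
for sensitivity analysis. Coordinates are 0-based (row, col) with pixel
centers at integers. Holes inside components are not filled, and no
watershed splitting is attempted: merged objects are corrected by
weighting, not splitting.

### The median-area weighting rule

Touching cells merge into single segmented objects and would be
undercounted. `assignWeights()` corrects this with the median object
area $m$ of the image:

$$w_i = \max\!\left(1,\ \mathrm{round}\!\left(\frac{a_i}{m}\right)\right)$$

so an object about twice the median area counts as two cells, three
times as three, and so on. Midpoints round half up (2.5× the median
counts as 3); R's default banker's rounding is deliberately not used,
because "twice as large" reads most naturally as a nearest-integer rule
with ties going up. `weightedTotal()` sums the weights into the image's
cell count. The rule is idempotent and, on clean synthetic scenes with
equal-area cells, recovers cluster multiplicities exactly.

### Dual-channel classification

For objects detected on the composite, `classifyDual()` computes the
mean-intensity ratio $r = \bar{I}_A / \bar{I}_B$ and assigns:

* $r > 2$: A-positive only,
* $r < 0.5$: B-positive only,
* $0.5 \le r \le 2$: double positive.

The boundaries are **inclusive** for the double class: the defining
conditions for the single-positive classes are strict inequalities,
which leaves the closed interval to the double class. A zero denominator
with positive numerator maps to $r = +\infty$ (A-only), the limiting
behavior of the rule; an object with zero signal in both channels cannot
exist above threshold and raises an error. Mean rather than integrated
intensity is used (integrated intensity would multiply both channels by
the same area and give identical ratios for uniform objects, but mean is
the configurable default). Labels are invariant under common rescaling
of both channels, and each object carries its full weight into its
single class, so class totals always partition the weighted total.

## The gut axis

Each image carries two manually placed markers, the gut start and end.
`normalizePosition()` maps a cell to

$$s = \mathrm{clamp}_{[0,1]}\
\frac{(p - \mathrm{start}) \cdot (\mathrm{end} - \mathrm{start})}
     {\lVert \mathrm{end} - \mathrm{start} \rVert^2},$$

the scalar projection onto the start–end chord as a fraction of chord
length. Only two markers are recorded, so arc length along a curved
midline is unrecoverable; the chord is an approximation that is good for
the near-straight larval gut, and the synthetic generator's curved-path
option quantifies the error it introduces. A pure x-coordinate
normalization is available via `method = "x"`. The coordinate $s$ is
invariant to rigid transformations and to displacement perpendicular to
the chord.

`assignBins()` divides [0, 1] into $n$ even bins, left-closed with the
last bin closed at 1; $n = 4$ gives the gut quarters qrt1–qrt4
(1-based, proximal to distal) and $n = 100$ the percentile bins used for
density profiles. Weights are respected, so quarter counts and
percentile counts each sum to the weighted total. `smoothDensity()`
applies a Gaussian kernel (default bandwidth 3 bins, reflected at the
edges, rescaled to conserve the total) for visualization only; it never
feeds the statistics, and the bandwidth is a cosmetic default.
`excludeRegion()` drops a quarter — in practice qrt4, where ablation is
inefficient — before totals are recomputed.

## Group statistics

`unpairedTTest()` is Student's pooled-variance two-sample t test,
two-sided. "Unpaired t test" in the source workflow (GraphPad Prism)
defaults to the pooled-variance form, so that is the default here, with
Welch's correction available. The degenerate all-constant case reports
$t = 0, p = 1$ by convention.

`twoWayANOVA()` fits `count ~ group * quarter` by least squares. For
balanced tables the decomposition
$SS_\text{total} = SS_\text{group} + SS_\text{quarter} +
SS_\text{interaction} + SS_\text{error}$ is exact (verified to 1e-9
against an independent cell-means oracle in the tests). Real cohorts are
rarely perfectly balanced; unbalanced tables use Type-II sums of squares
by default, with Type III available, since which of the two Prism used
is not determinable — both are exposed and the choice is documented per
result. A saturated fit (zero residual variance) reports degenerate F
statistics explicitly rather than failing.

`tukeyHSD()` compares factor levels pairwise with studentized-range
p-values using the ANOVA's MSE and residual df; with two levels it
reproduces the F-test p exactly ($q^2 = F$). `starAnnotation()` maps
p-values to the usual star convention (ns, \*, \*\*, \*\*\*, \*\*\*\*
at 0.05, 0.01, 0.001, 0.0001); the convention's strict inequalities
leave boundary values unassigned, and they are mapped to the less
significant label.

## The peptide atlas

`locatePeptide()` places an identified peptide on a precursor by
substring search (all overlapping occurrences, left to right), extended
by single-missense-variant images of the precursor: each observed
variant is substituted one at a time and hits spanning the variant
position are annotated with it. Multi-variant combinations are not
attempted — this matches how variant peptide databases are built and
keeps matching tractable.

`peptideMass()` computes monoisotopic masses from a bundled residue
table plus one water, with modification deltas keyed by Unimod-style
names covering the search parameters used for the identifications:
carbamidomethyl (fixed, Cys), oxidation (Met), C-terminal amidation,
N-terminal acetylation and pyroglutamate (from Gln or Glu, modeled as a
delta on residue 1 and restricted to those residues), and the
octanoyl/decanoyl acylations from the dedicated ghrelin search. Numeric
deltas are accepted for anything outside that set. `ppmMatch()`
implements the relative mass criterion
$|m_\text{obs} - m_\text{theo}| / m_\text{theo} \le$ 10 ppm (the MS1
tolerance of the searches), symmetric in its arguments to well below
that tolerance and monotone in it.

`findDibasicSites()` reports every adjacent K/R pair (KK, KR, RK, RR),
overlaps allowed — the canonical prohormone convertase motif.
`buildAtlas()` aggregates aligned peptides into per-residue coverage
depth, junction positions (a peptide ending at $p$ with another starting
at $p+1$: abutting peptides sharing one boundary), dibasic sites, and
per-peptide overlaps with annotated functional regions. Protein
coordinates are 1-based inclusive throughout, in contrast to the 0-based
pixel convention; each side documents its own convention and they never
mix.

## The synthetic-data module

The generator produces the three kinds of input the pipeline consumes.
Its defaults are fixed study-scale conditions, not tuning knobs.

**Images.** Cells are Gaussian discs: amplitude × $\exp(-d^2/2\sigma^2)$
truncated at $3\sigma$, with the nominal cell radius at the $1/e^2$
intensity level ($\sigma = r/2$, the Gaussian-beam convention) and the
point-spread blur added in quadrature. Overlapping cells add, as
fluorescence does. Cells sharing a cluster id are chained at
center-to-center spacing 1.2 × radius, which merges them into one
connected component at realistic thresholds — the deterministic exercise
of the weighting rule. Cell centers sit at a requested arc-length
fraction along a configurable gut midline polyline, jittered
perpendicular by at most one radius, giving exact ground truth for
position recovery. Default intensities are background 0.05, amplitude
0.8, noise SD 0.01 on a [0, 1] scale with radius 6 px on a 256–512 px
image: the per-image intensity distribution of the real data is not
published, so these are synthetic conveniences chosen to resemble a
clean confocal projection, and nothing downstream depends on their exact
values. Rendering is a pure function of the spec including its seed.

**Counts.** `simulateCounts()` draws per-fish, per-quarter counts from a
negative binomial (variance $\mu + \phi\mu^2$, Poisson at $\phi = 0$)
with ablated-group means multiplied by $1 - \text{effect}$. Defaults — 15
fish per group, control mean 30 cells per quarter (120 per fish), mild
overdispersion $\phi = 0.05$ — match the scale of the larval ablation
cohorts, and the effect sizes of interest are the 30–50% reductions the
ablation comparisons are designed around.

**Peptides.** `simulatePeptides()` draws true substrings of a precursor
with termini sampled from cleavage-point weights that strongly favor
points adjacent to dibasic sites (default weight 50 versus 1, with
protein termini at 5), reflecting the dominance of convertase processing
in real prohormone peptidomics. The first terminus is drawn from the
marginal weights and the second conditionally among spans of allowed
length (default 2–30 residues — the lower bound admits the excised
basic-pair dipeptide, a legitimate processing product in no-enzyme
searches). Modifications are sampled from the supported set with fixed
carbamidomethyl on Cys.

**What passing tests show and what they do not.** The synthetic images
are noise-controlled, hole-free Gaussian blobs on a uniform background;
they exercise the threshold/size-filter/weighting logic exactly but do
not emulate autofluorescent gut structures, uneven illumination, or the
intensity heterogeneity that pushed parts of the real data to manual
counting. Exact count recovery on these images validates the
arithmetic of the pipeline, not the segmentability of any particular
real image. Similarly the count simulator validates the statistical
machinery (type-I error, power, effect recovery) under a clean
negative-binomial model, not the biological variance structure of real
cohorts.

## Numerical and design choices

* Area/median rounding: round-half-up, floor 1 (see above).
* Ratio boundaries 2 and 0.5: inclusive into "double".
* Zero-denominator ratios: $+\infty$, hence A-only.
* Bin edges: left-closed, last bin closed at 1; 1-based labels.
* Star boundaries: mapped to the less significant label.
* Otsu is computed on a 256-level histogram of the min–max-normalized
  image; thresholding is strict (`> t`).
* Unbalanced ANOVA: Type II default, Type III available.
* Pixel coordinates 0-based; protein coordinates 1-based inclusive.
* All generators save and restore the caller's RNG state.

## Problem sizes used in the checks

The bundled tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is sharp: 20 images of 100
well-separated cells (512²) for exact count recovery; 10 clustered
scenes for merge correction; 200 simulated cohorts at the 50% and 30%
effect sizes and 2000 null cohorts for power, effect recovery and type-I
error; 10 random balanced designs for the ANOVA identity; 200 random
modified peptides against an elemental-composition mass oracle; 100
simulated peptide sets against interval-stabbing and pair-scan oracles.

## Known limitations

* The chord-projection gut axis underestimates arc length on strongly
  curved guts; only the two manual markers are available.
* The weighting rule assumes roughly equal cell sizes within an image;
  strongly size-heterogeneous populations would bias the median anchor.
* The exact ImageJ auto-threshold variant is not reproduced; Otsu is a
  close stand-in and a fixed threshold override exists.
* The atlas deduplicates on (sequence, span, modifications); whether
  per-gene tallies should merge identical sequences with different
  modifications is left to the caller, and both views are retained.
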