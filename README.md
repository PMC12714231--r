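# eecquant

Quantification of enteroendocrine cells (EECs) in fluorescence images of
the larval zebrafish intestine, and construction of peptide-to-prohormone
atlases from peptidomic identifications.

EECs are hormone-secreting cells scattered along the gut. Experiments that
ablate or perturb them reduce to a few quantitative questions: how many
reporter-positive cells does each fish have, which reporters do they
co-express, where along the gut do they sit, and — on the peptidomics
side — which processed peptides does each prohormone precursor actually
yield? `eecquant` implements the full analysis chain for these questions,
plus a synthetic-data module that generates images, count tables and
peptide sets with exact ground truth so the chain can be validated end to
end without microscope or mass-spectrometry data.

## The methods at its core

**Weighted automated counting.** Cells are detected on maximum-intensity
projections by thresholding (Otsu by default) and 8-connected particle
analysis with a minimum object size of 10 px². Touching cells merge into
single objects, so each object is assigned a multiplicity from the median
object area *m* of its image:

    w = max(1, round(area / m))        (midpoints round half-up)

and the cell count of an image is Σw. Dual-reporter objects are
classified by their mean-intensity ratio r = A/B: r > 2 → A-only,
r < 0.5 → B-only, 0.5 ≤ r ≤ 2 → double positive.

**Gut-axis registration.** Each cell position is projected onto the chord
between the manually marked gut start and end, giving a normalized
coordinate s ∈ [0, 1], then binned into 4 quarters (qrt1–qrt4) or 100
percentile bins. Quarter and percentile counts conserve the weighted
total; qrt4 can be excluded where ablation is inefficient.

**Group statistics.** Unpaired (pooled-variance) t tests on per-fish
totals; two-way group × quarter ANOVA (Type-II SS for unbalanced cohorts)
with Tukey's multiple comparisons; significance stars at the usual
0.05/0.01/0.001/0.0001 boundaries.

**Peptide atlas.** Identified peptides are located on precursors by
substring search extended with single-missense-variant substitutions;
monoisotopic masses are computed from a bundled residue/modification
table (carbamidomethyl, oxidation, amidation, acetyl, pyroglutamate,
octanoyl/decanoyl) and matched at ppm tolerance; dibasic (K/R pair)
cleavage sites, per-residue coverage and abutting-peptide junctions are
annotated per precursor.

See the methods vignette
(`vignettes/eec-quantification-methods.Rmd`) for the models, conventions
and design choices in full.

## Worked example

```r
library(eecquant)

## a synthetic image: 6 single cells, one 2-cell and one 3-cell cluster
spec <- simImageSpec(clusterScene(), noiseSd = 0, seed = 42)
res  <- renderImage(spec)
obj  <- detectCells(res)          # composite -> segment -> weight
obj[, c("object_id", "area", "weight")]
#>   object_id area weight
#> 1         1   65      1
#> ...
#> 7         7  133      2
#> 8         8  200      3
weightedTotal(obj)
#> [1] 11
```

Eight segmented objects, but the two clusters carry weights 2 and 3 from
the median-area rule, recovering the true 11 cells. Classification and
gut-axis binning:

```r
classTotals(classifyDual(obj))
#> A_only B_only double
#>      0      0     11
loc <- localizeCells(obj, gutFrame(spec@gutStart, spec@gutEnd))
binPositions(loc$s, 4, loc$weight)     # cells per gut quarter
#> [1] 3 2 3 3
```

A simulated ablation cohort (15 fish/group, control mean 120 cells/fish,
50% reduction) analyzed exactly like a real one:

```r
tab <- simulateCounts(simCohortSpec(groupMeans = 30, effect = 0.5,
                                    seed = 42))
tot <- fishTotals(tab)
unpairedTTest(tot$total[tot$group == "control"],
              tot$total[tot$group == "ablated"])
#>                  test statistic df   p_value stars mean_x mean_y reduction_pct
#> 1 unpaired t (pooled)     12.61 28 4.593e-13  ****  118.5     55          53.6
twoWayANOVA(tab)
#>          effect  df  sum_sq  mean_sq statistic   p_value stars
#> 1         group   1 7568.41 7568.408  174.8285 1.291e-24  ****
#> 2       quarter   3   21.96    7.319    0.1691 9.171e-01    ns
#> 3 group:quarter   3   90.69   30.231    0.6983 5.550e-01    ns
#> 4     Residuals 112 4848.53   43.290        NA        NA  <NA>
```

The t test detects the ablation (p ≈ 5e-13) and estimates a 53.6%
reduction; the ANOVA attributes the variance to the group effect with no
regional interaction, as simulated. A peptide atlas from simulated
identifications:

```r
pre  <- precursor("ghrl_like", "MGSSFLSPSQKPQGKRRSLLDMDDLIEKRQAEHNTQ",
                  regions = data.frame(name = "functional",
                                       start = 18, end = 28))
atl  <- buildAtlas(pre, simulatePeptides(pre, 40, seed = 42))
atl
#> PrecursorAtlas ghrl_like - 36 aa
#>   40 peptide hit(s); 34/36 residues covered (94.4%), max depth 25
#>   5 abutting-peptide junction(s); 3 dibasic site(s)
peptideMass("SLLDMDDLIEK", "5|oxidation")
#> [1] 1306.633
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/eecquant.R` (subcommands `simulate-*`, `detect`, `count`,
`spatial`, `stats`, `atlas`).

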