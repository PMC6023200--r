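---
title: "Methods: image-based NF-kB translocation screening with nucshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based NF-kB translocation screening with nucshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucshift)
```

## The measurement

Resting NF-kB (p65) sits in the cytoplasm; on activation it moves into the
nucleus. A high-content screen for activators images each well of a
384-well plate in two channels - a nuclear stain (DAPI) that defines cell
geometry and an immunofluorescent reporter (FITC) that tracks p65 - and
summarises each cell by the ratio of its mean nuclear reporter intensity
to its mean cytoplasmic reporter intensity, written NUC/CYT. Unstimulated
cells sit near 1; strong activation (e.g. 100 ng/mL TNF-alpha) raises the
ratio well above it. A well's *translocation value* aggregates its cells'
ratios; compounds are called active when that value reaches a fixed
cutoff (1.3 by default).

nucshift implements this measurement end to end, and ships a synthetic
image generator with per-cell ground truth so that every stage - masks,
per-cell means, well aggregation, plate statistics - can be validated
against known answers rather than against another image-analysis package.

## The mask pipeline

Segmentation uses only the nuclear channel, in five steps
(`build_masks()`):

1. **Band threshold** (`threshold_nuclei()`): a pixel is foreground iff
   `threshold_low <= I <= threshold_high`, both bounds inclusive. The low
   bound separates dim-but-real nuclei from background; the high bound
   rejects saturated objects (dead cells, mitotic figures, debris). The
   defaults (1000, 60000) are calibrated to the generator's intensity
   scale: background 500, nuclear peak 10000, debris at the 16-bit
   sensor maximum. An optional Otsu low bound (`auto_threshold`) is
   provided for images on other scales, but the fixed band is the default
   because it is reproducible run to run.
2. **Fill holes** (`fill_holes()`): background components not 4-connected
   to the image border become foreground, so uneven staining inside a
   nucleus does not fragment its mask. Foreground is 8-connected and
   background 4-connected throughout; the pair must differ or hole
   filling is ambiguous on diagonal chains.
3. **Label and shrink** (`label_and_shrink()`): connected components are
   labelled, then each object is independently eroded by a disk
   (`shrink_radius`, default 2 px) to pull mask edges inside the true
   nuclear boundary. Objects erased entirely are dropped. Touching nuclei
   remain one object; watershed splitting is out of scope, and the area
   filter below removes most merged clumps instead.
4. **Area/border filter** (`filter_objects()`): objects outside the
   inclusive `[min_area, max_area]` band (defaults 20 and 500 px^2,
   bracketing the ~110 px^2 nuclei the generator draws) are removed, as
   are objects touching the image border, whose cytoplasm would be
   truncated.
5. **Derived masks**: the extended-nuclei mask dilates each nucleus by
   `extend_radius` (2 px) - a guard ring that keeps nuclear fluorescence
   out of the cytoplasm measurement - and the whole-cell mask dilates by
   `cell_radius` (8 px), which the constructor requires to exceed three
   times the extend radius. Cytoplasm is whole cell minus extended
   nuclei, per cell.

Where dilations of different cells collide, each contested pixel goes to
the cell whose nucleus centroid is nearest (Euclidean; the lower label
wins exact ties), a deterministic, seed-free rule. Nucleus pixels always
keep their own label, and the guard ring adopts the whole-cell owner's
label on every pixel within `extend_radius` of *any* nucleus; together
these guarantee, exactly and per cell: nucleus ⊆ extended ⊆ whole cell,
cytoplasm ∩ extended = ∅, and cytoplasm ∪ extended = whole cell. The test
suite checks these invariants on batches of random fields and checks the
morphology primitives against brute-force disk-kernel oracles on small
rasters.

All dilations/erosions use the explicit disk kernel
`{(dx, dy) : dx^2 + dy^2 <= r^2}` (`disk_kernel()`), so "radius" means
the same thing in every step.

## Quantification and aggregation

`measure_cells()` computes each cell's mean reporter intensity over its
nucleus and cytoplasm pixels and their ratio. Cells whose cytoplasm was
consumed entirely by neighbour competition are discarded (and tallied),
not imputed. `aggregate_well()` pools cells across a well's fields
(default nine, the screen's acquisition plan) and averages the per-cell
ratios - the `mean_of_ratios` default, matching a per-cell assay readout;
`ratio_of_means` (ratio of the well-level mean intensities) is available
as a configuration switch because either aggregation is defensible and
the choice is not recoverable from typical vendor-software descriptions.
Pooled-mean aggregation is invariant to how cells are split across
fields, which the tests assert. Wells with fewer than
`min_cells_per_well` cells (default 50, about one well-sparse field at
screen density) are flagged invalid, carry no value, and are excluded
from every downstream statistic.

## Plate quality control

For each plate, the maximal-activation (TNF-alpha) and vehicle (DMSO)
control wells give means and sample (n-1) standard deviations, from
which:

* the Z-prime factor
  `Z' = 1 - 3 (SD_max + SD_min) / |mu_max - mu_min|` (`zprime()`), and
* coefficients of variation `100 * SD / mean` (`cv_percent()`) for the
  positive controls, negative controls and - when present - the 320
  compound wells.

A plate passes (`qc_plate()`) when every computed CV is strictly below 20%
and Z' exceeds 0.5. The CV gate is applied to all three CV figures
conservatively, since the validation rule is stated once but all three
are computed. `kruskal_wallis()` (rank-based, tie-corrected, chi-squared
p) compares stimulation conditions during assay development, with
`dunn_posthoc()` as an optional adjusted pairwise follow-up.

## Hit calling and dose-response

`call_hits()` applies the inclusive cutoff NUC/CYT >= 1.3 to the raw
(un-normalised) well values - exactly 1.3 is a hit, 1.299 is not - and
never calls invalid wells. `tabulate_hit_rates()` reports per-library and
overall rates rounded to one decimal (raw rates retained);
`rank_compounds()` orders by effect size with lexicographic id
tie-breaks.

Dose-response confirmation fits the four-parameter logistic
`y = bottom + (top - bottom) / (1 + (EC50/x)^hill)` by
Levenberg-Marquardt least squares (`fit_4pl()`, on `minpack.lm`). The
model is fitted on the asymptote pair (response at dose 0 and at
infinite dose) so rising activation curves and falling growth-inhibition
curves share one parameterisation, with orientation detected from the
data. Initialisation: asymptotes from the extreme dose means, EC50 by
log-linear interpolation of the half-span crossing, Hill slope 1; bounds:
Hill in [0.2, 10], EC50 within [min dose / 10, max dose x 10]. The EC50
reported is the fitted inflection parameter (the standard relative EC50),
not an absolute 50% crossing. Fits are censored - never silently
numeric - when the response span is below 20% of the control range
(default 100, the percent-of-control scale) or the midpoint falls outside
the tested dose range; non-convergence is flagged. Cytotoxicity uses the
same machinery on percent growth (`percent_growth()`, RLU normalised by
the vehicle-control mean), reporting the midpoint as IC50 and censoring
at the top tested dose (`fit_cytotox()`).

`selectivity()` reports SI = IC50 / EC50 rounded to two significant
figures and classifies it: good (SI > 5), some (2-5), none (< 2). A
censored IC50 propagates as a flagged lower bound classified at that
bound; a censored EC50 makes the compound unclassifiable.

## The synthetic generator

`generate_field()` emulates what the pipeline must tolerate, not optics:

* elliptical nuclei (semi-axes N(6, 1) px, truncated at 2) at the
  nuclear-stain peak with a few percent per-cell brightness jitter;
* a cytoplasmic annulus (6 px) around each nucleus; crowded cells'
  nuclei may overwrite a neighbour's cytoplasm, as in a monolayer;
* a reporter channel that is piecewise constant before noise - cytoplasm
  at 2000, nucleus at `ratio x 2000` - so the NUC/CYT over the true masks
  equals the requested ratio exactly in the noiseless case (the in-memory
  rasters stay floating point; quantisation happens only on TIFF export);
* additive Gaussian read-out noise on both channels (default SD 100, i.e.
  5% of the cytoplasmic reporter signal), clipped to the 16-bit range;
* Poisson-count debris rendered saturated in the nuclear channel, which
  the threshold band must reject;
* optional clumping: placement mixes uniform sampling (with a
  minimum-separation constraint that relaxes as clumping grows) with
  Gaussian attraction to already-placed cells.

Default density is 60 cells per 256 x 256 field - a plausible 20X field
of a well seeded at a few thousand cells; published protocols do not
state per-field counts, so this is a declared choice. One seeded RNG
stream drives each generator call and is restored afterwards; fixed
seeds give bit-identical fields, which the tests use for regression
checks. `generate_plate()` derives per-field seeds deterministically
from the plate seed, well index and site.

What the generator does *not* emulate - point-spread blur, illumination
gradients, chromatic shift, cell-cycle morphology, true marker
biology - bounds what passing tests show: they validate the analysis
contracts (mask geometry, measurement arithmetic, statistics, gates) on
images with realistic structure, not the pipeline's robustness to every
real-world artefact. Threshold defaults in particular are tied to the
generator's intensity scale and must be re-set (or `auto_threshold`
enabled) for real instruments, mirroring practice, where thresholds are
adjusted per run.

## Validation problem sizes

The shipped checks use: a scaled-down validation plate (the four control
columns of rows A-D; 16 wells x 9 fields at 256 x 256) for the in-suite
end-to-end QC check, and the full 64 control wells for the standalone
validation script; 200 seeded noisy dose-response simulations for EC50
recovery (median relative error under 10% at noise 5% of span, with
noiseless recovery within 1%); 30 random fields for the mask-invariant
property suite; rasters up to 64 x 64 for the brute-force morphology
oracles. Simulated validation plates clear the pass gates with wide
margin (Z' above 0.9) because the generator's well-to-well variability is
pure sampling noise; real plates add biological and liquid-handling
variance, which is why the gates, not the margins, are the contract.

## Known limitations

* No watershed separation: heavily clumped nuclei merge and are mostly
  removed by the area filter, biasing dense fields toward sparser
  measured populations.
* Nearest-centroid territory assignment approximates cell boundaries; in
  very dense monolayers true boundaries are not Voronoi-like.
* The 4PL fitter handles monotone curves only; bell-shaped dose-response
  (e.g. toxicity masking activation at high dose) is censored or fits
  poorly rather than being modelled.
* Hit calling operates on raw NUC/CYT, matching single-point screening
  practice; percent-of-control normalisation is reserved for
  dose-response (`normalize_activation()`).
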