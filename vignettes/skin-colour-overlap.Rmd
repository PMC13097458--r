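---
title: "Measuring skin colour variation and overlap in CIELAB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring skin colour variation and overlap in CIELAB}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinoverlap)
```

## The question and the measurement space

How well does skin colour separate self-identified ethnic groups? The
package answers this with two complementary statistics computed on
objective colour measurements, both living in CIELAB — the CIE 1976
L\*a\*b\* space, chosen because Euclidean distance in it (ΔE\*~ab~)
approximates perceived colour difference. L\* is lightness (0–100), a\*
the red–green axis, b\* the yellow–blue axis; chroma
C\* = √(a\*² + b\*²) is the distance from the neutral axis.

Incoming data may already be CIELAB, or CIE XYZ tristimulus values, or
reflectance spectra. XYZ converts through the standard CIE 1976
transform (cube root above t = (6/29)³, linear below) against a
configurable reference white. Spectra integrate to XYZ over 400–700 nm at
a 10 nm step (rectangular rule), normalised so a perfect reflector returns
the illuminant white with Y = 100.

### Colorimetric defaults

The default illuminant is D65. For the XYZ→CIELAB step both the 2° (1931)
and 10° (1964) observer white points are available as exact published
constants. For the spectral integration step the package evaluates the
1931 2° colour-matching functions from a compact multi-lobe
piecewise-Gaussian analytic fit (accurate to about 1 % of peak) rather
than bundling data tables; consequently the spectral path defaults to the
2° observer, and a dataset derived from spectra uses the *computed*
spectral white point so a unit reflector maps exactly to L\* = 100. Skin
archives typically store already-converted XYZ or CIELAB values, so the
spectral path is a convenience, not the accuracy-critical route. Archived
CIELAB tables should always record which illuminant/observer produced
them; small shifts between observer conventions are of the order of
fractions of a ΔE unit for skin-like spectra.

L\* values are never clamped to [0, 100]; out-of-range conversions warn
with the offending record ids, because silent clamping would bias group
moments.

## Within-group variation

`summarize_groups()` reports, per group, the mean and SD of L\*, a\*, b\*
and of per-sample chroma, plus the mean ΔE\*~ab~ of each sample to the
group's mean colour — a single perceptually meaningful dispersion number.
`anova_two_way()` fits a fixed-effects ethnicity × gender ANOVA with
interaction per attribute. Sums of squares are Type II by default:
archive designs are unbalanced, and Type II keeps main effects free of
interaction bias (Type III, under sum-to-zero contrasts, is available by
flag). The effect size is partial η² = SS~effect~ / (SS~effect~ +
SS~residual~). Measurements are treated as independent observations,
matching the per-spectra convention of archive analyses, even though each
subject contributes about ten body sites; `aggregate_subjects()` provides
a subject-level sensitivity mode.

## Between-group overlap

**Individual level.** For every ordered pair (reference A, comparison B),
`min_delta_e_profile()` finds for each A-sample the exact minimum
ΔE\*~ab~ to any B-sample (an exhaustive compiled scan — ΔE\*~ab~ is
Euclidean, so the minima are exact, verified against a double-loop oracle
in the tests). `overlap_fraction()` is the percentage of minima strictly
below the perceptibility threshold, default PT = 2 ΔE units — a
suprathreshold just-noticeable difference that a majority of observers
can detect. Strict `<` is the default reading of "falls below the
threshold"; a `<=` flag exists for sensitivity analysis. The matrix
diagonal is 100 by convention (a sample is indistinguishable from itself)
and is excluded from all medians and correlations, leaving 56 ordered
cells for eight groups.

**Group level.** Skin colour clouds are concave ("banana-shaped" in the
L\*–C\* plane), so convex hulls overestimate gamut volume. Instead each
group's cloud is voxelized into cubes of edge 3 CIELAB units — large
enough that adjacent cube centres differ by more than the PT — on a
global grid anchored at the origin with half-open cells
[3k, 3(k+1)); anchoring is dataset-independent, so cube sets are
comparable across groups and runs, at the cost of a boundary-placement
sensitivity of a few percent of cubes. Negative coordinates floor
downwards, keeping cells uniform across zero. Refinement applies two
criteria, once each, in order, each pass judged on a snapshot of its
input (no cascading, no iteration to a fixpoint — the simplest reading of
a one-shot clean-up): isolated cubes (six empty face neighbours) are
removed, then cavities (six filled face neighbours) are filled. Cubes
with one to five filled neighbours are never touched. Overlap of A on B
is the share of A's refined cubes also occupied by B's refined gamut;
the intersection is symmetric, so pct(A→B)·|A| = pct(B→A)·|B| holds
exactly and is asserted in the tests.

## Robust summaries

Overlap percentages are skewed, so central tendency is the median, with a
bootstrap percentile CI (default 1000 resamples, 95 %). The resampling
unit is the set of 56 ordered off-diagonal matrix cells — the "overlap
results" being summarised — not the underlying measurements; a
sample-level bootstrap would answer a different (measurement-sampling)
question and can be run by bootstrapping the dataset upstream. Percentile
rather than BCa intervals keep the procedure simple and transparent; even
lengths use the mean of the central order statistics. Agreement between
the two matrices is Pearson's r over the off-diagonal cells, reported as
*undefined* (not NaN) when either matrix has zero variance or fewer than
three paired cells exist.

All randomness — generator, bootstrap — flows from explicit integer
seeds; the global RNG state is never disturbed, and seeds are recorded in
provenance and outputs.

## The synthetic generator

`generate_dataset()` draws, per subject, a trivariate Gaussian
(L\*, a\*, b\*) level from the group model, then one measurement per body
site as level + site offset + within-subject Gaussian noise (default SD
0.5 ΔE per axis, small against between-subject spreads of 2–7), with an
optional additive offset for one gender. The `issa_like` preset places
eight groups at published archive means and SDs at the archive's scale
(subject counts × 10 sites ≈ 14 500 measurements, cohort female
fractions); subject-level SDs are shrunk so that subject spread plus
noise reproduces the target marginal SD exactly. Only marginal moments
are published, so the default covariance is diagonal, with an optional
positive L\*–b\* coupling to imitate the curved lightness–chroma
distribution of real skin. Gaussian tails are kept (no truncation), so
configured moments are preserved.

What the generator does *not* emulate: skewness and heavy tails of real
skin clouds, site-specific colour structure (palms lighter, forehead
redder), subject-level correlation structure beyond a single optional
coupling, age effects, and spectral-level physics. Passing tests on
synthetic data therefore validate the *machinery* — exact search,
voxel semantics, bootstrap calibration, pipeline determinism — not the
real-data values; a diagonal-Gaussian world is more separable than real
skin, so synthetic overlap medians run below archived ones. Reproducing
the published numbers requires the archived measurements themselves
(see the README).

Preset notes: the `identical` preset centres all eight groups on a voxel
cube centre with site offsets that translate whole cubes, making every
group occupy the same refinement-stable ten-cube set with overwhelming
probability — this is what lets the degenerate all-100 % expectation be
asserted exactly. The `disjoint` preset spaces group means 30 L\* units
apart (≫ PT and cube edge), forcing 0 % everywhere off-diagonal.

## Problem sizes and numerical choices

The test suite runs the full archive-scale scenario (~14 500
measurements) directly — the compiled nearest-neighbour scan covers all
56 ordered pairs in about a second — and uses 10⁴ samples per group for
moment-recovery checks, where tolerances are four standard errors derived
for the clustered design (ten correlated measurements per subject make
the subject count, not the measurement count, govern the SE of a group
mean). Bootstrap coverage is checked over 500 Gaussian replications at
the 56-cell size. "Identical colour" comparisons use an absolute
tolerance of 1e−12; overlap matrices serialise at full precision so CSV
round-trips agree to 1e−12, with 1-decimal copies for reporting.

## Known limitations

* The spectral path supports the 2° observer only and D65/A/E
  illuminants; 10° support at the white-point level covers the common
  case of externally converted XYZ.
* Single-pass refinement is a convention; gamuts with pathological
  topology could depend on pass order or iteration, which the package
  deliberately does not explore beyond its documented semantics.
* Overlap statistics are computed per measurement, not per subject;
  subjects contributing many sites weigh proportionally.
* The voxel grid anchor is fixed at the origin; cube counts carry a
  boundary sensitivity of roughly ±5 % between anchoring conventions.
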