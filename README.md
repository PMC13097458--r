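# skinoverlap

Quantifying within-group variation and between-group overlap of human skin
colour in CIELAB space.

Skin colour is routinely treated as a proxy for ethnicity — in dermatology,
cosmetics, imaging and machine-learning pipelines alike — yet objective
colorimetry shows that within-group variability is large and group colour
distributions overlap heavily. `skinoverlap` provides a tested, reusable R
implementation of the analysis pipeline behind that claim, for researchers
working with ISSA-style skin reflectance archives (per-measurement tables of
subject, self-identified ethnic group, gender, body site and colour as
CIELAB, XYZ or reflectance spectra).

## What it computes

All statistics live in CIELAB (L\* lightness, a\* red–green, b\*
yellow–blue), with chroma C\* = √(a\*² + b\*²) and the perceptual colour
difference

ΔE\*~ab~ = √((ΔL\*)² + (Δa\*)² + (Δb\*)²).

Two complementary overlap statistics are built per ordered pair of groups:

* **Individual-level overlap** — for each sample of a reference group, the
  minimal ΔE\*~ab~ to any sample of a comparison group; the statistic is the
  percentage of those minima strictly below the perceptibility threshold
  (PT, default ΔE\*~ab~ = 2, a just-noticeable difference most observers can
  detect).
* **Shared-gamut overlap** — each group's point cloud is voxelized into
  3×3×3 CIELAB unit cubes on a global origin-anchored grid, refined by two
  morphological criteria (remove isolated cubes with six empty face
  neighbours; fill cavities with six filled face neighbours), and the
  statistic is 100·|cubes(A) ∩ cubes(B)| / |cubes(A)|.

Around these sit per-group summaries (CIELAB moments plus the mean ΔE\*~ab~
of samples to their group centroid), a two-way ethnicity × gender ANOVA with
partial η² effect sizes, bootstrap percentile confidence intervals for
overlap medians (1000 resamples of the 56 ordered off-diagonal matrix
cells), Pearson agreement between the two overlap matrices, and a seeded
synthetic cohort generator so that every stage is testable without any data
download.

## Worked example

Run the whole pipeline on the bundled archive-like synthetic scenario
(eight groups at published archive moments, ~14 500 measurements):

```r
library(skinoverlap)
cfg <- run_config(issa_like_scenario(seed = 42), seed = 42)
bundle <- run_full_analysis(cfg)
print(bundle)
#> <report_bundle>
#>   measurements: 14530
#>   individual overlap median: 74.5 [65.1-80.4]
#>   gamut overlap median:     53.5 [46.0-56.9]
#>   matrix agreement: r = 0.97 (p = 5.9e-34)
```

Reading: the median cell of the individual overlap matrix says that for a
typical ordered pair of groups, about three quarters of the reference
group's samples have a perceptually indistinguishable counterpart (ΔE\*~ab~
< 2) in the comparison group; the bracket is the bootstrap 95% CI of that
median. The gamut median says a typical group shares about half of its
refined colour volume with another group, and the two methods agree
strongly across the 56 ordered group pairs. (A diagonal-Gaussian synthetic
cohort is more separable than real skin data, which is skewed and
heavy-tailed, so these synthetic medians sit below the values reported on
the real archive.)

Individual stages are available as plain functions (`filter_sites()`,
`summarize_groups()`, `anova_two_way()`, `individual_overlap_matrix()`,
`gamut_overlap_matrix()`, `bootstrap_median_ci()`, `matrix_correlation()`),
and a thin command-line wrapper covers the same pipeline:

```sh
Rscript exec/skinoverlap run-all --scenario issa_like --seed 42 --out-dir out/
Rscript exec/skinoverlap simulate --scenario two_group_partial --separation 12 --seed 3 --out data.csv
```

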