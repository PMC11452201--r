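# fibromorph

3D morphometry of the liver sinusoid network in high-resolution micro-CT
volumes, built around the structural signature of fibrotic remodelling:
lesions occupy a growing share of the tissue as disease progresses, and the
sinusoids inside them are **sparser but wider** than in unaffected tissue.

The package is aimed at imaging scientists quantifying microvascular change
in fixed-tissue micro-CT (synchrotron or lab source) of liver — or any organ
with a dense capillary bed — and at method developers who need a fully
synthetic, ground-truthed test bed for such pipelines.

## What it computes

For a volume with aligned region masks (`sinusoid`, `vessel`, `lesion`,
tissue `domain`):

- **Lesion volume proportion** — lesion voxels over the tissue volume with
  vessels excluded: `|L ∩ D \ V| / |D \ V|`, an exact integer-count ratio.
- **Sinusoid volume proportion per region** — `|S ∩ R| / |R|` for the
  lesion region and for unaffected tissue (`D \ L \ V`).
- **Local thickness** — each object voxel is assigned the radius (µm) of
  the largest sphere that fits entirely inside the object while containing
  that voxel (the Hildebrand–Rüegsegger measure). The implementation is an
  exact Euclidean distance transform plus distance-ridge sphere painting,
  and matches an exhaustive maximal-inscribed-sphere search voxel for voxel
  on isotropic grids.
- **Stage statistics** — Kruskal–Wallis with Dunn post-hoc tests,
  Dunnett many-to-one comparisons, multiple unpaired t-tests with
  Bonferroni correction, and two-way ANOVA with an interaction-triggered
  one-way fallback.

Around this core sit a preprocessing chain (block binning, multiplicative
trilinear bias-field correction, bright-artifact clamping, robust
percentile normalization), a transparent rules-based segmenter
(Otsu lumen threshold → thickness-based vessel/sinusoid split →
sinusoid-reach lesion detection), and a synthetic phantom generator that
produces vascular-network volumes with exact ground truth.

## Worked example

```r
library(fibromorph)

# a synthetic liver volume: 40% lesion burden, 2 large vessels,
# 5 µm sinusoids in unaffected tissue vs 9 µm inside lesions
p <- generate_phantom(phantom_spec(shape = c(96, 96, 96),
                                   lesion_target_fraction = 0.4, seed = 7))
p$truth
#> phantom_truth: lesion 0.400, sinusoid lesion 0.067 / healthy 0.116 (seed 7)

q <- quantify_sample(p$truth$masks, sample_id = "demo")
round(t(q[, c("lesion_volume_proportion",
              "sinusoid_volume_proportion_lesion",
              "sinusoid_volume_proportion_healthy",
              "thickness_mean_lesion", "thickness_mean_healthy")]), 4)
#> lesion_volume_proportion           0.4000
#> sinusoid_volume_proportion_lesion  0.0670
#> sinusoid_volume_proportion_healthy 0.1164
#> thickness_mean_lesion              7.3401
#> thickness_mean_healthy             4.3549
```

Reading the output: 40.0% of the non-vessel tissue is lesion; sinusoids
fill 6.7% of the lesion volume against 11.6% of unaffected tissue (the
vascular rarefaction), while their mean local thickness is 7.3 µm inside
lesions against 4.4 µm outside (the compensatory widening). The thickness
means are slightly below the generating tube radii because tubes are
clipped at region boundaries.

A full staged run — simulate a three-stage cohort, preprocess, segment (or
load truth masks), quantify, and test — is one call:

```r
cfg <- read_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "fibromorph"))
res <- run_pipeline(cfg, out_dir = "demo_run")
```

which writes `results.csv` (one row per sample), `stats.csv`,
`decision_trace.json` and the resolved configuration. The same pipeline is
scriptable from a shell via `exec/fibromorph`
(`simulate`, `preprocess`, `segment`, `quantify`, `stats`, `run-all`).

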