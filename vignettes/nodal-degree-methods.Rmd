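---
title: "Nodal-degree analysis of functional connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nodal-degree analysis of functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndgraph)
```

## The analysis in one paragraph

ndgraph quantifies how central each brain region is within a resting-state
network, and whether that centrality differs between cohorts. For each
subject, region-averaged BOLD-like time series are correlated pairwise
(Pearson), the correlations are variance-stabilised (Fisher r-to-z),
negative weights are removed, and the weighted matrix is binarised by
keeping the strongest D% of all possible edges for every density D on a
5–50% grid. The nodal degree of region *i* at density D is
$ND_i = \sum_j a_{ij}$, the number of edges incident to it in that binary
graph. Cohorts are compared cell by cell (region × density) on the
difference in mean nodal degree, with inference by nonparametric
permutation (subject relabeling for cross-sectional contrasts,
within-subject timepoint swaps for longitudinal ones) and
Benjamini–Hochberg FDR control over each contrast's family of cells.

The packaged region set is a 25-node rodent default mode-like network
(DMLN) parcellation: bilateral cingulate (areas 1 and 2), orbitofrontal,
prelimbic, primary/secondary visual, retrosplenial, hippocampal
CA1/CA2/CA3, auditory/temporal association and parietal association
cortices, plus a single midline basal forebrain node.

## Why these processing choices

**Fisher z before rectification.** Since `atanh` preserves sign, applying
the z-transform first and zeroing negatives afterwards gives the same
result as the reverse order; the package fixes the z-first order so runs
are bit-reproducible. Correlations are clipped at `1 - 1e-7` in absolute
value before `atanh`: real recordings never reach ±1, but synthetic or
degenerate inputs can, and the clip keeps every weight finite.

**Negative edges.** Negative correlations are set to zero before graph
construction; degree-based measures on signed graphs are harder to
interpret and less reliable, so only positive coupling defines edges.
Self-loops are excluded throughout (zero diagonal).

**Proportional thresholding and the density grid.** A density threshold
fixes the edge count rather than the weight cutoff, so group differences
in degree are not confounded by global differences in correlation
strength. The grid spans 5–50% in 1% steps: below ~5% the graph
fragments; above ~50% it approaches a complete (random-like) graph. With
R = 25 regions there are 300 possible edges, so the kept edge count is
exactly m = 3D at integer densities; in general m = round(D/100 ·
R(R−1)/2) with half-up rounding. Edges are ranked once per subject, ties
broken lexicographically (smaller row, then column index); thresholding
at increasing densities therefore yields *nested* graphs, which makes
each region's degree a monotone non-decreasing function of density and
the sweep deterministic and reproducible.

**Permutation inference.** For each contrast, the observed statistic per
cell is the difference in cohort mean nodal degree. The null is built
from `n_perm` (default 10 000) random relabelings: unpaired contrasts
permute subjects across the two cohorts preserving group sizes; paired
contrasts swap each subject's two timepoint labels independently with
probability ½ (the 2^n sign-flip scheme), so no permuted group ever
mixes timepoints within a subject. The two-sided p-value uses the
add-one convention, p = (#{|null| ≥ |observed|} + 1)/(n_perm + 1), which
cannot return zero from a sampled null. Nulls for unpaired contrasts are
generated in a canonical side order, so exchanging the two sides of a
contrast under the same seed negates every difference exactly and leaves
every p-value unchanged.

**Confidence bands and significance.** The reported band is the
equal-tail percentile interval of the permutation null (95% by default),
centred at zero — the display criterion "the observed point falls
outside the light-blue zone". The *decision* criterion is the
FDR-adjusted p-value: Benjamini–Hochberg step-up over all region ×
density cells of one contrast jointly (`fdr_family = "joint"`). A
per-density family is available as an option since correction scope is a
genuinely open choice; the joint family is the stricter default for a
region × density results table. `significant` always means
`p_fdr < alpha`; `outside_ci` is reported alongside for figure-style
display.

## The synthetic cohort generator

No imaging data ship with the package; a generative stand-in makes every
stage testable. The generator emulates the reference study design: 13
case ("TG") and 11 control ("WT") subjects, two timepoints (4M, 6M), 25
regions, 980 usable samples per series at TR = 0.6 s, signals
band-limited to 0.01–0.17 Hz.

**Model.** Region signals follow a Gaussian factor model: with loadings
λ (default 0.6 for every region, giving pairwise r = 0.36, a typical
within-network coupling), the target correlation is ΛΛᵀ off the diagonal
and 1 on it — positive semi-definite by construction. The unique-noise
standard deviation is fixed at √(1 − Σλ²) by the unit-variance
constraint, so it is not a free parameter. Correlated samples are drawn
via the symmetric eigendecomposition square root (tolerant of
semi-definite targets), band-pass filtered with a zero-phase 2nd-order
Butterworth filter (applied forward and backward via `filtfilt`), and
de-meaned per column. Filtering every channel with the same zero-phase
filter preserves the cross-correlation structure.

**Lesions.** A connectivity lesion multiplies the loadings of target
regions by a factor in chosen cohort cells: a multiplier of 0.5 on node
*i* halves all of its model correlations (to multiplier·λᵢ·λⱼ), which
depresses its edge ranks and hence its degree across the density sweep —
a generative analog of the hypo-connectivity the pipeline is designed to
detect. Left/right homologous regions share loadings by default, and a
lesion can target a single hemisphere. The default lesion magnitude
(0.5) is a tunable emulation parameter, not a value calibrated to any
dataset: the reference findings are reported as significance patterns,
not correlation-scale effect sizes.

**Determinism.** One master seed plus the cohort spec determines every
sample: each subject × timepoint stream is seeded by a hash of
(seed, subject id, timepoint), so a subject's series does not depend on
cohort composition and regenerated cohorts are bit-identical.

**What the generator does not emulate.** Motion and physiological
artifacts, scanner noise spectra, hemodynamic response shapes,
voxel-level structure, and preprocessing (realignment, normalisation,
nuisance regression) are all out of scope — inputs are assumed clean,
as if preprocessing had already run. Passing tests on synthetic cohorts
therefore validates the *pipeline machinery and its statistical
calibration*, not claims about real rsfMRI data.

**A numerical note on band-limited sampling noise.** Band-pass filtering
autocorrelates the samples: the effective number of independent samples
in a series of length T is about b·T, where b is the band fraction of
Nyquist (≈ 0.19 for 0.01–0.17 Hz at TR 0.6 s). Empirical correlations
therefore converge to the target at rate 1/√(bT), not 1/√T; the
package's convergence tests use the corrected bound for filtered series
and the plain bound for unfiltered ones.

## Degenerate inputs and numerical conventions

- Constant region signals make Pearson correlation undefined; the
  connectivity stage rejects them with an error naming the region.
- A density too low to keep a single edge (m = 0 after rounding) is an
  error, not an empty graph.
- A zero-variance permutation null (identical profiles everywhere)
  yields p = 1 by the add-one rule rather than a division error.
- Tie comparison between |null| and |observed| uses a 1e-9 absolute
  tolerance so exact ties in the integer-degree statistic are not lost
  to floating-point error.
- Paired contrasts require complete pairs; the pipeline excludes
  subjects missing a timepoint with a warning and lists them in the run
  report (mirroring real longitudinal attrition), never silently.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to exercise the study design
while staying desk-scale: the null-calibration simulation uses 200
global-null cohorts of 6 + 6 subjects (T = 200, 10 regions, 1000
resamples) and checks the type-I rate of a fixed cell against the
binomial band around 0.05; the lesion-recovery simulation uses 50
cohorts at the full study size (13 + 11 subjects, T = 980, 25 regions,
full density grid, 1000 resamples) with a half-loading lesion on left
CA2 and requires detection in ≥ 80% of runs with no other region
flagged in > 20%. Exhaustive sign-flip enumeration (2⁸ patterns for
n = 8 pairs) validates the sampled paired null by KS distance.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(seed = 42)          # 13 + 11 subjects, 2 timepoints
eff <- effect_spec("CA2_L", 0.5, groups = "TG", timepoints = "4M")
cohort <- generate_cohort(spec, effects = eff)
run <- run_pipeline(cohort, n_perm = 10000, seed = 42)
res <- run$results[["TG_4M_vs_WT_4M"]]
subset(res, significant & region == "CA2_L")
plot_difference_curves(res, "CA2_L")
```

## Known limitations

- Only nodal degree is implemented; other centralities (betweenness,
  clustering coefficient, closeness) are out of scope.
- The binary graphs are undirected and unweighted after thresholding;
  no weighted-degree variant is provided.
- The joint-vs-per-density FDR family choice changes which cells pass at
  the margin; both are exposed, only one can be the default.
- Confidence bands are percentile-based; no normal-approximation bands.
- The generator's factor model produces (near-)exchangeable regions
  apart from planted lesions; it does not reproduce the block structure
  or hemispheric asymmetries of real connectomes.
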