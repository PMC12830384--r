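---
title: "Segmenting aggregate point clouds into spherical components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting aggregate point clouds into spherical components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-view reconstruction (structure-from-motion followed by dense stereo)
of an *aggregate* — a bunch of grapes, a pile of cherry tomatoes — returns
one fused point cloud in which the individual components are not separated.
`aggseg` segments such a cloud into its components under a single geometric
assumption: each component is approximately a sphere (optionally an
ellipsoid or a slightly deformed sphere described by a user template mesh).
The output is one placed template mesh per component, together with the
component count and localization accuracy when ground truth is available.

The pipeline has five stages:

1. **Preprocessing** — optional color/crop filtering, normalization of the
   cloud into the $[-1,1]^3$ box by one uniform scale, and voxel-grid
   downsampling on a $200^3$ grid (each occupied voxel is replaced by the
   centroid of its points).
2. **Over-clustering** — k-means with a user-chosen $k$ larger than the
   expected component count $N_e$ (1.5–2$\times$ is recommended). Too-large
   clusters spanning several components are the failure mode this guards
   against; over-splitting is corrected later by merging.
3. **Component fitting** — per cluster, a RANSAC search: each of
   $N_{hypo}=50$ hypotheses samples 10% of the cluster, places a sphere of
   the user-set initial radius at the sample centroid, and refines it
   greedily. Each refinement iteration scores 35 candidates — 7
   translations $\times$ 5 radius scalings, the scalings forming a fixed
   grid over the *initial* radius so the search stays anchored to the
   user's size prior (this anchoring is what makes the method sensitive to
   an initial radius below the smallest component and tolerant of one up
   to $\sim$1.3$\times$ it) — by the symmetric Chamfer distance
   $$d_{CD}(P, V) = \frac{1}{|P|}\sum_{q \in P}\min_{v \in V}\lVert x_q - x_v\rVert_2
     + \frac{1}{|V|}\sum_{v \in V}\min_{q \in P}\lVert x_v - x_q\rVert_2$$
   between the sample points $P$ and the placed template vertices $V$, and
   adopts the minimizer; it stops when the score falls below
   $d_{th1}=0.015$, the improvement falls below $d_{th2}=0.001$, or 50
   iterations elapse. The refined sphere is then validated on the whole
   cluster: points whose surface distance $|r - \lVert x_p - c\rVert_2|$ is
   below $\varepsilon = 0.015$ are inliers, and the hypothesis is valid
   when the inlier fraction exceeds 50%. The valid hypothesis with the
   smallest Chamfer score against its inliers wins.
4. **Merging** — two fitted spheres overlap when their centers are closer
   than $\alpha = 0.9$ times the sum of their radii. Connected groups of
   $m \ge 2$ overlapping fits have their clusters pooled and re-clustered
   at $k = m - 1$, then refitted; this repeats until no overlaps remain
   (guaranteed within the initial $k$ rounds, since the cluster count
   strictly decreases). Clusters without a valid fit are refitted each
   round with fresh sub-seeds, so transient RANSAC failures do not
   permanently lose a component.
5. **Detailed fitting** — each surviving fit is refined once more with an
   extended move set: per-axis scaling and $\pm 10^\circ$ rotations about
   the coordinate axes, giving ellipsoidal freedom to the final component.

## Parameters that matter

All lengths are in normalized units (the largest extent of the input cloud
spans $[-1, 1]$ after preprocessing).

| parameter | default | role |
|---|---|---|
| `k` | user | initial cluster count; 1.5–2$\times$ expected $N_e$ |
| `initial_radius` | user | starting sphere radius; $\approx$ the smallest component radius, in input units |
| `n_hypo`, `n_refi` | 50, 50 | RANSAC hypotheses; refinement iteration cap |
| `sample_fraction` | 0.10 | per-hypothesis subsample (min 3 points) |
| `epsilon` | 0.015 | inlier distance threshold (strict `<`) |
| `min_inlier_ratio` | 0.5 | validity cutoff (strict `>`) |
| `d_th1`, `d_th2` | 0.015, 0.001 | refinement stopping thresholds |
| `translation_step` | 0.01 | candidate translation width |
| `scale_factors` | 0.8–1.2 | candidate radius scalings (always contain 1) |
| `alpha` | 0.9 | sphere-overlap fraction for merging |
| `voxel_resolution` | 200 | per-axis downsampling grid |
| `template_subdivisions` | 2 | icosphere tessellation (162 vertices) |

The defaults are a calibrated set: $\varepsilon$, the steps, and the
stopping thresholds are meaningful when component radii are roughly
0.08–0.2 in normalized units, which is the regime of a typical fruit
aggregate photographed as a whole. The template tessellation sets the
floor of the Chamfer score (the score of a perfect fit is the mean
vertex-to-sample spacing, not zero), which is why it is exposed in the
configuration.

`initial_radius` is intentionally expressed in the *input* frame — the
radius of the smallest component as the user would measure it — and is
converted internally using the recorded normalization scale.

## Non-spherical components

With `shape = "ellipsoid"` or `"deformed"` three extensions activate:

- the inlier criterion generalizes to the fraction of placed-template
  vertices within $\varepsilon$ of the cluster (validity still at 50%);
- each hypothesis evaluates 7 rotated initializations (identity and
  $\pm 10^\circ$ per axis) and keeps the best refinement;
- the merge test replaces sphere overlap with an inside–outside rule: two
  components merge when more than $n$% of either's vertices lie strictly
  inside the other ($n = 2$ for ellipsoids, $n = 10$ for deformed shapes).

Inside/outside is decided by ray-crossing parity against the watertight
template, with on-surface vertices (within $10^{-9}$) counting as outside,
so coincident meshes do not merge spuriously.

## The synthetic-aggregate generator

Because real aggregate clouds depend on a capture rig and a
structure-from-motion run, the package ships a generator that emulates the
relevant properties of that output so the whole pipeline is testable:

- **Packing.** Components are placed by seeded sequential rejection
  sampling: each new component attaches to an existing one (center
  distance 0.98–1.02 of the radius sum) with growth biased down a central
  vertical axis and a bounded vertical span, producing an elongated,
  connected, non-interpenetrating bunch whose largest extent lands near
  the unit-box scale for 10–25 components. One base radius is drawn per
  aggregate and individual components vary by $\pm 10\%$ around it —
  components of one bunch are near-uniform in size, as berries of one
  bunch are, while the base radius spans the configured range (default
  0.08–0.15) across aggregates. This matters for the method's operating
  envelope: the fitting search explores radii multiplicatively from the
  single user-set initial radius, so an aggregate whose components differ
  by 2$\times$ in radius is outside the regime the parameter defaults are
  calibrated for.
- **Sampling.** Points are drawn uniformly on each component's surface at
  a density of 10,000 points per unit area (about 800–2,000 points per
  component, matching the per-component density of a typical multi-image
  reconstruction), then thinned by two occlusion mechanisms: points
  falling inside a neighboring component are removed (contact occlusion),
  and a random spherical cap covering `occlusion_fraction` (default 0.2)
  of each component's surface is removed (camera occlusion). Isotropic
  Gaussian noise (default sd 0.005) is added last.
- **Shapes.** Ellipsoids elongate one axis by a factor of 1.2–1.4 under a
  random rotation; "deformed" components perturb the radius by a smooth
  low-frequency bump field with amplitude 10% of the radius. Ellipsoid
  surface sampling maps uniform sphere directions through the per-axis
  radii, which is not exactly area-uniform; the deviation is below the
  other modeled effects and irrelevant to the tests.

What the generator does **not** emulate: structured reconstruction
artifacts (streaks, drift, density gradients along the camera path),
outlier points from the background, and stem/rachis geometry. Passing
recovery tests on synthetic aggregates therefore demonstrates the
correctness and calibration of the algorithm, not robustness to every
artifact of real photogrammetry.

## Numerical choices

- **Tie-breaking.** A refinement iteration adopts a candidate only on
  strict improvement; the identity candidate is the implicit current
  state, so ties keep the sphere where it is (no move, scale 1.0), and
  ties among non-identity candidates resolve in enumeration order.
- **Strict boundaries.** The inlier test (`< epsilon`), validity test
  (`> 0.5`), and sphere-overlap test (`< alpha * (r_i + r_j)`) are all
  strict; points or pairs exactly at a threshold do not qualify.
- **Voxel assignment** uses half-open intervals per axis with the last
  voxel closed, so boundary points are deterministic; a $10^{-9}$ slack
  absorbs floating-point overshoot at the normalized box faces.
- **Empty k-means clusters** are re-seeded at the point farthest from its
  nearest centroid, so a cluster set always partitions the cloud into
  non-empty clusters.
- **Rotation composition** in detailed fitting re-orthonormalizes after
  every increment (modified Gram–Schmidt), keeping the rotation proper to
  $10^{-9}$ under arbitrarily many compositions.
- **Seeds.** One master seed; every stage, hypothesis, and merge round
  derives its own sub-seed through a fixed multiplicative counter scheme
  (`derive_seed`), so adding hypotheses or rounds does not shift unrelated
  draws and identical configurations give byte-identical reports.
- **Per-axis scale clamping** in detailed fitting ([0.4, 2.5]$\times$ the
  entry radius) prevents degenerate flattening on sparse clusters.

## Design decisions taken where the procedure was open

- *Chamfer for ranking valid hypotheses* is computed against the inlier
  points only (the spherical path) — the no-inlier generalization for
  templates scores against all cluster points.
- *"Mutually overlapping" groups* are connected components of the overlap
  graph, not cliques: chains of pairwise overlaps describe one over-split
  component and should merge together.
- *Detailed fitting* evaluates the union of single moves (one translation,
  one single-axis scaling, or one rotation per candidate) rather than the
  full product of all three move families, i.e. coordinate descent; the
  full product would evaluate thousands of candidates per iteration for
  no practical gain.
- *Correspondence for evaluation* uses optimal (Hungarian) assignment on
  center distances, with the sample (n−1) convention for the distance
  standard deviation; unmatched surplus components are counted separately
  rather than folded into the mean.
- *Merging a pair* (m = 2) unions the two clusters directly — re-running
  k-means with k = 1 would produce the same single cluster.

## Problem sizes used in the shipped tests

The recovery suites run the full pipeline on aggregates of 10–25
components (about 10,000–30,000 points before downsampling) with
$k = 2 N_e$, ten seeds for the recovery suite and one fixture for the
parameter-sensitivity suite; these sizes give stable statistics while
keeping the whole test suite comfortably interactive. Larger clouds only
increase runtime: every stage is linear or near-linear in the point count
except the Chamfer evaluations, which are quadratic in per-cluster sample
sizes that the 10% subsampling keeps small.

## Known limitations

- A cluster covering less than roughly half of a component's surface has a
  Chamfer landscape whose global minimum is a smaller sphere hugging the
  visible cap; such fits are usually rejected by the 50% inlier rule and
  recovered later through merging and per-round refits, but a component
  whose every cluster is a small cap can be lost (reported as a missing
  component, never as a phantom).
- An initial radius chosen well below the smallest component (multiplier
  $\le 0.9$) degrades the result, but the failure signature depends on the
  noise-to-threshold ratio: when undersized fits still pass the 50% inlier
  rule they persist unmerged and the component count inflates
  (over-segmentation); at the default noise level they fail validity
  instead and components go missing (under-detection). Either way the
  merge step loses its effectiveness, which is why the initial radius
  should match — or slightly exceed — the smallest component.
- The merge step only reduces the cluster count; a single cluster spanning
  two components without any overlapping fit cannot be split. The
  recommended over-provisioned $k$ makes this rare.
- Components differing by more than about 1.5$\times$ in radius within one
  aggregate exceed what a single initial radius can serve (see the
  generator notes above).
- Wall-clock performance: the per-cluster search is quadratic in the
  sample size; pathological configurations (thousands of points per
  sample) are slow although correct.
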