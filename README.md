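# aggseg

Geometry-aware segmentation of aggregate point clouds into spherical
components.

## The problem

Photogrammetric reconstruction (structure-from-motion + dense stereo) of an
*aggregate* — a grape bunch, a cluster of cherry tomatoes — produces one
fused point cloud: the individual berries are not separated, and generic
3D segmentation struggles with many small, densely packed, near-identical
objects. `aggseg` is for researchers in plant phenotyping and 3D content
creation who need **one mesh per component**: it segments such a cloud
under the assumption that each component is approximately a sphere (or an
ellipsoid / slightly deformed sphere given a template mesh), and emits the
fitted component transforms, meshes, and recovery metrics.

## The method

Given a cloud normalized to $[-1,1]^3$ and voxel-downsampled on a $200^3$
grid, the pipeline:

1. **over-clusters** with k-means ($k \approx$ 1.5–2$\times$ the expected
   component count $N_e$);
2. **fits a sphere per cluster by RANSAC**: each of 50 hypotheses samples
   10% of the cluster, places a sphere of the user-set initial radius $r_0$
   at the sample centroid, and refines it greedily — every iteration scores
   35 candidates (7 translations of width 0.01 $\times$ radius grid
   $\{0.8, 0.9, 1.0, 1.1, 1.2\} \cdot r_0$) by the symmetric Chamfer
   distance between sample points $P$ and placed template vertices $V$,

   $$d_{CD}(P,V) = \tfrac{1}{|P|}\textstyle\sum_{q}\min_v \|x_q - x_v\| +
     \tfrac{1}{|V|}\sum_{v}\min_q \|x_v - x_q\|,$$

   stopping at $d_{CD} < 0.015$, improvement $< 0.001$, or 50 iterations.
   A hypothesis is **valid** if over 50% of the cluster lies within
   $\varepsilon = 0.015$ of the sphere surface
   ($d_p = |r - \|x_p - c\|_2| < \varepsilon$); the valid hypothesis with
   the smallest Chamfer score against its inliers wins;
3. **merges** clusters whose fitted spheres overlap
   ($\|c_i - c_j\| < 0.9\,(r_i + r_j)$): each connected group of $m$
   overlapping fits is pooled, re-clustered at $k = m-1$, and refitted,
   until no overlaps remain;
4. **refines each component in detail** with per-axis scaling and
   $\pm10^\circ$ rotations.

Recovery is scored by the component count $N_m$ vs the true $N_e$, and by
$M_d$/$M_s$ — mean/sd of matched center-to-center distances (optimal
assignment), normalized by the input bounding-box diagonal.

A ground-truthed synthetic-aggregate generator (packing, surface sampling,
occlusion, noise — emulating SfM output) makes the whole pipeline testable
without image capture; see the methods vignette
(`vignettes/aggregate-segmentation.Rmd`) for the model, parameter, and
design details.

## Worked example

```r
library(aggseg)

# a synthetic bunch of 15 berries, SfM-like sampling
agg <- generate_packing(15, seed = 42)
sim <- sample_surface(agg, seed = 43)          # 26,394 points

rmin <- min(sapply(agg$components, function(c) min(c$radii)))  # 0.121
cfg  <- pipeline_config(k = 30, initial_radius = rmin, seed = 7)
res  <- run_pipeline(sim$cloud, cfg, truth = agg)
res
#> <aggseg_result: 13 components from 21 final clusters>
#> Component recovery report
#>   N_e (true components)      : 15
#>   N_m (recovered components) : 13
#>   M_d (mean center distance) : 0.008899
#>   M_s (sd center distance)   : 0.006149
#>   matched pairs: 13; unmatched truth: 2; unmatched found: 0

res$components[[1]]
#> <fitted_component: c = (-0.042, -0.069, 0.899), scales = (0.111, 0.101, 0.091), chamfer = 0.03162>
```

13 of the 15 berries are recovered (two were lost to heavy occlusion), and
the recovered centers sit within 0.9% of the bounding-box diagonal of
their true positions — comparable localization to dedicated berry-counting
systems. `run_pipeline(..., output_dir = "out")` additionally writes
`components.obj` (one mesh group per component, in the input frame),
`report.json`, and per-point cluster labels.

For real data: `read_pointcloud("bunch.ply")`, filter with
`hsv_range_predicate()` / a crop box, and set `initial_radius` to the
radius of the smallest component in the cloud's units. A thin CLI wrapping
these functions is in `inst/cli/aggseg`
(`fit` / `simulate` / `evaluate` / `sweep`).

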