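# tasselseg

Organ-level analysis of 3-D maize tassel point clouds: from a raw colored
cloud to six morphological traits.

Maize tassels — the male inflorescences — carry DUS-testing characters
(branch count, branch length, insertion angle) that are slow and error-prone
to measure by hand. Multi-view reconstruction produces dense colored point
clouds of cut tassels, but the branches are thin and adherent near their
bases, which defeats direct instance segmentation. `tasselseg` takes the
tip-first route: a hierarchical point-set network (set-abstraction encoder,
feature-propagation decoder) labels only the branch *tips* — the distal
3–5 cm, which are well separated and cheap to annotate — and the full
branches are then recovered geometrically:

1. **Preprocess**: HSV foreground mask (H 15–180 on the 0–180 scale,
   S 0.05–1, V 0–1), statistical outlier removal (n = 20 neighbors,
   α = 0.5: remove points whose mean neighbor distance exceeds the global
   mean + α·sd), random then farthest-point downsampling to 4000 points.
2. **Segment tips** with the network (or pass through ground-truth labels).
3. **Cluster** tips into branch instances with DBSCAN
   (ε = 3·d_mean, minPts = 5).
4. **Skeletonize**: Dijkstra spanning tree over the downsampled remainder,
   rooted at the point whose convex hull with all branch growth points is
   largest; per-branch shortest paths; main-stem identification; fusion of
   every point onto its nearest skeleton polyline.
5. **Traits** per tassel: branch count; per-branch length L (polyline from
   distal tip to branch base), insertion angle θ (near-base secant vs local
   stem direction, degrees), curvature L/‖chord‖ ≥ 1; tassel convex-hull
   volume (cm³); dispersion = mean(θ)/(π/2) with θ in radians.

A parametric generator produces synthetic tassels (quadratic-Bézier branches
with analytic length/angle/curvature ground truth, tip labels, colors,
optional outliers), so the whole pipeline is testable offline.

## Worked example

```r
library(tasselseg)

# a synthetic tassel with known ground truth (noiseless for clarity)
gt  <- generate_tassel(tassel_spec(radial_jitter_sd = 0, seed = 7))
gt$truth$traits$branch_count
#> [1] 15

# full pipeline in ground-truth-tips mode
res <- run_pipeline(gt$cloud, pipeline_config(), checkpoint = "ground-truth-tips")
res$traits$branch_count
#> [1] 15
round(sort(res$traits$branch_lengths), 2)
#>  [1] 13.48 13.58 13.77 15.37 17.58 17.66 20.21 20.72 22.58 23.75 24.08 24.42
#> [13] 24.54 25.37 25.66
round(sort(gt$truth$traits$branch_lengths), 2)   # generator truth
#>  [1] 13.26 13.74 13.84 15.48 17.74 17.82 20.09 20.88 22.56 23.18 23.87 24.40
#> [13] 24.46 25.28 25.48
trait_row(res$traits, "demo")[, c("branch_count", "branch_length_mean",
                                  "branch_angle_mean", "tassel_volume_cm3")]
#>   branch_count branch_length_mean branch_angle_mean tassel_volume_cm3
#> 1           15           20.18473          47.43997          12587.56
```

The measured branch count matches the generator's 15 branches and the sorted
branch lengths agree with the analytic truth to a few millimetres; the
recovery criteria (length error ≤ 5%, angle error ≤ 5°, exact counts on
≥ 18/20 tassels) are enforced in `tests/testthat/test-acceptance.R`.

Training the tip network on synthetic data:

```r
clouds <- lapply(1:8, function(i) {
  gt <- generate_tassel(tassel_spec(seed = 100 + i))
  estimate_normals(random_downsample(gt$cloud, 1024, seed = i), 16L)
})
fit <- train_tipnet(init_tipnet(reduced_network_config(), seed = 1), clouds,
                    config = train_config(batch_size = 2, epochs = 50, seed = 1))
tail(fit$history, 1)
#>    epoch      lr       loss  accuracy
#> 50    49 0.00025 0.08953993 0.9696045
```

## Command line

An executable wrapper is installed at
`system.file("cli", "tasselseg", package = "tasselseg")`:

```sh
tasselseg simulate --n 3 --seed 1 --out data/
tasselseg run --in data/ --out results/        # ground-truth-tips mode
tasselseg train --data data/ --out model.rds --epochs 50
tasselseg segment --checkpoint model.rds --in cloud.ply --out labeled.ply
```

Subcommands: `simulate`, `preprocess`, `train`, `segment`, `cluster`,
`skeletonize`, `traits`, `run`; `--config file.json` supplies a
`pipeline_config()` that individual flags override.

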