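# frontfish

Quantifying RNA accumulation at the invasive front of leader cells.

During collective 3D invasion, strands of tumor cells are headed by
*leader cells* whose front cytoplasm protrudes into the extracellular
matrix. Specific transcripts (such as *RAB13* and *NET1*) accumulate at
this invasive front, while a co-detected control RNA stays diffuse.
frontfish is an R package for the image-quantification chain behind such
findings, aimed at groups doing smFISH on invasive spheroids, single
cells, or tissue sections:

* **Normalized front distance** — for each RNA spot *i*, the distances to
  the manually drawn invasive edge (*Id<sub>i</sub>*) and nuclear edge
  (*Nd<sub>i</sub>*) give *d<sub>i</sub>* = *Id<sub>i</sub>* /
  (*Id<sub>i</sub>* + *Nd<sub>i</sub>*) ∈ [0, 1] (0 = invasive edge,
  1 = nuclear edge); per-cell means are compared against the internal
  control by the Wilcoxon signed-rank test, across conditions by
  ANOVA/Dunnett or Kruskal–Wallis/Dunn, and summarized as
  boundary-reflected probability densities on [0, 1].
* **Spheroid invasion complexity** — perimeter² / (4π · area), the
  reciprocal isoperimetric quotient: 1 for a circle, higher for branched
  (more invasive) silhouettes; includes segmentation and sub-pixel
  contour measurement.
* **Perimeter intensity profiles** — ECM-stain intensity along the
  front-cytoplasm contour as signed arc length from the protrusion tip,
  aggregated across cells with a t-based 95% confidence band.
* **Peripheral Distribution Index (PDI)** — second-moment ratio about the
  nucleus centroid against a uniform-cytoplasm reference; 1 = diffuse,
  \> 1 = peripheral.
* **GA-content scan** — sliding-window %GA along a 3'UTR with GA-rich
  region calling, for positioning antisense morpholinos.
* **smFISH spot detection** — single-scale Laplacian-of-Gaussian detector
  with robust thresholding and sub-pixel localization.
* **Synthetic scenes** — seeded leader-cell geometries whose spot
  distances follow a chosen Beta law, rendered channels, and branched
  spheroid silhouettes with exact polygon ground truth, so the whole
  pipeline is verifiable without raw images.

## Worked example

Simulate a leader-cell scene with a front-biased target RNA
(Beta(2, 6) normalized distances, mean 0.25) and a uniform internal
control, detect spots, and recover the bias:

```r
library(frontfish)

cfg <- scene_config(seed = 42)           # 25 spots/species, SNR 8
scene <- make_leader_scene(cfg)

det <- detect_spots(scene$rendered$target, spot_params(scale_um = 0.15),
                    mask = scene$cell_mask)
det
#> <spot_set: 23 spots from channel 'target'>

rec <- spot_edge_distances(det, scene$edge_annotation)
head(rec, 3)
#>   spot_id species Id_um Nd_um L_um     d
#> 1       1  target  4.97  20.0   25 0.199
#> 2       2  target  8.87  16.1   25 0.355
#> 3       3  target  8.04  17.0   25 0.322

summarize_cell(rec, cell_id = "scene42")
#>   cell_id species n_spots mean_d
#> 1 scene42  target      23  0.302
```

The per-spot `d` runs from 0 at the invasive edge to 1 at the nuclear
edge, so a mean of 0.30 means this cell's target RNA sits well toward the
invasive front. Across 12 simulated cells, the paired comparison against
the internal control separates cleanly:

```r
cells <- lapply(1:12, function(s) {
  sc <- make_leader_scene(scene_config(seed = s))
  sapply(c("target", "control"), function(sp) {
    d <- detect_spots(sc$rendered[[sp]], spot_params(scale_um = 0.15),
                      mask = sc$cell_mask)
    mean(spot_edge_distances(d, sc$edge_annotation)$d)
  })
})
m <- do.call(rbind, cells)
paired_shift_test(data.frame(cell_id = 1:12, mean_d = m[, "target"]),
                  data.frame(cell_id = 1:12, mean_d = m[, "control"]))
#> $n_pairs  12
#> $statistic  0
#> $p_value  0.000488
#> $median_paired_difference  -0.227
```

The target's grand mean (0.255) recovers the generative Beta(2, 6) mean
of 0.25; the control sits at 0.492 ≈ 0.5, and the signed-rank test
rejects with the smallest p attainable at n = 12. Silhouette complexity
ranks invasiveness:

```r
make_spheroid_silhouette(n_branches = 0, seed = 1)$complexity  # 1.000
make_spheroid_silhouette(n_branches = 6, seed = 1)$complexity  # 6.132
```

and the GA scan calls the GA-rich half of a synthetic UTR:

```r
prof <- ga_window_profile(paste0(strrep("GA", 25), strrep("CT", 25)),
                          window_nt = 30)
call_ga_rich_regions(prof, threshold_percent = 60)
#>   start end max_percent_ga
#> 1     0  62            100
```

A command-line layer over the same functions is installed at
`inst/scripts/frontfish.R` (subcommands `simulate`, `spots`,
`front-distance`, `complexity`, `profile`, `pdi`, `ga-scan`, `run
--config config.yaml`), emitting CSV tables and a JSON run manifest.

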