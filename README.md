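# pgcquant

Quantitative phenotyping of primordial germ cells (PGCs) from multi-channel
3D fluorescence stacks, for developmental biologists counting and
characterizing migratory germ cells in wholemount embryos and in culture.

PGCs are detected in a marker channel (GCNA or SSEA1) by
standard-deviation intensity thresholding (`I > mean + k·SD`, k ∈ 3.2–3.7),
hole filling, 26-connected labelling, exclusion of objects under 20 µm³,
size-guided splitting of touching cells (guides 200/750 µm³), and a
cluster-aware count estimate: clustered volume is divided by the average
cell volume (300 µm³), and when clusters exceed 20% of total volume the
whole volume is divided instead. Cultured cells are characterized by the
Elongation Index

    EI = (A_Long − A_Short) / (A_Long + A_Short)

measured on the largest cross-sectional plane, the folded angle
θ = arccos|⟨axis, gradient⟩| ∈ [0°, 90°] between the long axis and an
SCF/KitL gradient, and Golgi/centrosome polarity Classes I–IV. Downstream
statistics: population doubling time `T_d = Δt·ln2/ln(N₂/N₁)`, Student's t,
Fisher's exact, and two orientation-uniformity tests. A seeded synthetic
generator supplies ground-truthed stacks and culture fields so every stage
is testable without microscope data.

## Worked example

```r
library(pgcquant)

# a ground-truthed stack: 80 ellipsoidal cells (~300 um^3), 20% in
# touching clusters, blur + noise, plus PHH3/cPARP marker subsets
sc  <- scene_config(n_cells = 80, stack_shape = c(32L, 200L, 200L),
                    volume_range = c(150, 430), cell_volume_cv = 0.15,
                    cluster_fraction = 0.2, seed = 42)
out <- generate_stack(sc)
out$stack
#> <intensity_stack> 32 x 200 x 200 voxels (z y x), 3 channel(s): GCNA, PHH3, cPARP
#>   voxel size (um): 1 x 1 x 1; voxel volume 1 um^3

# counting chain, calibrated to the generator's stated world
cfg <- counting_config(size_guide = c(GCNA = 300), v_avg = 300,
                       single_cell_max = 450)
res <- count_cells(out$stack, "GCNA", cfg)
res$estimate
#> <count_estimate> n_total = 80 (singles 80, from clusters 0; clustered volume fraction 0.0%)
```

The estimate equals the true 80 cells: the touching clusters were split by
distance-transform-seeded geodesic partition before counting.

```r
# apoptotic co-label frequency with exact binomial CI
colabel_fraction(res$objects, out$stack, colabel_criteria("cPARP"))
#> <colabel_result> 7 / 80 positive = 8.8% (95% CI 3.6-17.2%)
# (the generator's truth table also flags exactly those 7 cells)

# doubling time from two counts 30 h apart
round(doubling_time(551, 2598, 30), 1)
#> [1] 13.4

# a gradient-aligned culture field and its orientation statistics
f  <- generate_culture_field(
  scene_config(n_cells = 100, stack_shape = c(1L, 600L, 600L),
               voxel_size = c(1, 0.5, 0.5),
               orientation_concentration = 4, seed = 42))
r2 <- count_cells(f$stack, "GCNA",
                  counting_config(size_guide = c(GCNA = 30), v_avg = 40,
                                  v_min = 5, single_cell_max = 90))
sh <- measure_cells(r2$objects, gradient_axis = f$gradient_axis)
round(mean(sh$ei), 3)
#> [1] 0.153
angle_uniformity_test(sh$theta_deg, "rayleigh_axial")
#> z = 10.37, p = 1.65e-25  (***)
```

A concentration of κ = 4 about the gradient is detected decisively; with
κ = 0 the folded angles are uniform on [0°, 90°) and the test holds its
5% level (verified over 1000 simulations in the acceptance suite).

## Command line

```sh
inst/cli/pgcquant simulate --n-cells 50 --seed 1 --out scene
inst/cli/pgcquant count --stack scene.stack.txt --size-guide 300 \
    --v-avg 300 --single-cell-max 450 --out counts
inst/cli/pgcquant stats --test doubling --n1 551 --n2 2598 --dt 30 --out td
```

Subcommands: `simulate`, `count`, `colabel`, `shape`, `classify`, `stats`,
`run`. Exit codes: 0 ok, 2 configuration, 3 I/O, 4 computation.

## Package layout

- `R/synthetic.R` — scene configuration and the stack / culture-field
  generators with truth tables
- `R/segment.R` — thresholding, hole filling, labelling, size exclusion,
  splitting, count estimation
- `R/coloc.R`, `R/morpho.R`, `R/polarity.R`, `R/stats.R` — co-labeling,
  morphometry, polarity classes, statistics
- `R/io.R`, `R/pipeline.R`, `R/cli.R` — text/CSV/JSON I/O, the end-to-end
  pipeline, the CLI dispatcher
- `src/primitives.cpp` — 3D connected components, hole fill, Euclidean
  distance transform, separable Gaussian blur, geodesic partition
- `vignettes/pgc-phenotyping-methods.Rmd` — the methods vignette
  (models, assumptions, parameter defaults, limitations)
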