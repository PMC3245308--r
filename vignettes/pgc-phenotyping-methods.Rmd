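---
title: "Methods: 3D germ-cell counting and phenotyping in pgcquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D germ-cell counting and phenotyping in pgcquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgcquant)
```

## The problem

Primordial germ cells (PGCs) migrate from the embryonic hindgut through the
dorsal mesentery into the genital ridges. Quantifying this process from
wholemount confocal stacks requires (i) counting hundreds to thousands of
marker-positive cells in 3D, where many cells touch; (ii) measuring per-cell
frequencies of co-labels such as mitotic (PHH3) and apoptotic (cPARP)
markers; (iii) morphometry of cultured cells responding to a Stem Cell
Factor (SCF/KitL) gradient — elongation and orientation; (iv) classifying
Golgi/centrosome polarity; and (v) a small set of downstream statistics.
`pgcquant` implements that protocol as open, seeded, testable code, driven
by a synthetic generator that provides exact ground truth.

## The counting protocol

Detection operates on one channel (GCNA or SSEA1) of an `intensity_stack`:

1. **SD threshold.** A voxel is foreground iff
   `I > mean + k_sd * SD`, with mean and *population* SD taken over all
   voxels of the channel, background included. `k_sd` defaults to 3.5, the
   midpoint of the protocol's working range 3.2–3.7. The population SD and
   the strictly-greater comparison are pinned decisions: the original
   commercial tool does not document its convention, a global-image
   statistic is the reproducible reading, and strictness guarantees a
   constant channel yields an empty mask rather than a flooded one.
2. **Hole filling.** Background cavities with no 6-connected path to the
   stack border become foreground (3D).
3. **Labelling.** Maximal 26-connected components; 26-connectivity is the
   common blob-detection default and is stated explicitly because the
   original software's choice is unknown. Volumes are physical
   (`voxel count × voxel volume`, µm³).
4. **Size exclusion.** Objects strictly under `v_min = 20` µm³ are removed
   ("under 20 excluded" keeps an exactly-20 object). This step runs again
   after splitting, mirroring the protocol.
5. **Size-guided splitting.** Objects above the single-object cutoff
   (`single_cell_max`) are re-partitioned into
   `n = max(1, round(volume / size_guide))` connected pieces
   (`size_guide` = 200 µm³ for GCNA, 750 for SSEA1; rounding is half away
   from zero). Seeds are peaks of the anisotropy-aware Euclidean distance
   transform, ordered by depth with lexicographic `(z, y, x)` tie-breaks and
   a minimum mutual separation of 1.5 guide-equivalent radii (halved until
   enough peaks exist); voxels join the geodesically nearest seed, so child
   volumes sum exactly to the parent. The trigger is `single_cell_max`, not
   `size_guide` itself: with a 200 µm³ guide and 300 µm³ average cells, a
   guide-based trigger would split typical single cells in two, which
   contradicts the protocol's own recovery behaviour.
6. **Count estimation.** Objects at or below `single_cell_max` count one
   cell each. Clustered objects are summed and divided by the average cell
   volume `v_avg` (300 µm³ for GCNA; at least one cell per clustered
   object). If the clustered volume exceeds 20% of the total measured
   volume, the fallback applies: total volume / `v_avg`.

`single_cell_max` defaults to `2 × size_guide`. The protocol determined
this cutoff by visual inspection per specimen; we expose it as a knob, and
in tests calibrate it to 450 µm³ against the generator's truth volume range
(150–430 µm³) — the in-silico analogue of that visual inspection step.

## Co-labeling

An object is marker-positive iff its mean marker intensity exceeds the
marker channel's `mean + k_marker × SD` *and* at least
`min_overlap_fraction` (default 0.5) of its voxels individually do. The
original protocol names "intensity and colocalization functions" without
formulas; the dual rule covers both readings and both knobs are exposed.
Frequencies are reported with totals and exact Clopper–Pearson 95%
intervals because the compared groups are small.

## Morphometry

For 3D objects, axes are measured on the single z-plane of largest
cross-sectional area (ties resolved toward the object's centroid z) —
no z-extent enters, matching the in-vivo protocol's stated practice. On
that plane, the long axis is the maximal caliper width over a dense angular
sweep (0.25° steps over hull points; for a convex body this equals the
maximal chord, i.e. the Feret diameter), and the short axis is the maximal
extent orthogonal to it — through the whole body mask, not through a
midpoint, which is robust to crescent shapes. Widths are pixel-centre
spreads: centres undershoot a smooth boundary by up to one pixel per axis,
but the shared bias cancels in the Elongation Index

\[ EI = \frac{A_{Long} - A_{Short}}{A_{Long} + A_{Short}} \in [0, 1), \]

and a direction-dependent footprint correction was tested and rejected (it
biases the short axis when the long direction is quantization-limited; the
measured worst-case EI error on analytic ellipses with ≥10 px short axes is
< 0.02 either way, but smaller without it). Filopodia/lamellipodia are
excluded by morphological opening with a physical disk of radius `r_open`
(default 1 µm — filopodia are sub-micron-wide); an opening that erases the
mask is an error naming `r_open`.

Orientation to a gradient is axial: `θ = arccos |⟨axis, gradient⟩|`
∈ [0°, 90°], invariant to sign flips of either vector.

## Polarity classes

Classification is a fixed rule order: Class IV (dispersed Golgi,
`≥ dispersal_min_foci` foci, default 3) → Class III (round cell,
`EI < ei_round_threshold`) → Class I (principal Golgi centroid projected on
the long axis within `pole_margin` = 0.5 µm of, or beyond, a nuclear
extreme) → Class II (central) — so every classifiable record maps to
exactly one class. `ei_round_threshold` defaults to 0.10, midway between
the reported round (~0.044) and elongated (~0.169) culture means; the
original round/elongated criterion is unstated, so this is a documented
knob. The centrosome is a consistency check only (flag when >3 µm from the
Golgi, since the two are reported co-localized), never a classification
input. A second summary pools Classes I+III as "asymmetric Golgi", since
round Class III cells also carry eccentric organelles.

## Statistics

* Doubling time `T_d = Δt·ln2 / ln(N₂/N₁)`; negative under decline,
  infinite (with warning) when counts are equal. The wild-type worked
  example (551 → 2598 PGCs in 30 h) gives 13.4 h; the slow-growth example
  (443 → 1243) gives 20 h.
* Student's t (pooled variance, two-sided) is the default, matching the
  protocol's label; Welch is exposed.
* Fisher's exact test sums hypergeometric probabilities of all
  fixed-margin tables no more probable than the observed one (conventional
  `1 + 1e-7` tie tolerance), from an in-package log-factorial table.
* Orientation uniformity has two labelled methods, because the original
  test is unnamed: a one-sample KS test against Uniform(0°, 90°), and an
  axial concentration test. For the latter note that folded angles make the
  sine component of the doubled-angle resultant non-identified
  (E[sin 2θ] ≠ 0 under uniformity), so the classical Rayleigh statistic is
  miscalibrated; we use the V-test-type statistic
  `z = mean(cos 2θ)·√(2n)`, standard normal under uniformity, one-sided
  toward alignment at 0°. p-values are stored un-truncated; the figure-style
  star bins exist only in report rendering.

## The synthetic world

`generate_stack()` emulates a wholemount stack: freely oriented triaxial
ellipsoids (semi-axis ratios uniform on [0.7, 1]) with gamma-distributed
volumes of mean 300 µm³ (the protocol's average PGC volume) and CV 0.2,
painted at intensity 150 on background 20, blurred by an isotropic physical
Gaussian (σ = 0.5 µm, a simple PSF stand-in), then clipped additive
Gaussian noise (SD 5 — SNR 26, comfortably above the SNR ≥ 5 regime the
recovery property assumes). Marker-positive subsets are Bernoulli flags
(defaults PHH3 4%, cPARP 12%, matching reported mitotic/apoptotic
frequencies in order of magnitude). Clustered cells are placed touching —
the next member sits at 0.92× the sum of the two ellipsoid supports along a
random direction, guaranteeing mask overlap whatever the orientations.
Placement is rejection sampling with a 2000-attempt budget; exceeding it is
an explicit error naming the budget.

`generate_culture_field()` emulates culture beside an SCF source strip: a
single-plane field of ellipses whose EI is drawn from a truncated normal
(default mean 0.15, SD 0.08, near the reported 20 h SCF mean) and whose
long-axis offsets from the gradient follow an axial von-Mises-type law —
a von Mises angle on the doubled circle, halved, so the distribution has
period 180° and κ = 0 gives folded angles uniform on [0°, 90°). The paper
specifies only the folded-angle readout; the generative model is ours.

What a green test does *not* establish: the generator has no spectral
bleed-through, depth attenuation, uneven illumination, or tissue context,
and its intensity statistics are calibrated only to make the SD-threshold
protocol meaningful, not to match any microscope. Recovery results
therefore validate the algorithmic chain, not performance on real stacks.

## Numerical choices and edge cases

* Rounding of counts and split multiplicities is half-away-from-zero
  (base R `round()` is banker's).
* Coordinates are 0-based physical (z, y, x) with voxel-centre convention;
  volumes always physical µm³.
* Degenerate inputs have defined behaviour: constant channel → empty mask
  + warning; empty object list → count 0, co-label percentage `NA` +
  warning; equal counts → infinite doubling time + warning; identical
  constant groups → t = 0, p = 1; missing Golgi → unclassifiable, distinct
  from Classes I–IV.
* All randomness flows from a single integer seed; identical config + seed
  is bit-identical, and stage sub-seeds are derived deterministically.

## File formats

No offline R TIFF reader exists in the supported environment, so stacks
serialize to a documented plain-text format (JSON header; per-channel,
per-slice numeric rows; lossless at double precision) via `write_stack()` /
`read_stack()`, truth tables and per-object tables to CSV, and
configurations to JSON. The CLI front-end (`inst/cli/pgcquant`, or
`pgcq_cli()` programmatically) exposes `simulate`, `count`, `colabel`,
`shape`, `classify`, `stats` and `run`, with exit codes 0 (ok),
2 (configuration), 3 (I/O), 4 (computation).

## Known limitations

* The split-and-divide estimator is intentionally approximate on heavily
  clustered material; the documented tolerance is 15% at cluster fractions
  ≤ 0.3, and the 20% fallback inherits the accuracy of `v_avg`.
* Axis measurement reports caliper widths of pixel-centre sets; absolute
  lengths carry up to one pixel of quantization (the EI does not).
* The orientation tests assume independent cells; fields with strong
  spatial correlation would need a per-field summary first.
* 3D EI uses the largest plane only, by design; strongly z-tilted cells are
  foreshortened, exactly as in the original measurement.
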