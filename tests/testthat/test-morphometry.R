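test_that("largest_plane finds the equator of spheres and ellipsoids", {
  m <- ellipsoid_mask(c(15L, 15L, 15L), c(8, 8, 8), c(5, 5, 5))
  obj <- label_objects(m, mask_stack(m))
  expect_identical(largest_plane(obj, 1L), 8L)
  # ellipsoid centred at z = 10 with c = 5 in a taller stack
  m2 <- ellipsoid_mask(c(20L, 15L, 15L), c(10, 8, 8), c(5, 4, 6))
  o2 <- label_objects(m2, mask_stack(m2))
  expect_identical(largest_plane(o2, 1L), 10L)
})

test_that("largest_plane equals the brute-force slice-area maximum", {
  sc <- recovery_scene(10, 31)
  out <- generate_stack(sc)
  m <- fill_holes(sd_threshold_mask(out$stack, "GCNA", 3.5))
  obj <- exclude_small(label_objects(m, out$stack, 450), 20)
  lab <- attr(obj, "label_array")
  for (l in obj$label) {
    areas <- apply(lab == l, 1, sum)
    expect_identical(unname(areas[largest_plane(obj, l)]), max(areas))
  }
})

test_that("axes of a disk: both calipers equal the diameter", {
  ax <- measure_axes(disk_mask(5, c(1, 1)), c(1, 1))
  expect_lt(abs(ax$a_long - 10), 1)
  expect_lt(abs(ax$a_short - 10), 1)
  # anisotropic pixels
  ax2 <- measure_axes(disk_mask(5, c(0.5, 0.5)), c(0.5, 0.5))
  expect_lt(abs(ax2$a_long - 10), 0.5)
  expect_lt(abs(ax2$a_short - 10), 0.5)
})

test_that("axes of an ellipse match analytic geometry", {
  ax <- measure_axes(ellipse_mask(10, 4, c(1, 1)), c(1, 1))
  expect_lt(abs(ax$a_long - 20), 1)
  expect_lt(abs(ax$a_short - 8), 1)
  expect_gt(abs(ax$long_axis_dir[2]), 0.98)   # x-aligned
})

test_that("protrusion exclusion removes a thin spike (compare to bare disk)", {
  px <- c(0.5, 0.5)
  d <- disk_mask(5, px, pad = 14)
  bare <- measure_axes(d, px)
  spiky <- d
  mid <- (nrow(d) + 1) / 2
  spike_cols <- (ncol(d) - 8):ncol(d)
  spiky[mid, spike_cols] <- TRUE          # 1-px-wide filopodium
  with_spike <- measure_axes(spiky, px)
  expect_gt(with_spike$a_long, bare$a_long + 2)
  opened <- measure_axes(spiky, px, exclude_protrusions = TRUE, r_open = 1)
  expect_lt(abs(opened$a_long - bare$a_long), 1.01)
  expect_lt(abs(opened$a_short - bare$a_short), 1.01)
})

test_that("opening that erases the mask names r_open in the failure", {
  tiny <- matrix(FALSE, 9, 9); tiny[5, 5] <- TRUE
  expect_error(measure_axes(tiny, c(1, 1), exclude_protrusions = TRUE,
                            r_open = 2), "r_open = 2")
})

test_that("elongation_index follows the closed form and its domain", {
  expect_identical(elongation_index(5, 5), 0)
  expect_identical(elongation_index(3, 1), 0.5)
  expect_equal(elongation_index(10, 5), 1 / 3)
  expect_equal(elongation_index(2, 1), 1 / 3)    # scale invariance
  expect_error(elongation_index(1, 0), "a_short")
  expect_error(elongation_index(1, 2), "a_long")
})

test_that("orientation_angle folds to [0, 90] and ignores axis sign", {
  expect_equal(orientation_angle(c(1, 0), c(1, 0)), 0)
  expect_equal(orientation_angle(c(0, 1), c(1, 0)), 90)
  expect_equal(orientation_angle(c(-1, -1), c(1, 0)), 45)
  for (seed in 1:10) {
    v <- pgcquant:::with_seed(seed, rnorm(2))
    g <- pgcquant:::with_seed(seed + 100, rnorm(2))
    th <- orientation_angle(v, g)
    expect_gte(th, 0); expect_lte(th, 90)
    expect_equal(orientation_angle(-v, g), th)
    expect_equal(orientation_angle(v, -g), th)
  }
  expect_error(orientation_angle(c(0, 0), c(1, 0)), "zero vector")
})

test_that("EI of analytic ellipse masks is within 0.02 of closed form", {
  px <- c(0.5, 0.5)
  cases <- rbind(c(5, 5), c(6, 4), c(8, 3), c(10, 2.5), c(7, 5), c(12, 6))
  for (i in seq_len(nrow(cases))) {
    a <- cases[i, 1]; b <- cases[i, 2]
    for (ang in c(0, 17, 45, 73)) {
      # short axis >= 10 px across: 2*b/0.5 >= 10 for all cases
      ax <- measure_axes(ellipse_mask(a, b, px, angle_deg = ang), px)
      ei <- elongation_index(ax$a_long, ax$a_short)
      expect_lt(abs(ei - (a - b) / (a + b)), 0.02)
    }
  }
})

test_that("measure_axes is invariant to translation and 90-degree rotation", {
  px <- c(1, 1)
  m <- ellipse_mask(8, 4, px, angle_deg = 30)
  base <- measure_axes(m, px)
  # translation: pad asymmetrically
  shifted <- rbind(matrix(FALSE, 5, ncol(m)), m)
  shifted <- cbind(shifted, matrix(FALSE, nrow(shifted), 7))
  tr <- measure_axes(shifted, px)
  expect_equal(tr$a_long, base$a_long)
  expect_equal(tr$a_short, base$a_short)
  # 90-degree rotation (transpose + flip)
  rot <- t(m)[ncol(m):1, ]
  rr <- measure_axes(rot, px)
  expect_lt(abs(rr$a_long - base$a_long), 1)
  expect_lt(abs(rr$a_short - base$a_short), 1)
})

test_that("measure_cells recovers generator EI on a culture field", {
  f <- generate_culture_field(
    scene_config(n_cells = 30, stack_shape = c(1L, 360L, 360L),
                 voxel_size = c(1, 0.5, 0.5),
                 ei_distribution = c(0.25, 0.1), seed = 41))
  res <- count_cells(f$stack, "GCNA",
                     counting_config(size_guide = c(GCNA = 30), v_avg = 40,
                                     v_min = 5, single_cell_max = 90))
  expect_identical(nrow(res$objects), 30L)
  sh <- measure_cells(res$objects, gradient_axis = f$gradient_axis)
  # match measured objects to truth by centroid
  truth <- f$truth
  match_id <- vapply(seq_len(nrow(sh)), function(i) {
    d2 <- (truth$cy_um - res$objects$centroid_y_um[i])^2 +
      (truth$cx_um - res$objects$centroid_x_um[i])^2
    which.min(d2)
  }, integer(1))
  err <- abs(sh$ei - truth$ei[match_id])
  expect_lt(median(err), 0.03)
  # orientation of clearly elongated cells matches truth within 10 degrees
  el <- truth$ei[match_id] > 0.15
  if (any(el)) {
    dth <- abs(sh$theta_deg[el] - truth$theta_deg[match_id][el])
    expect_lt(median(dth), 10)
  }
})
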