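test_that("empty scene gives an empty truth table and pure background", {
  sc <- scene_config(n_cells = 0, stack_shape = c(8L, 16L, 16L),
                     noise_sd = 0, blur_sigma = 0, seed = 1)
  out <- generate_stack(sc)
  expect_identical(nrow(out$truth), 0L)
  expect_true(all(get_channel(out$stack, "GCNA") == sc$background_level))
})

test_that("identical config and seed reproduce stacks bit-for-bit", {
  sc <- scene_config(n_cells = 12, stack_shape = c(16L, 64L, 64L), seed = 7)
  a <- generate_stack(sc)
  b <- generate_stack(sc)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth, b$truth)
})

test_that("truth volumes match the analytic ellipsoid volume and calibrate
           to cell_volume_mean", {
  sc <- scene_config(n_cells = 100, stack_shape = c(40L, 220L, 220L),
                     cell_volume_mean = 300, cell_volume_cv = 0.1, seed = 11)
  out <- generate_stack(sc)
  with(out$truth, expect_equal(volume_um3, 4 / 3 * pi * sa_um * sb_um * sc_um))
  expect_lt(abs(mean(out$truth$volume_um3) - 300) / 300, 0.10)
  # and within 2 standard errors, the stated calibration bound
  se <- sd(out$truth$volume_um3) / sqrt(nrow(out$truth))
  expect_lt(abs(mean(out$truth$volume_um3) - 300), 2 * se)
})

test_that("marker-positive cells are bright inside their own mask", {
  sc <- scene_config(n_cells = 40, stack_shape = c(28L, 130L, 130L),
                     marker_positive_fraction = c(PHH3 = 0.5), seed = 3)
  out <- generate_stack(sc)
  ph <- get_channel(out$stack, "PHH3")
  d <- dim(ph)
  for (i in which(out$truth$PHH3_pos)) {
    r <- out$truth[i, ]
    ctr <- round(c(r$cz_um, r$cy_um, r$cx_um) / sc$voxel_size)
    box <- ph[max(1, ctr[1] - 1):min(d[1], ctr[1] + 1),
              max(1, ctr[2] - 1):min(d[2], ctr[2] + 1),
              max(1, ctr[3] - 1):min(d[3], ctr[3] + 1)]
    expect_gt(mean(box), sc$background_level + 3 * sc$noise_sd)
  }
  # negative cells stay at background in the marker channel
  neg <- which(!out$truth$PHH3_pos)[1]
  r <- out$truth[neg, ]
  ctr <- round(c(r$cz_um, r$cy_um, r$cx_um) / sc$voxel_size)
  expect_lt(ph[ctr[1], ctr[2], ctr[3]],
            sc$background_level + 6 * sc$noise_sd)
})

test_that("cells sharing a cluster id form a single connected component", {
  sc <- scene_config(n_cells = 20, stack_shape = c(30L, 110L, 110L),
                     cluster_fraction = 0.5, noise_sd = 0, blur_sigma = 0,
                     seed = 9)
  out <- generate_stack(sc)
  m <- get_channel(out$stack, "GCNA") > sc$background_level
  lab <- pgcquant:::.cc_label_3d(m, 26L)
  d <- dim(lab)
  for (cid in unique(na.omit(out$truth$cluster_id))) {
    mem <- out$truth[which(out$truth$cluster_id == cid), ]
    comp <- vapply(seq_len(nrow(mem)), function(j) {
      v <- round(c(mem$cz_um[j], mem$cy_um[j], mem$cx_um[j]) / sc$voxel_size)
      lab[v[1], v[2], v[3]]
    }, integer(1))
    expect_true(all(comp > 0L))
    expect_length(unique(comp), 1L)
  }
})

test_that("placement failure names the attempt budget", {
  sc <- scene_config(n_cells = 80, stack_shape = c(10L, 24L, 24L), seed = 1)
  expect_error(generate_stack(sc), "placement-attempt budget \\(2000\\)")
})

test_that("scene_config rejects invalid parameters", {
  expect_error(scene_config(n_cells = -1), "n_cells")
  expect_error(scene_config(voxel_size = c(1, 0, 1)), "voxel_size")
  expect_error(scene_config(cluster_fraction = 1.2), "\\[0, 1\\]")
  expect_error(scene_config(orientation_concentration = -1), "kappa")
})

test_that("kappa = 0 field orientations are uniform on [0, 90) after folding", {
  th <- pgcquant:::with_seed(21, abs(sample_axial_angles(10000, 0)))
  ks <- suppressWarnings(ks.test(th, "punif", 0, 90))
  expect_gt(ks$p.value, 0.01)
  # and the full culture field's truth passes the same check at n = 300
  f <- generate_culture_field(
    scene_config(n_cells = 300, stack_shape = c(1L, 900L, 900L),
                 orientation_concentration = 0, seed = 5))
  expect_gt(suppressWarnings(ks.test(f$truth$theta_deg, "punif", 0, 90))$p.value,
            0.01)
})

test_that("large kappa concentrates folded angles near zero", {
  th <- pgcquant:::with_seed(22, abs(sample_axial_angles(100, 100)))
  expect_lt(mean(th), 10)
})

test_that("a one-cell field is reproducible and has exactly one mask", {
  sc <- scene_config(n_cells = 1, stack_shape = c(1L, 60L, 60L),
                     orientation_concentration = 2, seed = 13)
  a <- generate_culture_field(sc)
  b <- generate_culture_field(sc)
  expect_identical(a$stack, b$stack)
  expect_identical(nrow(a$truth), 1L)
  m <- get_channel(a$stack, "GCNA") > 80
  expect_identical(attr(pgcquant:::.cc_label_3d(m, 26L), "n_components"), 1L)
})

test_that("culture field rejects negative kappa and zero gradient", {
  sc <- scene_config(n_cells = 2)
  sc$orientation_concentration <- -2
  expect_error(generate_culture_field(sc), "kappa")
  sc2 <- scene_config(n_cells = 2, gradient_axis = c(0, 0))
  expect_error(generate_culture_field(sc2), "gradient_axis")
})

test_that("field truth EI matches the drawn semi-axes", {
  f <- generate_culture_field(
    scene_config(n_cells = 40, stack_shape = c(1L, 420L, 420L),
                 ei_distribution = c(0.2, 0.1), seed = 17))
  expect_equal(f$truth$ei,
               (f$truth$sa_um - f$truth$sb_um) /
                 (f$truth$sa_um + f$truth$sb_um))
  expect_true(all(f$truth$theta_deg >= 0 & f$truth$theta_deg <= 90))
})
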