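test_that("sd_threshold_mask matches hand-computed mean/SD on a tiny stack", {
  a <- array(0, c(1, 2, 2))
  a[1, 2, 2] <- 10
  s <- as_stack(a)
  # mean 2.5, population SD sqrt(mean((x-2.5)^2)) = 4.330127
  m <- sd_threshold_mask(s, "GCNA", k_sd = 1)
  expect_identical(sum(m), 1L)
  expect_true(m[1, 2, 2])
  # threshold just above the bright voxel excludes it
  expect_identical(sum(sd_threshold_mask(s, "GCNA", k_sd = 1.74)), 0L)
})

test_that("constant channel yields an empty mask with a warning, not an error", {
  s <- as_stack(array(7, c(3, 4, 4)))
  expect_warning(m <- sd_threshold_mask(s, "GCNA", 3.5), "constant")
  expect_identical(sum(m), 0L)
})

test_that("threshold masks are nested in k_sd (monotonicity property)", {
  for (seed in 1:5) {
    a <- pgcquant:::with_seed(seed, array(rgamma(4 * 12 * 12, 2, 0.1),
                                          c(4L, 12L, 12L)))
    s <- as_stack(a)
    m32 <- sd_threshold_mask(s, "GCNA", 3.2)
    m35 <- sd_threshold_mask(s, "GCNA", 3.5)
    m37 <- sd_threshold_mask(s, "GCNA", 3.7)
    expect_true(all(m37 <= m35))
    expect_true(all(m35 <= m32))
  }
})

test_that("fill_holes turns a hollow shell solid and is idempotent", {
  shell <- array(FALSE, c(7, 7, 7))
  shell[2:6, 2:6, 2:6] <- TRUE
  shell[3:5, 3:5, 3:5] <- FALSE
  filled <- fill_holes(shell)
  expect_true(all(filled[2:6, 2:6, 2:6]))
  expect_identical(sum(filled), 125L)
  expect_identical(fill_holes(filled), filled)
  # a mask without cavities is unchanged
  solid <- ellipsoid_mask(c(9L, 9L, 9L), c(5, 5, 5), c(3, 3, 3))
  expect_identical(fill_holes(solid), solid)
})

test_that("an open channel reaching the border is not filled (flood oracle)", {
  # C-shaped cavity: tube through a block, open at the z = 1 face
  m <- array(TRUE, c(6, 7, 7))
  m[1:5, 4, 4] <- FALSE           # open channel to border
  filled <- fill_holes(m)
  # independent oracle: flood fill background from the border (6-conn) in R
  flood <- function(mask) {
    d <- dim(mask)
    outside <- array(FALSE, d)
    queue <- which(!mask & slice.index(mask, 1) %in% c(1, d[1]) |
                   !mask & slice.index(mask, 2) %in% c(1, d[2]) |
                   !mask & slice.index(mask, 3) %in% c(1, d[3]))
    outside[queue] <- TRUE
    repeat {
      grew <- FALSE
      idx <- which(outside)
      zyx <- arrayInd(idx, d)
      for (k in seq_len(nrow(zyx))) {
        for (dd in list(c(1,0,0), c(-1,0,0), c(0,1,0),
                        c(0,-1,0), c(0,0,1), c(0,0,-1))) {
          p <- zyx[k, ] + dd
          if (all(p >= 1) && all(p <= d) &&
              !mask[p[1], p[2], p[3]] && !outside[p[1], p[2], p[3]]) {
            outside[p[1], p[2], p[3]] <- TRUE
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    mask | !outside
  }
  expect_identical(filled, flood(m))
  expect_identical(filled, m)   # nothing enclosed, so unchanged
})

test_that("label_objects separates blobs and converts volumes to um^3", {
  m <- array(FALSE, c(5, 12, 12))
  m[2:4, 2:4, 2:4] <- TRUE
  m[2:4, 8:10, 8:10] <- TRUE
  s <- mask_stack(m, voxel_size = c(1, 0.5, 0.5))
  obj <- label_objects(m, s)
  expect_identical(nrow(obj), 2L)
  expect_equal(obj$volume_um3, rep(27 * 0.25, 2))
  # single voxel, anisotropic voxel size
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  o1 <- label_objects(m1, mask_stack(m1, voxel_size = c(1, 0.5, 0.5)))
  expect_equal(o1$volume_um3, 0.25)
  # mean intensity is attached per channel
  expect_equal(o1$mean_GCNA, 100)
})

test_that("object volumes conserve the foreground voxel count (oracle)", {
  for (seed in 1:5) {
    m <- pgcquant:::with_seed(seed,
      array(runif(6 * 15 * 15) < 0.25, c(6L, 15L, 15L)))
    vs <- c(1, 0.7, 0.4)
    obj <- label_objects(m, mask_stack(m, voxel_size = vs))
    expect_equal(sum(obj$volume_um3), sum(m) * prod(vs))
    expect_equal(sum(obj$n_voxels), sum(m))
  }
})

test_that("touching diagonal voxels are one object under 26-connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  obj <- label_objects(m, mask_stack(m))
  expect_identical(nrow(obj), 1L)
})

test_that("exclude_small drops strictly-under objects and keeps the boundary", {
  # volumes 15, 20, 300 as cubes of voxels with voxel volume 1
  m <- array(FALSE, c(30, 40, 12))
  m[1:15, 1, 1] <- TRUE                      # 15 voxels
  m[1:20, 10, 1] <- TRUE                     # 20 voxels
  m[1:10, 20:25, 3:7] <- TRUE                # 300 voxels
  obj <- label_objects(m, mask_stack(m))
  kept <- exclude_small(obj, v_min = 20)
  expect_identical(sort(kept$volume_um3), c(20, 300))
  # identity when everything passes
  expect_identical(nrow(exclude_small(kept, 20)), 2L)
  # label array was compacted consistently
  expect_identical(max(attr(kept, "label_array")), 2L)
})

test_that("exclude_small equals a brute-force filter on random volumes", {
  for (seed in 1:3) {
    m <- pgcquant:::with_seed(seed,
      array(runif(8 * 20 * 20) < 0.12, c(8L, 20L, 20L)))
    obj <- label_objects(m, mask_stack(m))
    v_min <- 3
    kept <- exclude_small(obj, v_min)
    expect_setequal(kept$volume_um3, obj$volume_um3[obj$volume_um3 >= v_min])
  }
})

test_that("split_touching leaves single-scale objects alone", {
  m <- ellipsoid_mask(c(14L, 14L, 14L), c(7, 7, 7), c(4.5, 4.5, 4.5))
  s <- mask_stack(m)
  obj <- label_objects(m, s)
  expect_lt(obj$volume_um3, 750)   # ~380 voxels
  out <- split_touching(obj, s, size_guide = 750)
  expect_identical(nrow(out), 1L)
  expect_equal(out$volume_um3, obj$volume_um3)
})

test_that("a dumbbell of two fused spheres splits into two conserved halves", {
  # two 750 um^3 spheres (r = 5.64 um) fused at 8 um separation
  r <- (3 * 750 / (4 * pi))^(1 / 3)
  m <- ellipsoid_mask(c(16L, 16L, 26L),
                      rbind(c(8, 8, 9), c(8, 8, 17)),
                      rbind(rep(r, 3), rep(r, 3)))
  s <- mask_stack(m)
  obj <- label_objects(m, s)
  expect_identical(nrow(obj), 1L)
  out <- split_touching(obj, s, size_guide = 750, single_cell_max = 1000)
  expect_identical(nrow(out), 2L)
  expect_equal(sum(out$volume_um3), obj$volume_um3)
  # each child is connected by construction; check roughly equal halves
  expect_lt(max(out$volume_um3) / min(out$volume_um3), 1.5)
})

test_that("split volumes always sum to the parent volume (property)", {
  for (seed in 1:4) {
    sc <- recovery_scene(25, seed, cluster_fraction = 0.4)
    out <- generate_stack(sc)
    m <- fill_holes(sd_threshold_mask(out$stack, "GCNA", 3.5))
    obj <- exclude_small(label_objects(m, out$stack, 450), 20)
    tot_before <- sum(obj$volume_um3)
    sp <- split_touching(obj, out$stack, 300, single_cell_max = 450)
    expect_equal(sum(sp$volume_um3), tot_before)
    expect_gte(nrow(sp), nrow(obj))
  }
})

test_that("estimate_count follows the printed rules, branch by branch", {
  cfg <- counting_config(v_avg = 300, single_cell_max = 600)
  # all singles
  est <- estimate_count(c(300, 280, 320), cfg)
  expect_identical(est$n_total, 3L)
  expect_false(est$fallback_used)
  expect_identical(est$n_single, 3L)
  # clustered 900 of 1200 = 75% > 20% -> fallback round(1200/300) = 4
  est2 <- estimate_count(c(300, 900), cfg)
  expect_true(est2$fallback_used)
  expect_identical(est2$n_total, 4L)
  expect_equal(est2$clustered_volume_fraction, 0.75)
  # 650/3050 ~ 21.3% > 20% -> fallback round(3050/300) = 10
  vols <- c(rep(300, 8), 650)
  est3 <- estimate_count(vols, cfg)
  expect_true(est3$fallback_used)
  expect_identical(est3$n_total, 10L)
  # raising the threshold to 25% switches branch: 8 + round(650/300) = 10
  cfg25 <- counting_config(v_avg = 300, single_cell_max = 600,
                           cluster_fraction_threshold = 0.25)
  est4 <- estimate_count(vols, cfg25)
  expect_false(est4$fallback_used)
  expect_identical(est4$n_single, 8L)
  expect_identical(est4$n_from_clusters, 2L)
  expect_identical(est4$n_total, 10L)
})

test_that("estimate_count is invariant to object order and handles empties", {
  cfg <- counting_config(v_avg = 300, single_cell_max = 600)
  vols <- c(310, 250, 700, 890, 120, 300)
  for (seed in 1:5) {
    p <- pgcquant:::with_seed(seed, sample(vols))
    expect_identical(estimate_count(p, cfg), estimate_count(vols, cfg))
  }
  empty <- estimate_count(numeric(0), cfg)
  expect_identical(empty$n_total, 0L)
  expect_false(empty$fallback_used)
})

test_that("counts round half away from zero, minimum one per clustered object", {
  cfg <- counting_config(v_avg = 300, single_cell_max = 600,
                         cluster_fraction_threshold = 0.95)
  # 750/300 = 2.5 -> 3 (banker's rounding would give 2)
  est <- estimate_count(c(100, 750), cfg)
  expect_identical(est$n_from_clusters, 3L)
  expect_identical(est$n_total, 4L)
})
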