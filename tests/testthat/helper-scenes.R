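# Shared fixture builders: everything is generated in code, no stored data.

# Binary 3D array with axis-aligned ellipsoids at given centres (voxel
# units); used where a known-geometry mask is needed without the generator.
ellipsoid_mask <- function(dims, centres, semi_axes) {
  a <- array(FALSE, dims)
  centres <- rbind(centres)
  semi_axes <- rbind(semi_axes)
  for (i in seq_len(nrow(centres))) {
    for (z in 1:dims[1]) for (y in 1:dims[2]) for (x in 1:dims[3]) {
      if (((z - centres[i, 1]) / semi_axes[i, 1])^2 +
          ((y - centres[i, 2]) / semi_axes[i, 2])^2 +
          ((x - centres[i, 3]) / semi_axes[i, 3])^2 <= 1)
        a[z, y, x] <- TRUE
    }
  }
  a
}

# Wrap a single channel array as a stack.
as_stack <- function(arr, voxel_size = c(1, 1, 1), name = "GCNA") {
  lst <- list(arr)
  names(lst) <- name
  intensity_stack(lst, voxel_size)
}

# Stack whose GCNA channel is `base + amp * mask` (no blur/noise).
mask_stack <- function(mask, voxel_size = c(1, 1, 1), base = 0, amp = 100) {
  as_stack(array(base + amp * mask, dim(mask)), voxel_size)
}

# Counting configuration calibrated to the generator's stated world
# (mean volume 300 um^3; single-object cutoff from the truth volume range).
calibrated_counting <- function() {
  counting_config(size_guide = c(GCNA = 300), v_avg = 300,
                  single_cell_max = 450)
}

# Non-clustered recovery scene at the spec's conditions (volumes inside
# [2*v_min, single_cell_max], SNR = (150-20)/5 = 26 >= 5).
recovery_scene <- function(n_cells, seed, cluster_fraction = 0) {
  side <- as.integer(ceiling(sqrt(n_cells * 300 / 0.025 / 32)))
  scene_config(n_cells = n_cells,
               stack_shape = c(32L, side, side),
               volume_range = c(150, 430), cell_volume_cv = 0.15,
               cluster_fraction = cluster_fraction,
               seed = seed)
}

# 2D disk mask (matrix) of radius r_um at pixel size px.
disk_mask <- function(r_um, px = c(1, 1), pad = 3) {
  ny <- as.integer(2 * ceiling(r_um / px[1]) + 2 * pad)
  nx <- as.integer(2 * ceiling(r_um / px[2]) + 2 * pad)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  yy <- ((1:ny) - cy) * px[1]
  xx <- ((1:nx) - cx) * px[2]
  outer(yy, xx, function(y, x) y^2 + x^2 <= r_um^2)
}

# 2D axis-aligned ellipse mask, semi-axes in um.
ellipse_mask <- function(a_um, b_um, px = c(1, 1), angle_deg = 0, pad = 3) {
  r <- max(a_um, b_um)
  ny <- as.integer(2 * ceiling(r / px[1]) + 2 * pad)
  nx <- as.integer(2 * ceiling(r / px[2]) + 2 * pad)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  th <- angle_deg * pi / 180
  yy <- ((1:ny) - cy) * px[1]
  xx <- ((1:nx) - cx) * px[2]
  f <- function(y, x) {
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    (u / a_um)^2 + (v / b_um)^2 <= 1
  }
  outer(yy, xx, f)
}
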