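#' SD-intensity threshold mask
#'
#' Reimplements the "find objects by standard-deviation intensity" step: a
#' voxel is foreground iff its intensity is strictly greater than
#' `mean + k_sd * SD`, where mean and SD are the population statistics over
#' every voxel of the channel (background included). The strict comparison
#' means a constant channel (SD = 0) yields an empty mask, with a warning.
#'
#' @param stack an [intensity_stack()].
#' @param channel channel role to threshold.
#' @param k_sd SD multiplier; the protocol's working range is 3.2-3.7
#'   (default 3.5).
#' @return logical 3D array, same dimensions as the stack.
#' @examples
#' a <- array(0, c(2, 2, 2)); a[1, 1, 1] <- 10
#' s <- intensity_stack(list(GCNA = a))
#' sum(sd_threshold_mask(s, "GCNA", k_sd = 1))
#' @export
sd_threshold_mask <- function(stack, channel, k_sd = 3.5) {
  stopifnot(inherits(stack, "intensity_stack"))
  if (k_sd <= 0) stop("k_sd must be > 0", call. = FALSE)
  v <- get_channel(stack, channel)
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))   # population SD
  if (sdev == 0)
    warning("channel '", channel, "' is constant (SD = 0); mask is empty",
            call. = FALSE)
  m <- v > mu + k_sd * sdev
  dim(m) <- dim(v)
  m
}

#' Fill enclosed cavities in a binary 3D mask
#'
#' Background cavities completely enclosed by foreground (no 6-connected
#' path to the stack border) become foreground; foreground never shrinks,
#' and the operation is idempotent.
#'
#' @param mask logical 3D array.
#' @return logical 3D array.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  .fill_holes_3d(mask)
}

#' Label connected objects and measure them
#'
#' Maximal 26-connected components of the mask become segmented objects with
#' physical volume, centroid (um, voxel-centre convention) and per-channel
#' mean intensity. `cluster_flag` marks objects larger than
#' `single_cell_max`.
#'
#' @param mask logical 3D array, congruent with `stack`.
#' @param stack an [intensity_stack()] supplying intensities and voxel size.
#' @param single_cell_max um^3 cutoff above which an object is flagged as a
#'   probable cluster of touching cells.
#' @return An object of class `pgc_objects`: a data.frame (one row per
#'   object: `label`, `n_voxels`, `volume_um3`, `centroid_z/y/x_um`,
#'   `mean_<channel>` per channel, `cluster_flag`) carrying the integer label
#'   array and voxel size as attributes `label_array` / `voxel_size`.
#' @export
label_objects <- function(mask, stack, single_cell_max = Inf) {
  stopifnot(inherits(stack, "intensity_stack"),
            is.logical(mask), all(dim(mask) == dim(stack)))
  lab <- .cc_label_3d(mask, 26L)
  objects_from_labels(lab, stack, single_cell_max)
}

# Build the pgc_objects table from an integer label array.
objects_from_labels <- function(lab, stack, single_cell_max = Inf) {
  nlab <- max(0L, max(lab))
  vs <- stack$voxel_size
  vv <- prod(vs)
  d <- dim(stack)
  if (nlab == 0L) {
    df <- data.frame(label = integer(0), n_voxels = integer(0),
                     volume_um3 = numeric(0), centroid_z_um = numeric(0),
                     centroid_y_um = numeric(0), centroid_x_um = numeric(0))
    for (ch in names(stack$channels)) df[[paste0("mean_", ch)]] <- numeric(0)
    df$cluster_flag <- logical(0)
    return(new_pgc_objects(df, lab, stack, single_cell_max))
  }
  idx <- which(lab > 0L)
  labs <- lab[idx]
  nvox <- tabulate(labs, nbins = nlab)
  # voxel-centre coordinates (um) from linear indices, (z, y, x) order
  z <- (idx - 1L) %% d[1] + 1L
  r <- (idx - 1L) %/% d[1]
  y <- r %% d[2] + 1L
  x <- r %/% d[2] + 1L
  cz <- (tapply_sum(z, labs, nlab) / nvox - 0.5) * vs[1]
  cy <- (tapply_sum(y, labs, nlab) / nvox - 0.5) * vs[2]
  cx <- (tapply_sum(x, labs, nlab) / nvox - 0.5) * vs[3]
  df <- data.frame(label = seq_len(nlab), n_voxels = nvox,
                   volume_um3 = nvox * vv,
                   centroid_z_um = cz, centroid_y_um = cy, centroid_x_um = cx)
  for (ch in names(stack$channels)) {
    v <- stack$channels[[ch]][idx]
    df[[paste0("mean_", ch)]] <- tapply_sum(v, labs, nlab) / nvox
  }
  df$cluster_flag <- df$volume_um3 > single_cell_max
  new_pgc_objects(df, lab, stack, single_cell_max)
}

tapply_sum <- function(v, g, n) {
  out <- numeric(n)
  s <- rowsum(as.numeric(v), g, reorder = TRUE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

new_pgc_objects <- function(df, lab, stack, single_cell_max) {
  structure(df, label_array = lab, voxel_size = stack$voxel_size,
            single_cell_max = single_cell_max,
            class = c("pgc_objects", "data.frame"))
}

#' @export
print.pgc_objects <- function(x, ...) {
  cat("<pgc_objects> ", nrow(x), " object(s); total volume ",
      format(sum(x$volume_um3)), " um^3\n", sep = "")
  NextMethod()
}

#' Exclude objects below a volume cutoff
#'
#' Objects strictly under `v_min` um^3 are removed (an object exactly at the
#' cutoff is kept). Applied once after labelling and again after splitting,
#' mirroring the counting protocol.
#'
#' @param objects a `pgc_objects` table.
#' @param v_min minimum volume in um^3 (default 20).
#' @return filtered `pgc_objects`; removed objects are zeroed in the label
#'   array.
#' @export
exclude_small <- function(objects, v_min = 20) {
  stopifnot(inherits(objects, "pgc_objects"))
  if (v_min <= 0) stop("v_min must be > 0", call. = FALSE)
  keep <- objects$volume_um3 >= v_min
  subset_objects(objects, keep)
}

# Keep rows where `keep`; relabel 1..k in former order; zero dropped voxels.
subset_objects <- function(objects, keep) {
  lab <- attr(objects, "label_array")
  old <- objects$label[keep]
  map <- integer(max(0L, max(lab)))
  map[old] <- seq_along(old)
  newlab <- lab
  pos <- lab > 0L
  newlab[pos] <- map[lab[pos]]
  df <- objects[keep, , drop = FALSE]
  df$label <- seq_len(sum(keep))
  rownames(df) <- NULL
  structure(df, label_array = newlab, voxel_size = attr(objects, "voxel_size"),
            single_cell_max = attr(objects, "single_cell_max"),
            class = class(objects))
}

#' Split touching cells with a size guide
#'
#' Objects larger than the single-object cutoff (`single_cell_max`) are
#' re-partitioned into `n = max(1, round(volume / size_guide))` connected
#' sub-objects (rounding half away from zero): seeds are peaks of the
#' anisotropy-aware Euclidean distance transform (ordered by depth, ties by
#' lexicographic `(z, y, x)` voxel order, with a minimum mutual separation
#' that is relaxed if too few peaks exist), and voxels are assigned to the
#' geodesically nearest seed, so child volumes always sum exactly to the
#' parent volume. Objects at or below the cutoff pass through unchanged.
#'
#' @param objects a `pgc_objects` table with label array.
#' @param stack the source [intensity_stack()] (for re-measuring children).
#' @param size_guide um^3 target single-cell volume (200 for a GCNA channel,
#'   750 for SSEA1).
#' @param single_cell_max um^3 cutoff defining a "clustered" object; default
#'   `2 * size_guide` (the protocol's visually determined single-object
#'   cutoff, exposed as a knob).
#' @return a new `pgc_objects` table.
#' @export
split_touching <- function(objects, stack, size_guide,
                           single_cell_max = 2 * size_guide) {
  stopifnot(inherits(objects, "pgc_objects"),
            inherits(stack, "intensity_stack"))
  if (size_guide <= 0) stop("size_guide must be > 0", call. = FALSE)
  lab <- attr(objects, "label_array")
  vs <- attr(objects, "voxel_size")
  big <- which(objects$volume_um3 > single_cell_max)
  if (length(big) == 0L) {
    attr(objects, "single_cell_max") <- single_cell_max
    objects$cluster_flag <- objects$volume_um3 > single_cell_max
    return(objects)
  }
  out <- lab
  next_label <- max(objects$label)
  d <- dim(lab)
  for (b in big) {
    n_target <- max(1, round_half_away(objects$volume_um3[b] / size_guide))
    if (n_target <= 1) next
    idx <- which(lab == objects$label[b])
    # local bounding box
    z <- (idx - 1L) %% d[1] + 1L
    r <- (idx - 1L) %/% d[1]
    y <- r %% d[2] + 1L
    x <- r %/% d[2] + 1L
    lo <- c(min(z), min(y), min(x))
    hi <- c(max(z), max(y), max(x))
    sub <- array(FALSE, hi - lo + 1L)
    sub[cbind(z - lo[1] + 1L, y - lo[2] + 1L, x - lo[3] + 1L)] <- TRUE
    seeds <- edt_seeds(sub, vs, n_target, size_guide)
    if (length(seeds) <= 1L) next
    part <- .geodesic_partition(sub, seeds, vs)
    # write child labels back: first child keeps parent label
    child <- part[sub]
    newlabs <- c(objects$label[b], next_label + seq_len(max(child) - 1L))
    next_label <- next_label + max(child) - 1L
    out[idx] <- newlabs[child]
  }
  res <- objects_from_labels(compact_labels(out), stack, single_cell_max)
  res
}

# Pick up to n seeds from EDT peaks: voxels ordered by (depth desc, z, y, x),
# greedily accepted at pairwise physical distance >= d_min; d_min starts at
# 1.5x the guide-equivalent radius and halves until enough seeds are found.
edt_seeds <- function(sub, vs, n, size_guide) {
  edt <- .edt_3d(sub, vs)
  idx <- which(sub)
  o <- order(-edt[idx], idx)          # lexicographic tie-break via linear idx
  idx <- idx[o]
  d <- dim(sub)
  z <- ((idx - 1L) %% d[1] + 1L) * vs[1]
  r <- (idx - 1L) %/% d[1]
  y <- (r %% d[2] + 1L) * vs[2]
  x <- (r %/% d[2] + 1L) * vs[3]
  pts <- cbind(z, y, x)
  d_min <- 1.5 * (3 * size_guide / (4 * pi))^(1 / 3)
  repeat {
    sel <- integer(0)
    for (i in seq_along(idx)) {
      if (length(sel) == 0L ||
          all(sqrt(colSums((t(pts[sel, , drop = FALSE]) - pts[i, ])^2)) >=
              d_min)) {
        sel <- c(sel, i)
        if (length(sel) == n) break
      }
    }
    if (length(sel) == n || d_min <= max(vs)) break
    d_min <- d_min / 2
  }
  idx[sel]
}

# Relabel a label array to consecutive 1..k preserving first-encounter order
# of the existing (ascending) label values.
compact_labels <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) == 0L) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  pos <- lab > 0L
  lab[pos] <- map[lab[pos]]
  lab
}

#' Counting configuration
#'
#' Bundles the parameters of the counting protocol: the SD multiplier for
#' thresholding (working range 3.2-3.7), the 20 um^3 small-object exclusion,
#' the channel size guides (GCNA 200, SSEA1 750 um^3), the average
#' single-cell volume used for cluster division (300 um^3 for GCNA), the
#' single-object volume cutoff, and the 20% clustered-volume fraction that
#' triggers the whole-volume fallback estimate.
#'
#' @param k_sd SD multiplier, in `[3.2, 3.7]` by convention (default 3.5).
#' @param v_min minimum object volume, um^3 (default 20).
#' @param size_guide named um^3 per channel role
#'   (default `c(GCNA = 200, SSEA1 = 750)`).
#' @param v_avg average single-cell volume, um^3 (default 300).
#' @param single_cell_max single-object cutoff, um^3; default
#'   `2 * size_guide` of the channel in use (passed as `NULL` here and
#'   resolved per channel).
#' @param cluster_fraction_threshold clustered-volume fraction above which
#'   the fallback total-volume estimate is used (default 0.20).
#' @return list of class `counting_config`.
#' @export
counting_config <- function(k_sd = 3.5, v_min = 20,
                            size_guide = c(GCNA = 200, SSEA1 = 750),
                            v_avg = 300, single_cell_max = NULL,
                            cluster_fraction_threshold = 0.20) {
  cfg <- list(k_sd = k_sd, v_min = v_min, size_guide = size_guide,
              v_avg = v_avg, single_cell_max = single_cell_max,
              cluster_fraction_threshold = cluster_fraction_threshold)
  if (k_sd <= 0) stop("k_sd must be > 0", call. = FALSE)
  scm <- if (is.null(single_cell_max)) 2 * max(size_guide) else single_cell_max
  if (!(0 < v_min && v_min < v_avg && v_avg <= scm))
    stop("need 0 < v_min < v_avg <= single_cell_max", call. = FALSE)
  if (cluster_fraction_threshold <= 0 || cluster_fraction_threshold >= 1)
    stop("cluster_fraction_threshold must lie in (0, 1)", call. = FALSE)
  class(cfg) <- "counting_config"
  cfg
}

#' Estimate the cell count from segmented objects
#'
#' Objects at or below the single-object cutoff each count one cell.
#' Clustered objects (volume above the cutoff) are summed and divided by the
#' average cell volume `v_avg` (rounding half away from zero, at least one
#' cell per clustered object). If the clustered volume exceeds
#' `cluster_fraction_threshold` (20%) of the total measured volume, the
#' fallback applies instead: the whole measured volume is divided by `v_avg`.
#'
#' @param objects a `pgc_objects` table (post-splitting), or a numeric vector
#'   of object volumes in um^3.
#' @param config a [counting_config()].
#' @param channel channel role used to resolve the per-channel
#'   `single_cell_max` default (`2 * size_guide[channel]`); ignored when
#'   `config$single_cell_max` is set.
#' @return list of class `count_estimate`: `n_single`, `n_from_clusters`,
#'   `n_total`, `fallback_used`, `clustered_volume_fraction`,
#'   `total_volume_um3`.
#' @examples
#' estimate_count(c(300, 900), counting_config(single_cell_max = 600))$n_total
#' @export
estimate_count <- function(objects, config = counting_config(),
                           channel = "GCNA") {
  vols <- if (inherits(objects, "pgc_objects")) objects$volume_um3
          else as.numeric(objects)
  scm <- config$single_cell_max
  if (is.null(scm)) {
    g <- if (channel %in% names(config$size_guide))
      config$size_guide[[channel]] else max(config$size_guide)
    scm <- 2 * g
  }
  if (length(vols) == 0L)
    return(structure(list(n_single = 0L, n_from_clusters = 0L, n_total = 0L,
                          fallback_used = FALSE,
                          clustered_volume_fraction = 0,
                          total_volume_um3 = 0),
                     class = "count_estimate"))
  clustered <- vols > scm
  total <- sum(vols)
  cl_vol <- sum(vols[clustered])
  frac <- cl_vol / total
  n_single <- sum(!clustered)
  n_from_clusters <- if (any(clustered)) {
    max(as.integer(round_half_away(cl_vol / config$v_avg)), sum(clustered))
  } else 0L
  if (frac > config$cluster_fraction_threshold) {
    n_total <- as.integer(round_half_away(total / config$v_avg))
    fallback <- TRUE
    n_from_clusters <- n_total - n_single
  } else {
    n_total <- as.integer(n_single + n_from_clusters)
    fallback <- FALSE
  }
  structure(list(n_single = as.integer(n_single),
                 n_from_clusters = as.integer(n_from_clusters),
                 n_total = n_total, fallback_used = fallback,
                 clustered_volume_fraction = frac,
                 total_volume_um3 = total),
            class = "count_estimate")
}

#' @export
print.count_estimate <- function(x, ...) {
  cat("<count_estimate> n_total = ", x$n_total,
      " (singles ", x$n_single, ", from clusters ", x$n_from_clusters,
      if (x$fallback_used) "; 20% fallback used" else "",
      "; clustered volume fraction ",
      sprintf("%.1f%%", 100 * x$clustered_volume_fraction), ")\n", sep = "")
  invisible(x)
}

#' Run the full counting chain on one channel
#'
#' threshold -> fill holes -> label -> exclude small -> split touching ->
#' exclude small -> estimate. Convenience wrapper used by the pipeline and
#' the acceptance tests.
#'
#' @param stack an [intensity_stack()].
#' @param channel detection channel role.
#' @param config a [counting_config()].
#' @return list with `objects` (final `pgc_objects`) and `estimate`
#'   (`count_estimate`).
#' @export
count_cells <- function(stack, channel = "GCNA", config = counting_config()) {
  g <- if (channel %in% names(config$size_guide))
    config$size_guide[[channel]] else max(config$size_guide)
  scm <- if (is.null(config$single_cell_max)) 2 * g else config$single_cell_max
  m <- sd_threshold_mask(stack, channel, config$k_sd)
  m <- fill_holes(m)
  obj <- label_objects(m, stack, single_cell_max = scm)
  obj <- exclude_small(obj, config$v_min)
  obj <- split_touching(obj, stack, g, single_cell_max = scm)
  obj <- exclude_small(obj, config$v_min)
  est <- estimate_count(obj, config, channel = channel)
  list(objects = obj, estimate = est)
}
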