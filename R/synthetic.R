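#' Configuration for a synthetic ground-truthed scene
#'
#' Describes the world the generator emulates: ellipsoidal germ cells of
#' roughly 300 um^3 scattered (and optionally clustered) in a confocal-like
#' 3D stack, with marker-positive subsets, Gaussian blur emulating the PSF,
#' and additive Gaussian noise; or, for culture fields, elongated cells whose
#' long-axis orientations follow an axial (period-180 degree) von Mises
#' distribution about a declared gradient axis.
#'
#' @param stack_shape integer length-3, voxels along `(z, y, x)`.
#' @param voxel_size numeric length-3, um per voxel `(z, y, x)`.
#' @param n_cells number of cells to place.
#' @param cell_volume_mean mean cell volume in um^3 (default 300, the average
#'   germ-cell volume used by the counting protocol).
#' @param cell_volume_cv coefficient of variation of cell volume.
#' @param volume_range optional `c(lo, hi)` um^3; volumes are resampled into
#'   this range (truncated distribution).
#' @param cluster_fraction fraction of cells placed in touching groups.
#' @param cluster_size_range integer `c(min, max)` cells per cluster.
#' @param marker_positive_fraction named numeric, fraction of cells positive
#'   per marker channel (e.g. `c(PHH3 = 0.04, cPARP = 0.12)`).
#' @param ei_distribution `c(mean, sd)` of the target Elongation Index for
#'   culture-field cells.
#' @param orientation_concentration kappa >= 0 of the axial orientation
#'   distribution about the gradient axis; 0 means uniform.
#' @param gradient_axis unit vector `(y, x)` of the gradient (culture fields).
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param blur_sigma isotropic Gaussian blur sigma in um (PSF stand-in).
#' @param background_level background intensity.
#' @param foreground_level in-cell intensity before blur.
#' @param cell_channel name of the channel containing every cell.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated list of class `scene_config`.
#' @seealso [generate_stack()], [generate_culture_field()]
#' @export
scene_config <- function(stack_shape = c(32L, 128L, 128L),
                         voxel_size = c(1, 1, 1),
                         n_cells = 50,
                         cell_volume_mean = 300,
                         cell_volume_cv = 0.2,
                         volume_range = NULL,
                         cluster_fraction = 0,
                         cluster_size_range = c(2L, 3L),
                         marker_positive_fraction = c(PHH3 = 0.04, cPARP = 0.12),
                         ei_distribution = c(mean = 0.15, sd = 0.08),
                         orientation_concentration = 0,
                         gradient_axis = c(0, 1),
                         noise_sd = 5,
                         blur_sigma = 0.5,
                         background_level = 20,
                         foreground_level = 150,
                         cell_channel = "GCNA",
                         seed = 1L) {
  cfg <- list(
    stack_shape = as.integer(stack_shape), voxel_size = as.numeric(voxel_size),
    n_cells = as.integer(n_cells), cell_volume_mean = cell_volume_mean,
    cell_volume_cv = cell_volume_cv, volume_range = volume_range,
    cluster_fraction = cluster_fraction,
    cluster_size_range = as.integer(cluster_size_range),
    marker_positive_fraction = marker_positive_fraction,
    ei_distribution = as.numeric(ei_distribution),
    orientation_concentration = orientation_concentration,
    gradient_axis = as.numeric(gradient_axis),
    noise_sd = noise_sd, blur_sigma = blur_sigma,
    background_level = background_level, foreground_level = foreground_level,
    cell_channel = cell_channel, seed = as.integer(seed)
  )
  validate_scene_config(cfg)
  class(cfg) <- "scene_config"
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(length(cfg$stack_shape) == 3L, all(cfg$stack_shape >= 1L))
  if (cfg$n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
  if (any(cfg$voxel_size <= 0) || any(!is.finite(cfg$voxel_size)))
    stop("voxel_size must be strictly positive on all axes", call. = FALSE)
  fr <- c(cfg$cluster_fraction, cfg$marker_positive_fraction)
  if (any(fr < 0 | fr > 1))
    stop("cluster_fraction and marker fractions must lie in [0, 1]",
         call. = FALSE)
  if (cfg$orientation_concentration < 0)
    stop("orientation_concentration (kappa) must be >= 0", call. = FALSE)
  if (cfg$cell_volume_mean <= 0 || cfg$cell_volume_cv < 0)
    stop("cell volume parameters must be positive", call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$blur_sigma < 0 || cfg$background_level < 0)
    stop("noise_sd, blur_sigma and background_level must be >= 0",
         call. = FALSE)
  if (cfg$foreground_level <= cfg$background_level)
    stop("foreground_level must exceed background_level", call. = FALSE)
  invisible(cfg)
}

# Sample cell volumes (um^3): gamma with given mean and CV, optionally
# truncated to `range` by rejection.
sample_volumes <- function(n, mean, cv, range = NULL) {
  if (n == 0L) return(numeric(0))
  draw <- function(m) {
    if (cv == 0) rep(mean, m)
    else rgamma(m, shape = 1 / cv^2, scale = mean * cv^2)
  }
  v <- draw(n)
  if (!is.null(range)) {
    for (i in seq_len(1000L)) {
      bad <- v < range[1] | v > range[2]
      if (!any(bad)) break
      v[bad] <- draw(sum(bad))
    }
    if (any(v < range[1] | v > range[2]))
      stop("could not sample volumes inside volume_range after 1000 rounds",
           call. = FALSE)
  }
  v
}

# Random orthonormal frame (3x3, columns = ellipsoid axes), det +1.
random_frame <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Sample signed axial angles about a gradient axis
#'
#' Draws orientation offsets (degrees, in `(-90, 90]`) from an axial
#' von-Mises-type distribution with concentration `kappa`: a von Mises angle
#' on the doubled circle is sampled and halved, so the distribution has
#' period 180 degrees. `kappa = 0` yields angles uniform on `(-90, 90]`,
#' hence folded angles uniform on `[0, 90)`.
#'
#' @param n number of draws.
#' @param kappa concentration, `>= 0`.
#' @return numeric vector of signed angles in degrees.
#' @export
sample_axial_angles <- function(n, kappa) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(runif(n, -90, 90))
  rvonmises(n, kappa) * 90 / pi
}

# Von Mises sampler, mean 0, on (-pi, pi]; Best & Fisher (1979) rejection.
rvonmises <- function(n, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

# Place n cells with bounding radius `rad` (um) in the box `extent` (um,
# per-axis length vector) with pairwise clearance, cluster-aware. Returns
# centre matrix. `touch` marks, for each cell, the index of a previously
# placed cell it must touch (clusters), or 0. `support(i, u)` gives cell i's
# ellipsoid support (extent from centre) along unit direction u, so cluster
# members overlap slightly whatever their orientation.
place_centres <- function(rad, extent, touch, clearance, support,
                          cluster_id = rep(NA_integer_, length(rad)),
                          budget = 2000L) {
  n <- length(rad)
  ctr <- matrix(NA_real_, n, 3)
  margin <- rad + clearance / 2
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(budget)) {
      if (touch[i] == 0L) {
        p <- runif(3) * (extent - 2 * margin[i]) + margin[i]
      } else {
        dirv <- rnorm(3)
        dirv <- dirv / sqrt(sum(dirv^2))
        d <- 0.92 * (support(i, dirv) + support(touch[i], dirv))
        p <- ctr[touch[i], ] + dirv * d
        if (any(p < margin[i]) || any(p > extent - margin[i])) next
      }
      ok <- TRUE
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        dd <- sqrt(colSums((t(ctr[prev, , drop = FALSE]) - p)^2))
        lim <- rad[prev] + rad[i] + clearance
        # members of the same cluster are allowed (required) to be close
        if (!is.na(cluster_id[i]))
          lim[which(cluster_id[prev] %in% cluster_id[i])] <- 0
        if (any(dd < lim)) ok <- FALSE
      }
      if (ok) break
    }
    if (!ok)
      stop("cell placement failed: placement-attempt budget (", budget,
           ") exceeded at cell ", i,
           "; enlarge stack_shape or reduce n_cells", call. = FALSE)
    ctr[i, ] <- p
  }
  ctr
}

# Paint an ellipsoid (centre um, frame columns=axes, semi-axes um) into `arr`
# at `level`, voxel centres at (index - 0.5) * voxel_size. Returns the array.
paint_ellipsoid <- function(arr, centre, frame, semi, voxel_size, level) {
  d <- dim(arr)
  rmax <- max(semi)
  lo <- pmax(1L, floor((centre - rmax) / voxel_size - 0.5) + 1L)
  hi <- pmin(d, ceiling((centre + rmax) / voxel_size + 0.5))
  if (any(lo > hi)) return(arr)
  zz <- (lo[1]:hi[1] - 0.5) * voxel_size[1] - centre[1]
  yy <- (lo[2]:hi[2] - 0.5) * voxel_size[2] - centre[2]
  xx <- (lo[3]:hi[3] - 0.5) * voxel_size[3] - centre[3]
  g <- as.matrix(expand.grid(z = zz, y = yy, x = xx))
  loc <- g %*% frame                      # coordinates in the ellipsoid frame
  inside <- (loc[, 1] / semi[1])^2 + (loc[, 2] / semi[2])^2 +
    (loc[, 3] / semi[3])^2 <= 1
  if (any(inside)) {
    sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sub[inside] <- pmax(sub[inside], level)
    arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  }
  arr
}

finish_channel <- function(arr, cfg) {
  sig <- cfg$blur_sigma / cfg$voxel_size
  if (cfg$blur_sigma > 0) arr <- .gaussian_blur_3d(arr, sig)
  if (cfg$noise_sd > 0)
    arr <- arr + rnorm(length(arr), 0, cfg$noise_sd)
  arr[arr < 0] <- 0
  dim(arr) <- cfg$stack_shape
  arr
}

#' Generate a ground-truthed multi-channel 3D stack
#'
#' Places ellipsoidal cells (freely oriented; optionally in touching
#' clusters), paints them into a cell-marker channel plus one channel per
#' marker in `marker_positive_fraction`, blurs with an isotropic physical
#' Gaussian, adds clipped Gaussian noise, and returns both the stack and the
#' exact truth table.
#'
#' @param config a [scene_config()].
#' @return list with elements `stack` (an [intensity_stack()]) and `truth`
#'   (data.frame: `id`, centroid `cz/cy/cx_um`, semi-axes `sa/sb/sc_um`,
#'   orientation `vz/vy/vx`, `volume_um3` (analytic `4/3*pi*a*b*c`),
#'   `cluster_id` (NA when unclustered) and one logical column per marker).
#' @examples
#' sc <- scene_config(n_cells = 5, stack_shape = c(16L, 48L, 48L), seed = 3)
#' out <- generate_stack(sc)
#' out$truth$volume_um3
#' @export
generate_stack <- function(config) {
  validate_scene_config(config)
  with_seed(config$seed, generate_stack_impl(config))
}

generate_stack_impl <- function(cfg) {
  n <- cfg$n_cells
  extent <- cfg$stack_shape * cfg$voxel_size
  vols <- sample_volumes(n, cfg$cell_volume_mean, cfg$cell_volume_cv,
                         cfg$volume_range)
  # mild triaxial shape: semi-axes a >= b >= c with ratios in [0.7, 1]
  u1 <- if (n) runif(n, 0.7, 1) else numeric(0)
  u2 <- if (n) runif(n, 0.7, 1) else numeric(0)
  a <- (3 * vols / (4 * pi * u1 * u2))^(1 / 3)
  semi <- cbind(a, a * u1, a * u2)
  frames <- lapply(seq_len(n), function(i) random_frame())

  # cluster bookkeeping: cells in a cluster are placed touching the previous
  # member of the same cluster
  cluster_id <- rep(NA_integer_, n)
  touch <- integer(n)
  n_clustered <- round_half_away(cfg$cluster_fraction * n)
  if (n_clustered >= 2) {
    remaining <- n_clustered
    cid <- 0L
    pos <- 1L
    while (remaining >= 2) {
      sz <- sample(seq(cfg$cluster_size_range[1], cfg$cluster_size_range[2]), 1L)
      sz <- min(sz, remaining)
      if (sz < 2L) break
      cid <- cid + 1L
      members <- pos:(pos + sz - 1L)
      cluster_id[members] <- cid
      touch[members[-1]] <- members[-length(members)]
      pos <- pos + sz
      remaining <- remaining - sz
    }
  }

  clearance <- max(2 * cfg$blur_sigma, 2) + max(cfg$voxel_size)
  support <- function(i, u) {
    sqrt(sum((semi[i, ] * drop(crossprod(frames[[i]], u)))^2))
  }
  ctr <- place_centres(semi[, 1], extent, touch, clearance, support,
                       cluster_id = cluster_id)

  marker_names <- names(cfg$marker_positive_fraction)
  flags <- matrix(FALSE, n, length(marker_names),
                  dimnames = list(NULL, marker_names))
  for (m in marker_names)
    flags[, m] <- runif(n) < cfg$marker_positive_fraction[[m]]

  channels <- c(cfg$cell_channel, marker_names)
  arrs <- lapply(channels, function(ch)
    array(cfg$background_level, cfg$stack_shape))
  names(arrs) <- channels
  for (i in seq_len(n)) {
    arrs[[cfg$cell_channel]] <- paint_ellipsoid(
      arrs[[cfg$cell_channel]], ctr[i, ], frames[[i]], semi[i, ],
      cfg$voxel_size, cfg$foreground_level)
    for (m in marker_names)
      if (flags[i, m])
        arrs[[m]] <- paint_ellipsoid(arrs[[m]], ctr[i, ], frames[[i]],
                                     semi[i, ], cfg$voxel_size,
                                     cfg$foreground_level)
  }
  arrs <- lapply(arrs, finish_channel, cfg = cfg)
  stack <- intensity_stack(arrs, cfg$voxel_size)

  orient <- t(vapply(frames, function(f) f[, 1], numeric(3)))
  truth <- data.frame(
    id = seq_len(n),
    cz_um = ctr[, 1], cy_um = ctr[, 2], cx_um = ctr[, 3],
    sa_um = semi[, 1], sb_um = semi[, 2], sc_um = semi[, 3],
    vz = orient[, 1], vy = orient[, 2], vx = orient[, 3],
    volume_um3 = 4 / 3 * pi * semi[, 1] * semi[, 2] * semi[, 3],
    cluster_id = cluster_id
  )
  if (n == 0L)
    truth <- truth[0, ]
  for (m in marker_names) truth[[paste0(m, "_pos")]] <- flags[, m]
  list(stack = stack, truth = truth)
}

#' Generate a 2D culture field with gradient-aligned elongated cells
#'
#' Emulates germ cells cultured beside a chemoattractant source strip: a
#' single-plane field of elongated elliptical cell masks whose long-axis
#' orientations are drawn from the axial distribution about
#' `config$gradient_axis` with concentration `config$orientation_concentration`
#' (kappa = 0 gives orientations uniform on `[0, 90)` after folding), and
#' whose Elongation Indices follow `config$ei_distribution` truncated to
#' `[0, 0.85]`.
#'
#' @param config a [scene_config()]; `stack_shape[1]` is forced to 1 plane.
#' @return list with `stack` (single-plane [intensity_stack()]) and `truth`
#'   (data.frame: `id`, `cy_um`, `cx_um`, in-plane semi-axes `sa_um >= sb_um`,
#'   true `ei`, signed angle `phi_deg` to the gradient, folded `theta_deg` in
#'   `[0, 90]`, long-axis components `vy`/`vx`, plus marker flags), and the
#'   `gradient_axis` unit vector.
#' @export
generate_culture_field <- function(config) {
  validate_scene_config(config)
  if (is.null(config$gradient_axis) || length(config$gradient_axis) != 2L ||
      all(config$gradient_axis == 0))
    stop("config must declare a nonzero 2D gradient_axis (y, x)", call. = FALSE)
  with_seed(config$seed, generate_field_impl(config))
}

generate_field_impl <- function(cfg) {
  n <- cfg$n_cells
  shape <- c(1L, cfg$stack_shape[2], cfg$stack_shape[3])
  cfg$stack_shape <- shape
  g <- cfg$gradient_axis / sqrt(sum(cfg$gradient_axis^2))
  vols <- sample_volumes(n, cfg$cell_volume_mean, cfg$cell_volume_cv,
                         cfg$volume_range)
  area <- pi * ((3 * vols / (4 * pi))^(1 / 3))^2   # equivalent-sphere section
  ei <- if (n) pmin(pmax(rnorm(n, cfg$ei_distribution[1],
                               cfg$ei_distribution[2]), 0), 0.85) else numeric(0)
  rho <- (1 + ei) / (1 - ei)                        # a/b axis ratio
  a <- sqrt(area * rho / pi)
  b <- a / rho
  phi <- sample_axial_angles(n, cfg$orientation_concentration)
  gang <- atan2(g[1], g[2])                         # gradient angle, rad
  ang <- gang + phi * pi / 180
  axis_yx <- cbind(sin(ang), cos(ang))              # (y, x) long-axis dir

  extent <- shape[2:3] * cfg$voxel_size[2:3]
  touch <- integer(n)
  ctr2 <- place_centres3_2d(a, extent, touch,
                            clearance = max(2 * cfg$blur_sigma, 1) +
                              max(cfg$voxel_size[2:3]))
  marker_names <- names(cfg$marker_positive_fraction)
  flags <- matrix(FALSE, n, length(marker_names),
                  dimnames = list(NULL, marker_names))
  for (m in marker_names)
    flags[, m] <- runif(n) < cfg$marker_positive_fraction[[m]]

  channels <- c(cfg$cell_channel, marker_names)
  arrs <- lapply(channels, function(ch) array(cfg$background_level, shape))
  names(arrs) <- channels
  for (i in seq_len(n)) {
    # in-plane ellipse as a degenerate ellipsoid: z semi-axis spans the plane
    frame <- rbind(c(0, 0, 1),
                   c(axis_yx[i, 1], -axis_yx[i, 2], 0),
                   c(axis_yx[i, 2], axis_yx[i, 1], 0))
    centre <- c(0.5 * cfg$voxel_size[1], ctr2[i, ])
    semi <- c(a[i], b[i], cfg$voxel_size[1])
    arrs[[cfg$cell_channel]] <- paint_ellipsoid(
      arrs[[cfg$cell_channel]], centre, frame, semi, cfg$voxel_size,
      cfg$foreground_level)
    for (m in marker_names)
      if (flags[i, m])
        arrs[[m]] <- paint_ellipsoid(arrs[[m]], centre, frame, semi,
                                     cfg$voxel_size, cfg$foreground_level)
  }
  arrs <- lapply(arrs, function(arr) {
    sig <- c(0, cfg$blur_sigma / cfg$voxel_size[2:3])
    if (cfg$blur_sigma > 0) arr <- .gaussian_blur_3d(arr, sig)
    if (cfg$noise_sd > 0) arr <- arr + rnorm(length(arr), 0, cfg$noise_sd)
    arr[arr < 0] <- 0
    dim(arr) <- shape
    arr
  })
  truth <- data.frame(
    id = seq_len(n), cy_um = ctr2[, 1], cx_um = ctr2[, 2],
    sa_um = a, sb_um = b, ei = ei,
    phi_deg = phi, theta_deg = abs(phi),
    vy = axis_yx[, 1], vx = axis_yx[, 2]
  )
  if (n == 0L) truth <- truth[0, ]
  for (m in marker_names) truth[[paste0(m, "_pos")]] <- flags[, m]
  list(stack = intensity_stack(arrs, cfg$voxel_size), truth = truth,
       gradient_axis = g)
}

# 2D uniform placement with clearance; same budget semantics as 3D.
place_centres3_2d <- function(rad, extent, touch, clearance, budget = 2000L) {
  n <- length(rad)
  ctr <- matrix(NA_real_, n, 2)
  margin <- rad + clearance / 2
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(budget)) {
      p <- runif(2) * (extent - 2 * margin[i]) + margin[i]
      ok <- TRUE
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        dd <- sqrt(colSums((t(ctr[prev, , drop = FALSE]) - p)^2))
        if (any(dd < rad[prev] + rad[i] + clearance)) ok <- FALSE
      }
      if (ok) break
    }
    if (!ok)
      stop("cell placement failed: placement-attempt budget (", budget,
           ") exceeded at cell ", i, "; enlarge the field or reduce n_cells",
           call. = FALSE)
    ctr[i, ] <- p
  }
  ctr
}
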