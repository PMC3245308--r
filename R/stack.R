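#' Multi-channel 3D intensity stack
#'
#' The raw input container for segmentation: one 3D voxel array per channel,
#' all congruent, in `(z, y, x)` order, plus the physical voxel dimensions in
#' micrometres. Channel names are role labels (e.g. `"GCNA"`, `"PHH3"`).
#'
#' @param channels named list of numeric 3D arrays, all with identical
#'   dimensions `(z, y, x)`; intensities must be finite and non-negative.
#' @param voxel_size numeric length-3, micrometres per voxel along `(z, y, x)`;
#'   strictly positive.
#' @return An object of class `intensity_stack`: a list with elements
#'   `channels`, `voxel_size` and `dim`.
#' @examples
#' a <- array(0, c(4, 8, 8))
#' s <- intensity_stack(list(GCNA = a), voxel_size = c(1, 0.5, 0.5))
#' dim(s)
#' @export
intensity_stack <- function(channels, voxel_size = c(1, 1, 1)) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty named list of 3D arrays", call. = FALSE)
  if (is.null(names(channels)) || anyNA(names(channels)) ||
      any(!nzchar(names(channels))) || anyDuplicated(names(channels)))
    stop("channel names must be unique and non-empty", call. = FALSE)
  dims <- lapply(channels, function(a) dim(a))
  if (any(vapply(dims, length, 1L) != 3L))
    stop("every channel must be a 3D array (z, y, x)", call. = FALSE)
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) all(d == d0), TRUE)))
    stop("all channels must share the same dimensions", call. = FALSE)
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (!all(is.finite(v)) || any(v < 0))
      stop("channel '", nm, "' has non-finite or negative intensities",
           call. = FALSE)
    storage.mode(channels[[nm]]) <- "double"
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive numbers (z, y, x) in um",
         call. = FALSE)
  structure(
    list(channels = channels, voxel_size = voxel_size, dim = d0),
    class = "intensity_stack"
  )
}

#' @export
dim.intensity_stack <- function(x) x$dim

#' @export
print.intensity_stack <- function(x, ...) {
  cat("<intensity_stack> ", paste(x$dim, collapse = " x "),
      " voxels (z y x), ", length(x$channels), " channel(s): ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  cat("  voxel size (um): ", paste(format(x$voxel_size), collapse = " x "),
      "; voxel volume ", format(prod(x$voxel_size)), " um^3\n", sep = "")
  invisible(x)
}

#' Extract one channel of a stack
#'
#' @param stack an [intensity_stack()].
#' @param channel channel role name.
#' @return The channel's 3D numeric array.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "intensity_stack"))
  if (!channel %in% names(stack$channels))
    stop("channel '", channel, "' not present; stack has: ",
         paste(names(stack$channels), collapse = ", "), call. = FALSE)
  stack$channels[[channel]]
}

# physical voxel volume in um^3
voxel_volume <- function(stack) prod(stack$voxel_size)
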