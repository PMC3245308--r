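#' Write a stack to a plain-text file
#'
#' Portable text serialization of an [intensity_stack()] (no binary image
#' library is assumed): line 1 is a JSON header
#' `{"format":"pgcquant-stack","version":1,"dim":[z,y,x],
#' "voxel_size_um":[...],"channels":[...]}`; then, for each channel in
#' order and each z slice, `y` rows of `x` space-separated intensities.
#' The round trip is lossless at full double precision.
#'
#' @param stack an [intensity_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "intensity_stack"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(format = "pgcquant-stack", version = 1L,
                               dim = stack$dim,
                               voxel_size_um = stack$voxel_size,
                               channels = names(stack$channels)),
                          auto_unbox = FALSE, digits = NA)
  writeLines(as.character(hdr), con)
  d <- stack$dim
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    for (z in seq_len(d[1])) {
      sl <- matrix(a[z, , ], d[2], d[3])
      writeLines(apply(format(sl, digits = 17, scientific = TRUE,
                              trim = TRUE), 1, paste, collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' @param path file path.
#' @return an [intensity_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path))
    stop("stack file not found: ", path, call. = FALSE)
  con <- file(path, open = "rt")
  on.exit(close(con))
  hdr <- tryCatch(jsonlite::fromJSON(readLines(con, n = 1L)),
                  error = function(e)
                    stop("malformed stack header in ", path, call. = FALSE))
  if (!identical(hdr$format, "pgcquant-stack"))
    stop("not a pgcquant stack file: ", path, call. = FALSE)
  d <- as.integer(hdr$dim)
  vals <- scan(con, what = double(), quiet = TRUE)
  nchan <- length(hdr$channels)
  if (length(vals) != nchan * prod(d))
    stop("stack file ", path, " is truncated", call. = FALSE)
  channels <- vector("list", nchan)
  names(channels) <- hdr$channels
  per <- prod(d)
  for (i in seq_len(nchan)) {
    block <- vals[((i - 1) * per + 1):(i * per)]
    # file order: z slices, each y rows of x values
    a <- aperm(array(block, c(d[3], d[2], d[1])), c(3, 2, 1))
    channels[[i]] <- a
  }
  intensity_stack(channels, as.numeric(hdr$voxel_size_um))
}

#' Write / read a ground-truth table
#'
#' Plain CSV with the documented column names of the generator truth table.
#'
#' @param truth data.frame from [generate_stack()] / [generate_culture_field()].
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_truth_csv <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  if (!file.exists(path))
    stop("truth file not found: ", path, call. = FALSE)
  read.csv(path)
}

#' Serialize / restore a configuration as JSON
#'
#' Round-trips [scene_config()], [counting_config()] and
#' [pipeline_config()] objects without loss (class recorded in the file).
#'
#' @param config a configuration object.
#' @param path file path.
#' @return `path` (write) or the restored object (read).
#' @export
write_config_json <- function(config, path) {
  # named atomic vectors serialize as JSON objects only via lists (recurse
  # into nested configs such as pipeline_config$counting)
  namedify <- function(x) {
    if (is.list(x)) lapply(x, namedify)
    else if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else x
  }
  payload <- list(class = class(config)[1], fields = namedify(unclass(config)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  f <- payload$fields
  # fromJSON turns named numeric vectors into lists; restore them
  restore_named <- function(x) {
    if (is.list(x) && length(x) && all(vapply(x, is.numeric, TRUE)))
      unlist(x)
    else x
  }
  cls <- payload$class
  if (cls == "scene_config") {
    f$marker_positive_fraction <- restore_named(f$marker_positive_fraction)
    do.call(scene_config, f)
  } else if (cls == "counting_config") {
    f$size_guide <- restore_named(f$size_guide)
    do.call(counting_config, f)
  } else if (cls == "pipeline_config") {
    f$counting <- restore_counting(f$counting)
    do.call(pipeline_config, f)
  } else stop("unknown config class: ", cls, call. = FALSE)
}

restore_counting <- function(x) {
  if (inherits(x, "counting_config")) return(x)
  x$size_guide <- unlist(x$size_guide)
  do.call(counting_config, x)
}

#' Write the per-object table as CSV
#'
#' @param objects a `pgc_objects` table.
#' @param path file path.
#' @export
write_objects_csv <- function(objects, path) {
  write.csv(as.data.frame(objects), path, row.names = FALSE)
  invisible(path)
}
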