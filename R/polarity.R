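#' Per-cell organelle polarity record
#'
#' Bundles the geometry the Class I-IV assignment needs: the cell's
#' Elongation Index and long-axis direction, the nuclear extent projected on
#' that axis, the Golgi focus centroids and (optionally) the centrosome
#' centroid, all in one coordinate frame (um). When `nucleus_extent_along_axis`
#' is not given it is computed by projecting `nucleus_centroid +/-
#' nucleus_half_length` onto the axis.
#'
#' @param cell_id identifier.
#' @param ei Elongation Index of the cell.
#' @param long_axis_dir nonzero axis vector (2D or 3D).
#' @param golgi_foci matrix of Golgi focus centroids (one row each, um), or
#'   `NULL` when no Golgi signal was found.
#' @param nucleus_centroid nucleus centroid (um).
#' @param nucleus_half_length half-length of the nucleus along the cell axis
#'   (um); used when `nucleus_extent_along_axis` is absent.
#' @param nucleus_extent_along_axis optional `c(min, max)` scalar projections
#'   of the nuclear extent onto the long axis.
#' @param centrosome_centroid optional centrosome position (um); used only as
#'   a consistency check (Golgi and centrosome are expected co-localized).
#' @return list of class `polarity_record`.
#' @export
polarity_record <- function(cell_id, ei, long_axis_dir, golgi_foci,
                            nucleus_centroid,
                            nucleus_half_length = NULL,
                            nucleus_extent_along_axis = NULL,
                            centrosome_centroid = NULL) {
  u <- as.numeric(long_axis_dir)
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("long_axis_dir must be nonzero", call. = FALSE)
  u <- u / nu
  if (!is.null(golgi_foci)) {
    golgi_foci <- rbind(golgi_foci)
    storage.mode(golgi_foci) <- "double"
  }
  if (is.null(nucleus_extent_along_axis)) {
    if (is.null(nucleus_half_length))
      stop("give nucleus_extent_along_axis or nucleus_half_length",
           call. = FALSE)
    p <- sum(as.numeric(nucleus_centroid) * u)
    nucleus_extent_along_axis <- c(p - nucleus_half_length,
                                   p + nucleus_half_length)
  }
  structure(list(cell_id = cell_id, ei = ei, long_axis_dir = u,
                 golgi_foci = golgi_foci,
                 nucleus_centroid = as.numeric(nucleus_centroid),
                 nucleus_extent_along_axis =
                   as.numeric(nucleus_extent_along_axis),
                 centrosome_centroid =
                   if (is.null(centrosome_centroid)) NULL
                   else as.numeric(centrosome_centroid)),
            class = "polarity_record")
}

#' Classify Golgi/centrosome polarity (Classes I-IV)
#'
#' Rule order (total and deterministic):
#' \enumerate{
#'   \item Class IV - dispersed Golgi: `>= dispersal_min_foci` foci
#'     (typically mitotic cells).
#'   \item Class III - geometrically round cell (`ei < ei_round_threshold`)
#'     with eccentric Golgi.
#'   \item Class I - elongated cell whose principal Golgi centroid projects
#'     beyond a nuclear extreme (within `pole_margin` of, or past, the
#'     nuclear min/max along the long axis).
#'   \item Class II - elongated cell with central Golgi, adjacent to or above
#'     the nucleus.
#' }
#' Records with no Golgi signal are unclassifiable (`NA` with reason
#' attribute), reported distinctly from the four classes. When a centrosome
#' centroid is present and lies more than 3 um from the principal Golgi
#' centroid, a `colocalization_warning` attribute is set (the two are
#' expected co-localized); it does not change the class.
#'
#' @param record a [polarity_record()].
#' @param ei_round_threshold EI below which a cell counts as round
#'   (default 0.10, between reported round ~0.04 and elongated ~0.17 means).
#' @param pole_margin um tolerance around the nuclear extremes (default 0.5).
#' @param dispersal_min_foci focus count that defines dispersal (default 3).
#' @return factor level among `"I"`, `"II"`, `"III"`, `"IV"`, or `NA` for
#'   unclassifiable records.
#' @export
classify_polarity <- function(record, ei_round_threshold = 0.10,
                              pole_margin = 0.5, dispersal_min_foci = 3) {
  stopifnot(inherits(record, "polarity_record"))
  lev <- c("I", "II", "III", "IV")
  if (is.null(record$golgi_foci) || nrow(record$golgi_foci) == 0L) {
    out <- factor(NA_character_, levels = lev)
    attr(out, "reason") <- "no Golgi signal"
    return(out)
  }
  cls <- if (nrow(record$golgi_foci) >= dispersal_min_foci) {
    "IV"
  } else if (record$ei < ei_round_threshold) {
    "III"
  } else {
    g <- colMeans(record$golgi_foci)          # principal Golgi centroid
    p <- sum(g * record$long_axis_dir)
    ext <- record$nucleus_extent_along_axis
    if (p >= max(ext) - pole_margin || p <= min(ext) + pole_margin) "I"
    else "II"
  }
  out <- factor(cls, levels = lev)
  if (!is.null(record$centrosome_centroid) &&
      !is.null(record$golgi_foci) && nrow(record$golgi_foci) > 0L) {
    g <- colMeans(record$golgi_foci)
    d <- sqrt(sum((g - record$centrosome_centroid)^2))
    if (d > 3) attr(out, "colocalization_warning") <-
        sprintf("Golgi-centrosome distance %.1f um > 3 um", d)
  }
  out
}

#' Tally polarity classes
#'
#' Counts and percentages per class over a set of records, plus the
#' alternative "asymmetric Golgi" grouping (Class I + Class III combined,
#' since round Class III cells also carry eccentric Golgi/centrosome).
#'
#' @param records list of [polarity_record()]s, or a factor/character vector
#'   of pre-assigned classes.
#' @param ... passed to [classify_polarity()] when records are given.
#' @return list of class `class_distribution`: `counts` (named, I-IV),
#'   `percentages` (of classified records), `n_classified`,
#'   `n_unclassifiable`, `asymmetric_count` and `asymmetric_percentage`
#'   (Class I + III).
#' @export
class_distribution <- function(records, ...) {
  lev <- c("I", "II", "III", "IV")
  cls <- if (is.list(records) && all(vapply(records, inherits, TRUE,
                                            "polarity_record"))) {
    vapply(records, function(r) as.character(classify_polarity(r, ...)),
           character(1))
  } else {
    as.character(records)
  }
  if (length(cls) && any(!cls %in% c(lev, NA)))
    stop("classes must be among I, II, III, IV or NA", call. = FALSE)
  f <- factor(cls, levels = lev)
  counts <- table(f)
  n <- sum(counts)
  pct <- if (n > 0) 100 * as.numeric(counts) / n else rep(0, 4)
  names(pct) <- lev
  asym <- unname(counts["I"] + counts["III"])
  structure(list(counts = stats::setNames(as.integer(counts), lev),
                 percentages = pct,
                 n_classified = as.integer(n),
                 n_unclassifiable = sum(is.na(cls)),
                 asymmetric_count = as.integer(asym),
                 asymmetric_percentage = if (n > 0) 100 * asym / n else 0),
            class = "class_distribution")
}

#' @export
print.class_distribution <- function(x, ...) {
  cat("<class_distribution> n =", x$n_classified, "classified")
  if (x$n_unclassifiable) cat(" (", x$n_unclassifiable, " unclassifiable)",
                              sep = "")
  cat("\n")
  for (k in names(x$counts))
    cat(sprintf("  Class %-3s %4d  (%5.1f%%)\n", k, x$counts[[k]],
                x$percentages[[k]]))
  cat(sprintf("  asymmetric Golgi (I+III): %d (%.1f%%)\n",
              x$asymmetric_count, x$asymmetric_percentage))
  invisible(x)
}
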