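#' Criteria for marker co-labeling
#'
#' An object counts as marker-positive when it passes both rules: its mean
#' intensity in the marker channel exceeds the channel's global
#' `mean + k_marker * SD`, and at least `min_overlap_fraction` of its voxels
#' individually exceed that same threshold. Both knobs are exposed because
#' the original protocol names "intensity and colocalization functions"
#' without formulas.
#'
#' @param marker_channel marker channel role (e.g. `"PHH3"`, `"cPARP"`).
#' @param k_marker SD multiplier for the marker threshold (default 3.5).
#' @param min_overlap_fraction fraction of object voxels that must be above
#'   the marker threshold, in `(0, 1]` (default 0.5).
#' @return list of class `colabel_criteria`.
#' @export
colabel_criteria <- function(marker_channel, k_marker = 3.5,
                             min_overlap_fraction = 0.5) {
  if (k_marker <= 0) stop("k_marker must be > 0", call. = FALSE)
  if (min_overlap_fraction <= 0 || min_overlap_fraction > 1)
    stop("min_overlap_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(marker_channel = marker_channel, k_marker = k_marker,
                 min_overlap_fraction = min_overlap_fraction),
            class = "colabel_criteria")
}

#' Marker-positive subset and frequency
#'
#' Applies [colabel_criteria()] to every segmented object and reports the
#' positive subset with its frequency as a percentage of all objects, plus
#' an exact (Clopper-Pearson) binomial 95% confidence interval.
#'
#' @param objects a `pgc_objects` table with label array.
#' @param stack the source [intensity_stack()] containing the marker channel.
#' @param criteria a [colabel_criteria()].
#' @return list of class `colabel_result`: `table` (per-object data.frame
#'   with `label`, `marker_mean`, `overlap_fraction`, `positive`),
#'   `positive_ids`, `n_positive`, `n_total`, `percentage` (NA with a
#'   warning when there are no objects), `ci95` (percent).
#' @export
colabel_fraction <- function(objects, stack, criteria) {
  stopifnot(inherits(objects, "pgc_objects"),
            inherits(stack, "intensity_stack"),
            inherits(criteria, "colabel_criteria"))
  ch <- criteria$marker_channel
  v <- get_channel(stack, ch)
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))
  thr <- mu + criteria$k_marker * sdev
  lab <- attr(objects, "label_array")
  n <- nrow(objects)
  if (n == 0L) {
    warning("no objects: co-label percentage undefined", call. = FALSE)
    return(structure(list(table = data.frame(), positive_ids = integer(0),
                          n_positive = 0L, n_total = 0L,
                          percentage = NA_real_, ci95 = c(NA_real_, NA_real_)),
                     class = "colabel_result"))
  }
  idx <- which(lab > 0L)
  labs <- lab[idx]
  nvox <- tabulate(labs, nbins = max(objects$label))[objects$label]
  means <- tapply_sum(v[idx], labs, max(objects$label))[objects$label] / nvox
  over <- tapply_sum(v[idx] > thr, labs, max(objects$label))[objects$label] /
    nvox
  pos <- means > thr & over >= criteria$min_overlap_fraction
  k <- sum(pos)
  ci <- binom_ci_exact(k, n)
  structure(list(
    table = data.frame(label = objects$label, marker_mean = means,
                       overlap_fraction = over, positive = pos),
    positive_ids = objects$label[pos],
    n_positive = as.integer(k), n_total = as.integer(n),
    percentage = 100 * k / n, ci95 = 100 * ci),
    class = "colabel_result")
}

#' @export
print.colabel_result <- function(x, ...) {
  if (is.na(x$percentage)) cat("<colabel_result> no objects\n")
  else cat(sprintf(
    "<colabel_result> %d / %d positive = %.1f%% (95%% CI %.1f-%.1f%%)\n",
    x$n_positive, x$n_total, x$percentage, x$ci95[1], x$ci95[2]))
  invisible(x)
}

# Clopper-Pearson exact binomial CI (two-sided 95%), as a proportion.
binom_ci_exact <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lo, hi)
}
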