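#' Population doubling time from two counts
#'
#' `T_d = dt * ln 2 / ln(n2 / n1)` for counts `n1 -> n2` over `dt` hours.
#' Negative when the population declines (halving time, reported with sign);
#' `n2 == n1` gives `Inf` with a warning.
#'
#' @param n1,n2 positive counts at the two stages.
#' @param dt_hours elapsed time in hours, `> 0`.
#' @return doubling time in hours.
#' @examples
#' doubling_time(551, 2598, 30)   # ~13.4 h
#' @export
doubling_time <- function(n1, n2, dt_hours) {
  if (any(n1 <= 0) || any(n2 <= 0) || any(dt_hours <= 0))
    stop("n1, n2 and dt_hours must be positive", call. = FALSE)
  out <- dt_hours * log(2) / log(n2 / n1)
  if (any(n1 == n2)) {
    warning("n2 == n1: doubling time undefined, reporting Inf", call. = FALSE)
    out[n1 == n2] <- Inf
  }
  out
}

#' Two-sample t test (pooled or Welch)
#'
#' Closed-form two-sided test. The pooled variant is the classical Student's
#' t; Welch is exposed for unequal variances.
#'
#' @param group_a,group_b numeric vectors, each of length `>= 2`.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return list: `t`, `df`, `p` (two-sided), `variant`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(group_a, group_b,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2)
    stop("each group needs n >= 2", call. = FALSE)
  va <- var(group_a); vb <- var(group_b)
  if (va == 0 && vb == 0 && mean(group_a) == mean(group_b)) {
    # degenerate but well-defined: identical constant groups
    return(list(t = 0, df = if (variant == "pooled") na + nb - 2 else NA_real_,
                p = 1, variant = variant,
                mean_a = mean(group_a), mean_b = mean(group_b)))
  }
  if (va == 0 && vb == 0)
    stop("zero variance in both groups: t statistic undefined", call. = FALSE)
  dm <- mean(group_a) - mean(group_b)
  if (variant == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- dm / se
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = max(p, .Machine$double.xmin), variant = variant,
       mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Fisher's exact test (two-sided) for a 2x2 table
#'
#' Enumerates all tables with the observed margins and sums the
#' hypergeometric probabilities of those no more probable than the observed
#' table (with the conventional `1 + 1e-7` relative tolerance for ties).
#' Probabilities come from an in-package log-factorial table.
#'
#' @param table 2x2 matrix of non-negative integer counts, at least one
#'   positive.
#' @return two-sided p-value in `(0, 1]`.
#' @examples
#' fisher_exact(matrix(c(0, 5, 5, 0), 2))   # ~0.00794
#' @export
fisher_exact <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L)))
    stop("table must be 2x2", call. = FALSE)
  if (any(tb < 0) || any(tb != round(tb)))
    stop("cells must be non-negative integers", call. = FALSE)
  if (sum(tb) == 0) stop("at least one cell must be positive", call. = FALSE)
  r1 <- sum(tb[1, ]); c1 <- sum(tb[, 1]); n <- sum(tb)
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  lf <- lgamma(seq_len(n + 1))                      # lf[k+1] = log(k!)
  lchoose2 <- function(a, b) lf[a + 1] - lf[b + 1] - lf[a - b + 1]
  logp <- function(k)
    lchoose2(c1, k) + lchoose2(n - c1, r1 - k) - lchoose2(n, r1)
  ks <- lo:hi
  pk <- exp(vapply(ks, logp, numeric(1)))
  obs <- pk[ks == tb[1, 1]]
  min(1, sum(pk[pk <= obs * (1 + 1e-7)]))
}

#' Uniformity test for folded orientation angles
#'
#' Tests whether folded long-axis angles (degrees in `[0, 90]` relative to a
#' gradient) are uniform. `"ks"` is a one-sample Kolmogorov-Smirnov test
#' against Uniform(0, 90) (two-sided; any deviation). `"rayleigh_axial"` is
#' an axial concentration test: with folded axial data the sine component of
#' the doubled-angle resultant is not identified, so the statistic is the
#' V-test-type `z = mean(cos(2 theta)) * sqrt(2 n)`, standard normal under
#' uniformity, with a one-sided p toward alignment at 0 degrees.
#'
#' @param angles degrees in `[0, 90]`, `n >= 5`.
#' @param method `"ks"` or `"rayleigh_axial"`.
#' @return list: `p`, `statistic`, `method`, `n`.
#' @export
angle_uniformity_test <- function(angles, method = c("ks", "rayleigh_axial")) {
  method <- match.arg(method)
  if (length(angles) < 5) stop("need n >= 5 angles", call. = FALSE)
  if (any(angles < 0 | angles > 90))
    stop("angles must lie in [0, 90] degrees", call. = FALSE)
  if (method == "ks") {
    kt <- suppressWarnings(ks.test(angles, "punif", 0, 90))
    list(p = max(kt$p.value, .Machine$double.xmin),
         statistic = unname(kt$statistic), method = method,
         n = length(angles))
  } else {
    n <- length(angles)
    cbar <- mean(cos(2 * angles * pi / 180))
    z <- cbar * sqrt(2 * n)
    list(p = max(pnorm(z, lower.tail = FALSE), .Machine$double.xmin),
         statistic = z, method = method, n = length(angles))
  }
}

#' Significance stars
#'
#' Bins a p-value the way the figure legends do; applied only at report
#' rendering, never to stored p-values.
#'
#' @param p p-value(s).
#' @return character: `"***"` p<0.001, `"**"` p<0.01, `"*"` p<0.05,
#'   `"ns"` otherwise.
#' @export
p_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) NA_character_
    else if (x < 0.001) "***"
    else if (x < 0.01) "**"
    else if (x < 0.05) "*"
    else "ns"
  }, character(1))
}
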