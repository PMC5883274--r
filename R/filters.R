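#' Low-signal cutoff from the rank-intensity curve
#'
#' Oligos that never rise above the array's background regime detect nothing
#' and are removed before testing. Each probe is summarized by the maximum of
#' its two per-region mean intensities (a probe expressed in either region is
#' informative); probes are ranked high-to-low and the rank-intensity curve is
#' examined for the shoulder that separates the expressed regime from the
#' near-background plateau. The shoulder is localized automatically: the
#' curve is smoothed with a running mean (window `w` = 1% of probes, at least
#' 25), the steepest point of descent is found, and a shoulder is declared
#' only when that slope is at least four times steeper than the curve on both
#' flanks - a featureless unimodal curve has no such point and triggers the
#' no-removal fallback. The detection threshold is the paper-rule statistic
#' computed where the curve has flattened into the background plateau: the
#' mean over a window of 2w+1 probes starting at the flattening point plus
#' 2.5 times the standard deviation over that window. Probes whose statistic
#' falls below the threshold are removed.
#'
#' @param region_means probes-by-2 matrix (or data.frame) of per-region mean
#'   intensities, rownames = probe ids; or a plain named vector already
#'   summarized per probe.
#' @param statistic `"max"` (default) takes the maximum over region means,
#'   `"mean"` their average; ignored when a vector is supplied.
#' @return list of class `low_signal_cutoff`: `threshold`, `removed`
#'   (character vector of probe ids), `found` (was a shoulder detected),
#'   `window` (index range, in rank order, of the statistics window),
#'   `stat` (the sorted per-probe statistic used).
#' @export
low_signal_cutoff <- function(region_means, statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  if (is.matrix(region_means) || is.data.frame(region_means)) {
    rm <- as.matrix(region_means)
    stat <- if (statistic == "max") apply(rm, 1L, max) else rowMeans(rm)
    names(stat) <- rownames(rm)
  } else {
    stat <- region_means
  }
  if (is.null(names(stat))) names(stat) <- as.character(seq_along(stat))
  s <- sort(stat, decreasing = TRUE)
  n <- length(s)
  w <- max(25L, round(0.01 * n))
  fallback <- list(threshold = NA_real_, removed = character(0),
                   found = FALSE, window = NULL, stat = s)
  class(fallback) <- "low_signal_cutoff"
  if (n < 8L * w + 2L) {
    warning("too few probes to detect an inflection; nothing removed")
    return(fallback)
  }
  sm <- stats::filter(as.numeric(s), rep(1 / w, w), sides = 2)
  sm[seq_len(w)] <- sm[w + 1L]
  sm[(n - w):n] <- sm[n - w - 1L]
  slope <- c(NA_real_, diff(sm))
  lo <- 2L * w
  hi <- n - 2L * w
  i <- lo + which.min(slope[lo:hi]) - 1L
  lf <- (i - 6L * w):(i - 3L * w)
  rf <- (i + 3L * w):(i + 6L * w)
  if (min(lf) < 1L || max(rf) > n) {
    warning("no interior inflection detectable; nothing removed")
    return(fallback)
  }
  steep <- abs(slope[i])
  flank_l <- abs(median(slope[lf], na.rm = TRUE))
  flank_r <- abs(median(slope[rf], na.rm = TRUE))
  if (!(steep > 4 * flank_l && steep > 4 * flank_r)) {
    warning("rank-intensity curve has no pronounced shoulder; nothing removed")
    return(fallback)
  }
  # walk right until the curve flattens into the background plateau
  j <- i
  while (j < i + 6L * w && j < n - 2L * w && abs(slope[j]) > steep / 4)
    j <- j + 1L
  win <- j:min(n, j + 2L * w)
  threshold <- mean(s[win]) + 2.5 * sd(s[win])
  removed <- names(stat)[stat < threshold]
  out <- list(threshold = threshold, removed = removed, found = TRUE,
              window = range(win), stat = s)
  class(out) <- "low_signal_cutoff"
  out
}

#' High-variance (coefficient of variation) probe filter
#'
#' Probes whose stdev/mean is more than two times the average stdev/mean of
#' the whole probe population are too noisy to contribute reliable per-gene
#' information and are removed. The boundary is strict: a probe exactly at
#' twice the population mean CV is retained. CVs are computed on the
#' unlogged scale; probes with a non-positive mean have no defined CV and
#' are removed with their own flag. When a `group` assignment is supplied
#' (the nucleus/surround regions), the CV is computed within each group and
#' the probe is summarized by its largest group CV, so that a genuine
#' between-region fold change does not masquerade as noise.
#'
#' @param values probes-by-samples matrix of unlogged intensities, rownames
#'   = probe ids.
#' @param group optional vector of length `ncol(values)` assigning samples
#'   to groups; `NULL` treats all samples as one group.
#' @return list: `removed` (probe ids above the line), `undefined` (probe
#'   ids with non-positive mean), `cv` (per-probe CV), `threshold`.
#' @export
high_variance_filter <- function(values, group = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- as.character(seq_len(nrow(values)))
  if (is.null(group)) group <- rep("all", ncol(values))
  stopifnot(length(group) == ncol(values))
  cv_mat <- vapply(unique(group), function(g) {
    v <- values[, group == g, drop = FALSE]
    mu <- rowMeans(v)
    sdv <- apply(v, 1L, sd)
    ifelse(mu > 0, sdv / mu, NA_real_)
  }, numeric(nrow(values)))
  cv_mat <- matrix(cv_mat, nrow = nrow(values))
  cv <- apply(cv_mat, 1L, function(x) if (all(is.na(x))) NA_real_
              else max(x, na.rm = TRUE))
  names(cv) <- rownames(values)
  undefined <- names(cv)[is.na(cv)]
  ok <- !is.na(cv)
  threshold <- 2 * mean(cv[ok])
  removed <- names(cv)[ok][cv[ok] > threshold]
  list(removed = removed, undefined = undefined, cv = cv,
       threshold = threshold)
}
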