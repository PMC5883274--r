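#' Default p-value histogram bin edges for cutoff calibration
#'
#' Twenty equal-width bins on \[0, 1\] plus refined edges at 0.001, 0.005,
#' 0.01 and 0.02 to resolve the small-p region where validated cutoffs live.
#'
#' @return increasing numeric vector of bin edges from 0 to 1.
#' @export
calibration_bins <- function() {
  sort(unique(c(seq(0, 1, by = 0.05), 0.001, 0.005, 0.01, 0.02)))
}

#' Collect probe-level p-values for labeled validation genes
#'
#' For every retained probe annotated to a gene carrying an independent
#' validation label, retrieves its p-value into the differential or
#' non-differential list (a gene contributes as many p-values as it has
#' retained probes). Excluded labels are dropped.
#'
#' @param stats per-probe statistics (needs `probe_id`, `p`).
#' @param annotations probe-to-gene map (needs `probe_id`, `gene_id`).
#' @param labels validation label table (`gene_id`, `label` in
#'   differential/nondifferential/excluded).
#' @return list with numeric vectors `diff` and `nondiff`.
#' @export
collect_labeled_pvalues <- function(stats, annotations, labels) {
  labels <- labels[labels$label != "excluded", , drop = FALSE]
  m <- merge(stats[, c("probe_id", "p")],
             annotations[!is.na(annotations$gene_id),
                         c("probe_id", "gene_id")], by = "probe_id")
  m <- merge(m, labels[, c("gene_id", "label")], by = "gene_id")
  d <- m$p[m$label == "differential"]
  nd <- m$p[m$label == "nondifferential"]
  if (length(d) == 0L || length(nd) == 0L)
    stop_nucmark(paste("no labeled probes in one or both classes;",
                       "fall back to default_cutoff()"),
                 "nucmark_no_labels")
  list(diff = d, nondiff = nd)
}

#' Choose a significance cutoff from class-conditional p-value histograms
#'
#' Builds p-value frequency histograms for probes of independently validated
#' differential and non-differential genes, and picks, over the cumulative
#' bin edges, the cutoff capturing the highest proportion of true versus
#' false positives: the maximizer of TPR - FPR (Youden's J), where TPR is
#' the fraction of differential-probe p-values at or below the cutoff and
#' FPR the same fraction for non-differential probes. Ties are broken toward
#' the smaller, more conservative cutoff. When the two distributions are
#' indistinguishable (max J <= 0) the standard default of 0.05 is returned
#' with a warning.
#'
#' @param diff_p,nondiff_p probe-level p-values of the two labeled classes.
#' @param bin_edges histogram bin edges; see [calibration_bins()].
#' @param contrast optional contrast name stored in the result.
#' @return object of class `calibration_result`: `contrast`, `cutoff_p`,
#'   `bin_edges`, `diff_hist` and `nondiff_hist` (per-bin proportions,
#'   each summing to 1), `tpr_at_cutoff`, `fpr_at_cutoff`, `n_diff_probes`,
#'   `n_nondiff_probes`, `method` ("calibrated" or "default").
#' @export
choose_cutoff <- function(diff_p, nondiff_p, bin_edges = calibration_bins(),
                          contrast = NA_character_) {
  stopifnot(length(diff_p) > 0L, length(nondiff_p) > 0L)
  bin_edges <- sort(unique(bin_edges))
  candidates <- bin_edges[bin_edges > 0 & bin_edges < 1]
  tpr <- vapply(candidates, function(c) mean(diff_p <= c), numeric(1))
  fpr <- vapply(candidates, function(c) mean(nondiff_p <= c), numeric(1))
  j <- tpr - fpr
  if (max(j) <= 0) {
    warning("differential and non-differential p-value distributions are ",
            "indistinguishable; using default cutoff 0.05")
    res <- default_cutoff(contrast = contrast)
    res$bin_edges <- bin_edges
    res$diff_hist <- p_hist(diff_p, bin_edges)
    res$nondiff_hist <- p_hist(nondiff_p, bin_edges)
    res$n_diff_probes <- length(diff_p)
    res$n_nondiff_probes <- length(nondiff_p)
    res$tpr_at_cutoff <- mean(diff_p <= res$cutoff_p)
    res$fpr_at_cutoff <- mean(nondiff_p <= res$cutoff_p)
    return(res)
  }
  best <- which(j == max(j))[1L]  # candidates ascending: first max = smallest
  structure(list(
    contrast = contrast,
    cutoff_p = candidates[best],
    bin_edges = bin_edges,
    diff_hist = p_hist(diff_p, bin_edges),
    nondiff_hist = p_hist(nondiff_p, bin_edges),
    tpr_at_cutoff = tpr[best],
    fpr_at_cutoff = fpr[best],
    n_diff_probes = length(diff_p),
    n_nondiff_probes = length(nondiff_p),
    method = "calibrated"
  ), class = "calibration_result")
}

# per-bin proportions with right-closed bins (a, b]; p = 0 lands in bin 1
p_hist <- function(p, edges) {
  idx <- findInterval(p, edges, left.open = TRUE)
  idx <- pmin(pmax(idx, 1L), length(edges) - 1L)
  tabulate(idx, nbins = length(edges) - 1L) / length(p)
}

#' Default significance cutoff
#'
#' Used for contrasts with no validation labels (or as an explicit manual
#' override to reproduce a visually chosen cutoff): the standard p < 0.05
#' rule.
#'
#' @param cutoff_p the cutoff to use; default 0.05.
#' @param contrast optional contrast name.
#' @return a `calibration_result` with `method = "default"`.
#' @export
default_cutoff <- function(cutoff_p = 0.05, contrast = NA_character_) {
  stopifnot(cutoff_p > 0, cutoff_p < 1)
  structure(list(
    contrast = contrast, cutoff_p = cutoff_p,
    bin_edges = calibration_bins(),
    diff_hist = NULL, nondiff_hist = NULL,
    tpr_at_cutoff = NA_real_, fpr_at_cutoff = NA_real_,
    n_diff_probes = 0L, n_nondiff_probes = 0L,
    method = "default"
  ), class = "calibration_result")
}

#' Calibrate a contrast, falling back to the default when labels are absent
#'
#' @param stats per-probe statistics table.
#' @param annotations probe-to-gene map.
#' @param labels validation labels, or `NULL`.
#' @param manual_cutoff optional explicit cutoff that wins over calibration.
#' @param contrast contrast name.
#' @return a `calibration_result`.
#' @export
calibrate_cutoff <- function(stats, annotations, labels = NULL,
                             manual_cutoff = NULL, contrast = NA_character_) {
  if (!is.null(manual_cutoff)) {
    message("using manually specified cutoff ", manual_cutoff)
    return(default_cutoff(manual_cutoff, contrast = contrast))
  }
  if (is.null(labels) || nrow(labels) == 0L)
    return(default_cutoff(contrast = contrast))
  tryCatch({
    pv <- collect_labeled_pvalues(stats, annotations, labels)
    choose_cutoff(pv$diff, pv$nondiff, contrast = contrast)
  }, nucmark_no_labels = function(e) {
    warning(conditionMessage(e))
    default_cutoff(contrast = contrast)
  })
}
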