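#' Run the full marker-discovery pipeline on one contrast
#'
#' Chains every stage for a single nucleus-versus-surround experiment:
#' probe curation (sequence and alignment QC, strand-aware annotation), then
#' platform-specific preprocessing - for the two-channel common-reference
#' design, background correction, print-tip loess normalization and
#' orientation to log2(sample/reference); for single-channel data, the
#' low-signal and high-variance probe filters - then moderated t-statistics
#' with multiple-testing adjustment, cutoff calibration against the
#' validation labels (default p < 0.05 when labels are absent), and
#' majority-rule gene scoring.
#'
#' @param library probe library ([generate_probe_library()] or equivalent
#'   tables).
#' @param intensities intensity data ([generate_intensities()] shape).
#' @param labels validation label table or `NULL`.
#' @param contrast contrast name.
#' @param adjust_method q-value method; defaults to Storey's estimator for
#'   the two-channel platform and Benjamini-Hochberg for single-channel,
#'   mirroring common practice for the two array generations.
#' @param manual_cutoff optional explicit p cutoff overriding calibration.
#' @param insitu optional in-situ call table merged into the final scores.
#' @return list: `curated`, `stats` (per-probe M, A, t, p, q), `calibration`,
#'   `scores`, `filter_report` (probe removals with reasons), `model`.
#' @export
run_contrast <- function(library, intensities, labels = NULL,
                         contrast = "nucleus", adjust_method = NULL,
                         manual_cutoff = NULL, insitu = NULL) {
  platform <- intensities$platform
  if (is.null(adjust_method))
    adjust_method <- if (platform == "two_channel") "storey" else "BH"
  curated <- curate_probes(library$probes, library$alignments,
                           library$gene_models)
  report <- data.frame(probe_id = curated$probe_id[!curated$keep],
                       reason = curated$qc_flags[!curated$keep],
                       stringsAsFactors = FALSE)
  retained <- curated$probe_id[curated$keep]

  if (platform == "two_channel") {
    proc <- process_two_channel(intensities)
    values <- proc$M[retained, , drop = FALSE]
    group <- intensities$design$region
  } else {
    values <- intensities$values[retained, , drop = FALSE]
    group <- intensities$design$region
    rmeans <- cbind(
      nucleus = rowMeans(values[, group == "nucleus", drop = FALSE]),
      surround = rowMeans(values[, group == "surround", drop = FALSE]))
    ls <- low_signal_cutoff(rmeans)
    if (length(ls$removed)) {
      report <- rbind(report, data.frame(probe_id = ls$removed,
                                         reason = "low_signal",
                                         stringsAsFactors = FALSE))
      values <- values[setdiff(rownames(values), ls$removed), , drop = FALSE]
    }
    hv <- high_variance_filter(2^values, group = group)
    drop <- union(hv$removed, hv$undefined)
    if (length(drop)) {
      report <- rbind(report, data.frame(
        probe_id = drop,
        reason = ifelse(drop %in% hv$undefined, "cv_undefined",
                        "high_variance"),
        stringsAsFactors = FALSE))
      values <- values[setdiff(rownames(values), drop), , drop = FALSE]
    }
  }

  fit <- fit_moderated_t(values, group, contrast = c("nucleus", "surround"))
  stats <- fit$table
  stats$q <- adjust_pvalues(stats$p, method = adjust_method)

  calibration <- calibrate_cutoff(stats, curated, labels,
                                  manual_cutoff = manual_cutoff,
                                  contrast = contrast)
  scores <- score_genes(stats, curated, calibration$cutoff_p,
                        contrast = contrast,
                        universe_genes = library$gene_models$gene_id)
  scores <- merge_insitu(scores, insitu)
  list(curated = curated, stats = stats, calibration = calibration,
       scores = scores, filter_report = report, model = fit$model)
}

#' Compare gene scores against the simulation ground truth
#'
#' Gene-level operating characteristics of a pipeline run on synthetic data:
#' sensitivity (truly differential genes called differential, among those
#' assessed), empirical false-discovery proportion among differential calls,
#' and the fraction of true positives with the correct direction.
#'
#' @param scores gene score table from [score_genes()].
#' @param truth `truth` element of the probe library.
#' @return list: `sensitivity`, `fdp`, `direction_accuracy`, `n_assessed`,
#'   `n_called`, `n_true_positive`.
#' @export
evaluate_scores <- function(scores, truth) {
  tg <- truth$genes[, c("gene_id", "true_log2fc")]
  m <- merge(scores, tg, by = "gene_id")
  assessed <- m$status %in% c("differential", "nondifferential")
  called <- m$status == "differential"
  is_diff <- m$true_log2fc != 0
  tp <- called & is_diff
  sens <- if (any(is_diff & assessed)) sum(tp) / sum(is_diff & assessed)
          else NA_real_
  fdp <- if (any(called)) sum(called & !is_diff) / sum(called) else 0
  dir_ok <- m$direction[tp] == ifelse(m$true_log2fc[tp] > 0, "up", "down")
  list(sensitivity = sens, fdp = fdp,
       direction_accuracy = if (any(tp)) mean(dir_ok) else NA_real_,
       n_assessed = sum(assessed), n_called = sum(called),
       n_true_positive = sum(tp))
}
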