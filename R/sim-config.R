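#' Configuration for the synthetic paired-region study generator
#'
#' Bundles and validates every knob of the synthetic-data module. The defaults
#' describe the study conditions the rest of the package is exercised under: a
#' nucleus-versus-surround contrast with `n_pairs` paired laser-capture samples
#' per region, two probes per gene on average, 10% of genes truly differential
#' with a log2 fold change of magnitude `effect_size`, per-channel log2 noise
#' of `noise_sd`, and a probe library contaminated with the artifact classes
#' the curation stage screens for (5' poly-T cloning artifacts, multi-locus
#' probes, probes that fail to align, and benign chrUn allelic secondaries).
#'
#' @param seed master seed; per-stage substreams are derived from it, so a
#'   config generates byte-identical data every time.
#' @param n_genes number of gene models on the synthetic genome.
#' @param probes_per_gene either a single count (1-6) used for every gene, or
#'   a probability vector over 1..6 probes.
#' @param frac_differential fraction of genes truly differential.
#' @param frac_up_among_diff fraction of differential genes up-regulated in
#'   the nucleus.
#' @param effect_size true log2 fold change magnitude (nucleus over surround)
#'   planted for differential genes.
#' @param noise_sd per-sample, per-channel noise SD on the log2 scale.
#' @param pair_sd SD of an optional per-pair (per-bird) random effect shared
#'   by the nucleus and surround sample of a pair; 0 disables it.
#' @param n_pairs number of sample pairs (arrays per region).
#' @param platform `"two_channel"` for the common-reference cDNA design
#'   (foreground/background per dye channel, dye-balanced) or
#'   `"single_channel"` for pre-normalized oligo-array values.
#' @param artifact_rates named list of fractions: `polyT`, `multilocus`,
#'   `unaligned` (exclusion classes, mutually exclusive) and `chrun_secondary`
#'   (benign retained flag).
#' @param redundant_rate fraction of multi-probe genes whose first two probes
#'   are placed with >75% mutual overlap, to exercise redundant-probe
#'   collapsing.
#' @param label_coverage fraction of genes receiving an in-situ-style
#'   validation label.
#' @param label_error_rate fraction of labels flipped relative to truth.
#' @param label_excluded_rate fraction of labeled genes marked `excluded`
#'   (unevaluable in-situ material).
#' @param low_expression_fraction fraction of probes drawn from the
#'   near-background intensity regime.
#' @param print_tip_groups number of print-tip groups on a two-channel array.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       probes_per_gene = 2L,
                       frac_differential = 0.1,
                       frac_up_among_diff = 0.6,
                       effect_size = 2,
                       noise_sd = 0.4,
                       pair_sd = 0,
                       n_pairs = 6L,
                       platform = c("two_channel", "single_channel"),
                       artifact_rates = list(polyT = 0.05, multilocus = 0.03,
                                             unaligned = 0.02,
                                             chrun_secondary = 0.05),
                       redundant_rate = 0.2,
                       label_coverage = 0.3,
                       label_error_rate = 0.05,
                       label_excluded_rate = 0.05,
                       low_expression_fraction = 0.2,
                       print_tip_groups = 4L) {
  platform <- match.arg(platform)
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  stopifnot(is.numeric(n_genes), n_genes >= 1)
  if (length(probes_per_gene) == 1L) {
    stopifnot(probes_per_gene >= 1, probes_per_gene <= 6)
    p <- numeric(6); p[as.integer(probes_per_gene)] <- 1
    probes_per_gene <- p
  }
  stopifnot(length(probes_per_gene) == 6L, all(probes_per_gene >= 0),
            sum(probes_per_gene) > 0)
  probes_per_gene <- probes_per_gene / sum(probes_per_gene)
  for (f in list(frac_differential, frac_up_among_diff, redundant_rate,
                 label_coverage, label_error_rate, label_excluded_rate,
                 low_expression_fraction)) {
    if (!is_fraction(f)) stop("all fractions must be single values in [0,1]")
  }
  stopifnot(is.numeric(effect_size), effect_size >= 0,
            is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(pair_sd), pair_sd >= 0,
            n_pairs >= 2, print_tip_groups >= 1)
  need <- c("polyT", "multilocus", "unaligned", "chrun_secondary")
  if (!all(need %in% names(artifact_rates)))
    stop("artifact_rates must name polyT, multilocus, unaligned, chrun_secondary")
  for (f in artifact_rates[need]) {
    if (!is_fraction(f)) stop("artifact rates must be fractions in [0,1]")
  }
  if (sum(unlist(artifact_rates[c("polyT", "multilocus", "unaligned")])) > 1)
    stop("exclusion artifact rates must sum to at most 1")
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    probes_per_gene = probes_per_gene,
    frac_differential = frac_differential,
    frac_up_among_diff = frac_up_among_diff,
    effect_size = effect_size, noise_sd = noise_sd, pair_sd = pair_sd,
    n_pairs = as.integer(n_pairs), platform = platform,
    artifact_rates = artifact_rates[need], redundant_rate = redundant_rate,
    label_coverage = label_coverage, label_error_rate = label_error_rate,
    label_excluded_rate = label_excluded_rate,
    low_expression_fraction = low_expression_fraction,
    print_tip_groups = as.integer(print_tip_groups)
  ), class = "sim_config")
}
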