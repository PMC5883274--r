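#' Generate a synthetic probe library, genome, and ground truth
#'
#' Builds a small synthetic genome (four named chromosomes plus a `chrUn`
#' pseudo-chromosome of unplaced scaffolds), lays out one gene model per gene
#' with random strand, and places each gene's probes inside its span. A
#' configurable fraction of probes carries one of the defects the curation
#' stage screens for: a 5' poly-T run (second-strand oligo-dT priming
#' artifact), passing alignments on two different named chromosomes, no
#' genome alignment at all, or a retained high-identity secondary alignment
#' on `chrUn` (benign, presumed allelic). Some multi-probe genes get a probe
#' pair with >75% mutual overlap to exercise redundant-probe collapsing.
#'
#' @param config a [sim_config()].
#' @return a list with elements `probes` (probe table), `alignments`
#'   (PSL-like table: probe_id, chrom, strand, start, end, identity, score,
#'   rank), `gene_models`, and `truth` (per-gene status/true log2 fold change
#'   and per-probe artifact class, regime, and parent gene). Coordinates are
#'   0-based half-open throughout.
#' @export
generate_probe_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  run_with_seed(substream_seed(config$seed, "library"), {
    n_genes <- config$n_genes
    chroms <- c("chr1", "chr2", "chr3", "chr4")
    probe_len <- if (config$platform == "two_channel") 500L else 60L

    gene_len <- sample(2000:8000, n_genes, replace = TRUE)
    gap <- sample(3000:15000, n_genes, replace = TRUE)
    chrom <- rep(chroms, length.out = n_genes)
    start <- integer(n_genes)
    pos <- setNames(rep(0L, length(chroms)), chroms)
    for (i in seq_len(n_genes)) {
      start[i] <- pos[chrom[i]] + gap[i]
      pos[chrom[i]] <- start[i] + gene_len[i]
    }
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    gene_models <- data.frame(
      gene_id = gene_id,
      symbol = sprintf("GENE%04d", seq_len(n_genes)),
      chrom = chrom,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      start = start,
      end = start + gene_len,
      stringsAsFactors = FALSE
    )

    # gene-level truth
    n_diff <- round(config$frac_differential * n_genes)
    diff_idx <- sample.int(n_genes, n_diff)
    status <- rep("null", n_genes)
    n_up <- round(config$frac_up_among_diff * n_diff)
    up_idx <- if (n_diff) diff_idx[seq_len(n_up)] else integer(0)
    status[diff_idx] <- "down"
    status[up_idx] <- "up"
    lfc <- ifelse(status == "up", config$effect_size,
                  ifelse(status == "down", -config$effect_size, 0))
    truth_genes <- data.frame(gene_id = gene_id, status = status,
                              true_log2fc = lfc, stringsAsFactors = FALSE)

    # probes per gene
    k <- sample(1:6, n_genes, replace = TRUE, prob = config$probes_per_gene)
    parent <- rep(seq_len(n_genes), k)
    n_probes <- length(parent)
    probe_id <- sprintf("P%05d", seq_len(n_probes))

    # placement within the gene span; optionally make the first two probes of
    # a gene near-copies (>75% mutual overlap)
    p_start <- integer(n_probes)
    redundant <- rep(FALSE, n_probes)
    idx_by_gene <- split(seq_len(n_probes), parent)
    for (g in seq_len(n_genes)) {
      ii <- idx_by_gene[[as.character(g)]]
      span <- gene_len[g] - probe_len
      p_start[ii] <- gene_models$start[g] + sample.int(max(span, 1L), length(ii),
                                                       replace = TRUE) - 1L
      if (length(ii) >= 2L && runif(1) < config$redundant_rate) {
        shift <- sample.int(max(1L, floor(probe_len * 0.2)), 1L)
        p_start[ii[2L]] <- min(p_start[ii[1L]] + shift,
                               gene_models$end[g] - probe_len)
        redundant[ii[2L]] <- TRUE
      }
    }
    p_end <- p_start + probe_len

    # artifact classes (mutually exclusive exclusion classes)
    rates <- config$artifact_rates
    u <- runif(n_probes)
    artifact <- rep("none", n_probes)
    b1 <- rates$polyT
    b2 <- b1 + rates$multilocus
    b3 <- b2 + rates$unaligned
    artifact[u < b1] <- "polyT"
    artifact[u >= b1 & u < b2] <- "multilocus"
    artifact[u >= b2 & u < b3] <- "unaligned"
    chrun_sec <- artifact == "none" & runif(n_probes) < rates$chrun_secondary

    # expression regime (near-background probes exercise the low-signal filter)
    regime <- ifelse(runif(n_probes) < config$low_expression_fraction,
                     "background", "expressed")

    sequence <- random_probe_sequence(n_probes, probe_len)
    polyT_idx <- which(artifact == "polyT")
    for (i in polyT_idx) {
      lead <- sample(0:4, 1L)
      run <- sample(15:20, 1L)
      prefix <- paste0(random_dna(lead, exclude_t = TRUE),
                       strrep("T", run))
      sequence[i] <- paste0(prefix, substr(sequence[i], nchar(prefix) + 1L,
                                           probe_len))
    }
    # guarantee the defect exists only where planted
    bad <- setdiff(which(detect_polyT_artifact(sequence)), polyT_idx)
    for (i in bad) sequence[i] <- paste0("A", substr(sequence[i], 2L, probe_len))

    aln <- make_alignments(probe_id, parent, gene_models, p_start, p_end,
                           artifact, chrun_sec, config$platform)

    probes <- data.frame(
      probe_id = probe_id,
      platform = if (config$platform == "two_channel") "cDNA" else "oligo",
      sequence = sequence,
      stringsAsFactors = FALSE
    )
    truth_probes <- data.frame(
      probe_id = probe_id,
      parent_gene = gene_id[parent],
      artifact_class = artifact,
      chrun_secondary = chrun_sec,
      regime = regime,
      redundant_pair = redundant,
      stringsAsFactors = FALSE
    )
    list(probes = probes, alignments = aln, gene_models = gene_models,
         truth = list(genes = truth_genes, probes = truth_probes),
         platform = config$platform)
  })
}

random_dna <- function(n, exclude_t = FALSE) {
  if (n == 0L) return("")
  alpha <- if (exclude_t) c("A", "C", "G") else c("A", "C", "G", "T")
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

random_probe_sequence <- function(n, len) {
  vapply(seq_len(n), function(i) random_dna(len), character(1))
}

make_alignments <- function(probe_id, parent, gene_models, p_start, p_end,
                            artifact, chrun_sec, platform) {
  named <- setdiff(unique(gene_models$chrom), "chrUn")
  rows <- vector("list", length(probe_id))
  cdna <- platform == "two_channel"
  for (i in seq_along(probe_id)) {
    if (artifact[i] == "unaligned") next
    g <- parent[i]
    len <- p_end[i] - p_start[i]
    primary <- data.frame(
      probe_id = probe_id[i], chrom = gene_models$chrom[g],
      strand = gene_models$strand[g], start = p_start[i], end = p_end[i],
      identity = round(runif(1, 96.5, 100), 2),
      score = if (cdna) round(len * runif(1, 0.8, 1)) else round(runif(1, 28, 45)),
      rank = "primary", stringsAsFactors = FALSE
    )
    extra <- NULL
    if (artifact[i] == "multilocus") {
      other <- sample(setdiff(named, gene_models$chrom[g]), 1L)
      st <- sample.int(5e5, 1L)
      extra <- data.frame(
        probe_id = probe_id[i], chrom = other, strand = sample(c("+", "-"), 1L),
        start = st, end = st + len,
        identity = round(runif(1, 96, 99.5), 2),
        score = if (cdna) round(len * runif(1, 0.8, 1)) else round(runif(1, 27, 40)),
        rank = "secondary", stringsAsFactors = FALSE
      )
    } else if (chrun_sec[i]) {
      st <- sample.int(5e5, 1L)
      extra <- data.frame(
        probe_id = probe_id[i], chrom = "chrUn", strand = sample(c("+", "-"), 1L),
        start = st, end = st + len,
        identity = round(runif(1, 95.6, 99.5), 2),
        score = if (cdna) round(len * runif(1, 0.8, 1)) else round(runif(1, 26, 40)),
        rank = "secondary", stringsAsFactors = FALSE
      )
    } else if (runif(1) < 0.1) {
      # spurious low-quality secondary hit; fails both platform thresholds
      st <- sample.int(5e5, 1L)
      extra <- data.frame(
        probe_id = probe_id[i], chrom = sample(named, 1L),
        strand = sample(c("+", "-"), 1L), start = st, end = st + len,
        identity = round(runif(1, 75, 90), 2),
        score = round(runif(1, 8, 20)),
        rank = "secondary", stringsAsFactors = FALSE
      )
    }
    rows[[i]] <- rbind(primary, extra)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Simulate per-array intensities for one nucleus-versus-surround contrast
#'
#' For the two-channel common-reference design, every sample is hybridized
#' against the same reference on its own array: the sample's dye alternates
#' (dye balancing), each channel gets log-normal signal plus an additive
#' local background, and a smooth intensity-dependent per-print-tip bias is
#' injected into the log-ratio so the within-array normalization has
#' structure to remove. For the single-channel platform, pre-normalized log2
#' values per sample are returned. Truly differential genes are shifted by
#' their true log2 fold change in nucleus samples only; near-background
#' probes are drawn close to the background level in both regions.
#'
#' @param library result of [generate_probe_library()].
#' @param config the same [sim_config()].
#' @return a list with `design` (array/sample table: id, region, pair, and
#'   for two-channel the dye carrying the sample), plus either `arrays`
#'   (named list of per-array foreground/background tables) and `tip`
#'   (probe print-tip assignment) for two-channel data, or `values`
#'   (probes-by-samples matrix of normalized log2 intensities) for
#'   single-channel data.
#' @export
generate_intensities <- function(library, config) {
  if (missing(library) || is.null(library))
    stop("'library' must be a probe library from generate_probe_library()")
  stopifnot(inherits(config, "sim_config"))
  run_with_seed(substream_seed(config$seed, "intensities"), {
    tp <- library$truth$probes
    tg <- library$truth$genes
    lfc <- setNames(tg$true_log2fc, tg$gene_id)[tp$parent_gene]
    n_probes <- nrow(tp)
    baseline <- ifelse(tp$regime == "background",
                       rnorm(n_probes, 4, 0.5), rnorm(n_probes, 10, 1))
    n_pairs <- config$n_pairs
    pair_eff <- matrix(rnorm(n_probes * n_pairs, 0, config$pair_sd),
                       n_probes, n_pairs)

    if (config$platform == "single_channel") {
      regions <- rep(c("nucleus", "surround"), each = n_pairs)
      sample_id <- sprintf("S%02d_%s", rep(seq_len(n_pairs), 2),
                           substr(regions, 1, 1))
      vals <- matrix(0, n_probes, 2L * n_pairs,
                     dimnames = list(tp$probe_id, sample_id))
      for (j in seq_len(2L * n_pairs)) {
        pr <- ((j - 1L) %% n_pairs) + 1L
        shift <- if (regions[j] == "nucleus") lfc else 0
        vals[, j] <- baseline + shift + pair_eff[, pr] +
          rnorm(n_probes, 0, config$noise_sd)
      }
      design <- data.frame(sample_id = sample_id, region = regions,
                           pair = rep(seq_len(n_pairs), 2),
                           stringsAsFactors = FALSE)
      return(list(design = design, values = vals, platform = "single_channel"))
    }

    # two-channel common-reference design
    G <- config$print_tip_groups
    tip <- setNames(rep(seq_len(G), length.out = n_probes), tp$probe_id)
    amp <- runif(G, 0.1, 0.4)
    phase <- runif(G, 0, 2 * pi)
    regions <- rep(c("nucleus", "surround"), each = n_pairs)
    dye <- c(rep(c("Cy5", "Cy3"), length.out = n_pairs),
             rep(c("Cy5", "Cy3"), length.out = n_pairs))
    array_id <- sprintf("A%02d_%s", rep(seq_len(n_pairs), 2),
                        substr(regions, 1, 1))
    arrays <- vector("list", 2L * n_pairs)
    names(arrays) <- array_id
    for (j in seq_len(2L * n_pairs)) {
      pr <- ((j - 1L) %% n_pairs) + 1L
      shift <- if (regions[j] == "nucleus") lfc else 0
      sample_log <- baseline + shift + pair_eff[, pr] +
        rnorm(n_probes, 0, config$noise_sd)
      ref_log <- baseline + rnorm(n_probes, 0, config$noise_sd)
      a_true <- (sample_log + ref_log) / 2
      bias <- amp[tip] * sin(0.7 * a_true + phase[tip])
      sample_log <- sample_log + bias / 2
      ref_log <- ref_log - bias / 2
      bg_true <- 2^rnorm(n_probes, 7, 0.15)
      f_sample <- bg_true + 2^sample_log
      f_ref <- bg_true + 2^ref_log
      b_meas_5 <- bg_true * 2^rnorm(n_probes, 0, 0.1)
      b_meas_3 <- bg_true * 2^rnorm(n_probes, 0, 0.1)
      if (dye[j] == "Cy5") {
        tab <- data.frame(probe_id = tp$probe_id,
                          F_Cy5 = f_sample, B_Cy5 = b_meas_5,
                          F_Cy3 = f_ref, B_Cy3 = b_meas_3,
                          stringsAsFactors = FALSE)
      } else {
        tab <- data.frame(probe_id = tp$probe_id,
                          F_Cy5 = f_ref, B_Cy5 = b_meas_5,
                          F_Cy3 = f_sample, B_Cy3 = b_meas_3,
                          stringsAsFactors = FALSE)
      }
      arrays[[j]] <- tab
    }
    design <- data.frame(array_id = array_id, region = regions,
                         pair = rep(seq_len(n_pairs), 2),
                         dye_of_sample = dye, stringsAsFactors = FALSE)
    list(design = design, arrays = arrays, tip = tip, platform = "two_channel")
  })
}

#' Sample an in-situ-style validation label set from the ground truth
#'
#' Emulates the independent atlas-derived label set used to calibrate
#' significance cutoffs: a fraction of genes gets a label (truth collapsed to
#' differential / nondifferential), a fraction of those labels is flipped
#' (observer error), and a fraction is marked `excluded` (sections whose
#' folds or artifacts made evaluation impossible).
#'
#' @param truth `truth` element of a probe library.
#' @param config the [sim_config()].
#' @return data.frame with columns `gene_id`, `label`
#'   (differential/nondifferential/excluded) and `provenance`.
#' @export
generate_validation_labels <- function(truth, config) {
  stopifnot(!is.null(truth$genes), inherits(config, "sim_config"))
  run_with_seed(substream_seed(config$seed, "labels"), {
    tg <- truth$genes
    n <- nrow(tg)
    take <- runif(n) < config$label_coverage
    tg <- tg[take, , drop = FALSE]
    if (nrow(tg) == 0L) {
      return(data.frame(gene_id = character(0), label = character(0),
                        provenance = character(0), stringsAsFactors = FALSE))
    }
    label <- ifelse(tg$status == "null", "nondifferential", "differential")
    flip <- runif(nrow(tg)) < config$label_error_rate
    label[flip] <- ifelse(label[flip] == "differential",
                          "nondifferential", "differential")
    excl <- runif(nrow(tg)) < config$label_excluded_rate
    label[excl] <- "excluded"
    data.frame(gene_id = tg$gene_id, label = label,
               provenance = "synthetic expression atlas",
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic gene-set collection
#'
#' Builds `n_sets` gene sets over the gene universe of a ground truth.
#' `n_enriched` of them are over-sampled from truly differential genes with
#' the given odds ratio; the rest are drawn uniformly, giving a null
#' collection for false-positive-rate checks.
#'
#' @param truth `truth` element of a probe library.
#' @param n_sets total number of sets.
#' @param n_enriched number of sets enriched for differential genes.
#' @param odds_ratio sampling odds of a differential gene relative to a null
#'   gene within enriched sets.
#' @param set_sizes inclusive range of set sizes.
#' @param seed seed for the draw.
#' @return named list of character vectors (a GMT collection in memory).
#' @export
generate_gmt <- function(truth, n_sets = 50, n_enriched = 0, odds_ratio = 4,
                         set_sizes = c(10, 60), seed = 1L) {
  stopifnot(!is.null(truth$genes), n_sets >= 1, odds_ratio > 0)
  run_with_seed(substream_seed(seed, "gmt"), {
    genes <- truth$genes$gene_id
    is_diff <- truth$genes$status != "null"
    w <- ifelse(is_diff, odds_ratio, 1)
    sizes <- sample(set_sizes[1]:set_sizes[2], n_sets, replace = TRUE)
    sets <- vector("list", n_sets)
    names(sets) <- sprintf("SET%03d", seq_len(n_sets))
    for (s in seq_len(n_sets)) {
      prob <- if (s <= n_enriched) w else NULL
      sets[[s]] <- sort(sample(genes, min(sizes[s], length(genes)),
                               prob = prob))
    }
    sets
  })
}

#' Run the full synthetic-study generator
#'
#' Convenience wrapper: probe library, intensities, and validation labels
#' from one config.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `library`, `intensities`, `labels`.
#' @export
simulate_study <- function(config) {
  library <- generate_probe_library(config)
  intensities <- generate_intensities(library, config)
  labels <- generate_validation_labels(library$truth, config)
  list(config = config, library = library, intensities = intensities,
       labels = labels)
}
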