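#' Collapse redundant probes of one gene
#'
#' Probes probing an identical region of a gene (more than 75% overlap at the
#' nucleotide level, where the denominator is the shorter probe) cannot be
#' counted as independent assessments. Probes are grouped by single linkage
#' on that pairwise relation (connected components), restricted to probes on
#' the same chromosome and strand; each group contributes a single averaged
#' p-value and averaged M. Probes without coordinates form their own
#' singleton group and are flagged.
#'
#' @param probes data.frame for one gene: `probe_id`, `chrom`, `strand`,
#'   `start`, `end`, `p`, `M`.
#' @return data.frame of unique probe groups: `group`, `n_probes`,
#'   `probe_ids` (comma-joined), `p` (mean), `M` (mean), `no_coord` flag.
#' @export
collapse_redundant <- function(probes) {
  n <- nrow(probes)
  if (n == 0L) {
    return(data.frame(group = integer(0), n_probes = integer(0),
                      probe_ids = character(0), p = numeric(0), M = numeric(0),
                      no_coord = logical(0), stringsAsFactors = FALSE))
  }
  no_coord <- is.na(probes$start) | is.na(probes$end) | is.na(probes$chrom)
  pairs <- NULL
  idx <- which(!no_coord)
  if (length(idx) >= 2L) {
    cmb <- utils::combn(idx, 2L)
    keep <- logical(ncol(cmb))
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1L, k]; b <- cmb[2L, k]
      if (probes$chrom[a] != probes$chrom[b] ||
          probes$strand[a] != probes$strand[b]) next
      ov <- min(probes$end[a], probes$end[b]) -
        max(probes$start[a], probes$start[b])
      shorter <- min(probes$end[a] - probes$start[a],
                     probes$end[b] - probes$start[b])
      keep[k] <- shorter > 0 && ov / shorter > 0.75
    }
    if (any(keep)) pairs <- t(cmb[, keep, drop = FALSE])
  }
  comp <- uf_groups(n, pairs)
  comp[no_coord] <- n + which(no_coord)  # force singletons
  gid <- match(comp, unique(comp))
  agg <- lapply(split(seq_len(n), gid), function(ii) {
    data.frame(n_probes = length(ii),
               probe_ids = paste(probes$probe_id[ii], collapse = ","),
               p = mean(probes$p[ii]), M = mean(probes$M[ii]),
               no_coord = any(no_coord[ii]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- cbind(group = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Majority-rule differential call for one gene
#'
#' A unique probe group is significant when its averaged p-value is at or
#' below the calibrated cutoff. When at least 50% of a gene's unique groups
#' are significant the gene is scored differential; in all other cases
#' non-differential. A gene with no retained groups is not assessed.
#'
#' @param groups collapsed probe groups from [collapse_redundant()].
#' @param cutoff_p calibrated significance cutoff.
#' @return list: `status` (differential/nondifferential/not_assessed),
#'   `direction` (up/down/conflict/none), `n_sig_unique`, `n_nonsig_unique`.
#' @export
score_gene <- function(groups, cutoff_p) {
  if (is.null(groups) || nrow(groups) == 0L) {
    return(list(status = "not_assessed", direction = "none",
                n_sig_unique = 0L, n_nonsig_unique = 0L))
  }
  sig <- groups$p <= cutoff_p
  n_sig <- sum(sig)
  n_nonsig <- sum(!sig)
  if (n_sig / (n_sig + n_nonsig) >= 0.5) {
    list(status = "differential",
         direction = assign_direction(groups$M[sig]),
         n_sig_unique = n_sig, n_nonsig_unique = n_nonsig)
  } else {
    list(status = "nondifferential", direction = "none",
         n_sig_unique = n_sig, n_nonsig_unique = n_nonsig)
  }
}

#' Direction of regulation from significant probe groups
#'
#' Up when every significant group has positive M, down when every one is
#' negative, conflict otherwise. Conflicts are surfaced for manual review,
#' never majority-voted away.
#'
#' @param M_sig M values of the significant groups.
#' @return `"up"`, `"down"` or `"conflict"`.
#' @export
assign_direction <- function(M_sig) {
  if (length(M_sig) == 0L) return("none")
  if (all(M_sig > 0)) "up"
  else if (all(M_sig < 0)) "down"
  else "conflict"
}

#' Score every gene of a contrast
#'
#' Joins per-probe statistics with curated annotations, collapses redundant
#' probes per gene, and applies the majority rule at the calibrated cutoff.
#' Genes listed in `universe_genes` (e.g. every annotated gene on the
#' platform) that end up with zero retained probes are reported as
#' `not_assessed`.
#'
#' @param stats per-probe statistics table (`probe_id`, `M`, `p`).
#' @param curated curated probe table ([curate_probes()]); only retained,
#'   gene-assigned probes are used.
#' @param cutoff_p calibrated cutoff.
#' @param contrast contrast name recorded in the output.
#' @param universe_genes optional character vector of genes to report even
#'   when unassessed.
#' @return data.frame: `gene_id`, `contrast`, `status`, `direction`,
#'   `n_sig_unique`, `n_nonsig_unique`, `evidence`.
#' @export
score_genes <- function(stats, curated, cutoff_p, contrast = "contrast",
                        universe_genes = NULL) {
  keep <- curated$keep & !is.na(curated$gene_id) &
    curated$relation %in% c("exonic_or_overlapping", "proximal")
  ann <- curated[keep, c("probe_id", "gene_id", "chrom", "strand",
                         "start", "end")]
  m <- merge(stats[, c("probe_id", "M", "p")], ann, by = "probe_id")
  by_gene <- split(m, m$gene_id)
  rows <- lapply(names(by_gene), function(g) {
    groups <- collapse_redundant(by_gene[[g]])
    sc <- score_gene(groups, cutoff_p)
    data.frame(gene_id = g, contrast = contrast, status = sc$status,
               direction = sc$direction, n_sig_unique = sc$n_sig_unique,
               n_nonsig_unique = sc$n_nonsig_unique, evidence = "array",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), contrast = character(0),
                      status = character(0), direction = character(0),
                      n_sig_unique = integer(0), n_nonsig_unique = integer(0),
                      evidence = character(0), stringsAsFactors = FALSE)
  }
  if (!is.null(universe_genes)) {
    missing <- setdiff(universe_genes, out$gene_id)
    if (length(missing)) {
      out <- rbind(out, data.frame(
        gene_id = missing, contrast = contrast, status = "not_assessed",
        direction = "none", n_sig_unique = 0L, n_nonsig_unique = 0L,
        evidence = "array", stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge array scores with in-situ hybridization calls
#'
#' In-situ evidence is the more rigorous validation, so on conflict the
#' in-situ call overrides the array call (the gene is flagged discordant,
#' evidence `both`). Genes not assessed by array but called in-situ take the
#' in-situ call (evidence `insitu`); an unevaluable in-situ leaves the array
#' call untouched.
#'
#' @param scores gene score table from [score_genes()].
#' @param insitu data.frame: `gene_id`, `call` in up/down/nondifferential/
#'   unevaluable (optionally `contrast`).
#' @return score table with updated `status`, `direction`, `evidence`, and a
#'   logical `discordant` column (the "$" flag of the marker tables).
#' @export
merge_insitu <- function(scores, insitu) {
  scores$discordant <- FALSE
  if (is.null(insitu) || nrow(insitu) == 0L) return(scores)
  stopifnot(!anyDuplicated(insitu$gene_id))
  for (r in seq_len(nrow(insitu))) {
    g <- insitu$gene_id[r]
    call <- insitu$call[r]
    if (call == "unevaluable") next
    i <- which(scores$gene_id == g)
    in_status <- if (call %in% c("up", "down")) "differential"
                 else "nondifferential"
    in_dir <- if (call %in% c("up", "down")) call else "none"
    if (length(i) == 0L) {
      scores <- rbind(scores, data.frame(
        gene_id = g, contrast = scores$contrast[1] %||% NA_character_,
        status = in_status, direction = in_dir, n_sig_unique = 0L,
        n_nonsig_unique = 0L, evidence = "insitu", discordant = FALSE,
        stringsAsFactors = FALSE))
      next
    }
    if (scores$status[i] == "not_assessed") {
      scores$status[i] <- in_status
      scores$direction[i] <- in_dir
      scores$evidence[i] <- "insitu"
    } else {
      agree <- scores$status[i] == in_status &&
        (in_status != "differential" || scores$direction[i] == in_dir)
      scores$evidence[i] <- "both"
      if (!agree) {
        scores$status[i] <- in_status
        scores$direction[i] <- in_dir
        scores$discordant[i] <- TRUE
      }
    }
  }
  rownames(scores) <- NULL
  scores
}
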