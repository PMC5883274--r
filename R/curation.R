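#' Detect a 5' poly-T cloning artifact
#'
#' cDNA clones produced by second-strand oligo-dT priming carry a long run of
#' T's at the 5' end of the EST; such probes read the wrong strand and are
#' removed. A sequence is flagged when a run of at least 15 consecutive T's
#' begins within the first 5 bases (the small start tolerance absorbs vector
#' trimming slop).
#'
#' @param sequence character vector of uppercase nucleotide sequences.
#' @return logical vector, `TRUE` where the artifact is present.
#' @export
detect_polyT_artifact <- function(sequence) {
  if (length(sequence) == 0L) return(logical(0))
  if (any(is.na(sequence)) || any(!nzchar(sequence)))
    stop("empty sequence")
  grepl("^.{0,4}T{15}", sequence)
}

#' Platform alignment thresholds
#'
#' A cDNA/EST alignment passes at >= 95% identity; a 60-mer oligo alignment
#' passes at alignment score >= 25.
#' @keywords internal
alignment_passes <- function(alignments, platform) {
  if (platform == "cDNA") {
    alignments$identity >= 95
  } else if (platform == "oligo") {
    alignments$score >= 25
  } else {
    stop("unknown platform: ", platform)
  }
}

#' Alignment-level QC for one probe
#'
#' Applies the alignment filters: a probe is removed when it has no
#' alignments at all (`unaligned`), when none of its alignments passes the
#' platform threshold (`low_score`), or when passing alignments land on two
#' or more distinct named chromosomes (`multilocus`). `chrUn` is not a named
#' chromosome: passing secondary alignments there at >95% identity are
#' retained as presumed allelic copies and only flagged
#' (`chrun_allelic_retained`). A probe whose only passing alignments are on
#' `chrUn` is likewise kept but flagged.
#'
#' @param alignments data.frame of this probe's alignments (columns `chrom`,
#'   `strand`, `start`, `end`, `identity`, `score`, `rank`).
#' @param platform `"cDNA"` or `"oligo"`.
#' @return list with `keep` (logical) and `flags` (character vector).
#' @export
filter_alignments <- function(alignments, platform) {
  platform <- match.arg(platform, c("cDNA", "oligo"))
  if (is.null(alignments) || nrow(alignments) == 0L)
    return(list(keep = FALSE, flags = "unaligned"))
  pass <- alignment_passes(alignments, platform)
  if (!any(pass)) return(list(keep = FALSE, flags = "low_score"))
  passing <- alignments[pass, , drop = FALSE]
  named <- setdiff(unique(passing$chrom), "chrUn")
  if (length(named) >= 2L)
    return(list(keep = FALSE, flags = "multilocus"))
  flags <- character(0)
  on_un <- passing$chrom == "chrUn"
  if (any(on_un & passing$identity > 95) || all(on_un))
    flags <- "chrun_allelic_retained"
  list(keep = TRUE, flags = flags)
}

#' Strand-aware probe-to-gene annotation
#'
#' Assigns a retained probe to a gene model using its best passing alignment.
#' Assignment is same-strand only: a same-strand overlap gives
#' `exonic_or_overlapping` (probes fully inside the model span are intronic
#' or exonic; without exon structure both fall here), otherwise the nearest
#' same-strand model within the platform proximity window (3 kb for cDNA,
#' 5 kb for oligo, closest edges) gives `proximal`. A probe whose only
#' overlap is with an opposite-strand model is reported as
#' `antisense_conflict` and treated as unassigned downstream; anything else
#' is `unassigned`.
#'
#' @param probe_aln one-row data.frame: the probe's annotation alignment
#'   (`chrom`, `strand`, `start`, `end`).
#' @param models gene model table (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`), 0-based half-open.
#' @param platform `"cDNA"` or `"oligo"`.
#' @return list with `gene_id` (or `NA`) and `relation`.
#' @export
assign_annotation <- function(probe_aln, models, platform) {
  platform <- match.arg(platform, c("cDNA", "oligo"))
  window <- if (platform == "cDNA") 3000L else 5000L
  gr_models <- GenomicRanges::GRanges(
    models$chrom,
    IRanges::IRanges(models$start + 1L, models$end),
    strand = models$strand
  )
  gr_probe <- GenomicRanges::GRanges(
    probe_aln$chrom,
    IRanges::IRanges(probe_aln$start + 1L, probe_aln$end),
    strand = probe_aln$strand
  )
  # same-strand overlap
  ov <- GenomicRanges::findOverlaps(gr_probe, gr_models, ignore.strand = FALSE)
  if (length(ov) > 0L) {
    hit <- S4Vectors::subjectHits(ov)[1L]
    return(list(gene_id = models$gene_id[hit], relation = "exonic_or_overlapping"))
  }
  # nearest same-strand model within the platform window (edge to edge)
  d <- GenomicRanges::distanceToNearest(gr_probe, gr_models, ignore.strand = FALSE)
  if (length(d) > 0L) {
    dist <- S4Vectors::mcols(d)$distance
    if (!is.na(dist) && dist <= window) {
      hit <- S4Vectors::subjectHits(d)[1L]
      return(list(gene_id = models$gene_id[hit], relation = "proximal"))
    }
  }
  # opposite-strand overlap only
  ov2 <- GenomicRanges::findOverlaps(gr_probe, gr_models, ignore.strand = TRUE)
  if (length(ov2) > 0L) {
    return(list(gene_id = NA_character_, relation = "antisense_conflict"))
  }
  list(gene_id = NA_character_, relation = "unassigned")
}

# Vectorized version of assign_annotation over many probes (same rules).
annotate_probes <- function(aln, models, platform) {
  window <- ifelse(platform == "cDNA", 3000L, 5000L)
  gr_models <- GenomicRanges::GRanges(
    models$chrom, IRanges::IRanges(models$start + 1L, models$end),
    strand = models$strand)
  gr <- GenomicRanges::GRanges(
    aln$chrom, IRanges::IRanges(aln$start + 1L, aln$end), strand = aln$strand)
  n <- length(gr)
  gene_id <- rep(NA_character_, n)
  relation <- rep("unassigned", n)

  ov <- GenomicRanges::findOverlaps(gr, gr_models, ignore.strand = FALSE)
  first <- !duplicated(S4Vectors::queryHits(ov))
  qi <- S4Vectors::queryHits(ov)[first]
  gene_id[qi] <- models$gene_id[S4Vectors::subjectHits(ov)[first]]
  relation[qi] <- "exonic_or_overlapping"

  rest <- setdiff(seq_len(n), qi)
  if (length(rest)) {
    d <- GenomicRanges::distanceToNearest(gr[rest], gr_models,
                                          ignore.strand = FALSE)
    di <- S4Vectors::queryHits(d)
    dist <- S4Vectors::mcols(d)$distance
    okd <- !is.na(dist) & dist <= window[rest][di]
    prox <- rest[di[okd]]
    gene_id[prox] <- models$gene_id[S4Vectors::subjectHits(d)[okd]]
    relation[prox] <- "proximal"
    rest2 <- setdiff(rest, prox)
    if (length(rest2)) {
      ov2 <- GenomicRanges::findOverlaps(gr[rest2], gr_models,
                                         ignore.strand = TRUE)
      anti <- rest2[unique(S4Vectors::queryHits(ov2))]
      relation[anti] <- "antisense_conflict"
    }
  }
  data.frame(gene_id = gene_id, relation = relation, stringsAsFactors = FALSE)
}

#' Curate a probe library
#'
#' Runs the full sequence- and alignment-level QC over a probe table:
#' poly-T artifact screen on the sequences, alignment filters, and
#' strand-aware annotation of every retained probe against the gene models.
#' Filters are idempotent: curating an already-curated (retained) set changes
#' nothing.
#'
#' @param probes probe table (`probe_id`, `platform`, optionally `sequence`).
#' @param alignments alignment table for all probes.
#' @param models gene model table.
#' @return data.frame with one row per probe: `probe_id`, `platform`,
#'   `keep`, `qc_flags` (comma-separated), `gene_id`, `relation`, and the
#'   annotation alignment coordinates (`chrom`, `strand`, `start`, `end`).
#' @export
curate_probes <- function(probes, alignments, models) {
  stopifnot(all(c("probe_id", "platform") %in% names(probes)))
  n <- nrow(probes)
  keep <- logical(n)
  flags <- character(n)
  gene_id <- rep(NA_character_, n)
  relation <- rep(NA_character_, n)
  chrom <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)
  start <- rep(NA_integer_, n)
  end <- rep(NA_integer_, n)

  has_seq <- "sequence" %in% names(probes) && !all(is.na(probes$sequence))
  polyt <- if (has_seq) detect_polyT_artifact(probes$sequence) else rep(FALSE, n)

  aln_by_probe <- split(alignments, alignments$probe_id)
  for (i in seq_len(n)) {
    if (polyt[i]) {
      flags[i] <- "polyT_artifact"
      next
    }
    a <- aln_by_probe[[probes$probe_id[i]]]
    res <- filter_alignments(a, probes$platform[i])
    keep[i] <- res$keep
    flags[i] <- paste(res$flags, collapse = ",")
    if (!res$keep) next
    pass <- a[alignment_passes(a, probes$platform[i]), , drop = FALSE]
    named <- pass[pass$chrom != "chrUn", , drop = FALSE]
    best <- if (nrow(named)) named else pass
    best <- best[order(-best$identity, -best$score), , drop = FALSE][1L, ]
    chrom[i] <- best$chrom
    strand[i] <- best$strand
    start[i] <- best$start
    end[i] <- best$end
  }

  # annotate all retained probes in one vectorized pass
  ki <- which(keep)
  if (length(ki)) {
    ann <- annotate_probes(data.frame(chrom = chrom[ki], strand = strand[ki],
                                      start = start[ki], end = end[ki],
                                      stringsAsFactors = FALSE),
                           models, probes$platform[ki])
    gene_id[ki] <- ann$gene_id
    relation[ki] <- ann$relation
  }
  data.frame(probe_id = probes$probe_id, platform = probes$platform,
             keep = keep, qc_flags = flags, gene_id = gene_id,
             relation = relation, chrom = chrom, strand = strand,
             start = start, end = end, stringsAsFactors = FALSE)
}
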