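#' Export per-probe regulation calls as a BED9 track
#'
#' Writes one BED9 line per assessed probe for one contrast, suitable for
#' loading as a custom genome-browser track when reviewing annotations. The
#' name field is `<probe_id>_<nucleus>_<regulation>`; itemRgb encodes the
#' call: green (`0,170,0`) up-regulated, red (`200,0,0`) down-regulated,
#' black (`0,0,0`) assessed but not differential. Probes without a retained
#' statistic are omitted; retained probes without coordinates are skipped
#' with a warning. Coordinates are 0-based half-open, per the BED standard.
#'
#' @param stats per-probe statistics table (needs `probe_id`, `M`, `p`).
#' @param curated curated probe table from [curate_probes()] (coordinates).
#' @param cutoff_p significance cutoff applied to `p`.
#' @param nucleus contrast/nucleus name embedded in the line names.
#' @param file path to write; `NULL` returns the BED data.frame invisibly
#'   without writing.
#' @return the BED9 data.frame, invisibly.
#' @export
export_bed <- function(stats, curated, cutoff_p, nucleus, file = NULL) {
  m <- merge(stats[, c("probe_id", "M", "p")],
             curated[, c("probe_id", "chrom", "strand", "start", "end")],
             by = "probe_id")
  no_coord <- is.na(m$chrom) | is.na(m$start)
  if (any(no_coord)) {
    warning(sum(no_coord), " probe(s) without alignment skipped in BED export")
    m <- m[!no_coord, , drop = FALSE]
  }
  if (nrow(m) == 0L) {
    bed <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0), score = integer(0),
                      strand = character(0), thickStart = integer(0),
                      thickEnd = integer(0), itemRgb = character(0),
                      stringsAsFactors = FALSE)
  } else {
    sig <- m$p <= cutoff_p
    regulation <- ifelse(sig & m$M > 0, "up",
                         ifelse(sig & m$M < 0, "down", "nondiff"))
    rgb <- c(up = "0,170,0", down = "200,0,0", nondiff = "0,0,0")[regulation]
    bed <- data.frame(
      chrom = m$chrom, start = as.integer(m$start), end = as.integer(m$end),
      name = paste(m$probe_id, nucleus, regulation, sep = "_"),
      score = 0L, strand = m$strand,
      thickStart = as.integer(m$start), thickEnd = as.integer(m$end),
      itemRgb = unname(rgb), stringsAsFactors = FALSE
    )
    bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
    rownames(bed) <- NULL
  }
  if (!is.null(file)) {
    write.table(bed, file, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(bed)
}

#' Read a BED9 file written by [export_bed()]
#'
#' @param file path to a headerless BED9 file.
#' @return data.frame with the nine standard BED columns.
#' @export
read_bed9 <- function(file) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "thickStart", "thickEnd", "itemRgb")
  if (file.size(file) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0), score = integer(0),
                      strand = character(0), thickStart = integer(0),
                      thickEnd = integer(0), itemRgb = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- read.delim(file, header = FALSE, col.names = cols,
                    colClasses = c("character", "integer", "integer",
                                   "character", "integer", "character",
                                   "integer", "integer", "character"))
  out
}

#' Write a gene-set collection in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param sets named list of character vectors.
#' @param file output path.
#' @param description single description string or vector (recycled).
#' @export
write_gmt <- function(sets, file, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Read a GMT gene-set collection
#'
#' @param file path to a GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Write the tables of a simulated study to a directory
#'
#' Emits plain-text files: probe table, alignment table, gene models,
#' intensities (one TSV per array, or one matrix for single-channel), design,
#' labels, and the ground truth as JSON.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(sim$library$probes, "probes.tsv")
  tsv(sim$library$alignments, "alignments.tsv")
  tsv(sim$library$gene_models, "gene_models.tsv")
  tsv(sim$labels, "labels.tsv")
  tsv(sim$intensities$design, "design.tsv")
  if (sim$intensities$platform == "two_channel") {
    for (a in names(sim$intensities$arrays)) {
      tsv(sim$intensities$arrays[[a]], paste0("intensity_", a, ".tsv"))
    }
    tsv(data.frame(probe_id = names(sim$intensities$tip),
                   tip_group = unname(sim$intensities$tip)), "tip_map.tsv")
  } else {
    v <- data.frame(probe_id = rownames(sim$intensities$values),
                    sim$intensities$values, check.names = FALSE)
    tsv(v, "values.tsv")
  }
  jsonlite::write_json(sim$library$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
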