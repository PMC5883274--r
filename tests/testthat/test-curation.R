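test_that("poly-T artifact rule fires on 5'-runs of >= 15 T within 5 nt", {
  expect_true(detect_polyT_artifact(paste0(strrep("T", 15), "ACGTACGT")))
  expect_false(detect_polyT_artifact(paste0("A", strrep("T", 14), "GCAGCA")))
  # a long run starting deeper than position 5 is not a priming artifact
  expect_false(detect_polyT_artifact(paste0("ACGTACGTAC", strrep("T", 20))))
  expect_true(detect_polyT_artifact(paste0("ACGA", strrep("T", 15), "G")))
  expect_false(detect_polyT_artifact(paste0("ACGAC", strrep("T", 15), "G")))
  expect_error(detect_polyT_artifact(""), "empty")
})

test_that("poly-T detection agrees with a brute-force run scanner", {
  set.seed(101)
  seqs <- vapply(1:400, function(i) {
    lead <- paste(sample(c("A", "C", "G", "T"), sample(0:8, 1), TRUE),
                  collapse = "")
    run <- strrep("T", sample(10:22, 1))
    tail <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    paste0(lead, run, tail)
  }, character(1))
  expect_identical(detect_polyT_artifact(seqs),
                   vapply(seqs, oracle_polyt, logical(1), USE.NAMES = FALSE))
})

test_that("alignment filters apply platform thresholds and locus rules", {
  aln <- function(...) {
    data.frame(..., rank = "primary", stringsAsFactors = FALSE)
  }
  # single good oligo hit
  r <- filter_alignments(aln(probe_id = "p", chrom = "chr2", strand = "+",
                             start = 10L, end = 70L, identity = 99,
                             score = 30), "oligo")
  expect_true(r$keep); expect_length(r$flags, 0L)
  # passing hits on two named chromosomes
  two <- rbind(aln(probe_id = "p", chrom = "chr1", strand = "+", start = 0L,
                   end = 60L, identity = 99, score = 30),
               aln(probe_id = "p", chrom = "chr5", strand = "-", start = 0L,
                   end = 60L, identity = 98, score = 28))
  r <- filter_alignments(two, "oligo")
  expect_false(r$keep); expect_identical(r$flags, "multilocus")
  # two passing hits on the SAME named chromosome are kept
  same <- two; same$chrom <- "chr1"
  expect_true(filter_alignments(same, "oligo")$keep)
  # EST with chrUn secondary at high identity: retained, flagged
  est <- rbind(aln(probe_id = "p", chrom = "chr3", strand = "+", start = 0L,
                   end = 500L, identity = 98, score = 400),
               data.frame(probe_id = "p", chrom = "chrUn", strand = "+",
                          start = 0L, end = 500L, identity = 97, score = 380,
                          rank = "secondary", stringsAsFactors = FALSE))
  r <- filter_alignments(est, "cDNA")
  expect_true(r$keep); expect_identical(r$flags, "chrun_allelic_retained")
  # no alignment at all vs failing alignments
  expect_identical(filter_alignments(NULL, "oligo")$flags, "unaligned")
  low <- aln(probe_id = "p", chrom = "chr1", strand = "+", start = 0L,
             end = 60L, identity = 80, score = 12)
  expect_identical(filter_alignments(low, "oligo")$flags, "low_score")
  expect_identical(filter_alignments(low, "cDNA")$flags, "low_score")
  # chrUn-only probe: kept but flagged
  un <- aln(probe_id = "p", chrom = "chrUn", strand = "+", start = 0L,
            end = 60L, identity = 99, score = 30)
  r <- filter_alignments(un, "oligo")
  expect_true(r$keep); expect_identical(r$flags, "chrun_allelic_retained")
  expect_error(filter_alignments(low, "nanopore"))
})

test_that("annotation respects strand and the platform proximity window", {
  models <- data.frame(
    gene_id = c("gA", "gB"), symbol = c("A", "B"),
    chrom = c("chr1", "chr1"), strand = c("+", "-"),
    start = c(10000L, 40000L), end = c(12000L, 42000L),
    stringsAsFactors = FALSE)
  probe <- function(start, end, strand = "+", chrom = "chr1") {
    data.frame(chrom = chrom, strand = strand, start = start, end = end,
               stringsAsFactors = FALSE)
  }
  # inside a same-strand model
  a <- assign_annotation(probe(10500L, 10560L), models, "oligo")
  expect_identical(a$relation, "exonic_or_overlapping")
  expect_identical(a$gene_id, "gA")
  # proximity boundary, cDNA window 3 kb (edge-to-edge gap)
  expect_identical(
    assign_annotation(probe(14999L, 15499L), models, "cDNA")$relation,
    "proximal")
  expect_identical(
    assign_annotation(probe(15001L, 15501L), models, "cDNA")$relation,
    "unassigned")
  # oligo window 5 kb
  expect_identical(
    assign_annotation(probe(16999L, 17059L), models, "oligo")$relation,
    "proximal")
  expect_identical(
    assign_annotation(probe(17001L, 17061L), models, "oligo")$relation,
    "unassigned")
  # overlap with an opposite-strand model only
  a <- assign_annotation(probe(40500L, 40560L, strand = "+"), models, "oligo")
  expect_identical(a$relation, "antisense_conflict")
  expect_true(is.na(a$gene_id))
})

test_that("annotation matches hand enumeration on a five-model toy locus", {
  models <- data.frame(
    gene_id = paste0("g", 1:5), symbol = paste0("G", 1:5),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
    strand = c("+", "-", "+", "+", "-"),
    start = c(1000L, 6000L, 20000L, 1000L, 30000L),
    end = c(3000L, 8000L, 22000L, 3000L, 32000L),
    stringsAsFactors = FALSE)
  # hand-enumerated expectations for a systematic sweep of oligo probes
  cases <- list(
    list(s = 1500L, strand = "+", rel = "exonic_or_overlapping", g = "g1"),
    list(s = 1500L, strand = "-", rel = "proximal", g = "g2"),  # 4.4 kb gap
    list(s = 3500L, strand = "+", rel = "proximal", g = "g1"),
    list(s = 6500L, strand = "-", rel = "exonic_or_overlapping", g = "g2"),
    list(s = 6500L, strand = "+", rel = "proximal", g = "g1"),
    list(s = 14000L, strand = "+", rel = "unassigned", g = NA),
    list(s = 14000L, strand = "-", rel = "unassigned", g = NA),
    list(s = 16000L, strand = "+", rel = "proximal", g = "g3"),
    list(s = 21000L, strand = "-", rel = "antisense_conflict", g = NA),
    list(s = 31000L, strand = "-", rel = "exonic_or_overlapping", g = "g5"),
    list(s = 50000L, strand = "+", rel = "unassigned", g = NA))
  for (cs in cases) {
    a <- assign_annotation(
      data.frame(chrom = "chr1", strand = cs$strand, start = cs$s,
                 end = cs$s + 60L, stringsAsFactors = FALSE),
      models, "oligo")
    expect_identical(a$relation, cs$rel,
                     label = sprintf("start=%d strand=%s", cs$s, cs$strand))
    if (!is.na(cs$g)) expect_identical(a$gene_id, cs$g)
  }
})

test_that("curation is idempotent and never keeps a flagged probe", {
  cfg <- quick_config(seed = 17L)
  lib <- generate_probe_library(cfg)
  cur1 <- curate_probes(lib$probes, lib$alignments, lib$gene_models)
  kept <- cur1$probe_id[cur1$keep]
  cur2 <- curate_probes(lib$probes[lib$probes$probe_id %in% kept, ],
                        lib$alignments[lib$alignments$probe_id %in% kept, ],
                        lib$gene_models)
  expect_equal(cur2, `rownames<-`(cur1[cur1$keep, ], NULL))
  bad <- c("polyT_artifact", "unaligned", "low_score", "multilocus")
  expect_false(any(cur1$keep & cur1$qc_flags %in% bad))
})

test_that("per-class removals equal planted artifact counts exactly", {
  cfg <- quick_config(seed = 23L)
  lib <- generate_probe_library(cfg)
  cur <- curate_probes(lib$probes, lib$alignments, lib$gene_models)
  tp <- lib$truth$probes
  for (cls in c("polyT", "multilocus", "unaligned")) {
    planted <- tp$probe_id[tp$artifact_class == cls]
    flag <- c(polyT = "polyT_artifact", multilocus = "multilocus",
              unaligned = "unaligned")[[cls]]
    expect_setequal(cur$probe_id[cur$qc_flags == flag], planted)
  }
  expect_setequal(cur$probe_id[grepl("chrun_allelic_retained", cur$qc_flags)],
                  tp$probe_id[tp$chrun_secondary])
})
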