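test_that("identical seed and config give byte-identical outputs", {
  cfg <- quick_config(seed = 11L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)
  cfg2 <- quick_config(seed = 12L)
  expect_false(identical(generate_probe_library(cfg2),
                         generate_probe_library(cfg)))
})

test_that("zero artifact rates give a clean library", {
  cfg <- quick_config(seed = 3L, artifact_rates = list(
    polyT = 0, multilocus = 0, unaligned = 0, chrun_secondary = 0))
  lib <- generate_probe_library(cfg)
  expect_true(all(lib$truth$probes$artifact_class == "none"))
  expect_false(any(lib$truth$probes$chrun_secondary))
  cur <- curate_probes(lib$probes, lib$alignments, lib$gene_models)
  expect_true(all(cur$keep))
})

test_that("planted poly-T probes are exactly the ones the filter flags", {
  cfg <- sim_config(seed = 1L, n_genes = 100L, probes_per_gene = 2L,
                    artifact_rates = list(polyT = 0.1, multilocus = 0,
                                          unaligned = 0, chrun_secondary = 0))
  lib <- generate_probe_library(cfg)
  planted <- lib$truth$probes$probe_id[lib$truth$probes$artifact_class == "polyT"]
  flagged <- lib$probes$probe_id[detect_polyT_artifact(lib$probes$sequence)]
  expect_gt(length(planted), 0L)
  expect_setequal(flagged, planted)
})

test_that("config validation rejects malformed inputs", {
  expect_error(sim_config(frac_differential = 1.2), "fraction")
  expect_error(sim_config(artifact_rates = list(polyT = 0.6, multilocus = 0.6,
                                                unaligned = 0, chrun_secondary = 0)),
               "sum")
  expect_error(sim_config(probes_per_gene = 9))
  expect_error(generate_intensities(NULL, sim_config()), "library")
})

test_that("null simulation has near-zero fold changes, tightening with n", {
  mean_abs_m <- function(n_pairs) {
    cfg <- sim_config(seed = 5L, n_genes = 150L, frac_differential = 0,
                      n_pairs = n_pairs, platform = "single_channel",
                      low_expression_fraction = 0,
                      artifact_rates = list(polyT = 0, multilocus = 0,
                                            unaligned = 0, chrun_secondary = 0))
    sim <- simulate_study(cfg)
    v <- sim$intensities$values
    g <- sim$intensities$design$region
    m <- rowMeans(v[, g == "nucleus"]) - rowMeans(v[, g == "surround"])
    c(mean(m), mean(abs(m)))
  }
  small <- mean_abs_m(3L)
  big <- mean_abs_m(30L)
  # grand mean of M near 0 within 3 standard errors
  expect_lt(abs(small[1]), 3 * 0.4 * sqrt(2 / 3) / sqrt(150))
  expect_lt(abs(big[1]), 3 * 0.4 * sqrt(2 / 30) / sqrt(150))
  # per-probe deviation shrinks as pairs accumulate
  expect_lt(big[2], small[2] / 2)
})

test_that("planted fold change is recovered within sampling error", {
  # a handful of spiked genes in an otherwise null background, so the
  # normalization curve is anchored by null probes
  cfg <- sim_config(seed = 8L, n_genes = 300L, frac_differential = 0.01,
                    effect_size = 2, noise_sd = 0.4, n_pairs = 6L,
                    platform = "two_channel",
                    artifact_rates = list(polyT = 0, multilocus = 0,
                                          unaligned = 0, chrun_secondary = 0))
  sim <- simulate_study(cfg)
  proc <- process_two_channel(sim$intensities)
  g <- sim$intensities$design$region
  m_hat <- rowMeans(proc$M[, g == "nucleus"]) -
    rowMeans(proc$M[, g == "surround"])
  tp <- sim$library$truth$probes
  tg <- sim$library$truth$genes
  lfc <- setNames(tg$true_log2fc, tg$gene_id)[tp$parent_gene]
  sel <- tp$regime == "expressed" & lfc != 0
  null_sel <- tp$regime == "expressed" & lfc == 0
  # empirical SE from the expressed null probes (includes normalization and
  # background-correction noise on top of the sqrt(2)*noise_sd/sqrt(3) floor)
  se <- sd(m_hat[null_sel])
  expect_lt(se, 2 * sqrt(2) * 0.4 * sqrt(1 / 6 + 1 / 6))
  frac_in <- mean(abs(m_hat[sel] - lfc[sel]) <= 3 * se)
  expect_gt(frac_in, 0.95)
})

test_that("oriented log-ratios are invariant to dye orientation", {
  cfg <- quick_config(seed = 21L, platform = "two_channel")
  sim <- simulate_study(cfg)
  flipped <- sim$intensities
  flipped$design$dye_of_sample <- ifelse(
    flipped$design$dye_of_sample == "Cy5", "Cy3", "Cy5")
  flipped$arrays <- lapply(flipped$arrays, function(tab) {
    data.frame(probe_id = tab$probe_id,
               F_Cy5 = tab$F_Cy3, B_Cy5 = tab$B_Cy3,
               F_Cy3 = tab$F_Cy5, B_Cy3 = tab$B_Cy5,
               stringsAsFactors = FALSE)
  })
  m1 <- process_two_channel(sim$intensities)$M
  m2 <- process_two_channel(flipped)$M
  expect_equal(m1, m2, tolerance = 1e-10)
})

test_that("noise-free labels reproduce the truth, empty coverage degrades", {
  cfg <- quick_config(seed = 4L, label_coverage = 1, label_error_rate = 0,
                      label_excluded_rate = 0)
  lib <- generate_probe_library(cfg)
  lab <- generate_validation_labels(lib$truth, cfg)
  expect_equal(nrow(lab), cfg$n_genes)
  want <- ifelse(lib$truth$genes$status == "null",
                 "nondifferential", "differential")
  expect_identical(lab$label[match(lib$truth$genes$gene_id, lab$gene_id)],
                   want)

  cfg0 <- quick_config(seed = 4L, label_coverage = 0)
  lab0 <- generate_validation_labels(lib$truth, cfg0)
  expect_equal(nrow(lab0), 0L)
})

test_that("label error rate is realized at its nominal binomial rate", {
  cfg <- sim_config(seed = 9L, n_genes = 800L, label_coverage = 1,
                    label_error_rate = 0.1, label_excluded_rate = 0)
  lib <- generate_probe_library(cfg)
  lab <- generate_validation_labels(lib$truth, cfg)
  want <- ifelse(lib$truth$genes$status == "null",
                 "nondifferential", "differential")
  obs <- mean(lab$label[match(lib$truth$genes$gene_id, lab$gene_id)] != want)
  ci <- qbinom(c(0.005, 0.995), 800, 0.1) / 800
  expect_gte(obs, ci[1]); expect_lte(obs, ci[2])
})

test_that("written simulation files are plain-text and re-readable", {
  dir <- withr::local_tempdir()
  cfg <- quick_config(seed = 2L, platform = "single_channel")
  sim <- simulate_study(cfg)
  write_simulation(sim, dir)
  vals <- read.delim(file.path(dir, "values.tsv"), check.names = FALSE)
  expect_equal(nrow(vals), nrow(sim$intensities$values))
  expect_equal(as.matrix(vals[, -1]),
               sim$intensities$values, ignore_attr = TRUE, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$genes$status, sim$library$truth$genes$status)
})
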