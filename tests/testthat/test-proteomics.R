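test_that("protein ratio is the intensity-weighted peptide average", {
  expect_equal(protein_ratio(c(2, 4), c(1, 3))$ratio, 3.5)
  expect_equal(protein_ratio(5, 10)$ratio, 5)
  expect_equal(protein_ratio(c(2, 4, 6), c(7, 7, 7))$ratio, 4)
  expect_error(protein_ratio(c(2, 4), c(0, 0)), "zero total intensity")
})

test_that("orientation inverts label-switched replicates only", {
  expect_equal(orient_ratios(0.25, "B"), 4)
  expect_equal(orient_ratios(4, "A"), 4)
  expect_equal(orient_ratios(orient_ratios(0.25, "B"), "B"), 0.25)
  expect_error(orient_ratios(1, "C"), "unknown replicate")
})

test_that("GST normalization divides by the same-replicate GST ratio", {
  expect_equal(normalize_by_gst(3.5, "A", c(A = 0.7, B = 1.2)), 5)
  expect_equal(normalize_by_gst(2, "B", c(A = 0.7, B = 1)), 2)
  expect_error(normalize_by_gst(2, "B", c(A = 0.7)), "replicate: B")
})

test_that("geometric SD filter removes dispersed proteins (worked example)", {
  gsd <- geometric_sd(c(2, 8))
  expect_equal(gsd, exp(stats::sd(log(c(2, 8)))))
  expect_equal(gsd, 2.66, tolerance = 0.01)
  expect_equal(geometric_sd(c(3, 3)), 1)
  tab <- data.frame(protein = c("P1", "P2", "P3"),
                    ratio_A = c(2, 3, 2), ratio_B = c(8, 3, NA),
                    n_peptides_A = c(3, 3, 3),
                    n_peptides_B = c(3, 3, NA))
  tab$geometric_sd <- c(geometric_sd(c(2, 8)), 1, NA)
  kept <- suppressMessages(apply_quant_filters(tab))
  expect_equal(kept$protein, "P2")
})

test_that("quadrant classification and strict 7-fold selection", {
  expect_equal(classify_quadrant(5, 4.2)$quadrant, "PSD95-enriched")
  q <- classify_quadrant(0.10, 0.08)
  expect_equal(q$quadrant, "MPP2-enriched")
  expect_equal(q$mpp2_fold_enrichment, 10)
  expect_equal(classify_quadrant(1.2, 0.8)$quadrant, "unassigned")
  expect_error(classify_quadrant(-1, 1), "> 0")
  tab <- data.frame(protein = c("at7", "over7"),
                    ratio_A = c(1 / 7, 1 / 10),
                    ratio_B = c(1 / 7, 1 / 9),
                    n_peptides_A = 3, n_peptides_B = 3,
                    geometric_sd = 1)
  cls <- classify_proteins(tab)
  expect_equal(select_enriched(cls, "MPP2", 7), "over7")
})

test_that("pipeline is scale invariant and label-swap symmetric", {
  sim <- simulate_peptide_table(peptide_table_config(n_proteins = 20),
                                seed = 5)
  pep <- sim$peptides
  # label-swap symmetry is exact for noise-free tables (weighted
  # arithmetic averaging precedes orientation)
  sim0 <- simulate_peptide_table(
    peptide_table_config(n_proteins = 20,
                         peptide_log_ratio_noise_sd = 0), seed = 5)
  pep0 <- sim0$peptides
  res1 <- suppressMessages(run_proteomics(pep))
  # intensity scale invariance per protein
  pep2 <- pep
  pick <- pep2$protein == pep2$protein[1]
  pep2$intensity[pick] <- pep2$intensity[pick] * 1000
  res2 <- suppressMessages(run_proteomics(pep2))
  expect_equal(res1$proteins$ratio_A, res2$proteins$ratio_A)
  # label-swap symmetry: invert every stored ratio and flip the
  # orientation map; the final table is unchanged
  res0 <- suppressMessages(run_proteomics(pep0))
  pep3 <- pep0
  pep3$ratio <- 1 / pep3$ratio
  res3 <- suppressMessages(run_proteomics(pep3,
                                          inverted_replicates = "A"))
  expect_equal(res0$proteins$ratio_A, res3$proteins$ratio_A,
               tolerance = 1e-12)
  expect_equal(res0$proteins$ratio_B, res3$proteins$ratio_B,
               tolerance = 1e-12)
})

test_that("GST self-normalizes to exactly 1 in every replicate", {
  sim <- simulate_peptide_table(seed = 9)
  quant <- quantify_proteins(sim$peptides)
  gst <- quant[quant$protein == "GST", ]
  expect_equal(gst$ratio_A, 1)
  expect_equal(gst$ratio_B, 1)
})

test_that("planted enriched set is recovered end to end", {
  sim <- simulate_peptide_table(seed = 11)
  res <- suppressMessages(run_proteomics(sim$peptides))
  truth_mpp2 <- sort(sim$truth$protein[sim$truth$enriched &
                                         sim$truth$side == "MPP2"])
  truth_psd <- sort(sim$truth$protein[sim$truth$enriched &
                                        sim$truth$side == "PSD95"])
  expect_equal(sort(res$mpp2_enriched), truth_mpp2)
  expect_equal(sort(res$psd95_enriched), truth_psd)
  expect_equal(res$n_quantified, sum(sim$truth$stable) - 1L)  # minus GST
})

test_that("peptide TSV round-trip", {
  sim <- simulate_peptide_table(peptide_table_config(n_proteins = 12),
                                seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(sim$peptides, f, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  back <- read_peptide_table(f)
  expect_equal(nrow(back), nrow(sim$peptides))
  expect_error(read_peptide_table({
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines("protein\tratio", f2); f2
  }), "missing column")
})
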