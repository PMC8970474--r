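test_that("bracelet generator conserves counts and is deterministic", {
  geom <- bracelet_geometry(background_density = 0)
  s1 <- simulate_bracelet_synapse(geom, seed = 7)
  expect_equal(nrow(s1$localizations$SynCAM1), 6 * 50)
  expect_equal(nrow(s1$localizations$MPP2), 6 * 50)
  expect_equal(nrow(s1$localizations$PSD95), 200)
  s2 <- simulate_bracelet_synapse(geom, seed = 7)
  expect_identical(s1, s2)
  s3 <- simulate_bracelet_synapse(geom, seed = 8)
  expect_false(identical(s1$localizations$SynCAM1,
                         s3$localizations$SynCAM1))
})

test_that("bracelet geometry validates its invariants", {
  expect_error(bracelet_geometry(psd_disc_diameter = NA), "non-finite")
  expect_error(bracelet_geometry(ring_diameter_species_A = 300),
               "exceed")
  expect_error(bracelet_geometry(bracelet_probability = 1.5), "0, 1")
})

test_that("satellite centres sit on the configured ring (MC average)", {
  geom <- bracelet_geometry(bracelet_probability = 1)
  # oracle: direct averaging of generated truth centres
  radii <- unlist(lapply(1:100, function(i) {
    tr <- simulate_bracelet_synapse(geom, seed = i)$truth
    sqrt(rowSums(tr$satellite_centres$SynCAM1^2))
  }))
  expect_equal(mean(radii), 894 / 2, tolerance = 0.02)
})

test_that("voxel scene handles edge cases and conserves blob mass", {
  cfg <- voxel_scene_config(field_size = c(48, 48, 10), noise_sd = 0)
  empty <- simulate_voxel_scene(cfg, n_synapses = 0, seed = 1)
  expect_equal(length(empty$truth), 0L)
  expect_true(all(empty$stack$PSD95 == 0))

  one <- simulate_voxel_scene(cfg, n_synapses = 1, seed = 2)
  pk <- arrayInd(which.max(one$stack$PSD95), dim(one$stack$PSD95))
  ctr_vox <- one$truth[[1]]$centre / one$voxel_size + 0.5
  expect_true(all(abs(pk - ctr_vox) <= 1.5))

  # channel sums scale linearly with blob amplitude (analytic Gaussian
  # mass oracle: total mass = photon_scale * locs_per_satellite * n_sat)
  g <- bracelet_geometry()
  s_lo <- simulate_voxel_scene(cfg, g, n_synapses = 1, seed = 3)
  cfg_hi <- voxel_scene_config(field_size = c(48, 48, 10), noise_sd = 0,
                               photon_scale = 200)
  s_hi <- simulate_voxel_scene(cfg_hi, g, n_synapses = 1, seed = 3)
  expect_equal(sum(s_hi$stack$MPP2) / sum(s_lo$stack$MPP2), 2,
               tolerance = 1e-6)
  expect_equal(sum(s_lo$stack$SynCAM1),
               100 * g$locs_per_satellite * g$n_satellites_per_species,
               tolerance = 0.05)

  expect_error(simulate_voxel_scene(cfg, n_synapses = 100, seed = 1),
               "at most")
})

test_that("confocal truth matches the configured co-occurrence fraction", {
  z <- simulate_confocal_scene(
    confocal_scene_config(cooccurrence_fraction = 0), seed = 1)
  expect_false(any(z$truth$positive))
  o <- simulate_confocal_scene(
    confocal_scene_config(cooccurrence_fraction = 1), seed = 1)
  expect_true(all(o$truth$positive))
  # 500 spines: binomial-oracle check of the planted fraction
  big <- simulate_confocal_scene(
    confocal_scene_config(cooccurrence_fraction = 0.3,
                          n_homer_spines = 500L,
                          image_size = c(512L, 512L)), seed = 2)
  expect_equal(mean(big$truth$positive), 0.3, tolerance = 0.03)
  expect_error(
    confocal_scene_config(dendrite_path = cbind(c(-5, 100), c(0, 100))),
    "bounds")
})

test_that("peptide generator inverts replicate B and plants recoverable truth", {
  cfg <- peptide_table_config(
    n_proteins = 1, mpp2_enriched = c(X = 4)[0],
    psd95_enriched = c(Target = 4), background_log2_sd = 0,
    peptide_log_ratio_noise_sd = 0, n_single_replicate = 0L,
    n_high_dispersion = 0L)
  sim <- simulate_peptide_table(cfg, seed = 1)
  pep <- sim$peptides
  tA <- pep[pep$protein == "Target" & pep$replicate == "A", ]
  tB <- pep[pep$protein == "Target" & pep$replicate == "B", ]
  expect_true(all(tA$ratio == 4))
  expect_true(all(tB$ratio == 0.25))  # stored inverted before orientation
  res <- suppressMessages(run_proteomics(pep))
  prot <- res$proteins
  expect_equal(prot$ratio_A[prot$protein == "Target"], 4)
  expect_equal(prot$ratio_B[prot$protein == "Target"], 4)
})

test_that("generator truth marks proteins beyond 7-fold as enriched", {
  sim <- simulate_peptide_table(seed = 3)
  tr <- sim$truth
  expect_true(all(abs(log2(tr$true_ratio[tr$enriched])) > log2(7)))
  expect_equal(sum(tr$enriched & tr$side == "MPP2"), 7L)
  expect_identical(sim$peptides,
                   simulate_peptide_table(seed = 3)$peptides)
})
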