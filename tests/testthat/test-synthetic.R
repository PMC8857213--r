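test_that("invalid configs are rejected with the offending field named", {
  expect_error(community_config(true_abundances = matrix(0.6, 3, 4)),
               "true_abundances")
  expect_error(community_config(min_contig_length = 2000),
               "min_contig_length")
  expect_error(community_config(within_cluster_ani = 79,
                                between_cluster_ani = 80),
               "within_cluster_ani")
  expect_error(community_config(strains_per_cluster = 2, strain_ani = 70),
               "strain_ani")
})

test_that("the planted cluster structure is emitted and deterministic", {
  cfg <- community_config(n_clusters = 3, bins_per_cluster = 2, seed = 5)
  com <- generate_community(cfg)
  expect_equal(length(unique(com$truth$cluster_of)), 3)
  expect_equal(length(com$truth$cluster_of), 6)
  com2 <- generate_community(community_config(n_clusters = 3,
                                              bins_per_cluster = 2,
                                              seed = 5))
  expect_identical(com, com2)  # byte-identical under identical seed
  com3 <- generate_community(community_config(n_clusters = 3,
                                              bins_per_cluster = 2,
                                              seed = 6))
  expect_false(identical(com$ani, com3$ani))
})

test_that("any threshold between the planted ANI levels recovers the truth", {
  cfg <- community_config(n_clusters = 4, bins_per_cluster = 3,
                          within_cluster_ani = 99.5,
                          between_cluster_ani = 80, seed = 19)
  com <- generate_community(cfg)
  truth_part <- unname(lapply(split(names(com$truth$cluster_of),
                                    com$truth$cluster_of), sort))
  for (t in c(85, 90, 95, 99)) {
    got <- cluster_bins(com$quality$bin_id,
                        build_ani_graph(com$ani, t, 0.65))
    expect_true(same_partition(partition_of(got), truth_part))
  }
})

test_that("strain substructure separates at 99 but not at 95", {
  cfg <- community_config(n_clusters = 2, bins_per_cluster = 2,
                          strains_per_cluster = 2, strain_ani = 96.5,
                          seed = 23)
  com <- generate_community(cfg)
  at <- function(t) partition_of(cluster_bins(
    com$quality$bin_id, build_ani_graph(com$ani, t, 0.65)))
  strain_part <- unname(lapply(split(names(com$truth$strain_of),
                                     com$truth$strain_of), sort))
  species_part <- unname(lapply(split(names(com$truth$cluster_of),
                                      com$truth$cluster_of), sort))
  expect_true(same_partition(at(99), strain_part))
  expect_true(same_partition(at(95), species_part))
})

test_that("depth tables realise planted abundances under each noise model", {
  fr <- matrix(c(0.5, 0.3, 0.2), 3, 1)
  for (nm in c("none", "poisson", "lognormal-multiplier")) {
    cfg <- community_config(n_clusters = 3, n_samples = 1,
                            true_abundances = fr, depth_noise_model = nm,
                            total_depth = 400, seed = 29)
    com <- generate_community(cfg)
    ab <- abundance_series(com$mag_contigs, com$depths, com$rpob_regions)
    want <- fr[match(com$truth$cluster_of[ab$mag_id],
                     rownames(com$truth$planted_abundance)), 1]
    tol <- if (nm == "none") 1e-12 else 0.05
    expect_equal(ab$relative_abundance, want, tolerance = tol)
  }
})

test_that("every planted locus references an existing gene", {
  com <- generate_community(community_config(seed = 37))
  expect_true(all(com$truth$planted_loci$anchor %in% com$genes$gene_id))
  expect_true(all(com$truth$planted_loci$bin %in% com$quality$bin_id))
})

test_that("spectral tables respect replicates, dropout and determinism", {
  com <- generate_community(community_config(seed = 41,
                                             n_proteins_per_bin = 56))
  spc0 <- generate_spectra(com$truth, n_replicates = 3, dropout_rate = 0)
  expect_false(anyNA(spc0$spectral_count))
  expect_equal(length(unique(spc0$replicate_id)), 3)
  spc_a <- generate_spectra(com$truth, 3, 0.2)
  spc_b <- generate_spectra(com$truth, 3, 0.2)
  expect_identical(spc_a, spc_b)
  # dropout fraction within the binomial 99% interval at rate 0.5
  spc <- generate_spectra(com$truth, 3, 0.5)
  n <- nrow(spc)
  expect_gt(n, 1000)
  ci <- qbinom(c(0.005, 0.995), n, 0.5) / n
  frac <- mean(is.na(spc$spectral_count))
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  expect_error(generate_spectra(com$truth, 3, 1), "dropout_rate")
})

test_that("planted spectra scale with planted abundance", {
  fr <- matrix(c(0.6, 0.05), 2, 1)
  cfg <- community_config(n_clusters = 2, bins_per_cluster = 1,
                          n_samples = 1, true_abundances = fr, seed = 43)
  com <- generate_community(cfg)
  spc <- generate_spectra(com$truth, 3, 0)
  by_bin <- tapply(spc$spectral_count,
                   com$truth$planted_protein_origin[spc$protein_id], sum)
  expect_gt(by_bin[["bin001"]], 5 * by_bin[["bin002"]])
})
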