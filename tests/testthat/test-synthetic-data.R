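test_that("genome annotation honours the genic fraction, including edge cases", {
  g0 <- simulate_genome(1e6, 0, seed = 1)
  expect_equal(g0$genic_bp, 0)
  expect_equal(nrow(g0$genic), 0)
  expect_true(all(space_of(g0, c(1, 5e5, 1e6)) == "intergenic"))

  g1 <- simulate_genome(1e6, 1, seed = 1)
  expect_equal(g1$genic_bp, 1e6)
  expect_true(all(space_of(g1, c(1, 5e5, 1e6)) == "genic"))

  g <- simulate_genome(1e6, 0.2, seed = 7)
  expect_equal(g$genic_bp, 0.2 * 1e6, tolerance = g$block_size / 1e6)
  # intervals are non-overlapping and sorted
  expect_true(all(diff(g$genic$start) > 0))
  expect_true(all(g$genic$end[-nrow(g$genic)] < g$genic$start[-1]))

  expect_error(simulate_genome(5000, 0.2, seed = 1), "too small")
  expect_error(simulate_genome(1e6, 1.2, seed = 1), "genic_fraction")
})

test_that("genome simulation is deterministic for a fixed seed", {
  g1 <- simulate_genome(1e6, 0.2, seed = 7)
  g2 <- simulate_genome(1e6, 0.2, seed = 7)
  expect_identical(g1$genic, g2$genic)
  pos <- c(1, 17, 999999, 123456)
  expect_identical(ref_base(g1, pos), ref_base(g2, pos))
  g3 <- simulate_genome(1e6, 0.2, seed = 8)
  expect_false(identical(g1$genic, g3$genic))
})

test_that("reference bases are stable, valid and roughly uniform", {
  g <- simulate_genome(1e6, 0.2, seed = 3)
  b <- ref_base(g, 1:20000)
  expect_true(all(b %in% c("A", "C", "G", "T")))
  frac <- table(b) / length(b)
  expect_true(all(abs(frac - 0.25) < 0.02))
  ctx <- ref_context(g, c(1, 500, 1e6))
  expect_true(is.na(ctx[1]) && is.na(ctx[3]))
  expect_equal(substr(ctx[2], 2, 2), ref_base(g, 500))
})

test_that("zero rates and zero residual counts give an empty history", {
  cfg <- sim_config(rate_L1_genic = 0, rate_L1_intergenic = 0,
                    rate_L23_genic = 0, rate_L23_intergenic = 0,
                    n_ancestral = 0, n_root_unique = 0)
  g <- simulate_genome(cfg$genome_length, cfg$genic_fraction, cfg$seed)
  truth <- simulate_clone_history(cfg, g)
  expect_equal(nrow(truth), 0)
})

test_that("event counts follow the Poisson mean rate * bp * years", {
  # mean = 1e-6 * 800,000 * 10 = 8 events; check the replicate mean to 3 SE
  cfg <- sim_config(genome_length = 1e6, genic_fraction = 0.2, years = 10,
                    rate_L1_genic = 0, rate_L1_intergenic = 1e-6,
                    rate_L23_genic = 0, rate_L23_intergenic = 0,
                    n_ancestral = 0, n_root_unique = 0)
  g <- simulate_genome(1e6, 0.2, seed = 99)
  expect_equal(g$genic_bp, 2e5)
  counts <- vapply(1:200, function(s) {
    cfg$seed <- s
    nrow(simulate_clone_history(cfg, g))
  }, numeric(1))
  se <- sqrt(8 / 200)
  expect_lt(abs(mean(counts) - 8), 3 * se)
})

test_that("simulated mutations have unique positions, consistent space and simplex VAF", {
  cfg <- small_config(seed = 11)
  g <- simulate_genome(cfg$genome_length, cfg$genic_fraction, cfg$seed)
  truth <- simulate_clone_history(cfg, g)
  expect_equal(anyDuplicated(truth$pos), 0)
  expect_identical(truth$space, space_of(g, truth$pos))
  expect_identical(truth$ref, ref_base(g, truth$pos))
  expect_true(all(truth$ref != truth$alt))
  expect_true(all(truth$true_cell_vaf == 1 / cfg$ploidy))
  expect_identical(base_change_class(truth$ref, truth$alt), truth$base_change)
})

test_that("clone history errors when a space saturates", {
  cfg <- sim_config(genome_length = 1e4, genic_fraction = 0.5, years = 100,
                    rate_L1_genic = 1e-2, seed = 1)
  g <- simulate_genome(1e4, 0.5, 1)
  expect_error(simulate_clone_history(cfg, g), "saturated")
})

test_that("tissue VAF dilution follows true_cell_VAF x layer fraction", {
  cfg <- sim_config(rate_L1_intergenic = 4e-5, rate_L1_genic = 4e-5,
                    rate_L23_genic = 0, rate_L23_intergenic = 0,
                    n_ancestral = 0, n_root_unique = 0, seed = 5)
  g <- simulate_genome(cfg$genome_length, cfg$genic_fraction, cfg$seed)
  truth <- simulate_clone_history(cfg, g)
  expect_gt(nrow(truth), 500)

  for (case in list(list(comp = c(L1 = 1, L23 = 0), ev = 0.25),
                    list(comp = c(L1 = 0.24, L23 = 0.76), ev = 0.06))) {
    obs <- simulate_tissue_readcounts(truth, case$comp, depth_mean = 60,
                                      seed = 42, sample_id = "x", genome = g)
    v <- obs$alt_reads / obs$depth
    # 3-sigma band for the mean of n binomial-over-Poisson VAFs
    se <- sqrt(case$ev * (1 - case$ev) / 60 / nrow(obs))
    expect_lt(abs(mean(v) - case$ev), 3 * se)
  }

  # absent compartment: zero alt reads
  obs0 <- simulate_tissue_readcounts(truth, c(L1 = 0, L23 = 1), depth_mean = 60,
                                     seed = 42, sample_id = "x", genome = g)
  expect_true(all(obs0$alt_reads == 0))
})

test_that("regenerant panels share their layer's mutations and carry private ones", {
  cfg <- small_config(seed = 3, contaminant_rate = 0, mq_artifact_rate = 0)
  sim <- simulate_dataset(cfg)
  truth <- sim$truth
  regen <- sim$samples[sim$samples$role == "regenerant", ]

  # exclusivity: an L1 regenerant has no alt reads at L23-fixed sites
  l23_sites <- truth$site_id[truth$compartment == "L23"]
  l1_samples <- regen$sample_id[regen$layer == "L1"]
  cross <- sim$observations[sim$observations$site_id %in% l23_sites &
                              sim$observations$sample_id %in% l1_samples, ]
  expect_true(all(cross$alt_reads == 0))

  # private counts within the configured range
  priv <- truth[truth$compartment == "regenerant_private", ]
  counts <- table(priv$regenerant)
  expect_true(all(counts >= cfg$private_mutation_range[1]))
  expect_true(all(counts <= cfg$private_mutation_range[2]))
  expect_setequal(names(counts), regen$sample_id)

  expect_error(
    simulate_regenerant_panel(truth, sim$genome, "L2", 4, cfg, seed = 1),
    "layer")
  expect_error(
    simulate_regenerant_panel(truth, sim$genome, "L1", 0, cfg, seed = 1),
    "n_regen")
})

test_that("private-mutation C>A fraction matches the configured ROS bias", {
  cfg <- sim_config(ros_bias = 0.5, private_mutation_range = c(250, 250),
                    n_regenerants_L1 = 4, n_regenerants_L23 = 0,
                    genome_length = 5e5, seed = 21)
  g <- simulate_genome(cfg$genome_length, cfg$genic_fraction, cfg$seed)
  truth <- simulate_clone_history(cfg, g)
  pan <- simulate_regenerant_panel(truth, g, "L1", 4, cfg, seed = 77)
  n <- nrow(pan$truth)
  expect_equal(n, 1000)
  frac_ca <- mean(pan$truth$base_change == "C>A")
  expect_lt(abs(frac_ca - 0.5), 3 * sqrt(0.25 / n))
  # alleles remain consistent with the hashed reference
  expect_identical(pan$truth$ref, ref_base(g, pan$truth$pos))
  expect_identical(base_change_class(pan$truth$ref, pan$truth$alt),
                   pan$truth$base_change)
})

test_that("the full dataset generator is deterministic and internally consistent", {
  cfg <- small_config(seed = 8)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$observations, s2$observations)

  # compartment exclusivity between pure-L1 trichome and pure-L23 root
  wide <- tidyr::pivot_wider(
    s1$observations[s1$observations$sample_id %in% c("trichome", "root"),
                    c("site_id", "sample_id", "alt_reads")],
    names_from = "sample_id", values_from = "alt_reads")
  comp <- s1$truth$compartment[match(wide$site_id, s1$truth$site_id)]
  both <- !is.na(wide$trichome) & !is.na(wide$root) &
    wide$trichome > 0 & wide$root > 0
  expect_true(all(comp[both] == "ancestral"))

  # invalid configs are rejected
  expect_error(sim_config(leaf_composition = c(L1 = 0.5, L23 = 0.4)), "sum to 1")
  expect_error(sim_config(ploidy = 1), "ploidy")
  expect_error(sim_config(rate_L1_genic = -1), "rates")
})
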