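p_def <- classify_params()

classify_one <- function(...) {
  classify_tissue_mutations(obs_row("x", ...),
                            roles = c(trichome = "trichome", leaf = "leaf",
                                      root = "root"))$class
}

test_that("tissue triplet rule reproduces the canonical layer patterns", {
  # L1: simplex in trichome (0.25), diluted in leaf (~0.06), absent in root
  expect_equal(classify_one(trichome = c(60, 15), leaf = c(60, 4), root = c(60, 0)), "L1")
  # L2,3: absent in trichome, ~0.2 in leaf, simplex in root
  expect_equal(classify_one(trichome = c(60, 0), leaf = c(60, 12), root = c(60, 15)), "L23")
  # ancestral: simplex everywhere
  expect_equal(classify_one(trichome = c(60, 15), leaf = c(60, 15), root = c(60, 15)), "ancestral")
  # root-unique: only the root carries it
  expect_equal(classify_one(trichome = c(60, 0), leaf = c(60, 0), root = c(60, 15)), "root_unique")
  # below the 0.125 VAF floor in the trichome: no call
  expect_equal(classify_one(trichome = c(60, 7), leaf = c(60, 4), root = c(60, 0)), "unassigned")
})

test_that("confident presence needs both the depth and the VAF floors", {
  # depth boundary: 7x fails, 8x passes (VAF 0.25 in both)
  expect_equal(classify_one(trichome = c(7, 2), leaf = c(60, 4), root = c(60, 0)),
               "unassigned")
  expect_equal(classify_one(trichome = c(8, 2), leaf = c(60, 4), root = c(60, 0)),
               "L1")
  # VAF boundary at 8 reads of depth 64: 8/64 = 0.125 passes, 7/64 fails
  expect_equal(classify_one(trichome = c(64, 8), leaf = c(60, 4), root = c(60, 0)),
               "L1")
  expect_equal(classify_one(trichome = c(64, 7), leaf = c(60, 4), root = c(60, 0)),
               "unassigned")
  # absence claims need coverage: root at 5x cannot support an L1 call
  expect_equal(classify_one(trichome = c(60, 15), leaf = c(60, 4), root = c(5, 0)),
               "unassigned")
})

test_that("tissue classification matches the literal per-site oracle", {
  obs <- random_panel_obs(300, c("trichome", "leaf", "root"), seed = 42)
  got <- classify_tissue_mutations(obs)
  wide_d <- tidyr::pivot_wider(obs[, c("site_id", "sample_id", "depth")],
                               names_from = "sample_id", values_from = "depth")
  wide_a <- tidyr::pivot_wider(obs[, c("site_id", "sample_id", "alt_reads")],
                               names_from = "sample_id", values_from = "alt_reads")
  m <- match(got$site_id, wide_d$site_id)
  want <- vapply(seq_along(m), function(k) {
    i <- m[k]
    oracle_tissue_one(c(wide_d$trichome[i], wide_a$trichome[i]),
                      c(wide_d$leaf[i], wide_a$leaf[i]),
                      c(wide_d$root[i], wide_a$root[i]), p_def)
  }, character(1))
  expect_identical(got$class, want)
  expect_true(all(table(got$site_id) == 1))  # exactly one class per site
})

test_that("regenerant-panel classification matches its oracle and thresholds", {
  l1 <- paste0("r1_", 1:5); l23 <- paste0("r2_", 1:5); anc <- "anc"
  obs <- random_panel_obs(250, c(l1, l23, anc), seed = 7)
  got <- classify_regenerant_mutations(obs, panels = list(L1 = l1, L23 = l23),
                                       ancestors = anc)
  per_site <- split(obs, obs$site_id)
  want <- vapply(got$site_id, function(id) {
    s <- per_site[[id]]
    grab <- function(ids) lapply(ids, function(x) {
      row <- s[s$sample_id == x, ]
      c(row$depth, row$alt_reads)
    })
    oracle_regenerant_one(grab(l1), grab(l23), grab(anc), p_def)
  }, character(1))
  expect_identical(got$class, unname(want))
})

test_that("regenerant calls enforce panel support, other-layer absence and ancestors", {
  l1 <- paste0("a", 1:6); l23 <- paste0("b", 1:7)
  mk <- function(n_pass, anc_alt = 0, other_depth = 60) {
    args <- c(
      setNames(lapply(seq_along(l1), function(i)
        if (i <= n_pass) c(60, 15) else c(60, 0)), l1),
      setNames(lapply(l23, function(s) c(other_depth, 0)), l23),
      list(anc = c(60, anc_alt))
    )
    do.call(obs_row, c(list(site_id = "x"), args))
  }
  cls <- function(obs) classify_regenerant_mutations(
    obs, panels = list(L1 = l1, L23 = l23), ancestors = "anc")$class

  expect_equal(cls(mk(5)), "L1")       # 5 supporting regenerants
  expect_equal(cls(mk(4)), "L1")       # exactly the minimum
  expect_equal(cls(mk(3)), "unassigned")  # below min_regenerants
  expect_equal(cls(mk(5, anc_alt = 15)), "unassigned")  # present in ancestor
  expect_equal(cls(mk(5, other_depth = 0)), "unassigned")  # no coverage for absence
})

test_that("swapping panel labels mirrors L1 and L23 calls", {
  sim <- simulate_dataset(small_config(seed = 13))
  regen <- sim$samples[sim$samples$role == "regenerant", ]
  panels <- list(L1 = regen$sample_id[regen$layer == "L1"],
                 L23 = regen$sample_id[regen$layer == "L23"])
  obs <- sim$observations[sim$observations$sample_id %in%
                            c(regen$sample_id, "ancestor"), ]
  a <- classify_regenerant_mutations(obs, panels, "ancestor")
  b <- classify_regenerant_mutations(obs, list(L1 = panels$L23, L23 = panels$L1),
                                     "ancestor")
  swap <- c(L1 = "L23", L23 = "L1", unassigned = "unassigned",
            conflicted = "conflicted")
  expect_identical(unname(swap[a$class]), b$class)
})

test_that("private calls require exactly one confidently mutant regenerant", {
  regs <- paste0("r", 1:12)
  mk <- function(n_pass) {
    args <- setNames(lapply(seq_along(regs), function(i)
      if (i <= n_pass) c(80, 20) else c(20, 0)), regs)
    do.call(obs_row, c(list(site_id = "x"), args))
  }
  cls <- function(obs) call_private_mutations(obs, regs)$class
  expect_equal(cls(mk(1)), "private:r1")
  expect_equal(cls(mk(2)), "unassigned")
  expect_equal(cls(mk(0)), "unassigned")
})

test_that("contaminant filter triggers at four foreign reads summed over samples", {
  mk <- function(f1, f2) dplyr::bind_rows(
    tibble::tibble(site_id = "x", sample_id = "a", depth = 60, alt_reads = 10,
                   mean_mq = 60, foreign_reads = f1),
    tibble::tibble(site_id = "x", sample_id = "b", depth = 60, alt_reads = 10,
                   mean_mq = 60, foreign_reads = f2))
  expect_true(contaminant_filter(mk(4, 0))$contaminant)
  expect_true(contaminant_filter(mk(2, 2))$contaminant)   # summed across samples
  expect_false(contaminant_filter(mk(3, 0))$contaminant)
  expect_false(contaminant_filter(mk(0, 0))$contaminant)
})

test_that("classify_sites applies filters before rules and keeps classes exclusive", {
  obs <- dplyr::bind_rows(
    obs_row("good", trichome = c(60, 15), leaf = c(60, 4), root = c(60, 0)),
    obs_row("dirty", trichome = c(60, 15), leaf = c(60, 4), root = c(60, 0),
            foreign_reads = 2),  # 2 reads in each of 3 samples = 6 total
    obs_row("lowmq", trichome = c(60, 15), leaf = c(60, 4), root = c(60, 0),
            mean_mq = 39)
  )
  got <- classify_sites(obs, mode = "tissue")
  lut <- setNames(got$class, got$site_id)
  expect_equal(unname(lut["good"]), "L1")
  expect_equal(unname(lut["dirty"]), "contaminant")
  expect_equal(unname(lut["lowmq"]), "filtered_mq")
  expect_equal(nrow(got), 3)
})
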