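# Build a long observation tibble from named per-sample (depth, alt) pairs.
# obs_row("t1", trichome = c(60, 15), leaf = c(60, 4), root = c(60, 0))
obs_row <- function(site_id, ..., mean_mq = 60, foreign_reads = 0) {
  samples <- list(...)
  dplyr::bind_rows(lapply(names(samples), function(s) {
    tibble::tibble(site_id = site_id, sample_id = s,
                   depth = samples[[s]][1], alt_reads = samples[[s]][2],
                   mean_mq = mean_mq, foreign_reads = foreign_reads)
  }))
}

# small, fast simulation config for unit tests (not the acceptance conditions)
small_config <- function(seed = 1, ...) {
  args <- list(genome_length = 2e5, genic_fraction = 0.2, years = 10,
               rate_L1_genic = 2e-5, rate_L1_intergenic = 2e-5,
               rate_L23_genic = 5e-6, rate_L23_intergenic = 5e-6,
               n_ancestral = 10, n_root_unique = 10,
               n_regenerants_L1 = 4, n_regenerants_L23 = 4,
               private_mutation_range = c(10, 30),
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Literal per-site re-statement of the tissue rule, evaluated sample by
# sample with scalar logic: the independent oracle for the vectorized
# classifier.
oracle_tissue_one <- function(t, l, r, p) {
  vaf1 <- function(x) if (x[1] > 0) x[2] / x[1] else NA_real_
  pass <- function(x) x[1] >= p$min_depth && !is.na(vaf1(x)) && vaf1(x) >= p$min_vaf
  absent <- function(x) x[1] >= p$min_depth && x[2] <= p$absence_max_alt
  present <- function(x) x[2] >= p$presence_min_alt
  is_L1 <- pass(t) && absent(r) && present(l)
  is_L23 <- pass(r) && absent(t) && present(l)
  if (is_L1 && is_L23) return("conflicted")
  if (is_L1) return("L1")
  if (is_L23) return("L23")
  if (pass(t) && pass(l) && pass(r)) return("ancestral")
  if (pass(r) && absent(t) && absent(l) && !present(l)) return("root_unique")
  "unassigned"
}

oracle_regenerant_one <- function(panel_L1, panel_L23, ancestors, p) {
  pass <- function(x) x[1] >= p$min_depth && x[1] > 0 && x[2] / x[1] >= p$min_vaf
  absent <- function(x) x[1] >= p$min_depth && x[2] <= p$absence_max_alt
  anc_ok <- all(vapply(ancestors, function(x) {
    x[1] < p$min_depth || x[2] <= p$absence_max_alt
  }, logical(1)))
  n1 <- sum(vapply(panel_L1, pass, logical(1)))
  n2 <- sum(vapply(panel_L23, pass, logical(1)))
  is_L1 <- anc_ok && n1 >= p$min_regenerants &&
    all(vapply(panel_L23, absent, logical(1)))
  is_L23 <- anc_ok && n2 >= p$min_regenerants &&
    all(vapply(panel_L1, absent, logical(1)))
  if (is_L1 && is_L23) return("conflicted")
  if (is_L1) return("L1")
  if (is_L23) return("L23")
  "unassigned"
}

# random panel observations for oracle-equivalence checks
random_panel_obs <- function(n_sites, samples, seed) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_sites), function(i) {
      dplyr::bind_rows(lapply(samples, function(s) {
        d <- sample(0:30, 1)
        tibble::tibble(site_id = sprintf("s%04d", i), sample_id = s,
                       depth = d, alt_reads = if (d > 0) sample(0:d, 1) else 0L,
                       mean_mq = 60, foreign_reads = 0)
      }))
    }))
  })
}
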