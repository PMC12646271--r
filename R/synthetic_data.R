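#' Simulation configuration for a synthetic tetraploid clone
#'
#' Builds and validates the parameter set that drives the synthetic dataset
#' generator. Defaults emulate a Desiree-like tetraploid potato clone: 34
#' years of vegetative propagation, an L1 (epidermal) compartment that
#' accumulates mutations four times faster than the homogenized L2,3
#' compartment, leaf tissue that is a 24:76 mixture of L1- and L2,3-derived
#' cells, trichomes that are essentially pure L1 and adventitious roots that
#' are essentially pure L2,3, plus two regenerant panels of single-layer
#' origin carrying private, C>A-biased mutations acquired during protoplast
#' regeneration.
#'
#' Rates are expressed in mutations per base pair per year. The defaults are
#' scaled for a small synthetic genome (1 Mb) so that compartment counts land
#' in the hundreds; the *ratios* between them (L1/L2,3 = 4, intergenic/genic
#' = 2.5) mirror the magnitudes observed in clonal potato.
#'
#' @param genome_length genome size in bp (>= 10000).
#' @param genic_fraction proportion of the genome annotated as genic.
#' @param ploidy integer ploidy; a fresh simplex mutation has cell-level
#'   VAF `1/ploidy`.
#' @param years clonal divergence time in years.
#' @param rate_L1_genic,rate_L1_intergenic,rate_L23_genic,rate_L23_intergenic
#'   per-space accumulation rates, mutations * bp^-1 * y^-1.
#' @param n_ancestral number of ancestral mutations (present in every sample).
#' @param n_root_unique number of root-only residual mutations.
#' @param leaf_composition,trichome_composition,root_composition named
#'   numeric vectors `c(L1 = ..., L23 = ...)` of layer cell fractions,
#'   each summing to 1.
#' @param depth_mean mean sequencing depth per site (Poisson).
#' @param n_regenerants_L1,n_regenerants_L23 regenerant panel sizes.
#' @param private_mutation_range integer `c(min, max)` private mutations per
#'   regenerant (drawn uniformly).
#' @param ros_bias proportion of regenerant-private mutations forced to the
#'   C>A class (oxidative-damage signature).
#' @param contaminant_rate proportion of mutation sites given >= 4
#'   foreign-taxon reads (stand-in for cross-species contamination).
#' @param mq_artifact_rate proportion of mutation sites assigned a low
#'   (<= 40) site mean mapping quality, to exercise the MQ filter.
#' @param seed integer RNG seed; every simulation product is a pure function
#'   of the config (including this seed).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genome_length = 1e6,
                       genic_fraction = 0.2,
                       ploidy = 4L,
                       years = 34L,
                       rate_L1_genic = 8e-6,
                       rate_L1_intergenic = 2e-5,
                       rate_L23_genic = 2e-6,
                       rate_L23_intergenic = 5e-6,
                       n_ancestral = 53L,
                       n_root_unique = 52L,
                       leaf_composition = c(L1 = 0.24, L23 = 0.76),
                       trichome_composition = c(L1 = 1, L23 = 0),
                       root_composition = c(L1 = 0, L23 = 1),
                       depth_mean = 60,
                       n_regenerants_L1 = 6L,
                       n_regenerants_L23 = 7L,
                       private_mutation_range = c(36L, 984L),
                       ros_bias = 0.5,
                       contaminant_rate = 0.01,
                       mq_artifact_rate = 0.01,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.numeric(genome_length),
    genic_fraction = genic_fraction,
    ploidy = as.integer(ploidy),
    years = as.numeric(years),
    rate_L1_genic = rate_L1_genic,
    rate_L1_intergenic = rate_L1_intergenic,
    rate_L23_genic = rate_L23_genic,
    rate_L23_intergenic = rate_L23_intergenic,
    n_ancestral = as.integer(n_ancestral),
    n_root_unique = as.integer(n_root_unique),
    leaf_composition = leaf_composition,
    trichome_composition = trichome_composition,
    root_composition = root_composition,
    depth_mean = depth_mean,
    n_regenerants_L1 = as.integer(n_regenerants_L1),
    n_regenerants_L23 = as.integer(n_regenerants_L23),
    private_mutation_range = as.integer(private_mutation_range),
    ros_bias = ros_bias,
    contaminant_rate = contaminant_rate,
    mq_artifact_rate = mq_artifact_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$genome_length >= 10000)
  if (cfg$genic_fraction < 0 || cfg$genic_fraction > 1) {
    stop("genic_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$ploidy < 2) stop("ploidy must be >= 2", call. = FALSE)
  if (cfg$depth_mean <= 0) stop("depth_mean must be > 0", call. = FALSE)
  rates <- c(cfg$rate_L1_genic, cfg$rate_L1_intergenic,
             cfg$rate_L23_genic, cfg$rate_L23_intergenic)
  if (any(rates < 0)) stop("mutation rates must be >= 0", call. = FALSE)
  for (nm in c("leaf_composition", "trichome_composition", "root_composition")) {
    check_composition(cfg[[nm]], nm)
  }
  if (cfg$ros_bias < 0 || cfg$ros_bias > 1) {
    stop("ros_bias must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$private_mutation_range) != 2 ||
      cfg$private_mutation_range[1] > cfg$private_mutation_range[2] ||
      cfg$private_mutation_range[1] < 0) {
    stop("private_mutation_range must be an ordered nonnegative pair", call. = FALSE)
  }
  if (cfg$contaminant_rate < 0 || cfg$contaminant_rate > 1 ||
      cfg$mq_artifact_rate < 0 || cfg$mq_artifact_rate > 1) {
    stop("artifact rates must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

check_composition <- function(comp, what = "composition") {
  if (is.null(names(comp)) || !all(c("L1", "L23") %in% names(comp))) {
    stop(what, " must be a named vector with L1 and L23 entries", call. = FALSE)
  }
  if (any(comp < 0) || abs(sum(comp) - 1) > 1e-9) {
    stop(what, " fractions must be nonnegative and sum to 1", call. = FALSE)
  }
  invisible(comp)
}

BASES <- c("A", "C", "G", "T")

# Deterministic O(1) per-position base hash. Constants are kept small enough
# that all intermediates stay below 2^53 (exact in doubles).
position_base_hash <- function(pos, seed) {
  s <- seed %% 100000
  x <- (pos * 69069 + s * 2654435761 + 1442695040888963 %% 4294967296) %% 4294967296
  x <- (x * 69069 + 12345) %% 4294967296
  x <- (x * 69069 + 12345) %% 4294967296
  ((x %/% 65536) %% 4) + 1
}

#' Simulate a reference genome with genic/intergenic annotation
#'
#' Produces a single-contig synthetic reference: a set of non-overlapping
#' genic intervals covering `genic_fraction * length` bp (to within one
#' interval granule) and a deterministic per-position base assignment used
#' for ref/alt draws and trinucleotide contexts. A stand-in for a real
#' assembly plus gene annotation.
#'
#' @param length genome length in bp, >= 10000.
#' @param genic_fraction proportion of positions annotated genic.
#' @param seed integer seed; output is a pure function of the arguments.
#' @param block_size granule size in bp for genic interval placement.
#' @return an object of class `sim_genome`: list with `length`, `genic`
#'   (tibble of 1-based closed intervals `start`, `end`), `seed`,
#'   `genic_bp`, `chrom`.
#' @export
simulate_genome <- function(length, genic_fraction, seed, block_size = 5000) {
  if (length < 10000) stop("genome too small: length must be >= 10000", call. = FALSE)
  if (genic_fraction < 0 || genic_fraction > 1) {
    stop("genic_fraction must lie in [0, 1]", call. = FALSE)
  }
  length <- as.numeric(length)
  n_blocks <- floor(length / block_size)
  n_genic <- round(genic_fraction * n_blocks)
  genic_blocks <- withr::with_seed(seed, sort(sample.int(n_blocks, n_genic)))
  if (n_genic > 0) {
    start <- (genic_blocks - 1) * block_size + 1
    end <- genic_blocks * block_size
    # merge adjacent blocks into maximal intervals
    brk <- c(TRUE, start[-1] != end[-n_genic] + 1)
    grp <- cumsum(brk)
    genic <- tibble::tibble(
      start = tapply(start, grp, min)[order(unique(grp))],
      end = tapply(end, grp, max)[order(unique(grp))]
    )
    genic <- tibble::tibble(start = as.numeric(genic$start), end = as.numeric(genic$end))
  } else {
    genic <- tibble::tibble(start = numeric(0), end = numeric(0))
  }
  structure(
    list(chrom = "chr1", length = length, genic = genic,
         genic_bp = n_genic * block_size, seed = as.integer(seed),
         block_size = block_size),
    class = "sim_genome"
  )
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %s: %.0f bp, %.0f genic bp in %d intervals\n",
              x$chrom, x$length, x$genic_bp, nrow(x$genic)))
  invisible(x)
}

#' Reference base at given positions
#'
#' @param genome a `sim_genome`.
#' @param pos 1-based positions.
#' @return character vector of bases in A/C/G/T.
#' @export
ref_base <- function(genome, pos) {
  BASES[position_base_hash(as.numeric(pos), genome$seed)]
}

#' Trinucleotide reference context at given positions
#'
#' Returns the 3-base reference context centred on each position, or `NA`
#' at contig edges.
#'
#' @inheritParams ref_base
#' @return character vector of 3-mers (NA at contig edges).
#' @export
ref_context <- function(genome, pos) {
  pos <- as.numeric(pos)
  ctx <- paste0(ref_base(genome, pos - 1), ref_base(genome, pos), ref_base(genome, pos + 1))
  ctx[pos <= 1 | pos >= genome$length] <- NA_character_
  ctx
}

#' Genomic space (genic/intergenic) of positions
#'
#' @inheritParams ref_base
#' @return character vector, "genic" or "intergenic".
#' @export
space_of <- function(genome, pos) {
  if (nrow(genome$genic) == 0) return(rep("intergenic", length(pos)))
  idx <- findInterval(as.numeric(pos), genome$genic$start)
  genic <- idx >= 1 & as.numeric(pos) <= genome$genic$end[pmax(idx, 1)]
  ifelse(genic, "genic", "intergenic")
}

# Map the k-th genic basepair (1..genic_bp) to its genomic position.
genic_offset_to_pos <- function(genome, k) {
  w <- genome$genic$end - genome$genic$start + 1
  cw <- cumsum(w)
  i <- findInterval(k - 1, c(0, cw), rightmost.closed = FALSE)
  genome$genic$start[i] + (k - 1) - c(0, cw)[i]
}

# Sample n unique positions uniformly within one space of the genome.
sample_space_positions <- function(genome, space, n, exclude = numeric(0)) {
  total <- if (space == "genic") genome$genic_bp else genome$length - genome$genic_bp
  if (n > total * 0.5) stop("space saturated: too many mutations for available positions", call. = FALSE)
  if (n == 0) return(numeric(0))
  pos <- numeric(0)
  while (length(pos) < n) {
    draw <- ceiling(stats::runif(2 * (n - length(pos))) * genome$length)
    draw <- draw[space_of(genome, draw) == space]
    pos <- unique(c(pos, setdiff(draw, exclude)))
  }
  pos[seq_len(n)]
}

SIX_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# Given reference bases and target 6-class labels, return the alt base that
# realises each class at that ref (purine refs via reverse complement).
alt_for_class <- function(ref, class) {
  pyr_ref <- substr(class, 1, 1)
  pyr_alt <- substr(class, 3, 3)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- ifelse(ref %in% c("C", "T"), pyr_alt, comp[pyr_alt])
  bad <- (ref %in% c("C", "G") & pyr_ref != "C") | (ref %in% c("A", "T") & pyr_ref != "T")
  out[bad] <- NA_character_
  unname(out)
}

# Draw base-change classes for given refs: uniform over the 3 classes
# compatible with each ref (pyrimidine-equivalence).
draw_classes_for_refs <- function(ref) {
  pyr <- ifelse(ref %in% c("C", "G"), "C", "T")
  offset <- ifelse(pyr == "C", 0L, 3L)
  SIX_CLASSES[offset + sample.int(3, length(ref), replace = TRUE)]
}

# Sample positions in either space whose ref base maps to the requested
# pyrimidine class family ("C" = ref in {C,G}, "T" = ref in {A,T}).
sample_positions_for_family <- function(genome, n, family, exclude) {
  pos <- numeric(0)
  while (length(pos) < n) {
    cand <- ceiling(stats::runif(3 * (n - length(pos))) * genome$length)
    fam <- ifelse(ref_base(genome, cand) %in% c("C", "G"), "C", "T")
    cand <- cand[fam == family]
    pos <- unique(c(pos, setdiff(cand, exclude)))
  }
  pos[seq_len(n)]
}

new_truth_rows <- function(genome, pos, compartment, ploidy, alt = NULL, class = NULL) {
  ref <- ref_base(genome, pos)
  if (is.null(class)) class <- draw_classes_for_refs(ref)
  if (is.null(alt)) alt <- alt_for_class(ref, class)
  tibble::tibble(
    chrom = genome$chrom, pos = pos, ref = ref, alt = alt,
    compartment = compartment, space = space_of(genome, pos),
    true_cell_vaf = 1 / ploidy, base_change = class
  )
}

#' Simulate the mutational history of a clonal plant
#'
#' Draws, per compartment (L1, L2,3) and genomic space (genic, intergenic),
#' a Poisson number of fixed simplex mutations with mean
#' `rate * space_bp * years`, assigns each a unique position, reference-
#' consistent ref/alt alleles (uniform over the six pyrimidine-centred
#' base-change classes), and appends ancestral and root-only residual
#' mutations. Site-level artifact flags (low mapping quality, foreign-taxon
#' contamination) are drawn here so that all downstream sample tables agree
#' on them.
#'
#' @param config a [sim_config()].
#' @param genome a [simulate_genome()] result.
#' @return a tibble of ground-truth mutations with columns `site_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `compartment` (L1 / L23 / root_unique /
#'   ancestral), `space`, `true_cell_vaf`, `base_change`, `mq_artifact`,
#'   `contaminant`.
#' @export
simulate_clone_history <- function(config, genome) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    specs <- list(
      list("L1", "genic", config$rate_L1_genic),
      list("L1", "intergenic", config$rate_L1_intergenic),
      list("L23", "genic", config$rate_L23_genic),
      list("L23", "intergenic", config$rate_L23_intergenic)
    )
    used <- numeric(0)
    rows <- list()
    for (sp in specs) {
      bp <- if (sp[[2]] == "genic") genome$genic_bp else genome$length - genome$genic_bp
      lambda <- sp[[3]] * bp * config$years
      n <- if (lambda > 0) stats::rpois(1, lambda) else 0L
      if (n > 0) {
        pos <- sample_space_positions(genome, sp[[2]], n, exclude = used)
        used <- c(used, pos)
        rows[[length(rows) + 1]] <- new_truth_rows(genome, pos, sp[[1]], config$ploidy)
      }
    }
    for (residual in c("ancestral", "root_unique")) {
      n <- if (residual == "ancestral") config$n_ancestral else config$n_root_unique
      if (n > 0) {
        pos <- sample_genome_positions(genome, n, exclude = used)
        used <- c(used, pos)
        rows[[length(rows) + 1]] <- new_truth_rows(genome, pos, residual, config$ploidy)
      }
    }
    truth <- if (length(rows)) dplyr::bind_rows(rows) else new_truth_rows(genome, numeric(0), character(0), config$ploidy)
    truth$mq_artifact <- stats::runif(nrow(truth)) < config$mq_artifact_rate
    truth$contaminant <- stats::runif(nrow(truth)) < config$contaminant_rate
    truth$site_id <- if (nrow(truth)) sprintf("site%05d", seq_len(nrow(truth))) else character(0)
    dplyr::relocate(dplyr::arrange(truth, pos), "site_id")
  })
}

sample_genome_positions <- function(genome, n, exclude = numeric(0)) {
  pos <- numeric(0)
  while (length(pos) < n) {
    draw <- ceiling(stats::runif(2 * (n - length(pos))) * genome$length)
    pos <- unique(c(pos, setdiff(draw, exclude)))
  }
  pos[seq_len(n)]
}

# Expected VAF of each truth row in a tissue with the given layer composition.
expected_tissue_vaf <- function(truth, composition, root_unique_fraction = 0) {
  frac <- dplyr::case_when(
    truth$compartment == "L1" ~ composition[["L1"]],
    truth$compartment == "L23" ~ composition[["L23"]],
    truth$compartment == "ancestral" ~ 1,
    truth$compartment == "root_unique" ~ root_unique_fraction,
    TRUE ~ 0
  )
  truth$true_cell_vaf * frac
}

# Shared site-level nuisance draws (MQ, foreign reads) must be identical
# across samples; derive them deterministically from the genome seed + pos.
site_mq <- function(truth, genome) {
  low <- 20 + (position_base_hash(truth$pos, genome$seed + 7) %% 4) * 5 +
    (position_base_hash(truth$pos, genome$seed + 11) %% 2) * 0.5
  ifelse(truth$mq_artifact, low, 60)
}

site_foreign_reads <- function(truth, genome) {
  ifelse(truth$contaminant,
         4 + (position_base_hash(truth$pos, genome$seed + 13) %% 5), 0)
}

#' Simulate read counts for one tissue sample
#'
#' At every ground-truth site, draws total depth from Poisson(`depth_mean`)
#' and alt reads from Binomial(depth, expected VAF), where the expected VAF
#' is `true_cell_vaf` times the fraction of the tissue's cells that descend
#' from the mutation's compartment (ancestral mutations use fraction 1).
#' Site mean mapping quality is 60 except at flagged artifact sites
#' (assigned values <= 40); flagged contaminant sites carry >= 4
#' foreign-taxon reads. Both flags are site-level, so every sample simulated
#' from the same truth agrees on them.
#'
#' @param truth ground truth from [simulate_clone_history()].
#' @param composition named layer fractions `c(L1 = , L23 = )` summing to 1.
#' @param depth_mean mean depth.
#' @param seed integer seed for this sample's read sampling.
#' @param sample_id sample name stored in the output.
#' @param genome the `sim_genome` (for site-level nuisance draws).
#' @param root_unique_fraction cell fraction carrying root-only mutations in
#'   this tissue (1 for the root sample, 0 elsewhere).
#' @return tibble with columns `site_id`, `sample_id`, `depth`, `alt_reads`,
#'   `mean_mq`, `foreign_reads`.
#' @export
simulate_tissue_readcounts <- function(truth, composition, depth_mean, seed,
                                       sample_id, genome,
                                       root_unique_fraction = 0) {
  check_composition(composition)
  ev <- pmin(expected_tissue_vaf(truth, composition, root_unique_fraction), 1)
  withr::with_seed(seed, {
    depth <- stats::rpois(nrow(truth), depth_mean)
    alt <- stats::rbinom(nrow(truth), depth, ev)
  })
  tibble::tibble(
    site_id = truth$site_id, sample_id = sample_id,
    depth = depth, alt_reads = alt,
    mean_mq = site_mq(truth, genome),
    foreign_reads = site_foreign_reads(truth, genome)
  )
}

#' Simulate a panel of single-layer protoplast regenerants
#'
#' Each regenerant descends from a single cell of the given layer: it
#' carries all of that layer's fixed mutations (and the ancestral ones) at
#' expected VAF `1/ploidy`, none of the other layer's, plus a private set of
#' mutations acquired around regeneration. Private counts are uniform on
#' `private_mutation_range`; private base changes are C>A with probability
#' `ros_bias` (the oxidative-damage signature) and uniform over the other
#' five classes otherwise.
#'
#' @param truth fixed-mutation ground truth ([simulate_clone_history()]).
#' @param genome the `sim_genome`.
#' @param layer "L1" or "L23".
#' @param n_regen panel size (>= 1).
#' @param config the [sim_config()].
#' @param seed seed for this panel.
#' @param id_prefix prefix for sample names (default `reg_<layer>_`).
#' @return list with `truth` (private-mutation rows, compartment
#'   `"regenerant_private"`, column `regenerant` naming the carrier) and
#'   `observations` (read counts for every panel sample at all fixed +
#'   panel-private sites).
#' @export
simulate_regenerant_panel <- function(truth, genome, layer, n_regen, config,
                                      seed, id_prefix = NULL) {
  if (!layer %in% c("L1", "L23")) stop("layer must be 'L1' or 'L23'", call. = FALSE)
  if (n_regen < 1) stop("n_regen must be >= 1", call. = FALSE)
  if (is.null(id_prefix)) id_prefix <- paste0("reg_", layer, "_")
  samples <- paste0(id_prefix, seq_len(n_regen))

  withr::with_seed(seed, {
    pr <- config$private_mutation_range
    counts <- pr[1] + sample.int(pr[2] - pr[1] + 1, n_regen, replace = TRUE) - 1L
    used <- truth$pos
    priv_rows <- list()
    for (i in seq_len(n_regen)) {
      n <- counts[i]
      is_ca <- stats::runif(n) < config$ros_bias
      n_ca <- sum(is_ca)
      cls <- character(n)
      cls[is_ca] <- "C>A"
      if (n - n_ca > 0) cls[!is_ca] <- sample(SIX_CLASSES[-1], n - n_ca, replace = TRUE)
      fam <- ifelse(substr(cls, 1, 1) == "C", "C", "T")
      pos <- numeric(n)
      for (f in c("C", "T")) {
        k <- sum(fam == f)
        if (k > 0) {
          p <- sample_positions_for_family(genome, k, f, exclude = used)
          pos[fam == f] <- p
          used <- c(used, p)
        }
      }
      rows <- new_truth_rows(genome, pos, "regenerant_private", config$ploidy, class = cls)
      rows$regenerant <- samples[i]
      priv_rows[[i]] <- rows
    }
    priv <- dplyr::bind_rows(priv_rows)
    priv$mq_artifact <- FALSE
    priv$contaminant <- FALSE
    priv$site_id <- sprintf("%spriv%05d", id_prefix, seq_len(nrow(priv)))

    all_sites <- dplyr::bind_rows(
      dplyr::mutate(truth, regenerant = NA_character_), priv
    )
    obs <- lapply(seq_len(n_regen), function(i) {
      frac <- dplyr::case_when(
        all_sites$compartment == layer ~ 1,
        all_sites$compartment == "ancestral" ~ 1,
        all_sites$compartment == "regenerant_private" &
          all_sites$regenerant == samples[i] ~ 1,
        TRUE ~ 0
      )
      ev <- pmin(all_sites$true_cell_vaf * frac, 1)
      depth <- stats::rpois(nrow(all_sites), config$depth_mean)
      alt <- stats::rbinom(nrow(all_sites), depth, ev)
      tibble::tibble(
        site_id = all_sites$site_id, sample_id = samples[i],
        depth = depth, alt_reads = alt,
        mean_mq = site_mq(all_sites, genome),
        foreign_reads = site_foreign_reads(all_sites, genome)
      )
    })
    list(truth = priv, observations = dplyr::bind_rows(obs), samples = samples)
  })
}

#' Simulate a complete labeled dataset
#'
#' End-to-end generator: genome, fixed-mutation history, tissue triplet
#' (trichome / leaf / root), ancestor sample, and both regenerant panels.
#' Everything is a pure function of the config.
#'
#' @param config a [sim_config()].
#' @return an object of class `layer_sim`: list with `config`, `genome`,
#'   `truth` (fixed + private mutations), `observations` (long tibble over
#'   all samples and sites), `samples` (metadata tibble: `sample_id`,
#'   `role`, `layer`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  genome <- simulate_genome(config$genome_length, config$genic_fraction,
                            seed = config$seed)
  fixed <- simulate_clone_history(config, genome)

  tissue <- list(
    trichome = list(comp = config$trichome_composition, root_frac = 0),
    leaf = list(comp = config$leaf_composition, root_frac = 0),
    root = list(comp = config$root_composition, root_frac = 1)
  )
  obs <- list()
  for (nm in names(tissue)) {
    obs[[nm]] <- simulate_tissue_readcounts(
      fixed, tissue[[nm]]$comp, config$depth_mean,
      seed = config$seed + match(nm, names(tissue)), sample_id = nm,
      genome = genome, root_unique_fraction = tissue[[nm]]$root_frac
    )
  }

  pan_L1 <- simulate_regenerant_panel(fixed, genome, "L1", config$n_regenerants_L1,
                                      config, seed = config$seed + 101)
  pan_L23 <- simulate_regenerant_panel(fixed, genome, "L23", config$n_regenerants_L23,
                                       config, seed = config$seed + 202)

  truth <- dplyr::bind_rows(
    dplyr::mutate(fixed, regenerant = NA_character_),
    pan_L1$truth, pan_L23$truth
  )

  # the ancestor clone carries only ancestral mutations
  anc_frac <- ifelse(truth$compartment == "ancestral", 1, 0)
  anc <- withr::with_seed(config$seed + 303, {
    depth <- stats::rpois(nrow(truth), config$depth_mean)
    tibble::tibble(
      site_id = truth$site_id, sample_id = "ancestor",
      depth = depth,
      alt_reads = stats::rbinom(nrow(truth), depth,
                                pmin(truth$true_cell_vaf * anc_frac, 1)),
      mean_mq = site_mq(truth, genome),
      foreign_reads = site_foreign_reads(truth, genome)
    )
  })

  # tissue samples have no observations at regenerant-private sites (those
  # mutations postdate the sampled plant); represent as depth-only records.
  priv_ids <- truth$site_id[truth$compartment == "regenerant_private"]
  tissue_priv <- list()
  if (length(priv_ids)) {
    priv_truth <- truth[match(priv_ids, truth$site_id), ]
    for (nm in names(tissue)) {
      tissue_priv[[nm]] <- withr::with_seed(config$seed + 404 + match(nm, names(tissue)), {
        depth <- stats::rpois(length(priv_ids), config$depth_mean)
        tibble::tibble(site_id = priv_ids, sample_id = nm, depth = depth,
                       alt_reads = 0L,
                       mean_mq = site_mq(priv_truth, genome),
                       foreign_reads = site_foreign_reads(priv_truth, genome))
      })
    }
  }

  # each panel also sequences the other panel's private sites (no alt reads
  # expected there: those mutations arose in a different regenerant)
  cross_obs <- function(panel_samples, other_truth, seed_off) {
    if (nrow(other_truth) == 0) return(NULL)
    withr::with_seed(config$seed + seed_off, {
      dplyr::bind_rows(lapply(panel_samples, function(s) {
        tibble::tibble(
          site_id = other_truth$site_id, sample_id = s,
          depth = stats::rpois(nrow(other_truth), config$depth_mean),
          alt_reads = 0L,
          mean_mq = site_mq(other_truth, genome),
          foreign_reads = site_foreign_reads(other_truth, genome)
        )
      }))
    })
  }

  observations <- dplyr::bind_rows(
    dplyr::bind_rows(obs), dplyr::bind_rows(tissue_priv),
    pan_L1$observations, pan_L23$observations,
    cross_obs(pan_L1$samples, pan_L23$truth, 505),
    cross_obs(pan_L23$samples, pan_L1$truth, 606),
    anc
  )

  samples <- tibble::tibble(
    sample_id = c("trichome", "leaf", "root", "ancestor",
                  pan_L1$samples, pan_L23$samples),
    role = c("tissue", "tissue", "tissue", "ancestor",
             rep("regenerant", length(pan_L1$samples) + length(pan_L23$samples))),
    layer = c(NA, NA, NA, NA,
              rep("L1", length(pan_L1$samples)),
              rep("L23", length(pan_L23$samples)))
  )

  structure(list(config = config, genome = genome, truth = truth,
                 observations = observations, samples = samples),
            class = "layer_sim")
}

#' @export
print.layer_sim <- function(x, ...) {
  tab <- table(x$truth$compartment)
  cat(sprintf("<layer_sim> %.0f bp genome, %d mutation sites, %d samples\n",
              x$genome$length, nrow(x$truth), nrow(x$samples)))
  print(tab)
  invisible(x)
}
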