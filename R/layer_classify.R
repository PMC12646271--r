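#' Classification thresholds
#'
#' Parameters shared by the tissue-triplet and regenerant-panel
#' classifiers.
#'
#' `min_depth`/`min_vaf` define *confident presence*: a sample supports a
#' mutation iff it has at least `min_depth` reads and VAF at least
#' `min_vaf` (8x and 0.125 by default — half the expected simplex VAF of a
#' tetraploid). `presence_min_alt` operationalizes "present at any VAF" in
#' mosaic tissue: at least one supporting read. `absence_max_alt`
#' operationalizes "not detected": at most one alt read, and only at
#' `min_depth` coverage or better, since absence cannot be claimed without
#' coverage.
#'
#' @param min_depth minimum depth for confident presence/absence calls.
#' @param min_vaf minimum VAF for confident presence.
#' @param min_regenerants minimum number of supporting regenerants for a
#'   layer-specific call.
#' @param presence_min_alt minimum alt reads for presence at any VAF.
#' @param absence_max_alt maximum alt reads tolerated in a "not detected"
#'   sample.
#' @param contaminant_min_reads minimum foreign-taxon reads (summed over
#'   samples) that flag a site as contaminant.
#' @return a `classify_params` list.
#' @export
classify_params <- function(min_depth = 8, min_vaf = 0.125, min_regenerants = 4,
                            presence_min_alt = 1, absence_max_alt = 1,
                            contaminant_min_reads = 4) {
  stopifnot(min_depth >= 1, min_vaf > 0, min_vaf < 1, min_regenerants >= 1,
            presence_min_alt >= 1, absence_max_alt >= 0,
            contaminant_min_reads >= 1)
  structure(list(min_depth = min_depth, min_vaf = min_vaf,
                 min_regenerants = min_regenerants,
                 presence_min_alt = presence_min_alt,
                 absence_max_alt = absence_max_alt,
                 contaminant_min_reads = contaminant_min_reads),
            class = "classify_params")
}

# wide per-site evidence matrix for a set of samples
obs_wide <- function(observations, samples, field) {
  sub <- observations[observations$sample_id %in% samples,
                      c("site_id", "sample_id", field)]
  w <- tidyr::pivot_wider(sub, names_from = "sample_id",
                          values_from = dplyr::all_of(field))
  for (s in samples) {
    if (!s %in% names(w)) w[[s]] <- 0L   # sample never observed at these sites
    w[[s]][is.na(w[[s]])] <- 0L          # missing genotype observation = depth 0
  }
  w[, c("site_id", samples)]
}

# per-site evidence predicates for one sample column
ev_pass <- function(depth, alt, p) depth >= p$min_depth & vaf(alt, depth) >= p$min_vaf
ev_present <- function(depth, alt, p) alt >= p$presence_min_alt
ev_absent <- function(depth, alt, p) depth >= p$min_depth & alt <= p$absence_max_alt

#' Classify mutations from the trichome / leaf / root tissue triplet
#'
#' Implements the tissue-triplet rule set for a periclinal chimera:
#' * `L1`: confidently present in the trichome sample (depth >= `min_depth`
#'   and VAF >= `min_vaf`), not detected in root (coverage-backed absence),
#'   and present at any VAF in the mosaic leaf.
#' * `L23`: the same with trichome and root roles swapped.
#' * `ancestral`: confidently present in all three samples.
#' * `root_unique`: confidently present in root, absent in trichome and
#'   leaf.
#' * `conflicted`: both the L1 and L23 clauses hold (surfaced, not
#'   dropped).
#' * otherwise `unassigned` (including any site lacking the coverage an
#'   absence claim requires).
#'
#' Precedence when clauses overlap at boundary read counts:
#' conflicted > L1/L23 > ancestral > root_unique.
#'
#' @param observations long observation tibble.
#' @param roles named character vector mapping `trichome`, `leaf`, `root`
#'   to sample ids.
#' @param params a [classify_params()].
#' @return tibble `site_id`, `class`.
#' @export
classify_tissue_mutations <- function(observations, roles = c(trichome = "trichome",
                                                              leaf = "leaf",
                                                              root = "root"),
                                      params = classify_params()) {
  if (!all(c("trichome", "leaf", "root") %in% names(roles))) {
    stop("roles must name trichome, leaf and root samples", call. = FALSE)
  }
  missing <- setdiff(roles, unique(observations$sample_id))
  if (length(missing)) stop("missing role sample(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  dp <- obs_wide(observations, unname(roles), "depth")
  ad <- obs_wide(observations, unname(roles), "alt_reads")
  p <- params
  tdep <- dp[[roles[["trichome"]]]]; talt <- ad[[roles[["trichome"]]]]
  ldep <- dp[[roles[["leaf"]]]];     lalt <- ad[[roles[["leaf"]]]]
  rdep <- dp[[roles[["root"]]]];     ralt <- ad[[roles[["root"]]]]

  is_L1 <- ev_pass(tdep, talt, p) & ev_absent(rdep, ralt, p) & ev_present(ldep, lalt, p)
  is_L23 <- ev_pass(rdep, ralt, p) & ev_absent(tdep, talt, p) & ev_present(ldep, lalt, p)
  is_anc <- ev_pass(tdep, talt, p) & ev_pass(ldep, lalt, p) & ev_pass(rdep, ralt, p)
  is_root <- ev_pass(rdep, ralt, p) & ev_absent(tdep, talt, p) & ev_absent(ldep, lalt, p) &
    !ev_present(ldep, lalt, p)

  class <- rep("unassigned", nrow(dp))
  class[is_root] <- "root_unique"
  class[is_anc] <- "ancestral"
  class[is_L23] <- "L23"
  class[is_L1] <- "L1"
  class[is_L1 & is_L23] <- "conflicted"
  tibble::tibble(site_id = dp$site_id, class = class)
}

#' Classify layer-specific mutations from regenerant panels
#'
#' A mutation is layer-specific to L1 iff (a) it is not detected in any
#' ancestor clone that has `min_depth` coverage, (b) at least
#' `min_regenerants` L1-panel samples show confident presence (depth >=
#' `min_depth`, VAF >= `min_vaf`), and (c) every L23-panel sample has
#' `min_depth` coverage with at most `absence_max_alt` supporting reads
#' (a panel sample without coverage makes the absence clause unsatisfiable,
#' so the site stays unassigned). Symmetric for L23.
#'
#' @param observations long observation tibble.
#' @param panels list `list(L1 = <sample ids>, L23 = <sample ids>)`.
#' @param ancestors character vector of ancestor sample ids.
#' @param params a [classify_params()].
#' @return tibble `site_id`, `class` in `{L1, L23, conflicted, unassigned}`.
#' @export
classify_regenerant_mutations <- function(observations, panels, ancestors,
                                          params = classify_params()) {
  stopifnot(length(panels$L1) >= 1, length(panels$L23) >= 1)
  p <- params
  all_samp <- c(panels$L1, panels$L23, ancestors)
  dp <- obs_wide(observations, all_samp, "depth")
  ad <- obs_wide(observations, all_samp, "alt_reads")

  n_pass <- function(samps) {
    Reduce(`+`, lapply(samps, function(s) ev_pass(dp[[s]], ad[[s]], p)))
  }
  all_absent <- function(samps) {
    Reduce(`&`, lapply(samps, function(s) ev_absent(dp[[s]], ad[[s]], p)))
  }
  anc_clean <- if (length(ancestors) == 0) rep(TRUE, nrow(dp)) else {
    Reduce(`&`, lapply(ancestors, function(s) {
      covered <- dp[[s]] >= p$min_depth
      !covered | ad[[s]] <= p$absence_max_alt
    }))
  }

  is_L1 <- anc_clean & n_pass(panels$L1) >= p$min_regenerants & all_absent(panels$L23)
  is_L23 <- anc_clean & n_pass(panels$L23) >= p$min_regenerants & all_absent(panels$L1)
  class <- rep("unassigned", nrow(dp))
  class[is_L23] <- "L23"
  class[is_L1] <- "L1"
  class[is_L1 & is_L23] <- "conflicted"
  tibble::tibble(site_id = dp$site_id, class = class)
}

#' Call regenerant-private mutations
#'
#' A mutation is private to a regenerant iff exactly one regenerant shows
#' confident presence (depth >= `min_depth`, VAF >= `min_vaf`) and every
#' other regenerant with `min_depth` coverage shows at most
#' `absence_max_alt` supporting reads.
#'
#' @param observations long observation tibble.
#' @param regenerants character vector of all regenerant sample ids.
#' @param params a [classify_params()].
#' @return tibble `site_id`, `class` (`private:<sample>` or `unassigned`).
#' @export
call_private_mutations <- function(observations, regenerants,
                                   params = classify_params()) {
  p <- params
  dp <- obs_wide(observations, regenerants, "depth")
  ad <- obs_wide(observations, regenerants, "alt_reads")
  pass <- vapply(regenerants, function(s) ev_pass(dp[[s]], ad[[s]], p),
                 logical(nrow(dp)))
  pass <- matrix(pass, nrow = nrow(dp), dimnames = list(NULL, regenerants))
  clean <- vapply(regenerants, function(s) {
    covered <- dp[[s]] >= p$min_depth
    !covered | ad[[s]] <= p$absence_max_alt
  }, logical(nrow(dp)))
  clean <- matrix(clean, nrow = nrow(dp), dimnames = list(NULL, regenerants))
  n_pass <- rowSums(pass)
  others_clean <- vapply(seq_len(nrow(dp)), function(i) {
    if (n_pass[i] != 1) return(FALSE)
    all(clean[i, !pass[i, ], drop = FALSE])
  }, logical(1))
  class <- rep("unassigned", nrow(dp))
  hit <- n_pass == 1 & others_clean
  class[hit] <- paste0("private:",
                       regenerants[apply(pass[hit, , drop = FALSE], 1, which)])
  tibble::tibble(site_id = dp$site_id, class = class)
}

#' Flag cross-species contaminant sites
#'
#' A site is a contaminant iff the foreign-taxon reads summed over all
#' samples reach `contaminant_min_reads` (default 4). Foreign-taxon read
#' counts stand in for cross-species alignment screening of the reads
#' overlapping each candidate site.
#'
#' @param observations long observation tibble with `foreign_reads`.
#' @param params a [classify_params()].
#' @return tibble `site_id`, `foreign_reads` (total), `contaminant`
#'   (logical).
#' @export
contaminant_filter <- function(observations, params = classify_params()) {
  agg <- stats::aggregate(foreign_reads ~ site_id, observations, sum)
  tibble::tibble(site_id = agg$site_id, foreign_reads = agg$foreign_reads,
                 contaminant = agg$foreign_reads >= params$contaminant_min_reads)
}

#' Full site classification for a dataset
#'
#' Applies, in order: the contaminant filter, the mean mapping-quality
#' filter, and then either the tissue-triplet or the regenerant-panel rule
#' set. Sites removed by a filter receive the terminal classes
#' `contaminant` / `filtered_mq` and are excluded from rule evaluation.
#'
#' @param observations long observation tibble.
#' @param mode `"tissue"` or `"regenerant"`.
#' @param roles tissue roles (for `mode = "tissue"`).
#' @param panels,ancestors panel spec (for `mode = "regenerant"`).
#' @param params a [classify_params()].
#' @param mq_threshold mean-MQ removal threshold.
#' @param mq_samples samples over which site MQ is averaged (default all).
#' @return tibble `site_id`, `class`.
#' @export
classify_sites <- function(observations, mode = c("tissue", "regenerant"),
                           roles = c(trichome = "trichome", leaf = "leaf",
                                     root = "root"),
                           panels = NULL, ancestors = character(0),
                           params = classify_params(), mq_threshold = 40,
                           mq_samples = NULL) {
  mode <- match.arg(mode)
  cont <- contaminant_filter(observations, params)
  mq <- filter_mean_mq(observations, samples = mq_samples, threshold = mq_threshold)
  drop <- tibble::tibble(
    site_id = cont$site_id,
    class = dplyr::case_when(
      cont$contaminant ~ "contaminant",
      mq$filtered_mq[match(cont$site_id, mq$site_id)] ~ "filtered_mq",
      TRUE ~ NA_character_
    )
  )
  keep_ids <- drop$site_id[is.na(drop$class)]
  obs_keep <- observations[observations$site_id %in% keep_ids, ]
  res <- if (mode == "tissue") {
    classify_tissue_mutations(obs_keep, roles, params)
  } else {
    classify_regenerant_mutations(obs_keep, panels, ancestors, params)
  }
  out <- rbind(res, drop[!is.na(drop$class), ])
  out[match(sort(unique(observations$site_id)), out$site_id), ]
}
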