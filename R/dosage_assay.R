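#' Aggregate read support over a layer-specific marker set
#'
#' Sums alt reads and total depth over all informative marker loci (those
#' with at least `min_depth` coverage in the sample) and returns the pooled
#' fraction of reads supporting the layer-specific alleles. Pooling read
#' counts (rather than averaging per-locus VAFs) weights each locus by its
#' depth.
#'
#' @param observations observation tibble for one sample (`site_id`,
#'   `depth`, `alt_reads`).
#' @param marker_sites site ids of the marker loci.
#' @param min_depth minimum depth for a locus to be informative.
#' @return list with `fraction`, `n_informative`, `n_below_depth`.
#' @export
aggregate_marker_fraction <- function(observations, marker_sites, min_depth = 8) {
  obs <- observations[observations$site_id %in% marker_sites, ]
  inf <- obs$depth >= min_depth
  if (!any(inf)) stop("assay uninformative: no marker locus at sufficient depth",
                      call. = FALSE)
  list(fraction = sum(obs$alt_reads[inf]) / sum(obs$depth[inf]),
       n_informative = sum(inf), n_below_depth = sum(!inf))
}

#' Layer-of-origin verdict from marker fractions
#'
#' Given the aggregated alt-read fractions over the L1-specific and
#' L2,3-specific marker sets, calls the sample's origin: a pure
#' single-layer regenerant shows one fraction near the simplex expectation
#' (1/ploidy) and the other near zero; a chimeric sample shows both above
#' background.
#'
#' @param f_L1,f_L23 aggregated marker fractions.
#' @param pure_min minimum fraction supporting a pure-layer call.
#' @param absent_max maximum fraction compatible with marker absence.
#' @return `"L1"`, `"L23"`, `"chimeric"` or `"ambiguous"`.
#' @export
classify_origin <- function(f_L1, f_L23, pure_min = 0.15, absent_max = 0.02) {
  stopifnot(f_L1 >= 0, f_L1 <= 1, f_L23 >= 0, f_L23 <= 1)
  if (f_L1 >= pure_min && f_L23 <= absent_max) return("L1")
  if (f_L23 >= pure_min && f_L1 <= absent_max) return("L23")
  if (f_L1 > absent_max && f_L23 > absent_max) return("chimeric")
  "ambiguous"
}

#' Haplotype copy number from marker VAFs
#'
#' Estimates the dosage of a marker haplotype in a polyploid sample as
#' `round(ploidy * mean(VAF))`, clamped to `[0, ploidy]`. A warning field
#' flags samples whose mean VAF exceeds `absent_max` while rounding to 0
#' copies — the chimeric-presence signature of a haplotype carried by only
#' part of the sampled cells.
#'
#' @param vafs per-marker VAF observations (>= 10 required).
#' @param ploidy sample ploidy.
#' @param absent_max background VAF below which the haplotype is absent.
#' @return list with `copies`, `mean_vaf`, `sd_vaf`, `n_markers`,
#'   `chimeric_presence` (logical).
#' @export
haplotype_dosage <- function(vafs, ploidy = 4, absent_max = 0.02) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) < 10) stop("insufficient markers: need >= 10 VAF observations",
                              call. = FALSE)
  m <- mean(vafs)
  copies <- max(0, min(ploidy, round(ploidy * m)))
  list(copies = copies, mean_vaf = m, sd_vaf = stats::sd(vafs),
       n_markers = length(vafs),
       chimeric_presence = copies == 0 && m > absent_max)
}

#' Run the marker dosage assay for a set of samples
#'
#' Convenience wrapper: aggregates both marker sets in each sample and
#' returns the origin verdict for each.
#'
#' @param observations long observation tibble over samples.
#' @param markers list `list(L1 = <site ids>, L23 = <site ids>)` (disjoint).
#' @param samples sample ids to assay (default: all in `observations`).
#' @param min_depth minimum informative depth per locus.
#' @param pure_min,absent_max verdict thresholds (see [classify_origin()]).
#' @return tibble: `sample_id`, `f_L1`, `f_L23`, `n_L1`, `n_L23`,
#'   `verdict`.
#' @export
dosage_assay <- function(observations, markers, samples = NULL, min_depth = 8,
                         pure_min = 0.15, absent_max = 0.02) {
  if (length(intersect(markers$L1, markers$L23)) > 0) {
    stop("marker sets must be disjoint", call. = FALSE)
  }
  if (is.null(samples)) samples <- unique(observations$sample_id)
  rows <- lapply(samples, function(s) {
    obs <- observations[observations$sample_id == s, ]
    a1 <- aggregate_marker_fraction(obs, markers$L1, min_depth)
    a2 <- aggregate_marker_fraction(obs, markers$L23, min_depth)
    tibble::tibble(sample_id = s, f_L1 = a1$fraction, f_L23 = a2$fraction,
                   n_L1 = a1$n_informative, n_L23 = a2$n_informative,
                   verdict = classify_origin(a1$fraction, a2$fraction,
                                             pure_min, absent_max))
  })
  dplyr::bind_rows(rows)
}
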