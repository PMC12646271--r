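#' Write a simulated dataset to standard text formats
#'
#' Emits the ground truth as TSV, observations as a minimal multi-sample VCF
#' (FORMAT `DP` and `AD`; site mean mapping quality in INFO `MMQ`, total
#' foreign-taxon reads in INFO `FTR`) and the genic annotation as a BED file
#' (0-based half-open).
#'
#' @param sim a `layer_sim` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named paths written.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    truth = file.path(dir, "ground_truth.tsv"),
    vcf = file.path(dir, "observations.vcf"),
    bed = file.path(dir, "genic.bed")
  )
  truth <- sim$truth[, c("chrom", "pos", "ref", "alt", "compartment", "space")]
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_observations_vcf(sim$truth, sim$observations, paths[["vcf"]])
  write_genic_bed(sim$genome, paths[["bed"]])
  invisible(paths)
}

#' Write genic intervals as BED (0-based half-open)
#'
#' @param genome a `sim_genome`.
#' @param path output path.
#' @export
write_genic_bed <- function(genome, path) {
  bed <- data.frame(chrom = genome$chrom,
                    start = format(genome$genic$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(genome$genic$end, scientific = FALSE, trim = TRUE))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of genic intervals
#'
#' @param path BED path (0-based half-open).
#' @return tibble of 1-based closed intervals (`chrom`, `start`, `end`).
#' @export
read_genic_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", col.names = c("chrom", "start", "end"),
                           colClasses = c("character", "numeric", "numeric"))
  tibble::tibble(chrom = bed$chrom, start = bed$start + 1, end = bed$end)
}

#' Write per-site observations as a minimal multi-sample VCF
#'
#' One record per site; per-sample FORMAT fields `DP` (total depth) and `AD`
#' (ref,alt read counts, ref = DP - alt). Site mean mapping quality and total
#' foreign-taxon reads go to INFO (`MMQ`, `FTR`).
#'
#' @param sites tibble with `site_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param observations long tibble (`site_id`, `sample_id`, `depth`,
#'   `alt_reads`, `mean_mq`, `foreign_reads`).
#' @param path output path.
#' @export
write_observations_vcf <- function(sites, observations, path) {
  samples <- unique(observations$sample_id)
  wide_dp <- tidyr::pivot_wider(observations[, c("site_id", "sample_id", "depth")],
                                names_from = "sample_id", values_from = "depth")
  wide_ad <- tidyr::pivot_wider(observations[, c("site_id", "sample_id", "alt_reads")],
                                names_from = "sample_id", values_from = "alt_reads")
  ord <- match(sites$site_id, wide_dp$site_id)
  mmq <- observations[!duplicated(observations$site_id), c("site_id", "mean_mq")]
  ftr <- stats::aggregate(foreign_reads ~ site_id, observations, sum)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MMQ,Number=1,Type=Float,Description=\"Site mean mapping quality\">",
    "##INFO=<ID=FTR,Number=1,Type=Integer,Description=\"Foreign-taxon reads across samples\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            samples), collapse = "\t")
  )
  gt <- vapply(seq_len(nrow(sites)), function(i) {
    row <- ord[i]
    dp <- unlist(wide_dp[row, samples])
    ad <- unlist(wide_ad[row, samples])
    dp[is.na(dp)] <- 0L
    ad[is.na(ad)] <- 0L
    paste(sprintf("%d:%d,%d", dp, dp - ad, ad), collapse = "\t")
  }, character(1))
  info <- sprintf("MMQ=%.2f;FTR=%d",
                  mmq$mean_mq[match(sites$site_id, mmq$site_id)],
                  ftr$foreign_reads[match(sites$site_id, ftr$site_id)])
  body <- sprintf("%s\t%.0f\t%s\t%s\t%s\t.\tPASS\t%s\tDP:AD\t%s",
                  sites$chrom, sites$pos, sites$site_id, sites$ref, sites$alt,
                  info, gt)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a variant table with per-sample depths and alt counts
#'
#' Supports two dialects: a minimal multi-sample VCF with FORMAT fields
#' `DP`/`AD` (parsed with \pkg{vcfR}), or a long TSV with columns `site_id`,
#' `sample_id`, `depth`, `alt_reads` (and optionally `mean_mq`,
#' `foreign_reads`). Missing genotype observations become depth 0. Positions
#' are 1-based.
#'
#' @param path input file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @return list with `sites` (tibble: `site_id`, `chrom`, `pos`, `ref`,
#'   `alt`, and for VCF input `mean_mq`, `foreign_reads`) and `observations`
#'   (long tibble as written by the simulator).
#' @export
read_variant_table <- function(path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    obs <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                               stringsAsFactors = FALSE))
    need <- c("site_id", "sample_id", "depth", "alt_reads")
    if (!all(need %in% names(obs))) {
      stop("malformed TSV: requires columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    return(list(sites = NULL, observations = obs))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE))
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  alt_reads <- apply(ad, 2, function(x) {
    as.integer(vapply(strsplit(x, ","), function(p) {
      if (length(p) < 2 || anyNA(p)) "0" else p[2]
    }, character(1)))
  })
  dp[is.na(dp)] <- 0
  info <- vcfR::getINFO(vcf)
  mmq <- suppressWarnings(as.numeric(sub(".*MMQ=([0-9.eE+-]+).*", "\\1", info)))
  ftr <- suppressWarnings(as.integer(sub(".*FTR=([0-9]+).*", "\\1", info)))
  ftr[is.na(ftr)] <- 0L
  sites <- tibble::tibble(
    site_id = fix$ID, chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT, mean_mq = mmq, foreign_reads = ftr
  )
  samples <- colnames(dp)
  observations <- tibble::tibble(
    site_id = rep(sites$site_id, times = length(samples)),
    sample_id = rep(samples, each = nrow(sites)),
    depth = as.integer(dp),
    alt_reads = as.integer(alt_reads),
    mean_mq = rep(mmq, times = length(samples)),
    foreign_reads = rep(ftr, times = length(samples))
  )
  list(sites = sites, observations = observations)
}

#' Callable-site rule constructors
#'
#' A callable-site rule states which samples must pass the per-position
#' depth/quality criteria for the position to count as assayed. `all_of`
#' clauses require every listed sample to pass; `k_of` clauses require at
#' least `k` passing samples within each listed group (e.g. at least four
#' regenerants from each layer).
#'
#' @param all_of character vector of sample names that must all pass.
#' @param k_of optional list of `list(samples = <chr>, k = <int>)` group
#'   clauses.
#' @return a `callable_rule` object.
#' @export
callable_rule <- function(all_of = character(0), k_of = list()) {
  stopifnot(is.character(all_of))
  for (cl in k_of) stopifnot(is.character(cl$samples), cl$k >= 1)
  structure(list(all_of = all_of, k_of = k_of), class = "callable_rule")
}

#' Tally callable positions per genomic space
#'
#' A position is callable iff every clause of the rule passes there, where a
#' sample passes iff its depth of reads meeting the mapping- and
#' base-quality minima is at least `min_depth`. Depth tracks are per-sample
#' integer vectors of quality-passing read counts over the whole (synthetic)
#' genome, so the base/mapping-quality minima are honoured upstream in how
#' the tracks are counted.
#'
#' @param depth named list of integer vectors, one per sample, all the same
#'   length (positions 1..L).
#' @param rule a [callable_rule()].
#' @param annotation tibble of 1-based closed genic intervals (`start`,
#'   `end`), or a `sim_genome`. Positions outside any interval are
#'   intergenic.
#' @param min_depth minimum passing-read depth (default 8).
#' @return a tibble with one row per space: `space`, `callable_bp`.
#' @export
tally_callable_sites <- function(depth, rule, annotation, min_depth = 8) {
  stopifnot(min_depth >= 1, length(depth) >= 1)
  L <- length(depth[[1]])
  stopifnot(all(vapply(depth, length, 1L) == L))
  missing <- setdiff(c(rule$all_of, unlist(lapply(rule$k_of, `[[`, "samples"))),
                     names(depth))
  if (length(missing)) {
    stop("unknown sample in rule: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  ok <- rep(TRUE, L)
  for (s in rule$all_of) ok <- ok & depth[[s]] >= min_depth
  for (cl in rule$k_of) {
    passing <- Reduce(`+`, lapply(depth[cl$samples], function(d) d >= min_depth))
    ok <- ok & passing >= cl$k
  }
  if (inherits(annotation, "sim_genome")) annotation <- annotation$genic
  genic <- rep(FALSE, L)
  for (i in seq_len(nrow(annotation))) {
    genic[annotation$start[i]:annotation$end[i]] <- TRUE
  }
  tibble::tibble(
    space = c("genic", "intergenic"),
    callable_bp = c(sum(ok & genic), sum(ok & !genic))
  )
}

#' Flag sites failing the mean mapping-quality filter
#'
#' A site fails iff the mean of the per-sample site mean mapping qualities,
#' taken over the considered samples, is less than or equal to the
#' threshold (the boundary value itself is removed). Failing sites are
#' excluded from all downstream classification.
#'
#' @param observations long observation tibble (needs `site_id`,
#'   `sample_id`, `mean_mq`).
#' @param samples samples over which to average (default: all present).
#' @param threshold inclusive removal threshold (default 40).
#' @return tibble `site_id`, `mean_mq` (across-sample mean), `filtered_mq`
#'   (logical).
#' @export
filter_mean_mq <- function(observations, samples = NULL, threshold = 40) {
  obs <- observations
  if (!is.null(samples)) obs <- obs[obs$sample_id %in% samples, ]
  agg <- stats::aggregate(mean_mq ~ site_id, obs, mean)
  tibble::tibble(site_id = agg$site_id, mean_mq = agg$mean_mq,
                 filtered_mq = agg$mean_mq <= threshold)
}

#' Per-sample variant allele frequency
#'
#' `alt_reads / depth`, defined only at positive depth (NA otherwise).
#'
#' @param alt_reads,depth integer vectors.
#' @return numeric VAF vector.
#' @export
vaf <- function(alt_reads, depth) {
  ifelse(depth > 0, alt_reads / depth, NA_real_)
}
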