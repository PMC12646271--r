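#' Tissue-triplet analysis of a dataset
#'
#' Runs the full tissue pipeline on a simulated (or equivalently shaped)
#' dataset: contaminant and mapping-quality filters, tissue-triplet layer
#' classification, per-class counts and per-tissue VAF summaries, a
#' layer-by-space rate table, per-layer base-change spectra, and the two
#' chi-squared tests (equal-representation goodness of fit on the L1/L2,3
#' totals; layer x space independence). Deterministic given the input.
#'
#' @param sim a `layer_sim` from [simulate_dataset()].
#' @param params a [classify_params()].
#' @return list with `classes`, `class_counts`, `vaf_summary`,
#'   `rate_table`, `spectra`, `tests`, `seed`.
#' @export
run_tissue_analysis <- function(sim, params = classify_params()) {
  need <- c("trichome", "leaf", "root")
  if (!all(need %in% sim$samples$sample_id)) {
    stop("missing sample role: ", paste(setdiff(need, sim$samples$sample_id),
                                        collapse = ", "), call. = FALSE)
  }
  tissue_obs <- sim$observations[sim$observations$sample_id %in% need, ]
  fixed_ids <- sim$truth$site_id[sim$truth$compartment != "regenerant_private"]
  tissue_obs <- tissue_obs[tissue_obs$site_id %in% fixed_ids, ]

  classes <- classify_sites(tissue_obs, mode = "tissue", params = params)
  class_counts <- dplyr::count(classes, .data$class, name = "n")

  merged <- dplyr::left_join(tissue_obs, classes, by = "site_id")
  merged$vaf <- vaf(merged$alt_reads, merged$depth)
  vaf_summary <- dplyr::summarise(
    dplyr::group_by(merged, .data$class, .data$sample_id),
    mean_vaf = mean(.data$vaf, na.rm = TRUE), n = dplyr::n(), .groups = "drop"
  )

  truth_idx <- match(classes$site_id, sim$truth$site_id)
  space <- sim$truth$space[truth_idx]
  keep <- classes$class %in% c("L1", "L23")
  counts <- dplyr::count(
    tibble::tibble(clone = "sim", compartment = classes$class[keep],
                   space = space[keep]),
    .data$clone, .data$compartment, .data$space, name = "count"
  )
  counts <- tidyr::complete(counts,
                            clone = "sim",
                            compartment = c("L1", "L23"),
                            space = c("genic", "intergenic"),
                            fill = list(count = 0L))
  callable <- tibble::tibble(
    clone = "sim", space = c("genic", "intergenic"),
    bp = c(sim$genome$genic_bp, sim$genome$length - sim$genome$genic_bp)
  )
  years <- tibble::tibble(clone = "sim", years = sim$config$years)
  rate_table <- build_rate_table(counts, callable, years)

  spectra <- lapply(c("L1", "L23"), function(cl) {
    ids <- classes$site_id[classes$class == cl]
    tr <- sim$truth[match(ids, sim$truth$site_id), ]
    spectrum_counts(tr$ref, tr$alt, context = ref_context(sim$genome, tr$pos),
                    group_label = cl)
  })
  names(spectra) <- c("L1", "L23")

  n1 <- sum(classes$class == "L1"); n2 <- sum(classes$class == "L23")
  sq <- stats::xtabs(count ~ compartment + space, counts)
  tests <- list(
    layer_equal_representation = if (n1 + n2 > 0)
      chi2_goodness_of_fit(c(n1, n2)) else NULL,
    layer_by_space = if (all(rowSums(sq) > 0) && all(colSums(sq) > 0))
      chi2_independence(sq) else NULL
  )

  list(classes = classes, class_counts = class_counts,
       vaf_summary = vaf_summary, rate_table = rate_table,
       spectra = spectra, tests = tests, seed = sim$config$seed)
}

#' Regenerant-panel analysis of a dataset
#'
#' Runs the regenerant pipeline: layer-specific classification against the
#' two single-layer panels and the ancestor clone, private-mutation calling
#' across all regenerants, per-regenerant private counts, the fixed-vs-
#' private spectrum contrast, a rate table with regenerant rows, and
#' marker-dosage origin verdicts for every regenerant (markers = the
#' layer-specific calls themselves).
#'
#' @param sim a `layer_sim`.
#' @param params a [classify_params()].
#' @return list with `layer_classes`, `private_calls`, `private_counts`,
#'   `spectra`, `spectrum_test`, `rate_table`, `dosage`, `seed`.
#' @export
run_regenerant_analysis <- function(sim, params = classify_params()) {
  regen <- sim$samples[sim$samples$role == "regenerant", ]
  panels <- list(L1 = regen$sample_id[regen$layer == "L1"],
                 L23 = regen$sample_id[regen$layer == "L23"])
  ancestors <- sim$samples$sample_id[sim$samples$role == "ancestor"]
  if (length(panels$L1) == 0 || length(panels$L23) == 0) {
    stop("both regenerant panels must be present", call. = FALSE)
  }
  small <- lengths(panels) < params$min_regenerants
  if (any(small)) {
    warning("panel smaller than min_regenerants: ",
            paste(names(panels)[small], collapse = ", "),
            "; all sites will be unassigned", call. = FALSE)
  }
  panel_obs <- sim$observations[
    sim$observations$sample_id %in% c(regen$sample_id, ancestors), ]

  layer_classes <- classify_sites(panel_obs, mode = "regenerant",
                                  panels = panels, ancestors = ancestors,
                                  params = params)
  regen_obs <- panel_obs[panel_obs$sample_id %in% regen$sample_id, ]
  unassigned_ids <- layer_classes$site_id[layer_classes$class == "unassigned"]
  private_calls <- call_private_mutations(
    regen_obs[regen_obs$site_id %in% unassigned_ids, ], regen$sample_id, params)
  private_calls <- private_calls[private_calls$class != "unassigned", ]
  private_counts <- dplyr::count(
    tibble::tibble(sample_id = sub("^private:", "", private_calls$class)),
    .data$sample_id, name = "n_private")

  fixed_ids <- layer_classes$site_id[layer_classes$class %in% c("L1", "L23")]
  sp_of <- function(ids, label) {
    tr <- sim$truth[match(ids, sim$truth$site_id), ]
    spectrum_counts(tr$ref, tr$alt, context = ref_context(sim$genome, tr$pos),
                    group_label = label)
  }
  spectra <- list(fixed = sp_of(fixed_ids, "fixed"),
                  private = sp_of(private_calls$site_id, "private"))
  spectrum_test <- if (spectra$fixed$n_snv > 0 && spectra$private$n_snv > 0) {
    compare_spectra(spectra, mode = "six_class")
  } else NULL

  truth_idx <- match(layer_classes$site_id, sim$truth$site_id)
  space <- sim$truth$space[truth_idx]
  keep <- layer_classes$class %in% c("L1", "L23")
  counts <- dplyr::count(
    tibble::tibble(clone = "sim", compartment = layer_classes$class[keep],
                   space = space[keep]),
    .data$clone, .data$compartment, .data$space, name = "count")
  priv_space <- sim$truth$space[match(private_calls$site_id, sim$truth$site_id)]
  priv_counts <- dplyr::count(
    tibble::tibble(clone = "sim",
                   compartment = paste0("regenerant_",
                                        sub("^private:", "", private_calls$class)),
                   space = priv_space),
    .data$clone, .data$compartment, .data$space, name = "count")
  counts <- dplyr::bind_rows(counts, priv_counts)
  callable <- tibble::tibble(
    clone = "sim", space = c("genic", "intergenic"),
    bp = c(sim$genome$genic_bp, sim$genome$length - sim$genome$genic_bp))
  years <- tibble::tibble(clone = "sim", years = sim$config$years)
  rate_table <- build_rate_table(counts, callable, years)

  markers <- list(L1 = layer_classes$site_id[layer_classes$class == "L1"],
                  L23 = layer_classes$site_id[layer_classes$class == "L23"])
  dosage <- if (length(markers$L1) && length(markers$L23)) {
    dosage_assay(regen_obs, markers, samples = regen$sample_id)
  } else NULL

  list(layer_classes = layer_classes, private_calls = private_calls,
       private_counts = private_counts, spectra = spectra,
       spectrum_test = spectrum_test, rate_table = rate_table,
       dosage = dosage, seed = sim$config$seed)
}
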