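#' Callable-site-normalized mutation rate
#'
#' `count / (bp * years)`, in mutations per base pair per year.
#'
#' @param count mutation count (>= 0).
#' @param bp callable positions (> 0).
#' @param years divergence time in years (> 0).
#' @return numeric rate(s); vectorized.
#' @export
mutation_rate <- function(count, bp, years) {
  if (any(bp <= 0) || any(years <= 0)) {
    stop("bp and years must be positive", call. = FALSE)
  }
  if (any(count < 0)) stop("count must be nonnegative", call. = FALSE)
  count / (bp * years)
}

#' Build a mutation-rate table with layer and space ratios
#'
#' Takes per-(clone, compartment, space) mutation counts, the callable
#' space sizes, and per-clone divergence times, and returns one row per
#' input count with its normalized rate plus three ratio families:
#' `L1_L23_ratio` (L1 rate over L2,3 rate, per clone and space),
#' `regen_L23_ratio` (a regenerant's rate over the matching clone's L2,3
#' rate in the same space; regenerant rows use `regenerant_years`), and
#' `intergenic_genic_ratio` (per clone and compartment). Ratios whose
#' denominator count is zero are `NA`.
#'
#' @param counts tibble with columns `clone`, `compartment` (`L1`, `L23`,
#'   or a regenerant label), `space` (`genic`/`intergenic`), `count`.
#' @param callable tibble with `clone`, `space`, `bp`.
#' @param years tibble with `clone`, `years`; regenerant compartments use
#'   `regenerant_years` instead.
#' @param regenerant_years years assigned to one regeneration episode
#'   (default 1 generation-equivalent).
#' @param regenerant_ref clone whose L2,3 rate anchors `regen_L23_ratio`
#'   for regenerant compartments of that clone.
#' @return tibble: the `counts` rows plus `bp`, `years`, `rate`,
#'   `L1_L23_ratio`, `regen_L23_ratio`, `intergenic_genic_ratio`.
#' @export
build_rate_table <- function(counts, callable, years, regenerant_years = 1,
                             regenerant_ref = NULL) {
  stopifnot(all(c("clone", "compartment", "space", "count") %in% names(counts)))
  tab <- dplyr::left_join(counts, callable, by = c("clone", "space"))
  tab <- dplyr::left_join(tab, years, by = "clone")
  is_regen <- !(tab$compartment %in% c("L1", "L23"))
  tab$years[is_regen] <- regenerant_years
  if (any(is.na(tab$bp)) || any(is.na(tab$years))) {
    stop("callable bp or years missing for some rows", call. = FALSE)
  }
  tab$rate <- mutation_rate(tab$count, tab$bp, tab$years)

  rate_of <- function(clone, compartment, space) {
    i <- tab$clone == clone & tab$compartment == compartment & tab$space == space
    if (!any(i) || tab$count[which(i)[1]] == 0) return(NA_real_)
    tab$rate[which(i)[1]]
  }
  tab$L1_L23_ratio <- NA_real_
  l1 <- tab$compartment == "L1"
  tab$L1_L23_ratio[l1] <- tab$rate[l1] /
    mapply(rate_of, tab$clone[l1], "L23", tab$space[l1])
  tab$regen_L23_ratio <- NA_real_
  if (any(is_regen)) {
    ref_clone <- if (is.null(regenerant_ref)) tab$clone[is_regen] else regenerant_ref
    tab$regen_L23_ratio[is_regen] <- tab$rate[is_regen] /
      mapply(rate_of, ref_clone, "L23", tab$space[is_regen])
  }
  tab$intergenic_genic_ratio <- NA_real_
  ig <- tab$space == "intergenic"
  tab$intergenic_genic_ratio[ig] <- tab$rate[ig] / mapply(function(cl, cp) {
    i <- tab$clone == cl & tab$compartment == cp & tab$space == "genic"
    if (!any(i) || tab$count[which(i)[1]] == 0) return(NA_real_)
    tab$rate[which(i)[1]]
  }, tab$clone[ig], tab$compartment[ig])
  tibble::as_tibble(tab)
}

#' Intergenic-to-genic rate ratio
#'
#' @param rate_intergenic,rate_genic rates on the same clone/compartment.
#' @return the quotient; `NA` when the genic rate is 0.
#' @export
space_bias_ratio <- function(rate_intergenic, rate_genic) {
  ifelse(rate_genic > 0, rate_intergenic / rate_genic, NA_real_)
}

#' Chi-squared goodness-of-fit test
#'
#' Pearson goodness-of-fit of observed counts against expected proportions
#' (equal representation by default), without continuity correction.
#'
#' @param counts nonnegative integer vector of observed counts.
#' @param expected vector of expected proportions (> 0, normalized
#'   internally); defaults to equal.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi2_goodness_of_fit <- function(counts, expected = NULL) {
  if (sum(counts) == 0) stop("total count is zero", call. = FALSE)
  if (is.null(expected)) expected <- rep(1 / length(counts), length(counts))
  if (any(expected <= 0)) stop("expected proportions must be positive", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, p = expected / sum(expected)))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Chi-squared test of independence
#'
#' Pearson statistic on an r x c contingency table, no continuity
#' correction (the correction is available via `correct = TRUE`).
#'
#' @param table matrix of counts with positive row and column sums.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi2_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Published layer-specific mutation counts for two potato clones
#'
#' The published per-space mutation counts, callable space sizes and
#' divergence times for tetraploid potato clones Desiree (34 y of
#' propagation) and Red Polenta (60 y), plus three Red Polenta protoplast
#' regenerants (one regeneration episode each). These are the inputs from
#' which the published rate and ratio tables are reproduced; the raw
#' sequencing data behind them are not needed.
#'
#' @return list of three tibbles: `counts` (`clone`, `compartment`,
#'   `space`, `count`), `callable` (`clone`, `space`, `bp`), `years`
#'   (`clone`, `years`).
#' @export
potato_clone_mutation_counts <- function() {
  counts <- tibble::tribble(
    ~clone, ~compartment, ~space, ~count,
    "Desiree", "L1", "genic", 158,
    "Desiree", "L23", "genic", 19,
    "Desiree", "L1", "intergenic", 1619,
    "Desiree", "L23", "intergenic", 364,
    "RedPolenta", "L1", "genic", 98,
    "RedPolenta", "L23", "genic", 67,
    "RedPolenta", "L1", "intergenic", 1097,
    "RedPolenta", "L23", "intergenic", 683,
    "RedPolenta", "regenerant_105", "genic", 64,
    "RedPolenta", "regenerant_105", "intergenic", 920,
    "RedPolenta", "regenerant_83", "genic", 70,
    "RedPolenta", "regenerant_83", "intergenic", 674,
    "RedPolenta", "regenerant_63", "genic", 3,
    "RedPolenta", "regenerant_63", "intergenic", 33
  )
  callable <- tibble::tribble(
    ~clone, ~space, ~bp,
    "Desiree", "genic", 133000000,
    "Desiree", "intergenic", 547467000,
    "RedPolenta", "genic", 144046000,
    "RedPolenta", "intergenic", 657050000
  )
  years <- tibble::tibble(clone = c("Desiree", "RedPolenta"), years = c(34, 60))
  list(counts = counts, callable = callable, years = years)
}
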