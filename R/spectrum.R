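COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

check_snv <- function(ref, alt) {
  ok <- ref %in% names(COMPLEMENT) & alt %in% names(COMPLEMENT) & ref != alt
  if (!all(ok)) stop("ref/alt must be distinct single bases in A/C/G/T", call. = FALSE)
}

#' Pyrimidine-centred base-change class of an SNV
#'
#' Maps an SNV to one of the six classes C>A, C>G, C>T, T>A, T>C, T>G;
#' purine-reference changes are reverse-complemented (G>T becomes C>A,
#' A>G becomes T>C, ...). Vectorized.
#'
#' @param ref,alt single reference/alternate bases.
#' @return character vector of 6-class labels.
#' @export
base_change_class <- function(ref, alt) {
  check_snv(ref, alt)
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, COMPLEMENT[ref], ref)
  a <- ifelse(pur, COMPLEMENT[alt], alt)
  paste0(r, ">", a)
}

#' Transition / transversion class of an SNV
#'
#' Transitions are A<->G and C<->T; everything else is a transversion.
#'
#' @inheritParams base_change_class
#' @return character vector, `"transition"` or `"transversion"`.
#' @export
titv_class <- function(ref, alt) {
  check_snv(ref, alt)
  purine <- c("A", "G")
  ti <- (ref %in% purine) == (alt %in% purine)
  ifelse(ti, "transition", "transversion")
}

#' 96-category trinucleotide substitution class
#'
#' Maps an SNV with its 3-base reference context (5' base, mutated base,
#' 3' base) to the pyrimidine-centred `5'[ref>alt]3'` category; when the
#' reference base is a purine, the whole context and the change are
#' reverse-complemented. Sites without full context (contig edges, `NA`)
#' return `NA`.
#'
#' @param context 3-character reference context strings, centre base =
#'   ref.
#' @param alt alternate base.
#' @return character vector of categories like `"A[C>A]A"` (96 possible).
#' @export
trinucleotide_class <- function(context, alt) {
  out <- rep(NA_character_, length(context))
  ok <- !is.na(context) & nchar(context) == 3
  if (!any(ok)) return(out)
  ctx <- context[ok]
  a <- alt[ok]
  five <- substr(ctx, 1, 1)
  ref <- substr(ctx, 2, 2)
  three <- substr(ctx, 3, 3)
  check_snv(ref, a)
  pur <- ref %in% c("A", "G")
  f <- ifelse(pur, COMPLEMENT[three], five)
  r <- ifelse(pur, COMPLEMENT[ref], ref)
  t3 <- ifelse(pur, COMPLEMENT[five], three)
  aa <- ifelse(pur, COMPLEMENT[a], a)
  out[ok] <- sprintf("%s[%s>%s]%s", f, r, aa, t3)
  out
}

#' Tabulate a mutation spectrum
#'
#' Counts SNVs by six-class base change, transition/transversion, and
#' (when contexts are supplied) the 96 trinucleotide categories. Indels
#' (multi-base ref or alt) are excluded from spectra.
#'
#' @param ref,alt allele vectors.
#' @param context optional 3-mer reference contexts.
#' @param group_label label stored with the spectrum.
#' @return a `spectrum_counts` list: `six_class` (named length-6 counts),
#'   `titv` (named length-2), `tri_class` (named length-96 or NULL),
#'   `n_snv`, `group_label`.
#' @export
spectrum_counts <- function(ref, alt, context = NULL, group_label = "") {
  snv <- nchar(ref) == 1 & nchar(alt) == 1 & ref != alt &
    ref %in% names(COMPLEMENT) & alt %in% names(COMPLEMENT)
  ref <- ref[snv]; alt <- alt[snv]
  six <- table(factor(base_change_class(ref, alt), levels = SIX_CLASSES))
  ti <- table(factor(titv_class(ref, alt), levels = c("transition", "transversion")))
  tri <- NULL
  if (!is.null(context)) {
    context <- context[snv]
    lv <- tri_levels()
    tri <- table(factor(trinucleotide_class(context, alt), levels = lv))
  }
  structure(list(six_class = c(six), titv = c(ti),
                 tri_class = if (is.null(tri)) NULL else c(tri),
                 n_snv = length(ref), group_label = group_label),
            class = "spectrum_counts")
}

tri_levels <- function() {
  b <- c("A", "C", "G", "T")
  unlist(lapply(SIX_CLASSES, function(cl) {
    as.vector(outer(b, b, function(f, t) sprintf("%s[%s]%s", f, cl, t)))
  }))
}

#' @export
print.spectrum_counts <- function(x, ...) {
  cat(sprintf("<spectrum_counts> %s: %d SNVs\n", x$group_label, x$n_snv))
  print(x$six_class)
  invisible(x)
}

#' Compare mutation spectra between groups
#'
#' Chi-squared test of independence on the groups x classes count matrix
#' (six-class or transition/transversion).
#'
#' @param groups list of [spectrum_counts()] objects (>= 2).
#' @param mode `"six_class"` or `"titv"`.
#' @return list with `statistic`, `df`, `p_value`, and the count `matrix`.
#' @export
compare_spectra <- function(groups, mode = c("six_class", "titv")) {
  mode <- match.arg(mode)
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  m <- do.call(rbind, lapply(groups, function(g) g[[mode]]))
  rownames(m) <- vapply(groups, function(g) g$group_label, character(1))
  if (any(rowSums(m) == 0)) stop("a group has zero SNVs", call. = FALSE)
  m_test <- m[, colSums(m) > 0, drop = FALSE]
  res <- chi2_independence(m_test)
  c(res, list(matrix = m))
}
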