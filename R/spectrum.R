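COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Canonical six-class label for a substitution; a substitution and its
# reverse complement map to the same class (G>A and C>T are both G:C>A:T).
spectrum_class <- function(ref, alt) {
  flip <- ref %in% c("C", "T")
  ref[flip] <- COMPLEMENT[ref[flip]]
  alt[flip] <- COMPLEMENT[alt[flip]]
  pair <- c(A = "A:T", C = "C:G", G = "G:C", T = "T:A")
  paste0(pair[ref], ">", pair[alt])
}

#' Tabulate SNVs into the six complementary substitution classes
#'
#' Pooled SNVs are grouped as complementary base pairs — G:C>C:G, A:T>C:G,
#' A:T>G:C, G:C>T:A, A:T>T:A, G:C>A:T — where the colon joins the two
#' strands of the base pair and the arrow marks the substitution. Each
#' valid SNV is counted exactly once; records with `ref == alt` or
#' non-ACGT bases are rejected (count kept in `attr(, "n_rejected")`).
#'
#' @param snvs data frame with `ref` and `alt` columns, or two character
#'   vectors via `alt`
#' @param alt alternate alleles when `snvs` is a ref vector
#' @return named integer vector over the six classes (class
#'   `spectrum_counts`)
#' @examples
#' classify_snv_spectrum(data.frame(ref = c("G", "C", "A"),
#'                                  alt = c("A", "T", "T")))
#' @export
classify_snv_spectrum <- function(snvs, alt = NULL) {
  if (is.data.frame(snvs)) {
    ref <- toupper(snvs$ref)
    alt <- toupper(snvs$alt)
  } else {
    ref <- toupper(snvs)
    alt <- toupper(alt)
  }
  valid <- ref %in% BASES & alt %in% BASES & ref != alt
  cls <- spectrum_class(ref[valid], alt[valid])
  counts <- setNames(integer(length(SPECTRUM_CLASSES)), SPECTRUM_CLASSES)
  if (length(cls)) {
    tb <- table(factor(cls, levels = SPECTRUM_CLASSES))
    counts[] <- as.integer(tb)
  }
  structure(counts, n_rejected = sum(!valid), class = "spectrum_counts")
}

#' Compare two substitution spectra with a Pearson chi-square test
#'
#' Tests whether two pooled SNV spectra (e.g. MMC-treated vs EMS-treated
#' cohorts) follow the same six-class distribution, via the Pearson
#' chi-square statistic on the 2 x 6 contingency table of class counts.
#' Classes empty in both spectra are dropped and the degrees of freedom
#' adjusted; `low_expected` is set when any expected count falls below 5
#' (the usual caution for the asymptotic approximation).
#'
#' @param counts_a,counts_b spectra from [classify_snv_spectrum()] (or any
#'   equal-length non-negative count vectors); totals must be > 0
#' @return list with `statistic`, `df`, `p_value`, `low_expected`
#' @examples
#' a <- classify_snv_spectrum(data.frame(ref = "G", alt = "A"))
#' @export
compare_spectra_chisq <- function(counts_a, counts_b) {
  a <- as.numeric(counts_a)
  b <- as.numeric(counts_b)
  if (length(a) != length(b))
    stop_mmcsig("spectra must have the same number of classes")
  if (sum(a) == 0 || sum(b) == 0)
    stop_mmcsig("both spectra must have a positive total count")
  mat <- rbind(a, b)
  mat <- mat[, colSums(mat) > 0, drop = FALSE]
  if (ncol(mat) < 2L)  # all counts in one shared class: no detectable shift
    return(list(statistic = 0, df = 0L, p_value = 1, low_expected = FALSE))
  res <- suppressWarnings(chisq.test(mat, correct = FALSE))
  list(statistic = unname(res$statistic),
       df = unname(res$parameter),
       p_value = res$p.value,
       low_expected = any(res$expected < 5))
}
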