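# Trophic fatty-acid biomarker indices. All three consume percent-of-total
# proportions directly; ratios with a zero denominator are returned as NA
# ("undefined") rather than raising, and downstream ANOVA drops them
# pairwise with a logged count.

fa_col <- function(x, label) {
  m <- fa_matrix(x)
  if (label %in% colnames(m)) m[, label] else numeric(nrow(m))
}

safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Ratio of 18:1n-7 to 18:1n-9
#'
#' Herbivory-vs-carnivory index: 18:1n-7 derives from elongation of
#' photosynthetically produced 16:1n-7, while 18:1n-9 is a major fatty acid
#' of most marine animals. Higher values indicate greater
#' photosynthesis-derived input.
#'
#' @param x An `fa_profiles` object.
#' @return Numeric vector, one value per sample; `NA` where 18:1n-9 is 0%.
#' @export
ratio_18_1 <- function(x) {
  safe_ratio(fa_col(x, "18:1n-7"), fa_col(x, "18:1n-9"))
}

#' Photosynthetic- versus animal-derived input index
#'
#' Ratio of typically photosynthesis-derived fatty acids (16:1n-7 + 18:1n-7)
#' to typically animal-derived fatty acids (18:1n-9 + 20:1n-9 + 22:1n-11).
#'
#' @param x An `fa_profiles` object.
#' @return Numeric vector; `NA` where the animal-derived sum is 0%.
#' @export
photo_animal_index <- function(x) {
  num <- fa_col(x, "16:1n-7") + fa_col(x, "18:1n-7")
  den <- fa_col(x, "18:1n-9") + fa_col(x, "20:1n-9") + fa_col(x, "22:1n-11")
  safe_ratio(num, den)
}

#' Sum of long-chain monounsaturated fatty acids
#'
#' Sum of the six C20/C22 MUFA isomers 20:1n-11, 20:1n-9, 20:1n-7, 22:1n-11,
#' 22:1n-9 and 22:1n-7, as percent of total fatty acids. Elevated LC-MUFA is
#' a biomarker of feeding on herbivorous copepods, which biosynthesise these
#' isomers in quantity. Exactly these six isomers enter the sum; other 20:1
#' or 22:1 isomers present in a profile do not.
#'
#' @param x An `fa_profiles` object.
#' @return Numeric vector (percent of total fatty acids), 0 when none of the
#'   six are present.
#' @export
sum_lc_mufa <- function(x) {
  Reduce(`+`, lapply(LC_MUFA, function(l) fa_col(x, l)))
}

#' Per-sample table of the three trophic indices
#'
#' @param x An `fa_profiles` object.
#' @return Tibble with the sample metadata followed by `ratio_18_1`,
#'   `photo_animal` and `lc_mufa_sum`, one row per sample in input order.
#'   Undefined ratios (zero denominators) appear as `NA`; their count is
#'   reported via [message()].
#' @export
index_table <- function(x) {
  out <- fa_meta(x)
  out$ratio_18_1 <- ratio_18_1(x)
  out$photo_animal <- photo_animal_index(x)
  out$lc_mufa_sum <- sum_lc_mufa(x)
  n_undef <- sum(is.na(out$ratio_18_1)) + sum(is.na(out$photo_animal))
  if (n_undef > 0) {
    message(n_undef, " undefined index value(s) (zero denominator) recorded as NA")
  }
  out
}
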