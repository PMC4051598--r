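# Significance computations on the fixed-allele tallies: chi-square test of
# mutation type (novel vs reference-matching) by strain, and a binomial sign
# test for an excess of unique fixed alleles in the selected strain (under
# neutrality a new allele is equally likely to fix in either strain).

#' Pearson chi-square test on a 2x2 strain-by-mutation-type table
#'
#' Rows are strains, columns are novel vs reference-matching allele counts.
#' No continuity correction by default (that is the variant consistent with
#' the published statistic); Yates correction is available behind `yates`.
#'
#' @param tab 2x2 matrix of non-negative counts
#' @param yates apply the continuity correction?
#' @return list with `statistic`, `df` (= 1) and `p_value`
#' @export
chi_square_2x2 <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stopf("table must be 2x2")
  if (any(tab < 0) || anyNA(tab)) stopf("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("zero marginal total: chi-square statistic undefined")
  }
  ht <- stats::chisq.test(tab, correct = yates)
  list(statistic = unname(ht$statistic), df = 1L,
       p_value = unname(ht$p.value))
}

#' Test for an excess of unique fixed alleles in the selected strain
#'
#' Two-sided sign test of `unique_R` successes in `unique_R + unique_C`
#' trials against p = 0.5: exact binomial for n <= 1000, normal
#' approximation z = (unique_R - n/2) / sqrt(n/4) above that.
#'
#' @param unique_R,unique_C unique fixed-allele counts per strain
#' @return list with `z`, `p_value` and `method`
#' @export
unique_excess_test <- function(unique_R, unique_C) {
  if (unique_R < 0 || unique_C < 0) stopf("counts must be non-negative")
  n <- unique_R + unique_C
  if (n == 0) stopf("both counts are zero")
  z <- (unique_R - n / 2) / sqrt(n / 4)
  if (n <= 1000) {
    p <- stats::binom.test(unique_R, n, p = 0.5)$p.value
    method <- "exact binomial"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(z = z, p_value = p, method = method)
}
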