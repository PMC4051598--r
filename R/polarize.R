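# Outgroup-based polarization of alleles and per-strain fixation status.
#
# An allele identical to the outgroup state is an "old" (ancestral) allele;
# an allele absent from the outgroup is a "new" (derived) mutation; sites
# with no usable outgroup base are "unpolarized" and excluded from old/new
# tallies. Multi-allelic sites are handled as one row per alternate allele.

#' Classify allele origin against the outgroup
#'
#' @param alt focal (non-reference) allele string(s)
#' @param outgroup_allele outgroup allele string(s) at the same site; `NA`,
#'   empty, or any string containing `N` counts as missing
#' @return character vector: `"old"`, `"new"` or `"unpolarized"`
#' @export
classify_origin <- function(alt, outgroup_allele) {
  og <- toupper(as.character(outgroup_allele))
  missing_og <- is.na(og) | og == "" | grepl("N", og, fixed = TRUE)
  out <- ifelse(missing_og, "unpolarized",
                ifelse(toupper(alt) == og, "old", "new"))
  as.character(out)
}

#' Classify per-strain fixation status from a pooled allele frequency
#'
#' @param freq non-reference allele frequency in `[0, 1]`
#' @param threshold fixation threshold in `(0.5, 1]`; the default 1 demands
#'   literal fixation, a value like 0.95 tolerates pooled-sequencing noise
#' @return character vector: `"fixed_novel"` (freq >= threshold),
#'   `"fixed_reference"` (freq <= 1 - threshold) or `"segregating"`
#' @export
classify_fixation <- function(freq, threshold = 1.0) {
  if (threshold <= 0.5 || threshold > 1) {
    stopf("fixation threshold must be in (0.5, 1]")
  }
  check_freq(freq)
  ifelse(freq >= threshold, "fixed_novel",
         ifelse(freq <= 1 - threshold, "fixed_reference", "segregating"))
}

#' Polarize filtered sites and assign fixation buckets
#'
#' Adds per-site origin, per-strain fixation states and the shared/unique
#' bucket: `fixed_shared` (same allele fixed in both strains), `unique_R` /
#' `unique_C` (fixed for the variant in exactly one strain, fixed reference
#' in the other) or `segregating_involved`.
#'
#' @param sites site table with `alt`, `outgroup_allele`, `freq_R`, `freq_C`
#' @param threshold fixation threshold passed to [classify_fixation()]
#' @return `sites` with columns `origin`, `state_R`, `state_C`, `shared`,
#'   `bucket` appended; class `polarized_sites`
#' @export
polarize_sites <- function(sites, threshold = 1.0) {
  sites$origin <- classify_origin(sites$alt, sites$outgroup_allele)
  sites$state_R <- classify_fixation(sites$freq_R, threshold)
  sites$state_C <- classify_fixation(sites$freq_C, threshold)
  fr <- sites$state_R == "fixed_novel"
  fc <- sites$state_C == "fixed_novel"
  rr <- sites$state_R == "fixed_reference"
  rc <- sites$state_C == "fixed_reference"
  sites$shared <- fr & fc
  sites$bucket <- ifelse(fr & fc, "fixed_shared",
                         ifelse(fr & rc, "unique_R",
                                ifelse(fc & rr, "unique_C",
                                       "segregating_involved")))
  class(sites) <- c("polarized_sites", class(sites))
  sites
}

#' Tally shared and strain-unique fixed alleles
#'
#' Counts the polarization buckets, asserts that they partition the input,
#' and derives the headline divergence summaries: the unique-allele
#' difference between strains and its percentage of all classified alleles
#' (with the drift complement).
#'
#' @param polarized output of [polarize_sites()] (or any data.frame with
#'   `bucket` and `origin` columns)
#' @return list of class `allele_tally`: `fixed_shared`, `unique_R`,
#'   `unique_C`, `segregating_involved`, `unpolarized` (informational),
#'   `difference`, `total_classified` (shared + unique), `pct_new_divergent`
#'   (100 * difference / total_classified), `pct_drift` (its complement,
#'   1 dp) and `by_origin` (bucket x origin table)
#' @export
tally_shared_unique <- function(polarized) {
  b <- factor(polarized$bucket,
              levels = c("fixed_shared", "unique_R", "unique_C",
                         "segregating_involved"))
  n <- table(b)
  stopifnot(sum(n) == nrow(polarized))  # buckets partition all sites
  counts <- as.list(as.integer(n))
  names(counts) <- levels(b)
  counts$unpolarized <- sum(polarized$origin == "unpolarized")
  counts$difference <- counts$unique_R - counts$unique_C
  counts$total_classified <-
    counts$fixed_shared + counts$unique_R + counts$unique_C
  counts$pct_new_divergent <- if (counts$total_classified > 0) {
    round_half_up(100 * counts$difference / counts$total_classified, 2)
  } else NA_real_
  counts$pct_drift <- if (counts$total_classified > 0) {
    round_half_up(100 - 100 * counts$difference / counts$total_classified, 1)
  } else NA_real_
  counts$by_origin <- table(bucket = b, origin = factor(
    polarized$origin, levels = c("old", "new", "unpolarized")))
  class(counts) <- "allele_tally"
  counts
}

#' Headline divergence summaries from plain unique/shared counts
#'
#' The same arithmetic as [tally_shared_unique()] but starting from counts
#' (e.g. from a published table) instead of per-site records.
#'
#' @param unique_R,unique_C strain-unique fixed-allele counts
#' @param fixed_shared fixed alleles common to both strains
#' @return list with `difference`, `total`, `pct_new_divergent` (2 dp),
#'   `pct_drift` (1 dp)
#' @export
summarize_unique_counts <- function(unique_R, unique_C, fixed_shared = 0) {
  total <- unique_R + unique_C + fixed_shared
  if (total <= 0) stopf("counts sum to zero")
  diff <- unique_R - unique_C
  list(difference = diff,
       total = total,
       pct_new_divergent = round_half_up(100 * diff / total, 2),
       pct_drift = round_half_up(100 - 100 * diff / total, 1))
}

#' @export
print.allele_tally <- function(x, ...) {
  cat("Fixed-allele tally\n")
  cat(sprintf("  shared fixed: %d | unique to R: %d | unique to C: %d | segregating-involved: %d\n",
              x$fixed_shared, x$unique_R, x$unique_C,
              x$segregating_involved))
  cat(sprintf("  unique difference (R - C): %d (%.2f%% of %d classified; drift complement %.1f%%)\n",
              x$difference, x$pct_new_divergent, x$total_classified,
              x$pct_drift))
  invisible(x)
}
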