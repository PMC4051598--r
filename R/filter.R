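# Call-acceptance filtering of candidate SNP/DIP sites.
#
# A candidate call is accepted when the central base has PHRED q >= 20, all
# 11 flanking bases on either side have q >= 15, read depth >= 10 and the
# variant nucleotide frequency >= 0.10 (all thresholds inclusive, applied
# identically to SNPs and DIPs).

FILTER_RULES <- c("central_quality", "flank_quality", "coverage", "frequency")

#' Simulate per-site PHRED quality contexts
#'
#' Gives every site a central PHRED score and 11 flanking scores per side.
#' Passing sites draw scores from truncated normals that respect the filter
#' thresholds (central ~ N(36, 4) clamped to \[20, 40\], flanks ~ N(32, 4)
#' clamped to \[15, 40\]); a `fail_fraction` of sites is deliberately broken
#' on one quality rule. The returned table also records the ground truth of
#' which sites should fail each filter rule (including the depth and
#' frequency rules evaluated from the site table), so filter output can be
#' checked exactly.
#'
#' @param sites site table with `arm`, `pos`, `freq_R`, `freq_C`, `depth_R`,
#'   `depth_C` (a `sim_study$sites` table)
#' @param fail_fraction fraction of sites given an injected quality failure
#' @param fail_mode `"random"` picks a quality rule per failing site;
#'   `"central_q"` forces central q = `fail_central_q`; `"flank_q"` breaks
#'   one flanking score
#' @param fail_central_q central score used for injected central failures
#' @param flank_width flanking bases per side (11 to match the call filter)
#' @param seed optional RNG seed for reproducible profiles
#' @return data.frame: `arm`, `pos`, `central_q`, `flank_qs` (comma-joined),
#'   `depth`, `variant_freq`, plus ground-truth columns `injected_fail`,
#'   `fail_rule`, `true_fail_central`, `true_fail_flank`,
#'   `true_fail_coverage`, `true_fail_frequency`, `should_pass`
#' @export
write_quality_profiles <- function(sites, fail_fraction = 0,
                                   fail_mode = c("random", "central_q",
                                                 "flank_q"),
                                   fail_central_q = 19L,
                                   flank_width = 11L,
                                   seed = NULL) {
  fail_mode <- match.arg(fail_mode)
  if (fail_fraction < 0 || fail_fraction > 1) {
    stopf("fail_fraction outside [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sites)
  nf <- 2L * flank_width

  central <- pmin(40L, pmax(20L, round(rnorm(n, 36, 4))))
  flanks <- matrix(pmin(40L, pmax(15L, round(rnorm(n * nf, 32, 4)))),
                   nrow = n)

  injected <- runif(n) < fail_fraction
  rule <- rep("none", n)
  for (i in which(injected)) {
    mode <- switch(fail_mode,
                   random = sample_safe(c("central_q", "flank_q"), 1L),
                   fail_mode)
    if (mode == "central_q") {
      central[i] <- fail_central_q
      rule[i] <- "central_quality"
    } else {
      flanks[i, sample.int(nf, 1L)] <- sample.int(15L, 1L) - 1L
      rule[i] <- "flank_quality"
    }
  }

  # the variant's supporting evidence: the strain carrying it at the higher
  # observed frequency
  use_R <- sites$freq_R >= sites$freq_C
  depth <- ifelse(use_R, sites$depth_R, sites$depth_C)
  vaf <- ifelse(use_R, sites$freq_R, sites$freq_C)

  out <- data.frame(
    arm = sites$arm, pos = sites$pos,
    central_q = as.integer(central),
    flank_qs = apply(flanks, 1L, paste, collapse = ","),
    depth = as.integer(depth),
    variant_freq = vaf,
    injected_fail = injected,
    fail_rule = rule,
    true_fail_central = central < 20L,
    true_fail_flank = apply(flanks < 15L, 1L, any),
    true_fail_coverage = depth < 10L,
    true_fail_frequency = vaf < 0.10,
    stringsAsFactors = FALSE)
  out$should_pass <- !(out$true_fail_central | out$true_fail_flank |
                         out$true_fail_coverage | out$true_fail_frequency)
  out
}

#' Test one quality context against the call-acceptance rules
#'
#' @param central_q PHRED score of the variant position
#' @param flank_qs numeric vector of flanking PHRED scores (normally 11 per
#'   side; fewer only near contig ends, where only existing flanks are
#'   evaluated)
#' @param depth reads covering the site
#' @param variant_freq fraction of reads supporting the variant
#' @param min_central_q,min_flank_q,min_depth,min_vaf inclusive thresholds;
#'   defaults are the published call-acceptance values
#' @return list with `pass` (logical) and `reasons` (character vector naming
#'   every violated rule; empty when passing)
#' @export
passes_call_filter <- function(central_q, flank_qs, depth, variant_freq,
                               min_central_q = 20, min_flank_q = 15,
                               min_depth = 10, min_vaf = 0.10) {
  if (is.na(depth) || depth < 0) stopf("negative or missing depth")
  if (any(c(central_q, flank_qs) < 0)) stopf("negative PHRED score")
  check_freq(variant_freq, "variant_freq")
  reasons <- character(0)
  if (central_q < min_central_q) reasons <- c(reasons, "central_quality")
  if (length(flank_qs) && any(flank_qs < min_flank_q)) {
    reasons <- c(reasons, "flank_quality")
  }
  if (depth < min_depth) reasons <- c(reasons, "coverage")
  if (variant_freq < min_vaf) reasons <- c(reasons, "frequency")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Filter candidate sites on their quality contexts
#'
#' Applies [passes_call_filter()] to every site, partitioning the input into
#' passed and rejected sets; the rejection tally is keyed by the full
#' combination of violated rules (e.g. `"coverage+frequency"`), so counts
#' always partition exactly: `nrow(passed) + sum(tally) == nrow(sites)`.
#'
#' @param sites site table with `arm` and `pos`
#' @param quality quality-context table from [write_quality_profiles()] (or
#'   equivalent, with `arm`, `pos`, `central_q`, `flank_qs`, `depth`,
#'   `variant_freq`)
#' @param min_central_q,min_flank_q,min_depth,min_vaf inclusive thresholds
#' @return list with `passed` (site rows accepted), `rejected` (site rows
#'   with a `reasons` column) and `tally` (named integer vector by rule
#'   combination)
#' @export
filter_sites <- function(sites, quality,
                         min_central_q = 20, min_flank_q = 15,
                         min_depth = 10, min_vaf = 0.10) {
  if (nrow(sites) == 0L) {
    return(list(passed = sites,
                rejected = cbind(sites, reasons = character(0)),
                tally = integer(0)))
  }
  key_s <- paste(sites$arm, sites$pos)
  key_q <- paste(quality$arm, quality$pos)
  idx <- match(key_s, key_q)
  if (anyNA(idx)) {
    stopf("missing quality context for site(s): %s",
          paste(utils::head(key_s[is.na(idx)], 5), collapse = "; "))
  }
  q <- quality[idx, , drop = FALSE]
  if (any(q$depth < 0)) stopf("negative depth in quality table")

  flank_min <- vapply(strsplit(q$flank_qs, ",", fixed = TRUE),
                      function(v) if (length(v)) min(as.numeric(v)) else Inf,
                      numeric(1))
  fails <- cbind(central_quality = q$central_q < min_central_q,
                 flank_quality = flank_min < min_flank_q,
                 coverage = q$depth < min_depth,
                 frequency = q$variant_freq < min_vaf)
  reasons <- apply(fails, 1L, function(f) {
    paste(FILTER_RULES[f[FILTER_RULES]], collapse = "+")
  })
  pass <- reasons == ""

  rejected <- sites[!pass, , drop = FALSE]
  rejected$reasons <- reasons[!pass]
  tally <- if (any(!pass)) {
    tab <- table(reasons[!pass])
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  list(passed = sites[pass, , drop = FALSE], rejected = rejected,
       tally = tally)
}
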