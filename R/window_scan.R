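# Sliding-window F_ST from population heterozygosities, and between-strain
# nucleotide diversity (d_xy), across the genome.
#
# Per-site Nei-style estimator for two equally weighted populations with
# frequencies p1, p2 of the variant allele:
#   H_i = 2 p_i (1 - p_i),  H_S = (H_1 + H_2) / 2,
#   p_bar = (p1 + p2) / 2,  H_T = 2 p_bar (1 - p_bar),
#   F_ST = (H_T - H_S) / H_T          (undefined when H_T = 0).
# Windows aggregate as a ratio of sums, (sum H_T - sum H_S) / sum H_T, the
# standard way to avoid small-H_T instability; the mean of per-site ratios
# is available as an alternative. Windows with F_ST > 0.8 are flagged
# extreme.

#' Per-site heterozygosities and F_ST
#'
#' @param p1,p2 variant-allele frequencies in the two strains (vectors)
#' @return data.frame with `H_T`, `H_S`, `fst` (NA where `H_T` is 0)
#' @export
fst_site <- function(p1, p2) {
  check_freq(p1, "p1"); check_freq(p2, "p2")
  h1 <- 2 * p1 * (1 - p1)
  h2 <- 2 * p2 * (1 - p2)
  hs <- (h1 + h2) / 2
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  data.frame(H_T = ht, H_S = hs,
             fst = ifelse(ht > 0, (ht - hs) / ht, NA_real_))
}

#' Window F_ST from per-site heterozygosities
#'
#' @param H_T,H_S per-site heterozygosities of the sites in the window
#' @param method `"ratio_of_sums"` (default) or `"mean_of_ratios"`
#' @return the window F_ST estimate; `NA` for an empty window or when the
#'   summed total heterozygosity is 0
#' @export
fst_window <- function(H_T, H_S, method = c("ratio_of_sums",
                                            "mean_of_ratios")) {
  method <- match.arg(method)
  if (length(H_T) == 0L) return(NA_real_)
  if (method == "ratio_of_sums") {
    st <- sum(H_T)
    if (st == 0) return(NA_real_)
    (st - sum(H_S)) / st
  } else {
    ok <- H_T > 0
    if (!any(ok)) return(NA_real_)
    mean((H_T[ok] - H_S[ok]) / H_T[ok])
  }
}

#' Between-strain nucleotide diversity of a window
#'
#' d_xy: the average per-site probability that two alleles, one drawn from
#' each strain, differ. Sites absent from the input (monomorphic identical)
#' contribute 0.
#'
#' @param p1,p2 variant-allele frequencies of the window's polymorphic sites
#' @param window_length window length L in bp
#' @return `sum(p1 (1 - p2) + p2 (1 - p1)) / L`
#' @export
dxy_window <- function(p1, p2, window_length) {
  if (window_length <= 0) stopf("window length must be > 0")
  check_freq(p1, "p1"); check_freq(p2, "p2")
  sum(p1 * (1 - p2) + p2 * (1 - p1)) / window_length
}

#' Sliding-window genome scan of F_ST and d_xy
#'
#' Windows tile each arm on the step grid; every site contributes to each
#' window that overlaps it. Window starts advance by `step` while a
#' full-width window fits; if the last full window stops short of the arm
#' end, one trailing partial window is added, and `d_xy` always uses the
#' true covered length. The unplaced arm `"U"` is excluded from scanning.
#'
#' @param sites site table with `arm`, `pos`, `freq_R`, `freq_C`, sorted by
#'   arm then position (unsorted input is an error, never silently sorted)
#' @param arm_lengths named vector of arm lengths in bp
#' @param window window width in bp
#' @param step step between window starts in bp
#' @param extreme_threshold windows with F_ST strictly above this are
#'   flagged extreme
#' @param method window aggregation, see [fst_window()]
#' @param exclude_arms arms to drop before scanning
#' @return data.frame of class `window_scan`: `arm`, `start`, `end` (1-based
#'   inclusive), `n_snps`, `sum_HT`, `sum_HS`, `fst`, `dxy`, `extreme`
#' @export
scan_genome <- function(sites, arm_lengths, window = 10000L, step = 1000L,
                        extreme_threshold = 0.8,
                        method = c("ratio_of_sums", "mean_of_ratios"),
                        exclude_arms = "U") {
  method <- match.arg(method)
  if (window <= 0 || step <= 0) stopf("window and step must be > 0")
  if (is.null(names(arm_lengths))) stopf("arm_lengths must be named")

  keep <- !(sites$arm %in% exclude_arms)
  sites <- sites[keep, , drop = FALSE]
  arm_lengths <- arm_lengths[setdiff(names(arm_lengths), exclude_arms)]
  if (nrow(sites)) {
    if (!all(sites$arm %in% names(arm_lengths))) {
      stopf("sites on arm(s) missing from arm_lengths: %s",
            paste(setdiff(unique(sites$arm), names(arm_lengths)),
                  collapse = ", "))
    }
    arm_runs <- rle(sites$arm)$values
    if (anyDuplicated(arm_runs) ||
        any(vapply(split(sites$pos, sites$arm), is.unsorted, logical(1)))) {
      stopf("sites must be sorted by (arm, pos); sort before scanning")
    }
  }

  per_site <- fst_site(sites$freq_R, sites$freq_C)
  dxy_term <- sites$freq_R * (1 - sites$freq_C) +
    sites$freq_C * (1 - sites$freq_R)

  res <- lapply(names(arm_lengths), function(arm) {
    alen <- as.integer(arm_lengths[[arm]])
    starts <- seq.int(1L, max(1L, alen - window + 1L), by = step)
    last_end <- starts[length(starts)] + window - 1L
    if (last_end < alen) starts <- c(starts, starts[length(starts)] + step)
    ends <- pmin(starts + window - 1L, alen)

    on_arm <- which(sites$arm == arm)
    pos <- sites$pos[on_arm]
    cht <- cumsum(per_site$H_T[on_arm])
    chs <- cumsum(per_site$H_S[on_arm])
    cdx <- cumsum(dxy_term[on_arm])
    # per-site ratio cumsum for the alternative aggregation
    ratio <- per_site$fst[on_arm]
    cok <- cumsum(!is.na(ratio))
    cra <- cumsum(ifelse(is.na(ratio), 0, ratio))

    lo <- findInterval(starts - 1L, pos)       # sites strictly before start
    hi <- findInterval(ends, pos)              # sites up to end
    n <- hi - lo
    at <- function(cs, i) ifelse(i > 0L, cs[pmax(i, 1L)], 0)
    sht <- at(cht, hi) - at(cht, lo)
    shs <- at(chs, hi) - at(chs, lo)
    sdx <- at(cdx, hi) - at(cdx, lo)
    fst <- if (method == "ratio_of_sums") {
      ifelse(n > 0L & sht > 0, (sht - shs) / sht, NA_real_)
    } else {
      nok <- at(cok, hi) - at(cok, lo)
      ifelse(nok > 0, (at(cra, hi) - at(cra, lo)) / nok, NA_real_)
    }
    data.frame(arm = arm, start = starts, end = ends, n_snps = as.integer(n),
               sum_HT = sht, sum_HS = shs, fst = fst,
               dxy = sdx / (ends - starts + 1L),
               extreme = !is.na(fst) & fst > extreme_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "extreme_threshold") <- extreme_threshold
  class(out) <- c("window_scan", class(out))
  out
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf("Genome scan: %d windows (%s bp, step %s bp) on %d arm(s)\n",
              nrow(x), format(attr(x, "window") %||% NA),
              format(attr(x, "step") %||% NA), length(unique(x$arm))))
  defined <- !is.na(x$fst)
  cat(sprintf("  windows with sites: %d; mean F_ST %.3f; extreme (> %s): %d\n",
              sum(x$n_snps > 0),
              if (any(defined)) mean(x$fst[defined]) else NA_real_,
              format(attr(x, "extreme_threshold") %||% NA), sum(x$extreme)))
  invisible(x)
}
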