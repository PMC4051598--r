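# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed tables in this field round
#' half up, so tallies like 1.79 and 98.2 reproduce exactly.
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# two-significant-figure percentage label, as printed in per-arm burden tables
format_percent2 <- function(p) signif(p, 2)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_freq <- function(x, what = "allele frequency") {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    stopf("%s outside [0, 1]: %s", what,
          paste(format(utils::head(x[bad], 3)), collapse = ", "))
  }
  invisible(x)
}

# sample() with size-1 safety (sample(5L, 1) lottery semantics)
sample_safe <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# reverse complement for plain character vectors of A/C/G/T/N strings
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)
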