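# Wright-Fisher two-strain simulator with known ground truth.
#
# Emulates the common-origin / divergent-selection design: an ancestral lab
# population at mutation-drift equilibrium is split into strains R (selected)
# and C (control), each drifting independently for t generations while new
# mutations enter; an outgroup diverged at a fixed per-site rate provides the
# ancestral-state reference; pooled sequencing is modeled as binomial read
# sampling of the true population frequency.

#' Configure a synthetic two-strain study
#'
#' @param arm_names chromosome-arm labels. The default mirrors the six
#'   analysed Drosophila arms; add `"U"` to exercise the unplaced-arm
#'   exclusion rule.
#' @param genome_length bases per arm (scalar, recycled)
#' @param n_genes total number of single-interval CDS gene models to place
#' @param cds_fraction proportion of each arm covered by CDS
#' @param pop_size diploid effective size N of each strain
#' @param generations generations t since the strain split
#' @param mutation_rate per-site per-generation mutation rate
#' @param outgroup_divergence per-site substitution probability between the
#'   reference and the outgroup
#' @param old_allele_fraction fraction of ancestral polymorphisms whose
#'   segregating allele is the outgroup-matching (old) allele
#' @param dip_fraction fraction of mutations that are short (1-10 bp)
#'   insertion/deletion polymorphisms rather than SNPs
#' @param selected_loci data.frame with columns `arm`, `pos`, `s`: loci under
#'   directional selection, applied only to strain R
#' @param selected_p0 initial frequency of each selected allele in strain R
#'   at the split (absent from strain C)
#' @param pool_coverage mean pooled read depth per strain
#' @param seed integer RNG seed; identical seed and config give
#'   byte-identical output
#' @return a `sim_config` list
#' @export
sim_config <- function(arm_names = c("2L", "2R", "3L", "3R", "4", "X"),
                       genome_length = 2e5,
                       n_genes = 30,
                       cds_fraction = 0.15,
                       pop_size = 100,
                       generations = 500,
                       mutation_rate = 1e-8,
                       outgroup_divergence = 0.05,
                       old_allele_fraction = 0.5,
                       dip_fraction = 0.1,
                       selected_loci = NULL,
                       selected_p0 = 0.05,
                       pool_coverage = 40,
                       seed = 1L) {
  cfg <- list(arm_names = as.character(arm_names),
              genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              cds_fraction = cds_fraction,
              pop_size = as.integer(pop_size),
              generations = as.integer(generations),
              mutation_rate = mutation_rate,
              outgroup_divergence = outgroup_divergence,
              old_allele_fraction = old_allele_fraction,
              dip_fraction = dip_fraction,
              selected_loci = selected_loci,
              selected_p0 = selected_p0,
              pool_coverage = pool_coverage,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c(mutation_rate = cfg$mutation_rate,
             outgroup_divergence = cfg$outgroup_divergence,
             old_allele_fraction = cfg$old_allele_fraction,
             dip_fraction = cfg$dip_fraction,
             cds_fraction = cfg$cds_fraction,
             selected_p0 = cfg$selected_p0)
  bad <- rates < 0 | rates > 1
  if (any(bad)) stopf("rates outside [0, 1]: %s",
                      paste(names(rates)[bad], collapse = ", "))
  if (cfg$genome_length <= 0) stopf("genome_length must be > 0")
  if (cfg$generations < 0) stopf("generations must be >= 0")
  if (cfg$pop_size <= 0) stopf("pop_size must be a positive diploid count")
  if (!length(cfg$arm_names) || anyDuplicated(cfg$arm_names)) {
    stopf("arm_names must be a non-empty set of unique labels")
  }
  sel <- cfg$selected_loci
  if (!is.null(sel)) {
    if (!all(c("arm", "pos", "s") %in% names(sel))) {
      stopf("selected_loci needs columns arm, pos, s")
    }
    if (!all(sel$arm %in% cfg$arm_names)) {
      stopf("selected locus on unknown arm: %s",
            paste(setdiff(sel$arm, cfg$arm_names), collapse = ", "))
    }
    if (any(sel$pos < 1 | sel$pos > cfg$genome_length)) {
      stopf("selected locus outside genome (1..%d)", cfg$genome_length)
    }
    if (any(sel$s < 0)) stopf("selection coefficients must be >= 0")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-strain Wright-Fisher study configuration\n")
  cat(sprintf("  arms: %s (%s bp each)\n", paste(x$arm_names, collapse = ", "),
              format(x$genome_length, big.mark = ",")))
  cat(sprintf("  N = %d diploids, t = %d generations, mu = %g /site/gen\n",
              x$pop_size, x$generations, x$mutation_rate))
  cat(sprintf("  outgroup divergence = %g, pool coverage = %g, seed = %d\n",
              x$outgroup_divergence, x$pool_coverage, x$seed))
  n_sel <- if (is.null(x$selected_loci)) 0L else nrow(x$selected_loci)
  cat(sprintf("  selected loci (strain R only): %d\n", n_sel))
  invisible(x)
}

# draw a base different from each element of `not1` (and `not2` if given)
draw_other_base <- function(not1, not2 = NULL) {
  vapply(seq_along(not1), function(i) {
    excl <- c(not1[i], not2[i])
    sample_safe(setdiff(DNA_BASES, excl), 1L)
  }, character(1))
}

# neutral site-frequency-spectrum draw: derived count i in 1..2N-1 w.p. 1/i
rsfs <- function(n, two_n) {
  i <- seq_len(two_n - 1)
  sample_safe(i, n, replace = TRUE, prob = 1 / i) / two_n
}

# build indel alleles anchored at pos against the reference characters
make_dip <- function(ref_chars, pos, max_len = 10L) {
  L <- length(ref_chars)
  del <- runif(1) < 0.5
  len <- sample.int(max_len, 1L)
  anchor <- ref_chars[pos]
  if (del && pos + len <= L) {
    ref <- paste(ref_chars[pos:(pos + len)], collapse = "")
    alt <- anchor
  } else {
    ref <- anchor
    alt <- paste(c(anchor, sample_safe(DNA_BASES, len, replace = TRUE)),
                 collapse = "")
  }
  list(ref = ref, alt = alt)
}

#' Simulate a complete synthetic two-strain study
#'
#' Generates, per arm: a random reference sequence; an outgroup copy
#' substituted at rate `outgroup_divergence`; non-overlapping CDS gene
#' models; ancestral polymorphisms at mutation-drift equilibrium
#' (theta = 4 N mu, neutral site-frequency spectrum), a configurable
#' fraction of which segregate for the outgroup-matching (old) allele;
#' then `generations` rounds of Wright-Fisher binomial resampling of 2N
#' gametes in each strain with Poisson influx of new mutations
#' (2 N mu L expected per strain per generation, entering at frequency
#' 1/2N). Selected loci enter strain R only, at frequency `selected_p0`,
#' and are pushed by p' = p(1+s)/(1+ps) before each resampling. Finally,
#' pooled sequencing is emulated: per strain, depth ~ Poisson(coverage) and
#' supporting reads ~ Binomial(depth, true frequency).
#'
#' New-mutation alleles are drawn to differ from both the reference and the
#' outgroup base at their site, so the ground-truth origin label ("old" =
#' equals the outgroup allele, "new" otherwise) is exact.
#'
#' @param config a [sim_config()] object
#' @return an object of class `sim_study`: list with `config`, `reference`
#'   and `outgroup` (named [Biostrings::DNAStringSet]), `genes` (gene-model
#'   data.frame), `sites` (emitted site records with observed pooled
#'   frequencies/depths), `truth` (full ground truth incl. true frequencies,
#'   origin, ancestral/selected flags and ancestral frequency `p0`) and
#'   `n_new_mutations` (count of mutation events that entered each strain)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  N2 <- 2L * config$pop_size
  L <- config$genome_length

  ref_l <- list(); out_l <- list(); truth_l <- list(); gene_l <- list()
  n_new <- c(R = 0L, C = 0L)
  genes_per_arm <- table(factor(
    config$arm_names[1L + (seq_len(config$n_genes) - 1L) %%
                       length(config$arm_names)],
    levels = config$arm_names))

  for (arm in config$arm_names) {
    ref_chars <- sample_safe(DNA_BASES, L, replace = TRUE)
    out_chars <- ref_chars
    div_idx <- which(runif(L) < config$outgroup_divergence)
    if (length(div_idx)) {
      out_chars[div_idx] <- draw_other_base(ref_chars[div_idx])
    }

    gene_l[[arm]] <- place_genes(arm, L, genes_per_arm[[arm]],
                                 config$cds_fraction)

    # site state vectors (sparse over the arm)
    pos <- integer(0); ref <- character(0); alt <- character(0)
    type <- character(0); origin <- character(0)
    ancestral <- logical(0); selected <- logical(0); s_coef <- numeric(0)
    p0 <- numeric(0); pR <- numeric(0); pC <- numeric(0)

    add_sites <- function(apos, aref, aalt, atype, aorigin, aanc, asel, as_,
                          ap0, apR, apC) {
      pos <<- c(pos, apos); ref <<- c(ref, aref); alt <<- c(alt, aalt)
      type <<- c(type, atype); origin <<- c(origin, aorigin)
      ancestral <<- c(ancestral, aanc); selected <<- c(selected, asel)
      s_coef <<- c(s_coef, as_); p0 <<- c(p0, ap0)
      pR <<- c(pR, apR); pC <<- c(pC, apC)
    }

    # selected loci on this arm: de novo in strain R at the split
    sel <- config$selected_loci
    sel <- if (is.null(sel)) NULL else sel[sel$arm == arm, , drop = FALSE]
    if (!is.null(sel) && nrow(sel)) {
      for (k in seq_len(nrow(sel))) {
        sp <- as.integer(sel$pos[k])
        allele <- draw_other_base(ref_chars[sp], out_chars[sp])
        add_sites(sp, ref_chars[sp], allele, "SNP", "new", FALSE, TRUE,
                  sel$s[k], 0, config$selected_p0, 0)
      }
    }

    # ancestral standing variation at mutation-drift equilibrium
    theta <- 4 * config$pop_size * config$mutation_rate
    h_2n <- sum(1 / seq_len(N2 - 1))
    n_anc <- rpois(1L, theta * L * h_2n)
    if (n_anc > 0) {
      free <- setdiff(seq_len(L), pos)
      apos <- sort(sample_safe(free, min(n_anc, length(free))))
      freq0 <- rsfs(length(apos), N2)
      is_old <- runif(length(apos)) < config$old_allele_fraction
      for (k in seq_along(apos)) {
        p <- apos[k]
        if (is_old[k]) {
          # segregating allele is the ancestral, outgroup-matching state:
          # pin the outgroup to it at this site
          allele <- draw_other_base(ref_chars[p])
          out_chars[p] <- allele
          add_sites(p, ref_chars[p], allele, "SNP", "old", TRUE, FALSE, 0,
                    freq0[k], freq0[k], freq0[k])
        } else if (runif(1) < config$dip_fraction) {
          d <- make_dip(ref_chars, p)
          n <- left_align_indel(paste(ref_chars, collapse = ""), p,
                                d$ref, d$alt)
          if (n$pos %in% pos) next
          add_sites(as.integer(n$pos), n$ref, n$alt, "DIP", "new", TRUE,
                    FALSE, 0, freq0[k], freq0[k], freq0[k])
        } else {
          allele <- draw_other_base(ref_chars[p], out_chars[p])
          add_sites(p, ref_chars[p], allele, "SNP", "new", TRUE, FALSE, 0,
                    freq0[k], freq0[k], freq0[k])
        }
      }
    }

    # Wright-Fisher drift with selection in R and new-mutation influx
    influx_mean <- 2 * config$pop_size * config$mutation_rate * L
    ref_str <- paste(ref_chars, collapse = "")
    for (g in seq_len(config$generations)) {
      if (length(pos)) {
        ps <- pR * (1 + s_coef) / (1 + pR * s_coef)
        pR <- rbinom(length(ps), N2, ps) / N2
        pC <- rbinom(length(pC), N2, pC) / N2
      }
      for (strain in c("R", "C")) {
        k <- rpois(1L, influx_mean)
        if (k == 0) next
        n_new[strain] <- n_new[strain] + k
        free <- setdiff(sample.int(L, min(4L * k + 16L, L)), pos)
        mpos <- utils::head(free, k)   # rare shortfall at tiny L is fine
        for (p in mpos) {
          if (runif(1) < config$dip_fraction) {
            d <- make_dip(ref_chars, p)
            n <- left_align_indel(ref_str, p, d$ref, d$alt)
            if (n$pos %in% pos) next
            add_sites(as.integer(n$pos), n$ref, n$alt, "DIP", "new", FALSE,
                      FALSE, 0, 0,
                      if (strain == "R") 1 / N2 else 0,
                      if (strain == "C") 1 / N2 else 0)
          } else {
            allele <- draw_other_base(ref_chars[p], out_chars[p])
            add_sites(p, ref_chars[p], allele, "SNP", "new", FALSE, FALSE,
                      0, 0,
                      if (strain == "R") 1 / N2 else 0,
                      if (strain == "C") 1 / N2 else 0)
          }
        }
      }
      # prune mutations lost from both strains; keep ancestral and selected
      # rows for ground-truth bookkeeping
      keep <- pR > 0 | pC > 0 | ancestral | selected
      if (!all(keep)) {
        pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
        type <- type[keep]; origin <- origin[keep]
        ancestral <- ancestral[keep]; selected <- selected[keep]
        s_coef <- s_coef[keep]; p0 <- p0[keep]
        pR <- pR[keep]; pC <- pC[keep]
      }
    }

    out_allele <- vapply(seq_along(pos), function(i) {
      substr(paste(out_chars[pos[i]:min(L, pos[i] + nchar(ref[i]) - 1L)],
                   collapse = ""), 1L, nchar(ref[i]))
    }, character(1))
    if (!length(pos)) out_allele <- character(0)

    truth_l[[arm]] <- data.frame(
      arm = rep(arm, length(pos)), pos = pos, ref = ref, alt = alt,
      outgroup_allele = out_allele, variant_type = type, origin = origin,
      ancestral = ancestral, selected = selected, s = s_coef, p0 = p0,
      true_freq_R = pR, true_freq_C = pC, stringsAsFactors = FALSE)
    ref_l[[arm]] <- paste(ref_chars, collapse = "")
    out_l[[arm]] <- paste(out_chars, collapse = "")
  }

  truth <- do.call(rbind, truth_l)
  rownames(truth) <- NULL
  truth <- truth[order(match(truth$arm, config$arm_names), truth$pos), ]
  rownames(truth) <- NULL

  # pooled sequencing of every site still carrying a variant allele
  live <- truth$true_freq_R > 0 | truth$true_freq_C > 0
  obs <- truth[live, , drop = FALSE]
  if (nrow(obs)) {
    obs$depth_R <- rpois(nrow(obs), config$pool_coverage)
    obs$depth_C <- rpois(nrow(obs), config$pool_coverage)
    reads_R <- rbinom(nrow(obs), obs$depth_R, obs$true_freq_R)
    reads_C <- rbinom(nrow(obs), obs$depth_C, obs$true_freq_C)
    obs$freq_R <- ifelse(obs$depth_R > 0, reads_R / obs$depth_R, 0)
    obs$freq_C <- ifelse(obs$depth_C > 0, reads_C / obs$depth_C, 0)
    obs <- obs[reads_R > 0 | reads_C > 0, , drop = FALSE]
  } else {
    obs$depth_R <- obs$depth_C <- integer(0)
    obs$freq_R <- obs$freq_C <- numeric(0)
  }
  sites <- obs[, c("arm", "pos", "ref", "alt", "outgroup_allele",
                   "variant_type", "freq_R", "freq_C", "depth_R", "depth_C",
                   "origin", "ancestral", "selected")]
  rownames(sites) <- NULL

  res <- list(
    config = config,
    reference = Biostrings::DNAStringSet(unlist(ref_l)),
    outgroup = Biostrings::DNAStringSet(unlist(out_l)),
    genes = {
      g <- do.call(rbind, gene_l); rownames(g) <- NULL
      g
    },
    sites = sites,
    truth = truth,
    n_new_mutations = n_new
  )
  class(res) <- "sim_study"
  res
}

# place n non-overlapping single-interval CDS genes on an arm, total length
# close to cds_fraction * L, lengths multiples of 3
place_genes <- function(arm, L, n, cds_fraction) {
  if (n == 0) {
    return(data.frame(gene_id = character(), arm = character(),
                      strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  slot <- L %/% n
  glen <- max(30L, 3L * ((min(floor(cds_fraction * L / n), slot - 2L)) %/% 3L))
  starts <- vapply(seq_len(n), function(i) {
    lo <- (i - 1L) * slot + 1L
    hi <- i * slot - glen
    if (hi < lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
  }, integer(1))
  data.frame(
    gene_id = sprintf("g%s_%03d", arm, seq_len(n)),
    arm = arm,
    strand = sample_safe(c("+", "-"), n, replace = TRUE),
    start = starts,
    end = starts + glen - 1L,
    stringsAsFactors = FALSE)
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic two-strain study\n")
  print(x$config)
  cat(sprintf("  emitted sites: %d (%d SNP, %d DIP); truth rows: %d\n",
              nrow(x$sites), sum(x$sites$variant_type == "SNP"),
              sum(x$sites$variant_type == "DIP"), nrow(x$truth)))
  cat(sprintf("  new-mutation events: R = %d, C = %d\n",
              x$n_new_mutations["R"], x$n_new_mutations["C"]))
  invisible(x)
}

#' Realized pure-drift F_ST of a simulated study
#'
#' Generator diagnostic: the classic drift expectation
#' F_ST = 1 - exp(-t / 2N) measures the loss of within-strain heterozygosity
#' relative to the *ancestral* heterozygosity, so this computes
#' `1 - sum(H_S) / sum(H_0)` over the ancestral polymorphic sites, using
#' true (noise-free) final frequencies; H_0 = 2 p0 (1 - p0) at the split and
#' H_S is the mean of the two strains' final expected heterozygosities.
#' Contrast with the windowed Nei estimator in [scan_genome()], whose total
#' heterozygosity is measured from contemporary frequencies and therefore
#' itself decays under drift.
#'
#' @param sim a `sim_study` object
#' @return realized drift F_ST (NA when the study holds no ancestral
#'   polymorphism)
#' @export
drift_fst <- function(sim) {
  stopifnot(inherits(sim, "sim_study"))
  tr <- sim$truth[sim$truth$ancestral & !sim$truth$selected, , drop = FALSE]
  if (!nrow(tr)) return(NA_real_)
  h0 <- 2 * tr$p0 * (1 - tr$p0)
  hs <- (2 * tr$true_freq_R * (1 - tr$true_freq_R) +
           2 * tr$true_freq_C * (1 - tr$true_freq_C)) / 2
  if (sum(h0) == 0) return(NA_real_)
  1 - sum(hs) / sum(h0)
}

#' Write a simulated study to standard files
#'
#' Emits `reference.fasta`, `outgroup.fasta`, `genes.gff3`,
#' `strain_R.vcf` / `strain_C.vcf`, `sites.tsv` and `truth.tsv`.
#'
#' @param sim a `sim_study` object
#' @param dir output directory (created if missing)
#' @return named character vector of written paths, invisibly
#' @export
write_study <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(sim$reference, p("reference.fasta"))
  write_fasta(sim$outgroup, p("outgroup.fasta"))
  write_gff_cds(sim$genes, p("genes.gff3"))
  write_vcf(sim$sites, p("strain_R.vcf"), strain = "R")
  write_vcf(sim$sites, p("strain_C.vcf"), strain = "C")
  write_tsv(sim$sites, p("sites.tsv"))
  write_tsv(sim$truth, p("truth.tsv"))
  invisible(c(reference = p("reference.fasta"), outgroup = p("outgroup.fasta"),
              genes = p("genes.gff3"), vcf_R = p("strain_R.vcf"),
              vcf_C = p("strain_C.vcf"), sites = p("sites.tsv"),
              truth = p("truth.tsv")))
}
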