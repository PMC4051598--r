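# Shared in-code fixtures for the test suite.

# a minimal site table with the columns the pipeline stages expect
make_sites <- function(arm, pos, ref = "A", alt = "T", outgroup = "A",
                       freq_R = 1, freq_C = 0, depth_R = 40L, depth_C = 40L,
                       type = "SNP") {
  n <- length(pos)
  data.frame(arm = rep_len(arm, n), pos = pos,
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             outgroup_allele = rep_len(outgroup, n),
             variant_type = rep_len(type, n),
             freq_R = rep_len(freq_R, n), freq_C = rep_len(freq_C, n),
             depth_R = rep_len(depth_R, n), depth_C = rep_len(depth_C, n),
             stringsAsFactors = FALSE)
}

# an all-passing quality table for a site table
make_quality <- function(sites, central_q = 36L, flank_q = 32L) {
  use_R <- sites$freq_R >= sites$freq_C
  data.frame(arm = sites$arm, pos = sites$pos,
             central_q = central_q,
             flank_qs = paste(rep(flank_q, 22L), collapse = ","),
             depth = ifelse(use_R, sites$depth_R, sites$depth_C),
             variant_freq = ifelse(use_R, sites$freq_R, sites$freq_C),
             stringsAsFactors = FALSE)
}

# one single-interval gene with a given CDS sequence planted in a random arm
plant_gene <- function(cds_seq, strand = "+", arm = "2L", start = 101L,
                       pad = 100L, seed = 1L) {
  set.seed(seed)
  L <- nchar(cds_seq) + 2L * pad
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  chars[start:(start + nchar(cds_seq) - 1L)] <-
    strsplit(cds_seq, "")[[1]]
  list(
    reference = stats::setNames(paste(chars, collapse = ""), arm),
    genes = data.frame(gene_id = "g1", arm = arm, strand = strand,
                       start = start, end = start + nchar(cds_seq) - 1L,
                       stringsAsFactors = FALSE)
  )
}

# effects table that reproduces a published per-arm count layout:
# for each (arm, category): n_variants rows hitting n_genes_hit distinct genes
make_counts_effects <- function(layout) {
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    nv <- layout$n_variants[i]; ng <- layout$n_genes_hit[i]
    if (nv == 0) return(NULL)
    gid <- if (ng > 0) {
      sprintf("FBgn_%s_%s_%d", layout$arm[i], layout$category[i],
              c(seq_len(ng), rep(1L, nv - ng)))
    } else rep(NA_character_, nv)
    data.frame(arm = layout$arm[i], strain_category = layout$category[i],
               gene_id = gid, effect = "missense", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# the published per-arm amino-acid-change layout (Table-2-like counts)
published_burden_layout <- function() {
  data.frame(
    arm = rep(c("2L", "2R", "3L", "3R", "4", "X", "U"), each = 3),
    category = rep(c("R_only", "both", "C_only"), times = 7),
    n_variants = c(136, 327, 130, 198, 278, 161, 6, 0, 25,
                   23, 39, 43, 3, 0, 0, 37, 52, 46, 2, 0, 0),
    n_genes_hit = c(42, 59, 51, 78, 51, 75, 1, 0, 4,
                    4, 6, 23, 2, 0, 0, 11, 11, 18, 0, 0, 0),
    stringsAsFactors = FALSE)
}

# brute-force translation of a CDS string via Biostrings (oracle path)
translate_cds <- function(cds, strand) {
  s <- Biostrings::DNAString(cds)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(Biostrings::translate(s, if.fuzzy.codon = "X"))
}
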