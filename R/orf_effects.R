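# Amino-acid-change annotation of coding variants, strain categorization,
# per-arm gene burden tables and consensus ORF extraction.

#' Published per-arm gene totals
#'
#' Total annotated genes per Drosophila melanogaster chromosome arm
#' (FlyBase annotation release 5.44), the denominators used to normalize
#' per-arm gene-burden counts into percentages. Supply your own totals for
#' any other annotation release.
#'
#' @return named integer vector of gene counts per arm
#' @export
dmel_arm_gene_totals <- function() {
  c("2L" = 2939L, "2R" = 3238L, "3L" = 2950L, "3R" = 3702L,
    "4" = 90L, "X" = 2381L)
}

# reference as a named character vector of arm sequences, whatever container
# it arrived in
as_ref_chars <- function(reference) {
  nm <- names(reference)
  x <- as.character(reference)
  names(x) <- nm
  if (is.null(names(x))) stopf("reference sequences must be named")
  x
}

# concatenated CDS of a gene in genome (+) orientation, with per-interval
# offsets for coordinate mapping
cds_layout <- function(gene, ref_seq) {
  gene <- gene[order(gene$start), , drop = FALSE]
  widths <- gene$end - gene$start + 1L
  offs <- c(0L, cumsum(widths))[seq_len(nrow(gene))]
  seq <- paste(substring(ref_seq, gene$start, gene$end), collapse = "")
  list(gene = gene, offsets = offs, seq = seq, width = sum(widths),
       strand = gene$strand[1])
}

# genome position -> 1-based position in the (+)-orientation CDS string
cds_coord <- function(layout, pos) {
  g <- layout$gene
  i <- which(pos >= g$start & pos <= g$end)
  if (!length(i)) return(NA_integer_)
  as.integer(layout$offsets[i[1]] + (pos - g$start[i[1]]) + 1L)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Annotate coding variants with their amino-acid effect
#'
#' SNPs are translated on the coding strand with the standard genetic code;
#' indels are classified by length modulo 3 (`frameshift` vs
#' `inframe_indel`), SNPs as `synonymous`, `missense`, `stop_gain` or
#' `stop_loss`. Variants must overlap a CDS interval of some gene; variants
#' outside every CDS are dropped (count reported via the `n_noncoding`
#' attribute). Genes whose CDS length is not divisible by 3 are annotated
#' best-effort on the 5' frame, with a warning.
#'
#' @param variants data.frame with `arm`, `pos`, `ref`, `alt`
#'   (anchor-base indel representation); extra columns are carried through
#' @param genes gene models as from [read_gff_cds()] / `sim_study$genes`
#' @param reference named [Biostrings::DNAStringSet] or character vector of
#'   arm sequences
#' @return data.frame with `gene_id`, `effect`, `codon_change`, `aa_change`,
#'   `cds_pos` appended to the overlapping variants; attribute
#'   `n_noncoding` counts dropped variants
#' @export
annotate_effects <- function(variants, genes, reference) {
  ref_chr <- as_ref_chars(reference)

  gene_split <- split(genes, genes$gene_id)
  layouts <- lapply(gene_split, function(g) {
    if (!g$arm[1] %in% names(ref_chr)) {
      stopf("gene %s on arm %s absent from reference", g$gene_id[1], g$arm[1])
    }
    cds_layout(g, ref_chr[[g$arm[1]]])
  })
  bad_frame <- names(layouts)[vapply(layouts, function(l) l$width %% 3L != 0L,
                                     logical(1))]
  if (length(bad_frame)) {
    warning(sprintf("CDS length not divisible by 3 (best-effort frame): %s",
                    paste(bad_frame, collapse = ", ")), call. = FALSE)
  }

  # map each variant to the gene whose CDS contains it
  gene_arm <- vapply(gene_split, function(g) g$arm[1], character(1))
  hit <- rep(NA_character_, nrow(variants))
  for (gid in names(gene_split)) {
    g <- gene_split[[gid]]
    on <- which(variants$arm == gene_arm[[gid]] & is.na(hit))
    if (!length(on)) next
    inside <- vapply(on, function(i) {
      any(variants$pos[i] >= g$start & variants$pos[i] <= g$end)
    }, logical(1))
    hit[on[inside]] <- gid
  }
  coding <- which(!is.na(hit))
  out <- variants[coding, , drop = FALSE]
  out$gene_id <- hit[coding]
  n <- nrow(out)
  eff <- character(n); codon_ch <- rep(NA_character_, n)
  aa_ch <- rep(NA_character_, n); cpos <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    lay <- layouts[[out$gene_id[i]]]
    ref <- out$ref[i]; alt <- out$alt[i]
    if (nchar(ref) != nchar(alt)) {
      eff[i] <- if ((abs(nchar(ref) - nchar(alt)) %% 3L) != 0L)
        "frameshift" else "inframe_indel"
      next
    }
    cp <- cds_coord(lay, out$pos[i])
    cpos[i] <- cp
    # coding-strand coordinate and bases
    cp_cod <- if (lay$strand == "-") lay$width - cp + 1L else cp
    codon_idx <- ((cp_cod - 1L) %/% 3L)
    cod_start <- codon_idx * 3L + 1L
    within <- cp_cod - cod_start + 1L
    plus_codon_pos <- if (lay$strand == "-") {
      lay$width - (cod_start + 2L) + 1L  # start of codon on + strand
    } else cod_start
    ref_codon_plus <- substr(lay$seq, plus_codon_pos, plus_codon_pos + 2L)
    if (nchar(ref_codon_plus) < 3L) { eff[i] <- "missense"; next }
    ref_codon <- if (lay$strand == "-") revcomp(ref_codon_plus)
                 else ref_codon_plus
    alt_codon <- ref_codon
    alt_base <- if (lay$strand == "-") comp_base(alt) else alt
    substr(alt_codon, within, within) <- alt_base
    aa_ref <- translate_codon(ref_codon)
    aa_alt <- translate_codon(alt_codon)
    codon_ch[i] <- paste0(ref_codon, ">", alt_codon)
    aa_ch[i] <- paste0(aa_ref, ">", aa_alt)
    eff[i] <- if (identical(aa_ref, aa_alt)) "synonymous"
      else if (identical(aa_alt, "*")) "stop_gain"
      else if (identical(aa_ref, "*")) "stop_loss"
      else "missense"
  }
  out$effect <- eff
  out$codon_change <- codon_ch
  out$aa_change <- aa_ch
  out$cds_pos <- cpos
  rownames(out) <- NULL
  attr(out, "n_noncoding") <- nrow(variants) - n
  out
}

#' Assign each variant to a strain category from fixation states
#'
#' A strain "carries" the variant when it is fixed for the novel allele:
#' `R_only` (fixed novel in R, not in C), `both` (same novel allele fixed in
#' both), `C_only`; variants fixed novel in neither strain get `NA` and are
#' excluded from burden tables.
#'
#' @param state_R,state_C fixation states from [classify_fixation()]
#' @return character vector of categories
#' @export
categorize_by_strain <- function(state_R, state_C) {
  fr <- state_R == "fixed_novel"
  fc <- state_C == "fixed_novel"
  ifelse(fr & fc, "both",
         ifelse(fr, "R_only", ifelse(fc, "C_only", NA_character_)))
}

#' Per-arm gene burden tables
#'
#' Counts, per chromosome arm and strain category, the amino-acid-changing
#' variants and the distinct genes they hit, then normalizes gene counts by
#' the per-arm gene totals into percentages. A `Totals` row sums each
#' category. Synonymous variants are excluded.
#'
#' @param effects annotated variants from [annotate_effects()] with a
#'   `strain_category` column
#' @param arm_totals named vector of per-arm gene totals (denominators);
#'   defaults to [dmel_arm_gene_totals()]. Arms present in `effects` but
#'   absent here (other than excluded arms, e.g. `"U"`) are an error
#' @param exclude_arms arms excluded from the percentage table (still
#'   counted in the counts table, as published)
#' @return list with `counts` (long data.frame: `arm`, `category`,
#'   `n_variants`, `n_genes_hit`, incl. `Totals` rows) and `percent`
#'   (`arm`, `category`, `n_genes_hit`, `n_genes_total`, `pct` raw,
#'   `pct_label` at 2 significant figures)
#' @export
burden_tables <- function(effects, arm_totals = dmel_arm_gene_totals(),
                          exclude_arms = "U") {
  aa <- effects[!is.na(effects$strain_category) &
                  effects$effect != "synonymous", , drop = FALSE]
  counts_df <- burden_counts(aa)
  list(counts = counts_df,
       percent = burden_percentages(counts_df, arm_totals, exclude_arms))
}

burden_counts <- function(aa) {
  cats <- c("R_only", "both", "C_only")
  arms <- unique(aa$arm)
  grid <- expand.grid(arm = arms, category = cats, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- aa[aa$arm == grid$arm[i] & aa$strain_category == grid$category[i],
              , drop = FALSE]
    data.frame(arm = grid$arm[i], category = grid$category[i],
               n_variants = nrow(sub),
               n_genes_hit = length(unique(sub$gene_id[!is.na(sub$gene_id)])),
               stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, rows)
  totals <- do.call(rbind, lapply(cats, function(cc) {
    sub <- counts[counts$category == cc, , drop = FALSE]
    data.frame(arm = "Totals", category = cc,
               n_variants = sum(sub$n_variants),
               n_genes_hit = sum(sub$n_genes_hit), stringsAsFactors = FALSE)
  }))
  out <- rbind(counts, totals)
  rownames(out) <- NULL
  out
}

#' Burden percentages from gene-hit counts
#'
#' Normalizes per-arm gene-hit counts by per-arm gene totals. Percentages
#' are reported raw and formatted to 2 significant figures (the printed
#' convention of the tables this reproduces).
#'
#' @param counts data.frame with `arm`, `category`, `n_genes_hit` (and
#'   optionally `n_variants`); `Totals` rows are ignored here
#' @param arm_totals named vector of per-arm gene totals
#' @param exclude_arms arms dropped from the percentage table
#' @return data.frame with `arm`, `category`, `n_genes_hit`,
#'   `n_genes_total`, `pct`, `pct_label`
#' @export
burden_percentages <- function(counts, arm_totals = dmel_arm_gene_totals(),
                               exclude_arms = "U") {
  x <- counts[counts$arm != "Totals" & !(counts$arm %in% exclude_arms), ,
              drop = FALSE]
  missing_arms <- setdiff(unique(x$arm), names(arm_totals))
  if (length(missing_arms)) {
    stopf("arm(s) missing from arm_totals: %s",
          paste(missing_arms, collapse = ", "))
  }
  x$n_genes_total <- as.integer(arm_totals[x$arm])
  x$pct <- 100 * x$n_genes_hit / x$n_genes_total
  x$pct_label <- format_percent2(x$pct)
  rownames(x) <- NULL
  x
}

#' Extract per-strain consensus ORF sequences
#'
#' For each gene, applies the strain's fixed variants to the reference CDS
#' (on the coding strand) and returns the consensus coding sequences;
#' genes without variants return the reference CDS. Indels shift downstream
#' coordinates consistently (variants are applied right-to-left). Variants
#' whose reference spans overlap within one gene are an error listing the
#' conflicts.
#'
#' @param genes gene models (as from [read_gff_cds()])
#' @param reference named [Biostrings::DNAStringSet] or character vector
#' @param variants data.frame of the strain's fixed variants: `arm`, `pos`,
#'   `ref`, `alt`
#' @param gene_ids genes to extract; default: all genes in `genes`
#' @return [Biostrings::DNAStringSet] named by gene id
#' @export
extract_orf_consensus <- function(genes, reference, variants,
                                  gene_ids = NULL) {
  ref_chr <- as_ref_chars(reference)
  gene_split <- split(genes, genes$gene_id)
  if (!is.null(gene_ids)) gene_split <- gene_split[gene_ids]

  seqs <- vapply(gene_split, function(g) {
    lay <- cds_layout(g, ref_chr[[g$arm[1]]])
    v <- variants[variants$arm == g$arm[1], , drop = FALSE]
    if (nrow(v)) {
      v$cds_pos <- vapply(v$pos, function(p) cds_coord(lay, p), integer(1))
      v <- v[!is.na(v$cds_pos), , drop = FALSE]
    }
    s <- lay$seq
    if (nrow(v)) {
      v <- v[order(v$cds_pos), , drop = FALSE]
      span_end <- v$cds_pos + nchar(v$ref) - 1L
      if (nrow(v) > 1L && any(v$cds_pos[-1L] <= span_end[-nrow(v)])) {
        j <- which(v$cds_pos[-1L] <= span_end[-nrow(v)])[1]
        stopf("overlapping variants in gene %s: pos %d and %d",
              g$gene_id[1], v$pos[j], v$pos[j + 1L])
      }
      for (k in rev(seq_len(nrow(v)))) {
        cp <- v$cds_pos[k]
        have <- substr(s, cp, cp + nchar(v$ref[k]) - 1L)
        if (have != v$ref[k]) {
          stopf("reference mismatch at %s:%d in gene %s (expected %s, CDS has %s)",
                v$arm[k], v$pos[k], g$gene_id[1], v$ref[k], have)
        }
        s <- paste0(substr(s, 1L, cp - 1L), v$alt[k],
                    substr(s, cp + nchar(v$ref[k]), nchar(s)))
      }
    }
    if (lay$strand == "-") revcomp(s) else s
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}
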