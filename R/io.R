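# Readers/writers for the standard formats the pipeline touches.
#
# Coordinate convention: every position in this package is 1-based inclusive
# (the GFF/VCF convention). The only half-open conversion lives in
# write_bed()/read_bed().

#' Read a FASTA file into a sequence map
#'
#' @param path path to a FASTA file
#' @return a named [Biostrings::DNAStringSet], one entry per sequence
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  Biostrings::readDNAStringSet(path)
}

#' Write a sequence map to FASTA
#'
#' @param seqs named [Biostrings::DNAStringSet] or named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stopf("sequences must be named")
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read CDS gene models from a GFF3 file
#'
#' CDS features are grouped into gene models by their gene of origin
#' (via `Parent` transcript where present, else directly). For genes with
#' several transcripts the longest CDS is kept. Genes whose total CDS length
#' is not divisible by 3 are flagged in the `frame_ok` column (with a
#' warning), never silently dropped.
#'
#' @param path path to a GFF3 file with CDS features (1-based inclusive)
#' @return data.frame with one row per CDS interval: `gene_id`, `arm`,
#'   `strand`, `start`, `end`, `frame_ok`, ordered 5' to 3' in genome
#'   coordinates within each gene
#' @export
read_gff_cds <- function(path) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_cds <- !is.na(md$type) & md$type == "CDS"
  if (!any(is_cds)) stopf("no CDS features in %s", path)
  cds <- gr[is_cds]

  # map each CDS to a gene id: prefer its transcript's Parent, else its own
  # Parent, else its ID
  parent_of <- function(x) {
    p <- S4Vectors::mcols(x)$Parent
    vapply(as.list(p), function(v) if (length(v)) v[[1]] else NA_character_,
           character(1))
  }
  tx_id <- parent_of(cds)
  feats <- gr[!is_cds]
  feat_ids <- S4Vectors::mcols(feats)$ID
  feat_parent <- parent_of(feats)
  gene_of_tx <- stats::setNames(feat_parent, feat_ids)
  gene_id <- ifelse(!is.na(tx_id) & tx_id %in% names(gene_of_tx) &
                      !is.na(gene_of_tx[tx_id]),
                    gene_of_tx[tx_id], tx_id)
  gene_id[is.na(gene_id)] <- S4Vectors::mcols(cds)$ID[is.na(gene_id)]
  if (anyNA(gene_id)) stopf("CDS features without Parent or ID in %s", path)

  df <- data.frame(
    gene_id = unname(gene_id),
    tx_id = unname(ifelse(is.na(tx_id), gene_id, tx_id)),
    arm = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds),
    stringsAsFactors = FALSE
  )
  # longest CDS per gene when several transcripts are annotated
  tx_len <- tapply(df$end - df$start + 1, df$tx_id, sum)
  best_tx <- vapply(split(df$tx_id, df$gene_id), function(txs) {
    txs <- unique(txs)
    txs[which.max(tx_len[txs])]
  }, character(1))
  df <- df[df$tx_id %in% best_tx, , drop = FALSE]
  df$tx_id <- NULL
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  rownames(df) <- NULL

  len3 <- tapply(df$end - df$start + 1, df$gene_id, sum) %% 3 == 0
  df$frame_ok <- unname(len3[df$gene_id])
  if (!all(df$frame_ok)) {
    warning(sprintf("CDS length not divisible by 3 for: %s",
                    paste(names(len3)[!len3], collapse = ", ")),
            call. = FALSE)
  }
  df
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS features for each gene model.
#'
#' @param genes data.frame with `gene_id`, `arm`, `strand`, `start`, `end`
#'   (one row per CDS interval, 1-based inclusive)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gff_cds <- function(genes, path) {
  need <- c("gene_id", "arm", "strand", "start", "end")
  if (!all(need %in% names(genes))) {
    stopf("genes must have columns: %s", paste(need, collapse = ", "))
  }
  span <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], arm = g$arm[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  gr_gene <- GenomicRanges::GRanges(
    span$arm, IRanges::IRanges(span$start, span$end), strand = span$strand,
    type = "gene", ID = span$gene_id)
  gr_mrna <- GenomicRanges::GRanges(
    span$arm, IRanges::IRanges(span$start, span$end), strand = span$strand,
    type = "mRNA", ID = paste0(span$gene_id, ".t1"))
  S4Vectors::mcols(gr_mrna)$Parent <- as.character(span$gene_id)
  gr_cds <- GenomicRanges::GRanges(
    genes$arm, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, type = "CDS",
    ID = paste0(genes$gene_id, ".cds"), phase = 0L)
  S4Vectors::mcols(gr_cds)$Parent <- paste0(genes$gene_id, ".t1")
  gr <- c(gr_gene, gr_mrna, gr_cds)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write per-strain variant calls to a VCF v4.2 file
#'
#' One row per site with `AF` (pooled non-reference allele frequency) and
#' `DP` (read depth) INFO fields for the chosen strain.
#'
#' @param sites site table with columns `arm`, `pos`, `ref`, `alt` and
#'   per-strain `freq_R`/`freq_C`, `depth_R`/`depth_C` (or plain
#'   `freq`/`depth`)
#' @param path output path
#' @param strain `"R"` or `"C"`; ignored when `sites` has plain
#'   `freq`/`depth` columns
#' @return `path`, invisibly
#' @export
write_vcf <- function(sites, path, strain = c("R", "C")) {
  strain <- match.arg(strain)
  af <- sites[[paste0("freq_", strain)]] %||% sites$freq
  dp <- sites[[paste0("depth_", strain)]] %||% sites$depth
  if (is.null(af) || is.null(dp)) stopf("sites lack freq/depth columns")
  check_freq(af, "AF")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=poolsweep",
    sprintf("##INFO=<ID=AF,Number=A,Type=Float,Description=%s>",
            "\"Pooled non-reference allele frequency\""),
    sprintf("##INFO=<ID=DP,Number=1,Type=Integer,Description=%s>",
            "\"Pooled read depth\""),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(sites)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAF=%s;DP=%d",
                       sites$arm, as.integer(sites$pos), sites$ref, sites$alt,
                       format(af, trim = TRUE, scientific = FALSE),
                       as.integer(dp)), con)
  }
  invisible(path)
}

#' Read a per-strain pooled VCF into site-record fragments
#'
#' @param path VCF v4.2 file with AF and DP INFO fields
#' @return data.frame with `arm`, `pos`, `ref`, `alt`, `freq`, `depth`,
#'   `variant_type` (`"SNP"` or `"DIP"`)
#' @export
read_strain_vcf <- function(path) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)  # always an 8-col matrix
  if (!nrow(fix)) {
    return(data.frame(arm = character(), pos = integer(), ref = character(),
                      alt = character(), freq = numeric(), depth = integer(),
                      variant_type = character(), stringsAsFactors = FALSE))
  }
  af <- as.numeric(vcfR::extract.info(v, "AF"))
  dp <- as.integer(vcfR::extract.info(v, "DP"))
  if (anyNA(af) || anyNA(dp)) stopf("missing AF/DP INFO fields in %s", path)
  check_freq(af, "AF")
  bad <- grepl("[^ACGTN]", toupper(paste0(fix$REF, fix$ALT)))
  if (any(bad)) {
    stopf("non-ACGTN allele at line(s): %s",
          paste(utils::head(which(bad), 5), collapse = ", "))
  }
  data.frame(
    arm = fix$CHROM, pos = as.integer(fix$POS),
    ref = toupper(fix$REF), alt = toupper(fix$ALT),
    freq = af, depth = dp,
    variant_type = ifelse(nchar(fix$REF) == nchar(fix$ALT), "SNP", "DIP"),
    stringsAsFactors = FALSE
  )
}

#' Write/read plain tab-separated tables
#'
#' Thin, convention-fixing wrappers (no quoting, no row names, header kept)
#' so that `read_tsv(write_tsv(x))` round-trips records exactly.
#'
#' @param x data.frame
#' @param path file path
#' @return `write_tsv`: `path` invisibly; `read_tsv`: a data.frame
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stopf("TSV file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write 1-based inclusive intervals as BED (0-based half-open)
#'
#' @param x data.frame with `arm`, `start`, `end` (1-based inclusive); any
#'   further columns are appended as BED extra fields
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(x, path) {
  if (any(x$start < 1 | x$end < x$start)) stopf("invalid interval(s)")
  extra <- x[, setdiff(names(x), c("arm", "start", "end")), drop = FALSE]
  bed <- cbind(data.frame(chrom = x$arm, chromStart = x$start - 1L,
                          chromEnd = x$end, stringsAsFactors = FALSE), extra)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file back to 1-based inclusive intervals
#'
#' @param path BED path
#' @param col_names names for any extra columns beyond the first three
#' @return data.frame with `arm`, `start`, `end` (1-based inclusive) and any
#'   extra columns
#' @export
read_bed <- function(path, col_names = NULL) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(arm = x[[1]], start = x[[2]] + 1L, end = x[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(x) > 3) {
    extra <- x[, -(1:3), drop = FALSE]
    names(extra) <- col_names %||% paste0("V", seq_len(ncol(extra)))
    out <- cbind(out, extra)
  }
  out
}

#' Left-align an insertion/deletion against the reference
#'
#' VCF-style normalization: while the variant can be shifted one base left
#' (the last base of both alleles matches and a reference base precedes the
#' site), shift it. SNPs are returned unchanged.
#'
#' @param ref_seq reference chromosome sequence as a single character string
#' @param pos 1-based anchor position
#' @param ref,alt allele strings (anchor-base representation)
#' @return list with normalized `pos`, `ref`, `alt`
#' @export
left_align_indel <- function(ref_seq, pos, ref, alt) {
  if (nchar(ref) == nchar(alt)) return(list(pos = pos, ref = ref, alt = alt))
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (pos <= 1L) break
    if (substr(ref, lr, lr) != substr(alt, la, la)) break
    prev <- substr(ref_seq, pos - 1L, pos - 1L)
    ref <- paste0(prev, substr(ref, 1L, lr - 1L))
    alt <- paste0(prev, substr(alt, 1L, la - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}
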