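# Amino-acid-change annotation, strain categories, burden tables and
# consensus ORF extraction.

test_that("SNP effects follow the genetic code on either strand", {
  fx <- plant_gene("AAACCCGGG", strand = "+")
  # AAA -> GAA : K -> E missense at codon 1 position 1
  v <- data.frame(arm = "2L", pos = 101L, ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  eff <- annotate_effects(v, fx$genes, fx$reference)
  expect_identical(eff$effect, "missense")
  expect_identical(eff$aa_change, "K>E")
  expect_identical(eff$codon_change, "AAA>GAA")

  # CTG -> CTA : synonymous leucine
  fx2 <- plant_gene("CTGAAATAA", strand = "+")
  v2 <- data.frame(arm = "2L", pos = 103L, ref = "G", alt = "A",
                   stringsAsFactors = FALSE)
  eff2 <- annotate_effects(v2, fx2$genes, fx2$reference)
  expect_identical(eff2$effect, "synonymous")
  expect_identical(eff2$aa_change, "L>L")

  # minus strand: genome CAT|TTT -> coding AAA|ATG read 5'->3'; the genome
  # base paired with the codon-3 position of ATG is the C at gene start
  fx3 <- plant_gene("CATTTT", strand = "-")
  # genome T (pos 104, first T of TTT) pairs with coding A; T->C makes
  # coding AAA -> GAA? position: coding pos of genome 104 on '-' is
  # width - cds + 1 = 6 - 4 + 1 = 3, codon 1 position 3: AAA -> AAG (K>K)
  v3 <- data.frame(arm = "2L", pos = 104L, ref = "T", alt = "C",
                   stringsAsFactors = FALSE)
  eff3 <- annotate_effects(v3, fx3$genes, fx3$reference)
  expect_identical(eff3$codon_change, "AAA>AAG")
  expect_identical(eff3$effect, "synonymous")

  # stop gain: TAC -> TAA (pos 3 C->A on +)
  fx4 <- plant_gene("TACGGG", strand = "+")
  v4 <- data.frame(arm = "2L", pos = 103L, ref = "C", alt = "A",
                   stringsAsFactors = FALSE)
  expect_identical(annotate_effects(v4, fx4$genes, fx4$reference)$effect,
                   "stop_gain")
})

test_that("indels classify by length modulo 3 and non-coding variants drop", {
  fx <- plant_gene("ATGAAACCCGGGTTTTAA", strand = "+")
  v <- data.frame(arm = "2L",
                  pos = c(104L, 107L, 1L),
                  ref = c("AAA", "C", "A"),
                  alt = c("A", "CTTT", "T"),
                  stringsAsFactors = FALSE)
  eff <- annotate_effects(v, fx$genes, fx$reference)
  expect_identical(nrow(eff), 2L)              # the pos-1 variant is dropped
  expect_identical(attr(eff, "n_noncoding"), 1L)
  expect_identical(eff$effect, c("frameshift", "inframe_indel"))
})

test_that("effect calls agree with full CDS re-translation", {
  cfg <- sim_config(arm_names = c("2L", "2R"), genome_length = 3e4,
                    n_genes = 10, cds_fraction = 0.5, generations = 50,
                    mutation_rate = 8e-7, dip_fraction = 0, seed = 23)
  sim <- simulate_study(cfg)
  eff <- annotate_effects(sim$sites, sim$genes, sim$reference)
  expect_gt(nrow(eff), 10)
  ref_chr <- as.character(sim$reference)
  for (i in seq_len(nrow(eff))) {
    g <- sim$genes[sim$genes$gene_id == eff$gene_id[i], ]
    cds_ref <- substr(ref_chr[[g$arm]], g$start, g$end)
    mut_pos <- eff$pos[i] - g$start + 1L
    cds_alt <- cds_ref
    substr(cds_alt, mut_pos, mut_pos) <- eff$alt[i]
    prot_ref <- translate_cds(cds_ref, g$strand)
    prot_alt <- translate_cds(cds_alt, g$strand)
    if (eff$effect[i] == "synonymous") {
      expect_identical(prot_alt, prot_ref)
    } else {
      expect_false(identical(prot_alt, prot_ref))
      d <- which(strsplit(prot_ref, "")[[1]] != strsplit(prot_alt, "")[[1]])
      expect_identical(paste0(substr(prot_ref, d, d), ">",
                              substr(prot_alt, d, d)),
                       eff$aa_change[i])
    }
  }
})

test_that("strain categories follow the fixed-novel carrier rule", {
  expect_identical(categorize_by_strain("fixed_novel", "fixed_reference"),
                   "R_only")
  expect_identical(categorize_by_strain("fixed_novel", "fixed_novel"),
                   "both")
  expect_identical(categorize_by_strain("segregating", "fixed_novel"),
                   "C_only")
  expect_true(is.na(categorize_by_strain("segregating", "fixed_reference")))
})

test_that("published per-arm counts reproduce the published percentages", {
  layout <- published_burden_layout()
  eff <- make_counts_effects(layout)
  eff$strain_category <- factor(eff$strain_category,
                                levels = c("R_only", "both", "C_only"))
  eff$strain_category <- as.character(eff$strain_category)
  tabs <- burden_tables(eff, arm_totals = dmel_arm_gene_totals())

  cts <- tabs$counts
  tot <- cts[cts$arm == "Totals", ]
  expect_identical(tot$n_variants[tot$category == "R_only"], 405L)
  expect_identical(tot$n_variants[tot$category == "both"], 696L)
  expect_identical(tot$n_variants[tot$category == "C_only"], 405L)
  expect_identical(tot$n_genes_hit[tot$category == "R_only"], 138L)
  expect_identical(tot$n_genes_hit[tot$category == "C_only"], 171L)

  pct <- tabs$percent
  g <- function(arm, cat) pct$pct_label[pct$arm == arm & pct$category == cat]
  expect_equal(g("2R", "R_only"), 2.4)
  expect_equal(g("X", "C_only"), 0.76)
  expect_equal(g("2L", "R_only"), 1.4)
  expect_equal(g("2L", "both"), 2.0)
  expect_equal(g("X", "R_only"), 0.46)
  expect_equal(g("3R", "C_only"), 0.62)
  expect_equal(g("4", "R_only"), 2.2)
  # percentages recompute from the counts exactly
  expect_equal(pct$pct, 100 * pct$n_genes_hit / pct$n_genes_total)
  # the excluded unplaced arm stays out of the percentage table
  expect_false(any(pct$arm == "U"))
  # unknown arm in effects is an error
  expect_error(burden_percentages(
    data.frame(arm = "Y", category = "R_only", n_genes_hit = 1),
    dmel_arm_gene_totals()), "missing from arm_totals")
})

test_that("category partition covers every categorized variant", {
  layout <- published_burden_layout()
  eff <- make_counts_effects(layout)
  tabs <- burden_tables(eff)
  cts <- tabs$counts[tabs$counts$arm != "Totals", ]
  expect_identical(sum(cts$n_variants), nrow(eff))
})

test_that("consensus ORFs apply fixed variants faithfully", {
  fx <- plant_gene("ATGAAACCCGGGTTTTAA", strand = "+")
  genes <- fx$genes
  ref <- fx$reference

  # no variants: identical to the reference CDS
  none <- extract_orf_consensus(genes, ref,
                                data.frame(arm = character(), pos = integer(),
                                           ref = character(),
                                           alt = character()))
  expect_identical(as.character(none[["g1"]]), "ATGAAACCCGGGTTTTAA")

  # one SNP: exactly one mismatch
  one <- extract_orf_consensus(genes, ref,
                               data.frame(arm = "2L", pos = 104L, ref = "A",
                                          alt = "G"))
  s <- as.character(one[["g1"]])
  expect_identical(nchar(s), 18L)
  expect_identical(sum(strsplit(s, "")[[1]] !=
                         strsplit("ATGAAACCCGGGTTTTAA", "")[[1]]), 1L)

  # one 3 bp insertion: length + 3, downstream shifted consistently
  ins <- extract_orf_consensus(genes, ref,
                               data.frame(arm = "2L", pos = 106L, ref = "A",
                                          alt = "AGGG"))
  expect_identical(nchar(as.character(ins[["g1"]])), 21L)
  expect_identical(as.character(ins[["g1"]]), "ATGAAAGGGCCCGGGTTTTAA")

  # minus strand emits the coding strand
  fxm <- plant_gene("CATTTT", strand = "-")
  m <- extract_orf_consensus(fxm$genes, fxm$reference,
                             data.frame(arm = character(), pos = integer(),
                                        ref = character(), alt = character()))
  expect_identical(as.character(m[["g1"]]), "AAAATG")

  # overlapping variants are an error listing the conflict
  expect_error(extract_orf_consensus(
    genes, ref, data.frame(arm = "2L", pos = c(104L, 105L),
                           ref = c("AA", "AC"), alt = c("A", "A"))),
    "overlapping")
  # reference mismatch is an error
  expect_error(extract_orf_consensus(
    genes, ref, data.frame(arm = "2L", pos = 104L, ref = "T", alt = "G")),
    "mismatch")
})
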