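# End-to-end orchestration: simulate (or load) -> quality filter -> polarize
# -> divergence tests -> window scan -> ORF annotation -> summary report.

#' Run the full two-strain divergence pipeline
#'
#' Executes every stage on a synthetic study and collects the headline
#' quantities: shared/unique fixed-allele tallies, the strain-by-mutation-
#' type chi-square on amino-acid-changing ORF variants, the unique-allele
#' excess test, the windowed F_ST / d_xy scan with extreme-window count,
#' and the per-arm gene burden tables. Every summary number is re-derivable
#' from the returned stage outputs; nothing is computed only in the report
#' layer.
#'
#' @param config a [sim_config()]; its `seed` drives all randomness
#' @param fail_fraction fraction of sites given injected quality failures
#' @param fixation_threshold per-strain fixation threshold, see
#'   [classify_fixation()]
#' @param window,step,extreme_threshold window-scan settings
#' @param min_central_q,min_flank_q,min_depth,min_vaf filter thresholds
#' @param arm_totals per-arm gene totals for burden percentages; default:
#'   gene counts of the simulated annotation
#' @param out_dir if non-NULL, stage artifacts (FASTA/GFF3/VCF/TSV/BED,
#'   consensus ORFs, `summary.json`, `config.yaml`) are written here
#' @return object of class `pipeline_report`: list with `sim`, `quality`,
#'   `filter` (passed/rejected/tally), `polarized`, `tally`, `chi2_table`,
#'   `chi2`, `excess`, `scan`, `effects`, `burden`, `summary`
#' @export
run_pipeline <- function(config = sim_config(),
                         fail_fraction = 0.05,
                         fixation_threshold = 1.0,
                         window = 10000L, step = 1000L,
                         extreme_threshold = 0.8,
                         min_central_q = 20, min_flank_q = 15,
                         min_depth = 10, min_vaf = 0.10,
                         arm_totals = NULL,
                         out_dir = NULL) {
  log_stage <- function(fmt, ...) message(sprintf(paste0("[poolsweep] ", fmt),
                                                  ...))
  sim <- simulate_study(config)
  log_stage("simulate: %d candidate sites (%d truth rows)",
            nrow(sim$sites), nrow(sim$truth))

  quality <- write_quality_profiles(sim$sites, fail_fraction = fail_fraction)
  filt <- filter_sites(sim$sites, quality,
                       min_central_q = min_central_q,
                       min_flank_q = min_flank_q,
                       min_depth = min_depth, min_vaf = min_vaf)
  log_stage("filter: %d passed, %d rejected (%s)",
            nrow(filt$passed), nrow(filt$rejected),
            if (length(filt$tally))
              paste(names(filt$tally), filt$tally, collapse = "; ")
            else "none")

  pol <- polarize_sites(filt$passed, threshold = fixation_threshold)
  tally <- tally_shared_unique(pol)
  log_stage("polarize: shared %d, unique_R %d, unique_C %d",
            tally$fixed_shared, tally$unique_R, tally$unique_C)

  excess <- if (tally$unique_R + tally$unique_C > 0) {
    unique_excess_test(tally$unique_R, tally$unique_C)
  } else NULL

  # ORF effects on fixed variants, and the strain-by-type contingency test
  pol$strain_category <- categorize_by_strain(pol$state_R, pol$state_C)
  fixed <- pol[!is.na(pol$strain_category), , drop = FALSE]
  effects <- annotate_effects(fixed, sim$genes, sim$reference)
  aa_changing <- effects[effects$effect != "synonymous", , drop = FALSE]
  chi2_table <- orf_type_table(aa_changing)
  # desk-scale synthetic tables can be small; the asymptotic-approximation
  # warning is expected here and not actionable
  chi2 <- tryCatch(suppressWarnings(chi_square_2x2(chi2_table)),
                   error = function(e) list(statistic = NA_real_, df = 1L,
                                            p_value = NA_real_,
                                            note = conditionMessage(e)))
  log_stage("orf: %d coding fixed variants, %d amino-acid-changing",
            nrow(effects), nrow(aa_changing))

  arm_len <- stats::setNames(Biostrings::width(sim$reference),
                             names(sim$reference))
  scan <- scan_genome(filt$passed, arm_len, window = window, step = step,
                      extreme_threshold = extreme_threshold)
  log_stage("scan: %d windows, %d extreme", nrow(scan), sum(scan$extreme))

  totals <- arm_totals %||% table_to_named(table(sim$genes$arm))
  burden <- burden_tables(aa_changing, arm_totals = totals)

  summary <- list(
    n_sites = nrow(sim$sites),
    n_passed = nrow(filt$passed),
    n_rejected = nrow(filt$rejected),
    fixed_shared = tally$fixed_shared,
    unique_R = tally$unique_R,
    unique_C = tally$unique_C,
    difference = tally$difference,
    pct_new_divergent = tally$pct_new_divergent,
    pct_drift = tally$pct_drift,
    excess_p = if (is.null(excess)) NA_real_ else excess$p_value,
    chi2 = chi2$statistic,
    chi2_p = chi2$p_value,
    n_windows = nrow(scan),
    n_extreme_windows = sum(scan$extreme),
    mean_window_fst = mean(scan$fst, na.rm = TRUE),
    mean_window_dxy = mean(scan$dxy, na.rm = TRUE),
    n_aa_changing = nrow(aa_changing),
    seed = config$seed
  )

  res <- list(sim = sim, quality = quality, filter = filt, polarized = pol,
              tally = tally, chi2_table = chi2_table, chi2 = chi2,
              excess = excess, scan = scan, effects = effects,
              burden = burden, summary = summary)
  class(res) <- "pipeline_report"

  if (!is.null(out_dir)) write_report_bundle(res, out_dir)
  res
}

table_to_named <- function(tb) stats::setNames(as.integer(tb), names(tb))

# 2x2 strain-by-mutation-type table (novel vs reference-matching) over
# amino-acid-changing fixed ORF variants; a variant counts for a strain when
# that strain is fixed for it
orf_type_table <- function(aa_changing) {
  in_R <- aa_changing$strain_category %in% c("R_only", "both")
  in_C <- aa_changing$strain_category %in% c("C_only", "both")
  novel <- aa_changing$origin == "new"
  old <- aa_changing$origin == "old"
  matrix(c(sum(in_R & novel), sum(in_R & old),
           sum(in_C & novel), sum(in_C & old)),
         nrow = 2L, byrow = TRUE,
         dimnames = list(strain = c("R", "C"),
                         type = c("novel", "reference")))
}

write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_study(res$sim, out_dir)
  write_tsv(res$quality, file.path(out_dir, "quality_profiles.tsv"))
  write_tsv(res$polarized[, c("arm", "pos", "origin", "state_R", "state_C",
                              "bucket")],
            file.path(out_dir, "polarized.tsv"))
  write_bed(as.data.frame(res$scan)[, c("arm", "start", "end", "fst", "dxy",
                                        "n_snps", "extreme")],
            file.path(out_dir, "windows.bed"))
  write_tsv(res$effects, file.path(out_dir, "orf_effects.tsv"))
  write_tsv(res$burden$counts, file.path(out_dir, "burden_counts.tsv"))
  write_tsv(res$burden$percent, file.path(out_dir, "burden_percent.tsv"))
  for (strain in c("R", "C")) {
    v <- res$polarized[res$polarized[[paste0("state_", strain)]] ==
                         "fixed_novel", , drop = FALSE]
    cons <- extract_orf_consensus(res$sim$genes, res$sim$reference, v)
    write_fasta(cons, file.path(out_dir,
                                sprintf("consensus_orf_%s.fasta", strain)))
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- res$sim$config
  cfg_plain <- unclass(cfg)
  if (!is.null(cfg_plain$selected_loci)) {
    cfg_plain$selected_loci <- as.list(cfg_plain$selected_loci)
  }
  yaml::write_yaml(cfg_plain, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("Two-strain divergence pipeline report\n")
  cat(sprintf("  sites: %d candidates -> %d passed filter\n",
              s$n_sites, s$n_passed))
  cat(sprintf("  fixed alleles: shared %d | unique R %d | unique C %d (diff %d, %.2f%% of classified)\n",
              s$fixed_shared, s$unique_R, s$unique_C, s$difference,
              s$pct_new_divergent))
  if (!is.na(s$chi2)) {
    cat(sprintf("  strain x type chi-square: %.2f (df 1, p = %.3g)\n",
                s$chi2, s$chi2_p))
  } else {
    cat("  strain x type chi-square: undefined (zero marginal)\n")
  }
  cat(sprintf("  scan: %d windows, %d extreme (F_ST > %.2f), mean F_ST %.3f\n",
              s$n_windows, s$n_extreme_windows,
              attr(x$scan, "extreme_threshold"), s$mean_window_fst))
  cat(sprintf("  amino-acid-changing fixed ORF variants: %d\n",
              s$n_aa_changing))
  invisible(x)
}

#' @export
summary.pipeline_report <- function(object, ...) object$summary
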