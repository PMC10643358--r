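#' Run the full association pipeline
#'
#' Orchestrates marker QC, LD and the effective number of tests, phenotype
#' preparation (normality transform, correlations, BLUE-vs-per-season
#' modes), the GLM + Q association scan with effective-test Bonferroni
#' correction, LD-block grouping of MTAs into MTA-QTLs, stability
#' annotation, high-density multi-trait regions, the DH-covariate re-test,
#' and (when gene models and expression are supplied) the candidate-gene
#' report. Writes stage outputs when \code{out_dir} is given.
#'
#' @param panel A \code{\link{marker_panel}}.
#' @param pheno A \code{phenotype_table}.
#' @param q Accession x subpopulation covariate matrix.
#' @param genes Optional gene data frame.
#' @param expr Optional gene x tissue TPM matrix.
#' @param alpha Family-wise error rate (default 0.05).
#' @param max_missing,min_maf QC thresholds.
#' @param min_overlap Minimum pair overlap for r2.
#' @param r2_block LD-block walk threshold (default 0.3).
#' @param min_traits High-density region threshold (default 4).
#' @param retest_alpha DH re-test significance (default 0.05).
#' @param stable_min_env Environments needed for a stable QTL (default 2).
#' @param blue_threshold Season-correlation threshold for BLUE mode.
#' @param tpm_min,target_tissues Expression-filter settings.
#' @param min_n Minimum accessions per marker test.
#' @param decay_span,decay_max_pairs LOESS decay settings.
#' @param seed Seed for the decay-curve subsample.
#' @param out_dir Optional output directory.
#' @return List with all stage outputs plus \code{manifest} (named counts:
#'   markers in/retained, n_eff, threshold, MTAs, distinct markers,
#'   MTA-QTLs, regions before/after the DH re-test, genes, expressed
#'   genes).
#' @export
run_pipeline <- function(panel, pheno, q, genes = NULL, expr = NULL,
                         alpha = 0.05, max_missing = 0.10, min_maf = 0.05,
                         min_overlap = 20, r2_block = 0.3, min_traits = 4,
                         retest_alpha = 0.05, stable_min_env = 2,
                         blue_threshold = 0.5, tpm_min = 0.5,
                         target_tissues = NULL, min_n = 30,
                         decay_span = 0.5, decay_max_pairs = 200000,
                         seed = 1L, out_dir = NULL) {
  params <- list(alpha = alpha, max_missing = max_missing, min_maf = min_maf,
                 r2_block = r2_block, min_traits = min_traits,
                 retest_alpha = retest_alpha, tpm_min = tpm_min, seed = seed)

  qc <- marker_qc(panel, max_missing, min_maf)
  panel_qc <- qc$panel

  ld <- pairwise_r2(panel_qc, min_overlap)
  decay <- tryCatch(ld_decay(ld, span = decay_span,
                             max_pairs = decay_max_pairs, seed = seed),
                    error = function(e) NULL)
  n_eff <- as.integer(effective_tests(panel_qc))

  pheno <- normality_transform(pheno)
  correlations <- trait_correlations(pheno)
  blues <- estimate_blues(pheno, threshold = blue_threshold,
                          correlations = correlations)

  scan <- association_scan(panel_qc, pheno, q, blues, min_n = min_n)
  threshold <- bonferroni_threshold(alpha, n_eff)
  mtas <- significant_mtas(scan, threshold, n_eff)

  grouped <- group_mtas(mtas, panel_qc, r2_min = r2_block,
                        min_overlap = min_overlap)
  stability <- stable_qtls(grouped, min_env = stable_min_env)
  regions <- high_density_regions(grouped, min_traits = min_traits)
  n_regions_before <- nrow(regions)

  retest <- NULL
  if ("DH" %in% pheno$trait && nrow(regions) > 0) {
    dhb <- blues$blues[blues$blues$trait == "DH", ]
    dh_values <- if (nrow(dhb))
      stats::setNames(dhb$value, dhb$accession)
    else {
      dm <- stats::aggregate(value ~ accession,
                             pheno[pheno$trait == "DH", ], mean, na.rm = TRUE)
      stats::setNames(dm$value, dm$accession)
    }
    retest <- dh_retest(regions, grouped, panel_qc, pheno, dh_values,
                        blues = blues, retest_alpha = retest_alpha,
                        min_traits = min_traits)
    regions <- retest$regions
  }
  surviving <- regions[regions$status %in% c("retained", "shrunk", "untested"), ,
                       drop = FALSE]

  genes_report <- NULL
  if (!is.null(genes) && !is.null(expr) && nrow(surviving) > 0) {
    tt <- if (is.null(target_tissues)) colnames(expr) else target_tissues
    genes_report <- candidate_report(surviving, genes, expr, grouped$mtas,
                                     tpm_min = tpm_min, target_tissues = tt)
  }

  manifest <- list(
    markers_input = length(panel$marker_ids),
    markers_retained = length(panel_qc$marker_ids),
    n_eff = n_eff,
    threshold = threshold,
    n_mtas = nrow(mtas),
    n_distinct_markers = length(unique(mtas$marker_id)),
    n_mta_qtls = nrow(grouped$qtls),
    n_regions_before_dh = n_regions_before,
    n_regions_after_dh = sum(regions$status %in% c("retained", "shrunk")),
    mean_r2 = ld$summary$overall$mean_r2,
    half_decay_distance_bp = if (is.null(decay)) NA_real_
    else decay$half_decay_distance_bp,
    total_genes = if (is.null(genes_report)) NA_integer_
    else sum(genes_report$summary$total_genes),
    expressed_genes = if (is.null(genes_report)) NA_integer_
    else sum(genes_report$summary$expressed_genes))

  res <- list(qc = qc$report, ld = ld, decay = decay, n_eff = n_eff,
              pheno = pheno, correlations = correlations, blues = blues,
              scan = scan, threshold = threshold, mtas = mtas,
              qtls = grouped$qtls, mtas_grouped = grouped$mtas,
              stability = stability, regions = regions,
              retest = if (is.null(retest)) NULL else retest$retests,
              genes_report = genes_report, manifest = manifest,
              params = params)

  if (!is.null(out_dir)) {
    write_outputs(list(mtas = grouped$mtas, qtls = grouped$qtls,
                       regions = regions, scan = scan),
                  out_dir, params)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
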