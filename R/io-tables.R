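#' Read a long-format phenotype CSV
#'
#' Expects columns accession, season, trait, value. Rows whose accession is
#' absent from the panel are dropped and counted; duplicate
#' (accession, season, trait) rows are fatal.
#'
#' @param path CSV path.
#' @param panel Optional \code{\link{marker_panel}} to join against.
#' @return A \code{phenotype_table} data frame with attributes
#'   \code{transform_log} (character) and \code{join_report} (list).
#' @export
read_phenotypes <- function(path, panel = NULL) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("accession", "season", "trait", "value")
  if (!all(need %in% names(d)))
    stop("phenotype CSV must have columns ", paste(need, collapse = ", "))
  key <- paste(d$accession, d$season, d$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (accession, season, trait) rows: ",
         paste(utils::head(which(duplicated(key) | duplicated(key, fromLast = TRUE)), 10),
               collapse = ", "))
  dropped <- 0L
  if (!is.null(panel)) {
    keep <- d$accession %in% panel$accession_ids
    if (!any(keep)) stop("no phenotype accessions match the panel")
    dropped <- sum(!keep)
    d <- d[keep, , drop = FALSE]
  }
  rownames(d) <- NULL
  class(d) <- c("phenotype_table", "data.frame")
  attr(d, "transform_log") <- character()
  attr(d, "join_report") <- list(rows_kept = nrow(d), rows_dropped = dropped)
  d
}

#' Write a phenotype table as CSV
#' @param pheno A \code{phenotype_table}.
#' @param path Output path.
#' @param params Provenance parameters.
#' @return Invisibly, \code{path}.
#' @export
write_phenotypes <- function(pheno, path, params = list()) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(provenance_line(params), con)
  utils::write.csv(as.data.frame(pheno)[, c("accession", "season", "trait", "value")],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a population-structure Q matrix CSV
#'
#' First column \code{accession}, remaining columns subpopulation covariates.
#' Rows are aligned (inner join) with the panel's accessions when given.
#'
#' @param path CSV path.
#' @param panel Optional panel to align against.
#' @return Numeric matrix with accession row names.
#' @export
read_qmatrix <- function(path, panel = NULL) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (names(d)[1] != "accession")
    stop("Q matrix CSV must start with an 'accession' column")
  q <- as.matrix(d[, -1, drop = FALSE])
  rownames(q) <- d$accession
  if (!is.null(panel)) {
    common <- intersect(panel$accession_ids, rownames(q))
    if (length(common) == 0) stop("no Q-matrix accessions match the panel")
    q <- q[panel$accession_ids[panel$accession_ids %in% common], , drop = FALSE]
  }
  q
}

#' Write a Q matrix as CSV
#' @param q Accession x subpopulation matrix.
#' @param path Output path.
#' @param params Provenance parameters.
#' @return Invisibly, \code{path}.
#' @export
write_qmatrix <- function(q, path, params = list()) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(provenance_line(params), con)
  utils::write.csv(data.frame(accession = rownames(q), q, check.names = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps \code{gene} features only (1-based inclusive coordinates, as in
#' GFF3). A file without gene features yields an empty gene set with a
#' warning.
#'
#' @param path GFF3 path.
#' @return Data frame gene_id, chrom, start_bp, end_bp, strand, annotation.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & gr$type == "gene"]
  if (length(gr) == 0) {
    warning("no 'gene' features in ", path)
    return(data.frame(gene_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      strand = character(), annotation = character()))
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  ann <- if (!is.null(gr$description)) as.character(gr$description)
  else if (!is.null(gr$Note)) vapply(gr$Note, function(x)
    paste(x, collapse = "; "), "")
  else rep("", length(gr))
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             annotation = ann)
}

#' Write gene models as GFF3
#' @param genes Gene data frame (see \code{\link{read_gff3}}).
#' @param path Output path.
#' @param params Provenance parameters.
#' @return Invisibly, \code{path}.
#' @export
write_gff3 <- function(genes, path, params = list()) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c("##gff-version 3",
               provenance_line(params)), con)
  if (nrow(genes)) {
    attrs <- paste0("ID=", genes$gene_id, ";description=", genes$annotation)
    writeLines(paste(genes$chrom, "landqtl", "gene", genes$start_bp,
                     genes$end_bp, ".", genes$strand, ".", attrs,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a gene-by-tissue TPM expression TSV
#'
#' First column \code{gene_id}; remaining columns tissue/stage TPM values.
#' Columns outside the declared vocabulary are dropped with a warning.
#'
#' @param path TSV path.
#' @param tissue_vocab Optional character vector of accepted column names.
#' @return Numeric matrix, genes in rows.
#' @export
read_expression <- function(path, tissue_vocab = NULL) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (names(d)[1] != "gene_id")
    stop("expression TSV must start with a 'gene_id' column")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  if (!is.null(tissue_vocab)) {
    unknown <- setdiff(colnames(m), tissue_vocab)
    if (length(unknown)) {
      warning("ignoring unknown tissue columns: ",
              paste(unknown, collapse = ", "))
      m <- m[, intersect(colnames(m), tissue_vocab), drop = FALSE]
    }
  }
  if (any(m < 0)) stop("negative TPM values")
  m
}

#' Write an expression matrix as TSV
#' @param expr Gene x tissue TPM matrix.
#' @param path Output path.
#' @param params Provenance parameters.
#' @return Invisibly, \code{path}.
#' @export
write_expression <- function(expr, path, params = list()) {
  write_tsv_prov(data.frame(gene_id = rownames(expr), expr,
                            check.names = FALSE), path, params)
}

#' Write a synthetic-truth table as JSON
#' @param truth Truth list (\code{causal}, \code{confounders}).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write pipeline result tables
#'
#' Emits the standard result files into a directory: significant-MTA TSV,
#' MTA-QTL TSV and BED (0-based half-open), region report TSV and JSON, and
#' a Manhattan-ready TSV of the full scan. Empty inputs produce headers-only
#' files.
#'
#' @param results List with any of \code{mtas}, \code{qtls}, \code{regions},
#'   \code{scan} (as produced by the gwas/qtl modules).
#' @param out_dir Output directory (created if needed).
#' @param params Provenance parameters echoed in every header.
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(results, out_dir, params = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  written <- character()
  emit <- function(df, cols, name) {
    if (is.null(df) || nrow(df) == 0)
      df <- as.data.frame(stats::setNames(
        rep(list(vector(mode = "character", 0)), length(cols)), cols))
    p <- file.path(out_dir, name)
    write_tsv_prov(df[, intersect(cols, names(df)), drop = FALSE], p, params)
    written <<- c(written, p)
  }
  if (!is.null(results$mtas))
    emit(results$mtas,
         c("marker_id", "chrom", "pos_bp", "trait", "environment", "p_raw",
           "p_bonferroni", "pve", "effect", "n_used"), "mtas.tsv")
  if (!is.null(results$qtls)) {
    emit(results$qtls,
         c("qtl_id", "chrom", "start_bp", "end_bp", "n_mtas", "base_traits"),
         "mta_qtls.tsv")
    bed <- file.path(out_dir, "mta_qtls.bed")
    con <- file(bed, "wt")
    writeLines(provenance_line(params), con)
    if (nrow(results$qtls))
      writeLines(paste(results$qtls$chrom,
                       format(results$qtls$start_bp - 1, scientific = FALSE,
                              trim = TRUE),
                       format(results$qtls$end_bp, scientific = FALSE,
                              trim = TRUE),
                       results$qtls$qtl_id, sep = "\t"), con)
    close(con)
    written <- c(written, bed)
  }
  if (!is.null(results$regions)) {
    emit(results$regions,
         c("region_id", "chrom", "start_bp", "end_bp", "n_traits",
           "base_traits", "status"), "regions.tsv")
    rj <- file.path(out_dir, "regions.json")
    jsonlite::write_json(results$regions, rj, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, rj)
  }
  if (!is.null(results$scan))
    emit(transform(results$scan, neg_log10_p = -log10(p_raw)),
         c("marker_id", "chrom", "pos_bp", "trait", "environment",
           "p_raw", "neg_log10_p", "p_bonferroni"), "manhattan.tsv")
  invisible(written)
}
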