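genes_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start_bp, end = genes$end_bp),
    gene_id = genes$gene_id)
}

#' Genes overlapping a region
#'
#' All genes overlapping the region interval by at least one base pair
#' (1-based inclusive coordinates on both sides), sorted by start. A
#' chromosome name present in the region but absent from the gene set is
#' fatal, with both name tables in the message.
#'
#' @param genes Gene data frame (gene_id, chrom, start_bp, end_bp, strand,
#'   annotation).
#' @param region A list or one-row data frame with chrom, start_bp, end_bp.
#' @return The overlapping rows of \code{genes}, sorted by start.
#' @export
genes_in_region <- function(genes, region) {
  if (nrow(genes) == 0) return(genes)
  if (!region$chrom %in% genes$chrom)
    stop("chromosome ", region$chrom, " absent from gene set (gene ",
         "chromosomes: ", paste(unique(genes$chrom), collapse = ", "), ")")
  gr <- genes_granges(genes)
  q <- GenomicRanges::GRanges(region$chrom,
                              IRanges::IRanges(region$start_bp,
                                               region$end_bp))
  hits <- GenomicRanges::findOverlaps(q, gr)
  sel <- genes[S4Vectors::subjectHits(hits), , drop = FALSE]
  sel <- sel[order(sel$start_bp), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Closest gene to a marker position
#'
#' Minimal distance from the marker position to each gene interval on the
#' same chromosome (0 when the marker lies inside the gene). Ties are
#' broken by smaller gene start, then lexicographic gene id.
#'
#' @param genes Gene data frame.
#' @param chrom Marker chromosome.
#' @param pos_bp Marker position (1-based).
#' @return List with \code{gene} (one-row data frame or NULL when the
#'   chromosome holds no genes) and \code{distance_bp}.
#' @export
closest_gene <- function(genes, chrom, pos_bp) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(list(gene = NULL, distance_bp = NA_real_))
  d <- pmax(0, pmax(g$start_bp - pos_bp, pos_bp - g$end_bp))
  ord <- order(d, g$start_bp, g$gene_id)
  best <- g[ord[1], , drop = FALSE]
  rownames(best) <- NULL
  list(gene = best, distance_bp = d[ord[1]])
}

#' Expression filter on target tissues
#'
#' Keeps a gene when its maximum TPM over the configured target
#' tissue/stage columns is at least \code{tpm_min} (boundary inclusive:
#' genes that do not reach the threshold are removed). Genes absent from
#' the expression matrix are dropped and counted separately.
#'
#' @param genes Gene data frame (the region subset).
#' @param expr Gene x tissue TPM matrix.
#' @param tpm_min Threshold in TPM (default 0.5).
#' @param target_tissues Character vector of tissue/stage columns; must be
#'   non-empty and present in \code{expr}.
#' @return List with \code{kept} (gene rows plus max_tpm column, descending
#'   max TPM), \code{n_no_data} (genes without expression rows).
#' @export
expression_filter <- function(genes, expr, tpm_min = 0.5,
                              target_tissues = colnames(expr)) {
  if (length(target_tissues) == 0) stop("empty target tissue set")
  missing_cols <- setdiff(target_tissues, colnames(expr))
  if (length(missing_cols))
    stop("target tissues absent from expression matrix: ",
         paste(missing_cols, collapse = ", "))
  present <- genes$gene_id %in% rownames(expr)
  n_no_data <- sum(!present)
  g <- genes[present, , drop = FALSE]
  if (nrow(g) == 0)
    return(list(kept = cbind(g, max_tpm = numeric(0)),
                n_no_data = n_no_data))
  mx <- apply(expr[g$gene_id, target_tissues, drop = FALSE], 1, max)
  g$max_tpm <- unname(mx)
  kept <- g[g$max_tpm >= tpm_min, , drop = FALSE]
  kept <- kept[order(-kept$max_tpm, kept$gene_id), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, n_no_data = n_no_data)
}

#' Candidate-gene report per region
#'
#' For each region: total genes inside, genes passing the expression
#' filter, the gene closest to the region's most significant MTA (smallest
#' raw p, then largest absolute effect, then smallest position), and the
#' candidate list sorted by maximum target-tissue TPM.
#'
#' @param regions Region data frame.
#' @param genes Gene data frame.
#' @param expr Gene x tissue TPM matrix.
#' @param mtas MTA data frame with qtl_id assignments
#'   (\code{\link{group_mtas}}'s \code{mtas}).
#' @param tpm_min,target_tissues Passed to \code{\link{expression_filter}}.
#' @return List with \code{summary} (data frame region_id, total_genes,
#'   expressed_genes, closest_gene_id, closest_gene_annotation,
#'   closest_distance_bp) and \code{candidates} (per-region list of kept
#'   gene data frames).
#' @export
candidate_report <- function(regions, genes, expr, mtas, tpm_min = 0.5,
                             target_tissues = colnames(expr)) {
  rows <- list(); cands <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    inside <- genes_in_region(genes, reg)
    ef <- expression_filter(inside, expr, tpm_min, target_tissues)
    qids <- strsplit(reg$member_qtls, ",")[[1]]
    mm <- mtas[mtas$qtl_id %in% qids, , drop = FALSE]
    cg_id <- cg_ann <- NA_character_; cg_d <- NA_real_
    if (nrow(mm)) {
      ord <- order(mm$p_raw, -abs(mm$effect), mm$pos_bp)
      top <- mm[ord[1], ]
      cg <- closest_gene(genes, top$chrom, top$pos_bp)
      if (!is.null(cg$gene)) {
        cg_id <- cg$gene$gene_id
        cg_ann <- cg$gene$annotation
        cg_d <- cg$distance_bp
      }
    }
    rows[[i]] <- data.frame(region_id = reg$region_id,
                            total_genes = nrow(inside),
                            expressed_genes = nrow(ef$kept),
                            no_data_genes = ef$n_no_data,
                            closest_gene_id = cg_id,
                            closest_gene_annotation = cg_ann,
                            closest_distance_bp = cg_d)
    cands[[reg$region_id]] <- ef$kept
  }
  list(summary = if (length(rows))
    do.call(rbind, c(rows, make.row.names = FALSE))
    else data.frame(region_id = character(), total_genes = integer(),
                    expressed_genes = integer(), no_data_genes = integer(),
                    closest_gene_id = character(),
                    closest_gene_annotation = character(),
                    closest_distance_bp = numeric()),
    candidates = cands)
}
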