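#' Simulate gene models and a TPM expression matrix
#'
#' Tiles non-overlapping gene intervals along each chromosome of a panel at a
#' target density and draws a transcripts-per-million (TPM) expression matrix
#' from a two-component mixture: an "expressed" fraction whose maximum TPM
#' over the target tissues is at least 0.5, and a silent fraction below 0.5
#' everywhere. The truth labels let downstream expression-filter results be
#' checked exactly.
#'
#' @param panel A \code{\link{marker_panel}} supplying chromosome names (and,
#'   by default, lengths as the maximum mapped position).
#' @param genes_per_mb Mean gene density per megabase (Poisson counts).
#' @param tissues Character vector of tissue/stage column names.
#' @param seed Integer seed.
#' @param expressed_fraction Fraction of genes drawn from the expressed
#'   component (set 0 for an all-silent annotation).
#' @param chrom_lengths_bp Optional named lengths; default max mapped pos.
#' @return List with \code{genes} (data frame gene_id, chrom, start_bp,
#'   end_bp, strand, annotation; 1-based inclusive), \code{expr} (gene x
#'   tissue TPM matrix) and \code{truth} (data frame gene_id, expressed).
#' @export
simulate_annotation <- function(panel, genes_per_mb = 10,
                                tissues = c("shoot_apical_meristem", "spike",
                                            "anther", "grain", "endosperm"),
                                seed = 1L,
                                expressed_fraction = 0.6,
                                chrom_lengths_bp = NULL) {
  stopifnot(inherits(panel, "marker_panel"), length(tissues) >= 1)
  if (genes_per_mb <= 0) stop("genes_per_mb must be > 0")
  chroms <- unique(panel$map$chrom)
  if (is.null(chrom_lengths_bp))
    chrom_lengths_bp <- vapply(chroms, function(ch)
      max(panel$map$pos_bp[panel$map$chrom == ch]), numeric(1))
  local_seed(seed, {
    gl <- list()
    for (ch in chroms) {
      len <- chrom_lengths_bp[[ch]]
      n_g <- stats::rpois(1, genes_per_mb * len / 1e6)
      if (n_g == 0) next
      starts <- sort(sample.int(max(1, len - 5000L), n_g))
      lens <- sample(2000:5000, n_g, replace = TRUE)
      ends <- pmin(starts + lens - 1L, len)
      if (n_g > 1)  # truncate at the next gene to keep intervals disjoint
        ends[-n_g] <- pmin(ends[-n_g], starts[-1] - 1L)
      ok <- ends >= starts
      gl[[ch]] <- data.frame(
        chrom = ch, start_bp = starts[ok], end_bp = ends[ok],
        strand = sample(c("+", "-"), sum(ok), replace = TRUE))
    }
    genes <- do.call(rbind, gl)
    if (is.null(genes))
      genes <- data.frame(chrom = character(), start_bp = integer(),
                          end_bp = integer(), strand = character())
    rownames(genes) <- NULL
    n <- nrow(genes)
    genes$gene_id <- sprintf("GENE%05d", seq_len(n))
    funs <- c("protein kinase", "MYB transcription factor",
              "E3 ubiquitin-protein ligase", "F-box family protein",
              "sugar transporter", "unknown function")
    genes$annotation <- if (n) sample(funs, n, replace = TRUE) else character()
    genes <- genes[, c("gene_id", "chrom", "start_bp", "end_bp",
                       "strand", "annotation")]

    expressed <- stats::runif(n) < expressed_fraction
    expr <- matrix(stats::runif(n * length(tissues), 0, 0.4), nrow = n,
                   dimnames = list(genes$gene_id, tissues))
    if (any(expressed)) {
      # expressed genes exceed 0.5 TPM in at least one random target tissue
      hit <- sample(length(tissues), sum(expressed), replace = TRUE)
      expr[cbind(which(expressed), hit)] <-
        0.5 + stats::rlnorm(sum(expressed), meanlog = 1, sdlog = 1)
    }
    list(genes = genes, expr = expr,
         truth = data.frame(gene_id = genes$gene_id, expressed = expressed))
  })
}
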