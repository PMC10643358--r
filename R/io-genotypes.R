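#' Read an inbred-coded genotype panel
#'
#' Reads genotypes from VCF or from a HapMap-style TSV into a
#' \code{\link{marker_panel}}. VCF GT fields are mapped 0/0 (or haploid 0) to
#' 0, 1/1 (or 1) to 1 and ./. to missing; heterozygous calls are handled per
#' \code{het_policy} (default: set missing with one warning per site, the
#' convention for a selfing crop). Markers without a genomic position are
#' assigned the pseudo-chromosome \code{"U"} in file order with synthetic
#' 1 Mb spacing. Multi-allelic sites and duplicate marker ids are fatal.
#'
#' @param path File path.
#' @param format \code{"vcf"} or \code{"hapmap_tsv"}.
#' @param het_policy \code{"missing"} (default) or \code{"reject"}.
#' @return A \code{\link{marker_panel}}.
#' @export
read_genotypes <- function(path, format = c("vcf", "hapmap_tsv"),
                           het_policy = c("missing", "reject")) {
  format <- match.arg(format)
  het_policy <- match.arg(het_policy)
  if (format == "vcf") read_genotypes_vcf(path, het_policy)
  else read_genotypes_hapmap(path, het_policy)
}

read_genotypes_vcf <- function(path, het_policy) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic sites not supported: ",
         paste(fix[multi, "ID"], collapse = ", "))
  ids <- fix[, "ID"]
  if (any(is.na(ids) | ids == "."))
    ids[is.na(ids) | ids == "."] <-
      paste0(fix[is.na(ids) | ids == ".", "CHROM"], "_",
             fix[is.na(ids) | ids == ".", "POS"])
  if (anyDuplicated(ids))
    stop("duplicate marker id: ", ids[duplicated(ids)][1])
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- gsub("\\|", "/", gt)
  calls <- matrix(NA_integer_, nrow(code), ncol(code), dimnames = dimnames(code))
  calls[code %in% c("0", "0/0")] <- 0L
  calls[code %in% c("1", "1/1")] <- 1L
  het <- code %in% c("0/1", "1/0")
  if (any(het)) {
    het_sites <- unique(ids[which(matrix(het, nrow(code)), arr.ind = TRUE)[, 1]])
    if (het_policy == "reject")
      stop("heterozygous calls at sites: ", paste(het_sites, collapse = ", "))
    for (s in het_sites)
      warning("heterozygous calls at site ", s, " set to missing",
              call. = FALSE)
  }
  chrom <- fix[, "CHROM"]; pos <- suppressWarnings(as.integer(fix[, "POS"]))
  unplaced <- is.na(pos) | pos <= 0 | is.na(chrom) | chrom %in% c(".", "U")
  chrom[unplaced] <- "U"
  pos[unplaced] <- seq_len(sum(unplaced)) * 1000000L
  map <- data.frame(marker_id = ids, chrom = chrom, pos_bp = pos)
  rownames(calls) <- ids
  marker_panel(t(calls), map)
}

read_genotypes_hapmap <- function(path, het_policy) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- c("marker_id", "alleles", "chrom", "pos")
  if (!all(need %in% names(d)))
    stop("hapmap TSV must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(d$marker_id))
    stop("duplicate marker id: ", d$marker_id[duplicated(d$marker_id)][1])
  acc_cols <- setdiff(names(d), need)
  raw <- as.matrix(d[, acc_cols, drop = FALSE])
  calls <- matrix(NA_integer_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  calls[raw %in% c("0", 0)] <- 0L
  calls[raw %in% c("1", 1)] <- 1L
  het <- raw %in% c("H", "0/1", "1/0")
  if (any(het)) {
    het_sites <- unique(d$marker_id[which(matrix(het, nrow(raw)),
                                          arr.ind = TRUE)[, 1]])
    if (het_policy == "reject")
      stop("heterozygous calls at sites: ", paste(het_sites, collapse = ", "))
    for (s in het_sites)
      warning("heterozygous calls at site ", s, " set to missing",
              call. = FALSE)
  }
  chrom <- as.character(d$chrom)
  pos <- suppressWarnings(as.integer(d$pos))
  unplaced <- is.na(pos) | pos <= 0 | is.na(chrom) | chrom %in% c("", ".", "U", "NA")
  chrom[unplaced] <- "U"
  pos[unplaced] <- seq_len(sum(unplaced)) * 1000000L
  rownames(calls) <- d$marker_id
  marker_panel(t(calls),
               data.frame(marker_id = d$marker_id, chrom = chrom, pos_bp = pos))
}

#' Write a panel as a haploid-GT VCF
#'
#' @param panel A \code{\link{marker_panel}}.
#' @param path Output path.
#' @param params Named list echoed into the provenance header.
#' @return Invisibly, \code{path}.
#' @export
write_genotypes_vcf <- function(panel, path, params = list()) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=", sub("^# ", "", provenance_line(params))),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$accession_ids),
                     collapse = "\t")), con)
  gt <- t(panel$calls)
  gt_chr <- matrix(".", nrow(gt), ncol(gt))
  gt_chr[!is.na(gt) & gt == 0] <- "0"
  gt_chr[!is.na(gt) & gt == 1] <- "1"
  lines <- paste(panel$map$chrom, panel$map$pos_bp, panel$map$marker_id,
                 "A", "G", ".", "PASS", ".", "GT",
                 apply(gt_chr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write a panel as a HapMap-style TSV
#'
#' @inheritParams write_genotypes_vcf
#' @return Invisibly, \code{path}.
#' @export
write_genotypes_hapmap <- function(panel, path, params = list()) {
  d <- data.frame(marker_id = panel$map$marker_id, alleles = "A/G",
                  chrom = panel$map$chrom, pos = panel$map$pos_bp,
                  check.names = FALSE)
  d <- cbind(d, as.data.frame(t(panel$calls), check.names = FALSE))
  write_tsv_prov(d, path, params)
}
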