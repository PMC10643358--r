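#' Marker panel container
#'
#' Bundles an inbred-coded genotype matrix (accessions x markers, values 0, 1
#' or \code{NA} for missing) with its physical map. Markers are stored sorted
#' by chromosome (in \code{chrom_order}) and base-pair position; ties keep the
#' incoming order. Unplaced markers live on the pseudo-chromosome \code{"U"}.
#'
#' @param calls Integer or numeric matrix, accessions in rows, markers in
#'   columns, entries in \{0, 1, NA\}. Row names are accession ids, column
#'   names marker ids.
#' @param map Data frame with columns \code{marker_id}, \code{chrom},
#'   \code{pos_bp} (1-based), one row per marker.
#' @param chrom_order Optional character vector fixing chromosome display
#'   order; defaults to order of first appearance, with \code{"U"} last.
#' @return An object of class \code{marker_panel} with elements \code{calls},
#'   \code{map}, \code{accession_ids}, \code{marker_ids}, \code{chrom_order}.
#' @export
marker_panel <- function(calls, map, chrom_order = NULL) {
  calls <- as.matrix(calls)
  stopifnot(is.data.frame(map),
            all(c("marker_id", "chrom", "pos_bp") %in% names(map)))
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.integer(map$pos_bp)
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker ids: ",
         paste(unique(map$marker_id[duplicated(map$marker_id)]), collapse = ", "))
  if (ncol(calls) != nrow(map))
    stop("calls has ", ncol(calls), " columns but map has ", nrow(map), " rows")
  if (is.null(colnames(calls))) colnames(calls) <- map$marker_id
  if (!identical(colnames(calls), map$marker_id))
    calls <- calls[, map$marker_id, drop = FALSE]
  bad <- calls[!is.na(calls) & calls != 0 & calls != 1]
  if (length(bad) > 0)
    stop("calls must be coded 0/1/NA; found ", paste(unique(bad), collapse = ", "))
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("acc%03d", seq_len(nrow(calls)))
  if (any(!is.na(map$pos_bp) & map$pos_bp < 1))
    stop("pos_bp must be >= 1")

  if (is.null(chrom_order)) {
    chrom_order <- unique(map$chrom)
    if ("U" %in% chrom_order)
      chrom_order <- c(setdiff(chrom_order, "U"), "U")
  }
  if (!all(map$chrom %in% chrom_order))
    stop("map chromosomes missing from chrom_order: ",
         paste(setdiff(map$chrom, chrom_order), collapse = ", "))

  ord <- order(match(map$chrom, chrom_order), map$pos_bp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  calls <- calls[, map$marker_id, drop = FALSE]

  structure(list(calls = calls, map = map,
                 accession_ids = rownames(calls),
                 marker_ids = map$marker_id,
                 chrom_order = chrom_order),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  miss <- mean(is.na(x$calls))
  cat("marker_panel: ", length(x$accession_ids), " accessions x ",
      length(x$marker_ids), " markers on ",
      length(unique(x$map$chrom)), " chromosomes (",
      sprintf("%.1f%%", 100 * miss), " missing)\n", sep = "")
  invisible(x)
}

#' @export
dim.marker_panel <- function(x) dim(x$calls)

# Subset a panel to a marker-id set, preserving map order.
panel_subset_markers <- function(panel, marker_ids) {
  keep <- panel$map$marker_id %in% marker_ids
  marker_panel(panel$calls[, panel$map$marker_id[keep], drop = FALSE],
               panel$map[keep, , drop = FALSE],
               chrom_order = panel$chrom_order)
}

# Minor allele frequency per marker from non-missing 0/1 calls.
panel_maf <- function(panel) {
  p <- colMeans(panel$calls, na.rm = TRUE)
  pmin(p, 1 - p)
}
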