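#' Marker quality control
#'
#' Removes, in this order: (1) duplicate allelic profiles (call vectors
#' identical on shared non-missing entries with identical missing patterns;
#' the first marker in map order is kept), (2) markers with a missing-data
#' fraction strictly above \code{max_missing}, (3) markers with minor allele
#' frequency strictly below \code{min_maf} (computed on non-missing calls).
#'
#' @param panel A \code{\link{marker_panel}}.
#' @param max_missing Maximum tolerated missing fraction (boundary kept).
#' @param min_maf Minimum MAF (boundary kept).
#' @return List with \code{panel} (filtered) and \code{report} (counts per
#'   filter and retained ids).
#' @export
marker_qc <- function(panel, max_missing = 0.10, min_maf = 0.05) {
  stopifnot(inherits(panel, "marker_panel"))
  calls <- panel$calls
  ids <- panel$map$marker_id

  key <- apply(calls, 2, function(x) paste(ifelse(is.na(x), ".", x),
                                           collapse = ""))
  dup <- duplicated(key)
  removed_dup <- ids[dup]

  keep1 <- !dup
  miss_frac <- colMeans(is.na(calls))
  over_missing <- keep1 & miss_frac > max_missing
  removed_missing <- ids[over_missing]

  keep2 <- keep1 & !over_missing
  p <- colMeans(calls, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  low_maf <- keep2 & maf < min_maf
  removed_maf <- ids[low_maf]

  keep <- keep2 & !low_maf
  if (!any(keep))
    stop("all markers removed by QC (duplicates: ", length(removed_dup),
         ", missing: ", length(removed_missing),
         ", MAF: ", length(removed_maf), ")")
  report <- list(n_input = length(ids),
                 removed = list(duplicate_profile = removed_dup,
                                missing_gt_threshold = removed_missing,
                                maf_lt_threshold = removed_maf,
                                unmapped = character()),
                 counts = c(duplicate_profile = length(removed_dup),
                            missing_gt_threshold = length(removed_missing),
                            maf_lt_threshold = length(removed_maf),
                            unmapped = 0L),
                 retained = ids[keep],
                 max_missing = max_missing, min_maf = min_maf)
  list(panel = panel_subset_markers(panel, ids[keep]), report = report)
}

#' Pairwise within-chromosome linkage disequilibrium (r2)
#'
#' For every same-chromosome marker pair with at least \code{min_overlap}
#' jointly non-missing accessions, r2 is the squared Pearson correlation of
#' the inbred 0/1 call vectors (equal to D^2 / (pA(1-pA) pB(1-pB)) under
#' this coding). Significance uses the chi-square approximation
#' n r2 ~ chi^2 with 1 df. Pairs below \code{min_overlap} are emitted with
#' r2 = NA and excluded from summaries.
#'
#' @param panel A QC-passed \code{\link{marker_panel}}.
#' @param min_overlap Minimum jointly non-missing accessions (default 20).
#' @return Object of class \code{ld_result}: list with \code{pairs} (data
#'   frame chrom, marker_i, marker_j, distance_bp, r2, n, p) and
#'   \code{summary} (per-chromosome and genome-wide mean r2, percent of
#'   pairs significant at p < 0.001, pair counts).
#' @export
pairwise_r2 <- function(panel, min_overlap = 20) {
  stopifnot(inherits(panel, "marker_panel"))
  out <- list()
  for (ch in unique(panel$map$chrom)) {
    sel <- panel$map$chrom == ch
    if (sum(sel) < 2) next
    ids <- panel$map$marker_id[sel]
    pos <- panel$map$pos_bp[sel]
    x <- panel$calls[, ids, drop = FALSE]
    r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    obs <- crossprod(!is.na(x))
    iu <- which(upper.tri(r), arr.ind = TRUE)
    r2 <- r[iu]^2
    n <- obs[iu]
    r2[n < min_overlap] <- NA_real_
    p <- ifelse(is.na(r2), NA_real_,
                stats::pchisq(n * r2, df = 1, lower.tail = FALSE))
    out[[ch]] <- data.frame(chrom = ch,
                            marker_i = ids[iu[, 1]], marker_j = ids[iu[, 2]],
                            distance_bp = abs(pos[iu[, 2]] - pos[iu[, 1]]),
                            r2 = r2, n = as.integer(n), p = p)
  }
  pairs <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(chrom = character(), marker_i = character(),
                  marker_j = character(), distance_bp = integer(),
                  r2 = numeric(), n = integer(), p = numeric())
  summ <- function(d) data.frame(
    n_pairs = sum(!is.na(d$r2)),
    mean_r2 = mean(d$r2, na.rm = TRUE),
    pct_significant = 100 * mean(d$p[!is.na(d$p)] < 0.001))
  per_chrom <- do.call(rbind, lapply(split(pairs, pairs$chrom), summ))
  per_chrom <- cbind(chrom = rownames(per_chrom), per_chrom)
  rownames(per_chrom) <- NULL
  structure(list(pairs = pairs,
                 summary = list(per_chrom = per_chrom,
                                overall = summ(pairs)),
                 min_overlap = min_overlap),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat("ld_result: ", nrow(x$pairs), " same-chromosome pairs, mean r2 = ",
      sprintf("%.4f", x$summary$overall$mean_r2), ", ",
      sprintf("%.1f%%", x$summary$overall$pct_significant),
      " significant at p < 0.001\n", sep = "")
  invisible(x)
}

#' LOESS LD-decay curve and half-decay distance
#'
#' Pools valid pairs genome-wide (subsampled to \code{max_pairs} under
#' \code{seed}), fits a LOESS curve of r2 on physical distance, clamps
#' fitted values to [0, 1], and reports the half-decay point: half the
#' fitted value at the minimum observed distance, and the first distance at
#' which the fitted curve crosses below it (linear interpolation on the
#' evaluation grid; \code{NA} if the curve never crosses).
#'
#' @param ld An \code{ld_result} (or its \code{pairs} data frame).
#' @param span LOESS span (default 0.5).
#' @param max_pairs Subsample cap for the fit (default 200000).
#' @param seed Seed for the subsample.
#' @param grid_n Number of grid points for curve evaluation.
#' @return Object of class \code{ld_decay_fit}: list with \code{curve}
#'   (data frame distance_bp, r2_fit), \code{half_decay_r2},
#'   \code{half_decay_distance_bp} (NA when undefined), \code{span},
#'   \code{n_pairs_used}.
#' @export
ld_decay <- function(ld, span = 0.5, max_pairs = 200000, seed = 1L,
                     grid_n = 512) {
  pairs <- if (inherits(ld, "ld_result")) ld$pairs else ld
  d <- pairs[!is.na(pairs$r2), c("distance_bp", "r2")]
  if (nrow(d) < 100) stop("need >= 100 valid pairs for a decay fit, have ",
                          nrow(d))
  if (nrow(d) > max_pairs)
    d <- local_seed(seed, d[sample.int(nrow(d), max_pairs), ])
  fit <- stats::loess(r2 ~ distance_bp, data = d, span = span,
                      degree = 1, family = "gaussian",
                      control = stats::loess.control(
                        statistics = "approximate",
                        trace.hat = "approximate"))
  grid <- seq(min(d$distance_bp), max(d$distance_bp), length.out = grid_n)
  yhat <- pmin(1, pmax(0, stats::predict(fit, newdata =
                                           data.frame(distance_bp = grid))))
  half_r2 <- yhat[1] / 2
  half_dist <- NA_real_
  below <- which(yhat < half_r2)
  if (length(below)) {
    j <- below[1]
    if (j == 1) half_dist <- grid[1]
    else {
      # linear interpolation between grid[j-1] and grid[j]
      f <- (yhat[j - 1] - half_r2) / (yhat[j - 1] - yhat[j])
      half_dist <- grid[j - 1] + f * (grid[j] - grid[j - 1])
    }
  }
  structure(list(curve = data.frame(distance_bp = grid, r2_fit = yhat),
                 half_decay_r2 = half_r2,
                 half_decay_distance_bp = half_dist,
                 loess_span = span, n_pairs_used = nrow(d)),
            class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat("ld_decay_fit: half-decay r2 = ", sprintf("%.4f", x$half_decay_r2),
      " at ", if (is.na(x$half_decay_distance_bp)) "no crossing"
      else sprintf("%.3f Mb", x$half_decay_distance_bp / 1e6),
      " (span ", x$loess_span, ", ", x$n_pairs_used, " pairs)\n", sep = "")
  invisible(x)
}

#' Effective number of independent tests
#'
#' Within each chromosome, markers are grouped into classes by the
#' transitive closure of pairwise r2 = 1 (tolerance \code{1 - tol} to absorb
#' floating-point noise; r2 on pairwise-complete accessions). The effective
#' number of tests is the total number of classes across chromosomes;
#' markers with no computable pair count as singletons. This is the divisor
#' used for Bonferroni correction.
#'
#' @param panel A QC-passed \code{\link{marker_panel}}.
#' @param tol Tolerance below 1 treated as r2 = 1 (default 1e-9).
#' @return Integer count of independent tests; attribute \code{classes}
#'   holds the per-marker class id.
#' @export
effective_tests <- function(panel, tol = 1e-9) {
  stopifnot(inherits(panel, "marker_panel"))
  total <- 0L
  class_id <- stats::setNames(integer(length(panel$marker_ids)),
                              panel$marker_ids)
  offset <- 0L
  for (ch in unique(panel$map$chrom)) {
    ids <- panel$map$marker_id[panel$map$chrom == ch]
    m <- length(ids)
    parent <- seq_len(m)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (m > 1) {
      x <- panel$calls[, ids, drop = FALSE]
      r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
      iu <- which(upper.tri(r) & !is.na(r) & r^2 >= 1 - tol, arr.ind = TRUE)
      for (k in seq_len(nrow(iu))) {
        a <- find(iu[k, 1]); b <- find(iu[k, 2])
        if (a != b) parent[b] <- a
      }
    }
    roots <- vapply(seq_len(m), find, integer(1))
    class_id[ids] <- offset + match(roots, unique(roots))
    n_classes <- length(unique(roots))
    offset <- offset + n_classes
    total <- total + n_classes
  }
  structure(total, classes = class_id)
}

#' Percent reduction from markers to independent tests
#'
#' The marker-redundancy summary 100 (n_markers - n_eff) / n_markers,
#' reported to one decimal as conventionally printed.
#'
#' @param n_markers Number of QC-passing markers.
#' @param n_eff Effective number of independent tests.
#' @return Percent reduction (numeric).
#' @export
test_reduction_percent <- function(n_markers, n_eff) {
  stopifnot(n_markers >= 1, n_eff >= 0, n_eff <= n_markers)
  100 * (n_markers - n_eff) / n_markers
}
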