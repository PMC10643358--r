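# Build the covariate design [intercept, Q columns], dropping collinear
# columns (e.g. the redundant one-hot column) with a warning when the drop
# is not the expected one-hot redundancy.
covariate_design <- function(q, accessions) {
  z <- cbind(`(Intercept)` = 1, q[accessions, , drop = FALSE])
  qr_z <- qr(z)
  if (qr_z$rank < ncol(z)) {
    keep <- qr_z$pivot[seq_len(qr_z$rank)]
    z <- z[, sort(keep), drop = FALSE]
  }
  z
}

#' Single-marker GLM association scan with structure covariates
#'
#' Per marker, ordinary least squares of the phenotype on
#' [intercept, Q columns, marker 0/1] over accessions with non-missing
#' genotype and phenotype. The marker p-value is the partial F-test
#' (equivalently squared t) for the marker term; the effect is the marker
#' coefficient (phenotype units, allele 1 vs allele 0); PVE is the
#' incremental R-squared of the full model over the covariates-only model on
#' the same accession subset. Markers monomorphic on the subset, or with
#' fewer than \code{min_n} usable accessions, are skipped with a reason.
#'
#' @param panel A QC-passed \code{\link{marker_panel}}.
#' @param y Named numeric vector of phenotype values (names = accessions),
#'   one trait-environment cell.
#' @param q Accession x subpopulation covariate matrix (one column is
#'   dropped automatically if collinear with the intercept); \code{NULL}
#'   scans without structure correction.
#' @param min_n Minimum accessions per marker test (default 30).
#' @return Data frame marker_id, chrom, pos_bp, p_raw, effect, pve, n_used,
#'   skipped (NA or reason).
#' @export
glm_scan <- function(panel, y, q = NULL, min_n = 30) {
  stopifnot(inherits(panel, "marker_panel"))
  acc <- intersect(panel$accession_ids, names(y))
  if (length(acc) == 0) stop("no accessions shared between panel and phenotype")
  yv <- y[acc]
  z_full <- if (is.null(q)) matrix(1, length(acc), 1,
                                   dimnames = list(acc, "(Intercept)"))
  else covariate_design(q, acc)
  calls <- panel$calls[acc, , drop = FALSE]

  m <- length(panel$marker_ids)
  p_raw <- effect <- pve <- rep(NA_real_, m)
  n_used <- integer(m)
  skipped <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    x <- calls[, j]
    ok <- !is.na(x) & !is.na(yv)
    n <- sum(ok)
    n_used[j] <- n
    if (n < min_n) { skipped[j] <- "min_n"; next }
    xs <- x[ok]
    if (length(unique(xs)) < 2) { skipped[j] <- "monomorphic"; next }
    zs <- z_full[ok, , drop = FALSE]
    ys <- yv[ok]
    fit0 <- stats::lm.fit(zs, ys)
    fit1 <- stats::lm.fit(cbind(zs, marker = xs), ys)
    rss0 <- sum(fit0$residuals^2)
    rss1 <- sum(fit1$residuals^2)
    df_res <- n - fit1$rank
    if (df_res < 1) { skipped[j] <- "min_n"; next }
    tss <- sum((ys - mean(ys))^2)
    if (tss == 0) { skipped[j] <- "constant_phenotype"; next }
    if (rss1 <= .Machine$double.eps * tss) {
      p_raw[j] <- .Machine$double.xmin
    } else {
      fstat <- (rss0 - rss1) / (rss1 / df_res)
      p_raw[j] <- stats::pf(fstat, 1, df_res, lower.tail = FALSE)
    }
    effect[j] <- fit1$coefficients["marker"]
    pve[j] <- max(0, (rss0 - rss1) / tss)
  }
  data.frame(marker_id = panel$map$marker_id, chrom = panel$map$chrom,
             pos_bp = panel$map$pos_bp, p_raw = p_raw, effect = effect,
             pve = pve, n_used = n_used, skipped = skipped)
}

#' Scan every trait-environment cell
#'
#' BLUE-mode traits (per \code{\link{estimate_blues}}) are scanned once on
#' their BLUEs (environment \code{"BLUE"}); per-season traits are scanned
#' season by season.
#'
#' @param panel,q As in \code{\link{glm_scan}}.
#' @param pheno A \code{phenotype_table}.
#' @param blues Output of \code{\link{estimate_blues}}; computed if missing.
#' @param min_n Passed to \code{\link{glm_scan}}.
#' @return Data frame: one row per marker x trait x environment, columns of
#'   \code{\link{glm_scan}} plus trait and environment.
#' @export
association_scan <- function(panel, pheno, q, blues = NULL, min_n = 30) {
  if (is.null(blues)) blues <- estimate_blues(pheno)
  out <- list()
  for (i in seq_len(nrow(blues$modes))) {
    tr <- blues$modes$trait[i]
    if (blues$modes$mode[i] == "blue") {
      b <- blues$blues[blues$blues$trait == tr, ]
      yv <- stats::setNames(b$value, b$accession)
      sc <- glm_scan(panel, yv, q, min_n)
      sc$trait <- tr; sc$environment <- "BLUE"
      out[[length(out) + 1L]] <- sc
    } else {
      for (s in unique(pheno$season[pheno$trait == tr])) {
        d <- pheno[pheno$trait == tr & pheno$season == s, ]
        yv <- stats::setNames(d$value, d$accession)
        sc <- glm_scan(panel, yv, q, min_n)
        sc$trait <- tr; sc$environment <- s
        out[[length(out) + 1L]] <- sc
      }
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Bonferroni threshold from the effective number of tests
#'
#' The genome-wide significance threshold alpha / n_eff, where n_eff is the
#' effective number of independent tests (\code{\link{effective_tests}}).
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_eff Effective number of independent tests (>= 1).
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_eff) {
  if (any(n_eff < 1)) stop("n_eff must be >= 1")
  alpha / n_eff
}

#' Bonferroni-corrected p-value
#' @param p Raw p-value(s).
#' @param n_eff Effective number of independent tests.
#' @return \code{min(1, p * n_eff)} elementwise.
#' @export
bonferroni_p <- function(p, n_eff) pmin(1, p * n_eff)

#' Select significant marker-trait associations
#'
#' Keeps scan rows with \code{p_raw <= threshold}, one MTA per
#' (marker, trait, environment), and attaches Bonferroni-corrected
#' p-values. The number of distinct markers is reported separately since
#' one marker can associate with several traits.
#'
#' @param scan Output of \code{\link{association_scan}} (or
#'   \code{\link{glm_scan}} with trait/environment columns added).
#' @param threshold Significance threshold on the raw p
#'   (\code{\link{bonferroni_threshold}}).
#' @param n_eff Effective number of tests used for the corrected p.
#' @return Data frame of MTAs (adds p_bonferroni), with attributes
#'   \code{n_mtas} and \code{n_distinct_markers}.
#' @export
significant_mtas <- function(scan, threshold, n_eff) {
  keep <- !is.na(scan$p_raw) & scan$p_raw <= threshold
  mtas <- scan[keep, , drop = FALSE]
  mtas$p_bonferroni <- bonferroni_p(mtas$p_raw, n_eff)
  rownames(mtas) <- NULL
  attr(mtas, "n_mtas") <- nrow(mtas)
  attr(mtas, "n_distinct_markers") <- length(unique(mtas$marker_id))
  mtas
}
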