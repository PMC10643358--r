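#' Simulate structured inbred genotypes with distance-decaying LD
#'
#' Draws a biallelic, inbred-coded \{0,1\} genotype panel for a structured
#' population. Ancestral allele frequencies are Uniform(0.1, 0.9) per marker;
#' each subpopulation's frequency is drawn from the Balding-Nichols
#' distribution Beta(p0(1-F)/F, (1-p0)(1-F)/F) at the configured FST. Along
#' each chromosome an accession copies its previous marker's allele with
#' probability \code{ld_rho} and otherwise draws afresh from its
#' subpopulation frequency, giving monotone distance decay of LD. Marker
#' positions are sorted Uniform over the chromosome length. A fraction
#' \code{missing_rate} of calls is masked at random.
#'
#' @param config A \code{\link{synth_config}}.
#' @return A list with \code{panel} (a \code{\link{marker_panel}}),
#'   \code{q} (accession x subpopulation one-hot indicator matrix; drop one
#'   column when using it as a regression covariate), and \code{subpop}
#'   (integer assignment per accession).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(config$seed, {
    n <- config$n_accessions
    k <- config$n_subpops
    fst <- config$fst
    rho <- config$ld_rho
    chroms <- names(config$chrom_lengths_bp)
    m_per <- config$n_markers_per_chrom

    subpop <- sort(rep_len(seq_len(k), n))
    acc_ids <- sprintf("acc%03d", seq_len(n))

    maps <- list(); calls <- list()
    for (ci in seq_along(chroms)) {
      m <- m_per
      pos <- sort(sample.int(config$chrom_lengths_bp[ci], m))
      p0 <- stats::runif(m, 0.1, 0.9)
      # subpop frequencies: k x m
      if (fst > 0) {
        a <- p0 * (1 - fst) / fst
        b <- (1 - p0) * (1 - fst) / fst
        pk <- matrix(stats::rbeta(k * m, rep(a, each = k), rep(b, each = k)),
                     nrow = k)
      } else {
        pk <- matrix(rep(p0, each = k), nrow = k)
      }
      pmat <- pk[subpop, , drop = FALSE]          # n x m per-accession freqs
      fresh <- matrix(stats::runif(n * m) < pmat, n, m)  # fresh draws
      g <- matrix(0L, n, m)
      g[, 1] <- fresh[, 1]
      if (m > 1) {
        copy <- matrix(stats::runif(n * (m - 1)) < rho, n, m - 1)
        for (j in 2:m)
          g[, j] <- ifelse(copy[, j - 1], g[, j - 1], fresh[, j])
      }
      colnames(g) <- sprintf("%s_m%04d", chroms[ci], seq_len(m))
      maps[[ci]] <- data.frame(marker_id = colnames(g),
                               chrom = chroms[ci], pos_bp = pos)
      calls[[ci]] <- g
    }
    calls <- do.call(cbind, calls)
    map <- do.call(rbind, maps)
    rownames(calls) <- acc_ids
    mode(calls) <- "integer"
    if (config$missing_rate > 0) {
      mask <- stats::runif(length(calls)) < config$missing_rate
      calls[mask] <- NA_integer_
    }
    q <- matrix(0L, n, k,
                dimnames = list(acc_ids, paste0("pop", seq_len(k))))
    q[cbind(seq_len(n), subpop)] <- 1L
    list(panel = marker_panel(calls, map, chrom_order = chroms),
         q = q, subpop = subpop)
  })
}
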