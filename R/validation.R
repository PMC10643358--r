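#' End-to-end recovery suite on synthetic panels with planted QTLs
#'
#' Repeatedly simulates the recovery design
#' (\code{\link{synth_config_recovery}}: 200 accessions, 1000 markers, 4
#' subpopulations, 3 seasons, 6 planted loci with per-cell variance
#' explained in the 0.10-0.15 band), runs the full pipeline at the
#' effective-test Bonferroni threshold, and scores: the fraction of planted
#' loci falling inside a reported MTA-QTL associated with their trait, and
#' the number of MTA-QTLs with no planted locus within
#' \code{false_margin_bp} (2 Mb) on the same chromosome.
#'
#' @param n_reps Number of replicates (default 50).
#' @param seed Base seed; replicate r uses seed + r.
#' @param alpha Family-wise error rate (default 0.05).
#' @param false_margin_bp Distance defining a false MTA-QTL (default 2e6).
#' @return List with \code{recovery_rate}, \code{mean_false_qtls}, and the
#'   per-replicate data frame \code{per_rep}.
#' @export
recovery_suite <- function(n_reps = 50, seed = 1L, alpha = 0.05,
                           false_margin_bp = 2e6) {
  per_rep <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- synth_config_recovery(seed = seed + r)
    st <- simulate_study(cfg)
    res <- run_pipeline(st$panel, st$pheno, st$q, alpha = alpha)
    truth <- st$truth$causal
    map <- st$panel$map
    tpos <- map$pos_bp[match(truth$marker_id, map$marker_id)]
    tchrom <- map$chrom[match(truth$marker_id, map$marker_id)]
    q <- res$qtls
    hit <- vapply(seq_len(nrow(truth)), function(i) {
      if (nrow(q) == 0) return(FALSE)
      traits <- strsplit(q$base_traits, ",")
      any(q$chrom == tchrom[i] & q$start_bp <= tpos[i] &
            q$end_bp >= tpos[i] &
            vapply(traits, function(tt) truth$trait[i] %in% tt, logical(1)))
    }, logical(1))
    false_q <- if (nrow(q) == 0) 0L else sum(vapply(seq_len(nrow(q)),
      function(j) {
        same <- tchrom == q$chrom[j]
        if (!any(same)) return(TRUE)
        d <- pmax(0, pmax(q$start_bp[j] - tpos[same],
                          tpos[same] - q$end_bp[j]))
        all(d > false_margin_bp)
      }, logical(1)))
    per_rep[[r]] <- data.frame(rep = r, n_recovered = sum(hit),
                               n_causal = nrow(truth),
                               n_qtls = nrow(q), n_false_qtls = false_q)
  }
  per_rep <- do.call(rbind, per_rep)
  list(recovery_rate = sum(per_rep$n_recovered) / sum(per_rep$n_causal),
       mean_false_qtls = mean(per_rep$n_false_qtls),
       per_rep = per_rep)
}

#' Type-I calibration of the structure-corrected scan
#'
#' Simulates a structured panel (4 subpopulations, FST 0.3, independent
#' markers) and a purely structure-driven null trait (subpopulation mean
#' plus noise; no marker effects), then scans all markers with and without
#' the Q covariates. With Q the rejection rate at \code{alpha} should sit
#' in the binomial confidence band around \code{alpha}; without Q,
#' population stratification inflates it.
#'
#' @param n_markers Number of null markers (default 2000).
#' @param n_accessions Panel size (default 200).
#' @param alpha Nominal level (default 0.05).
#' @param seed Seed.
#' @return List with \code{rate_with_q}, \code{rate_without_q},
#'   \code{ci} (binomial 95 percent band for the with-Q rate).
#' @export
type1_calibration <- function(n_markers = 2000, n_accessions = 200,
                              alpha = 0.05, seed = 1L) {
  n_chrom <- 4L
  cfg <- synth_config(n_accessions = n_accessions, n_subpops = 4, fst = 0.3,
                      chrom_lengths_bp = stats::setNames(
                        rep(5e7, n_chrom), paste0("chr", seq_len(n_chrom))),
                      n_markers_per_chrom = as.integer(n_markers / n_chrom),
                      ld_rho = 0, n_seasons = 1, missing_rate = 0,
                      seed = seed)
  g <- simulate_genotypes(cfg)
  y <- local_seed(seed + 1L, {
    pop_eff <- stats::rnorm(4, 0, 1)[g$subpop]
    stats::setNames(pop_eff + stats::rnorm(n_accessions),
                    g$panel$accession_ids)
  })
  with_q <- glm_scan(g$panel, y, g$q)
  no_q <- glm_scan(g$panel, y, q = NULL)
  m <- sum(!is.na(with_q$p_raw))
  list(rate_with_q = mean(with_q$p_raw < alpha, na.rm = TRUE),
       rate_without_q = mean(no_q$p_raw < alpha, na.rm = TRUE),
       ci = alpha + c(-1, 1) * 1.96 * sqrt(alpha * (1 - alpha) / m))
}

#' Operating characteristics of the DH-covariate re-test
#'
#' Paired simulation of the confounding scenario the re-test exists for.
#' Per replicate: a marker drives DH; a "confounded" trait is 0.9 DH plus
#' noise (its marker association is indirect), while a "direct" trait has
#' its own marker effect independent of DH. Both associations enter a
#' region and \code{\link{dh_retest}} is applied. Reports the fraction of
#' confounded associations removed and of direct associations retained.
#'
#' @param n_reps Number of replicates (default 200).
#' @param n_accessions Accessions per replicate (default 200).
#' @param seed Base seed.
#' @return List with \code{confounded_removed_rate},
#'   \code{direct_retained_rate}, \code{n_reps}.
#' @export
dh_retest_operating <- function(n_reps = 200, n_accessions = 200,
                                seed = 1L) {
  removed <- retained <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    res <- local_seed(seed + r, {
      n <- n_accessions
      calls <- matrix(stats::rbinom(n * 5, 1, 0.5), n, 5)
      ids <- sprintf("m%03d", 1:5)
      colnames(calls) <- ids
      panel <- marker_panel(calls,
                            data.frame(marker_id = ids, chrom = "1A",
                                       pos_bp = (1:5) * 1e6))
      acc <- panel$accession_ids
      dh <- stats::setNames(2 * calls[, 2] + stats::rnorm(n, 0, 0.5), acc)
      confounded <- 0.9 * dh + stats::rnorm(n, 0, 0.5)
      # direct effect sized for pve ~ 0.15
      direct <- 0.84 * calls[, 4] + stats::rnorm(n, 0, 1)
      ph <- data.frame(accession = rep(acc, 2), season = "season1",
                       trait = rep(c("Conf", "Dir"), each = n),
                       value = c(confounded, direct))
      class(ph) <- c("phenotype_table", "data.frame")
      mtas <- data.frame(marker_id = c("m002", "m004"), chrom = "1A",
                         pos_bp = c(2e6, 4e6), p_raw = 1e-8, effect = 1,
                         pve = 0.15, n_used = n, skipped = NA_character_,
                         trait = c("Conf", "Dir"), environment = "season1",
                         p_bonferroni = 1e-4)
      grouped <- group_mtas(mtas, panel, r2_lookup = function(a, b) 0)
      regions <- data.frame(region_id = "R1A.1", chrom = "1A",
                            start_bp = 1e6, end_bp = 5e6, n_traits = 2L,
                            base_traits = "Conf,Dir",
                            member_qtls = paste(grouped$qtls$qtl_id,
                                                collapse = ","),
                            status = "untested")
      dh_retest(regions, grouped, panel, ph, dh, min_traits = 1)
    })
    rt <- res$retests
    removed[r] <- !rt$retained[rt$trait == "Conf"]
    retained[r] <- rt$retained[rt$trait == "Dir"]
  }
  list(confounded_removed_rate = mean(removed),
       direct_retained_rate = mean(retained),
       n_reps = n_reps)
}

#' Half-decay recovery on synthetic exponential LD decay
#'
#' Generates marker pairs whose r2 decays as 0.4 exp(-d / scale) plus
#' Gaussian noise, fits the LOESS decay curve and compares the estimated
#' half-decay distance with the analytic half-life ln(2) x scale.
#'
#' @param n_pairs Number of synthetic pairs (default 5000).
#' @param scale_bp Exponential decay scale (default 1 Mb).
#' @param noise_sd Noise SD on r2 (default 0.02).
#' @param span LOESS span (default 0.2: a locally-linear smoother needs a
#'   tight window on a strongly curved exponential, or the short-range end
#'   of the curve is flattened and the half-decay point biased).
#' @param seed Seed.
#' @return List with \code{half_decay_bp}, \code{expected_bp},
#'   \code{relative_error}.
#' @export
decay_benchmark <- function(n_pairs = 5000, scale_bp = 1e6,
                            noise_sd = 0.02, span = 0.2, seed = 1L) {
  pairs <- local_seed(seed, {
    d <- stats::runif(n_pairs, 0, 5 * scale_bp)
    r2 <- pmin(1, pmax(0, 0.4 * exp(-d / scale_bp) +
                         stats::rnorm(n_pairs, 0, noise_sd)))
    data.frame(chrom = "1A", marker_i = "x", marker_j = "y",
               distance_bp = d, r2 = r2, n = 100L, p = NA_real_)
  })
  fit <- ld_decay(pairs, span = span, seed = seed)
  expected <- log(2) * scale_bp
  list(half_decay_bp = fit$half_decay_distance_bp,
       expected_bp = expected,
       relative_error = abs(fit$half_decay_distance_bp - expected) / expected)
}
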