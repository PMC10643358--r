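#' Simulate multi-season phenotypes with planted causal loci
#'
#' Builds phenotypes on top of a simulated panel. For each trait the model is
#' \deqn{y_{its} = \mu_t + m_s + \sum_k \beta_k x_{ik} + u_{pop(i)}
#'   + g_i \delta_s + \gamma_t DH_i + \epsilon_{its}}
#' where \eqn{m_s} is a season offset, \eqn{\beta_k} are the configured
#' causal-marker effects (phenotype-SD units, inbred 0/1 coding),
#' \eqn{u_{pop}} a subpopulation effect, \eqn{g_i} a latent polygenic value
#' whose variance is set so that total genetic variance equals the configured
#' broad-sense heritability, \eqn{\delta_s} season loadings
#' (\eqn{1 + N(0, gxe\_sd)}, normalised to unit mean square) producing
#' genotype-by-environment decorrelation, and \eqn{\epsilon} residual noise
#' with variance \eqn{1 - h^2}. When DH confounding is configured, the DH
#' trait is generated first and its standardised accession-level value enters
#' the target trait scaled by \eqn{\gamma}.
#'
#' @param panel,q,subpop Output of \code{\link{simulate_genotypes}}.
#' @param config The same \code{\link{synth_config}}.
#' @return A list with \code{pheno} (long data frame: accession, season,
#'   trait, value; class \code{phenotype_table}) and \code{truth} (list with
#'   \code{causal} data frame (marker_id, trait, environment, effect) and
#'   \code{confounders} data frame (trait, gamma)).
#' @export
simulate_phenotypes <- function(panel, q, config, subpop = NULL) {
  stopifnot(inherits(config, "synth_config"), inherits(panel, "marker_panel"))
  if (is.null(subpop)) subpop <- max.col(q)
  n <- length(panel$accession_ids)
  stopifnot(n == config$n_accessions, nrow(q) == n)

  # genome-wide marker order for marker_index resolution
  marker_ids <- panel$map$marker_id

  local_seed(config$seed + 1L, {
    # mean-impute missing calls for phenotype construction only
    calls <- panel$calls
    cm <- colMeans(calls, na.rm = TRUE)
    na_idx <- which(is.na(calls), arr.ind = TRUE)
    if (nrow(na_idx)) calls[na_idx] <- cm[na_idx[, 2]]

    traits <- config$traits
    # DH first so it can feed confounded traits
    ord <- order(traits$trait != "DH")
    traits <- traits[ord, , drop = FALSE]

    sd_pop <- 0.25  # subpopulation effect SD, phenotype-SD units
    baseline <- 10

    rows <- list()
    acc_genetic <- list()  # accession-level genetic+causal value per trait
    causal_rows <- list()
    for (ti in seq_len(nrow(traits))) {
      tr <- traits$trait[ti]
      h2 <- traits$h2[ti]
      q_tr <- config$qtls[config$qtls$trait == tr, , drop = FALSE]
      cvec <- numeric(n)
      if (nrow(q_tr)) {
        for (r in seq_len(nrow(q_tr))) {
          mid <- marker_ids[q_tr$marker_index[r]]
          cvec <- cvec + q_tr$effect[r] * calls[, mid]
          causal_rows[[length(causal_rows) + 1L]] <-
            data.frame(marker_id = mid, trait = tr, environment = "ALL",
                       effect = q_tr$effect[r])
        }
      }
      upop <- stats::rnorm(config$n_subpops, 0, sd_pop)[subpop]
      v_c <- stats::var(cvec) + stats::var(upop)
      sigma_g2 <- max(0, h2 - v_c)
      g <- stats::rnorm(n, 0, sqrt(sigma_g2))

      dh_term <- numeric(n)
      if (!is.null(config$dh_confounding) &&
          identical(config$dh_confounding$target_trait, tr)) {
        dh_acc <- acc_genetic[["DH"]]
        if (is.null(dh_acc)) stop("internal: DH must be generated first")
        dh_term <- config$dh_confounding$gamma *
          as.numeric(scale(dh_acc))
      }

      delta <- 1 + stats::rnorm(config$n_seasons, 0, traits$gxe_sd[ti])
      delta <- delta / sqrt(mean(delta^2))
      m_s <- stats::rnorm(config$n_seasons, 0, traits$season_effect_sd[ti])
      sd_e <- sqrt(max(0, 1 - h2))

      acc_val <- cvec + upop + g + dh_term
      acc_genetic[[tr]] <- acc_val
      for (s in seq_len(config$n_seasons)) {
        y <- baseline + m_s[s] + cvec + upop + g * delta[s] + dh_term +
          stats::rnorm(n, 0, sd_e)
        rows[[length(rows) + 1L]] <-
          data.frame(accession = panel$accession_ids,
                     season = sprintf("season%d", s),
                     trait = tr, value = y)
      }
    }
    pheno <- do.call(rbind, rows)
    rownames(pheno) <- NULL
    class(pheno) <- c("phenotype_table", "data.frame")
    attr(pheno, "transform_log") <- character()

    confounders <- if (is.null(config$dh_confounding))
      data.frame(trait = character(), gamma = numeric())
    else data.frame(trait = config$dh_confounding$target_trait,
                    gamma = config$dh_confounding$gamma)
    causal <- if (length(causal_rows)) do.call(rbind, causal_rows)
    else data.frame(marker_id = character(), trait = character(),
                    environment = character(), effect = numeric())
    list(pheno = pheno,
         truth = list(causal = causal, confounders = confounders))
  })
}

#' Simulate a complete study (genotypes, Q, phenotypes, truth)
#'
#' Convenience wrapper running \code{\link{simulate_genotypes}} and
#' \code{\link{simulate_phenotypes}} from one config.
#'
#' @param config A \code{\link{synth_config}}.
#' @return List with \code{panel}, \code{q}, \code{subpop}, \code{pheno},
#'   \code{truth}.
#' @export
simulate_study <- function(config) {
  geno <- simulate_genotypes(config)
  ph <- simulate_phenotypes(geno$panel, geno$q, config, geno$subpop)
  c(geno, ph)
}
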