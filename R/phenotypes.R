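#' Per-trait, per-season descriptive statistics
#'
#' Mean, sample SD, min, max and coefficient of variation (percent) per
#' trait and season, missing values excluded. Cells with fewer than two
#' observations are omitted with a warning.
#'
#' @param pheno A \code{phenotype_table} (long data frame: accession,
#'   season, trait, value).
#' @return Data frame with columns trait, season, n, mean, sd, min, max,
#'   cv_percent.
#' @export
summarize_traits <- function(pheno) {
  pheno <- as.data.frame(pheno)
  cells <- unique(pheno[, c("trait", "season")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    v <- pheno$value[pheno$trait == cells$trait[i] &
                     pheno$season == cells$season[i]]
    v <- v[!is.na(v)]
    if (length(v) < 2) {
      warning("trait ", cells$trait[i], " season ", cells$season[i],
              " has <2 observations; omitted", call. = FALSE)
      next
    }
    m <- mean(v)
    out[[length(out) + 1L]] <- data.frame(
      trait = cells$trait[i], season = cells$season[i], n = length(v),
      mean = m, sd = stats::sd(v), min = min(v), max = max(v),
      cv_percent = if (m != 0) 100 * stats::sd(v) / m else NA_real_)
  }
  do.call(rbind, out)
}

#' Shapiro-Wilk normality check with conditional log transform
#'
#' Per trait, Shapiro-Wilk is run within each season and the p-values are
#' combined as their minimum (conservative toward transforming). If the
#' combined p is below \code{alpha}, all raw values are positive, and the
#' log-transformed values pass Shapiro at \code{alpha}, the trait is
#' replaced by its natural log and flagged in the \code{transform_log}
#' attribute; otherwise values are kept and the reason recorded.
#'
#' @param pheno A \code{phenotype_table}.
#' @param alpha Significance level for the Shapiro-Wilk test (default 0.01).
#' @return The (possibly transformed) \code{phenotype_table}; the
#'   \code{transform_report} attribute records per-trait outcomes.
#' @export
normality_transform <- function(pheno, alpha = 0.01) {
  traits <- unique(pheno$trait)
  logged <- character()
  report <- list()
  shapiro_min <- function(vals, seas) {
    ps <- vapply(unique(seas), function(s) {
      v <- vals[seas == s]; v <- v[!is.na(v)]
      if (length(v) < 3 || length(unique(v)) == 1) return(NA_real_)
      stats::shapiro.test(v[seq_len(min(length(v), 5000))])$p.value
    }, numeric(1))
    if (all(is.na(ps))) NA_real_ else min(ps, na.rm = TRUE)
  }
  for (tr in traits) {
    sel <- pheno$trait == tr
    p_raw <- shapiro_min(pheno$value[sel], pheno$season[sel])
    if (is.na(p_raw) || p_raw >= alpha) {
      report[[tr]] <- list(applied = FALSE, reason = "raw passes", p_raw = p_raw)
      next
    }
    if (any(pheno$value[sel] <= 0, na.rm = TRUE)) {
      report[[tr]] <- list(applied = FALSE, reason = "non-positive values",
                           p_raw = p_raw)
      next
    }
    p_log <- shapiro_min(log(pheno$value[sel]), pheno$season[sel])
    if (!is.na(p_log) && p_log >= alpha) {
      pheno$value[sel] <- log(pheno$value[sel])
      logged <- c(logged, tr)
      report[[tr]] <- list(applied = TRUE, reason = "log restores normality",
                           p_raw = p_raw, p_log = p_log)
    } else {
      report[[tr]] <- list(applied = FALSE, reason = "log does not restore",
                           p_raw = p_raw, p_log = p_log)
    }
  }
  attr(pheno, "transform_log") <-
    union(attr(pheno, "transform_log"), logged)
  attr(pheno, "transform_report") <- report
  pheno
}

#' Season, structure and homoscedasticity tests per trait
#'
#' Kruskal-Wallis tests for a season effect and a subpopulation effect,
#' pairwise Wilcoxon rank-sum post-hoc tests with Holm adjustment, and the
#' Levene test (on season groups) per trait. Groups with fewer than two
#' observations are excluded with a warning.
#'
#' @param pheno A \code{phenotype_table}.
#' @param q Accession x subpopulation matrix (one-hot or admixture; the
#'   column of maximum membership defines the group).
#' @return Data frame with columns trait, season_effect_p, pop_effect_p,
#'   levene_p, plus a \code{posthoc} attribute (list of pairwise Wilcoxon
#'   matrices per trait).
#' @export
effect_tests <- function(pheno, q) {
  pop <- stats::setNames(paste0("pop", max.col(q)), rownames(q))
  out <- list(); posthoc <- list()
  drop_small <- function(vals, grp) {
    tab <- table(grp[!is.na(vals)])
    small <- names(tab)[tab < 2]
    if (length(small)) {
      warning("groups with <2 observations excluded: ",
              paste(small, collapse = ", "), call. = FALSE)
      keep <- !(grp %in% small)
      vals <- vals[keep]; grp <- grp[keep]
    }
    list(vals = vals, grp = factor(grp))
  }
  for (tr in unique(pheno$trait)) {
    d <- pheno[pheno$trait == tr & !is.na(pheno$value), , drop = FALSE]
    season_p <- pop_p <- levene_p <- NA_real_
    if (length(unique(d$season)) >= 2) {
      g <- drop_small(d$value, d$season)
      if (nlevels(g$grp) >= 2) {
        season_p <- stats::kruskal.test(g$vals, g$grp)$p.value
        levene_p <- car::leveneTest(g$vals, g$grp)[1, "Pr(>F)"]
        ph <- stats::pairwise.wilcox.test(g$vals, g$grp, p.adjust.method = "holm",
                                          exact = FALSE)
        posthoc[[tr]] <- ph$p.value
      }
    }
    pg <- pop[d$accession]
    if (length(unique(pg[!is.na(pg)])) >= 2) {
      ok <- !is.na(pg)
      g <- drop_small(d$value[ok], pg[ok])
      if (nlevels(g$grp) >= 2)
        pop_p <- stats::kruskal.test(g$vals, g$grp)$p.value
    }
    out[[tr]] <- data.frame(trait = tr, season_effect_p = season_p,
                            pop_effect_p = pop_p, levene_p = levene_p)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "posthoc") <- posthoc
  res
}

#' Spearman correlations between seasons and among traits
#'
#' Per trait, Spearman rho and p between every season pair on
#' pairwise-complete accessions; among traits, Spearman on per-accession
#' means across seasons. Cells with fewer than three paired observations are
#' reported as missing.
#'
#' @param pheno A \code{phenotype_table}.
#' @return List with \code{seasons} (data frame trait, season_a, season_b,
#'   rho, p, n) and \code{traits} (list with matrices \code{rho} and
#'   \code{p}).
#' @export
trait_correlations <- function(pheno) {
  pheno <- as.data.frame(pheno)
  srows <- list()
  for (tr in unique(pheno$trait)) {
    d <- pheno[pheno$trait == tr, , drop = FALSE]
    w <- stats::reshape(d[, c("accession", "season", "value")],
                        idvar = "accession", timevar = "season",
                        direction = "wide")
    seas <- sub("^value\\.", "", names(w)[-1])
    if (length(seas) < 2) next
    for (a in seq_along(seas)) for (b in seq_along(seas)) {
      if (a >= b) next
      x <- w[[a + 1]]; y <- w[[b + 1]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3) {
        srows[[length(srows) + 1L]] <- data.frame(
          trait = tr, season_a = seas[a], season_b = seas[b],
          rho = NA_real_, p = NA_real_, n = sum(ok))
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      srows[[length(srows) + 1L]] <- data.frame(
        trait = tr, season_a = seas[a], season_b = seas[b],
        rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
    }
  }
  seasons <- if (length(srows)) do.call(rbind, srows)
  else data.frame(trait = character(), season_a = character(),
                  season_b = character(), rho = numeric(), p = numeric(),
                  n = integer())

  means <- stats::aggregate(value ~ accession + trait, pheno, mean,
                            na.rm = TRUE)
  wide <- stats::reshape(means, idvar = "accession", timevar = "trait",
                         direction = "wide")
  tn <- sub("^value\\.", "", names(wide)[-1])
  k <- length(tn)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(tn, tn))
  diag(rho) <- 1; diag(p) <- 0
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a >= b) next
    x <- wide[[a + 1]]; y <- wide[[b + 1]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) next
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    rho[a, b] <- rho[b, a] <- unname(ct$estimate)
    p[a, b] <- p[b, a] <- ct$p.value
  }
  list(seasons = seasons, traits = list(rho = rho, p = p))
}

#' BLUEs or per-season mode per trait
#'
#' Traits whose pairwise between-season Spearman correlations all exceed
#' \code{threshold} get one best linear unbiased estimate (BLUE) per
#' accession from the fixed-effects model value ~ accession + season
#' (ordinary least squares, sum-to-zero season contrasts, BLUE = accession
#' estimate at the average season). Remaining traits are flagged
#' \code{per_season} and are scanned season by season downstream.
#' Single-season traits reduce to the observed values (mode \code{blue}).
#'
#' @param pheno A \code{phenotype_table}.
#' @param threshold Minimum pairwise season correlation (default 0.5,
#'   strictly exceeded).
#' @param correlations Optional precomputed \code{\link{trait_correlations}}.
#' @return List with \code{blues} (data frame trait, accession, value for
#'   BLUE-mode traits) and \code{modes} (data frame trait, mode, min_rho).
#' @export
estimate_blues <- function(pheno, threshold = 0.5, correlations = NULL) {
  if (is.null(correlations)) correlations <- trait_correlations(pheno)
  cs <- correlations$seasons
  modes <- list(); blues <- list()
  for (tr in unique(pheno$trait)) {
    d <- pheno[pheno$trait == tr & !is.na(pheno$value), , drop = FALSE]
    n_seas <- length(unique(d$season))
    rhos <- cs$rho[cs$trait == tr]
    min_rho <- if (length(rhos)) suppressWarnings(min(rhos, na.rm = TRUE))
    else NA_real_
    if (!is.finite(min_rho)) min_rho <- NA_real_
    mode <- if (n_seas <= 1 || (!is.na(min_rho) && min_rho > threshold))
      "blue" else "per_season"
    modes[[tr]] <- data.frame(trait = tr, mode = mode, min_rho = min_rho)
    if (mode != "blue") next
    if (n_seas <= 1) {
      blues[[tr]] <- data.frame(trait = tr, accession = d$accession,
                                value = d$value)
      next
    }
    d$accession <- factor(d$accession)
    d$season <- factor(d$season)
    # no intercept + sum-to-zero season: accession coefs are BLUEs at the
    # average season
    fit <- stats::lm(value ~ 0 + accession + season, data = d,
                     contrasts = list(season = stats::contr.sum))
    cf <- stats::coef(fit)
    acc_cf <- cf[grep("^accession", names(cf))]
    names(acc_cf) <- sub("^accession", "", names(acc_cf))
    blues[[tr]] <- data.frame(trait = tr, accession = names(acc_cf),
                              value = unname(acc_cf))
  }
  list(blues = if (length(blues)) do.call(rbind, c(blues, make.row.names = FALSE))
       else data.frame(trait = character(), accession = character(),
                       value = numeric()),
       modes = do.call(rbind, c(modes, make.row.names = FALSE)))
}
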