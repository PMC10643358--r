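# Sweep-merge 1-based inclusive intervals on one chromosome into groups of
# transitively overlapping intervals (>= 1 shared bp; adjacency does not
# merge). Returns an integer group id per input row, ids ordered by group
# start position.
merge_interval_groups <- function(start, end) {
  stopifnot(length(start) == length(end), all(end >= start))
  n <- length(start)
  if (n == 0) return(integer())
  ord <- order(start, end)
  grp <- integer(n)
  cur <- 0L; cur_end <- -Inf
  for (i in ord) {
    if (start[i] > cur_end) { cur <- cur + 1L; cur_end <- end[i] }
    else cur_end <- max(cur_end, end[i])
    grp[i] <- cur
  }
  grp
}

#' LD block around a significant seed marker
#'
#' Walks outward from the seed marker in map order, upstream and downstream
#' separately, including each neighbour while its r2 with the seed is
#' strictly greater than \code{r2_min}; the first neighbour at or below
#' \code{r2_min} (or with no computable r2) ends the walk and is excluded.
#' An r2 of exactly \code{r2_min} therefore terminates. Chromosome ends
#' terminate the walk. The block interval spans the positions of its
#' extreme member markers (1-based inclusive).
#'
#' @param panel A QC-passed \code{\link{marker_panel}}.
#' @param seed_marker Marker id of the significant association.
#' @param r2_min Walk threshold (default 0.3; continue requires r2 > 0.3).
#' @param min_overlap Minimum jointly non-missing accessions for a
#'   computable r2 (default 20).
#' @param r2_lookup Optional function(marker_a, marker_b) returning r2 or
#'   NA, overriding computation from the panel (used with a precomputed
#'   \code{\link{pairwise_r2}} table).
#' @return List with \code{chrom}, \code{seed_marker_id},
#'   \code{member_marker_ids} (contiguous in map order), \code{start_bp},
#'   \code{end_bp}.
#' @export
ld_block <- function(panel, seed_marker, r2_min = 0.3, min_overlap = 20,
                     r2_lookup = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  idx <- match(seed_marker, panel$map$marker_id)
  if (is.na(idx)) stop("seed marker absent from panel: ", seed_marker)
  ch <- panel$map$chrom[idx]
  on_ch <- which(panel$map$chrom == ch)
  pos_in_ch <- match(idx, on_ch)
  ids <- panel$map$marker_id[on_ch]

  r2_to_seed <- if (!is.null(r2_lookup)) {
    function(j) r2_lookup(seed_marker, ids[j])
  } else {
    seed_calls <- panel$calls[, seed_marker]
    function(j) {
      x <- panel$calls[, ids[j]]
      ok <- !is.na(x) & !is.na(seed_calls)
      if (sum(ok) < min_overlap) return(NA_real_)
      if (length(unique(x[ok])) < 2 || length(unique(seed_calls[ok])) < 2)
        return(NA_real_)
      stats::cor(x[ok], seed_calls[ok])^2
    }
  }

  lo <- hi <- pos_in_ch
  j <- pos_in_ch - 1L
  while (j >= 1) {
    r2 <- r2_to_seed(j)
    if (is.na(r2) || r2 <= r2_min) break
    lo <- j; j <- j - 1L
  }
  j <- pos_in_ch + 1L
  while (j <= length(ids)) {
    r2 <- r2_to_seed(j)
    if (is.na(r2) || r2 <= r2_min) break
    hi <- j; j <- j + 1L
  }
  members <- ids[lo:hi]
  pos <- panel$map$pos_bp[on_ch][lo:hi]
  list(chrom = ch, seed_marker_id = seed_marker,
       member_marker_ids = members,
       start_bp = min(pos), end_bp = max(pos))
}

#' Group MTAs into MTA-QTL intervals
#'
#' Computes one LD block per MTA seed marker and merges, per chromosome,
#' all MTAs whose blocks share at least one base pair (with transitive
#' closure) into MTA-QTLs. The QTL interval is the union span of its member
#' blocks; serial ids \code{<chrom>.<serial>} are assigned in positional
#' order along each chromosome. Base traits collapse season suffixes: an
#' MTA-QTL with TKW associations in two seasons counts TKW once.
#'
#' @param mtas Data frame of significant MTAs
#'   (\code{\link{significant_mtas}}).
#' @param panel QC-passed panel used for block walking.
#' @param r2_min,min_overlap,r2_lookup Passed to \code{\link{ld_block}}.
#' @return List with \code{qtls} (data frame qtl_id, chrom, start_bp,
#'   end_bp, n_mtas, n_traits, base_traits) and \code{mtas} (input rows
#'   plus qtl_id, block_start_bp, block_end_bp).
#' @export
group_mtas <- function(mtas, panel, r2_min = 0.3, min_overlap = 20,
                       r2_lookup = NULL) {
  if (nrow(mtas) == 0)
    return(list(qtls = data.frame(qtl_id = character(), chrom = character(),
                                  start_bp = integer(), end_bp = integer(),
                                  n_mtas = integer(), n_traits = integer(),
                                  base_traits = character()),
                mtas = cbind(mtas, qtl_id = character(0),
                             block_start_bp = integer(0),
                             block_end_bp = integer(0))))
  blocks <- lapply(unique(mtas$marker_id), function(m)
    ld_block(panel, m, r2_min, min_overlap, r2_lookup))
  names(blocks) <- unique(mtas$marker_id)
  mtas$block_start_bp <- vapply(mtas$marker_id,
                                function(m) blocks[[m]]$start_bp, numeric(1))
  mtas$block_end_bp <- vapply(mtas$marker_id,
                              function(m) blocks[[m]]$end_bp, numeric(1))
  mtas$qtl_id <- NA_character_
  qtl_rows <- list()
  for (ch in unique(mtas$chrom)) {
    sel <- which(mtas$chrom == ch)
    grp <- merge_interval_groups(mtas$block_start_bp[sel],
                                 mtas$block_end_bp[sel])
    for (g in sort(unique(grp))) {
      rows <- sel[grp == g]
      qid <- sprintf("%s.%d", ch, g)
      mtas$qtl_id[rows] <- qid
      traits <- sort(unique(mtas$trait[rows]))
      qtl_rows[[length(qtl_rows) + 1L]] <- data.frame(
        qtl_id = qid, chrom = ch,
        start_bp = min(mtas$block_start_bp[rows]),
        end_bp = max(mtas$block_end_bp[rows]),
        n_mtas = length(rows), n_traits = length(traits),
        base_traits = paste(traits, collapse = ","))
    }
  }
  qtls <- do.call(rbind, c(qtl_rows, make.row.names = FALSE))
  list(qtls = qtls, mtas = mtas)
}

#' Multi-environment stability of MTA-QTLs
#'
#' Per MTA-QTL and base trait, counts the distinct environments (seasons,
#' or the single BLUE cell) with a member MTA. QTLs with associations for
#' the same trait in \code{min_env} or more environments are annotated
#' stable.
#'
#' @param grouped Output of \code{\link{group_mtas}}.
#' @param min_env Minimum environments for stability (default 2).
#' @return Data frame qtl_id, trait, n_environments, stable.
#' @export
stable_qtls <- function(grouped, min_env = 2) {
  m <- grouped$mtas
  if (nrow(m) == 0)
    return(data.frame(qtl_id = character(), trait = character(),
                      n_environments = integer(), stable = logical()))
  agg <- stats::aggregate(environment ~ qtl_id + trait, m,
                          function(e) length(unique(e)))
  names(agg)[3] <- "n_environments"
  agg$stable <- agg$n_environments >= min_env
  agg[order(agg$qtl_id, agg$trait), , drop = FALSE]
}

#' High-density multi-trait regions
#'
#' Merges overlapping MTA-QTLs (>= 1 shared bp, transitive closure) into
#' candidate regions and keeps those whose union of base traits has at
#' least \code{min_traits} members. Region ids \code{R<chrom>.<serial>} are
#' assigned in positional order among the kept regions.
#'
#' @param grouped Output of \code{\link{group_mtas}}.
#' @param min_traits Minimum distinct base traits (default 4).
#' @return Data frame region_id, chrom, start_bp, end_bp, n_traits,
#'   base_traits, member_qtls, status (initially \code{"untested"}).
#' @export
high_density_regions <- function(grouped, min_traits = 4) {
  q <- grouped$qtls
  out <- list()
  for (ch in unique(q$chrom)) {
    sel <- which(q$chrom == ch)
    grp <- merge_interval_groups(q$start_bp[sel], q$end_bp[sel])
    serial <- 0L
    for (g in sort(unique(grp))) {
      rows <- sel[grp == g]
      traits <- sort(unique(unlist(strsplit(q$base_traits[rows], ","))))
      if (length(traits) < min_traits) next
      serial <- serial + 1L
      out[[length(out) + 1L]] <- data.frame(
        region_id = sprintf("R%s.%d", ch, serial), chrom = ch,
        start_bp = min(q$start_bp[rows]), end_bp = max(q$end_bp[rows]),
        n_traits = length(traits),
        base_traits = paste(traits, collapse = ","),
        member_qtls = paste(q$qtl_id[rows], collapse = ","),
        status = "untested")
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(region_id = character(), chrom = character(),
                  start_bp = integer(), end_bp = integer(),
                  n_traits = integer(), base_traits = character(),
                  member_qtls = character(), status = character())
}

#' Days-to-heading covariate re-test of region associations
#'
#' For every member MTA of every region whose trait is not DH or DM, fits
#' the linear model y = intercept + omega DH + M marker and retains the MTA
#' if the marker term stays significant at \code{retest_alpha}. Phenology
#' associations (DH, DM) are excluded from the retained set. Each region's
#' trait list and interval are then recomputed from the retained MTAs'
#' blocks: status \code{dropped} if fewer than \code{min_traits} traits
#' remain, \code{shrunk} if the interval contracted, else \code{retained}.
#' Regions where DH is missing for more than half the accessions are left
#' \code{untested}. The re-test never enlarges a region or adds traits.
#'
#' @param regions Output of \code{\link{high_density_regions}}.
#' @param grouped Output of \code{\link{group_mtas}} (supplies member MTAs
#'   and their blocks).
#' @param panel QC-passed panel.
#' @param pheno A \code{phenotype_table} (per-season trait values).
#' @param dh_values Named numeric vector of the DH covariate per accession
#'   (the DH BLUE).
#' @param blues Output of \code{\link{estimate_blues}} supplying BLUE-mode
#'   trait values.
#' @param retest_alpha Significance level for the marker term (default
#'   0.05, nominal: the re-test is confirmatory on pre-selected MTAs).
#' @param min_traits Minimum surviving traits (default 4).
#' @return List with \code{regions} (updated: status, dh_retained_traits,
#'   and possibly contracted intervals) and \code{retests} (per-MTA data
#'   frame region_id, marker_id, trait, environment, omega, marker_effect,
#'   p_adjusted, retained).
#' @export
dh_retest <- function(regions, grouped, panel, pheno, dh_values,
                      blues = NULL, retest_alpha = 0.05, min_traits = 4) {
  if (is.null(blues)) blues <- estimate_blues(pheno)
  m <- grouped$mtas
  retests <- list()
  regions$dh_retained_traits <- NA_character_
  for (i in seq_len(nrow(regions))) {
    qids <- strsplit(regions$member_qtls[i], ",")[[1]]
    rows <- which(m$qtl_id %in% qids)
    acc_needed <- panel$accession_ids
    if (mean(is.na(dh_values[acc_needed])) > 0.5) {
      regions$status[i] <- "untested"
      next
    }
    kept_rows <- integer()
    for (r in rows) {
      tr <- m$trait[r]
      if (tr %in% c("DH", "DM")) next
      env <- m$environment[r]
      yv <- if (env == "BLUE") {
        b <- blues$blues[blues$blues$trait == tr, ]
        stats::setNames(b$value, b$accession)
      } else {
        d <- pheno[pheno$trait == tr & pheno$season == env, ]
        stats::setNames(d$value, d$accession)
      }
      x <- panel$calls[, m$marker_id[r]]
      acc <- intersect(names(yv), panel$accession_ids)
      dh <- dh_values[acc]
      ok <- !is.na(yv[acc]) & !is.na(x[acc]) & !is.na(dh)
      acc <- acc[ok]
      if (length(acc) < 10 || length(unique(x[acc])) < 2) {
        retests[[length(retests) + 1L]] <- data.frame(
          region_id = regions$region_id[i], marker_id = m$marker_id[r],
          trait = tr, environment = env, omega = NA_real_,
          marker_effect = NA_real_, p_adjusted = NA_real_, retained = FALSE)
        next
      }
      fit <- stats::lm(yv[acc] ~ dh_values[acc] + x[acc])
      sm <- summary(fit)$coefficients
      p_adj <- if (nrow(sm) >= 3) sm[3, 4] else NA_real_
      retained <- !is.na(p_adj) && p_adj < retest_alpha
      retests[[length(retests) + 1L]] <- data.frame(
        region_id = regions$region_id[i], marker_id = m$marker_id[r],
        trait = tr, environment = env,
        omega = unname(stats::coef(fit)[2]),
        marker_effect = unname(stats::coef(fit)[3]),
        p_adjusted = p_adj, retained = retained)
      if (retained) kept_rows <- c(kept_rows, r)
    }
    traits_left <- sort(unique(m$trait[kept_rows]))
    if (length(traits_left) < min_traits) {
      regions$status[i] <- "dropped"
      regions$dh_retained_traits[i] <- paste(traits_left, collapse = ",")
      next
    }
    new_start <- min(m$block_start_bp[kept_rows])
    new_end <- max(m$block_end_bp[kept_rows])
    shrunk <- new_start > regions$start_bp[i] || new_end < regions$end_bp[i]
    regions$start_bp[i] <- max(new_start, regions$start_bp[i])
    regions$end_bp[i] <- min(new_end, regions$end_bp[i])
    regions$status[i] <- if (shrunk) "shrunk" else "retained"
    regions$dh_retained_traits[i] <- paste(traits_left, collapse = ",")
    regions$n_traits[i] <- length(traits_left)
    regions$base_traits[i] <- paste(traits_left, collapse = ",")
  }
  list(regions = regions,
       retests = if (length(retests))
         do.call(rbind, c(retests, make.row.names = FALSE))
       else data.frame(region_id = character(), marker_id = character(),
                       trait = character(), environment = character(),
                       omega = numeric(), marker_effect = numeric(),
                       p_adjusted = numeric(), retained = logical()))
}

#' Region report rows
#'
#' One report row per region: bounds and length in Mb (two decimals, length
#' computed from the printed bounds), trait list with the star convention
#' (one star per environment beyond the first would be redundant here; the
#' per-trait environment count is appended as repeated \code{*}), and an
#' optional gene count.
#'
#' @param regions Region data frame (bp coordinates).
#' @param stability Optional \code{\link{stable_qtls}}-style data frame
#'   (qtl_id or region-level trait environment counts) used to draw stars;
#'   may be an aggregate with columns trait, n_environments.
#' @param gene_counts Optional named vector region_id -> gene count.
#' @return Data frame region_id, chrom, start_mb, end_mb, length_mb,
#'   traits, n_genes.
#' @export
region_summary <- function(regions, stability = NULL, gene_counts = NULL) {
  if (nrow(regions) == 0)
    return(data.frame(region_id = character(), chrom = character(),
                      start_mb = numeric(), end_mb = numeric(),
                      length_mb = numeric(), traits = character(),
                      n_genes = integer()))
  start_mb <- round(regions$start_bp / 1e6, 2)
  end_mb <- round(regions$end_bp / 1e6, 2)
  star <- function(rid, traits) {
    if (is.null(stability)) return(traits)
    paste0(traits, vapply(traits, function(tr) {
      n <- stability$n_environments[stability$trait == tr]
      n <- if (length(n)) max(n) else 1L
      if (n > 1) strrep("*", n) else ""
    }, ""))
  }
  traits <- vapply(seq_len(nrow(regions)), function(i) {
    tl <- strsplit(regions$base_traits[i], ",")[[1]]
    paste(star(regions$region_id[i], tl), collapse = ", ")
  }, "")
  data.frame(region_id = regions$region_id, chrom = regions$chrom,
             start_mb = start_mb, end_mb = end_mb,
             length_mb = round(end_mb - start_mb, 2),
             traits = traits,
             n_genes = if (is.null(gene_counts)) NA_integer_
             else as.integer(gene_counts[regions$region_id]))
}
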