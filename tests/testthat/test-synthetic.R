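test_that("generator is deterministic and honours the missing rate", {
  cfg <- synth_config_paper_like(n_accessions = 60, n_markers_per_chrom = 50,
                                 seed = 5)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$panel$calls, b$panel$calls)
  expect_identical(a$panel$map, b$panel$map)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$q, b$q)

  cfg2 <- synth_config(n_accessions = 300, n_markers_per_chrom = 400,
                       chrom_lengths_bp = c(chr1 = 5e7),
                       missing_rate = 0.08, seed = 9)
  g <- simulate_genotypes(cfg2)
  expect_lt(abs(mean(is.na(g$panel$calls)) - 0.08), 0.01)
})

test_that("subpopulation differentiation matches the configured FST", {
  cfg <- synth_config(n_accessions = 400, n_subpops = 2, fst = 0.3,
                      chrom_lengths_bp = c(chr1 = 5e7),
                      n_markers_per_chrom = 500, ld_rho = 0,
                      missing_rate = 0, seed = 31)
  g <- simulate_genotypes(cfg)
  fst_hat <- hudson_fst(g$panel$calls, g$subpop)
  expect_lt(abs(fst_hat - 0.3), 0.05)
})

test_that("fst = 0 gives panmixia and is accepted with several subpops", {
  cfg <- synth_config(n_accessions = 300, n_subpops = 3, fst = 0,
                      chrom_lengths_bp = c(chr1 = 1e7),
                      n_markers_per_chrom = 300, ld_rho = 0,
                      missing_rate = 0, seed = 2)
  g <- simulate_genotypes(cfg)
  expect_lt(abs(hudson_fst(g$panel$calls[, 1:300],
                           ifelse(g$subpop == 1, 1, 2))), 0.02)
  expect_error(synth_config(ld_rho = 1), "degenerate")
})

test_that("adjacent-pair LD increases with ld_rho and vanishes at 0", {
  adj_r2 <- function(rho, seed = 77) {
    cfg <- synth_config(n_accessions = 300, n_subpops = 1, fst = 0,
                        chrom_lengths_bp = c(chr1 = 5e7),
                        n_markers_per_chrom = 200, ld_rho = rho,
                        missing_rate = 0, seed = seed)
    g <- simulate_genotypes(cfg)
    x <- g$panel$calls
    mean(vapply(seq_len(ncol(x) - 1), function(j)
      suppressWarnings(stats::cor(x[, j], x[, j + 1]))^2, numeric(1)),
      na.rm = TRUE)
  }
  r <- vapply(c(0, 0.5, 0.9), adj_r2, numeric(1))
  expect_true(r[1] < r[2] && r[2] < r[3])
  # at rho = 0 adjacent pairs look like random pairs (null r2 ~ 1/n)
  expect_lt(r[1], 3 / 300)
})

test_that("planted marker R2 matches the closed-form variance explained", {
  cfg <- synth_config(n_accessions = 300, n_subpops = 1, fst = 0,
                      chrom_lengths_bp = c(chr1 = 5e7),
                      n_markers_per_chrom = 100, ld_rho = 0,
                      n_seasons = 1,
                      traits = data.frame(trait = "T1", h2 = 0.8,
                                          season_effect_sd = 0, gxe_sd = 0),
                      qtls = data.frame(marker_index = 50, trait = "T1",
                                        effect = 1.0),
                      missing_rate = 0, seed = 13)
  st <- simulate_study(cfg)
  x <- st$panel$calls[, st$truth$causal$marker_id]
  y <- st$pheno$value[match(st$panel$accession_ids, st$pheno$accession)]
  r2_obs <- summary(stats::lm(y ~ x))$r.squared
  # haploid 0/1 coding: Var(x) = p(1-p); sigma_y^2 ~ 1 by construction
  p <- mean(x)
  r2_expected <- p * (1 - p) * 1.0^2 / stats::var(y)
  expect_lt(abs(r2_obs - r2_expected), 0.05)
})

test_that("season correlations follow the heritability structure", {
  base <- list(n_accessions = 300, n_subpops = 1, fst = 0,
               chrom_lengths_bp = c(chr1 = 1e7), n_markers_per_chrom = 20,
               ld_rho = 0, n_seasons = 3, missing_rate = 0)
  season_cors <- function(traits, seed) {
    cfg <- do.call(synth_config, c(base, list(traits = traits, seed = seed)))
    st <- simulate_study(cfg)
    w <- stats::reshape(st$pheno[, c("accession", "season", "value")],
                        idvar = "accession", timevar = "season",
                        direction = "wide")
    stats::cor(w[, -1], method = "spearman")[upper.tri(diag(3))]
  }
  # pure noise: h2 = 0, no effects -> correlations ~ 0
  r0 <- season_cors(data.frame(trait = "T1", h2 = 0, season_effect_sd = 1,
                               gxe_sd = 0), seed = 3)
  expect_true(all(abs(r0) < 0.15))
  # no G-by-E, h2 = 0.9 -> between-season correlation ~ h2
  r9 <- season_cors(data.frame(trait = "T1", h2 = 0.9, season_effect_sd = 0,
                               gxe_sd = 0), seed = 4)
  expect_true(all(abs(r9 - 0.9) < 0.05))
})

test_that("annotation generator honours density, silent fraction, determinism", {
  cfg <- synth_config(n_accessions = 20, chrom_lengths_bp = c(chr1 = 1e7),
                      n_markers_per_chrom = 20, missing_rate = 0, seed = 1)
  g <- simulate_genotypes(cfg)
  ann <- simulate_annotation(g$panel, genes_per_mb = 10, seed = 8,
                             chrom_lengths_bp = c(chr1 = 1e7))
  # ~100 genes expected on 10 Mb at 10 genes/Mb (Poisson noise)
  expect_gt(nrow(ann$genes), 100 - 4 * sqrt(100))
  expect_lt(nrow(ann$genes), 100 + 4 * sqrt(100))
  expect_true(all(ann$genes$end_bp >= ann$genes$start_bp))
  # intervals pairwise disjoint
  expect_true(all(diff(ann$genes$start_bp) >
                    (ann$genes$end_bp[-nrow(ann$genes)] -
                       ann$genes$start_bp[-nrow(ann$genes)])))

  silent <- simulate_annotation(g$panel, genes_per_mb = 5, seed = 8,
                                expressed_fraction = 0,
                                chrom_lengths_bp = c(chr1 = 1e7))
  ef <- expression_filter(silent$genes, silent$expr)
  expect_identical(nrow(ef$kept), 0L)

  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  ann2 <- simulate_annotation(g$panel, genes_per_mb = 10, seed = 8,
                              chrom_lengths_bp = c(chr1 = 1e7))
  write_gff3(ann$genes, f1); write_gff3(ann2$genes, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_annotation(g$panel, genes_per_mb = 0), "genes_per_mb")
})

test_that("truth table lists every planted locus with its panel marker", {
  cfg <- synth_config_recovery(seed = 21)
  st <- simulate_study(cfg)
  expect_identical(nrow(st$truth$causal), nrow(cfg$qtls))
  expect_true(all(st$truth$causal$marker_id %in% st$panel$marker_ids))
  expect_identical(st$truth$confounders$trait, "TKW")
  # DH confounding requires a DH trait
  expect_error(
    synth_config(traits = data.frame(trait = "T1", h2 = 0.5,
                                     season_effect_sd = 0, gxe_sd = 0),
                 dh_confounding = list(target_trait = "T1", gamma = 0.5)),
    "DH")
})
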