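test_that("LD-block walk follows the seed-anchored threshold rule", {
  # six markers A..F, seed C; r2 to seed: A 0.2, B 0.5, D 0.35, E 0.4, F 0.1
  r2 <- c(0.2, 0.5, NA, 0.35, 0.4, 0.1)  # NA at the seed itself
  p <- make_panel(matrix(0L, 4, 6))
  blk <- ld_block(p, "m003", r2_lookup = lookup_from_vector(r2, "m003"))
  expect_identical(blk$member_marker_ids, c("m002", "m003", "m004", "m005"))
  expect_equal(blk$start_bp, 2e6)
  expect_equal(blk$end_bp, 5e6)

  # all neighbours at or below the threshold: singleton block
  blk1 <- ld_block(p, "m003",
                   r2_lookup = lookup_from_vector(rep(0.3, 6), "m003"))
  expect_identical(blk1$member_marker_ids, "m003")
  expect_identical(blk1$start_bp, blk1$end_bp)

  # seed at chromosome start: upstream walk empty
  blk2 <- ld_block(p, "m001",
                   r2_lookup = lookup_from_vector(rep(0.9, 6), "m001"))
  expect_identical(blk2$member_marker_ids, sprintf("m%03d", 1:6))

  # exactly 0.3 terminates; undefined r2 terminates
  blk3 <- ld_block(p, "m003",
                   r2_lookup = lookup_from_vector(c(0.9, 0.3, NA, NA, 0.9, 0.9),
                                                  "m003"))
  expect_identical(blk3$member_marker_ids, "m003")
  expect_error(ld_block(p, "nope"), "absent")
})

test_that("LD-block walk equals the brute-force scanner", {
  set.seed(40)
  # exhaustive two-level r2 patterns for short chromosomes
  for (m in 3:8) {
    p <- make_panel(matrix(0L, 4, m))
    ids <- sprintf("m%03d", 1:m)
    for (mask in 0:(2^(m - 1) - 1)) {
      bits <- as.integer(intToBits(mask))[seq_len(m - 1)]
      for (seed_idx in c(1L, (m + 1L) %/% 2L, m)) {
        r2 <- numeric(m)
        r2[-seed_idx] <- ifelse(bits == 1, 0.5, 0.2)
        r2[seed_idx] <- NA
        blk <- ld_block(p, ids[seed_idx],
                        r2_lookup = lookup_from_vector(r2, ids[seed_idx]))
        # brute force walks by an all-of condition, not an outward walk
        exp_members <- ids[brute_block_members(r2, seed_idx)]
        expect_identical(blk$member_marker_ids, exp_members)
      }
    }
  }
  # random continuous r2 sequences (length 12) with NAs
  p <- make_panel(matrix(0L, 4, 12))
  ids <- sprintf("m%03d", 1:12)
  for (i in 1:1000) {
    r2 <- runif(12)
    r2[runif(12) < 0.1] <- NA
    seed_idx <- sample(12, 1)
    r2[seed_idx] <- NA
    blk <- ld_block(p, ids[seed_idx],
                    r2_lookup = lookup_from_vector(r2, ids[seed_idx]))
    expect_identical(blk$member_marker_ids,
                     ids[brute_block_members(r2, seed_idx)])
  }
})

test_that("block walking from real genotypes matches pairwise r2", {
  st <- simulate_study(synth_config_paper_like(n_accessions = 100,
                                               n_markers_per_chrom = 30,
                                               seed = 41))
  ld <- pairwise_r2(st$panel, min_overlap = 20)
  # lookup backed by the pair table must reproduce the panel-computed walk
  tab <- ld$pairs
  lookup <- function(a, b) {
    hit <- (tab$marker_i == a & tab$marker_j == b) |
      (tab$marker_i == b & tab$marker_j == a)
    if (!any(hit)) NA_real_ else tab$r2[which(hit)[1]]
  }
  for (seed_m in c("chr1_m0005", "chr2_m0015", "chr3_m0030")) {
    b1 <- ld_block(st$panel, seed_m)
    b2 <- ld_block(st$panel, seed_m, r2_lookup = lookup)
    expect_identical(b1$member_marker_ids, b2$member_marker_ids)
  }
})

make_mtas <- function(markers, traits, envs, panel) {
  data.frame(marker_id = markers,
             chrom = panel$map$chrom[match(markers, panel$map$marker_id)],
             pos_bp = panel$map$pos_bp[match(markers, panel$map$marker_id)],
             p_raw = 1e-8, effect = 1, pve = 0.1, n_used = 100L,
             skipped = NA_character_, trait = traits, environment = envs,
             p_bonferroni = 1e-4)
}

test_that("MTA grouping merges on shared base pairs with transitive closure", {
  # intervals via a lookup giving each seed a singleton block; positions
  # chosen so blocks are [pos, pos]
  p <- make_panel(matrix(0L, 4, 6),
                  pos = c(10e6, 10e6 + 1, 20e6, 30e6, 30e6 + 2e6, 50e6))
  no_ld <- function(a, b) 0
  m <- make_mtas(sprintf("m%03d", 1:6), rep("Ar", 6), rep("BLUE", 6), p)
  g <- group_mtas(m, p, r2_lookup = no_ld)
  # markers at distinct positions never merge with r2 = 0 blocks
  expect_identical(nrow(g$qtls), 6L)
  expect_identical(g$qtls$qtl_id[1:2], c("1A.1", "1A.2"))

  # overlapping blocks merge: [10-20] and [18-25] -> one QTL [10-25]
  p2 <- make_panel(matrix(0L, 4, 4), pos = c(10e6, 20e6, 18e6, 25e6))
  wide <- function(a, b) 0.9
  m2 <- make_mtas(c("m001", "m003"), c("Ar", "TKW"), c("BLUE", "season1"), p2)
  # m001's block walks to its neighbours; use full-LD lookup so each block
  # spans the chromosome, forcing a single QTL
  g2 <- group_mtas(m2, p2, r2_lookup = wide)
  expect_identical(nrow(g2$qtls), 1L)
  expect_identical(g2$qtls$start_bp, 10e6)
  expect_identical(g2$qtls$end_bp, 25e6)
  expect_identical(g2$qtls$base_traits, "Ar,TKW")

  # adjacency without a shared bp does not merge
  grp <- landqtl:::merge_interval_groups(c(10e6, 12000001), c(12e6, 15e6))
  expect_identical(grp, c(1L, 2L))
})

test_that("interval grouping equals union-find on random fixtures", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (rep in 1:5) {
    n <- 100
    start <- sample.int(1e6, n)
    end <- start + sample.int(5e4, n)
    # identical partitions up to label choice
    got <- canonical_partition(landqtl:::merge_interval_groups(start, end))
    want <- canonical_partition(unionfind_interval_groups(start, end))
    expect_identical(got, want)
  }
})

test_that("grouping and regions are idempotent and consistent", {
  st <- simulate_study(synth_config_recovery(seed = 43))
  res <- run_pipeline(st$panel, st$pheno, st$q)
  g <- list(qtls = res$qtls, mtas = res$mtas_grouped)
  # every MTA belongs to exactly one QTL
  expect_false(any(is.na(g$mtas$qtl_id)))
  expect_setequal(unique(g$mtas$qtl_id), g$qtls$qtl_id)
  # QTL interval = union of member blocks
  for (i in seq_len(nrow(g$qtls))) {
    mm <- g$mtas[g$mtas$qtl_id == g$qtls$qtl_id[i], ]
    expect_identical(g$qtls$start_bp[i], min(mm$block_start_bp))
    expect_identical(g$qtls$end_bp[i], max(mm$block_end_bp))
  }
  # re-grouping the QTL intervals changes nothing (idempotence): QTL spans
  # on one chromosome are pairwise non-overlapping
  for (ch in unique(g$qtls$chrom)) {
    sel <- g$qtls$chrom == ch
    regrp <- landqtl:::merge_interval_groups(g$qtls$start_bp[sel],
                                             g$qtls$end_bp[sel])
    expect_identical(anyDuplicated(regrp), 0L)
  }
})

test_that("stability counts environments per QTL and trait", {
  p <- make_panel(matrix(0L, 4, 3), pos = c(1e6, 2e6, 3e6))
  m <- make_mtas(c("m001", "m001", "m001", "m002"),
                 c("TKW", "TKW", "TKW", "Ar"),
                 c("season1", "season2", "season3", "BLUE"), p)
  g <- group_mtas(m, p, r2_lookup = function(a, b) 0)
  st <- stable_qtls(g)
  tkw <- st[st$trait == "TKW", ]
  expect_identical(tkw$n_environments, 3L)
  expect_true(tkw$stable)
  ar <- st[st$trait == "Ar", ]
  expect_identical(ar$n_environments, 1L)
  expect_false(ar$stable)
})

test_that("high-density regions require four base traits after collapsing", {
  p <- make_panel(matrix(0L, 4, 8), pos = (1:8) * 1e6)
  wide <- function(a, b) 0.9  # chromosome-wide blocks: everything merges
  # TKW in 3 seasons + Ar + Perim + Majell -> 4 base traits, kept
  m <- make_mtas(sprintf("m%03d", 1:6),
                 c("TKW", "TKW", "TKW", "Ar", "Perim", "Majell"),
                 c("season1", "season2", "season3", "BLUE", "BLUE", "BLUE"),
                 p)
  g <- group_mtas(m, p, r2_lookup = wide)
  r <- high_density_regions(g, min_traits = 4)
  expect_identical(nrow(r), 1L)
  expect_identical(r$n_traits, 4L)
  expect_identical(r$region_id, "R1A.1")

  # only 3 distinct traits -> no region
  m3 <- make_mtas(sprintf("m%03d", 1:3), c("Ar", "Perim", "Majell"),
                  rep("BLUE", 3), p)
  g3 <- group_mtas(m3, p, r2_lookup = wide)
  expect_identical(nrow(high_density_regions(g3, min_traits = 4)), 0L)
})

test_that("DH re-test drops confounded and keeps direct associations", {
  set.seed(44)
  n <- 200
  calls <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
  p <- make_panel(calls, pos = (1:5) * 1e6)
  acc <- p$accession_ids
  dh <- setNames(2 * calls[, 2] + rnorm(n, 0, 0.5), acc)  # m002 drives DH
  confounded <- 0.9 * dh + rnorm(n, 0, 0.5)               # trait via DH only
  direct <- 1.2 * calls[, 4] + rnorm(n, 0, 1)             # m004 direct

  ph <- data.frame(accession = rep(acc, 2),
                   season = "season1",
                   trait = rep(c("Conf", "Dir"), each = n),
                   value = c(confounded, direct))
  class(ph) <- c("phenotype_table", "data.frame")
  m <- make_mtas(c("m002", "m004"), c("Conf", "Dir"),
                 c("season1", "season1"), p)
  g <- group_mtas(m, p, r2_lookup = function(a, b) 0)
  regions <- data.frame(region_id = "R1A.1", chrom = "1A",
                        start_bp = 1e6, end_bp = 5e6, n_traits = 2L,
                        base_traits = "Conf,Dir",
                        member_qtls = paste(g$qtls$qtl_id, collapse = ","),
                        status = "untested")
  rt <- dh_retest(regions, g, p, ph, dh, min_traits = 1)
  conf_row <- rt$retests[rt$retests$trait == "Conf", ]
  dir_row <- rt$retests[rt$retests$trait == "Dir", ]
  expect_false(conf_row$retained)
  expect_true(dir_row$retained)
  # region never enlarges and traits never grow
  expect_gte(rt$regions$start_bp, regions$start_bp)
  expect_lte(rt$regions$end_bp, regions$end_bp)
  expect_lte(rt$regions$n_traits, regions$n_traits)
  expect_identical(rt$regions$status, "shrunk")

  # DH missing for most accessions: region flagged untested
  dh_na <- dh; dh_na[1:150] <- NA
  rt2 <- dh_retest(regions, g, p, ph, dh_na, min_traits = 1)
  expect_identical(rt2$regions$status, "untested")
})

test_that("region summaries report Mb bounds and lengths from printed values", {
  regions <- data.frame(
    region_id = c("R7B.2", "R2B.7", "R0.1"), chrom = c("7B", "2B", "1A"),
    start_bp = c(688210000, 758290000, 5000000),
    end_bp = c(690480000, 758420000, 5000000),
    n_traits = 4L, base_traits = "Ar,Majell,Perim,TKW",
    member_qtls = "x", status = "retained")
  rs <- region_summary(regions)
  expect_equal(rs$length_mb, c(2.27, 0.13, 0))
  expect_equal(rs$start_mb, c(688.21, 758.29, 5))
  # star convention from stability annotation
  stab <- data.frame(qtl_id = "x", trait = "TKW", n_environments = 3L,
                     stable = TRUE)
  rs2 <- region_summary(regions, stability = stab)
  expect_match(rs2$traits[1], "TKW\\*\\*\\*")
})
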