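test_that("QC boundaries follow the strict filter rules", {
  n <- 100
  set.seed(20)
  base <- matrix(rbinom(n * 6, 1, 0.5), n, 6)
  base[, 2] <- base[, 1]                      # duplicate profile
  base[1:11, 3] <- NA                         # 11% missing -> removed
  base[1:10, 4] <- NA                         # 10% missing -> kept
  base[, 5] <- c(rep(1L, 5), rep(0L, n - 5))  # MAF 0.05 -> kept
  base[, 6] <- c(rep(1L, 4), rep(0L, n - 4))  # MAF 0.04 -> removed
  p <- make_panel(base)
  qc <- marker_qc(p)
  expect_identical(qc$report$removed$duplicate_profile, "m002")
  expect_identical(qc$report$removed$missing_gt_threshold, "m003")
  expect_identical(qc$report$removed$maf_lt_threshold, "m006")
  expect_identical(qc$panel$marker_ids, c("m001", "m004", "m005"))
  expect_identical(sum(qc$report$counts) + length(qc$report$retained),
                   ncol(base))
})

test_that("QC filter order never changes the retained set", {
  # applying the three filters in any order retains the same markers;
  # verified against an order-permuted reference on random panels
  set.seed(21)
  for (rep in 1:5) {
    n <- 60; m <- 40
    calls <- matrix(rbinom(n * m, 1, runif(m, 0.02, 0.5)[rep(1:m, each = n)]),
                    n, m)
    calls[runif(n * m) < 0.08] <- NA
    calls[, 5] <- calls[, 4]
    p <- make_panel(calls)
    qc <- marker_qc(p)
    # reference: independent set computation, order-free
    key <- apply(calls, 2, paste, collapse = "|")
    dup <- duplicated(key)
    miss <- colMeans(is.na(calls)) > 0.10
    pf <- colMeans(calls, na.rm = TRUE)
    low <- pmin(pf, 1 - pf) < 0.05
    expected <- sprintf("m%03d", which(!dup & !miss & !low))
    expect_identical(qc$panel$marker_ids, expected)
  }
})

test_that("pairwise r2 equals the two-locus formula", {
  m1 <- c(0, 0, 1, 1, 0, 1)
  m2 <- c(0, 1, 1, 1, 0, 0)
  p <- make_panel(cbind(m1, m2, deparse.level = 0))
  ld <- pairwise_r2(p, min_overlap = 5)
  expect_equal(ld$pairs$r2, 1 / 9, tolerance = 1e-12)
  expect_equal(ld$pairs$r2, brute_r2(m1, m2), tolerance = 1e-12)

  # identical and complementary columns
  p2 <- make_panel(cbind(m1, m1, 1 - m1, deparse.level = 0))
  ld2 <- pairwise_r2(p2, min_overlap = 5)
  expect_equal(ld2$pairs$r2, rep(1, 3), tolerance = 1e-12)

  # random <=10-accession instances against the brute-force formula,
  # including allele-label swaps (r2 invariant)
  set.seed(22)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    x <- rbinom(n, 1, 0.5); y <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    pp <- make_panel(cbind(x, y, deparse.level = 0))
    got <- pairwise_r2(pp, min_overlap = 2)$pairs$r2
    expect_equal(got, brute_r2(x, y), tolerance = 1e-12)
    pp_swap <- make_panel(cbind(1 - x, y, deparse.level = 0))
    expect_equal(pairwise_r2(pp_swap, min_overlap = 2)$pairs$r2, got,
                 tolerance = 1e-12)
  }
})

test_that("pairs below the overlap floor are excluded from summaries", {
  set.seed(23)
  calls <- matrix(rbinom(120, 1, 0.5), 30, 4)
  calls[1:25, 4] <- NA  # only 5 joint observations with anything
  p <- make_panel(calls)
  ld <- pairwise_r2(p, min_overlap = 20)
  und <- ld$pairs[ld$pairs$marker_j == "m004" | ld$pairs$marker_i == "m004", ]
  expect_true(all(is.na(und$r2)))
  expect_identical(ld$summary$overall$n_pairs, 3L)
  # restricted to same chromosome
  p2 <- make_panel(calls, chrom = c("1A", "1A", "2A", "2A"))
  ld2 <- pairwise_r2(p2, min_overlap = 5)
  expect_true(all(paste(ld2$pairs$marker_i, ld2$pairs$marker_j) %in%
                    c("m001 m002", "m003 m004")))
})

test_that("LOESS decay recovers the half-life of an exponential curve", {
  set.seed(24)
  n <- 5000
  d <- runif(n, 0, 5e6)
  r2 <- pmin(1, pmax(0, 0.4 * exp(-d / 1e6) + rnorm(n, 0, 0.02)))
  pairs <- data.frame(chrom = "1A", marker_i = "x", marker_j = "y",
                      distance_bp = d, r2 = r2, n = 100L, p = NA_real_)
  fit <- ld_decay(pairs, span = 0.3, seed = 1)
  expect_lt(abs(fit$half_decay_distance_bp - log(2) * 1e6),
            0.15 * log(2) * 1e6)
  expect_true(all(fit$curve$r2_fit >= 0 & fit$curve$r2_fit <= 1))

  # flat curve: no crossing, half-decay undefined
  flat <- pairs; flat$r2 <- pmin(1, pmax(0, 0.2 + rnorm(n, 0, 0.01)))
  ffit <- ld_decay(flat, seed = 1)
  expect_true(is.na(ffit$half_decay_distance_bp))

  # determinism under subsampling with a fixed seed
  f1 <- ld_decay(pairs, span = 0.3, max_pairs = 2000, seed = 5)
  f2 <- ld_decay(pairs, span = 0.3, max_pairs = 2000, seed = 5)
  expect_identical(f1$curve, f2$curve)
  expect_error(ld_decay(pairs[1:50, ]), ">= 100")
})

test_that("effective tests counts r2 = 1 classes per chromosome", {
  set.seed(25)
  x <- rbinom(40, 1, 0.5); y <- rbinom(40, 1, 0.5); z <- rbinom(40, 1, 0.5)
  # m1 = m2; m3 = m4 = m5 (complement counts as r2 = 1)
  calls <- cbind(x, x, y, y, 1 - y, z)
  p <- make_panel(calls)
  ne <- effective_tests(p)
  expect_identical(as.integer(ne), 3L)

  # mutually independent markers -> N classes
  ind <- make_panel(matrix(rbinom(40 * 6, 1, 0.5), 40, 6))
  expect_identical(as.integer(effective_tests(ind)), 6L)

  # never exceeds the marker count; equality iff no duplicate-LD classes
  expect_lte(as.integer(ne), ncol(calls))
})

test_that("effective tests equals brute-force components on random panels", {
  skip_if_not_installed("igraph")
  set.seed(26)
  for (rep in 1:3) {
    n <- 30; m <- 60
    calls <- matrix(rbinom(n * m, 1, 0.5), n, m)
    # plant duplicate clusters
    calls[, 10] <- calls[, 9]; calls[, 11] <- 1 - calls[, 9]
    calls[, 30] <- calls[, 29]
    chrom <- rep(c("1A", "2A"), each = m / 2)
    p <- make_panel(calls, chrom = chrom)
    got <- as.integer(effective_tests(p))
    # oracle: connected components of the exact r2 = 1 graph per chromosome
    total <- 0L
    for (ch in c("1A", "2A")) {
      cc <- calls[, chrom == ch]
      r <- suppressWarnings(cor(cc))
      adj <- !is.na(r) & r^2 >= 1 - 1e-9
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                               diag = FALSE)
      total <- total + igraph::components(g)$no
    }
    expect_equal(got, total)
  }
})

test_that("marker-to-test reduction percent matches the worked example", {
  expect_equal(round(test_reduction_percent(4856, 4476), 1), 7.8)
  expect_equal(test_reduction_percent(100, 100), 0)
  expect_error(test_reduction_percent(10, 11), "n_eff")
})
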