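# Independent reference implementations used to cross-check the package.

# Hudson-style FST estimator (ratio of averages) for two haploid
# subpopulation samples, from allele frequencies and sample sizes.
hudson_fst <- function(calls, subpop) {
  stopifnot(length(unique(subpop)) == 2)
  pops <- sort(unique(subpop))
  num <- den <- numeric(0)
  for (j in seq_len(ncol(calls))) {
    x1 <- calls[subpop == pops[1], j]; x1 <- x1[!is.na(x1)]
    x2 <- calls[subpop == pops[2], j]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) next
    p1 <- mean(x1); p2 <- mean(x2)
    num <- c(num, (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
               p2 * (1 - p2) / (n2 - 1))
    den <- c(den, p1 * (1 - p2) + p2 * (1 - p1))
  }
  mean(num) / mean(den)
}

# Two-locus r2 from the textbook D^2 / (pA qA pB qB) formula on
# jointly non-missing haploid 0/1 calls.
brute_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  pA <- mean(x); pB <- mean(y)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  pAB <- mean(x == 1 & y == 1)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Brute-force LD-block scanner: candidate member j is included iff every
# marker strictly between j and the seed, j itself included, has
# r2(seed, .) > r2_min (checked as an all-of condition rather than a walk).
brute_block_members <- function(r2_to_seed, seed_idx, r2_min = 0.3) {
  m <- length(r2_to_seed)
  ok_self <- function(j) !is.na(r2_to_seed[j]) && r2_to_seed[j] > r2_min
  members <- seed_idx
  for (j in seq_len(m)) {
    if (j == seed_idx) next
    rng <- if (j < seed_idx) j:(seed_idx - 1) else (seed_idx + 1):j
    if (all(vapply(rng, ok_self, logical(1)))) members <- c(members, j)
  }
  sort(members)
}

# Union-find partition of intervals into transitively-overlapping groups
# via an explicit pairwise-overlap graph (igraph components).
unionfind_interval_groups <- function(start, end) {
  n <- length(start)
  if (n == 0) return(integer())
  edges <- c()
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a < b && start[a] <= end[b] && start[b] <= end[a])
      edges <- c(edges, a, b)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

# Normalise a grouping vector so partitions can be compared independently
# of label choice.
canonical_partition <- function(grp) {
  match(grp, unique(grp))
}

# Tiny panel builder: calls matrix (accessions x markers) on one or more
# chromosomes with explicit positions.
make_panel <- function(calls, chrom = "1A", pos = NULL) {
  m <- ncol(calls)
  if (length(chrom) == 1) chrom <- rep(chrom, m)
  if (is.null(pos)) pos <- seq_len(m) * 1e6
  ids <- sprintf("m%03d", seq_len(m))
  colnames(calls) <- ids
  marker_panel(calls, data.frame(marker_id = ids, chrom = chrom,
                                 pos_bp = as.integer(pos)))
}

# Seed-anchored r2 lookup for a synthetic vector of r2-to-seed values;
# markers named m001.. as in make_panel.
lookup_from_vector <- function(r2_vec, seed_id) {
  ids <- sprintf("m%03d", seq_along(r2_vec))
  function(a, b) {
    other <- if (a == seed_id) b else a
    r2_vec[match(other, ids)]
  }
}
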