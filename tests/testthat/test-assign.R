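# Specimen assignment: fuzzy membership, the three methods, consensus
# verdicts, and the ratio diagnostic.

# A small delimited reference: three well-separated OTUs of 3 sequences.
make_ref <- function(seed = 1, n_otus = 3, n_per = 3, L = 300) {
  set.seed(seed)
  anc <- lapply(seq_len(n_otus), function(i) rand_dna(L))
  seqs <- character(0); otu <- character(0)
  for (i in seq_len(n_otus)) for (j in seq_len(n_per)) {
    seqs <- c(seqs, mutate_seq(anc[[i]], n_ts = j - 1, n_tv = 0,
                               seed = 100 * i + j))
    otu <- c(otu, sprintf("OTU_%d", i))
  }
  lib <- make_library(seqs)
  part <- partition(stats::setNames(otu, lib$records$record_id))
  list(lib = lib, part = part,
       ref = build_assignment_reference(lib, part, seed = seed))
}

test_that("the fuzzy membership function honours its contract", {
  a <- 0.01; b <- 0.05
  expect_equal(fmf(0, a, b), 1)
  expect_equal(fmf(a, a, b), 1)
  expect_equal(fmf(b, a, b), 0)
  expect_equal(fmf(0.1, a, b), 0)
  expect_equal(fmf((a + b) / 2, a, b), 0.5)
  # non-increasing over a grid
  xs <- seq(0, 0.08, by = 0.001)
  vals <- vapply(xs, fmf, numeric(1), a = a, b = b)
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 0 & vals <= 1))
  # degenerate bounds collapse to a step at a
  expect_equal(fmf(0.009, 0.01, 0.01), 1)
  expect_equal(fmf(0.011, 0.01, 0.005), 0)
})

test_that("assignment references are reproducible and handle singletons", {
  r <- make_ref(seed = 1)
  expect_equal(nrow(r$ref$representatives), 3L)
  r2 <- build_assignment_reference(r$lib, r$part, seed = 1)
  expect_identical(r$ref$representatives, r2$representatives)
  # different seed: possibly different draws, identical OTU set
  r3 <- build_assignment_reference(r$lib, r$part, seed = 2)
  expect_equal(r3$representatives$otu_id, r$ref$representatives$otu_id)

  # singleton OTU: its member is the representative; theta1 falls back to
  # the global median of multi-member OTUs
  lib <- make_library(c(rand_dna(200, 1), rand_dna(200, 2),
                        mutate_seq(rand_dna(200, 2), 1, 0, 3)))
  part <- partition(stats::setNames(c("S", "M", "M"),
                                    lib$records$record_id))
  ref <- build_assignment_reference(lib, part, seed = 1)
  expect_equal(ref$representatives$record_id[
    ref$representatives$otu_id == "S"], "r01")
  multi_max <- k2p_distance(lib$records$sequence[2],
                            lib$records$sequence[3])$distance
  expect_equal(unname(ref$theta1["S"]), multi_max)
})

test_that("FZ selects the nearest OTU and probabilities follow the FMF", {
  r <- make_ref(seed = 3)
  # a query identical to a representative gets that OTU with probability 1
  q <- r$ref$rep_seqs[2]
  names(q) <- "q1"
  out <- assign_fz(q, r$ref)
  expect_equal(out$selected_otu, names(r$ref$rep_seqs)[2])
  expect_equal(out$probability, 1)
  expect_equal(out$dist_to_selected, 0)
  expect_lte(out$ratio, 1)

  # far-away query: beyond b, probability 0, still the nearest OTU
  far <- rand_dna(300, seed = 777)
  out2 <- assign_fz(c(qf = far), r$ref)
  if (out2$dist_to_selected >= r$ref$theta2[out2$selected_otu])
    expect_equal(out2$probability, 0)
  expect_lte(out2$ratio, 1)
})

test_that("FZ ratio never exceeds 1 across simulated queries", {
  sim <- simulate_library(sim_config(seed = 8, n_unsampled_query_otus = 2))
  del <- suppressWarnings(delimit_all(sim$reference, curation_config(),
                                      seed = 1))
  ref <- build_assignment_reference(sim$reference, del$consensus, seed = 1)
  out <- assign_fz(sim$queries, ref)
  expect_true(all(out$ratio <= 1 + 1e-12))
})

test_that("FZKMER picks an informative k and respects composition", {
  r <- make_ref(seed = 4)
  q <- r$ref$rep_seqs[1]; names(q) <- "q1"
  out <- assign_fzkmer(q, r$ref)
  expect_equal(out$selected_otu, names(r$ref$rep_seqs)[1])
  expect_equal(out$probability, 1)

  # two OTUs with disjoint trinucleotide composition: brute-force accuracy
  # over the k grid must make k = 3 (or smaller) perfect, and the query
  # goes to the right OTU
  a <- strrep("AAC", 60); b <- strrep("GTG", 60)
  lib <- make_library(c(a, a, b, b))
  part <- partition(stats::setNames(c("A", "A", "B", "B"),
                                    lib$records$record_id))
  ref <- build_assignment_reference(lib, part, seed = 1)
  out2 <- assign_fzkmer(c(q = strrep("AAC", 60)), ref)
  expect_equal(out2$selected_otu, "A")
  expect_gte(out2$probability, 0.99)

  # single-OTU reference: uninformative flag, probability 1
  lib1 <- make_library(c(a, a))
  part1 <- partition(stats::setNames(c("A", "A"), lib1$records$record_id))
  ref1 <- build_assignment_reference(lib1, part1, seed = 1)
  out3 <- assign_fzkmer(c(q = a), ref1)
  expect_true(out3$uninformative)
  expect_equal(out3$probability, 1)

  expect_error(assign_fzkmer(c(q = "ACG"), ref, k_max = 5), "k_max")
})

test_that("BP learns a separable fixture and is seed-deterministic", {
  r <- make_ref(seed = 5)
  queries <- stats::setNames(r$lib$records$sequence,
                             paste0("q_", r$lib$records$record_id))
  out <- assign_bp(queries, r$ref, seed = 7)
  truth <- unname(r$part$assignments[r$lib$records$record_id])
  expect_equal(out$selected_otu, truth)         # 100% training accuracy
  expect_true(all(out$probability > 0.5))

  # nearest-centroid oracle on the separable fixture agrees
  feats <- barcurate:::kmer_features(
    stats::setNames(r$lib$records$sequence, r$lib$records$record_id), 3)
  cent <- apply(feats, 2, function(col) tapply(col, truth, mean))
  oracle <- rownames(cent)[apply(feats, 1, function(f)
    which.min(colSums((t(cent) - f)^2)))]
  expect_equal(out$selected_otu, unname(oracle))

  # determinism: identical probabilities under the same seed
  out2 <- assign_bp(queries, r$ref, seed = 7)
  expect_identical(out$probability, out2$probability)

  # single-OTU reference is an error
  lib1 <- make_library(c(rand_dna(100, 1), rand_dna(100, 1)))
  p1 <- partition(stats::setNames(c("A", "A"), lib1$records$record_id))
  expect_error(assign_bp(c(q = rand_dna(100, 2)),
                         build_assignment_reference(lib1, p1, 1)),
               "2 OTUs")
})

test_that("BP is near-indifferent between exchangeable OTUs", {
  # two OTUs built by applying the same substitution in two identical
  # sequence contexts: the query (the unmutated ancestor) is equidistant
  # by construction, so by exchangeability the probability should sit
  # near 0.5
  ctx <- rand_dna(150, seed = 11)
  anc <- paste0(ctx, ctx)          # the two halves are identical contexts
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- c(A = "G", G = "A", C = "T", T = "C")[[ch[pos]]]
    paste(ch, collapse = "")
  }
  A <- vapply(c(10, 20, 30), function(p) mutate_at(anc, p), character(1))
  B <- vapply(c(160, 170, 180), function(p) mutate_at(anc, p), character(1))
  lib <- make_library(c(A, B))
  part <- partition(stats::setNames(rep(c("A", "B"), each = 3),
                                    lib$records$record_id))
  ref <- build_assignment_reference(lib, part, seed = 1)
  # the A/B members have pairwise-identical k-mer vectors, so the trained
  # softmax is pinned to ~0.5 on those inputs; query one of them
  probs <- vapply(1:5, function(s)
    assign_bp(c(q = A[1]), ref, seed = s)$probability, numeric(1))
  expect_lt(abs(mean(probs) - 0.5), 0.05)
  expect_true(all(abs(probs - 0.5) < 0.1))
})

test_that("the consensus verdict follows the 2-of-3 rule", {
  row <- function(otu, p) data.frame(query_id = "q", method = "m",
    selected_otu = otu, probability = p, dist_to_selected = 0,
    nn_otu = NA, dist_to_nn = NA, ratio = NA, stringsAsFactors = FALSE)
  v <- consensus_assignment(rbind(row("A", 0.9), row("A", 0.8),
                                  row("A", 0.7)))
  expect_equal(v$consensus_otu, "A")
  expect_equal(v$consensus_level, "3/3")
  expect_equal(v$mean_probability, 0.8)

  v2 <- consensus_assignment(rbind(row("A", 0.9), row("A", 0.6),
                                   row("B", 0.3)))
  expect_equal(v2$consensus_otu, "A")
  expect_equal(v2$consensus_level, "2/3")

  v3 <- consensus_assignment(rbind(row("A", 0.9), row("B", 0.6),
                                   row("C", 0.3)))
  expect_equal(v3$consensus_otu, "ambiguous")
  expect_equal(v3$consensus_level, "none")

  expect_error(consensus_assignment(rbind(row("A", 1), row("B", 1))),
               "three")
})

test_that("the ratio diagnostic flags non-nearest selections", {
  # representatives at K2P distance ~0.004 and ~0.008 from the query
  # (small distances, so K2P is essentially linear): forcing selection of
  # the farther OTU doubles the ratio
  base <- rand_dna(1000, seed = 13)
  near <- mutate_seq(base, n_ts = 4, n_tv = 0, seed = 14)
  far <- mutate_seq(base, n_ts = 8, n_tv = 0, seed = 15)
  lib <- make_library(c(near, near, far, far))
  part <- partition(stats::setNames(c("N", "N", "F", "F"),
                                    lib$records$record_id))
  ref <- build_assignment_reference(lib, part, seed = 1)
  expect_lt(ratio_diagnostic(base, "N", ref), 1)
  r <- ratio_diagnostic(base, "F", ref)
  expect_equal(r, 2, tolerance = 0.01)
  # the alternative reading uses the OTU's own theta parameters
  r2 <- ratio_diagnostic(base, "N", ref, mode = "otu")
  expect_equal(r2, unname(ref$theta1["N"] / ref$theta2["N"]))
})

test_that("unsampled-OTU queries get low fuzzy probabilities", {
  sim <- simulate_library(sim_config(seed = 6, n_unsampled_query_otus = 3))
  del <- suppressWarnings(delimit_all(sim$reference, curation_config(),
                                      seed = 1))
  ref <- build_assignment_reference(sim$reference, del$consensus, seed = 1)
  unsq <- sim$truth$flags$record_id[sim$truth$flags$is_unsampled_otu &
                                      sim$truth$flags$is_query]
  out <- assign_fz(subset_library(sim$queries, unsq), ref)
  beyond <- out$dist_to_selected > unname(ref$theta2[out$selected_otu])
  expect_true(all(out$probability[beyond] < 0.5))
  expect_true(any(beyond))
})
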