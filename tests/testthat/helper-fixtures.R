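# Shared fixture builders. Everything is generated in code; no data files.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate `n_ts` transitions and `n_tv` transversions at distinct sites.
mutate_seq <- function(seq, n_ts = 0, n_tv = 0, seed = 1) {
  set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  sites <- sample(length(ch), n_ts + n_tv)
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partner <- c(A = "C", G = "T", C = "A", T = "G")
  if (n_ts > 0)
    for (i in sites[seq_len(n_ts)]) ch[i] <- ts_partner[[ch[i]]]
  if (n_tv > 0)
    for (i in sites[n_ts + seq_len(n_tv)]) ch[i] <- tv_partner[[ch[i]]]
  paste(ch, collapse = "")
}

make_library <- function(seqs, taxa = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%02d", seq_along(seqs))
  if (is.null(taxa)) taxa <- character(length(seqs))
  barcode_library(data.frame(record_id = ids, nominal_taxon = taxa,
                             locality = character(length(seqs)),
                             sequence = seqs, stringsAsFactors = FALSE))
}

write_tmp_fasta <- function(seqs, ids = names(seqs)) {
  f <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), f)
  f
}

# Hand-built distance matrix: block structure with per-OTU intra distances
# and a matrix of between-block distances. `sizes` are block sizes.
make_block_dist <- function(sizes, intra, inter) {
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- if (block[i] == block[j]) intra[block[i]]
                          else inter[block[i], block[j]]
  }
  ids <- sprintf("x%02d", seq_len(n))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d,
                 n_sites = matrix(500L, n, n, dimnames = dimnames(d)),
                 n_saturated = 0L),
            class = "dist_matrix")
}

block_membership <- function(sizes) {
  ids <- sprintf("x%02d", seq_len(sum(sizes)))
  make_partition <- get("make_partition", asNamespace("barcurate"))
  make_partition(ids, rep(seq_along(sizes), sizes), method = "truth")
}

# Brute-force pair-counting adjusted Rand index.
ari_oracle <- function(a, b) {
  ids <- intersect(names(a), names(b))
  a <- a[ids]; b <- b[ids]
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# Naive K2P between two encoded sequences: per-site loop, pairwise deletion.
k2p_oracle <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  ts_pairs <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  n <- 0; ts <- 0; tv <- 0
  for (i in seq_along(a)) {
    if (!(a[i] %in% acgt) || !(b[i] %in% acgt)) next
    n <- n + 1
    if (a[i] != b[i]) {
      is_ts <- any(vapply(ts_pairs, function(p)
        a[i] == p[1] && b[i] == p[2], logical(1)))
      if (is_ts) ts <- ts + 1 else tv <- tv + 1
    }
  }
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(Inf)
  -0.5 * log(w1) - 0.25 * log(w2)
}

# Exhaustive frontier enumeration and independent likelihood for PTP.
enum_frontiers <- function(tree) {
  kids <- barcurate:::node_children(tree)
  root <- barcurate:::tree_root(tree)
  rec <- function(v) {
    own <- list(v)
    if (length(kids[[v]]) == 0) return(own)
    parts <- lapply(kids[[v]], rec)
    combo <- Reduce(function(a, b) {
      out <- list()
      for (x in a) for (y in b) out[[length(out) + 1]] <- c(x, y)
      out
    }, parts)
    c(own, combo)
  }
  rec(root)
}

ptp_ll_oracle <- function(tree, frontier, mode, min_br = 1e-7) {
  ntip <- length(tree$tip.label)
  tu <- barcurate:::tips_under(tree)
  # edge is coalescent iff its child lies inside (or is) a frontier node's
  # subtree below that node
  desc <- lapply(frontier, function(f) {
    under <- unlist(lapply(seq_len(ntip + tree$Nnode), function(v)
      if (all(tu[[v]] %in% tu[[f]]) && v != f) v else NULL))
    under
  })
  cls <- rep("sp", nrow(tree$edge))
  ent <- rep(NA_integer_, nrow(tree$edge))
  for (k in seq_along(frontier)) {
    inside <- tree$edge[, 2] %in% c(desc[[k]])
    cls[inside] <- "co"; ent[inside] <- k
  }
  use <- tree$edge.length >= min_br
  cll <- function(len) {
    n <- length(len); if (n == 0) return(0)
    n * log(n / sum(len)) - n
  }
  ll <- cll(tree$edge.length[cls == "sp" & use])
  if (mode == "single") ll + cll(tree$edge.length[cls == "co" & use])
  else ll + sum(vapply(seq_along(frontier), function(k)
    cll(tree$edge.length[cls == "co" & use & !is.na(ent) & ent == k]),
    numeric(1)))
}


# Fabricate an assignment_outcomes object plus the partitions needed to
# classify it: `n` queries of which `tp` are correctly assigned, `fp`
# wrongly assigned, and `amb` ambiguous; consensus levels set so that
# `n3` are 3/3 and `n2` are 2/3 (the rest "none").
fake_outcomes <- function(n, tp, n3, n2) {
  qids <- sprintf("q%03d", seq_len(n))
  ref_ids <- sprintf("ref%03d", seq_len(n))
  ref_part <- partition(stats::setNames(sprintf("OTU_%03d", seq_len(n)),
                                        ref_ids))
  # each query's pooled OTU contains exactly one reference member, so the
  # truth map is the identity OTU_i
  pooled <- partition(stats::setNames(
    rep(sprintf("P%03d", seq_len(n)), 2), c(ref_ids, qids)))
  amb <- n - n3 - n2
  level <- c(rep("3/3", n3), rep("2/3", n2), rep("none", amb))
  truth_otu <- sprintf("OTU_%03d", seq_len(n))
  sel <- truth_otu
  # wrong selections for the non-TP, non-ambiguous queries
  wrong <- which(level != "none")
  wrong <- wrong[seq_len(max(0, length(wrong) - tp))]
  if (length(wrong) > 0)
    sel[wrong] <- sprintf("OTU_%03d", (seq_along(wrong) %% n) + 1L)
  sel[level == "none"] <- "ambiguous"
  cons <- data.frame(query_id = qids, consensus_otu = sel,
                     consensus_level = level,
                     mean_probability = runif(n, 0.3, 0.9),
                     stringsAsFactors = FALSE)
  outcomes <- structure(list(methods = data.frame(), consensus = cons),
                        class = "assignment_outcomes")
  list(outcomes = outcomes, pooled = pooled, ref_part = ref_part)
}

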