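# Specimen assignment: three methods (BP back-propagation network, FZ
# fuzzy-set nearest neighbour, FZKMER alignment-free k-mer variant), a
# 2-of-3 consensus verdict, and the selected-OTU / nearest-neighbour ratio
# diagnostic used to spot candidate false positives.

#' Z-shaped fuzzy membership function
#'
#' Equals 1 for `x <= a`, decreases smoothly to 0 at `x >= b`, passing
#' through 0.5 at the midpoint `(a + b) / 2`. When `b <= a` (degenerate),
#' collapses to a step function at `a`.
#'
#' @param x distance of the query to the selected OTU.
#' @param a intra-OTU variability bound (distances below are full members).
#' @param b inter-OTU bound (distances beyond are non-members).
#' @return membership value in \[0, 1\].
#' @export
fmf <- function(x, a, b) {
  if (is.na(a) || is.na(b)) return(NA_real_)
  if (b <= a) return(as.numeric(x <= a))
  if (x <= a) return(1)
  if (x >= b) return(0)
  mid <- (a + b) / 2
  if (x <= mid) 1 - 2 * ((x - a) / (b - a))^2
  else 2 * ((x - b) / (b - a))^2
}

# K2P distances from one query sequence to a set of reference sequences.
query_dists <- function(query_seq, ref_seqs) {
  vapply(ref_seqs, function(s) k2p_distance(query_seq, s)$distance,
         numeric(1L))
}

# Normalised k-mer frequency vectors (columns = all ACGT words of length k;
# words containing ambiguity codes or gaps are skipped).
kmer_features <- function(seqs, k) {
  words <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                       stringsAsFactors = FALSE)[k:1])
  out <- matrix(0, nrow = length(seqs), ncol = length(words),
                dimnames = list(names(seqs), sort(words)))
  for (i in seq_along(seqs)) {
    s <- ungapped(seqs[i])
    n <- nchar(s)
    if (n < k) stop("sequence shorter than k-mer length ", k)
    km <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    tab <- table(km[km %in% colnames(out)])
    if (sum(tab) > 0) out[i, names(tab)] <- as.numeric(tab) / sum(tab)
  }
  out
}

#' Build an assignment reference from a delimited library
#'
#' Draws one representative sequence per OTU uniformly at random (seeded)
#' and computes, from the full library distances, the per-OTU intra-OTU
#' variability bound theta1 (maximum intraspecific K2P; singletons fall
#' back to the global median over multi-member OTUs, or 0.005 when none)
#' and the per-OTU nearest-neighbour distance theta2.
#'
#' @param library a [barcode_library].
#' @param partition a [partition] covering the library's (QC-passing)
#'   records.
#' @param seed RNG seed for the representative draw.
#' @return Object of class `assignment_reference`.
#' @export
build_assignment_reference <- function(library, partition, seed = 1L) {
  D <- k2p_matrix(library)
  gt <- gap_table(D, partition)
  tab <- gt$table
  theta1 <- stats::setNames(tab$max_intraspecific, tab$otu_id)
  multi <- tab$n >= 2L & is.finite(tab$max_intraspecific)
  fallback <- if (any(multi)) stats::median(tab$max_intraspecific[multi])
              else 0.005
  theta1[tab$n < 2L] <- fallback
  theta2 <- stats::setNames(tab$nn_distance, tab$otu_id)
  set.seed(seed)
  asg <- partition$assignments[D$ids]
  reps <- vapply(sort(unique(asg)), function(o) {
    members <- names(asg)[asg == o]
    members[sample.int(length(members), 1L)]
  }, character(1L))
  rec <- library$records
  rep_seqs <- stats::setNames(rec$sequence[match(reps, rec$record_id)],
                              names(reps))
  structure(list(representatives = data.frame(otu_id = names(reps),
                                              record_id = unname(reps),
                                              stringsAsFactors = FALSE),
                 rep_seqs = rep_seqs, theta1 = theta1, theta2 = theta2,
                 library = library, partition = partition, seed = seed),
            class = "assignment_reference")
}

#' @export
print.assignment_reference <- function(x, ...) {
  cat("assignment_reference:", length(x$rep_seqs), "OTU representatives\n")
  invisible(x)
}

# Shared per-query K2P diagnostics against the representatives.
k2p_entry <- function(query_seq, ref, selected) {
  d <- query_dists(query_seq, ref$rep_seqs)
  otus <- names(ref$rep_seqs)
  if (length(otus) == 1L)
    return(list(dist_to_selected = unname(d[selected]), nn_otu = NA_character_,
                dist_to_nn = NA_real_, ratio = NA_real_, d = d))
  others <- otus[otus != selected]
  nn <- others[which.min(d[others])]
  nn <- sort(others[d[others] == d[nn]])[1L]
  list(dist_to_selected = unname(d[selected]), nn_otu = nn,
       dist_to_nn = unname(d[nn]), ratio = unname(d[selected] / d[nn]),
       d = d)
}

as_query_seqs <- function(queries) {
  if (inherits(queries, "barcode_library"))
    stats::setNames(queries$records$sequence, queries$records$record_id)
  else if (is.character(queries)) {
    if (is.null(names(queries))) stop("query sequences must be named")
    queries
  } else stop("queries must be a barcode_library or named character vector")
}

#' Fuzzy-set nearest-neighbour assignment (FZ)
#'
#' Selects, for each query, the OTU whose representative is nearest in K2P
#' distance (1-nearest-neighbour) and attaches the Z-shaped fuzzy
#' membership [fmf()] probability with `a = theta1` and `b = theta2` of the
#' selected OTU. By construction FZ always selects the nearest OTU, so its
#' ratio diagnostic never exceeds 1.
#'
#' @param queries a [barcode_library] or named character vector of aligned
#'   query sequences.
#' @param ref an [build_assignment_reference()] object.
#' @return data.frame with one row per query: `query_id`, `method`,
#'   `selected_otu`, `probability`, `dist_to_selected`, `nn_otu`,
#'   `dist_to_nn`, `ratio`.
#' @export
assign_fz <- function(queries, ref) {
  seqs <- as_query_seqs(queries)
  otus <- names(ref$rep_seqs)
  rows <- lapply(seq_along(seqs), function(i) {
    d <- query_dists(seqs[i], ref$rep_seqs)
    sel <- sort(otus[d == min(d)])[1L]
    e <- k2p_entry(seqs[i], ref, sel)
    prob <- if (length(otus) == 1L) 1
            else fmf(e$dist_to_selected, ref$theta1[sel], ref$theta2[sel])
    data.frame(query_id = names(seqs)[i], method = "FZ", selected_otu = sel,
               probability = unname(prob),
               dist_to_selected = e$dist_to_selected, nn_otu = e$nn_otu,
               dist_to_nn = e$dist_to_nn, ratio = e$ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Leave-one-out self-assignment accuracy of the full library in k-mer space.
loo_accuracy <- function(feats, labels) {
  dm <- as.matrix(stats::dist(feats))
  diag(dm) <- Inf
  pred <- labels[apply(dm, 1L, which.min)]
  mean(pred == labels)
}

#' Alignment-free k-mer assignment (FZKMER)
#'
#' Chooses the k-mer length (1..`k_max`) maximising leave-one-out
#' self-assignment accuracy over the full reference library (smallest k on
#' ties), assigns each query to the OTU with the nearest representative in
#' normalised k-mer frequency space (Euclidean distance), and attaches a
#' fuzzy membership probability whose bounds are estimated from the k-mer
#' distance distributions: `a` = 95th percentile of intra-OTU distances,
#' `b` = 5th percentile of inter-OTU distances. The reported
#' `dist_to_selected`/`ratio` diagnostics are K2P-based, as for the other
#' methods.
#'
#' @inheritParams assign_fz
#' @param k_max maximum k-mer length searched (default 5).
#' @return data.frame as for [assign_fz()], with attribute `k` (chosen
#'   k-mer length) and an `uninformative` flag column when the reference
#'   holds a single OTU.
#' @export
assign_fzkmer <- function(queries, ref, k_max = 5L) {
  seqs <- as_query_seqs(queries)
  lib_rec <- ref$library$records
  keep <- is.na(lib_rec$qc_pass) | lib_rec$qc_pass
  lib_rec <- lib_rec[keep, , drop = FALSE]
  if (min(nchar(ungapped(c(lib_rec$sequence, seqs)))) < k_max)
    stop("k_max exceeds the shortest ungapped sequence")
  labels <- unname(ref$partition$assignments[lib_rec$record_id])
  lib_seqs <- stats::setNames(lib_rec$sequence, lib_rec$record_id)
  acc <- numeric(k_max)
  feats_k <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    feats_k[[k]] <- kmer_features(lib_seqs, k)
    acc[k] <- loo_accuracy(feats_k[[k]], labels)
  }
  k_best <- which(acc == max(acc))[1L]           # smallest k on ties
  feats <- feats_k[[k_best]]
  # fuzzy bounds from the k-mer distance distributions of the library
  dm <- as.matrix(stats::dist(feats))
  same <- outer(labels, labels, `==`)
  ut <- upper.tri(dm)
  intra <- dm[ut & same]
  inter <- dm[ut & !same]
  a <- if (length(intra) > 0) stats::quantile(intra, 0.95, names = FALSE)
       else 0
  b <- if (length(inter) > 0) stats::quantile(inter, 0.05, names = FALSE)
       else Inf
  single <- length(ref$rep_seqs) == 1L
  rep_feats <- feats[match(ref$representatives$record_id, rownames(feats)), ,
                     drop = FALSE]
  rownames(rep_feats) <- ref$representatives$otu_id
  otus <- rownames(rep_feats)
  rows <- lapply(seq_along(seqs), function(i) {
    qf <- kmer_features(seqs[i], k_best)
    kd <- sqrt(colSums((t(rep_feats) - as.numeric(qf))^2))
    sel <- sort(otus[kd == min(kd)])[1L]
    prob <- if (single) 1 else fmf(unname(kd[sel]), a, b)
    e <- k2p_entry(seqs[i], ref, sel)
    data.frame(query_id = names(seqs)[i], method = "FZKMER",
               selected_otu = sel, probability = unname(prob),
               dist_to_selected = e$dist_to_selected, nn_otu = e$nn_otu,
               dist_to_nn = e$dist_to_nn, ratio = e$ratio,
               kmer_dist = unname(kd[sel]),
               uninformative = single, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "k") <- k_best
  attr(out, "kmer_bounds") <- c(a = a, b = b)
  out
}

# One-hidden-layer softmax network trained by batch gradient descent.
# Features are z-scored (k-mer frequencies are tiny, which otherwise
# starves the gradients); the scaling is stored for prediction.
train_bp_network <- function(X, labels, hidden_units, epochs, learning_rate,
                             seed) {
  classes <- sort(unique(labels))
  K <- length(classes)
  Y <- matrix(0, nrow(X), K)
  Y[cbind(seq_len(nrow(X)), match(labels, classes))] <- 1
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  X <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  set.seed(seed)
  F_ <- ncol(X)
  W1 <- matrix(stats::runif((F_ + 1L) * hidden_units, -0.5, 0.5), F_ + 1L)
  W2 <- matrix(stats::runif((hidden_units + 1L) * K, -0.5, 0.5),
               hidden_units + 1L)
  Xb <- cbind(1, X)
  n <- nrow(X)
  V1 <- W1 * 0; V2 <- W2 * 0
  momentum <- 0.9
  for (it in seq_len(epochs)) {
    H <- 1 / (1 + exp(-(Xb %*% W1)))
    Hb <- cbind(1, H)
    Z <- Hb %*% W2
    Z <- Z - apply(Z, 1L, max)
    P <- exp(Z); P <- P / rowSums(P)
    dZ2 <- (P - Y) / n
    dW2 <- crossprod(Hb, dZ2)
    dH <- (dZ2 %*% t(W2[-1L, , drop = FALSE])) * H * (1 - H)
    dW1 <- crossprod(Xb, dH)
    V1 <- momentum * V1 - learning_rate * dW1
    V2 <- momentum * V2 - learning_rate * dW2
    W1 <- W1 + V1
    W2 <- W2 + V2
  }
  list(W1 = W1, W2 = W2, classes = classes, mu = mu, sd = sdv)
}

predict_bp_network <- function(net, X) {
  X <- sweep(sweep(X, 2L, net$mu), 2L, net$sd, "/")
  H <- 1 / (1 + exp(-(cbind(1, X) %*% net$W1)))
  Z <- cbind(1, H) %*% net$W2
  Z <- Z - apply(Z, 1L, max)
  P <- exp(Z); P <- P / rowSums(P)
  colnames(P) <- net$classes
  P
}

#' Back-propagation neural-network assignment (BP)
#'
#' Trains a one-hidden-layer network (logistic hidden units, softmax
#' output, batch gradient descent on cross-entropy) on the normalised
#' `k_feat`-mer frequency vectors of all library members, labelled by OTU,
#' and assigns each query to the class with the highest softmax output;
#' that output is the reported probability. Training is deterministic under
#' `seed`.
#'
#' @inheritParams assign_fz
#' @param hidden_units hidden-layer width (default 10).
#' @param epochs gradient-descent epochs (default 1000).
#' @param learning_rate gradient-descent step size (default 0.01).
#' @param k_feat k-mer length of the feature encoding (default 3).
#' @param seed RNG seed for the weight initialisation.
#' @return data.frame as for [assign_fz()].
#' @export
assign_bp <- function(queries, ref, hidden_units = 10L, epochs = 1000L,
                      learning_rate = 0.01, k_feat = 3L, seed = 1L) {
  if (length(ref$rep_seqs) < 2L)
    stop("BP needs at least 2 OTUs in the reference")
  seqs <- as_query_seqs(queries)
  lib_rec <- ref$library$records
  keep <- is.na(lib_rec$qc_pass) | lib_rec$qc_pass
  lib_rec <- lib_rec[keep, , drop = FALSE]
  labels <- unname(ref$partition$assignments[lib_rec$record_id])
  X <- kmer_features(stats::setNames(lib_rec$sequence, lib_rec$record_id),
                     k_feat)
  net <- train_bp_network(X, labels, hidden_units, epochs, learning_rate,
                          seed)
  Q <- kmer_features(seqs, k_feat)
  P <- predict_bp_network(net, Q)
  rows <- lapply(seq_along(seqs), function(i) {
    sel <- net$classes[which.max(P[i, ])]
    e <- k2p_entry(seqs[i], ref, sel)
    data.frame(query_id = names(seqs)[i], method = "BP", selected_otu = sel,
               probability = unname(max(P[i, ])),
               dist_to_selected = e$dist_to_selected, nn_otu = e$nn_otu,
               dist_to_nn = e$dist_to_nn, ratio = e$ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Consensus verdict over the three assignment methods
#'
#' @param entries data.frame of exactly three per-method rows for one query
#'   (as produced by the `assign_*` functions).
#' @return list with `consensus_otu` (or `"ambiguous"`), `consensus_level`
#'   (`"3/3"`, `"2/3"` or `"none"`), and `mean_probability` (arithmetic
#'   mean of the three probabilities).
#' @export
consensus_assignment <- function(entries) {
  if (nrow(entries) != 3L) stop("need exactly three per-method entries")
  sel <- entries$selected_otu
  tab <- sort(table(sel), decreasing = TRUE)
  mean_p <- mean(entries$probability)
  if (tab[1L] == 3L)
    list(consensus_otu = names(tab)[1L], consensus_level = "3/3",
         mean_probability = mean_p)
  else if (tab[1L] == 2L)
    list(consensus_otu = names(tab)[1L], consensus_level = "2/3",
         mean_probability = mean_p)
  else
    list(consensus_otu = "ambiguous", consensus_level = "none",
         mean_probability = mean_p)
}

#' Ratio diagnostic: selected OTU distance over nearest-other distance
#'
#' The default reading divides the query's K2P distance to the selected
#' OTU's representative by its distance to the nearest non-selected
#' representative; values above 1 flag that the selected OTU is not the
#' nearest (a candidate false positive). The alternative reading
#' (`mode = "otu"`) divides the selected OTU's own intra-OTU variability
#' (theta1) by that OTU's nearest-neighbour distance (theta2).
#'
#' @param query_seq one aligned query sequence (character scalar).
#' @param selected_otu OTU id whose distance goes in the numerator.
#' @param ref an `assignment_reference`.
#' @param mode `"query"` (default) or `"otu"`.
#' @return the ratio (numeric scalar).
#' @export
ratio_diagnostic <- function(query_seq, selected_otu, ref,
                             mode = c("query", "otu")) {
  mode <- match.arg(mode)
  if (mode == "otu")
    return(unname(ref$theta1[selected_otu] / ref$theta2[selected_otu]))
  k2p_entry(query_seq, ref, selected_otu)$ratio
}

#' Run all three assignment methods plus the consensus on a query set
#'
#' @inheritParams assign_fz
#' @param config a [curation_config()] list (assignment block used).
#' @param seed RNG seed passed to BP.
#' @return Object of class `assignment_outcomes`: list with `methods` (one
#'   row per query x method) and `consensus` (one row per query:
#'   `query_id`, `consensus_otu`, `consensus_level`, `mean_probability`).
#' @export
assign_all <- function(queries, ref, config = curation_config(), seed = 1L) {
  seqs <- as_query_seqs(queries)
  if (length(seqs) == 0L)
    return(structure(list(
      methods = data.frame(), consensus = data.frame(
        query_id = character(0), consensus_otu = character(0),
        consensus_level = character(0), mean_probability = numeric(0),
        stringsAsFactors = FALSE)), class = "assignment_outcomes"))
  ac <- config$assign
  fz <- assign_fz(seqs, ref)
  fzk <- assign_fzkmer(seqs, ref, k_max = ac$k_max)
  bp <- if (length(ref$rep_seqs) >= 2L)
    assign_bp(seqs, ref, hidden_units = ac$hidden_units,
              epochs = ac$epochs, learning_rate = ac$learning_rate,
              k_feat = ac$k_feat, seed = seed)
  else transform(fz, method = "BP", probability = 1)
  methods <- rbind(bp[names(fz)], fz, fzk[names(fz)])
  cons <- lapply(names(seqs), function(q) {
    e <- methods[methods$query_id == q, , drop = FALSE]
    v <- consensus_assignment(e)
    data.frame(query_id = q, consensus_otu = v$consensus_otu,
               consensus_level = v$consensus_level,
               mean_probability = v$mean_probability,
               stringsAsFactors = FALSE)
  })
  structure(list(methods = methods, consensus = do.call(rbind, cons),
                 fzkmer_k = attr(fzk, "k")),
            class = "assignment_outcomes")
}

#' @export
print.assignment_outcomes <- function(x, ...) {
  cat("assignment_outcomes:", nrow(x$consensus), "queries\n")
  if (nrow(x$consensus) > 0) {
    lv <- table(x$consensus$consensus_level)
    cat("  consensus levels:",
        paste(names(lv), as.integer(lv), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
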