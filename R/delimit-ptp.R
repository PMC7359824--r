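# Poisson tree process delimitation. Edges are classed speciation
# (between-species) vs coalescent (within-species) by a frontier of subtree
# roots; branch lengths in each class are modelled as exponential with
# class-specific rate (single mode) or one rate per within-species subtree
# plus one speciation rate (multi mode, after mPTP). The frontier is found
# by alternating an exact dynamic programme (optimal frontier at fixed
# rates) with closed-form rate re-estimation, from the one-species start
# plus seeded random restarts.

# --- generic rooted-tree helpers -------------------------------------------

# children[[v]]: child node ids of node v (empty for tips).
node_children <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  kids
}

tree_root <- function(tree) setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]

# tips_under[[v]]: tip ids in the subtree rooted at v.
tips_under <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  kids <- node_children(tree)
  out <- vector("list", n)
  po <- ape::reorder.phylo(tree, "postorder")
  for (v in seq_len(ntip)) out[[v]] <- v
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; c_ <- po$edge[e, 2L]
    out[[p]] <- c(out[[p]], out[[c_]])
  }
  out
}

# Partition of tips induced by a frontier (one OTU per frontier node).
frontier_partition <- function(tree, frontier, method, score = NULL) {
  tu <- tips_under(tree)
  mem <- integer(length(tree$tip.label))
  for (i in seq_along(frontier)) mem[tu[[frontier[i]]]] <- i
  make_partition(tree$tip.label, mem, method = method, score = score)
}

# Random frontier: from the root, descend into each child with prob p_desc.
random_frontier <- function(kids, root, ntip, p_desc = 0.5) {
  out <- integer(0)
  stack <- root
  while (length(stack) > 0) {
    v <- stack[1L]; stack <- stack[-1L]
    if (v <= ntip || stats::runif(1) > p_desc) out <- c(out, v)
    else stack <- c(stack, kids[[v]])
  }
  out
}

# --- PTP likelihood --------------------------------------------------------

# Exponential class log-likelihood at the MLE rate n/S.
exp_class_ll <- function(n, S) {
  if (n == 0L) return(0)
  n * log(n / S) - n
}

ptp_loglik <- function(frontier, sub_n, sub_S, total_n, total_S, mode) {
  nc <- sub_n[frontier]; Sc <- sub_S[frontier]
  n_sp <- total_n - sum(nc); S_sp <- total_S - sum(Sc)
  ll <- exp_class_ll(n_sp, S_sp)
  if (mode == "single") ll + exp_class_ll(sum(nc), sum(Sc))
  else ll + sum(mapply(exp_class_ll, nc, Sc))
}

#' OTU delimitation by the Poisson tree process
#'
#' @param tree rooted `phylo` with branch lengths (an unrooted tree is
#'   midpoint-rooted). Branches shorter than `min_br` are ignored in the
#'   likelihood.
#' @param mode `"multi"` (default; one coalescent rate per within-species
#'   subtree, after mPTP) or `"single"` (one shared coalescent rate).
#' @param seed RNG seed for the random restarts (default 1).
#' @param restarts number of seeded random restarts beyond the one-species
#'   start (default 10).
#' @param min_br minimum branch length entering the likelihood
#'   (default 1e-7).
#' @return Object of class `ptp_result`: list with `partition`, `logL`,
#'   `null_logL` (one-species model), `mode`, `degenerate` flag.
#' @export
delimit_ptp <- function(tree, mode = c("multi", "single"), seed = 1L,
                        restarts = 10L, min_br = 1e-7) {
  mode <- match.arg(mode)
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 4L) stop("PTP needs at least 4 tips")
  usable <- tree$edge.length >= min_br
  if (mean(usable) < 0.1) {
    warning("tree dominated by zero-length branches; returning one OTU")
    return(structure(list(
      partition = make_partition(tree$tip.label, rep(1L, ntip),
                                 method = paste0("PTP-", mode)),
      logL = NA_real_, null_logL = NA_real_, mode = mode,
      degenerate = TRUE), class = "ptp_result"))
  }
  kids <- node_children(tree)
  root <- tree_root(tree)
  nnode <- ntip + tree$Nnode
  # per-node count/sum of usable edge lengths in the subtree below the node
  sub_n <- integer(nnode); sub_S <- numeric(nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  po_len <- po$edge.length
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; c_ <- po$edge[e, 2L]
    use <- po_len[e] >= min_br
    sub_n[p] <- sub_n[p] + sub_n[c_] + as.integer(use)
    sub_S[p] <- sub_S[p] + sub_S[c_] + if (use) po_len[e] else 0
  }
  total_n <- sub_n[root]; total_S <- sub_S[root]
  ll_of <- function(f) ptp_loglik(f, sub_n, sub_S, total_n, total_S, mode)
  null_ll <- ll_of(root)

  # postorder node sequence: every child before its parent, root last
  po_nodes <- c(po$edge[, 2L], root)
  e_of_child <- match(seq_len(nnode), tree$edge[, 2L])

  # With the rates fixed, the best frontier is found exactly by a two-state
  # dynamic programme over the tree: A[v] scores v's subtree as one species
  # (coalescent class: per-subtree MLE rate in multi mode, the shared rate
  # in single mode); B[v] scores v as a speciating backbone node, each
  # child either becoming a frontier root or continuing the backbone. A
  # frontier root's stem must be an informative (>= min_br) branch:
  # zero-length edges carry no information and cannot delimit species,
  # though they may sit inside the backbone (ignored by the likelihood).
  dp_frontier <- function(lambda_sp, lambda_coal = NULL) {
    A <- numeric(nnode)
    Bv <- rep(-Inf, nnode)
    cutB <- vector("list", nnode)
    for (v in po_nodes) {
      if (v > ntip)
        A[v] <- if (is.null(lambda_coal)) exp_class_ll(sub_n[v], sub_S[v])
                else sub_n[v] * log(lambda_coal) - lambda_coal * sub_S[v]
      if (v <= ntip) next
      tot <- 0; cut <- integer(0)
      for (c_ in kids[[v]]) {
        e <- e_of_child[c_]
        if (usable[e])
          tot <- tot + log(lambda_sp) - lambda_sp * tree$edge.length[e]
        optA <- if (usable[e]) A[c_] else -Inf
        if (optA >= Bv[c_]) { tot <- tot + optA; cut <- c(cut, c_) }
        else { tot <- tot + Bv[c_]; cut <- c(cut, cutB[[c_]]) }
        if (!is.finite(tot)) break
      }
      if (is.finite(tot)) { Bv[v] <- tot; cutB[[v]] <- cut }
    }
    if (Bv[root] > A[root]) cutB[[root]] else root
  }

  # Alternate the exact DP (rates fixed) with closed-form rate
  # re-estimation; several seeded rate initialisations guard against local
  # optima of the profile likelihood.
  mean_len <- mean(tree$edge.length[usable])
  refine <- function(frontier) {
    cur <- ll_of(frontier)
    for (it in 1:25) {
      nc <- sub_n[frontier]; Sc <- sub_S[frontier]
      n_sp <- total_n - sum(nc); S_sp <- total_S - sum(Sc)
      lam_sp <- if (n_sp > 0L && S_sp > 0) n_sp / S_sp else 1 / mean_len
      f2 <- if (mode == "multi") dp_frontier(lam_sp)
            else dp_frontier(lam_sp, if (sum(nc) > 0L) sum(nc) / sum(Sc)
                                     else 1 / mean_len)
      l2 <- ll_of(f2)
      if (l2 <= cur + 1e-9) break
      frontier <- f2; cur <- l2
    }
    list(frontier = frontier, ll = cur)
  }

  set.seed(seed)
  best <- refine(root)
  for (r in seq_len(restarts)) {
    res <- refine(random_frontier(kids, root, ntip))
    if (res$ll > best$ll) best <- res
  }
  structure(list(
    partition = frontier_partition(tree, best$frontier,
                                   method = paste0("PTP-", mode),
                                   score = best$ll),
    logL = best$ll, null_logL = null_ll, mode = mode, degenerate = FALSE),
    class = "ptp_result")
}

#' @export
print.ptp_result <- function(x, ...) {
  cat("ptp_result (", x$mode, "): ", n_otus(x$partition), " OTUs, logL ",
      format(x$logL), " (null ", format(x$null_logL), ")\n", sep = "")
  invisible(x)
}
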