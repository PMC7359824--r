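# General mixed Yule-coalescent delimitation on an ultrametric chronogram.
#
# Events (branching times) are ordered from the root; a frontier of entity
# roots classes every lineage as diversification (above/at the frontier) or
# coalescent (inside an entity). Waiting times between events follow
# exponential rates: lambda_div * n^p_div for the diversification process and
# sum over entities of lambda_coal * choose(n_k, 2)^p_coal for the
# coalescent processes. Rates lambda are profiled out in closed form; the
# scaling exponents (p_div, p_coal) are optimised numerically. Single mode
# scans all time thresholds; multi mode refines the frontier greedily per
# lineage under AIC. The root event is conditioned on. The likelihood of a
# diversification event uses the lineage count of the interval preceding it
# (pre-split count, the forward Yule convention); a coalescent event uses
# the entity's count in the interval that the event starts (post-split
# count, the backward coalescent convention).

# Precompute the interval bookkeeping for a chronogram.
gmyc_data <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[seq_len(ntip)]) - depth
  age[seq_len(ntip)] <- 0
  parent <- integer(nnode)
  for (e in seq_len(nrow(tree$edge)))
    parent[tree$edge[e, 2L]] <- tree$edge[e, 1L]
  root <- tree_root(tree)
  internal <- setdiff(seq_len(nnode), seq_len(ntip))
  ev_node <- internal[order(age[internal], decreasing = TRUE)]
  t_ev <- age[ev_node]                      # t_1 (root) >= t_2 >= ...
  nev <- length(ev_node)
  t_lo <- c(t_ev[-1L], 0)                   # interval i spans (t_lo[i], t_ev[i])
  x <- t_ev - t_lo
  # branch b = edge row b; crossing[b, i]: branch present during interval i
  tol <- max(t_ev) * 1e-9 + 1e-12
  pa <- age[tree$edge[, 1L]]
  ca <- age[tree$edge[, 2L]]
  crossing <- outer(pa, t_ev, function(a, t) a >= t - tol) &
              outer(ca, t_lo, function(a, t) a <= t + tol)
  list(tree = tree, ntip = ntip, nnode = nnode, age = age, parent = parent,
       root = root, ev_node = ev_node, t_ev = t_ev, x = x, nev = nev,
       crossing = crossing, child = tree$edge[, 2L], tol = tol,
       topo_order = order(depth))
}

# Entity index of the nearest ancestor-or-self frontier node, per node
# (0 when none, i.e. the node lies on the diversification backbone).
entity_of_node <- function(gd, frontier) {
  inF <- integer(gd$nnode)
  inF[frontier] <- seq_along(frontier)
  ord <- gd$topo_order                                # root first
  ent <- integer(gd$nnode)
  for (v in ord) {
    ent[v] <- if (inF[v] > 0L) inF[v]
              else if (v == gd$root) 0L
              else ent[gd$parent[v]]
  }
  ent
}

# Per-interval lineage counts for a frontier: n_div (diversification
# lineages per interval), ent_raw (per-interval per-entity counts), and
# ev_ent (entity of each event's node; 0 = diversification event).
# Diversification lineages are the branches at or above the frontier
# (entity stems included: a not-yet-coalescing species is still one
# lineage of the diversification process); branches strictly inside an
# entity belong to that entity's coalescent.
gmyc_counts <- function(gd, frontier) {
  ent_node <- entity_of_node(gd, frontier)
  lab_b <- ent_node[gd$child]
  inF <- logical(gd$nnode); inF[frontier] <- TRUE
  lab_b[inF[gd$child]] <- 0L
  nf <- length(frontier)
  n_div <- integer(gd$nev)
  ent_raw <- vector("list", gd$nev)
  for (i in seq_len(gd$nev)) {
    lab <- lab_b[gd$crossing[, i]]
    n_div[i] <- sum(lab == 0L)
    ent_raw[[i]] <- tabulate(lab[lab > 0L], nbins = nf)
  }
  list(n_div = n_div, ent_raw = ent_raw, ev_ent = ent_node[gd$ev_node])
}

# Rate factors per interval at given scaling exponents: A (diversification,
# n_div^p_div) and B (coalescent, sum over entities of choose(n_k, 2)^p_coal).
gmyc_factors <- function(cnt, p_div, p_coal) {
  A <- ifelse(cnt$n_div > 0L, cnt$n_div^p_div, 0)
  B <- vapply(cnt$ent_raw, function(v) {
    v <- v[v >= 2L]
    if (length(v) == 0L) 0 else sum((v * (v - 1) / 2)^p_coal)
  }, numeric(1L))
  list(A = A, B = B)
}

# Mixed-process log-likelihood: the waiting time of each inter-event
# interval is exponential with the TOTAL rate b_i (diversification + all
# entity coalescents), and the event starting interval i contributes the
# factor b_i (post-split lineage counts: the backward-coalescent
# convention, which also keeps every observed event's rate positive). The
# root event is conditioned on.
# par = (log lambda_div, log lambda_coal, p_div, p_coal).
gmyc_loglik <- function(gd, cnt, par) {
  nev <- gd$nev
  if (nev < 2L) return(0)
  lam_d <- exp(par[1L]); lam_c <- exp(par[2L])
  fac <- gmyc_factors(cnt, par[3L], par[4L])
  rate <- lam_d * fac$A + lam_c * fac$B
  if (any(!is.finite(rate))) return(-Inf)
  f_ev <- rate[2:nev]                     # factor of events 2..nev
  if (any(f_ev <= 0)) return(-Inf)
  pos <- gd$x > 0                 # zero-length (tied) intervals: no exposure
  sum(log(f_ev)) - sum(rate[pos] * gd$x[pos])
}

# Fit the model for a fixed frontier: optimise the two rates and the two
# scaling exponents. Exponents are restricted to [0, 1]: p = 1 recovers
# the canonical Yule / coalescent rates, p < 1 damps the dependence on
# lineage count, and super-linear scaling is excluded because it lets a
# single process mimic the before/after rate jump of the mixed model.
gmyc_fit_frontier <- function(gd, frontier, p_init = c(1, 1)) {
  cnt <- gmyc_counts(gd, frontier)
  # starting rates: events per unit of accumulated rate-factor exposure
  fac <- gmyc_factors(cnt, p_init[1L], p_init[2L])
  pos <- gd$x > 0
  S_d <- sum(fac$A[pos] * gd$x[pos])
  S_c <- sum(fac$B[pos] * gd$x[pos])
  m <- gd$nev - 1L
  l0 <- c(if (S_d > 0) log(m / 2 / S_d) else 0,
          if (S_c > 0) log(m / 2 / S_c) else 0)
  nll <- function(par) {
    v <- -gmyc_loglik(gd, cnt, par)
    if (!is.finite(v)) 1e12 else v
  }
  opt <- stats::optim(c(l0, pmin(pmax(p_init, 0), 1)), nll,
                      method = "L-BFGS-B",
                      lower = c(-40, -40, 0, 0), upper = c(40, 40, 1, 1),
                      control = list(maxit = 200))
  list(logL = -opt$value, lambda_div = exp(opt$par[1L]),
       lambda_coal = exp(opt$par[2L]), p_div = opt$par[3L],
       p_coal = opt$par[4L], frontier = frontier)
}

# Threshold frontier k: lineages crossing interval k root the entities.
threshold_frontier <- function(gd, k) {
  sort(unique(gd$child[gd$crossing[, k]]))
}

#' OTU delimitation by the general mixed Yule-coalescent model
#'
#' Single mode scans every branching-time threshold, fits the mixed model at
#' each, and keeps the maximum-likelihood threshold; the result is accepted
#' against the single-coalescent null by a likelihood-ratio test
#' (chi-squared, `df` degrees of freedom): when non-significant at `alpha`
#' one OTU is returned. Multi mode refines the best single-threshold
#' frontier per lineage, greedily accepting splits/merges while AIC
#' improves (AIC parameter count: 4 rate/scaling parameters + one per
#' entity).
#'
#' @param chrono rooted ultrametric `phylo` (e.g. [upgma_chronogram()]).
#' @param mode `"multi"` (default) or `"single"`.
#' @param alpha significance level of the likelihood-ratio gate
#'   (default 0.05).
#' @param df degrees of freedom of the LR test (default 2; debated in the
#'   field, hence exposed).
#' @return Object of class `gmyc_result`: list with `partition`, `logL`,
#'   `null_logL`, `lr_p_value`, `threshold_age`, `mode`, `test_applicable`.
#' @export
delimit_gmyc <- function(chrono, mode = c("multi", "single"), alpha = 0.05,
                         df = 2) {
  mode <- match.arg(mode)
  ntip <- length(chrono$tip.label)
  if (!ape::is.rooted(chrono)) stop("chronogram must be rooted")
  if (!is_ultrametric(chrono, tol = 1e-6)) stop("tree is not ultrametric")
  one_otu <- function(applicable, p = NA_real_) structure(list(
    partition = make_partition(chrono$tip.label, rep(1L, ntip),
                               method = paste0("GMYC-", mode)),
    logL = NA_real_, null_logL = NA_real_, lr_p_value = p,
    threshold_age = NA_real_, mode = mode, test_applicable = applicable),
    class = "gmyc_result")
  if (ntip < 4L) return(one_otu(FALSE))
  chrono <- ape::multi2di(chrono)
  gd <- gmyc_data(chrono)
  null_fit <- gmyc_fit_frontier(gd, gd$root)
  best <- NULL
  for (k in seq_len(gd$nev)) {
    f <- threshold_frontier(gd, k)
    fit <- gmyc_fit_frontier(gd, f)
    fit$threshold_age <- gd$t_ev[k]
    if (is.null(best) || fit$logL > best$logL) best <- fit
  }
  lr <- 2 * (best$logL - null_fit$logL)
  p_val <- stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE)
  if (p_val >= alpha) return(one_otu(TRUE, p_val))
  if (mode == "multi") {
    kids <- node_children(chrono)
    aic <- function(fit) 2 * (4 + length(fit$frontier)) - 2 * fit$logL
    cur <- best
    repeat {
      improved <- FALSE
      cand <- list()
      for (i in seq_along(cur$frontier)) {        # split an entity
        v <- cur$frontier[i]
        if (v <= ntip) next
        cand <- c(cand, list(sort(c(cur$frontier[-i], kids[[v]]))))
      }
      pts <- unique(gd$parent[cur$frontier])       # merge sibling entities
      for (p in pts[pts > 0L]) {
        if (!all(kids[[p]] %in% cur$frontier)) next
        cand <- c(cand, list(sort(c(setdiff(cur$frontier, kids[[p]]), p))))
      }
      for (f2 in cand) {
        fit2 <- gmyc_fit_frontier(gd, f2, p_init = c(cur$p_div, cur$p_coal))
        fit2$threshold_age <- cur$threshold_age
        if (aic(fit2) < aic(cur)) { cur <- fit2; improved <- TRUE; break }
      }
      if (!improved) break
    }
    best <- cur
  }
  structure(list(
    partition = frontier_partition(chrono, best$frontier,
                                   method = paste0("GMYC-", mode),
                                   score = best$logL),
    logL = best$logL, null_logL = null_fit$logL, lr_p_value = p_val,
    threshold_age = best$threshold_age, mode = mode,
    test_applicable = TRUE), class = "gmyc_result")
}

#' @export
print.gmyc_result <- function(x, ...) {
  cat("gmyc_result (", x$mode, "): ", n_otus(x$partition), " OTUs", sep = "")
  if (isTRUE(x$test_applicable))
    cat(", LR p = ", format.pval(x$lr_p_value), sep = "")
  cat("\n")
  invisible(x)
}
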