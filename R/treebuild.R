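# Surrogate trees from distances: NJ (for PTP) and UPGMA chronograms (for
# GMYC), haplotype deduplication, and canonical newick io.

# Saturated (infinite) entries cannot enter agglomeration; cap them at twice
# the largest finite distance.
finite_dist <- function(d) {
  if (any(!is.finite(d))) {
    mx <- max(d[is.finite(d)])
    d[!is.finite(d)] <- 2 * mx
  }
  d
}

#' Neighbour-joining tree from a K2P distance matrix
#'
#' Standard Saitou-Nei NJ (via ape). Negative branch lengths are set to zero
#' with the deficit transferred to the sister branch, preserving path lengths
#' through the parent node.
#'
#' @param D a `dist_matrix` from [k2p_matrix()].
#' @return An unrooted `phylo` tree with tip labels equal to the matrix ids.
#' @export
nj_tree <- function(D) {
  if (length(D$ids) < 3L) stop("NJ needs at least 3 records")
  tr <- ape::nj(stats::as.dist(finite_dist(D$d)))
  clamp_negative_edges(tr)
}

clamp_negative_edges <- function(tr) {
  for (iter in 1:10) {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0L) break
    for (e in neg) {
      l <- tr$edge.length[e]
      if (l >= 0) next
      sib <- which(tr$edge[, 1L] == tr$edge[e, 1L])
      sib <- setdiff(sib, e)
      tr$edge.length[e] <- 0
      if (length(sib) > 0) # transfer deficit; path through parent preserved
        tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + l
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' UPGMA chronogram under a strict clock
#'
#' Average-linkage (UPGMA) clustering of the K2P distances gives an
#' ultrametric tree with node heights d/2 in distance units; ages are then
#' converted to million years with a strict clock in which *pairwise*
#' divergence accumulates at `clock_rate` per My (default 0.012, i.e. 1.2%
#' pairwise per My, 0.6% per lineage): a pair at distance d coalesces at age
#' d / clock_rate.
#'
#' @param D a `dist_matrix`.
#' @param clock_rate pairwise divergence per My (default 0.012).
#' @return A rooted ultrametric `phylo`; edge lengths in My
#'   (`attr(tree, "units") == "My"`).
#' @export
upgma_chronogram <- function(D, clock_rate = 0.012) {
  if (length(D$ids) < 2L) stop("need at least 2 records")
  hc <- stats::hclust(stats::as.dist(finite_dist(D$d)), method = "average")
  tr <- ape::as.phylo(hc)             # node heights = merge height / 2
  tr$edge.length <- tr$edge.length * 2 / clock_rate
  attr(tr, "units") <- "My"
  attr(tr, "clock_rate") <- clock_rate
  tr
}

#' Is a tree ultrametric (all root-to-tip paths equal)?
#' @param tree a rooted `phylo`.
#' @param tol relative tolerance (default 1e-9).
#' @return logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-9) {
  depth <- ape::node.depth.edgelength(tree)
  tips <- depth[seq_len(length(tree$tip.label))]
  mx <- max(tips)
  if (mx == 0) return(TRUE)
  (max(tips) - min(tips)) / mx <= tol
}

#' Collapse identical sequences to one representative per haplotype
#'
#' The representative is the first record (input order) of each
#' identical-sequence class. The returned map re-expands delimitation labels
#' from representatives to all records.
#'
#' @param library a [barcode_library].
#' @return list with `representative_ids` and `map` (named character vector:
#'   record id -> representative id).
#' @export
dedupe_tips <- function(library) {
  rec <- library$records
  cls <- match(rec$sequence, unique(rec$sequence))
  reps <- rec$record_id[!duplicated(cls)]
  map <- reps[cls]
  names(map) <- rec$record_id
  list(representative_ids = reps, map = map)
}

# Re-expand a partition over representatives to all records via a dedupe map.
expand_partition <- function(p, map) {
  asg <- p$assignments[map]
  names(asg) <- names(map)
  partition(asg, method = p$method, score = p$score)
}

#' Write a tree as canonical newick
#'
#' Children are ordered by their smallest descendant tip label, so
#' write -> read -> write is byte-stable. A `# units=` comment line records
#' the branch-length units.
#'
#' @param tree a `phylo`.
#' @param path output file.
#' @param units branch-length unit label (default from the tree attribute,
#'   else "substitutions/site").
#' @export
write_newick <- function(tree, path, units = NULL) {
  if (is.null(units))
    units <- if (!is.null(attr(tree, "units"))) attr(tree, "units")
             else "substitutions/site"
  writeLines(c(paste0("# units=", units), canonical_newick(tree)), path)
  invisible(path)
}

#' Read a newick tree (ignoring `#` comment lines)
#' @param path newick file.
#' @return a `phylo`.
#' @export
read_newick <- function(path) {
  lines <- readLines(path)
  units <- sub("^# units=", "", grep("^# units=", lines, value = TRUE))
  tr <- ape::read.tree(text = paste(grep("^#", lines, invert = TRUE,
                                         value = TRUE), collapse = ""))
  if (length(units) == 1L) attr(tr, "units") <- units
  tr
}

# Canonical newick string: children sorted by smallest descendant tip label.
canonical_newick <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  fmt <- function(x) {
    s <- sub("0+$", "", sprintf("%.10f", x))
    sub("\\.$", ".0", s)
  }
  rec <- function(node) {
    if (node <= ntip)
      return(list(str = tree$tip.label[node], key = tree$tip.label[node]))
    es <- kids[[as.character(node)]]
    ch <- lapply(es, function(e) {
      r <- rec(tree$edge[e, 2L])
      r$str <- paste0(r$str, ":", fmt(tree$edge.length[e]))
      r
    })
    ord <- order(vapply(ch, `[[`, character(1L), "key"))
    ch <- ch[ord]
    list(str = paste0("(", paste(vapply(ch, `[[`, character(1L), "str"),
                                 collapse = ","), ")"),
         key = ch[[1L]]$key)
  }
  paste0(rec(root)$str, ";")
}
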