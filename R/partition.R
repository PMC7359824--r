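# Partitions (record id -> OTU id), consensus over methods, and diffs.

#' Construct a partition
#'
#' A partition maps every record id to exactly one OTU id. OTU ids are opaque
#' labels; two partitions are equivalent up to relabeling.
#'
#' @param assignments named character vector: names are record ids, values
#'   OTU ids.
#' @param method label of the producing method.
#' @param score optional log-likelihood or other score.
#' @return Object of class `partition`.
#' @export
partition <- function(assignments, method = "unknown", score = NULL) {
  if (is.null(names(assignments)) || any(!nzchar(names(assignments))))
    stop("assignments must be named by record id")
  if (anyDuplicated(names(assignments)))
    stop("duplicated record id in partition")
  if (anyNA(assignments)) stop("every record must have an OTU")
  structure(list(assignments = vapply(assignments, as.character, character(1L)),
                 method = method, score = score),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("partition (", x$method, "): ", length(x$assignments), " records, ",
      n_otus(x), " OTUs", sep = "")
  if (!is.null(x$score)) cat(", logL ", format(x$score), sep = "")
  cat("\n")
  invisible(x)
}

#' Number of OTUs in a partition
#' @param p a [partition].
#' @return integer count.
#' @export
n_otus <- function(p) length(unique(p$assignments))

# Partition from a membership integer/character vector + ids, with OTU ids
# relabeled OTU_001... in order of first appearance.
make_partition <- function(ids, membership, method, score = NULL) {
  mem <- as.character(membership)
  lab <- paste0("OTU_", formatC(match(mem, unique(mem)),
                                width = 3, flag = "0"))
  names(lab) <- ids
  partition(lab, method = method, score = score)
}

#' Restrict a partition to a subset of ids
#' @param p a [partition].
#' @param ids record ids to keep (order preserved).
#' @return a [partition] over `ids`.
#' @export
subset_partition <- function(p, ids) {
  if (!all(ids %in% names(p$assignments))) stop("ids not in partition")
  partition(p$assignments[ids], method = p$method, score = NULL)
}

#' Consensus partition by co-membership voting
#'
#' Builds a graph over record ids with an edge between two ids whenever at
#' least `min_agree` of the input partitions place them in the same OTU; the
#' consensus OTUs are the connected components of that graph. With the
#' default `min_agree = 2` this is the "at least two methods converge" rule.
#'
#' @param partitions list of [partition] objects over the same id set.
#' @param min_agree minimum number of agreeing methods (default 2).
#' @return A [partition] with method `"consensus"`.
#' @export
consensus_partition <- function(partitions, min_agree = 2L) {
  if (length(partitions) < 2L) stop("need at least 2 partitions")
  ids <- sort(names(partitions[[1L]]$assignments))
  for (p in partitions)
    if (!identical(sort(names(p$assignments)), ids))
      stop("partitions must cover the same id set")
  ids <- names(partitions[[1L]]$assignments)
  n <- length(ids)
  votes <- matrix(0L, n, n)
  for (p in partitions) {
    a <- p$assignments[ids]
    votes <- votes + outer(a, a, `==`)
  }
  g <- igraph::graph_from_adjacency_matrix(votes >= min_agree,
                                           mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  make_partition(ids, comp, method = "consensus")
}

#' Adjusted Rand index between two partitions
#'
#' Computed on the shared ids.
#'
#' @param p1,p2 [partition] objects.
#' @return ARI in \[-1, 1\]; 1 means identical up to relabeling.
#' @export
adjusted_rand_index <- function(p1, p2) {
  ids <- intersect(names(p1$assignments), names(p2$assignments))
  if (length(ids) == 0L) stop("no shared ids")
  mclust::adjustedRandIndex(p1$assignments[ids], p2$assignments[ids])
}

#' Compare two partitions: matching, new/merged/split OTUs, ARI
#'
#' OTUs are matched by maximum overlap on the shared ids. OTUs of `p2` with
#' no member among `p1`'s ids are "new"; `p2` OTUs drawing members from more
#' than one `p1` OTU are "merged"; `p1` OTUs scattered over more than one
#' `p2` OTU are "split".
#'
#' @param p1 earlier [partition].
#' @param p2 later [partition]; its id set must contain `p1`'s.
#' @return Object of class `partition_diff`: list with `matching` (data.frame
#'   p1 OTU -> best p2 OTU), `new_otus`, `merged`, `split`,
#'   `adjusted_rand_index`.
#' @export
compare_partitions <- function(p1, p2) {
  ids1 <- names(p1$assignments)
  if (!all(ids1 %in% names(p2$assignments)))
    stop("p2 must cover all ids of p1")
  a1 <- p1$assignments[ids1]
  a2 <- p2$assignments[ids1]
  tab <- table(a1, a2)
  best2 <- apply(tab, 1L, function(r) {
    m <- colnames(tab)[r == max(r)]
    sort(m)[1L]
  })
  matching <- data.frame(otu_p1 = rownames(tab), otu_p2 = unname(best2),
                         overlap = apply(tab, 1L, max),
                         stringsAsFactors = FALSE)
  shared2 <- unique(a2)
  new_otus <- setdiff(unique(p2$assignments), shared2)
  merged <- names(which(apply(tab > 0, 2L, sum) > 1L))
  split <- rownames(tab)[apply(tab > 0, 1L, sum) > 1L]
  structure(list(matching = matching,
                 new_otus = sort(new_otus),
                 merged = sort(merged),
                 split = sort(split),
                 adjusted_rand_index = adjusted_rand_index(p1, p2)),
            class = "partition_diff")
}

#' @export
print.partition_diff <- function(x, ...) {
  cat("partition_diff: ARI", round(x$adjusted_rand_index, 4), "|",
      length(x$new_otus), "new,", length(x$merged), "merged,",
      length(x$split), "split\n")
  invisible(x)
}

#' Write a partition as a two-column TSV (record_id, otu_id)
#' @param p a [partition].
#' @param path output file.
#' @export
write_partition <- function(p, path) {
  utils::write.table(data.frame(record_id = names(p$assignments),
                                otu_id = unname(p$assignments)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
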