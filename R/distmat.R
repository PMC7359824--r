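# K2P pairwise distances (pairwise site deletion) and barcode-gap statistics.

# Encode sequences as integers: A=1, C=2, G=3, T=4, anything else NA.
# Ambiguity codes and gaps are excluded pairwise at distance time.
encode_dna <- function(seqs) {
  key <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  m <- matrix(NA_integer_, nrow = length(seqs), ncol = nchar(seqs[1L]))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1L]]
    m[i, ] <- unname(key[ch])
  }
  m
}

k2p_from_counts <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  ok <- w1 > 0 & w2 > 0
  d <- P
  d[] <- Inf
  d[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok])
  d
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Sites where either character is not one of A, C, G, T (ambiguity codes,
#' gaps) are excluded pairwise. With transition proportion P and transversion
#' proportion Q over the comparable sites, the distance is
#' d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q)). Saturated pairs (non-positive
#' logarithm argument) are reported as `Inf` with `saturated = TRUE`.
#'
#' @param seq_a,seq_b aligned DNA strings of equal length.
#' @return list with `distance`, `P`, `Q`, `n_sites`, `saturated`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must have equal length")
  m <- encode_dna(toupper(c(seq_a, seq_b)))
  x <- m[1L, ]; y <- m[2L, ]
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites")
  x <- x[ok]; y <- y[ok]
  diff <- x != y
  # transitions: A<->G (1,3) and C<->T (2,4); same parity of code
  ts <- diff & ((x %% 2L) == (y %% 2L))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  d <- k2p_from_counts(P, Q)
  list(distance = d, P = P, Q = Q, n_sites = n, saturated = !is.finite(d))
}

#' Pairwise K2P distance matrix over the QC-passing records of a library
#'
#' @param library a [barcode_library]; records with `qc_pass == FALSE` are
#'   excluded (records with unset QC are kept).
#' @return Object of class `dist_matrix`: list with `ids`, symmetric `d`
#'   (zero diagonal, `Inf` for saturated pairs), integer `n_sites` of
#'   comparable sites per pair, and `n_saturated`.
#' @export
k2p_matrix <- function(library) {
  rec <- library$records
  keep <- is.na(rec$qc_pass) | rec$qc_pass
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) < 2L) stop("need at least 2 (QC-passing) records")
  if (length(unique(nchar(rec$sequence))) != 1L)
    stop("sequences must be aligned to a common length")
  m <- encode_dna(rec$sequence)
  # one-hot per base; BLAS crossproducts give per-pair substitution counts
  I <- lapply(1:4, function(b) {
    z <- m == b
    z[is.na(z)] <- FALSE
    z * 1
  })
  V <- Reduce(`+`, I)                       # 1 where site is unambiguous ACGT
  comp <- V %*% t(V)
  match_ <- Reduce(`+`, lapply(I, function(a) a %*% t(a)))
  ts <- I[[1L]] %*% t(I[[3L]]) + I[[3L]] %*% t(I[[1L]]) +
        I[[2L]] %*% t(I[[4L]]) + I[[4L]] %*% t(I[[2L]])
  if (any(comp[upper.tri(comp)] < 1)) stop("pair with no comparable sites")
  P <- ts / comp
  Q <- (comp - match_ - ts) / comp
  d <- k2p_from_counts(P, Q)
  diag(d) <- 0
  dimnames(d) <- list(rec$record_id, rec$record_id)
  ns <- matrix(as.integer(round(comp)), nrow = nrow(comp),
               dimnames = dimnames(d))
  structure(list(ids = rec$record_id, d = d, n_sites = ns,
                 n_saturated = sum(!is.finite(d[upper.tri(d)]))),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix (K2P):", length(x$ids), "records")
  if (x$n_saturated > 0) cat(",", x$n_saturated, "saturated pairs")
  cat("\n")
  invisible(x)
}

# Subset a dist_matrix to a set of ids (order preserved as given).
subset_dist <- function(D, ids) {
  i <- match(ids, D$ids)
  if (anyNA(i)) stop("unknown ids in dist matrix subset")
  structure(list(ids = ids, d = D$d[i, i, drop = FALSE],
                 n_sites = D$n_sites[i, i, drop = FALSE],
                 n_saturated = sum(!is.finite(D$d[i, i][upper.tri(D$d[i, i])]))),
            class = "dist_matrix")
}

#' Barcode-gap table: maximum intraspecific and nearest-neighbour distances
#'
#' For each OTU of `partition`, reports the maximum intra-OTU K2P distance
#' (0 for singletons), the nearest other OTU and the distance to it (minimum
#' over all cross-OTU record pairs), and whether the OTU shows a barcode gap
#' (`nn_distance > max_intraspecific`, strict). Globally, reports the medians
#' of both columns over OTUs and their fold ratio
#' `median_nn / median_max_intra`. Saturated (infinite) distances are
#' excluded from the medians.
#'
#' @param D a `dist_matrix` from [k2p_matrix()].
#' @param partition a [partition] covering all matrix ids.
#' @return Object of class `gap_table`: list with `table` (one row per OTU),
#'   `median_max_intra`, `median_nn`, `fold_ratio`, `single_otu` flag.
#' @export
gap_table <- function(D, partition) {
  asg <- partition$assignments
  if (!all(D$ids %in% names(asg)))
    stop("partition does not cover all matrix ids")
  otu <- asg[D$ids]
  otus <- sort(unique(otu))
  single <- length(otus) == 1L
  rows <- lapply(otus, function(o) {
    inb <- otu == o
    di <- D$d[inb, inb, drop = FALSE]
    mx <- if (sum(inb) < 2L) 0 else {
      v <- di[upper.tri(di)]
      if (any(is.finite(v))) max(v[is.finite(v)]) else Inf
    }
    if (single) {
      return(data.frame(otu_id = o, n = sum(inb), max_intraspecific = mx,
                        nn_otu = NA_character_, nn_distance = NA_real_,
                        has_gap = NA, stringsAsFactors = FALSE))
    }
    cross <- D$d[inb, !inb, drop = FALSE]
    other <- otu[!inb]
    # nearest neighbour OTU: minimum cross distance; ties broken by
    # lexicographically smallest OTU id
    permin <- vapply(split(seq_along(other), other),
                     function(j) min(cross[, j, drop = FALSE]), numeric(1L))
    nnd <- min(permin)
    nno <- sort(names(permin)[permin == nnd])[1L]
    data.frame(otu_id = o, n = sum(inb), max_intraspecific = mx,
               nn_otu = nno, nn_distance = nnd,
               has_gap = nnd > mx, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  fin_i <- tab$max_intraspecific[is.finite(tab$max_intraspecific)]
  med_i <- stats::median(fin_i)
  med_n <- if (single) NA_real_ else
    stats::median(tab$nn_distance[is.finite(tab$nn_distance)])
  fold <- if (!single && isTRUE(med_i > 0)) med_n / med_i else NA_real_
  structure(list(table = tab, median_max_intra = med_i, median_nn = med_n,
                 fold_ratio = fold, single_otu = single),
            class = "gap_table")
}

#' @export
print.gap_table <- function(x, ...) {
  cat("gap_table:", nrow(x$table), "OTUs\n")
  if (!x$single_otu) {
    cat(sprintf("  median max-intra %.5f, median NN %.5f, fold ratio %.2f\n",
                x$median_max_intra, x$median_nn, x$fold_ratio))
    cat("  OTUs with barcode gap:", sum(x$table$has_gap), "/",
        nrow(x$table), "\n")
  } else cat("  single OTU: nearest-neighbour statistics undefined\n")
  invisible(x)
}

#' Write a distance matrix as square TSV or PHYLIP
#'
#' @param D a `dist_matrix`.
#' @param path output file.
#' @param format `"tsv"` (square, with header) or `"phylip"`.
#' @export
write_dist_matrix <- function(D, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(data.frame(record_id = D$ids, D$d,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(D$ids)), con)
    for (i in seq_along(D$ids))
      writeLines(paste(c(D$ids[i], sprintf("%.8f", D$d[i, ])),
                       collapse = "  "), con)
  }
  invisible(path)
}

#' Write a gap table as TSV
#' @param gt a `gap_table`.
#' @param path output file.
#' @export
write_gap_table <- function(gt, path) {
  utils::write.table(gt$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
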