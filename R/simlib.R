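# Synthetic barcode libraries with known OTU truth. Species relationships
# follow a Yule tree rescaled so that the smallest between-species
# divergence is gap_factor times the intraspecific depth; sequences evolve
# under the K2P substitution process (consistent with the K2P distance
# estimator); intraspecific genealogies default to a star from the species
# ancestor. Scenario knobs add cryptic lineages (two true OTUs under one
# nominal label), query-only unsampled OTUs, and mislabeled records.

#' Simulation configuration
#'
#' @param n_species number of species sampled in the reference library.
#' @param n_per_species reference sequences per species.
#' @param seq_length alignment length in bp (default 538).
#' @param kappa transition/transversion rate ratio (default 2).
#' @param intra_depth expected maximum intraspecific K2P distance
#'   (default 0.01).
#' @param gap_factor minimum inter-species divergence as a multiple of
#'   `intra_depth` (default 5; must be >= 1).
#' @param max_divergence ceiling on the true pairwise divergence between
#'   the deepest species (default 0.35 substitutions/site): node ages
#'   beyond it are compressed, emulating the mutational saturation that
#'   keeps real COI distances bounded.
#' @param n_cryptic number of nominal labels each hiding two true OTUs.
#' @param n_unsampled_query_otus species contributing queries but absent
#'   from the reference.
#' @param n_queries_per_otu queries drawn from every sampled species and
#'   every unsampled query OTU (default 2).
#' @param mislabel_rate probability that a reference record carries another
#'   species' nominal label (truth unchanged).
#' @param genealogy intraspecific genealogy: `"star"` (default) or
#'   `"coalescent"`.
#' @param seed RNG seed; the whole simulation is a deterministic function
#'   of the configuration.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 15L, n_per_species = 5L,
                       seq_length = 538L, kappa = 2, intra_depth = 0.01,
                       gap_factor = 5, max_divergence = 0.35,
                       n_cryptic = 0L,
                       n_unsampled_query_otus = 0L, n_queries_per_otu = 2L,
                       mislabel_rate = 0,
                       genealogy = c("star", "coalescent"), seed = 1L) {
  genealogy <- match.arg(genealogy)
  if (gap_factor < 1) stop("gap_factor must be >= 1")
  if (max_divergence < gap_factor * intra_depth)
    stop("max_divergence must be >= gap_factor * intra_depth")
  if (mislabel_rate < 0 || mislabel_rate >= 1)
    stop("mislabel_rate must be in [0, 1)")
  if (2L * n_cryptic > n_species)
    stop("n_cryptic requires at least 2 species each")
  stopifnot(n_species >= 1L, n_per_species >= 1L, seq_length >= 3L,
            intra_depth > 0, n_unsampled_query_otus >= 0L,
            n_queries_per_otu >= 0L)
  structure(list(n_species = n_species, n_per_species = n_per_species,
                 seq_length = seq_length, kappa = kappa,
                 intra_depth = intra_depth, gap_factor = gap_factor,
                 max_divergence = max_divergence, n_cryptic = n_cryptic,
                 n_unsampled_query_otus = n_unsampled_query_otus,
                 n_queries_per_otu = n_queries_per_otu,
                 mislabel_rate = mislabel_rate, genealogy = genealogy,
                 seed = seed),
            class = "sim_config")
}

# Evolve one sequence along a branch of expected length t substitutions per
# site under K80 with the given transition/transversion ratio kappa.
evolve_seq <- function(seq_int, t, kappa) {
  # rates normalised to one expected substitution per site per unit t
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2          # to the transition partner
  p_tv <- 0.25 - 0.25 * e1                     # to each transversion partner
  p_same <- 1 - p_ts - 2 * p_tv
  n <- length(seq_int)
  u <- stats::runif(n)
  out <- seq_int
  # transition partner: A<->G (1<->3), C<->T (2<->4)
  ts_partner <- c(3L, 4L, 1L, 2L)[seq_int]
  # transversion partners: the two bases of the other purine/pyrimidine class
  tv1 <- c(2L, 1L, 2L, 1L)[seq_int]
  tv2 <- c(4L, 3L, 4L, 3L)[seq_int]
  out[u < p_ts] <- ts_partner[u < p_ts]
  sel <- u >= p_ts & u < p_ts + p_tv
  out[sel] <- tv1[sel]
  sel <- u >= p_ts + p_tv & u < p_ts + 2 * p_tv
  out[sel] <- tv2[sel]
  out
}

int_to_dna <- function(x) paste(c("A", "C", "G", "T")[x], collapse = "")

# Tip-depth branch lengths for one species' individuals. intra_depth
# bounds the *estimated* intra distances: at barcode-scale alignments the
# K2P estimate of a true distance tau has sd ~ sqrt(tau/L), so the true
# pairwise divergence is calibrated to 0.5 * intra_depth, placing the
# typical maximum estimate near intra_depth and keeping ~99% of pairwise
# estimates below 1.5 * intra_depth.
INTRA_CALIBRATION <- 0.5

intra_depths <- function(n, intra_depth, genealogy) {
  tau <- INTRA_CALIBRATION * intra_depth
  if (genealogy == "star" || n == 1L)
    return(rep(tau / 2, n))
  # coalescent option: tree depths scaled so the deepest pair diverges by tau
  tr <- ape::rcoal(n)
  depth <- ape::node.depth.edgelength(tr)[seq_len(n)]
  depth / max(depth) * tau / 2
}

#' Simulate a reference library, a query batch, and the truth
#'
#' See [sim_config()] for the generating model. Sampled species contribute
#' `n_per_species` reference records and `n_queries_per_otu` queries;
#' unsampled query OTUs contribute queries only. Cryptic pairs are two true
#' OTUs sharing one nominal label; mislabeled reference records carry a
#' wrong nominal label with the truth unchanged. Queries carry empty
#' nominal labels (they are unknowns).
#'
#' @param config a [sim_config()].
#' @return Object of class `sim_library`: list with `reference`
#'   ([barcode_library]), `queries` ([barcode_library]), `truth` (list:
#'   `true_partition` over all records, `species_tree`, `flags`
#'   data.frame, `config`).
#' @export
simulate_library <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- config$n_species + config$n_unsampled_query_otus
  tree <- if (S >= 2L) ape::rphylo(S, birth = 1, death = 0) else NULL
  anc <- sample.int(4L, config$seq_length, replace = TRUE)
  target_min <- config$gap_factor * config$intra_depth
  if (!is.null(tree)) {
    coph <- ape::cophenetic.phylo(tree)
    mn <- min(coph[upper.tri(coph)])
    tree$edge.length <- tree$edge.length * target_min / mn
    # compress ages beyond the saturation ceiling (deep COI divergences
    # are bounded in real data; unbounded rescaling would saturate K2P)
    bt <- ape::branching.times(tree)
    cap <- config$max_divergence / 2
    if (max(bt) > cap) {
      age <- numeric(S + tree$Nnode)
      age[as.integer(names(bt))] <- pmin(bt, cap)
      tree$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
    }
    tree$tip.label <- sprintf("Species_%02d", seq_len(S))
    # species ancestor sequences by preorder traversal from the root sequence
    nnode <- S + tree$Nnode
    seqs <- vector("list", nnode)
    root <- tree_root(tree)
    seqs[[root]] <- anc
    for (e in seq_len(nrow(tree$edge))) {   # ape edges are preorder-compatible
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      seqs[[ch]] <- evolve_seq(seqs[[p]], tree$edge.length[e], config$kappa)
    }
    species_seq <- seqs[seq_len(S)]
  } else {
    tree <- NULL
    species_seq <- list(anc)
  }
  species_id <- sprintf("Species_%02d", seq_len(S))
  sampled <- seq_len(config$n_species)
  unsampled <- setdiff(seq_len(S), sampled)
  # nominal labels: cryptic pairs share one label
  nominal <- sprintf("Taxon_%02d", seq_len(S))
  if (config$n_cryptic > 0L)
    for (i in seq_len(config$n_cryptic))
      nominal[2L * i] <- nominal[2L * i - 1L]
  recs <- list(); flags <- list()
  add_records <- function(s, n, prefix, is_query) {
    if (n == 0L) return()
    depths <- intra_depths(n, config$intra_depth, config$genealogy)
    for (j in seq_len(n)) {
      id <- sprintf("%s_%02d_%02d", prefix, s, j)
      sq <- int_to_dna(evolve_seq(species_seq[[s]], depths[j], config$kappa))
      recs[[length(recs) + 1L]] <<- data.frame(
        record_id = id,
        nominal_taxon = if (is_query) "" else nominal[s],
        locality = sprintf("site_%02d", s),
        sequence = sq, stringsAsFactors = FALSE)
      flags[[length(flags) + 1L]] <<- data.frame(
        record_id = id, species = species_id[s], is_query = is_query,
        is_unsampled_otu = s %in% unsampled, is_mislabeled = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  for (s in sampled) add_records(s, config$n_per_species, "REF", FALSE)
  for (s in sampled) add_records(s, config$n_queries_per_otu, "QRY", TRUE)
  for (s in unsampled) add_records(s, config$n_queries_per_otu, "QRY", TRUE)
  rec <- do.call(rbind, recs)
  fl <- do.call(rbind, flags)
  # mislabeling: wrong nominal label, truth unchanged
  if (config$mislabel_rate > 0 && config$n_species > 1L) {
    refrows <- which(!fl$is_query)
    hit <- refrows[stats::runif(length(refrows)) < config$mislabel_rate]
    for (i in hit) {
      s_true <- match(fl$species[i], species_id)
      other <- sample(setdiff(sampled, s_true), 1L)
      rec$nominal_taxon[i] <- nominal[other]
      fl$is_mislabeled[i] <- TRUE
    }
  }
  truth_part <- partition(stats::setNames(fl$species, fl$record_id),
                          method = "truth")
  reference <- barcode_library(rec[!fl$is_query, , drop = FALSE])
  queries <- if (any(fl$is_query))
    barcode_library(rec[fl$is_query, , drop = FALSE])
  else barcode_library(rec[0L, , drop = FALSE])
  structure(list(reference = reference, queries = queries,
                 truth = list(true_partition = truth_part,
                              species_tree = tree, flags = fl,
                              config = config)),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cfg <- x$truth$config
  cat("sim_library:", n_records(x$reference), "reference records (",
      cfg$n_species, "species ),", n_records(x$queries), "queries\n")
  invisible(x)
}

#' Realized distance structure of a simulated library
#'
#' Recomputes, per true OTU, the realized maximum intraspecific K2P
#' distance, the minimum distance to any other OTU, their ratio, and the
#' barcode-gap flag, for assertions on what the generator actually
#' produced.
#'
#' @param library a [barcode_library] (e.g. the simulated reference).
#' @param truth the `truth` element of [simulate_library()].
#' @return list with `table` (per-OTU data.frame), `min_gap_ratio`
#'   (minimum over OTUs of min-inter / max-intra), `single_otu` flag.
#' @export
realized_structure <- function(library, truth) {
  D <- k2p_matrix(library)
  part <- subset_partition(truth$true_partition, D$ids)
  gt <- gap_table(D, part)
  if (gt$single_otu)
    return(list(table = gt$table, min_gap_ratio = NA_real_,
                single_otu = TRUE))
  tab <- gt$table
  ratio <- ifelse(tab$max_intraspecific > 0,
                  tab$nn_distance / tab$max_intraspecific, Inf)
  tab$gap_ratio <- ratio
  list(table = tab, min_gap_ratio = min(ratio), single_otu = FALSE)
}
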