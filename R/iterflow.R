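# Two-round iterative workflow: delimit the reference, assign queries,
# re-delimit the pooled data, promote new OTUs into the library, reassign.

#' Workflow configuration
#'
#' Collects every tunable of the pipeline with its default. Distances are
#' K2P substitutions/site throughout (0.022 = 2.2%).
#'
#' @param qc_min_length minimum ungapped length for QC (bp).
#' @param genetic_code genetic code for the stop-codon screen.
#' @param abgd list: `p_min`, `p_max`, `steps`, `gap_width_x`.
#' @param rsl list: `seed_threshold`.
#' @param ptp list: `mode`, `restarts`, `min_br`.
#' @param gmyc list: `mode`, `alpha`, `df`.
#' @param clock_rate pairwise divergence per My for the chronogram.
#' @param assign list: `k_max`, `hidden_units`, `epochs`, `learning_rate`,
#'   `k_feat`.
#' @param min_agree delimitation consensus vote threshold.
#' @param ratio_mode ratio diagnostic reading (see [ratio_diagnostic()]).
#' @return a named list of settings.
#' @export
curation_config <- function(qc_min_length = 500L,
                            genetic_code = "vertebrate_mito",
                            abgd = list(p_min = 0.001, p_max = 0.1,
                                        steps = 10L, gap_width_x = 1.5),
                            rsl = list(seed_threshold = 0.022),
                            ptp = list(mode = "multi", restarts = 10L,
                                       min_br = 1e-7),
                            gmyc = list(mode = "multi", alpha = 0.05,
                                        df = 2),
                            clock_rate = 0.012,
                            assign = list(k_max = 5L, hidden_units = 10L,
                                          epochs = 1000L,
                                          learning_rate = 0.01,
                                          k_feat = 3L),
                            min_agree = 2L,
                            ratio_mode = "query") {
  list(qc_min_length = qc_min_length, genetic_code = genetic_code,
       abgd = abgd, rsl = rsl, ptp = ptp, gmyc = gmyc,
       clock_rate = clock_rate, assign = assign, min_agree = min_agree,
       ratio_mode = ratio_mode)
}

single_otu_partition <- function(ids, method)
  make_partition(ids, rep(1L, length(ids)), method = method)

#' Run all four delimiters plus the consensus on a library
#'
#' Delimiters operate on deduplicated haplotypes (one representative per
#' identical-sequence class) and the resulting labels are re-expanded to
#' all records. PTP runs on a midpoint-rooted NJ tree, GMYC on a UPGMA
#' chronogram; both fall back to a single OTU when fewer than 4 haplotypes
#' exist.
#'
#' @param library a [barcode_library].
#' @param config a [curation_config()].
#' @param seed RNG seed (PTP restarts).
#' @return list with `partitions` (named list RSL/ABGD/PTP/GMYC),
#'   `consensus` ([partition]), `D` (full `dist_matrix`), `trees`.
#' @export
delimit_all <- function(library, config = curation_config(), seed = 1L) {
  D <- k2p_matrix(library)
  dd <- dedupe_tips(subset_library(library, D$ids))
  Dh <- subset_dist(D, dd$representative_ids)
  parts <- list()
  parts$RSL <- delimit_rsl(Dh, seed_threshold = config$rsl$seed_threshold)
  parts$ABGD <- delimit_abgd(Dh, p_min = config$abgd$p_min,
                             p_max = config$abgd$p_max,
                             steps = config$abgd$steps,
                             gap_width_x = config$abgd$gap_width_x)$partition
  trees <- list()
  if (length(dd$representative_ids) >= 4L) {
    trees$nj <- phangorn::midpoint(nj_tree(Dh))
    trees$chronogram <- upgma_chronogram(Dh, clock_rate = config$clock_rate)
    parts$PTP <- delimit_ptp(trees$nj, mode = config$ptp$mode, seed = seed,
                             restarts = config$ptp$restarts,
                             min_br = config$ptp$min_br)$partition
    parts$GMYC <- delimit_gmyc(trees$chronogram, mode = config$gmyc$mode,
                               alpha = config$gmyc$alpha,
                               df = config$gmyc$df)$partition
  } else {
    parts$PTP <- single_otu_partition(dd$representative_ids, "PTP-degenerate")
    parts$GMYC <- single_otu_partition(dd$representative_ids,
                                       "GMYC-degenerate")
  }
  parts <- lapply(parts, expand_partition, map = dd$map)
  cons <- consensus_partition(parts, min_agree = config$min_agree)
  list(partitions = parts, consensus = cons, D = D, trees = trees)
}

#' First round: delimit the reference library, assign the queries
#'
#' @param reference QC-ed [barcode_library] (the reference).
#' @param queries QC-ed [barcode_library] of unknown specimens.
#' @param config a [curation_config()].
#' @param seed master RNG seed; stage seeds are derived from it.
#' @return Object of class `curation_round` (round 1): `consensus`,
#'   `partitions`, `gap_table`, `assignment_reference`, `outcomes`.
#' @export
run_round1 <- function(reference, queries, config = curation_config(),
                       seed = 1L) {
  del <- delimit_all(reference, config, seed)
  ref_obj <- build_assignment_reference(reference, del$consensus,
                                        seed = seed + 1L)
  outcomes <- assign_all(queries, ref_obj, config, seed = seed + 2L)
  structure(list(round_index = 1L,
                 consensus = del$consensus,
                 partitions = del$partitions,
                 gap_table = gap_table(del$D, del$consensus),
                 assignment_reference = ref_obj,
                 outcomes = outcomes,
                 reference = reference),
            class = "curation_round")
}

#' Second round: pooled delimitation, OTU promotion, reassignment
#'
#' Delimits the pooled reference + query set, diffs the pooled consensus
#' against the round-1 consensus, promotes one seeded-random query of every
#' query-only ("new") consensus OTU into the reference, rebuilds the
#' assignment reference from the updated partition (which also honours
#' merges/splits), and reassigns all non-promoted queries.
#'
#' @param reference the round-1 reference [barcode_library].
#' @param queries the query [barcode_library].
#' @param round1 the result of [run_round1()].
#' @param config a [curation_config()].
#' @param seed master RNG seed.
#' @return Object of class `curation_round` (round 2): adds
#'   `pooled_consensus`, `diff` (vs round 1), `promoted_ids`,
#'   `updated_reference`, `updated_partition`, `n_new_otus`.
#' @export
run_round2 <- function(reference, queries, round1,
                       config = curation_config(), seed = 1L) {
  pooled <- bind_libraries(reference, queries)
  del <- delimit_all(pooled, config, seed)
  pooled_consensus <- del$consensus
  diff <- compare_partitions(round1$consensus, pooled_consensus)
  ref_ids <- reference$records$record_id
  asg <- pooled_consensus$assignments
  by_otu <- split(names(asg), asg)
  new_otus <- names(by_otu)[vapply(by_otu, function(m)
    !any(m %in% ref_ids), logical(1L))]
  set.seed(seed + 3L)
  promoted <- vapply(by_otu[new_otus], function(m)
    m[sample.int(length(m), 1L)], character(1L))
  updated_ids <- c(ref_ids, unname(promoted))
  updated_reference <- subset_library(pooled, updated_ids)
  updated_partition <- subset_partition(pooled_consensus, updated_ids)
  ref_obj <- build_assignment_reference(updated_reference,
                                        updated_partition, seed = seed + 4L)
  remaining <- setdiff(queries$records$record_id, promoted)
  outcomes <- assign_all(subset_library(queries, remaining), ref_obj, config,
                         seed = seed + 5L)
  structure(list(round_index = 2L,
                 consensus = pooled_consensus,
                 pooled_consensus = pooled_consensus,
                 partitions = del$partitions,
                 gap_table = gap_table(del$D, pooled_consensus),
                 diff = diff,
                 n_new_otus = length(new_otus),
                 promoted_ids = unname(promoted),
                 updated_reference = updated_reference,
                 updated_partition = updated_partition,
                 assignment_reference = ref_obj,
                 outcomes = outcomes),
            class = "curation_round")
}

#' @export
print.curation_round <- function(x, ...) {
  cat("curation_round", x$round_index, ":", n_otus(x$consensus),
      "consensus OTUs,", nrow(x$outcomes$consensus), "queries assigned\n")
  if (x$round_index == 2L)
    cat("  ", x$n_new_otus, "new OTUs,", length(x$promoted_ids),
        "representatives promoted\n")
  invisible(x)
}

round1dp <- function(x) round(x, 1L)

#' Classify assignment outcomes against the pooled delimitation
#'
#' A query's truth OTU is the OTU it receives in the pooled consensus,
#' mapped onto the reference partition's OTUs by maximum overlap (ties to
#' the smallest OTU id). The consensus assignment is a true positive iff it
#' equals the mapped truth; queries whose pooled OTU contains no reference
#' member (new OTUs) can never be true positives and are counted as false
#' positives; ambiguous consensus verdicts are excluded from the
#' numerator of `pct_correct` but kept in its denominator. Percentages are
#' rounded to 1 decimal place, and `pct_consensus_total` is the sum of the
#' rounded 3/3 and 2/3 components.
#'
#' @param outcomes an `assignment_outcomes` object.
#' @param pooled_consensus [partition] of the pooled (reference + query)
#'   records.
#' @param reference_partition [partition] of the reference records used for
#'   the assignments.
#' @param round_index 1 or 2 (annotation only).
#' @param gap_table,diff,promoted_ids optional snapshots stored in the
#'   report.
#' @return Object of class `round_report`.
#' @export
classify_outcomes <- function(outcomes, pooled_consensus,
                              reference_partition, round_index = 1L,
                              gap_table = NULL, diff = NULL,
                              promoted_ids = character(0)) {
  cons <- outcomes$consensus
  n <- nrow(cons)
  ref_ids <- names(reference_partition$assignments)
  # map each pooled OTU to the reference OTU with maximum overlap
  asg <- pooled_consensus$assignments
  shared <- intersect(names(asg), ref_ids)
  map <- tapply(reference_partition$assignments[shared], asg[shared],
                function(v) {
                  tb <- sort(table(v), decreasing = TRUE)
                  sort(names(tb)[tb == tb[1L]])[1L]
                })
  truth_of <- function(q) {
    po <- asg[q]
    if (is.na(po) || !(po %in% names(map))) NA_character_
    else unname(map[po])
  }
  truth <- vapply(cons$query_id, truth_of, character(1L))
  if (anyNA(asg[cons$query_id]))
    stop("pooled consensus does not cover all queries")
  is_amb <- cons$consensus_level == "none"
  is_tp <- !is_amb & !is.na(truth) & cons$consensus_otu == truth
  is_fp <- !is_amb & !is_tp
  per_method <- NULL
  if (n > 0 && nrow(outcomes$methods) > 0) {
    me <- outcomes$methods
    me$truth <- truth[match(me$query_id, cons$query_id)]
    me$tp <- !is.na(me$truth) & me$selected_otu == me$truth
    per_method <- do.call(rbind, lapply(split(me, me$method), function(g)
      data.frame(method = g$method[1L],
                 n_true_positive = sum(g$tp),
                 n_false_positive = sum(!g$tp),
                 pct_correct = round1dp(100 * mean(g$tp)),
                 mean_probability_tp = mean(g$probability[g$tp]),
                 mean_probability_fp = mean(g$probability[!g$tp]),
                 stringsAsFactors = FALSE)))
    rownames(per_method) <- NULL
  }
  p3 <- round1dp(100 * sum(cons$consensus_level == "3/3") / max(n, 1L))
  p2 <- round1dp(100 * sum(cons$consensus_level == "2/3") / max(n, 1L))
  structure(list(
    round_index = round_index,
    n_queries = n,
    n_true_positive = sum(is_tp),
    n_false_positive = sum(is_fp),
    n_ambiguous = sum(is_amb),
    pct_correct = round1dp(100 * sum(is_tp) / max(n, 1L)),
    pct_consensus_3of3 = p3,
    pct_consensus_2of3 = p2,
    pct_consensus_total = p3 + p2,
    mean_probability_tp = mean(cons$mean_probability[is_tp]),
    median_probability_tp = stats::median(cons$mean_probability[is_tp]),
    mean_probability_fp = mean(cons$mean_probability[is_fp]),
    median_probability_fp = stats::median(cons$mean_probability[is_fp]),
    per_method = per_method,
    truth = truth,
    is_true_positive = is_tp,
    is_false_positive = is_fp,
    gap_table = gap_table,
    partition_diff = diff,
    n_new_otus = if (is.null(diff)) 0L else length(diff$new_otus),
    promoted_representative_ids = promoted_ids),
    class = "round_report")
}

#' @export
print.round_report <- function(x, ...) {
  cat("round_report ", x$round_index, ": ", x$n_queries, " queries | TP ",
      x$n_true_positive, ", FP ", x$n_false_positive, ", ambiguous ",
      x$n_ambiguous, "\n", sep = "")
  cat(sprintf("  %% correct %.1f | consensus 3/3 %.1f + 2/3 %.1f = %.1f\n",
              x$pct_correct, x$pct_consensus_3of3, x$pct_consensus_2of3,
              x$pct_consensus_total))
  invisible(x)
}

#' Cryptic diversity excess of a delimitation over the nominal taxonomy
#'
#' @param consensus a [partition].
#' @param nominal_taxa character vector of nominal taxon labels (one per
#'   record or the unique labels; empty strings ignored).
#' @return percentage 100 * (n_OTUs - n_nominal) / n_nominal.
#' @export
cryptic_excess <- function(consensus, nominal_taxa) {
  taxa <- unique(nominal_taxa[nzchar(nominal_taxa)])
  if (length(taxa) == 0L) stop("no nominal taxa")
  100 * (n_otus(consensus) - length(taxa)) / length(taxa)
}

#' Curate a barcode reference library in two iterative rounds
#'
#' Runs the full workflow: round-1 delimitation of the reference and
#' assignment of the queries; round-2 pooled delimitation, promotion of new
#' OTUs into the library, and reassignment; classification of both rounds'
#' outcomes against the pooled consensus.
#'
#' @param reference QC-ed [barcode_library].
#' @param queries QC-ed [barcode_library] of unknowns.
#' @param config a [curation_config()].
#' @param seed master RNG seed; every stochastic stage derives its seed
#'   from it, so runs are exactly reproducible.
#' @return Object of class `barcode_curation`: list with `round1`,
#'   `round2` (`curation_round`s) and `report1`, `report2`
#'   (`round_report`s).
#' @export
curate <- function(reference, queries, config = curation_config(),
                   seed = 1L) {
  r1 <- run_round1(reference, queries, config, seed)
  r2 <- run_round2(reference, queries, r1, config, seed)
  rep1 <- classify_outcomes(r1$outcomes, r2$pooled_consensus, r1$consensus,
                            round_index = 1L, gap_table = r1$gap_table)
  rep2 <- classify_outcomes(r2$outcomes, r2$pooled_consensus,
                            r2$updated_partition, round_index = 2L,
                            gap_table = r2$gap_table, diff = r2$diff,
                            promoted_ids = r2$promoted_ids)
  structure(list(round1 = r1, round2 = r2, report1 = rep1, report2 = rep2,
                 config = config, seed = seed),
            class = "barcode_curation")
}

#' @export
print.barcode_curation <- function(x, ...) {
  cat("barcode_curation (two-round iterative workflow)\n")
  cat("  round 1:", n_otus(x$round1$consensus), "reference OTUs;",
      x$report1$n_queries, "queries,", x$report1$n_false_positive,
      "consensus FP\n")
  cat("  round 2:", n_otus(x$round2$pooled_consensus), "pooled OTUs;",
      x$round2$n_new_otus, "new,", length(x$round2$diff$merged), "merged,",
      length(x$round2$diff$split), "split;", x$report2$n_queries,
      "queries,", x$report2$n_false_positive, "consensus FP\n")
  invisible(x)
}

#' @export
summary.barcode_curation <- function(object, ...) {
  print(object)
  cat("\nRound 1 report:\n"); print(object$report1)
  cat("Round 2 report:\n"); print(object$report2)
  g1 <- object$report1$gap_table; g2 <- object$report2$gap_table
  if (!is.null(g1) && !g1$single_otu)
    cat(sprintf("\nGap fold ratio: round 1 %.2f, round 2 %.2f\n",
                g1$fold_ratio, g2$fold_ratio))
  invisible(object)
}

#' Write the per-round reports as JSON and TSV
#'
#' @param curation a `barcode_curation`.
#' @param out_dir output directory.
#' @return invisibly, the files written.
#' @export
write_curation_reports <- function(curation, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (i in 1:2) {
    rep <- curation[[paste0("report", i)]]
    keep <- c("round_index", "n_queries", "n_true_positive",
              "n_false_positive", "n_ambiguous", "pct_correct",
              "pct_consensus_3of3", "pct_consensus_2of3",
              "pct_consensus_total", "n_new_otus",
              "promoted_representative_ids")
    js <- file.path(out_dir, sprintf("round%d_report.json", i))
    jsonlite::write_json(rep[keep], js, auto_unbox = TRUE, pretty = TRUE)
    tsv <- file.path(out_dir, sprintf("round%d_outcomes.tsv", i))
    oc <- curation[[paste0("round", i)]]$outcomes
    me <- oc$methods
    me$probability <- round(me$probability, 2L)   # full precision in JSON
    utils::write.table(me, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, js, tsv)
  }
  invisible(files)
}
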