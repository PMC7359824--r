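# Sequence / metadata io, quality control and the barcode_library container.

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

# Stop codons of the vertebrate mitochondrial code.
STOP_CODONS <- list(vertebrate_mito = c("TAA", "TAG", "AGA", "AGG"),
                    standard        = c("TAA", "TAG", "TGA"))

#' Construct a barcode library
#'
#' A `barcode_library` bundles an ordered set of barcode records (id, nominal
#' taxon, locality, aligned sequence, QC status) with the alignment length and,
#' optionally, an OTU partition over the records.
#'
#' @param records data.frame with columns `record_id`, `nominal_taxon`,
#'   `locality`, `sequence`; QC columns are added if absent.
#' @param partition optional [partition] over the record ids.
#' @return An object of class `barcode_library`.
#' @export
barcode_library <- function(records, partition = NULL) {
  stopifnot(is.data.frame(records))
  needed <- c("record_id", "nominal_taxon", "locality", "sequence")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0)
    stop("records is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(records$record_id))
    stop("duplicated record_id: ",
         records$record_id[duplicated(records$record_id)][1L])
  records$sequence <- toupper(records$sequence)
  bad <- vapply(strsplit(records$sequence, ""),
                function(ch) any(!ch %in% IUPAC_CODES), logical(1L))
  if (any(bad))
    stop("non-IUPAC characters in sequence of record ",
         records$record_id[which(bad)[1L]])
  if (is.null(records$qc_pass)) records$qc_pass <- rep(NA, nrow(records))
  if (is.null(records$qc_reasons))
    records$qc_reasons <- character(nrow(records))
  rownames(records) <- NULL
  lens <- nchar(records$sequence)
  alen <- if (length(unique(lens)) == 1L) lens[1L] else NA_integer_
  structure(list(records = records,
                 alignment_length = as.integer(alen),
                 partition = partition),
            class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat("barcode_library:", nrow(x$records), "records")
  if (!is.na(x$alignment_length))
    cat(", alignment length", x$alignment_length)
  cat("\n")
  if (!all(is.na(x$records$qc_pass)))
    cat("  QC:", sum(x$records$qc_pass), "pass /",
        sum(!x$records$qc_pass), "fail\n")
  nt <- unique(x$records$nominal_taxon)
  cat("  nominal taxa:", length(nt[nzchar(nt)]), "\n")
  if (!is.null(x$partition))
    cat("  partition:", n_otus(x$partition), "OTUs (", x$partition$method, ")\n")
  invisible(x)
}

#' Number of records in a library
#' @param library a [barcode_library].
#' @return integer count.
#' @export
n_records <- function(library) nrow(library$records)

#' Read a barcode library from FASTA (+ optional TSV metadata)
#'
#' @param fasta_path path to an aligned FASTA file.
#' @param metadata_path optional path to a tab-separated metadata table with a
#'   header row and at least the columns `record_id`, `nominal_taxon`,
#'   `locality`. Extra (e.g. BOLD-style) columns are ignored with a warning.
#'   Metadata ids absent from the FASTA are an error; FASTA records without
#'   metadata get empty fields.
#' @return A [barcode_library] with records in file order, sequences uppercased.
#' @export
read_barcode_library <- function(fasta_path, metadata_path = NULL) {
  dna <- ape::read.FASTA(fasta_path)
  ids <- names(dna)
  if (anyDuplicated(ids))
    stop("duplicated FASTA id: ", ids[duplicated(ids)][1L])
  seqs <- vapply(as.character(dna), function(v) paste(toupper(v), collapse = ""),
                 character(1L))
  rec <- data.frame(record_id = ids,
                    nominal_taxon = "",
                    locality = "",
                    sequence = unname(seqs),
                    stringsAsFactors = FALSE)
  if (!is.null(metadata_path)) {
    md <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                            colClasses = "character",
                            fileEncoding = "UTF-8", check.names = FALSE)
    needed <- c("record_id", "nominal_taxon", "locality")
    if (!all(needed %in% names(md)))
      stop("metadata must have columns: ", paste(needed, collapse = ", "))
    extra <- setdiff(names(md), needed)
    if (length(extra) > 0)
      warning("ignoring metadata columns: ", paste(extra, collapse = ", "))
    unknown <- setdiff(md$record_id, ids)
    if (length(unknown) > 0)
      stop("metadata record_id absent from FASTA: ", unknown[1L])
    i <- match(rec$record_id, md$record_id)
    hit <- !is.na(i)
    rec$nominal_taxon[hit] <- md$nominal_taxon[i[hit]]
    rec$locality[hit] <- md$locality[i[hit]]
  }
  barcode_library(rec)
}

ungapped <- function(s) gsub("-", "", s, fixed = TRUE)

count_stops <- function(seq, frame, stops) {
  s <- ungapped(seq)
  n <- nchar(s)
  if (n - frame < 3L) return(0L)
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  # codons containing ambiguity codes are not counted as stops
  sum(codons %in% stops)
}

#' Quality-control filter: minimum length and stop-codon screen
#'
#' Flags records whose ungapped sequence is shorter than `min_length`
#' ("short") and records for which every forward reading frame contains at
#' least one stop codon under the chosen genetic code ("stop_codon"): the
#' screening frame is the one minimising the stop count, and a record passes
#' the codon screen if that minimum is zero. Records are flagged, never
#' dropped.
#'
#' @param library a [barcode_library].
#' @param min_length minimum ungapped length in bp (default 500).
#' @param genetic_code `"vertebrate_mito"` (default) or `"standard"`.
#' @return The library with `qc_pass` / `qc_reasons` filled in.
#' @export
qc_filter <- function(library, min_length = 500L,
                      genetic_code = c("vertebrate_mito", "standard")) {
  genetic_code <- match.arg(genetic_code)
  stops <- STOP_CODONS[[genetic_code]]
  rec <- library$records
  if (nrow(rec) == 0L) stop("empty library")
  reasons <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    r <- character(0)
    if (nchar(ungapped(rec$sequence[i])) < min_length) r <- c(r, "short")
    nstop <- min(vapply(0:2, count_stops, integer(1L),
                        seq = rec$sequence[i], stops = stops))
    if (nstop > 0L) r <- c(r, "stop_codon")
    reasons[i] <- paste(r, collapse = ";")
  }
  rec$qc_pass <- !nzchar(reasons)
  rec$qc_reasons <- reasons
  library$records <- rec
  library
}

#' Trim all sequences of an alignment to a column window
#'
#' Coordinates are 0-based, half-open: `trim_alignment(lib, 0, 538)` keeps the
#' first 538 alignment columns.
#'
#' @param library a [barcode_library].
#' @param start 0-based inclusive start column.
#' @param end 0-based exclusive end column.
#' @return The trimmed library with updated `alignment_length`.
#' @export
trim_alignment <- function(library, start, end) {
  if (!(start >= 0 && start < end))
    stop("need 0 <= start < end (0-based, half-open)")
  if (end > min(nchar(library$records$sequence)))
    stop("end (", end, ") beyond shortest aligned length")
  library$records$sequence <-
    substring(library$records$sequence, start + 1L, end)
  library$alignment_length <- as.integer(end - start)
  library
}

#' Write a library, partition and assignment outcomes to a directory
#'
#' Writes `sequences.fasta`, `metadata.tsv` (metadata + OTU + QC columns) and
#' `summary.json`. Sequences and metadata round-trip losslessly through
#' [read_barcode_library()].
#'
#' @param library a [barcode_library].
#' @param partition optional [partition] over the record ids.
#' @param outcomes optional assignment outcome list (see [assign_all]).
#' @param out_dir output directory; created if absent.
#' @return Invisibly, the paths written.
#' @export
write_library_outputs <- function(library, partition = NULL, outcomes = NULL,
                                  out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  rec <- library$records
  fa <- file.path(out_dir, "sequences.fasta")
  writeLines(paste0(">", rec$record_id, "\n", rec$sequence), fa)
  md <- rec[, c("record_id", "nominal_taxon", "locality")]
  md$otu_id <- if (!is.null(partition))
    unname(partition$assignments[rec$record_id]) else NA_character_
  md$qc_pass <- rec$qc_pass
  md$qc_reasons <- rec$qc_reasons
  tsv <- file.path(out_dir, "metadata.tsv")
  utils::write.table(md, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  summary <- list(n_records = nrow(rec),
                  alignment_length = library$alignment_length,
                  n_otus = if (is.null(partition)) 0L else n_otus(partition),
                  n_outcomes = if (is.null(outcomes)) 0L else length(outcomes),
                  n_qc_fail = if (all(is.na(rec$qc_pass))) 0L
                              else sum(!rec$qc_pass))
  js <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(fasta = fa, metadata = tsv, summary = js))
}

#' Subset a library by record ids (keeping the order of `ids`)
#' @param library a [barcode_library].
#' @param ids record ids to keep.
#' @return a [barcode_library].
#' @export
subset_library <- function(library, ids) {
  i <- match(ids, library$records$record_id)
  if (anyNA(i)) stop("unknown record ids")
  out <- library
  out$records <- library$records[i, , drop = FALSE]
  rownames(out$records) <- NULL
  out$partition <- NULL
  lens <- nchar(out$records$sequence)
  out$alignment_length <-
    if (length(unique(lens)) == 1L) lens[1L] else NA_integer_
  out
}

#' Concatenate two libraries (disjoint record ids required)
#' @param a,b [barcode_library] objects.
#' @return a [barcode_library].
#' @export
bind_libraries <- function(a, b) {
  common <- intersect(a$records$record_id, b$records$record_id)
  if (length(common) > 0) stop("libraries share record ids: ", common[1L])
  barcode_library(rbind(a$records[names(a$records)], b$records[names(a$records)]))
}
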