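# The bigtable: one row per (representative sequence, sample) joining
# counts, alignment metrics, 7-rank taxonomy and Baltimore classification;
# plus the identity/alignment-length quadrant QC classifier.

.BIGTABLE_COLS <- c("seq_id", "sample_id", "member_count", "cpm",
                    "verdict", "search_type", "augmented",
                    "target_id", "pident", "alnlen", "mismatch", "gapopen",
                    "qstart", "qend", "tstart", "tend", "evalue", "bitscore",
                    "taxid", .RANKS7, "baltimore_group", "nucleic_acid")

#' Assemble the bigtable
#'
#' Left-joins tier annotations onto the seqtable clusters by sequence id
#' (every representative yields a row; unannotated representatives carry the
#' sentinel taxonomy and empty metrics), recomputes counts per million from
#' the member counts and sample totals, expands taxids into 7-rank lineages,
#' and joins Baltimore group/nucleic-acid on the family name (\code{NA} for
#' non-viral and unknown families).  Rows are ordered by sample, descending
#' member count, then sequence id.
#'
#' @param seqtab a [SeqTable-class]
#' @param tiers data.frame from [tieredClassify()] (keyed by
#'   \code{query_id}); may omit representatives, never reference unknown ones
#' @param tree a [TaxonomyTree-class]
#' @param baltimore data.frame from [baltimoreTable()], or \code{NULL} to
#'   load the packaged table
#' @return data.frame with the fixed bigtable column order
#' @export
buildBigtable <- function(seqtab, tiers, tree, baltimore = NULL) {
  cl <- clusters(seqtab)
  tot <- sampleTotals(seqtab)
  if (is.null(baltimore)) baltimore <- baltimoreTable()
  stray <- setdiff(tiers$query_id, cl$seq_id)
  if (length(stray))
    stop("integrity error: tier annotations for unknown seq_id(s): ",
         paste(head(stray, 5L), collapse = ", "), call. = FALSE)

  idx <- match(cl$seq_id, tiers$query_id)
  metCols <- c("verdict", "search_type", "augmented", "target_id", "pident",
               "alnlen", "mismatch", "gapopen", "qstart", "qend", "tstart",
               "tend", "evalue", "bitscore", "taxid")
  ann <- tiers[idx, metCols, drop = FALSE]
  ann$verdict[is.na(idx)] <- "unclassified"
  ann$taxid[is.na(idx)] <- .SENTINEL_TAXID
  ann$augmented[is.na(idx)] <- FALSE

  lin <- lineageTable(tree, ann$taxid)
  bidx <- match(lin$family, baltimore$family)
  out <- cbind(
    data.frame(seq_id = cl$seq_id, sample_id = cl$sample_id,
               member_count = cl$member_count,
               cpm = cl$member_count * 1e6 / unname(tot[cl$sample_id]),
               stringsAsFactors = FALSE),
    ann[, setdiff(metCols, "taxid"), drop = FALSE],
    data.frame(taxid = lin$taxid, stringsAsFactors = FALSE),
    lin[, .RANKS7, drop = FALSE],
    data.frame(baltimore_group = baltimore$baltimore_group[bidx],
               nucleic_acid = baltimore$nucleic_acid[bidx],
               stringsAsFactors = FALSE))
  out <- out[order(out$sample_id, -out$member_count, out$seq_id),
             .BIGTABLE_COLS, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the bigtable as TSV
#'
#' Tab-separated, UTF-8, with a versioned \code{#}-prefixed header line so
#' downstream tooling can join positionally.
#'
#' @param bigtable data.frame from [buildBigtable()]
#' @param path output path
#' @export
writeBigtable <- function(bigtable, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", paste(.BIGTABLE_COLS, collapse = "\t")), con)
  write.table(bigtable[, .BIGTABLE_COLS], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bigtable TSV
#'
#' @param path path written by [writeBigtable()]
#' @return data.frame
#' @export
readBigtable <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  out <- read.delim(path, header = FALSE, skip = 1L, col.names = cols,
                    stringsAsFactors = FALSE)
  out
}

#' Identity/alignment-length quadrant call
#'
#' Triage of annotation quality on a 2x2 grid: percent identity against a
#' per-search-type cutoff (defaults 70 for translated/aa and 90 for
#' untranslated/nt hits) and alignment length against a length cutoff
#' (default 150 bases).  Q1 = high identity, short alignment; Q2 = high
#' identity, long; Q3 = low, short; Q4 = low, long.  Boundary values (equal
#' to a cutoff) classify as the high/long side.  Cutoffs are user-adjustable
#' per study.
#'
#' @param pident percent identity vector (0-100)
#' @param alnlen alignment length vector (bases or residues)
#' @param searchType \code{"aa"}/\code{"nt"} vector selecting the identity
#'   cutoff
#' @param idCutoffAA,idCutoffNT identity cutoffs (defaults 70, 90)
#' @param lenCutoff alignment-length cutoff (default 150)
#' @return character vector of \code{"Q1"}..\code{"Q4"}
#' @examples
#' quadrant(95, 200, "aa")  # high identity, long alignment -> Q2
#' @export
quadrant <- function(pident, alnlen, searchType,
                     idCutoffAA = 70, idCutoffNT = 90, lenCutoff = 150) {
  if (any(pident < 0, na.rm = TRUE) || any(alnlen < 0, na.rm = TRUE))
    stop("pident and alnlen must be non-negative", call. = FALSE)
  cutoff <- ifelse(searchType == "aa", idCutoffAA, idCutoffNT)
  high <- pident >= cutoff
  long <- alnlen >= lenCutoff
  ifelse(high & !long, "Q1",
         ifelse(high & long, "Q2",
                ifelse(!high & !long, "Q3", "Q4")))
}

#' Filter bigtable rows by simple predicates
#'
#' Each predicate is a list \code{(field, op, value)} with \code{op} one of
#' \code{==}, \code{!=}, \code{<}, \code{<=}, \code{>}, \code{>=},
#' \code{\%in\%}; rows satisfying all predicates are kept and the retained
#' count is reported.
#'
#' @param rows bigtable data.frame
#' @param predicates list of predicates (empty list = identity)
#' @param quiet suppress the count message
#' @return the filtered data.frame
#' @export
filterBigtable <- function(rows, predicates = list(), quiet = FALSE) {
  keep <- rep(TRUE, nrow(rows))
  for (p in predicates) {
    if (!p$field %in% names(rows))
      stop("unknown bigtable field: ", p$field, call. = FALSE)
    op <- match.fun(p$op)
    keep <- keep & op(rows[[p$field]], p$value)
  }
  out <- rows[keep & !is.na(keep), , drop = FALSE]
  if (!quiet)
    message("filterBigtable: kept ", nrow(out), " of ", nrow(rows), " rows")
  rownames(out) <- NULL
  out
}
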