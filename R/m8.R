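# BLAST-tabular (m8) ingestion and per-query hit ranking.

.M8_COLS <- c("query_id", "target_id", "pident", "alnlen", "mismatch",
              "gapopen", "qstart", "qend", "tstart", "tend",
              "evalue", "bitscore")
.M8_NUM <- c("pident", "alnlen", "mismatch", "gapopen",
             "qstart", "qend", "tstart", "tend", "evalue", "bitscore")

.emptyHits <- function(searchType = "nt") {
  out <- data.frame(query_id = character(0), target_id = character(0),
                    pident = numeric(0), alnlen = integer(0),
                    mismatch = integer(0), gapopen = integer(0),
                    qstart = integer(0), qend = integer(0),
                    tstart = integer(0), tend = integer(0),
                    evalue = numeric(0), bitscore = numeric(0),
                    target_taxid = integer(0),
                    strand = character(0),
                    search_type = character(0),
                    stringsAsFactors = FALSE)
  out
}

#' Parse a BLAST-tabular (m8) hit file
#'
#' Reads a 12-column tab-separated BLAST-tabular file (query, target, percent
#' identity, alignment length, mismatches, gap openings, qstart, qend, tstart,
#' tend, e-value, bitscore), optionally extended with a 13th target-taxid
#' column.  Without the 13th column a \code{taxidMap} (target_id to taxid)
#' must cover the targets; rows whose target cannot be mapped are collected
#' into a reject report attached as \code{attr(x, "rejects")}, never silently
#' dropped.  Reverse-strand hits (tstart > tend) are normalized to ascending
#' target coordinates with \code{strand = "-"}.  Hits above the e-value
#' ceiling are discarded at parse time.
#'
#' @param path m8 file path
#' @param searchType \code{"aa"} or \code{"nt"}; recorded on every hit
#' @param taxidMap named integer vector (names = target ids) or \code{NULL}
#'   when the file carries a 13th taxid column
#' @param maxEvalue e-value ceiling applied at parse time (default 1e-3)
#' @return data.frame of hits; rejected rows in \code{attr(,"rejects")}
#' @export
parseM8 <- function(path, searchType = c("nt", "aa"), taxidMap = NULL,
                    maxEvalue = 1e-3) {
  searchType <- match.arg(searchType)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(.emptyHits(searchType))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(!nf %in% c(12L, 13L))
  if (length(bad))
    stop("m8 format error at line ", bad[1L], ": ", nf[bad[1L]],
         " columns (expected 12 or 13)", call. = FALSE)
  hasTaxid <- nf == 13L
  mat <- do.call(rbind, lapply(fields, function(f) f[1:12]))
  df <- data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- .M8_COLS
  for (cn in .M8_NUM) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) {
      stop("m8 format error at line ", which(is.na(v))[1L],
           ": non-numeric field '", cn, "'", call. = FALSE)
    }
    df[[cn]] <- v
  }
  for (cn in c("alnlen", "mismatch", "gapopen", "qstart", "qend",
               "tstart", "tend"))
    df[[cn]] <- as.integer(df[[cn]])

  taxid <- rep(NA_integer_, nrow(df))
  if (any(hasTaxid)) {
    t13 <- vapply(fields[hasTaxid], `[[`, "", 13L)
    taxid[hasTaxid] <- suppressWarnings(as.integer(t13))
  }
  if (any(!hasTaxid)) {
    if (is.null(taxidMap))
      stop("m8 file has 12 columns but no taxidMap was supplied", call. = FALSE)
    taxid[!hasTaxid] <- unname(taxidMap[df$target_id[!hasTaxid]])
  }
  df$target_taxid <- taxid

  # strand orientation: normalize target coordinates ascending
  rev <- df$tstart > df$tend
  df$strand <- ifelse(rev, "-", "+")
  ts <- df$tstart
  df$tstart[rev] <- df$tend[rev]
  df$tend[rev] <- ts[rev]
  df$search_type <- searchType

  rejects <- df[is.na(df$target_taxid), , drop = FALSE]
  kept <- df[!is.na(df$target_taxid) & df$evalue <= maxEvalue, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "rejects") <- rejects
  kept
}

.rankHits <- function(hits) {
  # deterministic: higher bitscore, then lower evalue, then smallest target_id
  hits[order(-hits$bitscore, hits$evalue, hits$target_id), , drop = FALSE]
}

#' Top hit for a query
#'
#' The hit ranked first by higher bitscore, then lower e-value, then
#' lexicographically smallest target id -- deterministic under any permutation
#' of the input rows.
#'
#' @param hits data.frame of hits (from [parseM8()] or [naiveAlign()])
#' @param queryId query to rank
#' @return one-row data.frame
#' @export
topHit <- function(hits, queryId) {
  sub <- hits[hits$query_id == queryId, , drop = FALSE]
  if (!nrow(sub)) stop("no hits for query ", queryId, call. = FALSE)
  .rankHits(sub)[1L, , drop = FALSE]
}

#' Hit set retained for LCA assignment
#'
#' Top hit first, followed by every hit of the query whose e-value is within
#' \code{evalueFactor} of the top hit's (e-value <= top e-value x factor);
#' ordering as in [topHit()].  This is the hit set over which the
#' dual-search LCA is computed.
#'
#' @inheritParams topHit
#' @param evalueFactor positive multiplier on the top e-value (default 10)
#' @return data.frame of retained hits, best first
#' @export
lcaHitSet <- function(hits, queryId, evalueFactor = 10) {
  if (!is.numeric(evalueFactor) || evalueFactor <= 0)
    stop("evalueFactor must be a positive real", call. = FALSE)
  sub <- hits[hits$query_id == queryId, , drop = FALSE]
  if (!nrow(sub)) stop("no hits for query ", queryId, call. = FALSE)
  ranked <- .rankHits(sub)
  ceiling <- max(ranked$evalue[1L] * evalueFactor, ranked$evalue[1L])
  ranked[ranked$evalue <= ceiling, , drop = FALSE]
}

#' Write hits as 13-column m8
#'
#' Tab-separated, no header; the 13th column is the target taxid.  Reverse
#' strand hits are written with descending target coordinates, restoring the
#' aligner convention.
#'
#' @param hits hit data.frame
#' @param path output path
#' @export
writeM8 <- function(hits, path) {
  out <- hits[, c(.M8_COLS, "target_taxid"), drop = FALSE]
  rev <- hits$strand == "-"
  ts <- out$tstart
  out$tstart[rev] <- out$tend[rev]
  out$tend[rev] <- ts[rev]
  out$evalue <- formatC(out$evalue, format = "e", digits = 2)
  out$pident <- formatC(out$pident, format = "f", digits = 1)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
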