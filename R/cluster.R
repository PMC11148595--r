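# Read dereplication into representative sequences (the seqtable) and
# count-table construction.

#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   pairwiseAlignment nucleotideSubstitutionMatrix nmatch nmismatch
#'   alignedPattern alignedSubject writeXStringSet readDNAStringSet
#'   reverseComplement translate subseq letterFrequency
#' @importFrom IRanges IRanges reduce
#' @importFrom BiocGenerics score start end width
#' @importFrom utils data
NULL

.sanitizeReads <- function(seqs) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning(sum(bad), " read(s) contained non-ACGTN characters; mapped to N",
            call. = FALSE)
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  seqs
}

#' Pairwise identity and centroid coverage
#'
#' The identity definition that backs the clustering threshold: an ends-free
#' (overlap) alignment of the read against the centroid; identity = matches /
#' alignment columns, gap columns counting as mismatch; coverage = aligned
#' centroid span / centroid length.
#'
.NT_UNIT_MAT <- NULL  # populated lazily; nucleotideSubstitutionMatrix(1, -1)

.ntUnitMat <- function() {
  if (is.null(.NT_UNIT_MAT))
    utils::assignInMyNamespace(".NT_UNIT_MAT",
                               nucleotideSubstitutionMatrix(1, -1))
  .NT_UNIT_MAT
}

#' @param read,centroid nucleotide strings
#' @return list with \code{identity} and \code{coverage}, both in [0, 1]
#' @export
pairwiseIdentity <- function(read, centroid) {
  aln <- pairwiseAlignment(DNAString(read), DNAString(centroid),
                           type = "overlap",
                           substitutionMatrix = .ntUnitMat(),
                           gapOpening = 2, gapExtension = 1)
  m <- .alnMetrics(aln)
  if (m$cols == 0L) return(list(identity = 0, coverage = 0))
  list(identity = m$nmatch / m$cols,
       coverage = m$subjSpan / nchar(centroid))
}

.alnMetrics <- function(aln) {
  # alignment columns = aligned pairs + gap columns; indel events = gap
  # openings on either side
  ins <- Biostrings::insertion(Biostrings::nindel(aln))
  del <- Biostrings::deletion(Biostrings::nindel(aln))
  nm <- nmatch(aln)
  nmm <- nmismatch(aln)
  list(nmatch = nm, mismatch = nmm,
       cols = nm + nmm + ins[1L, "WidthSum"] + del[1L, "WidthSum"],
       gapEvents = ins[1L, "Length"] + del[1L, "Length"],
       subjSpan = width(aln@subject@range),
       subjStart = start(aln@subject@range),
       subjEnd = end(aln@subject@range))
}

.kmerPositions <- function(seq, k) {
  # first occurrence position of each distinct k-mer, named by k-mer
  n <- nchar(seq)
  if (n < k) return(integer(0))
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  keep <- !duplicated(kmers)
  setNames(which(keep), kmers[keep])
}

#' Greedy centroid clustering of one sample's reads
#'
#' Dereplicates reads into clusters: reads are processed longest-first (ties
#' broken lexicographically by read id); each read joins the first existing
#' centroid whose pairwise alignment identity is at least \code{minIdentity}
#' with the alignment covering at least \code{minTargetCoverage} of the
#' centroid, else it founds a new cluster.  Defaults mirror the production
#' clustering thresholds (97\% identity, 80\% target coverage).  A k-mer
#' prefilter skips centroids sharing no exact 16-mer with the read; at these
#' thresholds a qualifying pair always shares one.
#'
#' @param reads named character vector: names are read ids, values sequences
#' @param sampleId sample label recorded on every cluster
#' @param minIdentity minimum pairwise identity (default 0.97)
#' @param minTargetCoverage minimum centroid coverage (default 0.8)
#' @param sampleTotal read total used for \code{percent_of_sample}; defaults
#'   to \code{length(reads)} (the post-host total when host removal ran
#'   upstream)
#' @return a [SeqTable-class]
#' @export
greedyCluster <- function(reads, sampleId = "sample1",
                          minIdentity = 0.97, minTargetCoverage = 0.8,
                          sampleTotal = length(reads)) {
  if (!length(reads)) stop("no reads to cluster", call. = FALSE)
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    stop("reads must be named by read id", call. = FALSE)
  seqs <- .sanitizeReads(toupper(reads))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]

  k <- 16L
  kindex <- new.env(hash = TRUE, parent = emptyenv())
  centroids <- character(0)
  centroidIds <- character(0)
  centroidLens <- integer(0)
  assign_to <- integer(length(seqs))
  # a qualifying join (>= 97% identity over >= 80% of the centroid) always
  # shares an exact 16-mer near the true alignment diagonal, so candidates
  # whose best seed diagonal cannot reach the coverage floor are skipped
  # before alignment; small slack absorbs indel-induced diagonal shifts
  covSlack <- 0.03

  for (i in seq_along(seqs)) {
    rlen <- nchar(seqs[[i]])
    kpos <- .kmerPositions(seqs[[i]], k)
    cand <- integer(0)
    if (length(kpos)) {
      found <- mget(names(kpos), envir = kindex, ifnotfound = list(NULL))
      hits <- list()
      for (j in seq_along(found)) {
        v <- found[[j]]
        if (is.null(v)) next
        m <- matrix(v, ncol = 2L, byrow = TRUE)  # centroid idx, position
        hits[[length(hits) + 1L]] <- cbind(m[, 1L], m[, 2L] - kpos[[j]])
      }
      if (length(hits)) {
        hm <- do.call(rbind, hits)  # (centroid, diag = 0-based offset)
        clen <- centroidLens[hm[, 1L]]
        ov <- pmin(rlen, clen - pmax(hm[, 2L], 0L)) +
          pmin(hm[, 2L], 0L)  # attainable overlap at this diagonal
        ok <- ov / clen >= minTargetCoverage - covSlack
        cand <- sort(unique(hm[ok, 1L]))
      }
    }
    joined <- 0L
    for (ci in cand) {
      m <- pairwiseIdentity(seqs[[i]], centroids[[ci]])
      if (m$identity >= minIdentity && m$coverage >= minTargetCoverage) {
        joined <- ci
        break
      }
    }
    if (joined == 0L) {
      centroids <- c(centroids, seqs[[i]])
      centroidIds <- c(centroidIds, names(seqs)[i])
      centroidLens <- c(centroidLens, rlen)
      ci <- length(centroids)
      for (j in seq_along(kpos)) {
        km <- names(kpos)[j]
        kindex[[km]] <- c(kindex[[km]], ci, kpos[[j]])
      }
      assign_to[i] <- ci
    } else {
      assign_to[i] <- joined
    }
  }

  counts <- tabulate(assign_to, nbins = length(centroids))
  clustersDf <- data.frame(
    seq_id = centroidIds,
    sample_id = sampleId,
    cluster_index = seq_along(centroids) - 1L,
    member_count = counts,
    percent_of_sample = round(100 * counts / sampleTotal, 1L),
    sequence = unname(centroids),
    stringsAsFactors = FALSE)
  members <- data.frame(read_id = names(seqs),
                        seq_id = centroidIds[assign_to],
                        sample_id = sampleId,
                        stringsAsFactors = FALSE)
  new("SeqTable", clusters = clustersDf, members = members,
      sampleTotals = setNames(as.integer(sampleTotal), sampleId))
}

#' Build a SeqTable from an external clustering
#'
#' Accepts a read-to-representative mapping produced by a production
#' clusterer (2-column TSV dialect: read_id, representative_id) and performs
#' only the bookkeeping: member counts, percentages and representative
#' sequences.
#'
#' @param reads named character vector of the sample's reads
#' @param mapping data.frame with columns \code{read_id},
#'   \code{representative_id} (or a path to such a TSV, no header)
#' @inheritParams greedyCluster
#' @return a [SeqTable-class]
#' @export
externalClusters <- function(reads, mapping, sampleId = "sample1",
                             sampleTotal = length(reads)) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- read.delim(mapping, header = FALSE,
                          col.names = c("read_id", "representative_id"),
                          stringsAsFactors = FALSE)
  }
  missing <- setdiff(names(reads), mapping$read_id)
  if (length(missing))
    stop("mapping does not cover reads: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  reps <- unique(mapping$representative_id)
  if (!all(reps %in% names(reads)))
    stop("representative ids absent from reads", call. = FALSE)
  cnt <- table(factor(mapping$representative_id, levels = reps))
  clustersDf <- data.frame(
    seq_id = reps, sample_id = sampleId,
    cluster_index = seq_along(reps) - 1L,
    member_count = as.integer(cnt),
    percent_of_sample = round(100 * as.integer(cnt) / sampleTotal, 1L),
    sequence = unname(reads[reps]),
    stringsAsFactors = FALSE)
  members <- data.frame(read_id = mapping$read_id,
                        seq_id = mapping$representative_id,
                        sample_id = sampleId, stringsAsFactors = FALSE)
  new("SeqTable", clusters = clustersDf, members = members,
      sampleTotals = setNames(as.integer(sampleTotal), sampleId))
}

#' Combine per-sample SeqTables
#'
#' Concatenates clusters and memberships across samples; sample ids must be
#' distinct.
#'
#' @param ... \code{SeqTable} objects
#' @return a combined [SeqTable-class]
#' @export
combineSeqTables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) && !is(tabs[[1L]], "SeqTable"))
    tabs <- tabs[[1L]]
  samples <- unlist(lapply(tabs, function(t) names(t@sampleTotals)))
  if (anyDuplicated(samples))
    stop("duplicate sample ids across SeqTables", call. = FALSE)
  cl <- do.call(rbind, lapply(tabs, clusters))
  # representative ids must be unique across samples for downstream joins
  cl$seq_id <- paste(cl$sample_id, cl$seq_id, sep = ".")
  mem <- do.call(rbind, lapply(tabs, clusterMembers))
  mem$seq_id <- paste(mem$sample_id, mem$seq_id, sep = ".")
  tot <- do.call(c, lapply(tabs, sampleTotals))
  new("SeqTable", clusters = cl, members = mem, sampleTotals = tot)
}

.HEADER_DELIM <- ":"

#' Encode a SeqTable as FASTA records
#'
#' One record per cluster with header
#' \code{sample:index:count:percent} (percent with one decimal), so the
#' clustered sequence ids can be unpacked downstream into the sample id, the
#' number of reads the sequence represents, and the percentage of
#' (host-removed) reads.  \code{decodeSeqtable(encodeSeqtable(x))} recovers
#' every field.
#'
#' @param seqtab a [SeqTable-class]
#' @return a \code{DNAStringSet} with encoded names
#' @export
encodeSeqtable <- function(seqtab) {
  cl <- clusters(seqtab)
  if (any(grepl(.HEADER_DELIM, cl$sample_id, fixed = TRUE)))
    stop("sample_id contains the header delimiter '", .HEADER_DELIM,
         "'; sanitize sample ids before encoding", call. = FALSE)
  headers <- sprintf("%s%s%d%s%d%s%.1f",
                     cl$sample_id, .HEADER_DELIM, cl$cluster_index,
                     .HEADER_DELIM, cl$member_count, .HEADER_DELIM,
                     cl$percent_of_sample)
  out <- DNAStringSet(cl$sequence)
  names(out) <- headers
  out
}

#' Decode seqtable FASTA headers
#'
#' Inverse of [encodeSeqtable()]: unpacks \code{sample:index:count:percent}
#' headers back into a cluster data.frame.
#'
#' @param x a \code{DNAStringSet} with encoded names, or a FASTA path
#' @return data.frame with columns \code{sample_id}, \code{cluster_index},
#'   \code{member_count}, \code{percent_of_sample}, \code{sequence}
#' @export
decodeSeqtable <- function(x) {
  if (is.character(x)) x <- readDNAStringSet(x)
  parts <- strsplit(names(x), .HEADER_DELIM, fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("seqtable header does not have 4 ':'-delimited fields", call. = FALSE)
  data.frame(
    sample_id = vapply(parts, `[[`, "", 1L),
    cluster_index = as.integer(vapply(parts, `[[`, "", 2L)),
    member_count = as.integer(vapply(parts, `[[`, "", 3L)),
    percent_of_sample = as.numeric(vapply(parts, `[[`, "", 4L)),
    sequence = as.character(x),
    stringsAsFactors = FALSE)
}

#' Raw and library-size-normalized count table
#'
#' One row per (representative sequence, sample) with the raw member count
#' and the count normalized to library size (counts per million of the
#' sample's post-host read total).  Per sample the raw counts sum to the
#' sample total and the normalized counts sum to 1e6.
#'
#' @param seqtab a [SeqTable-class], or a clusters data.frame
#' @param sampleTotalsOverride optional named vector replacing the stored
#'   per-sample totals
#' @return data.frame: \code{seq_id}, \code{sample_id}, \code{raw_count},
#'   \code{cpm}, sorted by sample then descending raw count
#' @export
countTable <- function(seqtab, sampleTotalsOverride = NULL) {
  if (is(seqtab, "SeqTable")) {
    cl <- clusters(seqtab)
    tot <- sampleTotals(seqtab)
  } else {
    cl <- seqtab
    tot <- NULL
  }
  if (!is.null(sampleTotalsOverride)) tot <- sampleTotalsOverride
  if (is.null(tot)) stop("sample totals required", call. = FALSE)
  if (any(tot <= 0)) stop("zero or negative sample total", call. = FALSE)
  missing <- setdiff(unique(cl$sample_id), names(tot))
  if (length(missing))
    stop("no sample total for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- data.frame(seq_id = cl$seq_id, sample_id = cl$sample_id,
                    raw_count = cl$member_count,
                    cpm = cl$member_count * 1e6 / unname(tot[cl$sample_id]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, -out$raw_count, out$seq_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
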