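# Viral-aware host-genome masking: shred viral genomes into overlapping
# fragments, locate them on the host, and hard-mask matched intervals so
# host-read removal cannot delete genuine viral reads.

#' Shred a sequence into overlapping fragments
#'
#' Fixed windows of \code{fragmentLength} bases starting at multiples of
#' \code{fragmentLength - overlap} (step 55 at the defaults of 85 and 30),
#' with the final window truncated at the sequence end so every base is
#' covered.  Sequences shorter than one window yield a single full-length
#' fragment.
#'
#' @param seqId source sequence id
#' @param sequence nucleotide string
#' @param fragmentLength window length in bases (default 85)
#' @param overlap bases shared by adjacent windows (default 30)
#' @return data.frame: \code{source_id}, \code{start}, \code{end} (0-based,
#'   half-open), \code{sequence}
#' @examples
#' shred("v1", strrep("A", 140))[, 1:3]
#' @export
shred <- function(seqId, sequence, fragmentLength = 85L, overlap = 30L) {
  n <- nchar(sequence)
  if (n == 0L) stop("cannot shred an empty sequence", call. = FALSE)
  if (fragmentLength <= overlap || overlap < 0L)
    stop("need fragmentLength > overlap >= 0", call. = FALSE)
  step <- fragmentLength - overlap
  if (n <= fragmentLength) {
    starts <- 0L
  } else {
    starts <- seq(0L, n - 1L, by = step)
    # drop windows that start at/after the end of the previous full window's
    # coverage only when they add no new bases
    starts <- starts[starts < n]
    ends <- pmin(starts + fragmentLength, n)
    keep <- c(TRUE, ends[-1L] > ends[-length(ends)])
    starts <- starts[keep]
  }
  ends <- pmin(starts + fragmentLength, n)
  data.frame(source_id = seqId, start = as.integer(starts),
             end = as.integer(ends),
             sequence = substring(sequence, starts + 1L, ends),
             stringsAsFactors = FALSE)
}

#' Shred a whole FASTA of viral genomes
#'
#' @param viral named character vector or \code{DNAStringSet}
#' @inheritParams shred
#' @return row-bound [shred()] output over all sequences
#' @export
shredAll <- function(viral, fragmentLength = 85L, overlap = 30L) {
  if (is(viral, "DNAStringSet")) viral <- as.character(viral)
  do.call(rbind, lapply(names(viral), function(id)
    shred(id, viral[[id]], fragmentLength, overlap)))
}

.hostKmerIndex <- function(host, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (ci in seq_along(host)) {
    s <- host[[ci]]
    n <- nchar(s)
    if (n < k) next
    kmers <- substring(s, 1:(n - k + 1L), k:n)
    for (p in seq_along(kmers)) {
      km <- kmers[[p]]
      env[[km]] <- c(env[[km]], c(ci, p))
    }
  }
  env
}

.alignFragment <- function(frag, hostSeq, hostStart, pad, minIdentity,
                           maxIndels) {
  # hostStart: 1-based candidate start of the fragment on the host
  n <- nchar(hostSeq)
  lo <- max(1L, hostStart - pad)
  hi <- min(n, hostStart + nchar(frag) - 1L + pad)
  window <- substring(hostSeq, lo, hi)
  aln <- pairwiseAlignment(DNAString(frag), DNAString(window),
                           type = "global-local",
                           substitutionMatrix = .ntUnitMat(),
                           gapOpening = 2, gapExtension = 1)
  m <- .alnMetrics(aln)
  if (m$cols == 0L) return(NULL)
  if (m$nmatch / m$cols < minIdentity || m$gapEvents > maxIndels) return(NULL)
  c(lo + m$subjStart - 1L, lo + m$subjEnd)  # 1-based start, half-open end + 1
}

#' Locate shredded viral fragments on a host genome
#'
#' Naive seed-and-extend: exact 13-mer seeds anchor candidate placements on
#' both strands; candidates are extended by banded alignment and accepted
#' when the aligned-region identity is at least \code{minIdentity} (default
#' 90\%) with at most \code{maxIndels} insertion/deletion events (default 2;
#' events, i.e. gap openings, not gap columns).  The whole fragment must
#' align (pattern-global extension), so accepted placements cover the
#' fragment.
#'
#' @param fragments data.frame from [shred()]/[shredAll()]
#' @param host named character vector or \code{DNAStringSet} of host contigs
#' @param minIdentity minimum aligned-region identity (default 0.90)
#' @param maxIndels maximum indel events (default 2)
#' @param k seed length (default 13)
#' @return data.frame of mask intervals: \code{contig_id}, \code{start},
#'   \code{end} (0-based half-open), \code{provenance}
#' @export
mapFragments <- function(fragments, host, minIdentity = 0.90, maxIndels = 2L,
                         k = 13L) {
  if (is(host, "DNAStringSet")) host <- as.character(host)
  index <- .hostKmerIndex(host, k)
  pad <- maxIndels + 3L
  out <- list()
  for (fi in seq_len(nrow(fragments))) {
    frag <- fragments$sequence[[fi]]
    for (strandSeq in c(frag,
                        as.character(reverseComplement(DNAString(frag))))) {
      n <- nchar(strandSeq)
      if (n < k) next
      seedPos <- seq(1L, n - k + 1L, by = k)
      cands <- list()
      for (qp in seedPos) {
        km <- substring(strandSeq, qp, qp + k - 1L)
        hitvec <- index[[km]]
        if (is.null(hitvec)) next
        hits <- matrix(hitvec, ncol = 2L, byrow = TRUE)
        for (r in seq_len(nrow(hits))) {
          ci <- hits[r, 1L]
          diag <- hits[r, 2L] - qp + 1L
          cands[[length(cands) + 1L]] <- c(ci, diag)
        }
      }
      if (!length(cands)) next
      cm <- unique(do.call(rbind, cands))
      # merge near-identical diagonals (within the indel budget)
      keep <- rep(TRUE, nrow(cm))
      if (nrow(cm) > 1L) {
        ord <- order(cm[, 1L], cm[, 2L])
        cm <- cm[ord, , drop = FALSE]
        for (r in 2:nrow(cm)) {
          if (cm[r, 1L] == cm[r - 1L, 1L] &&
              abs(cm[r, 2L] - cm[r - 1L, 2L]) <= pad)
            keep[r] <- FALSE
        }
        cm <- cm[keep, , drop = FALSE]
      }
      for (r in seq_len(nrow(cm))) {
        ci <- cm[r, 1L]
        iv <- .alignFragment(strandSeq, host[[ci]], cm[r, 2L], pad,
                             minIdentity, maxIndels)
        if (!is.null(iv)) {
          out[[length(out) + 1L]] <-
            data.frame(contig_id = names(host)[ci],
                       start = iv[1L] - 1L, end = iv[2L] - 1L,
                       provenance = "internal_map",
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), provenance = character(0),
                      stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Read mask intervals from BED
#'
#' 3-column BED (contig, start, end; 0-based half-open), tagged as external
#' provenance, so a production mapper's intervals can drive the masking.
#'
#' @param path BED path
#' @return mask-interval data.frame as in [mapFragments()]
#' @export
readMaskBed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(contig_id = bed[[1L]], start = as.integer(bed[[2L]]),
             end = as.integer(bed[[3L]]), provenance = "external",
             stringsAsFactors = FALSE)
}

#' Hard-mask intervals on host contigs
#'
#' Overlapping intervals are merged; every position in their union is set to
#' \code{maskChar} (hard N masking, so downstream host mapping cannot match
#' masked regions); every other position and all sequence lengths are
#' unchanged.  Masking is idempotent.
#'
#' @param host named character vector or \code{DNAStringSet}
#' @param intervals mask-interval data.frame ([mapFragments()]/[readMaskBed()])
#' @param maskChar masking character (default \code{"N"})
#' @return named character vector of masked contigs
#' @export
maskIntervals <- function(host, intervals, maskChar = "N") {
  if (is(host, "DNAStringSet")) host <- as.character(host)
  out <- host
  if (!nrow(intervals)) return(out)
  unknown <- setdiff(unique(intervals$contig_id), names(host))
  if (length(unknown))
    stop("intervals reference unknown contig(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (ci in unique(intervals$contig_id)) {
    sub <- intervals[intervals$contig_id == ci, , drop = FALSE]
    n <- nchar(host[[ci]])
    if (any(sub$start < 0L) || any(sub$end > n) || any(sub$start >= sub$end))
      stop("interval out of bounds on contig ", ci, call. = FALSE)
    merged <- reduce(IRanges(start = sub$start + 1L, end = sub$end))
    s <- strsplit(out[[ci]], "", fixed = TRUE)[[1L]]
    for (r in seq_along(merged))
      s[start(merged)[r]:end(merged)[r]] <- maskChar
    out[[ci]] <- paste(s, collapse = "")
  }
  out
}

#' Full host-masking recipe
#'
#' Shred the viral genomes (85-base windows, 30-base overlap), map the
#' fragments on the host at >= 90\% identity with at most 2 indel events, and
#' hard-mask the matched intervals.
#'
#' @param host host contigs (named character vector or \code{DNAStringSet})
#' @param viral viral genomes to protect (same types)
#' @inheritParams shred
#' @inheritParams mapFragments
#' @param maskChar masking character (default \code{"N"})
#' @return list: \code{masked} (named character vector), \code{intervals}
#'   (the mask-interval data.frame), \code{fragments}
#' @export
maskHostGenome <- function(host, viral, fragmentLength = 85L, overlap = 30L,
                           minIdentity = 0.90, maxIndels = 2L,
                           maskChar = "N") {
  if (is(viral, "DNAStringSet")) viral <- as.character(viral)
  frags <- shredAll(viral, fragmentLength, overlap)
  ivs <- mapFragments(frags, host, minIdentity, maxIndels)
  list(masked = maskIntervals(host, ivs, maskChar), intervals = ivs,
       fragments = frags)
}
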