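# Built-in naive seed-and-extend aligner emitting 13-column m8 hit tables.
# A desk-scale stand-in for a production aligner so the classification
# contracts are exercisable on toy fixtures; its e-value is a documented
# Karlin-Altschul-style proxy with fixed constants, not comparable across
# aligners.

.NT_LAMBDA <- 0.625
.NT_K <- 0.41
.AA_LAMBDA <- 0.267
.AA_K <- 0.041

.kmerIndexSeqs <- function(seqs, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n < k) next
    kmers <- substring(s, 1:(n - k + 1L), k:n)
    for (p in seq_along(kmers)) {
      km <- kmers[[p]]
      env[[km]] <- c(env[[km]], i, p)
    }
  }
  env
}

.seedCandidates <- function(unit, index, k, stride) {
  n <- nchar(unit)
  if (n < k) return(NULL)
  qpos <- seq(1L, n - k + 1L, by = stride)
  kmers <- substring(unit, qpos, qpos + k - 1L)
  found <- mget(kmers, envir = index, ifnotfound = list(NULL))
  cands <- list()
  for (j in seq_along(found)) {
    v <- found[[j]]
    if (is.null(v)) next
    m <- matrix(v, ncol = 2L, byrow = TRUE)
    cands[[length(cands) + 1L]] <-
      cbind(target = m[, 1L], diag = m[, 2L] - qpos[j] + 1L)
  }
  if (!length(cands)) return(NULL)
  unique(do.call(rbind, cands))
}

.clusterDiags <- function(cands, gap) {
  ord <- order(cands[, 1L], cands[, 2L])
  cands <- cands[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cands))
  if (nrow(cands) > 1L) {
    for (r in 2:nrow(cands))
      if (cands[r, 1L] == cands[r - 1L, 1L] &&
          cands[r, 2L] - cands[r - 1L, 2L] <= gap)
        keep[r] <- FALSE
  }
  cands[keep, , drop = FALSE]
}

.extendHit <- function(unit, targetSeq, diag, pad, scoring) {
  qlen <- nchar(unit)
  tlen <- nchar(targetSeq)
  lo <- max(1L, diag - pad)
  hi <- min(tlen, diag + qlen - 1L + pad)
  if (hi - lo + 1L < 1L) return(NULL)
  aln <- if (scoring$type == "nt") {
    pairwiseAlignment(DNAString(unit), DNAString(substring(targetSeq, lo, hi)),
                      type = "global-local",
                      substitutionMatrix = scoring$mat,
                      gapOpening = scoring$gapOpen,
                      gapExtension = scoring$gapExt)
  } else {
    pairwiseAlignment(AAString(unit), AAString(substring(targetSeq, lo, hi)),
                      type = "global-local",
                      substitutionMatrix = scoring$mat,
                      gapOpening = scoring$gapOpen,
                      gapExtension = scoring$gapExt)
  }
  m <- .alnMetrics(aln)
  if (m$cols == 0L) return(NULL)
  list(score = score(aln),
       nmatch = m$nmatch,
       mismatch = m$mismatch,
       gapopen = m$gapEvents,
       alnlen = m$cols,
       tstart = lo + m$subjStart - 1L,
       tend = lo + m$subjEnd - 1L)
}

.translateFast <- function(s) {
  # standard genetic code; codons with ambiguity translate to X
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  starts <- seq(1L, n - 2L, by = 3L)
  aa <- Biostrings::GENETIC_CODE[substring(s, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.frameUnits <- function(query) {
  # six-frame translation with the standard genetic code
  rc <- as.character(reverseComplement(DNAString(query)))
  units <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") query else rc
    for (f in 0:2) {
      pep <- .translateFast(substring(s, f + 1L, nchar(s)))
      if (!nzchar(pep)) next
      units[[length(units) + 1L]] <-
        list(unit = pep, strand = strand, frame = f + 1L)
    }
  }
  units
}

#' Naive seed-and-extend alignment to m8 hits
#'
#' Exact k-mer seeds anchor candidate diagonals on the targets; candidates
#' are extended by a pattern-global alignment of the full query unit against
#' a padded target window and scored with a Karlin-Altschul-style bitscore
#' proxy (fixed lambda/K constants; e-value = m x n x 2^-bitscore over the
#' database size).  In \code{nt} mode both query strands are searched; in
#' \code{aa6} mode the query is translated in all six frames with the
#' standard genetic code and aligned under BLOSUM62.  One hit -- the best
#' scoring placement -- is emitted per (query, target) pair.  Deterministic.
#'
#' @param queries named character vector (nucleotide)
#' @param targets named character vector: nucleotide (\code{nt}) or protein
#'   (\code{aa6}) reference sequences
#' @param taxidMap named integer vector target id -> taxid
#' @param mode \code{"nt"} or \code{"aa6"}
#' @param minBitscore bitscore-proxy floor (default 30)
#' @param maxEvalue e-value-proxy ceiling (default 1e-3)
#' @param k seed length (default 13 nt / 5 aa)
#' @return hit data.frame in the [parseM8()] schema
#' @export
naiveAlign <- function(queries, targets, taxidMap, mode = c("nt", "aa6"),
                       minBitscore = 30, maxEvalue = 1e-3, k = NULL) {
  mode <- match.arg(mode)
  if (is(queries, "DNAStringSet")) queries <- as.character(queries)
  if (is(targets, "XStringSet")) targets <- as.character(targets)
  if (is.null(k)) k <- if (mode == "nt") 13L else 5L
  scoring <- if (mode == "nt") {
    list(type = "nt", mat = nucleotideSubstitutionMatrix(1, -2),
         gapOpen = 2, gapExt = 1, lambda = .NT_LAMBDA, kconst = .NT_K)
  } else {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    list(type = "aa", mat = get("BLOSUM62", envir = environment()),
         gapOpen = 11, gapExt = 1, lambda = .AA_LAMBDA, kconst = .AA_K)
  }
  index <- .kmerIndexSeqs(targets, k)
  dbLen <- sum(nchar(targets))
  pad <- 8L
  searchType <- if (mode == "nt") "nt" else "aa"

  allRows <- list()
  for (qi in seq_along(queries)) {
    qid <- names(queries)[qi]
    q <- queries[[qi]]
    units <- if (mode == "nt") {
      list(list(unit = q, strand = "+", frame = 0L),
           list(unit = as.character(reverseComplement(DNAString(q))),
                strand = "-", frame = 0L))
    } else {
      .frameUnits(q)
    }
    best <- list()  # per target id: best row
    for (u in units) {
      cands <- .seedCandidates(u$unit, index, k,
                               stride = if (mode == "nt") k else 1L)
      if (is.null(cands)) next
      cands <- .clusterDiags(cands, gap = pad)
      for (r in seq_len(nrow(cands))) {
        ti <- cands[r, 1L]
        ext <- .extendHit(u$unit, targets[[ti]], cands[r, 2L], pad, scoring)
        if (is.null(ext)) next
        bit <- (scoring$lambda * ext$score - log(scoring$kconst)) / log(2)
        ev <- nchar(u$unit) * dbLen * 2^(-bit)
        if (bit < minBitscore || ev > maxEvalue) next
        tid <- names(targets)[ti]
        minus <- u$strand == "-"
        row <- data.frame(
          query_id = qid, target_id = tid,
          pident = 100 * ext$nmatch / ext$alnlen,
          alnlen = ext$alnlen, mismatch = ext$mismatch,
          gapopen = ext$gapopen,
          qstart = 1L, qend = nchar(u$unit),
          tstart = ext$tstart, tend = ext$tend,
          evalue = ev, bitscore = round(bit, 1L),
          target_taxid = unname(taxidMap[tid]),
          strand = u$strand, search_type = searchType,
          stringsAsFactors = FALSE)
        if (is.null(best[[tid]]) || row$bitscore > best[[tid]]$bitscore)
          best[[tid]] <- row
      }
    }
    if (length(best))
      allRows[[length(allRows) + 1L]] <- do.call(rbind, best)
  }
  if (!length(allRows)) return(.emptyHits(searchType))
  out <- do.call(rbind, allRows)
  rownames(out) <- NULL
  out
}
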