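# Tiered viral/multikingdom classification over hit tables.
#
# Route per representative sequence:
#   1. viral amino-acid query          (primary evidence)
#   2. multikingdom amino-acid query   (confirmatory cross-check)
#   3. viral nucleotide query          (leftovers only)
#   4. polymicrobial nucleotide query  (confirmatory cross-check)
#   5. merge into one annotation per sequence
# An aa-tier verdict (viral or nonviral) is final and never re-routed to nt.

.tierConfig <- function(evalueFactor = 10) {
  list(evalueFactor = evalueFactor)
}

.emptyM8Metrics <- function() {
  data.frame(target_id = NA_character_, pident = NA_real_,
             alnlen = NA_integer_, mismatch = NA_integer_,
             gapopen = NA_integer_, qstart = NA_integer_,
             qend = NA_integer_, tstart = NA_integer_, tend = NA_integer_,
             evalue = NA_real_, bitscore = NA_real_,
             stringsAsFactors = FALSE)
}

#' Confirm or refute a putative viral annotation
#'
#' A query with primary evidence from a viral-only database is cross-checked
#' against that query's hits in a multikingdom database, removing
#' false-positive viral annotations.  With no secondary hits the primary
#' verdict stands.  Otherwise the secondary hits are ranked; if the best
#' secondary hit is non-viral and its bitscore strictly exceeds the best viral
#' secondary hit's (or no viral secondary hit exists), the verdict is
#' nonviral with the secondary top hit's taxonomy.  Otherwise the verdict is
#' viral, with taxonomy from the augmented LCA over the viral secondary hits
#' retained within the e-value window.
#'
#' Adding a strictly worse non-viral secondary hit can therefore never flip a
#' viral verdict to nonviral (monotone safety of the cross-check).
#'
#' @param primaryTop one-row hit data.frame: the query's top hit in the
#'   viral-only database
#' @param secondaryHits the same query's hits in the multikingdom database
#'   (possibly empty)
#' @param tree a [TaxonomyTree-class]
#' @param evalueFactor e-value window for the LCA hit set (default 10)
#' @return list: \code{verdict} (\code{"viral"}/\code{"nonviral"}),
#'   \code{lca} (as [augmentedLca()]), \code{hit} (the annotation-bearing hit)
#' @export
confirmViral <- function(primaryTop, secondaryHits, tree, evalueFactor = 10) {
  if (is.null(secondaryHits) || !nrow(secondaryHits)) {
    return(list(verdict = "viral",
                lca = list(taxid = primaryTop$target_taxid[1L],
                           augmented = FALSE, basis = "lca"),
                hit = primaryTop))
  }
  ranked <- .rankHits(secondaryHits)
  viral <- vapply(ranked$target_taxid, function(t) isViral(tree, t),
                  logical(1L))
  topIsViral <- viral[1L]
  if (!topIsViral) {
    bestViral <- if (any(viral)) max(ranked$bitscore[viral]) else -Inf
    if (ranked$bitscore[1L] > bestViral) {
      return(list(verdict = "nonviral",
                  lca = list(taxid = ranked$target_taxid[1L],
                             augmented = FALSE, basis = "lca"),
                  hit = ranked[1L, , drop = FALSE]))
    }
  }
  vhits <- ranked[viral, , drop = FALSE]
  hitset <- lcaHitSet(vhits, vhits$query_id[1L], evalueFactor)
  res <- augmentedLca(tree, hitset$target_taxid)
  list(verdict = "viral", lca = res, hit = hitset[1L, , drop = FALSE])
}

.annotateRow <- function(queryId, verdict, searchType, lcaRes, hit, trace) {
  metrics <- if (is.null(hit)) .emptyM8Metrics() else
    hit[1L, c("target_id", "pident", "alnlen", "mismatch", "gapopen",
              "qstart", "qend", "tstart", "tend", "evalue", "bitscore"),
        drop = FALSE]
  rownames(metrics) <- NULL
  cbind(data.frame(query_id = queryId, verdict = verdict,
                   taxid = if (is.null(lcaRes)) .SENTINEL_TAXID else
                     as.integer(lcaRes$taxid),
                   search_type = searchType,
                   augmented = if (is.null(lcaRes)) FALSE else lcaRes$augmented,
                   basis = if (is.null(lcaRes)) "none" else lcaRes$basis,
                   tier_trace = paste(trace, collapse = ","),
                   stringsAsFactors = FALSE),
        metrics)
}

#' Tiered classification of representative sequences
#'
#' Routes every query through the two-stage search: queries with viral
#' amino-acid hits are confirmed against the multikingdom amino-acid table
#' (search type \code{aa}); queries without viral aa hits but with viral
#' nucleotide hits are confirmed against the polymicrobial nucleotide table
#' (search type \code{nt}); queries with neither are reported unclassified
#' with the sentinel taxonomy (one row per query, so downstream counts are
#' conserved).  aa-tier verdicts are final: a query with any viral aa hit
#' never carries a nucleotide annotation.
#'
#' @param queries character vector: the universe of representative sequence ids
#' @param viralAA,mkAA,viralNT,polyNT hit data.frames for the four databases
#'   (viral amino acid, multikingdom amino acid, viral nucleotide,
#'   polymicrobial nucleotide)
#' @param tree a [TaxonomyTree-class]
#' @param evalueFactor e-value window for LCA hit sets (default 10)
#' @return data.frame: one row per query with verdict, taxid, search type,
#'   augmentation flag, tier trace, and the annotation-bearing hit's metrics
#' @export
tieredClassify <- function(queries, viralAA, mkAA, viralNT, polyNT, tree,
                           evalueFactor = 10) {
  allHits <- list(viralAA, mkAA, viralNT, polyNT)
  for (h in allHits) {
    if (!is.null(h) && nrow(h)) {
      stray <- setdiff(unique(h$query_id), queries)
      if (length(stray))
        stop("integrity error: hits for unknown queries: ",
             paste(head(stray, 5L), collapse = ", "), call. = FALSE)
    }
  }
  subHits <- function(h, q) {
    if (is.null(h) || !nrow(h)) return(.emptyHits())
    h[h$query_id == q, , drop = FALSE]
  }
  rows <- lapply(sort(queries), function(q) {
    vaa <- subHits(viralAA, q)
    if (nrow(vaa)) {
      res <- confirmViral(topHit(vaa, q), subHits(mkAA, q), tree, evalueFactor)
      return(.annotateRow(q, res$verdict, "aa", res$lca, res$hit,
                          c("viral_aa", "multikingdom_aa")))
    }
    vnt <- subHits(viralNT, q)
    if (nrow(vnt)) {
      res <- confirmViral(topHit(vnt, q), subHits(polyNT, q), tree,
                          evalueFactor)
      return(.annotateRow(q, res$verdict, "nt", res$lca, res$hit,
                          c("viral_aa", "viral_nt", "polymicrobial_nt")))
    }
    .annotateRow(q, "unclassified", NA_character_, NULL, NULL,
                 c("viral_aa", "viral_nt"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write tier annotations as TSV
#'
#' One row per query: verdict, taxid, search type, augmentation flag, tier
#' trace and the top hit's m8 metrics.
#'
#' @param tiers data.frame from [tieredClassify()]
#' @param path output path
#' @export
writeTierAnnotations <- function(tiers, path) {
  write.table(tiers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
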