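# Ground-truth evaluation of read-level annotations: per-genome confusion
# counts, sensitivity and false-positive rate.

#' Per-read annotations from a SeqTable and tier annotations
#'
#' Propagates each representative's verdict and taxonomy to every read in
#' its cluster.
#'
#' @param seqtab a [SeqTable-class]
#' @param tiers data.frame from [tieredClassify()]
#' @return data.frame: read_id, sample_id, seq_id, verdict, taxid, augmented
#' @export
readAnnotations <- function(seqtab, tiers) {
  mem <- clusterMembers(seqtab)
  idx <- match(mem$seq_id, tiers$query_id)
  out <- data.frame(read_id = mem$read_id, sample_id = mem$sample_id,
                    seq_id = mem$seq_id,
                    verdict = tiers$verdict[idx],
                    taxid = tiers$taxid[idx],
                    augmented = tiers$augmented[idx],
                    stringsAsFactors = FALSE)
  out$verdict[is.na(idx)] <- "unclassified"
  out$taxid[is.na(idx)] <- .SENTINEL_TAXID
  out$augmented[is.na(idx)] <- FALSE
  out
}

#' Evaluate annotations against ground truth
#'
#' A read whose true source is viral counts as a true positive when it is
#' annotated viral and its assigned lineage matches the truth lineage at the
#' requested rank (or the exact taxid when \code{rank = "taxid"}); viral
#' reads that are unclassified, nonviral or wrongly placed are false
#' negatives.  A read of non-viral origin annotated viral is a false
#' positive.  Sensitivity = TP / (TP + FN); false-positive rate = FP / total
#' non-viral reads.
#'
#' @param annotations per-read data.frame (read_id, verdict, taxid), e.g.
#'   from [readAnnotations()]
#' @param truth data.frame mapping read_id to source taxid (and optionally a
#'   genome label)
#' @param tree a [TaxonomyTree-class]
#' @param rank one of the 7 canonical ranks or \code{"taxid"}
#' @return list: \code{per_genome} data.frame of TP/FP/FN counts,
#'   \code{sensitivity}, \code{false_positive_rate}, and the raw totals
#' @export
evaluateAnnotations <- function(annotations, truth, tree, rank = "family") {
  stopifnot(rank %in% c(.RANKS7, "taxid"))
  missing <- setdiff(annotations$read_id, truth$read_id)
  if (length(missing))
    stop("integrity error: annotated reads missing from truth: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  tIdx <- match(truth$read_id, annotations$read_id)
  verdict <- annotations$verdict[tIdx]
  verdict[is.na(verdict)] <- "unclassified"
  assigned <- annotations$taxid[tIdx]
  assigned[is.na(assigned)] <- .SENTINEL_TAXID

  truthViral <- vapply(truth$taxid, function(t) isViral(tree, t), logical(1L))
  assignedViral <- verdict == "viral"

  if (rank == "taxid") {
    match_at_rank <- assigned == truth$taxid
  } else {
    truthRank <- lineageTable(tree, truth$taxid)[[rank]]
    assignedRank <- lineageTable(tree, assigned)[[rank]]
    match_at_rank <- truthRank == assignedRank & truthRank != .SENTINEL
  }

  tp <- truthViral & assignedViral & match_at_rank
  fn <- truthViral & !tp
  fp <- !truthViral & assignedViral

  group <- if ("label" %in% names(truth)) truth$label else
    as.character(truth$taxid)
  perGenome <- do.call(rbind, lapply(unique(group), function(g) {
    sel <- group == g
    data.frame(genome = g, taxid = truth$taxid[sel][1L],
               viral_truth = truthViral[sel][1L],
               n_reads = sum(sel),
               true_positive = sum(tp[sel]),
               false_positive = sum(fp[sel]),
               false_negative = sum(fn[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(perGenome) <- NULL
  negatives <- sum(!truthViral)
  list(per_genome = perGenome,
       sensitivity = if (sum(truthViral)) sum(tp) / (sum(tp) + sum(fn))
                     else NA_real_,
       false_positive_rate = if (negatives) sum(fp) / negatives else 0,
       n_viral_reads = sum(truthViral),
       n_nonviral_reads = negatives,
       rank = rank)
}

#' Write an evaluation report as TSV
#'
#' Per-genome counts followed by commented summary lines.
#'
#' @param report list from [evaluateAnnotations()]
#' @param path output path
#' @export
writeEvalReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rank\t%s", report$rank), con)
  writeLines(sprintf("# sensitivity\t%.6f", report$sensitivity), con)
  writeLines(sprintf("# false_positive_rate\t%.6f",
                     report$false_positive_rate), con)
  write.table(report$per_genome, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
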