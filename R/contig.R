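# Contig-level products: abundance normalization (RPKM/FPKM/SPM), contig
# properties, unmapped-read pooling, and the contig/read-annotation join.

.validateMappings <- function(mappings) {
  need <- c("read_id", "sample_id", "contig_id", "start", "end", "mapq",
            "is_mapped")
  miss <- setdiff(need, names(mappings))
  if (length(miss))
    stop("mapping table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  mappings
}

#' Read a native mapping TSV
#'
#' Columns: read_id, sample_id, contig_id, start, end, mapq, is_mapped
#' (header row required; unmapped rows carry empty contig and coordinates).
#'
#' @param path TSV path
#' @return mapping data.frame
#' @export
readMappingsTsv <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  m$is_mapped <- as.logical(m$is_mapped)
  .validateMappings(m)
}

#' Read mappings from a text SAM file
#'
#' Minimal SAM ingestion restricted to the fields the contig tables use:
#' QNAME, FLAG, RNAME, POS, MAPQ and the CIGAR reference span.  Secondary
#' (0x100) and supplementary (0x800) alignments are skipped so every read
#' counts once, at its primary alignment; flag 0x4 marks unmapped reads.
#'
#' @param path SAM path
#' @param sampleId sample label to record on every row
#' @return mapping data.frame as in [readMappingsTsv()]
#' @export
readMappingsSam <- function(path, sampleId) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  rows <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    flag <- as.integer(f[[2L]])
    if (bitwAnd(flag, 0x100L) > 0L || bitwAnd(flag, 0x800L) > 0L)
      return(NULL)
    unmapped <- bitwAnd(flag, 0x4L) > 0L
    if (unmapped) {
      data.frame(read_id = f[[1L]], sample_id = sampleId,
                 contig_id = NA_character_, start = NA_integer_,
                 end = NA_integer_, mapq = NA_integer_, is_mapped = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      cig <- f[[6L]]
      ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1L]]
      lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
      kinds <- sub("^[0-9]+", "", ops)
      span <- sum(lens[kinds %in% c("M", "D", "N", "=", "X")])
      pos0 <- as.integer(f[[4L]]) - 1L
      data.frame(read_id = f[[1L]], sample_id = sampleId,
                 contig_id = f[[3L]], start = pos0, end = pos0 + span,
                 mapq = as.integer(f[[5L]]), is_mapped = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  .validateMappings(out)
}

#' Pool unmapped reads across samples
#'
#' Returns exactly the reads flagged unmapped, pooled over all samples with
#' their sample provenance retained, ready for the next assembly round of the
#' merged-assembly flow.  A read appearing as both mapped and unmapped in
#' the same sample is a data-integrity error.
#'
#' @param mappings mapping data.frame covering all reads (mapped and
#'   unmapped rows)
#' @return data.frame: \code{read_id}, \code{sample_id} of the pooled reads
#' @export
poolUnmapped <- function(mappings) {
  .validateMappings(mappings)
  key <- paste(mappings$sample_id, mappings$read_id)
  mappedKeys <- unique(key[mappings$is_mapped])
  unmappedKeys <- unique(key[!mappings$is_mapped])
  both <- intersect(mappedKeys, unmappedKeys)
  if (length(both))
    stop("integrity error: read(s) both mapped and unmapped: ",
         paste(head(both, 5L), collapse = "; "), call. = FALSE)
  out <- mappings[!mappings$is_mapped, c("read_id", "sample_id"), drop = FALSE]
  rownames(out) <- NULL
  out
}

.gcFraction <- function(seq) {
  s <- DNAStringSet(seq)
  fr <- letterFrequency(s, c("A", "C", "G", "T"))
  tot <- rowSums(fr)
  ifelse(tot == 0, NA_real_, (fr[, "C"] + fr[, "G"]) / tot)
}

#' Per-sample contig abundances with RPKM, FPKM and SPM
#'
#' For each (contig i, sample): \code{r_i} mapped reads, contig length
#' \code{l_i} and sample mapped-read total \code{R} give
#' \code{rpkm = r_i * 1e9 / (R * l_i)}; FPKM is the same with fragments
#' (mate pairs collapse to one fragment when both map to the same contig);
#' \code{spm = 1e6 * (r_i/l_i) / sum_j(r_j/l_j)}, a TPM-style rate
#' normalization that sums to 1e6 per sample.  Coverage percent comes from
#' the union of mapping intervals; GC is computed over A/C/G/T only.
#'
#' @param mappings mapping data.frame (mapped rows drive the counts)
#' @param contigs named character vector or \code{DNAStringSet}
#' @return data.frame: one row per (contig, sample) with \code{length},
#'   \code{gc_fraction}, \code{raw_count}, \code{rpkm}, \code{fpkm},
#'   \code{spm}, \code{coverage_percent}
#' @export
contigAbundance <- function(mappings, contigs) {
  .validateMappings(mappings)
  if (is(contigs, "DNAStringSet")) contigs <- as.character(contigs)
  mapped <- mappings[mappings$is_mapped, , drop = FALSE]
  unknown <- setdiff(unique(mapped$contig_id), names(contigs))
  if (length(unknown))
    stop("integrity error: mappings to unknown contig(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  lens <- nchar(contigs)
  gc <- .gcFraction(unname(contigs))
  names(gc) <- names(contigs)

  combos <- expand.grid(contig_id = names(contigs),
                        sample_id = unique(mappings$sample_id),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    ci <- combos$contig_id[i]; si <- combos$sample_id[i]
    mi <- mapped[mapped$contig_id == ci & mapped$sample_id == si, ,
                 drop = FALSE]
    r <- nrow(mi)
    frag <- length(unique(sub("/[12]$", "", mi$read_id)))
    covered <- if (r) sum(width(reduce(IRanges(start = mi$start + 1L,
                                               end = mi$end)))) else 0L
    data.frame(contig_id = ci, sample_id = si,
               length = unname(lens[ci]), gc_fraction = unname(gc[ci]),
               raw_count = r, fragments = frag,
               covered_bases = covered, stringsAsFactors = FALSE)
  })
  ab <- do.call(rbind, rows)
  ab$coverage_percent <- 100 * ab$covered_bases / ab$length
  ab$rpkm <- 0; ab$fpkm <- 0; ab$spm <- 0
  for (si in unique(ab$sample_id)) {
    sel <- ab$sample_id == si
    R <- sum(ab$raw_count[sel])
    Rf <- sum(ab$fragments[sel])
    rate <- ab$raw_count[sel] / ab$length[sel]
    if (R > 0) {
      ab$rpkm[sel] <- ab$raw_count[sel] * 1e9 / (R * ab$length[sel])
      ab$spm[sel] <- 1e6 * rate / sum(rate)
    }
    if (Rf > 0)
      ab$fpkm[sel] <- ab$fragments[sel] * 1e9 / (Rf * ab$length[sel])
  }
  ab$covered_bases <- NULL
  ab$fragments <- NULL
  rownames(ab) <- NULL
  ab[, c("contig_id", "sample_id", "length", "gc_fraction", "raw_count",
         "rpkm", "fpkm", "spm", "coverage_percent")]
}

#' Join read mappings to read-level annotations (contigSeqTable)
#'
#' One row per mapped (read, contig) pair carrying the mapping coordinates
#' and quality plus the read's taxonomy from the bigtable; reads absent from
#' the bigtable join with the sentinel lineage (outer-join semantics), so the
#' row count always equals the mapped-pair count.
#'
#' @param mappings mapping data.frame
#' @param bigtable data.frame from [buildBigtable()]
#' @return the joined data.frame
#' @export
contigSeqTable <- function(mappings, bigtable) {
  .validateMappings(mappings)
  mapped <- mappings[mappings$is_mapped, , drop = FALSE]
  taxCols <- c("verdict", "taxid", .RANKS7)
  idx <- match(mapped$read_id, bigtable$seq_id)
  tax <- bigtable[idx, taxCols, drop = FALSE]
  tax$verdict[is.na(idx)] <- "unclassified"
  tax$taxid[is.na(idx)] <- .SENTINEL_TAXID
  for (r in .RANKS7) tax[[r]][is.na(idx)] <- .SENTINEL
  out <- cbind(mapped[, c("contig_id", "read_id", "sample_id", "start",
                          "end", "mapq")], tax)
  rownames(out) <- NULL
  out
}

#' Annotate contigs from polymicrobial-database hits
#'
#' Per contig: augmented LCA over the e-value-windowed hit set; the verdict
#' is viral exactly when the assigned taxid's lineage passes through the
#' virus root.  Contigs without hits get the sentinel lineage and an
#' unclassified verdict.
#'
#' @param contigIds character vector: the universe of contigs
#' @param contigHits m8 hit data.frame of contigs vs the polymicrobial
#'   nucleotide database
#' @param tree a [TaxonomyTree-class]
#' @param evalueFactor e-value window (default 10)
#' @return data.frame: contig_id, verdict, taxid, augmented plus the 7 ranks
#' @export
contigAnnotate <- function(contigIds, contigHits, tree, evalueFactor = 10) {
  rows <- lapply(sort(contigIds), function(ci) {
    sub <- contigHits[contigHits$query_id == ci, , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(contig_id = ci, verdict = "unclassified",
                        taxid = .SENTINEL_TAXID, augmented = FALSE,
                        stringsAsFactors = FALSE))
    }
    hitset <- lcaHitSet(sub, ci, evalueFactor)
    res <- augmentedLca(tree, hitset$target_taxid)
    data.frame(contig_id = ci,
               verdict = if (isViral(tree, res$taxid)) "viral" else "nonviral",
               taxid = as.integer(res$taxid), augmented = res$augmented,
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  cbind(ann, lineageTable(tree, ann$taxid)[, .RANKS7, drop = FALSE])
}

#' Write the contig count table
#'
#' contig_count_table.tsv dialect: abundance columns from
#' [contigAbundance()] joined with the contig taxonomy from
#' [contigAnnotate()].
#'
#' @param abundance data.frame from [contigAbundance()]
#' @param annotation data.frame from [contigAnnotate()] (optional)
#' @param path output TSV path
#' @return the joined table, invisibly written to \code{path}
#' @export
writeContigCountTable <- function(abundance, annotation = NULL, path) {
  out <- abundance
  if (!is.null(annotation)) {
    idx <- match(out$contig_id, annotation$contig_id)
    out <- cbind(out, annotation[idx, c("verdict", "taxid", .RANKS7),
                                 drop = FALSE])
  }
  rownames(out) <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
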