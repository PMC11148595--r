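#' @import methods
#' @importFrom stats runif setNames
#' @importFrom utils head read.delim write.table
NULL

#' Rank-annotated taxonomy over integer taxids
#'
#' Holds a parsed taxdump-dialect taxonomy: parent links, rank labels and
#' scientific names keyed by taxid, plus the identities of the global root and
#' of the virus root (the Viruses superkingdom, NCBI taxid 10239 by
#' convention).  All lineage, LCA and augmented-LCA queries run against this
#' object.
#'
#' @slot parent named integer vector; names are taxids (as character), values
#'   the parent taxid.  The root is its own parent.
#' @slot rank named character vector of rank labels, keyed like \code{parent}.
#'   Unknown rank labels are preserved verbatim.
#' @slot sciname named character vector of scientific names, keyed by taxid.
#' @slot rootId integer taxid of the global root (default 1).
#' @slot virusRootId integer taxid of the virus root (default 10239).
#' @slot merged named integer vector mapping retired taxids to their current
#'   ones (from a merged.dmp-dialect file); may be empty.
#'
#' @seealso [loadTaxdump()], [lineage7()], [lca()], [augmentedLca()]
#' @exportClass TaxonomyTree
setClass("TaxonomyTree",
  representation(
    parent = "integer",
    rank = "character",
    sciname = "character",
    rootId = "integer",
    virusRootId = "integer",
    merged = "integer"
  )
)

setValidity("TaxonomyTree", function(object) {
  msg <- character()
  ids <- names(object@parent)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "parent must be uniquely named by taxid")
  if (!as.character(object@rootId) %in% ids)
    msg <- c(msg, "rootId absent from nodes")
  orphans <- setdiff(as.character(object@parent), ids)
  if (length(orphans))
    msg <- c(msg, paste0("orphan parent taxids: ",
                         paste(head(orphans, 10L), collapse = ", ")))
  # acyclicity: every node must reach the root by parent walking
  if (!length(msg)) {
    for (id in ids) {
      seen <- character()
      cur <- id
      while (cur != as.character(object@rootId)) {
        if (cur %in% seen) return(paste0("cycle involving taxid ", cur))
        seen <- c(seen, cur)
        cur <- as.character(object@parent[[cur]])
        if (length(seen) > length(ids)) return("parent walk does not terminate")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TaxonomyTree", function(object) {
  cat("TaxonomyTree with", length(object@parent), "nodes\n")
  cat("  root:", object@rootId,
      " virus root:", object@virusRootId, "\n")
  rk <- table(object@rank)
  cat("  ranks:", paste(names(rk), rk, sep = ":", collapse = " "), "\n")
  if (length(object@merged))
    cat("  merged taxid aliases:", length(object@merged), "\n")
})

#' Dereplicated representative sequences with per-sample counts
#'
#' The seqtable: one representative sequence per cluster, with the sample it
#' came from, the number of reads it represents, and that count as a
#' percentage of the sample's (host-removed) read total.  Headers of the
#' FASTA serialization encode \code{sample:index:count:percent}.
#'
#' @slot clusters data.frame with columns \code{seq_id}, \code{sample_id},
#'   \code{cluster_index}, \code{member_count}, \code{percent_of_sample},
#'   \code{sequence}.
#' @slot members data.frame mapping \code{read_id} to \code{seq_id} and
#'   \code{sample_id} (one row per input read).
#' @slot sampleTotals named integer vector of per-sample read totals used for
#'   the percentages (post-host totals when host removal ran upstream).
#'
#' @seealso [greedyCluster()], [encodeSeqtable()], [countTable()]
#' @exportClass SeqTable
setClass("SeqTable",
  representation(
    clusters = "data.frame",
    members = "data.frame",
    sampleTotals = "integer"
  )
)

setValidity("SeqTable", function(object) {
  cl <- object@clusters
  need <- c("seq_id", "sample_id", "cluster_index", "member_count",
            "percent_of_sample", "sequence")
  if (!all(need %in% names(cl)))
    return(paste("clusters missing columns:",
                 paste(setdiff(need, names(cl)), collapse = ", ")))
  if (any(cl$member_count < 1L)) return("member_count must be >= 1")
  if (anyDuplicated(cl$seq_id)) return("seq_id must be unique")
  for (s in unique(cl$sample_id)) {
    tot <- object@sampleTotals[[s]]
    if (is.null(tot) || is.na(tot)) return(paste("no sample total for", s))
    got <- sum(cl$member_count[cl$sample_id == s])
    if (got > tot) return(paste("sample", s, "member counts exceed total"))
  }
  TRUE
})

setMethod("show", "SeqTable", function(object) {
  cl <- object@clusters
  cat("SeqTable:", nrow(cl), "representative sequences,",
      sum(cl$member_count), "reads,",
      length(unique(cl$sample_id)), "sample(s)\n")
})

#' @describeIn SeqTable-class data.frame of cluster records
#' @param x a \code{SeqTable}
#' @export
clusters <- function(x) {
  stopifnot(is(x, "SeqTable"))
  x@clusters
}

#' @describeIn SeqTable-class read-to-representative membership table
#' @export
clusterMembers <- function(x) {
  stopifnot(is(x, "SeqTable"))
  x@members
}

#' @describeIn SeqTable-class per-sample read totals backing the percentages
#' @export
sampleTotals <- function(x) {
  stopifnot(is(x, "SeqTable"))
  x@sampleTotals
}

#' @describeIn TaxonomyTree-class number of taxonomy nodes
#' @param x a \code{TaxonomyTree}
#' @export
nTaxa <- function(x) {
  stopifnot(is(x, "TaxonomyTree"))
  length(x@parent)
}

#' @describeIn TaxonomyTree-class all taxids in the tree
#' @export
taxIds <- function(x) {
  stopifnot(is(x, "TaxonomyTree"))
  as.integer(names(x@parent))
}

#' @describeIn TaxonomyTree-class the virus-root taxid
#' @export
virusRootId <- function(x) {
  stopifnot(is(x, "TaxonomyTree"))
  x@virusRootId
}

#' @describeIn TaxonomyTree-class the global-root taxid
#' @export
rootId <- function(x) {
  stopifnot(is(x, "TaxonomyTree"))
  x@rootId
}

# sentinel used everywhere a rank/lineage/taxid is absent
.SENTINEL <- "unclassified"
.SENTINEL_TAXID <- 0L

# the seven canonical rank slots, fixed order
.RANKS7 <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")

#' Sentinel values for absent taxonomy
#'
#' The literal rank/name sentinel (\code{"unclassified"}) and the sentinel
#' taxid (0) used for unannotated sequences throughout output tables.
#' @return a list with elements \code{name} and \code{taxid}
#' @export
taxonomySentinel <- function() list(name = .SENTINEL, taxid = .SENTINEL_TAXID)
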