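# Taxdump-dialect parsing, 7-rank lineages, LCA and augmented LCA.

.parseDmp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  # records terminated by "\t|", fields separated by "\t|\t"
  bad <- which(!grepl("\t\\|$", lines))
  if (length(bad))
    stop("malformed dmp record at line ", bad[1L], " of ", basename(path),
         ": missing record terminator", call. = FALSE)
  body <- sub("\t\\|$", "", lines)
  strsplit(body, "\t\\|\t")
}

#' Load a taxdump-dialect taxonomy
#'
#' Parses \code{nodes.dmp} / \code{names.dmp} (pipe-delimited dmp dialect:
#' fields separated by \code{"\\t|\\t"}, records terminated by \code{"\\t|"})
#' into a [TaxonomyTree-class].  Only scientific names are kept from the names
#' file.  A \code{merged.dmp}-dialect file, when supplied, is honored so that
#' retired taxids resolve to their current nodes.
#'
#' @param nodesPath path to the nodes file (taxid, parent taxid, rank, ...)
#' @param namesPath path to the names file (taxid, name, unique name, class)
#' @param mergedPath optional path to a merged file (old taxid, new taxid)
#' @param rootId taxid of the global root (default 1)
#' @param virusRootId taxid of the Viruses superkingdom (default 10239)
#' @return a validated [TaxonomyTree-class]
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' synthTaxonomy(2, 2, seed = 1, dir = dir)
#' tree <- loadTaxdump(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"))
#' tree
#' @export
loadTaxdump <- function(nodesPath, namesPath, mergedPath = NULL,
                        rootId = 1L, virusRootId = 10239L) {
  recs <- .parseDmp(nodesPath)
  nf <- lengths(recs)
  if (any(nf < 3L))
    stop("malformed nodes record at line ", which(nf < 3L)[1L],
         ": fewer than 3 fields", call. = FALSE)
  ids <- vapply(recs, `[[`, "", 1L)
  if (anyNA(suppressWarnings(as.integer(ids))))
    stop("non-integer taxid in nodes file", call. = FALSE)
  parent <- as.integer(vapply(recs, `[[`, "", 2L))
  rank <- vapply(recs, `[[`, "", 3L)
  names(parent) <- ids
  names(rank) <- ids

  orphans <- setdiff(as.character(parent), ids)
  if (length(orphans))
    stop("taxonomy integrity error: parent taxids absent from nodes: ",
         paste(orphans, collapse = ", "), call. = FALSE)

  nrecs <- .parseDmp(namesPath)
  keep <- vapply(nrecs, function(r)
    length(r) >= 4L && r[[4L]] == "scientific name", logical(1L))
  # tolerate 2/3-field toy names files: treat every record as a name
  if (!any(keep)) keep <- rep(TRUE, length(nrecs))
  sciname <- vapply(nrecs[keep], `[[`, "", 2L)
  names(sciname) <- vapply(nrecs[keep], `[[`, "", 1L)
  sciname <- sciname[names(sciname) %in% ids]
  missing <- setdiff(ids, names(sciname))
  if (length(missing)) {
    fill <- setNames(paste0("taxid_", missing), missing)
    sciname <- c(sciname, fill)
  }

  merged <- integer(0)
  if (!is.null(mergedPath)) {
    mrecs <- .parseDmp(mergedPath)
    merged <- as.integer(vapply(mrecs, `[[`, "", 2L))
    names(merged) <- vapply(mrecs, `[[`, "", 1L)
  }

  new("TaxonomyTree", parent = parent, rank = rank,
      sciname = sciname[ids], rootId = as.integer(rootId),
      virusRootId = as.integer(virusRootId), merged = merged)
}

#' Resolve a taxid through merged aliases
#'
#' Returns the current taxid for \code{taxid}, following the merged-taxid
#' table if needed; unknown taxids return the sentinel taxid (0) with a
#' warning rather than aborting, so hit tables referencing a stale taxonomy
#' degrade to the sentinel lineage instead of killing a run.
#'
#' @param tree a [TaxonomyTree-class]
#' @param taxid integer taxid
#' @param warn warn on unknown taxids (default TRUE)
#' @return an integer taxid present in the tree, or 0
#' @export
resolveTaxid <- function(tree, taxid, warn = TRUE) {
  key <- as.character(taxid)
  if (key %in% names(tree@parent)) return(as.integer(taxid))
  if (key %in% names(tree@merged)) {
    new <- tree@merged[[key]]
    if (as.character(new) %in% names(tree@parent)) return(new)
  }
  if (warn) warning("unknown taxid ", taxid,
                    "; classified to sentinel lineage", call. = FALSE)
  .SENTINEL_TAXID
}

#' Root path of a taxid
#'
#' The ancestry of \code{taxid} from itself up to (and including) the root.
#'
#' @inheritParams resolveTaxid
#' @return integer vector of taxids, \code{taxid} first, root last
#' @export
rootPath <- function(tree, taxid) {
  key <- as.character(taxid)
  if (!key %in% names(tree@parent))
    stop("unknown taxid: ", taxid, call. = FALSE)
  path <- integer(0)
  cur <- as.integer(taxid)
  repeat {
    path <- c(path, cur)
    if (cur == tree@rootId) break
    cur <- tree@parent[[as.character(cur)]]
  }
  path
}

#' Canonical 7-rank lineage
#'
#' Fills the seven Linnaean rank slots (kingdom, phylum, class, order, family,
#' genus, species) from the nearest node on the taxid's root path carrying
#' each rank label; absent ranks get the sentinel \code{"unclassified"}.  NCBI
#' dumps label the top split \code{superkingdom}; when no \code{kingdom}-ranked
#' ancestor exists the superkingdom fills the kingdom slot, matching the
#' 7-column contract of the output tables on real dumps.
#'
#' @inheritParams resolveTaxid
#' @return named character vector of length 7 (\code{kingdom} ... \code{species})
#' @export
lineage7 <- function(tree, taxid) {
  out <- setNames(rep(.SENTINEL, 7L), .RANKS7)
  if (taxid == .SENTINEL_TAXID) return(out)
  path <- rootPath(tree, taxid)
  rk <- tree@rank[as.character(path)]
  nm <- tree@sciname[as.character(path)]
  for (r in .RANKS7) {
    hit <- which(rk == r)
    if (length(hit)) out[[r]] <- nm[[hit[1L]]]  # nearest ancestor first
  }
  if (out[["kingdom"]] == .SENTINEL) {
    hit <- which(rk == "superkingdom")
    if (length(hit)) out[["kingdom"]] <- nm[[hit[1L]]]
  }
  out
}

#' Lineage table for many taxids
#'
#' Vectorized [lineage7()]: one row per input taxid, sentinel rows for
#' unknown/sentinel taxids (resolved through merged aliases first).
#'
#' @inheritParams resolveTaxid
#' @param taxids integer vector
#' @return data.frame with columns \code{taxid} and the 7 ranks
#' @export
lineageTable <- function(tree, taxids) {
  resolved <- vapply(taxids, function(t) resolveTaxid(tree, t, warn = FALSE),
                     integer(1L))
  rows <- lapply(resolved, function(t) lineage7(tree, t))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  cbind(data.frame(taxid = as.integer(resolved)), out)
}

#' Lowest common ancestor
#'
#' The deepest node present on the root path of every member of
#' \code{taxids}.
#'
#' @inheritParams resolveTaxid
#' @param taxids non-empty integer vector of taxids present in the tree
#' @return integer taxid of the LCA
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' synthTaxonomy(2, 1, seed = 1, dir = dir)
#' tree <- loadTaxdump(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"))
#' lca(tree, c(10239L, 1L))
#' @export
lca <- function(tree, taxids) {
  taxids <- unique(as.integer(taxids))
  if (!length(taxids)) stop("lca of an empty taxid set", call. = FALSE)
  if (length(taxids) == 1L) {
    rootPath(tree, taxids)  # validates presence
    return(taxids)
  }
  # intersect root->node paths; deepest shared prefix element
  paths <- lapply(taxids, function(t) rev(rootPath(tree, t)))
  minLen <- min(lengths(paths))
  depth <- 0L
  for (i in seq_len(minLen)) {
    level <- vapply(paths, `[[`, integer(1L), i)
    if (all(level == level[1L])) depth <- i else break
  }
  paths[[1L]][depth]
}

#' Is a taxid viral?
#'
#' TRUE when the virus root lies on the taxid's root path.
#'
#' @inheritParams resolveTaxid
#' @export
isViral <- function(tree, taxid) {
  if (taxid == .SENTINEL_TAXID) return(FALSE)
  t <- resolveTaxid(tree, taxid, warn = FALSE)
  if (t == .SENTINEL_TAXID) return(FALSE)
  tree@virusRootId %in% rootPath(tree, t)
}

#' LCA with top-hit reversion
#'
#' Plain LCA degenerates when evidence crosses high ranks: hits to both
#' bacterial and viral taxa meet only at the global root, and hits to viruses
#' from distinct viral realms (e.g., a bacteriophage and a vertebrate virus)
#' meet at the virus root.  In exactly those two cases -- the LCA equals the
#' global root or the virus root and the evidence is not unanimous -- the
#' assignment reverts to the top hit's taxid and is flagged, so downstream
#' users can include or exclude reverted assignments.  Intermediate unranked
#' nodes directly under the root do not trigger reversion.
#'
#' @inheritParams resolveTaxid
#' @param hitTaxids taxids ordered by hit priority; the first element is the
#'   top hit
#' @return list with \code{taxid}, \code{augmented} (logical) and \code{basis}
#'   (\code{"lca"} or \code{"top_hit_reverted"})
#' @export
augmentedLca <- function(tree, hitTaxids) {
  if (!length(hitTaxids)) stop("augmentedLca of an empty hit list", call. = FALSE)
  hitTaxids <- as.integer(hitTaxids)
  plain <- lca(tree, hitTaxids)
  trigger <- plain %in% c(tree@rootId, tree@virusRootId)
  if (trigger && length(unique(hitTaxids)) >= 2L) {
    list(taxid = hitTaxids[1L], augmented = TRUE, basis = "top_hit_reverted")
  } else {
    list(taxid = plain, augmented = FALSE, basis = "lca")
  }
}

#' Baltimore classification table
#'
#' Loads the packaged family-to-Baltimore-group table (or a user-supplied TSV
#' in the same 3-column dialect: \code{family}, \code{baltimore_group},
#' \code{nucleic_acid}, header row required).  The Baltimore scheme places
#' viruses into one of seven groups by genome nucleic acid, strandedness,
#' sense and replication mode; the join is data, not algorithm.
#'
#' @param path TSV path; default the packaged table
#' @return data.frame with the three columns
#' @export
baltimoreTable <- function(path = system.file("extdata",
                                              "baltimore_classification.tsv",
                                              package = "viroscreen")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "baltimore_group", "nucleic_acid")
  if (!all(need %in% names(tab)))
    stop("Baltimore table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  groups <- paste("Group", c("I", "II", "III", "IV", "V", "VI", "VII"))
  bad <- setdiff(unique(tab$baltimore_group), groups)
  if (length(bad))
    stop("Baltimore groups outside the 7-group vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  tab
}

#' Look up a viral family's Baltimore entry
#'
#' Exact, case-sensitive family-name match; a miss is a value (\code{NULL}),
#' not an error.
#'
#' @param table data.frame from [baltimoreTable()]
#' @param family family name string
#' @return a one-row data.frame, or \code{NULL} when absent
#' @export
baltimoreLookup <- function(table, family) {
  i <- which(table$family == family)
  if (!length(i)) return(NULL)
  table[i[1L], , drop = FALSE]
}
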