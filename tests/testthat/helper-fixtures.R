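# Fixture builders and independent oracles shared across the suite.
# All fixtures are generated in code under fixed seeds; nothing is stored.

# ---- taxonomy fixtures -----------------------------------------------------

# write a taxdump from a node table (taxid, parent, rank, name)
writeToyTaxdump <- function(nodes, dir = tempfile("tax")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dmp <- function(...) paste0(paste(..., sep = "\t|\t"), "\t|")
  writeLines(dmp(nodes$taxid, nodes$parent, nodes$rank),
             file.path(dir, "nodes.dmp"))
  writeLines(dmp(nodes$taxid, nodes$name, "", "scientific name"),
             file.path(dir, "names.dmp"))
  dir
}

# hand-built tree: root, Viruses/Bacteria superkingdoms, two viral family
# chains (full 7 ranks via superkingdom fallback) and one bacterial species
toyNodeTable <- function() {
  data.frame(
    taxid  = c(1, 10239, 2,
               11, 12, 13, 14, 15, 16,        # viral chain A (phage)
               21, 22, 23, 24, 25, 26,        # viral chain B (vertebrate)
               31, 32, 33, 34, 35, 36),       # bacterial chain
    parent = c(1, 1, 1,
               10239, 11, 12, 13, 14, 15,
               10239, 21, 22, 23, 24, 25,
               2, 31, 32, 33, 34, 35),
    rank   = c("no rank", "superkingdom", "superkingdom",
               rep(c("phylum", "class", "order", "family", "genus",
                     "species"), 2),
               c("phylum", "class", "order", "family", "genus", "species")),
    name   = c("root", "Viruses", "Bacteria",
               "PhgPhylum", "PhgClass", "PhgOrder", "Microviridae",
               "PhgGenus", "Phage species",
               "VrtPhylum", "VrtClass", "VrtOrder", "Adenoviridae",
               "VrtGenus", "Vertebrate virus species",
               "BacPhylum", "BacClass", "BacOrder", "BacFamily",
               "BacGenus", "Bacterium species"),
    stringsAsFactors = FALSE)
}

toyTree <- function() {
  dir <- writeToyTaxdump(toyNodeTable())
  loadTaxdump(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"))
}

# random tree: n nodes attached to earlier nodes; returns the node table too
randomTreeFixture <- function(n, seed) {
  set.seed(seed)
  ranks <- c("no rank", "superkingdom", "phylum", "class", "order",
             "family", "genus", "species")
  taxid <- c(1L, 10239L, sample(setdiff(100:9999, 1), n - 2L))
  parent <- c(1L, 1L,
              vapply(3:n, function(i) taxid[sample.int(i - 1L, 1L)],
                     integer(1L)))
  nodes <- data.frame(taxid = taxid, parent = parent,
                      rank = c("no rank", "superkingdom",
                               sample(ranks, n - 2L, replace = TRUE)),
                      name = paste0("node", taxid), stringsAsFactors = FALSE)
  dir <- writeToyTaxdump(nodes)
  list(tree = loadTaxdump(file.path(dir, "nodes.dmp"),
                          file.path(dir, "names.dmp")),
       nodes = nodes)
}

# ---- independent taxonomy oracles (data.frame parent walks) ---------------

oracleRootPath <- function(nodes, taxid) {
  path <- integer(0)
  cur <- taxid
  repeat {
    path <- c(path, cur)
    if (cur == 1L) break
    cur <- nodes$parent[match(cur, nodes$taxid)]
  }
  path
}

oracleLca <- function(nodes, taxids) {
  paths <- lapply(taxids, function(t) oracleRootPath(nodes, t))
  common <- Reduce(intersect, paths)
  depths <- vapply(common, function(t) length(oracleRootPath(nodes, t)),
                   integer(1L))
  common[which.max(depths)]
}

oracleLineage <- function(nodes, taxid) {
  ranks7 <- c("kingdom", "phylum", "class", "order", "family", "genus",
              "species")
  path <- oracleRootPath(nodes, taxid)
  out <- setNames(rep("unclassified", 7L), ranks7)
  for (r in ranks7) {
    hit <- path[nodes$rank[match(path, nodes$taxid)] == r]
    if (length(hit)) out[[r]] <- nodes$name[match(hit[1L], nodes$taxid)]
  }
  if (out[["kingdom"]] == "unclassified") {
    hit <- path[nodes$rank[match(path, nodes$taxid)] == "superkingdom"]
    if (length(hit))
      out[["kingdom"]] <- nodes$name[match(hit[1L], nodes$taxid)]
  }
  out
}

# ---- hit-table fixtures ----------------------------------------------------

makeHit <- function(query, target, taxid, bitscore = 100, evalue = 1e-20,
                    pident = 98, alnlen = 50, searchType = "aa") {
  data.frame(query_id = query, target_id = target, pident = pident,
             alnlen = as.integer(alnlen), mismatch = 1L, gapopen = 0L,
             qstart = 1L, qend = as.integer(alnlen),
             tstart = 1L, tend = as.integer(alnlen),
             evalue = evalue, bitscore = bitscore,
             target_taxid = as.integer(taxid), strand = "+",
             search_type = searchType, stringsAsFactors = FALSE)
}

makeHits <- function(...) {
  do.call(rbind, list(...))
}

# random sequence helpers
randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

mutateSeq <- function(seq, positions) {
  s <- strsplit(seq, "")[[1L]]
  for (p in positions) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1L]
  paste(s, collapse = "")
}

# 30-query tiered-routing fixture covering all routes with a hand-enumerated
# truth table: aa-confirmed viral, aa-refuted nonviral, nt-confirmed viral,
# nt-refuted nonviral, unclassified, plus cross-realm augmented variants
tieredFixture <- function() {
  va <- list(); mk <- list(); vn <- list(); pn <- list()
  truth <- list()
  add <- function(q, verdict, type) truth[[length(truth) + 1L]] <<-
    data.frame(query_id = q, verdict = verdict, search_type = type,
               stringsAsFactors = FALSE)
  for (i in 1:8) {  # aa viral, confirmed
    q <- sprintf("aaV%02d", i)
    va[[q]] <- makeHit(q, "vp1", 16, bitscore = 100)
    mk[[q]] <- makeHit(q, "vp1", 16, bitscore = 95)
    add(q, "viral", "aa")
  }
  for (i in 1:5) {  # aa refuted by dominant bacterial secondary
    q <- sprintf("aaN%02d", i)
    va[[q]] <- makeHit(q, "vp1", 16, bitscore = 80)
    mk[[q]] <- makeHits(makeHit(q, "bp1", 36, bitscore = 140),
                        makeHit(q, "vp1", 16, bitscore = 60))
    add(q, "nonviral", "aa")
  }
  for (i in 1:2) {  # aa viral via cross-realm reversion
    q <- sprintf("aaX%02d", i)
    va[[q]] <- makeHit(q, "vp1", 16, bitscore = 90)
    mk[[q]] <- makeHits(makeHit(q, "vpA", 16, bitscore = 88, evalue = 1e-30),
                        makeHit(q, "vpB", 26, bitscore = 87, evalue = 1e-30))
    add(q, "viral", "aa")
  }
  for (i in 1:6) {  # nt viral, confirmed
    q <- sprintf("ntV%02d", i)
    vn[[q]] <- makeHit(q, "g1", 16, bitscore = 200, searchType = "nt")
    pn[[q]] <- makeHit(q, "g1", 16, bitscore = 190, searchType = "nt")
    add(q, "viral", "nt")
  }
  for (i in 1:4) {  # nt refuted
    q <- sprintf("ntN%02d", i)
    vn[[q]] <- makeHit(q, "g1", 16, bitscore = 120, searchType = "nt")
    pn[[q]] <- makeHits(
      makeHit(q, "bg1", 36, bitscore = 220, searchType = "nt"),
      makeHit(q, "g1", 16, bitscore = 120, searchType = "nt"))
    add(q, "nonviral", "nt")
  }
  for (i in 1:5) {  # no evidence
    q <- sprintf("un%02d", i)
    add(q, "unclassified", NA_character_)
  }
  list(viralAA = do.call(rbind, va), mkAA = do.call(rbind, mk),
       viralNT = do.call(rbind, vn), polyNT = do.call(rbind, pn),
       truth = do.call(rbind, truth))
}
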