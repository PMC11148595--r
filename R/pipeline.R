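# End-to-end mock-community pipeline and the command-line front end.

#' Default mock-community study conditions
#'
#' Four viral genomes (one per broad genome type) and two bacterial genomes,
#' 200 reads per genome at 1\% per-base substitutions, split across two
#' samples -- a reduced analogue of a mixed virus-bacteria benchmark
#' community.
#'
#' @param seed RNG seed (default 42)
#' @param taxdumpDir where the toy taxdump is written
#' @return list: \code{spec} (a [mockCommunitySpec()]), \code{tree},
#'   \code{taxPaths}
#' @export
mockStudyConditions <- function(seed = 42L, taxdumpDir = tempfile("taxdump")) {
  tax <- synthTaxonomy(nViralFamilies = 4L, nBacterialGenera = 2L,
                       seed = seed, dir = taxdumpDir)
  tree <- loadTaxdump(tax$nodes, tax$names)
  viralGenomes <- data.frame(
    label = sprintf("virus%d", 1:4),
    length = rep(2000L, 4L),
    taxid = tax$viral_species,
    genome_type = c("dsDNA", "ssDNA", "ssRNA", "dsRNA"),
    stringsAsFactors = FALSE)
  bacterialGenomes <- data.frame(
    label = sprintf("bact%d", 1:2),
    length = rep(3000L, 2L),
    taxid = tax$bacterial_species,
    stringsAsFactors = FALSE)
  spec <- mockCommunitySpec(viralGenomes, bacterialGenomes,
                            readsPerGenome = 200L, readLength = 150L,
                            substitutionRate = 0.01, seed = seed,
                            nSamples = 2L)
  list(spec = spec, tree = tree, taxPaths = tax)
}

#' Run the full mock-community pipeline
#'
#' Chains every stage on synthetic data: taxonomy + community generation,
#' per-sample greedy clustering into a seqtable, naive alignment of the
#' representatives against the four toy databases, tiered classification,
#' bigtable assembly, and ground-truth evaluation at the requested rank.
#'
#' @param seed RNG seed driving every random choice
#' @param outDir optional directory; when given, seqtable FASTA, bigtable,
#'   tier annotations, per-sample FASTQ, truth and the evaluation report are
#'   written there
#' @param rank evaluation rank (default \code{"family"})
#' @param conditions optional list from [mockStudyConditions()]; built from
#'   \code{seed} when absent
#' @return list with \code{community}, \code{seqtab}, \code{hits},
#'   \code{tiers}, \code{bigtable}, \code{perRead}, \code{eval}, \code{tree}
#' @export
runMockPipeline <- function(seed = 42L, outDir = NULL, rank = "family",
                            conditions = NULL) {
  if (is.null(conditions)) conditions <- mockStudyConditions(seed)
  tree <- conditions$tree
  community <- synthCommunity(conditions$spec)
  dbs <- buildToyDatabases(community)

  tabs <- lapply(names(community$reads), function(s)
    greedyCluster(community$reads[[s]], sampleId = s))
  seqtab <- combineSeqTables(tabs)
  cl <- clusters(seqtab)
  reps <- setNames(cl$sequence, cl$seq_id)

  viralAA <- naiveAlign(reps, dbs$viral_aa$seqs, dbs$viral_aa$taxids, "aa6")
  withViralAA <- unique(viralAA$query_id)
  mkAA <- naiveAlign(reps[withViralAA], dbs$mk_aa$seqs, dbs$mk_aa$taxids,
                     "aa6")
  leftovers <- reps[setdiff(names(reps), withViralAA)]
  viralNT <- naiveAlign(leftovers, dbs$viral_nt$seqs, dbs$viral_nt$taxids,
                        "nt")
  withViralNT <- unique(viralNT$query_id)
  polyNT <- naiveAlign(leftovers[withViralNT], dbs$poly_nt$seqs,
                       dbs$poly_nt$taxids, "nt")

  tiers <- tieredClassify(names(reps), viralAA, mkAA, viralNT, polyNT, tree)
  bigtable <- buildBigtable(seqtab, tiers, tree)
  perRead <- readAnnotations(seqtab, tiers)
  evalRep <- evaluateAnnotations(perRead, community$truth, tree, rank = rank)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeCommunity(community, outDir)
    writeXStringSet(encodeSeqtable(seqtab),
                    file.path(outDir, "seqtable.fasta"))
    writeTierAnnotations(tiers, file.path(outDir, "tier_annotations.tsv"))
    writeBigtable(bigtable, file.path(outDir, "bigtable.tsv"))
    write.table(countTable(seqtab), file.path(outDir, "counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(perRead, file.path(outDir, "read_annotations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeEvalReport(evalRep, file.path(outDir, "eval_report.tsv"))
  }
  list(community = community, seqtab = seqtab,
       hits = list(viral_aa = viralAA, mk_aa = mkAA,
                   viral_nt = viralNT, poly_nt = polyNT),
       tiers = tiers, bigtable = bigtable, perRead = perRead,
       eval = evalRep, tree = tree)
}

#' Rebuild a SeqTable from an encoded seqtable FASTA
#'
#' Representative ids become the full encoded headers; per-sample totals are
#' taken as the per-sample member-count sums (valid when the seqtable covers
#' the whole sample).  Read-level memberships are not recoverable from the
#' FASTA and are left as the representatives themselves.
#'
#' @param path seqtable FASTA path
#' @return a [SeqTable-class]
#' @export
seqTableFromFasta <- function(path) {
  dec <- decodeSeqtable(path)
  hdr <- names(readDNAStringSet(path))
  cl <- data.frame(seq_id = hdr, sample_id = dec$sample_id,
                   cluster_index = dec$cluster_index,
                   member_count = dec$member_count,
                   percent_of_sample = dec$percent_of_sample,
                   sequence = dec$sequence, stringsAsFactors = FALSE)
  tot <- tapply(cl$member_count, cl$sample_id, sum)
  members <- data.frame(read_id = cl$seq_id, seq_id = cl$seq_id,
                        sample_id = cl$sample_id, stringsAsFactors = FALSE)
  new("SeqTable", clusters = cl, members = members,
      sampleTotals = setNames(as.integer(tot), names(tot)))
}
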