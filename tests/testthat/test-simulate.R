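# Synthetic taxonomy/community generators and the naive aligner.

test_that("synthetic taxdumps are deterministic and pass tree invariants", {
  d1 <- tempfile(); d2 <- tempfile()
  synthTaxonomy(3, 5, seed = 7, dir = d1)
  synthTaxonomy(3, 5, seed = 7, dir = d2)
  expect_identical(readLines(file.path(d1, "nodes.dmp")),
                   readLines(file.path(d2, "nodes.dmp")))
  expect_identical(readLines(file.path(d1, "names.dmp")),
                   readLines(file.path(d2, "names.dmp")))
  tree <- loadTaxdump(file.path(d1, "nodes.dmp"), file.path(d1, "names.dmp"))
  expect_s4_class(tree, "TaxonomyTree")  # validity ran at construction
  # every node walks to the root; viral species reach the virus root
  for (t in taxIds(tree)) expect_equal(tail(rootPath(tree, t), 1L), 1L)
  tx <- synthTaxonomy(2, 1, seed = 7, dir = tempfile())
  tree2 <- loadTaxdump(tx$nodes, tx$names)
  for (v in tx$viral_species) expect_true(isViral(tree2, v))
  for (b in tx$bacterial_species) expect_false(isViral(tree2, b))
  # a viral species has a full 7-slot lineage via superkingdom fallback
  lin <- lineage7(tree2, tx$viral_species[1])
  expect_equal(unname(lin["kingdom"]), "Viruses")
  expect_true(all(lin != "unclassified"))
})

test_that("error-free reads are exact substrings of their source genome", {
  tx <- synthTaxonomy(2, 1, seed = 3, dir = tempfile())
  spec <- mockCommunitySpec(
    viralGenomes = data.frame(label = c("v1", "v2"), length = 500L,
                              taxid = tx$viral_species,
                              genome_type = "dsDNA",
                              stringsAsFactors = FALSE),
    bacterialGenomes = data.frame(label = "b1", length = 600L,
                                  taxid = tx$bacterial_species,
                                  stringsAsFactors = FALSE),
    readsPerGenome = 20L, readLength = 100L, substitutionRate = 0,
    seed = 5L, nSamples = 1L)
  com <- synthCommunity(spec)
  for (i in seq_len(nrow(com$truth))) {
    tr <- com$truth[i, ]
    read <- com$reads[[tr$sample_id]][[tr$read_id]]
    g <- com$genomes[[tr$label]]
    hit <- grepl(read, g, fixed = TRUE) ||
      grepl(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(read))), g, fixed = TRUE)
    expect_true(hit, label = tr$read_id)
  }
})

test_that("community generation is bit-reproducible under a fixed seed", {
  tx <- synthTaxonomy(1, 1, seed = 3, dir = tempfile())
  spec <- mockCommunitySpec(
    viralGenomes = data.frame(label = "v1", length = 400L,
                              taxid = tx$viral_species,
                              genome_type = "ssRNA",
                              stringsAsFactors = FALSE),
    bacterialGenomes = data.frame(label = "b1", length = 400L,
                                  taxid = tx$bacterial_species,
                                  stringsAsFactors = FALSE),
    readsPerGenome = 30L, readLength = 80L, substitutionRate = 0.02,
    seed = 11L, nSamples = 2L)
  c1 <- synthCommunity(spec)
  c2 <- synthCommunity(spec)
  expect_identical(c1, c2)
  d1 <- tempfile(); d2 <- tempfile()
  writeCommunity(c1, d1); writeCommunity(c2, d2)
  expect_identical(readLines(file.path(d1, "sample1.fastq")),
                   readLines(file.path(d2, "sample1.fastq")))
  # FASTQ reader inverts the writer
  back <- readFastq(file.path(d1, "sample1.fastq"))
  expect_identical(back, c1$reads$sample1)
  # a too-long read length is an argument error
  expect_error(synthCommunity(mockCommunitySpec(
    viralGenomes = data.frame(label = "v1", length = 50L,
                              taxid = tx$viral_species,
                              genome_type = "ssRNA",
                              stringsAsFactors = FALSE),
    bacterialGenomes = data.frame(label = "b1", length = 400L,
                                  taxid = tx$bacterial_species,
                                  stringsAsFactors = FALSE),
    readLength = 80L)), "readLength")
})

test_that("substitution counts match the binomial error model", {
  tx <- synthTaxonomy(1, 1, seed = 3, dir = tempfile())
  spec <- mockCommunitySpec(
    viralGenomes = data.frame(label = "v1", length = 10000L,
                              taxid = tx$viral_species,
                              genome_type = "dsDNA",
                              stringsAsFactors = FALSE),
    bacterialGenomes = data.frame(label = "b1", length = 200L,
                                  taxid = tx$bacterial_species,
                                  stringsAsFactors = FALSE),
    readsPerGenome = 1000L, readLength = 150L, substitutionRate = 0.01,
    seed = 17L, nSamples = 1L)
  com <- synthCommunity(spec)
  truth <- com$truth[com$truth$label == "v1", ]
  g <- com$genomes[["v1"]]
  nsub <- vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    orig <- substring(g, tr$start, tr$start + 149L)
    read <- com$reads$sample1[[tr$read_id]]
    if (tr$strand == "-")
      read <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(read)))
    sum(strsplit(orig, "")[[1L]] != strsplit(read, "")[[1L]])
  }, numeric(1L))
  n <- length(nsub) * 150
  expect_lt(abs(mean(nsub) - 150 * 0.01),
            3 * sqrt(150 * 0.01 * 0.99 / length(nsub)))
})

test_that("the naive aligner recovers exact substrings at full identity", {
  set.seed(157)
  targets <- c(g1 = randSeq(2000), g2 = randSeq(2000))
  taxids <- c(g1 = 16L, g2 = 36L)
  q <- substring(targets[["g1"]], 501, 650)
  hits <- naiveAlign(c(q1 = q), targets, taxids, "nt")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$target_id, "g1")
  expect_equal(hits$pident, 100)
  expect_equal(hits$alnlen, 150L)
  expect_equal(c(hits$tstart, hits$tend), c(501L, 650L))
  expect_equal(hits$target_taxid, 16L)
  # reverse-complement query maps to the minus strand, same locus
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  hrc <- naiveAlign(c(q1 = rc), targets, taxids, "nt")
  expect_equal(hrc$strand, "-")
  expect_equal(c(hrc$tstart, hrc$tend), c(501L, 650L))
})

test_that("random queries hit nothing at default thresholds", {
  set.seed(163)
  targets <- c(g1 = randSeq(3000))
  qs <- setNames(replicate(20, randSeq(150)), sprintf("q%02d", 1:20))
  hits <- naiveAlign(qs, targets, c(g1 = 16L), "nt")
  expect_equal(nrow(hits), 0L)
})

test_that("planted 95%-identity queries come back within a point", {
  set.seed(167)
  targets <- c(g1 = randSeq(4000))
  for (i in 1:5) {
    start <- 700 * i
    frag <- substring(targets[["g1"]], start, start + 149)
    q <- mutateSeq(frag, sample.int(150, 8))  # 142/150 ~ 94.7%
    hits <- naiveAlign(setNames(c(q), "q"), targets, c(g1 = 16L), "nt")
    expect_equal(nrow(hits), 1L)
    expect_lt(abs(hits$pident - 100 * 142 / 150), 1)
  }
})

test_that("six-frame translated search finds protein-level hits", {
  set.seed(173)
  # codon-structured target so its frame-0 protein is stop-free
  tx <- synthTaxonomy(1, 1, seed = 3, dir = tempfile())
  spec <- mockCommunitySpec(
    viralGenomes = data.frame(label = "v1", length = 900L,
                              taxid = tx$viral_species,
                              genome_type = "dsDNA",
                              stringsAsFactors = FALSE),
    bacterialGenomes = data.frame(label = "b1", length = 300L,
                                  taxid = tx$bacterial_species,
                                  stringsAsFactors = FALSE),
    readsPerGenome = 2L, readLength = 120L, substitutionRate = 0,
    seed = 19L, nSamples = 1L)
  com <- synthCommunity(spec)
  dbs <- buildToyDatabases(com)
  # a read from any offset/strand hits the frame-0 protein of its genome
  reads <- com$reads$sample1[com$truth$label == "v1"]
  hits <- naiveAlign(reads, dbs$viral_aa$seqs, dbs$viral_aa$taxids, "aa6")
  expect_setequal(unique(hits$query_id), names(reads))
  expect_true(all(hits$pident > 95))
  expect_equal(unique(hits$target_id), "v1_p1")
})
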