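# Contig abundance tables, unmapped pooling, joins, SAM ingestion.

mkMapping <- function(read, sample, contig, start = 0L, end = 100L,
                      mapq = 60L, mapped = TRUE) {
  data.frame(read_id = read, sample_id = sample,
             contig_id = if (mapped) contig else NA_character_,
             start = if (mapped) as.integer(start) else NA_integer_,
             end = if (mapped) as.integer(end) else NA_integer_,
             mapq = if (mapped) as.integer(mapq) else NA_integer_,
             is_mapped = mapped, stringsAsFactors = FALSE)
}

test_that("unmapped pooling returns exactly the complement, with provenance", {
  allMapped <- do.call(rbind, lapply(1:5, function(i)
    mkMapping(sprintf("r%d", i), "s1", "c1")))
  expect_equal(nrow(poolUnmapped(allMapped)), 0L)
  noneMapped <- do.call(rbind, lapply(1:5, function(i)
    mkMapping(sprintf("r%d", i), "s1", "c1", mapped = FALSE)))
  expect_equal(nrow(poolUnmapped(noneMapped)), 5L)
  # planted mix across samples
  set.seed(127)
  rows <- lapply(1:500, function(i) {
    mkMapping(sprintf("r%03d", i), sprintf("s%d", 1 + i %% 3), "c1",
              mapped = i > 120)
  })
  pool <- poolUnmapped(do.call(rbind, rows))
  expect_equal(nrow(pool), 120L)
  expect_setequal(pool$read_id, sprintf("r%03d", 1:120))
  expect_equal(sort(unique(pool$sample_id)), c("s1", "s2", "s3"))
  # a read both mapped and unmapped in one sample is an integrity error
  dup <- rbind(mkMapping("rX", "s1", "c1"),
               mkMapping("rX", "s1", "c1", mapped = FALSE))
  expect_error(poolUnmapped(dup), "integrity")
})

test_that("the two-contig worked example yields equal SPM rates", {
  contigs <- c(cA = randSeq(100), cB = randSeq(300))
  rows <- c(lapply(1:10, function(i)
    mkMapping(sprintf("a%d", i), "s1", "cA", 0, 50)),
    lapply(1:30, function(i)
      mkMapping(sprintf("b%d", i), "s1", "cB", 0, 50)))
  ab <- contigAbundance(do.call(rbind, rows), contigs)
  expect_equal(sort(ab$spm), c(5e5, 5e5))
  expect_equal(sum(ab$spm), 1e6, tolerance = 1e-6)
  # RPKM by hand: r=10, R=40, l=100 -> 10 * 1e9 / (40*100)
  expect_equal(ab$rpkm[ab$contig_id == "cA"], 10 * 1e9 / (40 * 100))
})

test_that("SPM sums to one million per sample; ratios are scale-invariant", {
  set.seed(131)
  contigs <- setNames(replicate(4, randSeq(sample(200:800, 1))),
                      sprintf("c%d", 1:4))
  rows <- do.call(rbind, lapply(1:200, function(i)
    mkMapping(sprintf("r%03d", i), sprintf("s%d", 1 + i %% 2),
              sample(names(contigs), 1), 0, 80)))
  ab <- contigAbundance(rows, contigs)
  for (s in unique(ab$sample_id))
    expect_equal(sum(ab$spm[ab$sample_id == s]), 1e6, tolerance = 1e-6)
  # doubling every count leaves rpkm and spm unchanged, doubles raw
  rows2 <- rbind(rows, transform(rows, read_id = paste0(read_id, "_dup")))
  ab2 <- contigAbundance(rows2, contigs)
  key <- paste(ab$contig_id, ab$sample_id)
  key2 <- paste(ab2$contig_id, ab2$sample_id)
  idx <- match(key, key2)
  expect_equal(ab2$raw_count[idx], 2L * ab$raw_count)
  expect_equal(ab2$spm[idx], ab$spm, tolerance = 1e-9)
  expect_equal(ab2$rpkm[idx], ab$rpkm, tolerance = 1e-9)
})

test_that("coverage and GC come from interval unions and ACGT content", {
  contigs <- c(c1 = paste0(strrep("A", 50), strrep("G", 50)))
  rows <- rbind(mkMapping("r1", "s1", "c1", 0, 30),
                mkMapping("r2", "s1", "c1", 20, 60))
  ab <- contigAbundance(rows, contigs)
  expect_equal(ab$coverage_percent, 60)  # union [0,60)
  expect_equal(ab$gc_fraction, 0.5)
  expect_equal(ab$length, 100L)
  # fragment collapsing: mates named /1 /2 count once for FPKM
  rowsPE <- rbind(mkMapping("p1/1", "s1", "c1", 0, 30),
                  mkMapping("p1/2", "s1", "c1", 40, 70))
  abPE <- contigAbundance(rowsPE, contigs)
  expect_equal(abPE$raw_count, 2L)
  expect_equal(abPE$fpkm, 1 * 1e9 / (1 * 100))  # one fragment
  # unknown contig is an integrity error
  expect_error(contigAbundance(mkMapping("r", "s1", "ghost"), contigs),
               "integrity")
})

test_that("count conservation: mapped plus pooled equals the sample total", {
  set.seed(137)
  contigs <- c(c1 = randSeq(500), c2 = randSeq(400))
  rows <- do.call(rbind, lapply(1:300, function(i)
    mkMapping(sprintf("r%03d", i), "s1", sample(names(contigs), 1),
              0, 90, mapped = i %% 4 != 0)))
  ab <- contigAbundance(rows, contigs)
  pool <- poolUnmapped(rows)
  expect_equal(sum(ab$raw_count) + nrow(pool), 300L)
})

test_that("contigSeqTable joins row-for-row with sentinel fallback", {
  tree <- toyTree()
  reads <- setNames(replicate(3, randSeq(100)), c("q1", "q2", "q3"))
  st <- greedyCluster(reads, sampleId = "s1")
  tiers <- tieredClassify(clusters(st)$seq_id,
                          makeHit(clusters(st)$seq_id[1], "vp1", 16),
                          NULL, NULL, NULL, tree)
  bt <- buildBigtable(st, tiers, tree)
  rows <- rbind(mkMapping(clusters(st)$seq_id[1], "s1", "c1", 0, 100),
                mkMapping(clusters(st)$seq_id[2], "s1", "c1", 50, 150),
                mkMapping("absent_rep", "s1", "c2", 0, 100),
                mkMapping("un", "s1", "c1", mapped = FALSE))
  cst <- contigSeqTable(rows, bt)
  expect_equal(nrow(cst), 3L)  # mapped pairs only
  expect_equal(cst$family[1], "Microviridae")
  expect_equal(cst$family[cst$read_id == "absent_rep"], "unclassified")
  expect_equal(cst$verdict[cst$read_id == "absent_rep"], "unclassified")
  # per-contig family tallies equal a brute-force group-by
  tally <- table(cst$contig_id, cst$family)
  expect_equal(unname(tally["c1", "Microviridae"]), 1L)
})

test_that("contig annotation follows the augmented-LCA and virus-root rule", {
  tree <- toyTree()
  # homogeneous viral evidence -> that species
  h1 <- makeHits(makeHit("ctgA", "g1", 16, bitscore = 200, searchType = "nt"),
                 makeHit("ctgA", "g2", 16, bitscore = 190, searchType = "nt"))
  ann <- contigAnnotate("ctgA", h1, tree)
  expect_equal(ann$taxid, 16L)
  expect_equal(ann$verdict, "viral")
  expect_equal(ann$family, "Microviridae")
  # strong bacterial + weak viral -> bacterial lineage, nonviral
  h2 <- makeHits(
    makeHit("ctgB", "bg", 36, bitscore = 300, evalue = 1e-60,
            searchType = "nt"),
    makeHit("ctgB", "g1", 16, bitscore = 80, evalue = 1e-10,
            searchType = "nt"))
  ann2 <- contigAnnotate("ctgB", h2, tree)
  expect_equal(ann2$verdict, "nonviral")
  expect_equal(ann2$family, "BacFamily")
  # no hits -> sentinel
  ann3 <- contigAnnotate("ctgC", h1[0, ], tree)
  expect_equal(ann3$verdict, "unclassified")
  expect_equal(ann3$taxid, taxonomySentinel()$taxid)
})

test_that("the SAM reader keeps primary alignments and CIGAR spans", {
  p <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:c1\tLN:1000",
    "r1\t0\tc1\t101\t60\t50M\t*\t0\t0\t*\t*",
    "r2\t16\tc1\t201\t30\t20M5D25M\t*\t0\t0\t*\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r1\t256\tc1\t301\t0\t50M\t*\t0\t0\t*\t*"), p)
  m <- readMappingsSam(p, "s1")
  expect_equal(nrow(m), 3L)  # secondary dropped
  expect_equal(m$start[m$read_id == "r1"], 100L)
  expect_equal(m$end[m$read_id == "r1"], 150L)
  expect_equal(m$end[m$read_id == "r2"] - m$start[m$read_id == "r2"], 50L)
  expect_false(m$is_mapped[m$read_id == "r3"])
  # TSV round trip
  pt <- tempfile(fileext = ".tsv")
  write.table(m, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readMappingsTsv(pt), m)
})
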