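# Shred / map / mask recipe for viral-aware host masking.

test_that("shred windows enumerate at step 55 with end truncation", {
  f85 <- shred("v", randSeq(85))
  expect_equal(nrow(f85), 1L)
  expect_equal(c(f85$start, f85$end), c(0L, 85L))

  f140 <- shred("v", randSeq(140))
  expect_equal(f140$start, c(0L, 55L))
  expect_equal(f140$end, c(85L, 140L))

  f200 <- shred("v", randSeq(200))
  expect_equal(f200$start, c(0L, 55L, 110L, 165L))
  expect_equal(f200$end, c(85L, 140L, 195L, 200L))

  # shorter than one window -> single full-length fragment
  f40 <- shred("v", randSeq(40))
  expect_equal(nrow(f40), 1L)
  expect_equal(f40$end, 40L)

  expect_error(shred("v", ""), "empty")
  expect_error(shred("v", "ACGT", fragmentLength = 10, overlap = 10),
               "overlap")
})

test_that("every base is covered and fragments match their coordinates", {
  set.seed(97)
  for (len in c(85L, 99L, 140L, 200L, 1000L)) {
    s <- randSeq(len)
    fr <- shred("v", s)
    covered <- logical(len)
    for (i in seq_len(nrow(fr))) {
      covered[(fr$start[i] + 1L):fr$end[i]] <- TRUE
      expect_equal(fr$sequence[i],
                   substring(s, fr$start[i] + 1L, fr$end[i]))
      expect_equal(nchar(fr$sequence[i]), fr$end[i] - fr$start[i])
    }
    expect_true(all(covered))
  }
})

test_that("exact fragments map to their planted location", {
  set.seed(101)
  host <- c(chr1 = randSeq(3000))
  frag <- substring(host[["chr1"]], 501, 585)
  iv <- mapFragments(data.frame(source_id = "v", start = 0L, end = 85L,
                                sequence = frag, stringsAsFactors = FALSE),
                     host)
  expect_true(nrow(iv) >= 1L)
  expect_true(any(iv$start == 500L & iv$end == 585L))
})

test_that("the identity gate rejects diverged fragments", {
  set.seed(103)
  host <- c(chr1 = randSeq(3000))
  frag <- substring(host[["chr1"]], 1001, 1085)
  bad <- mutateSeq(frag, seq(5, 85, by = 8))  # 11 substitutions, ~87%
  iv <- mapFragments(data.frame(source_id = "v", start = 0L, end = 85L,
                                sequence = bad, stringsAsFactors = FALSE),
                     host)
  expect_true(!nrow(iv) || !any(iv$start == 1000L & iv$end == 1085L))
})

test_that("planted fragments are recovered on both strands within thresholds", {
  set.seed(107)
  host <- c(chr1 = randSeq(10000))
  plants <- list()
  fr <- list()
  for (i in 1:20) {
    start <- 400 * i + 1
    frag <- substring(host[["chr1"]], start, start + 84)
    edits <- (i - 1) %% 4  # 0-3 substitutions
    if (edits) frag <- mutateSeq(frag, sample.int(85, edits))
    if (i %% 5 == 0) frag <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(frag)))
    plants[[i]] <- c(start - 1, start + 84, edits)
    fr[[i]] <- data.frame(source_id = sprintf("v%d", i), start = 0L,
                          end = 85L, sequence = frag, stringsAsFactors = FALSE)
  }
  iv <- mapFragments(do.call(rbind, fr), host)
  for (i in 1:20) {
    p <- plants[[i]]
    ident <- (85 - p[3]) / 85
    found <- any(iv$start <= p[1] + 2 & iv$end >= p[2] - 2)
    if (ident >= 0.90) expect_true(found, label = sprintf("plant %d", i))
  }
})

test_that("interval masking is a union, idempotent, and length-conserving", {
  host <- c(c1 = strrep("ACGT", 25))
  iv <- data.frame(contig_id = "c1", start = c(10L, 15L), end = c(20L, 25L),
                   provenance = "external", stringsAsFactors = FALSE)
  masked <- maskIntervals(host, iv)
  s <- strsplit(masked[["c1"]], "")[[1L]]
  expect_equal(sum(s == "N"), 15L)  # union of [10,20) and [15,25)
  expect_equal(which(s == "N"), 11:25)
  expect_equal(nchar(masked), nchar(host))
  # untouched positions byte-identical
  expect_equal(s[-(11:25)], strsplit(host[["c1"]], "")[[1L]][-(11:25)])
  # idempotent
  expect_equal(maskIntervals(masked, iv), masked)
  # empty interval list is the identity
  expect_equal(maskIntervals(host, iv[0, ]), host)
  # out-of-bounds intervals name the contig
  bad <- data.frame(contig_id = "c1", start = 90L, end = 120L,
                    provenance = "external", stringsAsFactors = FALSE)
  expect_error(maskIntervals(host, bad), "c1")
  unknown <- data.frame(contig_id = "nope", start = 0L, end = 5L,
                        provenance = "external", stringsAsFactors = FALSE)
  expect_error(maskIntervals(host, unknown), "unknown contig")
})

test_that("masked-base counts match a per-position membership oracle", {
  set.seed(109)
  host <- c(c1 = randSeq(2000), c2 = randSeq(1500))
  iv <- do.call(rbind, lapply(1:50, function(i) {
    ci <- sample(c("c1", "c2"), 1)
    len <- if (ci == "c1") 2000L else 1500L
    s <- sample.int(len - 60L, 1) - 1L
    data.frame(contig_id = ci, start = s, end = s + sample.int(50, 1),
               provenance = "external", stringsAsFactors = FALSE)
  }))
  masked <- maskIntervals(host, iv)
  for (ci in names(host)) {
    inMask <- logical(nchar(host[[ci]]))
    sub <- iv[iv$contig_id == ci, ]
    for (r in seq_len(nrow(sub)))
      inMask[(sub$start[r] + 1L):sub$end[r]] <- TRUE
    expect_equal(sum(strsplit(masked[[ci]], "")[[1L]] == "N"), sum(inMask))
  }
})

test_that("after the full recipe, viral fragments find nothing unmasked", {
  set.seed(113)
  host <- c(chr1 = randSeq(8000))
  viral <- c(v1 = randSeq(400))
  # plant two viral stretches into the host
  h <- host[["chr1"]]
  substrAssign <- function(s, at, val)
    paste0(substring(s, 1, at - 1), val, substring(s, at + nchar(val)))
  h <- substrAssign(h, 2001, substring(viral[["v1"]], 1, 200))
  h <- substrAssign(h, 6001, substring(viral[["v1"]], 201, 400))
  host[["chr1"]] <- h
  res <- maskHostGenome(host, viral)
  expect_gt(nrow(res$intervals), 0)
  # re-mapping the same fragments on the masked host yields no interval
  # outside the already-masked union
  again <- mapFragments(res$fragments, res$masked)
  expect_equal(nrow(again), 0L)
  expect_equal(nchar(res$masked), nchar(host))
})
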