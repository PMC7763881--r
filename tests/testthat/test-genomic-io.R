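test_that("GTF transcripts use inclusive coordinates and spliced lengths", {
  ts <- tsFromList(list(
    list(id = "t1", chr = "chr1", strand = "+",
         exons = rbind(c(100, 200))),
    list(id = "t2", chr = "chr1", strand = "+",
         exons = rbind(c(100, 200), c(300, 400)))))
  f <- tempfile(fileext = ".gtf")
  writeGtf(ts, f)
  back <- readGtf(f)
  expect_equal(unname(txLengths(back)["t1"]), 101)
  expect_equal(unname(txLengths(back)["t2"]), 202)
  sp <- txSpans(back)["t2"]
  expect_equal(c(GenomicRanges::start(sp), GenomicRanges::end(sp)),
               c(100, 400))
})

test_that("GTF round-trip preserves a 50-transcript synthetic annotation", {
  set.seed(5)
  txs <- lapply(1:50, function(i) {
    chr <- sample(c("H01", "C01"), 1)
    nEx <- sample(1:4, 1)
    starts <- cumsum(sample(400:900, nEx)) + i * 5000
    ends <- starts + sample(80:300, nEx, replace = TRUE)
    list(id = sprintf("tx%02d", i), gene = sprintf("g%02d", (i + 1) %/% 2),
         chr = chr, strand = sample(c("+", "-"), 1),
         exons = cbind(starts, ends))
  })
  ts <- tsFromList(txs)
  f <- tempfile(fileext = ".gtf")
  writeGtf(ts, f)
  back <- readGtf(f)
  expect_setequal(txIds(back), txIds(ts))
  back <- back[txIds(ts)]
  expect_identical(geneIds(back), geneIds(ts))
  expect_equal(as.data.frame(unlist(exonRanges(back), use.names = FALSE)),
               as.data.frame(unlist(exonRanges(ts), use.names = FALSE)))
})

test_that("GTF reader rejects records without transcript_id and mixed strands", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t10\t50\t.\t+\t.\tgene_id "g1";'), f)
  expect_error(readGtf(f), "transcript_id")
  writeLines(c(
    'chr1\tsrc\texon\t10\t50\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t100\t150\t.\t-\t.\tgene_id "g1"; transcript_id "t1";'),
    f)
  expect_error(readGtf(f), "mixed strands")
})

test_that("BED intervals convert to 1-based inclusive and round-trip", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200", "chr1\t0\t1"), f)
  gr <- readBed(f)
  expect_equal(GenomicRanges::start(gr), c(100, 1))
  expect_equal(GenomicRanges::end(gr), c(200, 1))
  expect_equal(GenomicRanges::width(gr), c(101, 1))

  set.seed(9)
  starts <- sample.int(1e6, 1000)
  gr2 <- GenomicRanges::GRanges("H01",
    IRanges::IRanges(starts, starts + sample.int(5000, 1000)))
  f2 <- tempfile(fileext = ".bed")
  writeBed(gr2, f2)
  back <- readBed(f2)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr2))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr2))
})

test_that("overlapBp matches its definition, boundaries and symmetry", {
  g <- function(chr, s, e) GenomicRanges::GRanges(chr, IRanges::IRanges(s, e))
  expect_equal(overlapBp(g("c1", 100, 199), g("c1", 150, 249)), 50L)
  expect_equal(overlapBp(g("c1", 100, 199), g("c1", 200, 300)), 0L)
  expect_equal(overlapBp(g("c1", 100, 199), g("c2", 100, 199)), 0L)
  set.seed(3)
  a <- g(sample(c("c1", "c2"), 200, TRUE), s <- sample.int(1e4, 200),
         s + sample.int(500, 200))
  b <- g(sample(c("c1", "c2"), 200, TRUE), s2 <- sample.int(1e4, 200),
         s2 + sample.int(500, 200))
  expect_identical(overlapBp(a, b), overlapBp(b, a))
})

test_that("overlap queries through the interval index equal an all-pairs scan", {
  set.seed(21)
  n <- 1000
  q <- GenomicRanges::GRanges(sample(c("c1", "c2"), n, TRUE),
    IRanges::IRanges(s <- sample.int(2e5, n), s + sample.int(2000, n)))
  s2 <- sample.int(2e5, n)
  subj <- GenomicRanges::GRanges(sample(c("c1", "c2"), n, TRUE),
    IRanges::IRanges(s2, s2 + sample.int(2000, n)))
  hits <- GenomicRanges::findOverlaps(q, subj, ignore.strand = TRUE)
  got <- sort(paste(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits)))
  # brute force via the overlap arithmetic itself
  want <- character()
  qc <- as.character(GenomicRanges::seqnames(q))
  sc <- as.character(GenomicRanges::seqnames(subj))
  for (i in seq_len(n)) {
    ov <- qc[i] == sc &
      GenomicRanges::start(q)[i] <= GenomicRanges::end(subj) &
      GenomicRanges::end(q)[i] >= GenomicRanges::start(subj)
    if (any(ov)) want <- c(want, paste(i, which(ov)))
  }
  expect_identical(got, sort(want))
})

test_that("spliced sequence extraction respects exon order and strand", {
  genome <- Biostrings::DNAStringSet(c(c1 = "ACGTACGTACGTACGTACGT"))
  ts <- tsFromList(list(
    list(id = "p", chr = "c1", strand = "+",
         exons = rbind(c(1, 4), c(9, 12))),
    list(id = "m", chr = "c1", strand = "-",
         exons = rbind(c(1, 4), c(9, 12)))))
  sq <- extractTxSeqs(genome, ts)
  expect_equal(as.character(sq[["p"]]), "ACGTACGT")
  expect_equal(as.character(sq[["m"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("ACGTACGT"))))
})
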