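pcgRef <- tsFromList(list(
  list(id = "p1", gene = "gA", chr = "c1", strand = "+",
       exons = rbind(c(1000, 1500), c(3000, 3500))),
  list(id = "p2", gene = "gB", chr = "c1", strand = "-",
       exons = rbind(c(20000, 20800)))))

test_that("positional categories follow the precedence rules", {
  lnc <- tsFromList(list(
    list(id = "s", chr = "c1", strand = "+",        # sense: same-strand exon
         exons = rbind(c(1400, 1700), c(2000, 2200))),
    list(id = "as", chr = "c1", strand = "+",       # antisense vs gB (-)
         exons = rbind(c(20100, 20400))),
    list(id = "in", chr = "c1", strand = "-",       # inside gA intron 1
         exons = rbind(c(1700, 1900), c(2300, 2600))),
    list(id = "ig", chr = "c1", strand = "+",       # 50 kb from anything
         exons = rbind(c(70000, 70400)))))
  got <- classifyPosition(lnc, pcgRef)
  expect_equal(as.character(got$category),
               c("sense", "antisense", "intronic", "intergenic"))
  expect_equal(got["s", "related_pcg"], "gA")
  # sense beats antisense when both overlaps exist
  both <- tsFromList(list(
    list(id = "b", chr = "c1", strand = "-",
         exons = rbind(c(1400, 1600), c(20000, 20100)))))
  expect_equal(as.character(classifyPosition(both, pcgRef)$category),
               "sense")
})

test_that("category counts partition the identified set", {
  ss <- getSmallSim()
  truth <- ss$sim$truth
  lnc <- ss$sim$assembled[truth$tx_id[truth$is_lncRNA & !truth$is_isoform]]
  pos <- classifyPosition(lnc, ss$sim$reference)
  tab <- table(pos$category)
  expect_equal(sum(tab), length(lnc))
  # and matches the planted categories
  expect_equal(as.character(pos$category),
               as.character(truth[txIds(lnc), "category"]))
})

test_that("TE-derived flags obey the 10 bp threshold", {
  lnc <- tsFromList(list(
    list(id = "a", chr = "c1", strand = "+",
         exons = rbind(c(1000, 1400))),
    list(id = "b", chr = "c1", strand = "+",
         exons = rbind(c(5000, 5400))),
    list(id = "c", chr = "c2", strand = "+",
         exons = rbind(c(100, 500)))))
  te <- GenomicRanges::GRanges(c("c1", "c1"),
                               IRanges::IRanges(c(991, 4901),
                                                c(1009, 5008)))
  fl <- flagTeDerived(lnc, te)
  expect_equal(fl$te_overlap_bp, c(10L, 9L, 0L))
  expect_identical(fl$te_derived, c(TRUE, FALSE, FALSE))
})

test_that("subgenome assignment keys on the chromosome name", {
  got <- assignSubgenome(c("H03", "C07", "scaffold_12", "H1", "Chr1"))
  expect_equal(as.character(got),
               c("subH", "subC", "unplaced", "subH", "unplaced"))
})

test_that("collinear chaining keeps ordered anchors and rejects shuffled ones", {
  set.seed(12)
  mkseq <- function() paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                            collapse = "")
  hseqs <- vapply(1:6, function(i) mkseq(), "")
  cseqs <- vapply(hseqs, function(s) lncPloidy:::mutateSeq(s, 0.03), "",
                  USE.NAMES = FALSE)
  pos <- seq(10000, 60000, by = 10000)
  spans <- GenomicRanges::GRanges(rep(c("H01", "C01"), each = 6),
                                  IRanges::IRanges(c(pos, pos),
                                                   c(pos, pos) + 399))
  names(spans) <- c(paste0("h", 1:6), paste0("c", 1:6))
  seqs <- Biostrings::DNAStringSet(c(hseqs, cseqs))
  names(seqs) <- names(spans)
  hp <- findHomoeologPairs(spans, seqs)
  expect_equal(nrow(hp$pairs), 6L)
  expect_equal(nrow(hp$blocks), 1L)
  expect_setequal(paste(hp$pairs$h_gene, hp$pairs$c_gene),
                  paste(paste0("h", 1:6), paste0("c", 1:6)))
  # shuffling the C positions destroys every monotone run
  spans2 <- spans
  shuf <- c(3, 6, 1, 5, 2, 4)
  IRanges::ranges(spans2)[7:12] <- IRanges::IRanges(pos[shuf],
                                                    pos[shuf] + 399)
  hp2 <- findHomoeologPairs(spans2, seqs)
  expect_equal(nrow(hp2$blocks), 0L)
  # a reciprocal best match on a chromosome below the anchor minimum is
  # dropped with its block
  hp3 <- findHomoeologPairs(spans[c(1:3, 7:9)], seqs[c(1:3, 7:9)])
  expect_equal(nrow(hp3$pairs), 0L)
})

test_that("density bins count features per 100 kb window", {
  lncSp <- GenomicRanges::GRanges("H01", IRanges::IRanges(c(1e4, 2.5e5),
                                                          c(1.1e4, 2.6e5)))
  pcgSp <- GenomicRanges::GRanges("H01", IRanges::IRanges(5e4, 6e4))
  te <- GenomicRanges::GRanges("H01", IRanges::IRanges(1.5e5, 1.6e5))
  dens <- binDensity(lncSp, pcgSp, te, c(H01 = 3e5))
  expect_equal(nrow(dens), 3L)
  expect_equal(dens$n_lncrna, c(1, 0, 1))
  expect_equal(dens$n_gene, c(1, 0, 0))
  expect_equal(dens$n_te, c(0, 1, 0))
})
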