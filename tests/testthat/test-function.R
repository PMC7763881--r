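test_that("cis-target windows are span-to-span with signed distances", {
  lnc <- GenomicRanges::GRanges("c1", IRanges::IRanges(500000, 501000))
  names(lnc) <- "L1"
  pcg <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(c(551000, 651001, 500400, 420000, 1),
                     c(552000, 652001, 500600, 450000, 900)))
  names(pcg) <- paste0("P", 1:5)
  tg <- findCisTargets(lnc, pcg, window = 1e5)
  expect_setequal(tg$pcg, c("P1", "P3", "P4"))   # 50 kb in, 150 kb out
  expect_equal(tg$distance[tg$pcg == "P1"], 49999)
  expect_equal(tg$distance[tg$pcg == "P3"], 0)
  expect_equal(tg$relation[tg$pcg == "P3"], "overlapping")
  expect_equal(tg$distance[tg$pcg == "P4"], -49999)
  # chromosome edge: window truncates silently
  edge <- GenomicRanges::GRanges("c1", IRanges::IRanges(10, 400))
  names(edge) <- "L2"
  expect_silent(findCisTargets(edge, pcg, window = 1e5))
  # symmetry: P is a target of L iff L lies in P's window
  set.seed(23)
  a <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(s <- sample.int(3e6, 150), s + 500))
  names(a) <- paste0("a", 1:150)
  b <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(s2 <- sample.int(3e6, 150), s2 + 800))
  names(b) <- paste0("b", 1:150)
  ab <- findCisTargets(a, b)
  ba <- findCisTargets(b, a)
  expect_setequal(paste(ab$lncrna_gene, ab$pcg),
                  paste(ba$pcg, ba$lncrna_gene))
})

test_that("pair correlation uses the t-test on n-2 df with the n=12 floor", {
  tpm <- matrix(rlnorm(12 * 3, 4, 1), 3, 12)
  rownames(tpm) <- c("L", "Psame", "Pneg")
  tpm["Psame", ] <- tpm["L", ]
  tpm["Pneg", ] <- 2^(1 + max(log2(tpm["L", ] + 1))) / (tpm["L", ] + 1) - 1
  pairs <- S4Vectors::DataFrame(
    lncrna_gene = c("L", "L"), pcg = c("Psame", "Pneg"),
    distance = 0L, relation = "overlapping")
  got <- correlatePairs(pairs, tpm)
  expect_equal(got$pearson_r[1], 1)
  expect_true(got$passes[1])
  expect_equal(got$pearson_r[2], -1, tolerance = 1e-9)
  expect_true(got$passes[2])
  # minimal passing |r| at n = 12 equals the t-distribution quantile
  tcrit <- qt(0.975, df = 10)
  rcrit <- sqrt(tcrit^2 / (tcrit^2 + 10))
  expect_equal(rcrit, 0.5760, tolerance = 1e-3)
  set.seed(14)
  big <- matrix(rlnorm(200 * 12, 3, 1.5), 200, 12)
  rownames(big) <- paste0("g", 1:200)
  prs <- S4Vectors::DataFrame(
    lncrna_gene = rownames(big)[1:100], pcg = rownames(big)[101:200],
    distance = 0L, relation = "overlapping")
  res <- correlatePairs(prs, big)
  expect_true(all(abs(res$pearson_r[res$passes]) >= rcrit - 1e-9))
  expect_true(all(abs(res$pearson_r[!res$passes & !is.na(res$pearson_r)])
                  < rcrit + 1e-9))
  # zero variance -> undefined, fails
  zv <- big; zv[1, ] <- 5
  r0 <- correlatePairs(prs[1, ], zv)
  expect_true(is.na(r0$pearson_r))
  expect_false(r0$passes)
})

test_that("hypergeometric enrichment equals closed forms and enumeration", {
  tm <- data.frame(gene = paste0("g", 1:10),
                   term = rep(c("T1", "T2"), each = 5))
  res <- hypergeomEnrich(paste0("g", 1:5), paste0("g", 1:10), tm)
  expect_equal(res$p[res$term == "T1"], 1 / choose(10, 5))
  expect_equal(res$p[res$term == "T2"], 1)          # k = 0 upper tail
  # a term carried by every background gene has p = 1
  tm2 <- rbind(tm, data.frame(gene = paste0("g", 1:10), term = "ALL"))
  res2 <- hypergeomEnrich(paste0("g", 1:5), paste0("g", 1:10), tm2)
  expect_equal(res2$p[res2$term == "ALL"], 1)
  expect_error(hypergeomEnrich(character(), paste0("g", 1:10), tm), "empty")
  expect_error(hypergeomEnrich("zz", paste0("g", 1:10), tm), "subset")

  # exhaustive enumeration oracle on small instances
  set.seed(25)
  for (i in 1:10) {
    N <- sample(8:20, 1)
    bg <- paste0("b", seq_len(N))
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    tmr <- data.frame(gene = bg[seq_len(K)], term = "T")
    targets <- sample(bg, n)
    k <- sum(targets %in% tmr$gene)
    # P(X >= k) by enumerating the hypergeometric pmf
    pmf <- vapply(0:min(K, n), function(x)
      choose(K, x) * choose(N - K, n - x) / choose(N, n), 0)
    want <- sum(pmf[(k:min(K, n)) + 1])
    got <- hypergeomEnrich(targets, bg, tmr)
    expect_equal(got$p[got$term == "T"], want, tolerance = 1e-12)
  }
})

test_that("marker terms attached to genes near planted DE lncRNAs rank first", {
  ss <- getSmallSim()
  truth <- ss$sim$truth
  coupled <- unique(stats::na.omit(truth$coupled_pcg))
  expect_gt(length(coupled), 3)
  lncDe <- truth[truth$is_lncRNA & !truth$is_isoform &
                   !is.na(truth$coupled_pcg), ]
  lncSp <- txSpans(ss$sim$assembled)[lncDe$tx_id]
  names(lncSp) <- lncDe$gene_id
  pcgColl <- collapseToGenes(ss$sim$reference)
  tg <- findCisTargets(lncSp, pcgColl$spans)
  res <- hypergeomEnrich(unique(tg$pcg), unique(geneIds(ss$sim$reference)),
                         ss$sim$termMap)
  expect_equal(res$term[1], "GO:0009999")
  expect_lt(res$p[1], 0.05)
})
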