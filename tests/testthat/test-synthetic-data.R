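test_that("generator honours the per-category lncRNA budget", {
  cfg <- simConfig(seed = 3L, nChromH = 2L, nChromC = 1L,
                   chromLength = 400000L, nCodingGenes = 60L,
                   nLnc = c(intergenic = 5L, sense = 5L, antisense = 5L,
                            intronic = 5L),
                   nLncIsoforms = 0L, nDecoyCoding = 0L,
                   nDecoySingleExon = 0L, nDecoyLowTpm = 0L, nTe = 30L,
                   nLncHomoeologPairs = 2L)
  sim <- simulateGenomeAnnotation(cfg)
  lnc <- sim$truth[sim$truth$is_lncRNA, ]
  expect_equal(nrow(lnc), 20L)
  expect_equal(sort(as.vector(table(lnc$category))), rep(5L, 4))
})

test_that("planted intronic lncRNAs sit wholly inside a reference intron", {
  ss <- getSmallSim()
  truth <- ss$sim$truth
  intr <- truth$tx_id[truth$is_lncRNA & truth$category == "intronic"]
  expect_gt(length(intr), 0)
  sp <- txSpans(ss$sim$assembled)[intr]
  introns <- lncPloidy:::.intronsOf(ss$sim$reference)
  hits <- GenomicRanges::countOverlaps(sp, introns, type = "within",
                                       ignore.strand = TRUE)
  expect_true(all(hits > 0))
})

test_that("the same seed reproduces byte-identical artifacts", {
  cfg <- simConfig(seed = 17L, nChromH = 2L, nChromC = 1L,
                   chromLength = 300000L, nCodingGenes = 40L,
                   nLnc = c(intergenic = 6L, sense = 2L, antisense = 2L,
                            intronic = 1L),
                   nLncIsoforms = 2L, nDecoyCoding = 1L,
                   nDecoySingleExon = 1L, nDecoyLowTpm = 1L, nTe = 20L,
                   nLncHomoeologPairs = 2L)
  d1 <- tempfile(); d2 <- tempfile()
  writeSimulation(simulateGenomeAnnotation(cfg),
                  simulateCounts(cfg, simulateGenomeAnnotation(cfg)), d1)
  writeSimulation(simulateGenomeAnnotation(cfg),
                  simulateCounts(cfg, simulateGenomeAnnotation(cfg)), d2)
  for (f in c("genome.fa", "reference.gtf", "assembled.gtf", "te.bed",
              "counts.tsv", "truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("counts follow the planted group means", {
  ss <- getSmallSim()
  truth <- ss$sim$truth
  m <- countsOf(ss$counts)
  groups <- sampleGroups(ss$counts)
  # additive features: S14 replicate mean close to the parents' average on
  # the expected-count scale (within 3 SE of the NB sampling noise)
  addl <- truth$is_lncRNA & truth$s14_class == "additive" &
    truth$parent_class == "equal" & truth$f1_class == "additive" &
    !truth$is_isoform
  ids <- truth$tx_id[addl]
  s14 <- rowMeans(m[ids, groups == "S14", drop = FALSE])
  mpv <- (rowMeans(m[ids, groups == "CC", drop = FALSE]) +
            rowMeans(m[ids, groups == "HH", drop = FALSE])) / 2
  disp <- ss$cfg@dispersion
  se <- sqrt((mpv + disp * mpv^2) / 3)
  frac_in <- mean(abs(s14 - mpv) <= 3 * se + 3)
  expect_gt(frac_in, 0.95)
  # species-specific features are exactly zero in the silent parent
  cc_only <- truth$tx_id[truth$parent_class == "cc_only"]
  if (length(cc_only))
    expect_true(all(m[cc_only, groups == "HH"] == 0))
})

test_that("requesting more features than the genome can host errors", {
  cfg <- simConfig(seed = 2L, nChromH = 1L, nChromC = 1L,
                   chromLength = 30000L, nCodingGenes = 200L,
                   nLnc = c(intergenic = 2L, sense = 1L, antisense = 1L,
                            intronic = 1L),
                   nLncIsoforms = 0L, nDecoyCoding = 0L,
                   nDecoySingleExon = 0L, nDecoyLowTpm = 0L, nTe = 5L,
                   nLncHomoeologPairs = 1L)
  expect_error(simulateGenomeAnnotation(cfg), "capacity")
})

test_that("planted coding and noncoding transcripts separate by coding probability", {
  ss <- getSmallSim()
  sim <- ss$sim
  model <- lncPloidy:::trainCodingPipeline(sim$reference, sim$genome,
                                           seed = 5L, maxTrain = 150L)
  truth <- sim$truth
  pick <- c(truth$tx_id[truth$is_lncRNA],
            sample(truth$tx_id[truth$role == "pcg"], 80))
  seqs <- extractTxSeqs(sim$genome, sim$assembled[pick])
  feats <- lncPloidy:::codingFeatures(seqs, model$hexamers)
  p <- codingProbability(model$model, feats)
  lab <- truth[pick, "role"] == "pcg"
  auc <- mean(outer(p[lab], p[!lab], ">")) +
    0.5 * mean(outer(p[lab], p[!lab], "=="))
  expect_gte(auc, 0.95)
})

test_that("planted homoeologous pairs are recovered by collinearity", {
  ss <- getSmallSim()
  sim <- ss$sim
  truth <- sim$truth
  lnc <- truth[truth$is_lncRNA & !truth$is_isoform, ]
  sp <- txSpans(sim$assembled)[lnc$tx_id]
  names(sp) <- lnc$gene_id
  seqs <- extractTxSeqs(sim$genome, sim$assembled[lnc$tx_id])
  names(seqs) <- lnc$gene_id
  hp <- findHomoeologPairs(sp, seqs)
  planted <- lnc[!is.na(lnc$homoeolog_partner) & lnc$pair_side == "H", ]
  found <- paste(hp$pairs$h_gene, hp$pairs$c_gene)
  want <- paste(planted$gene_id, planted$homoeolog_partner)
  expect_gte(mean(want %in% found), 0.9)
  # one-to-one: no gene participates in two reported pairs
  expect_false(any(duplicated(c(hp$pairs$h_gene, hp$pairs$c_gene))))
})

test_that("TE-derived fraction matches the planted rate within binomial error", {
  ss <- getSmallSim()
  truth <- ss$sim$truth
  lnc <- truth[truth$is_lncRNA & !truth$is_isoform, ]
  reps <- ss$sim$assembled[lnc$tx_id]
  fl <- flagTeDerived(reps, ss$sim$te)
  phat <- mean(fl$te_derived)
  p0 <- ss$cfg@teDerivedFraction
  n <- nrow(lnc)
  expect_lt(abs(phat - p0), 1.96 * sqrt(p0 * (1 - p0) / n) + 0.02)
})
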