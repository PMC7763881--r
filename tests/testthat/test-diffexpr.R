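test_that("median-of-ratios size factors behave on exact and simulated data", {
  m <- matrix(rpois(300, 50) + 1, 50, 6)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(unname(medianRatioSizeFactors(same)), rep(1, 3))
  two <- cbind(a = m[, 1], b = 2 * m[, 1])
  sf <- medianRatioSizeFactors(two)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # normalized grand means agree across samples on NB data
  set.seed(33)
  mu <- rlnorm(800, log(80), 1)
  depth <- c(1, 1.6, 0.7, 1.2)
  nb <- sapply(depth, function(d) rnbinom(800, mu = mu * d, size = 10))
  sfa <- medianRatioSizeFactors(nb)
  norm <- t(t(nb) / sfa)
  gm <- colMeans(norm)
  expect_true(all(abs(gm / mean(gm) - 1) < 0.05))
  # cross-check against the established median-of-ratios implementation
  # (even-length medians interpolate on the ratio vs log-ratio scale, so
  # agreement is near- rather than bit-exact)
  expect_equal(unname(sfa),
               unname(DESeq2::estimateSizeFactorsForMatrix(nb)),
               tolerance = 0.01)
  expect_warning(medianRatioSizeFactors(rbind(c(0, 5), c(5, 0))),
                 "falling back")
})

test_that("BH adjustment equals the step-up rule and reference implementation", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(1:500, 1))
    expect_equal(bhAdjust(p), p.adjust(p, "BH"))
  }
  # NA p-values are excluded from m and preserved
  p <- c(0.01, NA, 0.04)
  expect_equal(bhAdjust(p), c(0.02, NA, 0.04))
})

test_that("NB Wald test: null behaviour, recall and antisymmetry", {
  g <- rep(c("A", "B"), each = 3)
  # identical groups, no dispersion -> log2FC 0 and ns
  flat <- matrix(100, 20, 6, dimnames = list(paste0("f", 1:20), NULL))
  de0 <- nbWaldTest(flat, g, c("A", "B"))
  expect_true(all(de0$log2FC == 0))
  expect_true(all(de0$call == "ns"))

  # seeded null: raw p < 0.05 fraction within 0.05 +/- 0.02, no padj hits
  set.seed(42)
  mu <- rlnorm(1000, log(100), 1)
  m <- sapply(1:6, function(s) rnbinom(1000, mu = mu, size = 20))
  rownames(m) <- paste0("f", 1:1000)
  den <- nbWaldTest(m, g, c("A", "B"))
  expect_gt(mean(den$wald_p < 0.05, na.rm = TRUE), 0.03)
  expect_lt(mean(den$wald_p < 0.05, na.rm = TRUE), 0.07)
  expect_equal(sum(den$padj < 1e-4, na.rm = TRUE), 0)
  expect_true(all(den$padj >= den$wald_p, na.rm = TRUE))

  # planted |log2FC| = 3 at mean 100: recall >= 0.8, no additive feature
  # crosses the non-additivity threshold
  set.seed(7)
  idx <- 1:200
  muA <- rep(100, 1000); muA[idx] <- 800
  mA <- sapply(1:3, function(s) rnbinom(1000, mu = muA, size = 20))
  mB <- sapply(1:3, function(s) rnbinom(1000, mu = 100, size = 20))
  m2 <- cbind(mA, mB); rownames(m2) <- paste0("f", 1:1000)
  de2 <- nbWaldTest(m2, g, c("A", "B"))
  expect_gte(mean(de2$call[idx] == "up_in_A"), 0.8)
  expect_equal(sum(de2$call[-idx] != "ns"), 0)

  # antisymmetry of calls under contrast reversal
  de3 <- nbWaldTest(m2, g, c("B", "A"))
  expect_equal(de2$call == "up_in_A", de3$call == "down_in_A")
  expect_equal(de2$log2FC, -de3$log2FC, tolerance = 1e-12)
})

test_that("additivity classification needs both thresholds", {
  g <- rep(c("S14", "MPV"), each = 3)
  # S14 identical to MPV -> additive
  m <- matrix(rep(c(50, 52, 48, 50, 52, 48), each = 10), 10, 6, byrow = FALSE,
              dimnames = list(paste0("f", 1:10), NULL))
  ad <- classifyAdditivity(nbWaldTest(m, g, c("S14", "MPV")))
  expect_true(all(ad$class == "additive"))
  # a strong but small fold change (|log2FC| < 2) stays additive
  set.seed(9)
  idx <- 1:100
  muA <- rep(100, 500); muA[idx] <- 300
  mA <- sapply(1:3, function(s) rnbinom(500, mu = muA, size = 60))
  mB <- sapply(1:3, function(s) rnbinom(500, mu = 100, size = 60))
  m2 <- cbind(mA, mB); rownames(m2) <- paste0("f", 1:500)
  de <- nbWaldTest(m2, g, c("S14", "MPV"))
  expect_gt(sum(de$padj[idx] < 1e-4, na.rm = TRUE), 80)  # highly significant
  expect_true(all(classifyAdditivity(de)$class == "additive"))
  # planted nonadditive-up recovered
  ss <- getSmallSim()
  truth <- ss$sim$truth
  lnc <- truth[truth$is_lncRNA & !truth$is_isoform, ]
  m3 <- countsOf(ss$counts)[lnc$tx_id, ]
  grp <- sampleGroups(ss$counts)
  mp <- midParent(m3, grp, type = "count")
  m4 <- cbind(m3, mp)
  g4 <- c(grp, rep("MPV", 3))
  ad4 <- classifyAdditivity(nbWaldTest(m4, g4, c("S14", "MPV")))
  up <- lnc$tx_id[lnc$s14_class == "nonadditive_up"]
  if (length(up))
    expect_true(all(ad4[up, "class"] == "nonadditive_up"))
})

test_that("species-specific expression is strict-zero on one side", {
  counts <- rbind(a = c(9, 14, 11, 0, 0, 0),
                  b = c(9, 14, 11, 0, 1, 0),
                  c = c(0, 0, 0, 0, 0, 0))
  tpm <- rbind(a = c(5, 6, 5, 0, 0, 0),
               b = c(5, 6, 5, 0, 0.4, 0),
               c = c(0, 0, 0, 0, 0, 0))
  g <- rep(c("CC", "HH"), each = 3)
  fl <- detectSpeciesSpecific(counts, tpm, g, c("CC", "HH"))
  expect_equal(as.character(fl), c("A_only", "none", "none"))
  # planted species-specific features recovered at 100%
  ss <- getSmallSim()
  truth <- ss$sim$truth
  lnc <- truth[truth$is_lncRNA & !truth$is_isoform, ]
  m <- countsOf(ss$counts)[lnc$tx_id, ]
  tp <- computeTpm(ss$counts)[lnc$tx_id, ]
  grp <- sampleGroups(ss$counts)
  fl2 <- detectSpeciesSpecific(m, tp, grp, c("CC", "HH"))
  names(fl2) <- lnc$tx_id
  ccOnly <- lnc$tx_id[lnc$parent_class == "cc_only"]
  hhOnly <- lnc$tx_id[lnc$parent_class == "hh_only"]
  if (length(ccOnly)) expect_true(all(fl2[ccOnly] == "A_only"))
  if (length(hhOnly)) expect_true(all(fl2[hhOnly] == "B_only"))
})
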