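# planted expression truth: gene-level group means in TPM space plus
# additive/non-additive classes across the allopolyploidization series
.simExpressionTruth <- function(cfg, layout) {
  md <- layout$truthBase
  drawDelta <- function(n) stats::runif(n, cfg@effectSizeRange[1],
                                        cfg@effectSizeRange[2])

  genes <- md[!md$is_isoform, ]
  ng <- nrow(genes)
  g <- data.frame(gene_id = genes$gene_id, role = genes$role,
                  chrom = genes$chrom, tx_id = genes$tx_id,
                  stringsAsFactors = FALSE)
  g$parent_class <- "equal"
  g$f1_class <- "additive"; g$s14_class <- "additive"
  g$delta_f1 <- 0; g$delta_s14 <- 0

  isPcg <- g$role == "pcg"
  isLnc <- g$role == "lnc"
  isLow <- g$role == "decoy_low_tpm"
  base <- numeric(ng)
  base[isPcg] <- stats::rlnorm(sum(isPcg), log(cfg@baseTpmCoding),
                               cfg@tpmSdLog)
  base[!isPcg] <- pmax(2, stats::rlnorm(sum(!isPcg), log(cfg@baseTpmLnc),
                                        cfg@tpmSdLog))
  base[isLow] <- cfg@lowTpm

  # parental difference / species-specific structure
  u <- stats::runif(ng)
  ss <- isLnc & u < cfg@speciesSpecificFraction
  pd <- isLnc & !ss & u < cfg@speciesSpecificFraction + cfg@parentDeFraction
  g$parent_class[ss] <- sample(c("cc_only", "hh_only"), sum(ss), TRUE)
  g$parent_class[pd] <- sample(c("hh_up", "hh_down"), sum(pd), TRUE)
  pcgDe <- isPcg & stats::runif(ng) < cfg@pcgParentDeFraction
  g$parent_class[pcgDe] <- sample(c("hh_up", "hh_down"), sum(pcgDe), TRUE)

  cc <- base; hh <- base
  dpar <- drawDelta(ng)
  hh[g$parent_class == "hh_up"] <- (base * 2^dpar)[g$parent_class == "hh_up"]
  hh[g$parent_class == "hh_down"] <- (base * 2^-dpar)[g$parent_class == "hh_down"]
  hh[g$parent_class == "cc_only"] <- 0
  cc[g$parent_class == "hh_only"] <- 0
  mpv <- (cc + hh) / 2

  # non-additive F1 (hybridization) and S14 (genome duplication) deviations
  f1roll <- stats::runif(ng)
  f1na <- isLnc & f1roll < cfg@nonAdditiveF1
  f1up <- f1na & stats::runif(ng) < cfg@nonAdditiveF1UpShare
  g$f1_class[f1na] <- ifelse(f1up[f1na], "nonadditive_up", "nonadditive_down")
  g$delta_f1[f1na] <- drawDelta(sum(f1na)) * ifelse(f1up[f1na], 1, -1)
  s14na <- isLnc & stats::runif(ng) < cfg@nonAdditiveS14
  s14up <- s14na & stats::runif(ng) < 0.5
  g$s14_class[s14na] <- ifelse(s14up[s14na], "nonadditive_up",
                               "nonadditive_down")
  g$delta_s14[s14na] <- drawDelta(sum(s14na)) * ifelse(s14up[s14na], 1, -1)

  f1 <- mpv * 2^g$delta_f1
  s14 <- mpv * 2^g$delta_s14

  g$mean_CC <- cc; g$mean_HH <- hh; g$mean_F1 <- f1; g$mean_S14 <- s14

  # couple some DE lncRNAs to a nearby coding gene (cis-target structure)
  g$coupled_pcg <- NA_character_
  eligible <- which(isLnc & (g$parent_class != "equal" |
                               g$s14_class != "additive"))
  nPairs <- min(cfg@nTargetPairs, length(eligible))
  sp <- txSpans(layout$assembled)
  used <- character()
  if (nPairs > 0L) {
    chosen <- sort(sample(eligible, nPairs))
    for (i in chosen) {
      li <- sp[g$tx_id[i]]
      cand <- which(isPcg & g$chrom == g$chrom[i] &
                      !(g$gene_id %in% used))
      if (!length(cand)) next
      pcgSpans <- sp[g$tx_id[cand]]
      dd <- GenomicRanges::distance(rep(li, length(cand)), pcgSpans,
                                    ignore.strand = TRUE)
      j <- cand[which.min(dd)]
      if (min(dd, na.rm = TRUE) > 1e5) next
      g$coupled_pcg[i] <- sub("^asmg_", "", g$gene_id[j])
      used <- c(used, g$gene_id[j])
      scale <- 5
      g[j, c("mean_CC", "mean_HH", "mean_F1", "mean_S14")] <-
        g[i, c("mean_CC", "mean_HH", "mean_F1", "mean_S14")] * scale + 0.5
    }
  }

  # implied trend profile over (MPV, F1, S14) on the log2(TPM + 1) scale
  mpv2 <- (g$mean_CC + g$mean_HH) / 2
  d1 <- log2(g$mean_F1 + 1) - log2(mpv2 + 1)
  d2 <- log2(g$mean_S14 + 1) - log2(g$mean_F1 + 1)
  u1 <- pmax(-2, pmin(2, round(d1)))
  u2 <- pmax(-2, pmin(2, round(d2)))
  g$true_profile <- ifelse(isLnc, (u1 + 2) * 5 + (u2 + 2), NA_real_)

  # per-transcript truth: isoforms get a fixed share of the gene mean
  tt <- merge(md, g[, setdiff(colnames(g), c("role", "chrom", "tx_id"))],
              by = "gene_id", sort = FALSE)
  tt <- tt[order(match(tt$tx_id, md$tx_id)), ]
  multi <- tt$gene_id %in% tt$gene_id[tt$is_isoform]
  share <- ifelse(!multi, 1, ifelse(tt$is_isoform, 0.3, 0.7))
  for (cl in c("mean_CC", "mean_HH", "mean_F1", "mean_S14"))
    tt[[cl]] <- tt[[cl]] * share
  tt$is_lncRNA <- tt$role == "lnc"

  # express group means on a true TPM scale (each group sums to 1e6), then
  # pin the barely-expressed decoys at their nominal TPM
  for (cl in c("mean_CC", "mean_HH", "mean_F1", "mean_S14"))
    tt[[cl]] <- tt[[cl]] / sum(tt[[cl]]) * 1e6
  lowIdx <- tt$role == "decoy_low_tpm"
  for (cl in c("mean_CC", "mean_HH", "mean_F1", "mean_S14"))
    tt[[cl]][lowIdx] <- cfg@lowTpm

  # homoeologous partner gene (lncRNA pairs planted in collinear order)
  partnerOf <- function(j, side) {
    if (is.na(j)) return(NA_character_)
    other <- tt$gene_id[!is.na(tt$pair_j) & tt$pair_j == j &
                          tt$pair_side != side]
    if (length(other)) other[1] else NA_character_
  }
  tt$homoeolog_partner <- mapply(partnerOf, tt$pair_j, tt$pair_side)
  tt$subgenome <- ifelse(grepl("^H\\d", tt$chrom), "subH",
                         ifelse(grepl("^C\\d", tt$chrom), "subC", "unplaced"))
  rownames(tt) <- tt$tx_id
  S4Vectors::DataFrame(tt)
}

# gene -> GO term map over reference coding genes; a marker term tags the
# coding genes coupled to planted DE lncRNAs so target enrichment has a
# recoverable signal
.simGoTerms <- function(cfg, layout, truth) {
  pcgGenes <- unique(geneIds(layout$reference))
  pool <- sprintf("GO:%07d", seq(10, 400, by = 10))
  rows <- lapply(pcgGenes, function(gn)
    data.frame(gene = gn, term = sample(pool, sample(2:4, 1)),
               stringsAsFactors = FALSE))
  tm <- do.call(rbind, rows)
  marker <- "GO:0009999"
  coupled <- unique(stats::na.omit(truth$coupled_pcg))
  extra <- sample(setdiff(pcgGenes, coupled), min(10L, length(pcgGenes)))
  tm <- rbind(tm, data.frame(gene = c(coupled, extra), term = marker,
                             stringsAsFactors = FALSE))
  tm[order(tm$gene, tm$term), ]
}

#' Draw negative-binomial counts from the planted truth
#'
#' Per-sample expected counts are proportional to true TPM times transcript
#' length (transcript-abundance quantification semantics), scaled to a
#' drawn library size; counts are NB with the configured dispersion.
#' Species-specific features have mean exactly zero in the silent parent.
#'
#' @param config A \code{\link{simConfig}}.
#' @param sim Output of \code{\link{simulateGenomeAnnotation}}.
#' @return An \code{\link{AlloCountSet}} over all assembled transcripts,
#'   4 groups x \code{nReplicates} samples.
#' @export
simulateCounts <- function(config, sim) {
  cfg <- config
  truth <- sim$truth
  withSeed(cfg@seed + 29L, {
    groups <- rep(c("CC", "HH", "F1", "S14"), each = cfg@nReplicates)
    reps <- rep(seq_len(cfg@nReplicates), times = 4L)
    libs <- round(cfg@librarySize * stats::runif(length(groups), 0.9, 1.1))
    M <- as.matrix(as.data.frame(
      truth[, c("mean_CC", "mean_HH", "mean_F1", "mean_S14")]))
    colnames(M) <- c("CC", "HH", "F1", "S14")
    cnt <- sapply(seq_along(groups), function(s) {
      mu <- M[, groups[s]] * truth$length
      mu <- mu / sum(mu) * libs[s]
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg@dispersion)
    })
    rownames(cnt) <- truth$tx_id
    colnames(cnt) <- paste0(groups, "_", reps)
    AlloCountSet(cnt, lengths = truth$length, group = groups,
                 replicate = reps)
  })
}

#' Write all simulation artifacts to a directory
#'
#' Emits \code{genome.fa}, \code{reference.gtf}, \code{assembled.gtf},
#' \code{te.bed}, \code{truth.tsv}, \code{go_terms.tsv} and, when counts
#' are supplied, \code{counts.tsv} and \code{design.tsv}.
#'
#' @param sim Output of \code{\link{simulateGenomeAnnotation}}.
#' @param counts Optional \code{AlloCountSet} from
#'   \code{\link{simulateCounts}}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeSimulation <- function(sim, counts = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  writeGtf(sim$reference, p("reference.gtf"))
  writeGtf(sim$assembled, p("assembled.gtf"))
  writeBed(sim$te, p("te.bed"))
  utils::write.table(as.data.frame(sim$truth), p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$termMap, p("go_terms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(counts)) {
    cm <- data.frame(feature_id = rownames(counts),
                     length = featureLengths(counts),
                     countsOf(counts), check.names = FALSE)
    utils::write.table(cm, p("counts.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ds <- data.frame(sample = colnames(counts),
                     group = counts$group, replicate = counts$replicate)
    utils::write.table(ds, p("design.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(dir)
}

#' Read a count matrix and its design into an AlloCountSet
#'
#' \code{counts.tsv} has columns \code{feature_id}, \code{length}, then one
#' column per sample; \code{design.tsv} has \code{sample}, \code{group},
#' \code{replicate}.
#'
#' @param countsPath,designPath File paths.
#' @return An \code{\link{AlloCountSet}}.
#' @export
readCountMatrix <- function(countsPath, designPath) {
  cm <- utils::read.table(countsPath, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ds <- utils::read.table(designPath, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  smp <- setdiff(colnames(cm), c("feature_id", "length"))
  missing <- setdiff(smp, ds$sample)
  if (length(missing))
    stop("design file lacks sample(s): ", paste(missing, collapse = ", "))
  m <- as.matrix(cm[, smp, drop = FALSE])
  rownames(m) <- cm$feature_id
  ds <- ds[match(smp, ds$sample), ]
  AlloCountSet(m, lengths = cm$length, group = ds$group,
               replicate = ds$replicate)
}
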