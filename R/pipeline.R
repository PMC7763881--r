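#' Rounded percentage and ratio helpers
#'
#' The arithmetic used for every reported percentage and ratio:
#' \code{percentage(352, 1593)} is 22.1, \code{ratio(153, 16)} is 9.56 and
#' \code{ratio(77, 8)} is 9.62. Rounding is R's IEC-60559 \code{round}
#' (half to even), which reproduces the conventional reported values.
#'
#' @param num,den Numerator and denominator (den > 0).
#' @param digits Decimal places (1 for percentages, 2 for ratios).
#' @return A single rounded value.
#' @export
percentage <- function(num, den, digits = 1) {
  if (!is.finite(den) || den <= 0) stop("percentage: denominator must be > 0")
  round(100 * num / den, digits)
}

#' @rdname percentage
#' @param a,b Ratio terms (b > 0).
#' @export
ratio <- function(a, b, digits = 2) {
  if (!is.finite(b) || b <= 0) stop("ratio: divisor must be > 0")
  round(a / b, digits)
}

# run one DE contrast at gene level, adding MPV pseudo-replicates when the
# contrast involves MPV and merging species-specific calls
runContrast <- function(m, tpm, groups, contrast, alpha = 1e-4, lfcMin = 2) {
  if ("MPV" %in% contrast) {
    m <- cbind(m, midParent(m, groups, type = "count"))
    tpm <- cbind(tpm, midParent(tpm, groups, type = "tpm"))
    groups <- c(groups, rep("MPV", sum(groups == "CC")))
  }
  de <- nbWaldTest(m, groups, contrast, alpha = alpha, lfcMin = lfcMin)
  flags <- detectSpeciesSpecific(m[, groups %in% contrast, drop = FALSE],
                                 tpm[, groups %in% contrast, drop = FALSE],
                                 groups[groups %in% contrast], contrast)
  mergeSpecificCalls(de, flags)
}

#' Run the complete pipeline on files
#'
#' Orchestrates identification, annotation, expression, differential
#' expression/additivity, trend profiling and cis-target prediction, and
#' writes every intermediate table under \code{outDir}. The run is fully
#' reproducible from the inputs plus \code{seed}.
#'
#' @param assembledGtf,referenceGtf,genomeFasta,teBed Input annotation and
#'   sequence files.
#' @param countsTsv,designTsv Transcript-level counts and sample design.
#' @param goTermsTsv Optional gene-to-GO-term map (two columns).
#' @param outDir Output directory.
#' @param seed Seed for the permutation test of the trend profiles.
#' @param alpha,lfcMin DE thresholds (defaults 1e-4 and 2).
#' @param tpmMin Expression threshold (default 0.3).
#' @param window Cis-target window in bp (default 100000).
#' @param nPerm Trend permutations (default 1000).
#' @return A \code{SummaryReport}-style list of per-stage counts and
#'   tables.
#' @export
runPipeline <- function(assembledGtf, referenceGtf, genomeFasta, teBed,
                        countsTsv, designTsv, goTermsTsv = NULL,
                        outDir = tempfile("lncpipe"), seed = 1L,
                        alpha = 1e-4, lfcMin = 2, tpmMin = 0.3,
                        window = 1e5, nPerm = 1000L) {
  for (f in c(assembledGtf, referenceGtf, genomeFasta, teBed, countsTsv,
              designTsv))
    if (!file.exists(f)) stop("input error: missing file ", f)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  wt <- function(x, f) utils::write.table(as.data.frame(x), p(f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)

  assembled <- readGtf(assembledGtf)
  ref <- readGtf(referenceGtf)
  genome <- Biostrings::readDNAStringSet(genomeFasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  te <- readBed(teBed)
  counts <- readCountMatrix(countsTsv, designTsv)

  ## 1. identification cascade
  idres <- identifyLncrnas(assembled, ref, counts, genome, tpmMin = tpmMin)
  lnc <- idres$lncrna
  writeGtf(lnc, p("lncrna.gtf"))
  wt(idres$audit, "audit.tsv")

  ## 2. gene collapse
  coll <- collapseToGenes(lnc, counts)
  wt(coll$genes, "gene_map.tsv")
  gCounts <- countsOf(coll$counts)
  gTpm <- computeTpm(coll$counts)
  groups <- coll$counts$group

  ## 3. annotation: position, TE, subgenome, collinearity, density
  repTx <- vapply(coll$genes$gene_id, function(g) {
    m <- which(geneIds(lnc) == g)
    txIds(lnc)[m[which.max(txLengths(lnc)[m])]]
  }, "")
  reps <- lnc[unname(repTx)]
  pos <- classifyPosition(reps, ref)
  teFlags <- flagTeDerived(reps, te)
  subg <- assignSubgenome(as.character(seqnames(txSpans(reps))))
  gSeqs <- extractTxSeqs(genome, reps)
  names(gSeqs) <- coll$genes$gene_id
  spans <- coll$spans
  hp <- findHomoeologPairs(spans, gSeqs)
  partner <- rep(NA_character_, length(spans))
  names(partner) <- names(spans)
  if (nrow(hp$pairs)) {
    partner[hp$pairs$h_gene] <- hp$pairs$c_gene
    partner[hp$pairs$c_gene] <- hp$pairs$h_gene
  }
  records <- DataFrame(gene_id = coll$genes$gene_id,
                       category = pos$category,
                       related_pcg = pos$related_pcg,
                       te_overlap_bp = teFlags$te_overlap_bp,
                       te_derived = teFlags$te_derived,
                       subgenome = subg,
                       homoeolog_partner = unname(partner))
  wt(records, "records.tsv")
  wt(hp$pairs, "blocks_pairs.tsv")
  wt(hp$blocks, "blocks.tsv")
  chromLens <- structure(width(genome), names = names(genome))
  pcgGeneSpans <- collapseToGenes(ref)$spans
  dens <- binDensity(spans, pcgGeneSpans, te, as.list(chromLens))
  wt(dens, "density.tsv")

  ## 4. expression QC and MPV
  repCor <- replicateCorrelation(idres$tpm, sampleGroups(counts))
  wt(data.frame(group = names(repCor), mean_pearson_r = repCor),
     "replicate_correlation.tsv")
  utils::write.table(data.frame(feature_id = rownames(gTpm),
                                length = coll$genes$length, gTpm,
                                check.names = FALSE),
                     p("lncrna_gene_tpm.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  wt(cbind(feature_id = rownames(gCounts),
           as.data.frame(midParent(gCounts, groups, type = "count"))),
     "mpv_counts.tsv")

  ## 5. differential expression over the eight contrasts
  contrasts <- list(c("HH", "CC"), c("S14", "CC"), c("S14", "HH"),
                    c("S14", "MPV"), c("F1", "CC"), c("F1", "HH"),
                    c("F1", "MPV"), c("S14", "F1"))
  deList <- list()
  for (ct in contrasts) {
    nm <- paste(ct, collapse = "-")
    deList[[nm]] <- runContrast(gCounts, gTpm, groups, ct,
                                alpha = alpha, lfcMin = lfcMin)
    wt(deList[[nm]], paste0("de_", nm, ".tsv"))
  }
  addS14 <- classifyAdditivity(deList[["S14-MPV"]])
  addF1 <- classifyAdditivity(deList[["F1-MPV"]])
  wt(cbind(addS14, f1_class = addF1$class), "additivity.tsv")

  ## 6. trend profiles over MPV -> F1 -> S14
  mpvTpm <- midParent(gTpm, groups, type = "tpm")
  lt <- function(m) log2(m + 1)
  series <- cbind(MPV = rowMeans(lt(mpvTpm)),
                  F1 = rowMeans(lt(gTpm[, groups == "F1", drop = FALSE])),
                  S14 = rowMeans(lt(gTpm[, groups == "S14", drop = FALSE])))
  profiles <- enumerateProfiles(T = 3L, c = 2L)
  assign <- assignProfiles(series, profiles)
  sig <- profileSignificance(series, profiles, nPerm = nPerm, seed = seed)
  cl <- clusterProfiles(profiles, sig$profile_id[sig$significant])
  profTab <- cbind(sig, DataFrame(
    changes = apply(profiles$changes, 1, paste, collapse = ","),
    cluster = unname(cl)))
  wt(profTab, "profiles.tsv")
  wt(data.frame(gene_id = names(assign), profile_id = unname(assign)),
     "profile_assignment.tsv")

  ## 7. cis targets and enrichment for the DE lncRNA sets
  deUnion <- function(cons) unique(unlist(lapply(cons, function(nm) {
    de <- deList[[nm]]
    de$feature[de$call != "ns"]
  })))
  deS14 <- deUnion(c("S14-CC", "S14-HH", "S14-MPV"))
  deF1 <- deUnion(c("F1-CC", "F1-HH", "F1-MPV"))
  km <- matchKnownTranscripts(assembled, ref)
  sel <- which(!is.na(km))
  pcgExpr <- rowsum(idres$tpm[txIds(assembled)[sel], , drop = FALSE],
                    geneIds(ref)[match(km[sel], txIds(ref))])
  exprTab <- rbind(gTpm, pcgExpr)
  targetsFor <- function(deGenes, label) {
    if (!length(deGenes)) return(NULL)
    tg <- findCisTargets(spans[deGenes], pcgGeneSpans, window = window)
    tg <- correlatePairs(tg, exprTab)
    wt(tg, paste0("targets_", label, ".tsv"))
    tg
  }
  tgS14 <- targetsFor(deS14, "S14")
  tgF1 <- targetsFor(deF1, "F1")
  enr <- NULL
  if (!is.null(goTermsTsv) && !is.null(tgS14) && nrow(tgS14)) {
    termMap <- utils::read.table(goTermsTsv, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    enr <- hypergeomEnrich(unique(tgS14$pcg),
                           unique(geneIds(ref)), termMap)
    wt(enr, "enrichment_S14.tsv")
  }

  ## 8. summary report
  nGenes <- nrow(coll$genes)
  catCounts <- table(pos$category)
  deCounts <- lapply(deList, function(de)
    c(up = sum(de$call == "up_in_A"), down = sum(de$call == "down_in_A")))
  report <- list(
    audit = table(idres$audit$status),
    n_lncrna_transcripts = length(lnc),
    n_lncrna_genes = nGenes,
    category_counts = catCounts,
    te_derived_fraction = mean(teFlags$te_derived),
    subgenome_counts = table(subg),
    n_homoeolog_pairs = nrow(hp$pairs),
    replicate_correlation = repCor,
    de_counts = deCounts,
    n_nonadditive_s14 = sum(addS14$class != "additive"),
    n_nonadditive_f1 = sum(addF1$class != "additive"),
    pct_nonadditive_s14 = percentage(sum(addS14$class != "additive"), nGenes),
    pct_nonadditive_f1 = percentage(sum(addF1$class != "additive"), nGenes),
    profile_table = profTab,
    n_targets_s14 = if (is.null(tgS14)) 0L else length(unique(tgS14$pcg)),
    n_targets_f1 = if (is.null(tgF1)) 0L else length(unique(tgF1$pcg)),
    enrichment = enr,
    records = records,
    assignment = assign,
    de = deList,
    audit_table = idres$audit,
    outDir = outDir)
  rl <- c(n_lncrna_transcripts = report$n_lncrna_transcripts,
          n_lncrna_genes = nGenes,
          structure(as.integer(catCounts), names = paste0("n_", names(catCounts))),
          n_homoeolog_pairs = report$n_homoeolog_pairs,
          n_nonadditive_s14 = report$n_nonadditive_s14,
          n_nonadditive_f1 = report$n_nonadditive_f1,
          n_targets_s14 = report$n_targets_s14)
  utils::write.table(data.frame(key = names(rl), value = unname(rl)),
                     p("report.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report
}
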