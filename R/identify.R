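#' Identify lncRNAs through the four-step cascade
#'
#' Applies, in order: novel-transcript extraction (class codes u/i/x,
#' spliced length >= \code{minLength}), the consensus coding-potential
#' filter (internal CPAT-style logistic scorer at \code{cpatThreshold},
#' intersected with any supplied external tool scores at their
#' thresholds), the multi-exon filter (exon count >= \code{minExons}), and
#' the expression filter (maximum across group-mean TPM > \code{tpmMin}).
#' The expression threshold is evaluated on the maximum of the four group
#' means, so a transcript expressed in any one species counts as
#' expressed.
#'
#' The internal scorer is trained on the fly: reference transcripts with
#' annotated CDS are the coding class and length-matched sequences drawn
#' from intergenic space the noncoding class.
#'
#' @param assembled Assembled transcripts (\code{TranscriptSet}).
#' @param ref Reference annotation (\code{TranscriptSet}, CDS required for
#'   coding genes).
#' @param counts \code{\link{AlloCountSet}} over all assembled transcripts.
#' @param genome \code{DNAStringSet} of chromosome sequences.
#' @param minLength,minExons,tpmMin,cpatThreshold Cascade thresholds
#'   (defaults 200 bp, 2 exons, 0.3 TPM, 0.36).
#' @param externalScores Optional data.frame with \code{transcript_id} plus
#'   one column per external tool (e.g. CPC2/PLEK/CNCI).
#' @param externalThresholds Named thresholds for the external columns
#'   (default 0 for each supplied tool).
#' @param trainSeed Seed for the intergenic negative draws.
#' @return List with \code{lncrna} (surviving \code{TranscriptSet}),
#'   \code{audit} (\code{DataFrame} transcript_id/status, where status is
#'   the removal step or "retained"), \code{scores} (coding features and
#'   probability for all novel candidates), \code{tpm} and
#'   \code{groupTpm} matrices over all assembled transcripts.
#' @export
identifyLncrnas <- function(assembled, ref, counts, genome,
                            minLength = 200, minExons = 2, tpmMin = 0.3,
                            cpatThreshold = 0.36, externalScores = NULL,
                            externalThresholds = NULL, trainSeed = 1L) {
  missing <- setdiff(txIds(assembled), rownames(counts))
  if (length(missing))
    stop("reconciliation error: transcript(s) absent from counts: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))

  status <- rep("retained", length(assembled))
  names(status) <- txIds(assembled)

  codes <- assignClassCodes(assembled, ref)
  novelCode <- codes %in% c("u", "i", "x")
  status[!novelCode] <- "class_code"
  longEnough <- txLengths(assembled) >= minLength
  status[novelCode & !longEnough] <- "min_length"
  cand <- assembled[which(novelCode & longEnough)]

  # coding-potential consensus on the candidates
  model <- trainCodingPipeline(ref, genome, seed = trainSeed)
  candSeqs <- extractTxSeqs(genome, cand)
  feats <- codingFeatures(candSeqs, model$hexamers)
  prob <- codingProbability(model$model, feats)
  scoreTab <- data.frame(transcript_id = txIds(cand), feats,
                         CPAT = prob, stringsAsFactors = FALSE)
  thresholds <- c(CPAT = cpatThreshold)
  if (!is.null(externalScores)) {
    tools <- setdiff(colnames(externalScores), "transcript_id")
    idx <- match(scoreTab$transcript_id, externalScores$transcript_id)
    for (tool in tools) scoreTab[[tool]] <- externalScores[[tool]][idx]
    th <- externalThresholds %||% structure(rep(0, length(tools)),
                                            names = tools)
    thresholds <- c(thresholds, th)
  }
  noncoding <- consensusNoncoding(scoreTab, thresholds)
  status[txIds(cand)[!noncoding]] <- "coding_potential"
  cand <- cand[which(noncoding)]

  multiExon <- exonCounts(cand) >= minExons
  status[txIds(cand)[!multiExon]] <- "exon_filter"
  cand <- cand[which(multiExon)]

  tpm <- computeTpm(counts)
  gTpm <- groupMeans(tpm, sampleGroups(counts))
  expressed <- apply(gTpm[txIds(cand), , drop = FALSE], 1, max) > tpmMin
  status[txIds(cand)[!expressed]] <- "tpm_filter"
  cand <- cand[which(expressed)]

  list(lncrna = cand,
       audit = DataFrame(transcript_id = names(status), status = status),
       scores = scoreTab, tpm = tpm, groupTpm = gTpm)
}

# train the internal coding-potential model from a reference annotation:
# coding = reference mRNAs with CDS; noncoding = length-matched draws from
# intergenic space
trainCodingPipeline <- function(ref, genome, seed = 1L, maxTrain = 600L) {
  codingTx <- names(cdsRanges(ref))
  if (!length(codingTx)) stop("reference annotation carries no CDS")
  withSeed(seed, {
    if (length(codingTx) > maxTrain) codingTx <- sample(codingTx, maxTrain)
    pos <- extractTxSeqs(genome, ref[codingTx])
    occupied <- txSpans(ref)
    chroms <- names(genome)
    lens <- width(pos)
    negs <- character(length(pos))
    for (i in seq_along(negs)) {
      repeat {
        chr <- sample(chroms, 1)
        L <- unname(lens[i])
        maxS <- length(genome[[chr]]) - L
        if (maxS < 1) next
        s <- sample.int(maxS, 1)
        cand <- GRanges(chr, IRanges(s, s + L - 1L))
        if (!length(findOverlaps(cand, occupied, ignore.strand = TRUE))) {
          negs[i] <- as.character(Biostrings::extractAt(
            genome[[chr]], IRanges(s, s + L - 1L)))
          break
        }
      }
    }
    hex <- trainHexamerTable(pos, negs)
    featPos <- codingFeatures(pos, hex)
    featNeg <- codingFeatures(negs, hex)
    feats <- rbind(featPos, featNeg)
    labels <- rep(c(1L, 0L), c(nrow(featPos), nrow(featNeg)))
    list(model = trainCodingModel(feats, labels), hexamers = hex,
         training = cbind(feats, label = labels))
  })
}

# the four features feeding the logistic coding-potential model
codingFeatures <- function(seqs, hexTable) {
  seqs <- as.character(seqs)
  orf <- findLongestOrf(seqs)
  data.frame(orf_length = orf$orf_length,
             orf_coverage = orf$orf_length / pmax(1, nchar(seqs)),
             fickett = fickettScore(seqs),
             hexamer = hexamerBias(seqs, hexTable))
}

#' Collapse lncRNA transcripts to gene level
#'
#' Groups transcripts by gene id; gene-level counts are the per-sample sums
#' of the member transcripts, the gene length is the spliced length of the
#' longest member, and the representative interval the span over all
#' members.
#'
#' @param lnc \code{TranscriptSet} of identified lncRNA transcripts.
#' @param counts \code{\link{AlloCountSet}} at transcript level.
#' @return List with \code{genes} (\code{DataFrame}), \code{counts}
#'   (gene-level \code{AlloCountSet}) and \code{spans} (named
#'   \code{GRanges}).
#' @export
collapseToGenes <- function(lnc, counts = NULL) {
  gid <- geneIds(lnc)
  genes <- unique(gid)
  f <- factor(gid, levels = genes)
  sp <- txSpans(lnc)
  lens <- txLengths(lnc)
  first <- !duplicated(f)
  gSpans <- GRanges(as.character(seqnames(sp))[first],
                    IRanges(vapply(split(start(sp), f), min, 0L),
                            vapply(split(end(sp), f), max, 0L)),
                    strand = as.character(strand(sp))[first])
  names(gSpans) <- genes
  gLen <- vapply(split(as.numeric(lens), f), max, 0)
  members <- vapply(split(txIds(lnc), f), paste, "", collapse = ",")
  out <- list(genes = DataFrame(gene_id = genes, members = members,
                                length = gLen, row.names = genes),
              spans = gSpans)
  if (!is.null(counts)) {
    m <- countsOf(counts)[txIds(lnc), , drop = FALSE]
    gm <- rowsum(m, group = gid, reorder = FALSE)
    gm <- gm[genes, , drop = FALSE]
    out$counts <- AlloCountSet(gm, lengths = gLen,
                               group = counts$group,
                               replicate = counts$replicate)
  }
  out
}
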