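#' Positional classification of lncRNAs
#'
#' Relative to the protein-coding annotation: \code{sense} = >= 1 bp
#' exonic overlap with a coding exon on the same strand; \code{antisense}
#' = exonic overlap on the opposite strand only; \code{intronic} = span
#' fully inside a coding-gene intron with no exonic overlap;
#' \code{intergenic} otherwise. Precedence sense > antisense > intronic >
#' intergenic. Among several qualifying coding genes, the one with the
#' largest exonic overlap defines the relation (ties to the
#' lexicographically smaller gene id). This classification is independent
#' of the earlier class-code extraction.
#'
#' @param lnc \code{TranscriptSet} of lncRNA representatives (one per
#'   gene).
#' @param pcg Protein-coding annotation (\code{TranscriptSet}).
#' @return \code{DataFrame}: category, related_pcg, overlap_bp; rows
#'   named by lnc transcript id.
#' @export
classifyPosition <- function(lnc, pcg) {
  n <- length(lnc)
  cat <- rep("intergenic", n)
  rel <- rep(NA_character_, n)
  ovl <- rep(0L, n)

  lncEx <- unlist(exonRanges(lnc), use.names = FALSE)
  lncTx <- rep(seq_len(n), lengths(exonRanges(lnc)))
  pcgEx <- unlist(exonRanges(pcg), use.names = FALSE)
  pcgTx <- rep(seq_along(pcg@exons), lengths(exonRanges(pcg)))
  pcgGene <- geneIds(pcg)

  h <- findOverlaps(lncEx, pcgEx, ignore.strand = TRUE)
  if (length(h)) {
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    ow <- width(pintersect(lncEx[qi], pcgEx[si], ignore.strand = TRUE))
    same <- as.character(strand(lncEx))[qi] ==
      as.character(strand(pcgEx))[si]
    tab <- data.frame(tx = lncTx[qi], gene = pcgGene[pcgTx[si]],
                      same = same, bp = ow)
    agg <- stats::aggregate(bp ~ tx + gene + same, tab, sum)
    for (i in unique(agg$tx)) {
      sub <- agg[agg$tx == i, ]
      pick <- sub[sub$same, , drop = FALSE]
      cat[i] <- if (nrow(pick)) "sense" else "antisense"
      if (!nrow(pick)) pick <- sub
      pick <- pick[order(-pick$bp, pick$gene), ]
      rel[i] <- pick$gene[1]
      ovl[i] <- pick$bp[1]
    }
  }

  # intron containment for the remaining transcripts
  noExonOv <- setdiff(seq_len(n), unique(lncTx[S4Vectors::queryHits(h)]))
  if (length(noExonOv)) {
    introns <- .intronsOf(pcg, withGene = TRUE)
    if (length(introns)) {
      sp <- txSpans(lnc)[noExonOv]
      hi <- findOverlaps(sp, introns, type = "within", ignore.strand = TRUE)
      if (length(hi)) {
        for (q in unique(S4Vectors::queryHits(hi))) {
          i <- noExonOv[q]
          gs <- sort(introns$gene[S4Vectors::subjectHits(hi)[
            S4Vectors::queryHits(hi) == q]])
          cat[i] <- "intronic"
          rel[i] <- gs[1]
        }
      }
    }
  }
  DataFrame(category = factor(cat, levels = c("intergenic", "sense",
                                              "antisense", "intronic")),
            related_pcg = rel, overlap_bp = ovl, row.names = txIds(lnc))
}

#' Transposable-element overlap of lncRNA exons
#'
#' For each transcript, the largest total overlap between any single TE
#' interval and the transcript's exons; a transcript is TE-derived when
#' that overlap reaches \code{minBp} (10 bp, the usual criterion).
#' Overlap is strand-blind.
#'
#' @param lnc \code{TranscriptSet}.
#' @param te \code{GRanges} of TE intervals.
#' @param minBp Minimum overlap (default 10).
#' @return \code{DataFrame}: te_overlap_bp, te_derived.
#' @export
flagTeDerived <- function(lnc, te, minBp = 10L) {
  n <- length(lnc)
  best <- integer(n)
  ex <- unlist(exonRanges(lnc), use.names = FALSE)
  txf <- rep(seq_len(n), lengths(exonRanges(lnc)))
  h <- findOverlaps(ex, te, ignore.strand = TRUE)
  if (length(h)) {
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    ow <- width(pintersect(ex[qi], te[si], ignore.strand = TRUE))
    key <- paste(txf[qi], si)
    tot <- rowsum(ow, key)
    txOf <- as.integer(sub(" .*", "", rownames(tot)))
    mx <- tapply(tot[, 1], txOf, max)
    best[as.integer(names(mx))] <- as.integer(mx)
  }
  DataFrame(te_overlap_bp = best, te_derived = best >= minBp,
            row.names = txIds(lnc))
}

#' Subgenome assignment by chromosome name
#'
#' Chromosomes starting H/C followed by a digit map to subH/subC;
#' everything else (scaffolds) is unplaced.
#'
#' @param chrom Character vector of chromosome names.
#' @return Factor with levels subH, subC, unplaced.
#' @export
assignSubgenome <- function(chrom) {
  out <- ifelse(grepl("^H\\d", chrom), "subH",
                ifelse(grepl("^C\\d", chrom), "subC", "unplaced"))
  factor(out, levels = c("subH", "subC", "unplaced"))
}

#' Homoeologous lncRNA pairs by reciprocal best match and collinearity
#'
#' Stage 1: similarity between every subH and subC lncRNA sequence as the
#' Jaccard index of shared k-mers (k = 11); only reciprocal best matches
#' with similarity >= \code{minSim} are kept, which makes the matching
#' one-to-one. Stage 2: matches on a chromosome pair are sorted by H
#' position and chained into blocks where the C positions are monotone
#' (either orientation) with rank gaps <= \code{maxGap}; blocks with at
#' least \code{minAnchors} anchors are reported, and only pairs inside
#' kept blocks count as homoeologs.
#'
#' @param spans Named \code{GRanges} of lncRNA-gene spans (names = gene
#'   ids; chromosome names encode the subgenome).
#' @param seqs Named \code{DNAStringSet} of the gene sequences (same
#'   names).
#' @param k K-mer size (default 11).
#' @param minSim Minimum Jaccard similarity (default 0.2).
#' @param maxGap Maximum anchor rank gap inside a block (default 25).
#' @param minAnchors Minimum anchors per block (default 4).
#' @return List with \code{pairs} (\code{DataFrame}: h_gene, c_gene,
#'   similarity, block_id) and \code{blocks} (\code{DataFrame}).
#' @export
findHomoeologPairs <- function(spans, seqs, k = 11L, minSim = 0.2,
                               maxGap = 25L, minAnchors = 4L) {
  if (is.null(names(spans)) || is.null(names(seqs)))
    stop("input error: spans and seqs must be named by gene id")
  seqs <- seqs[names(spans)]
  if (anyNA(names(seqs)))
    stop("input error: missing genome sequence for some genes")
  sg <- assignSubgenome(as.character(seqnames(spans)))
  hIdx <- which(sg == "subH"); cIdx <- which(sg == "subC")
  emptyPairs <- DataFrame(h_gene = character(), c_gene = character(),
                          similarity = numeric(), block_id = integer())
  emptyBlocks <- DataFrame(block_id = integer(), chrom_h = character(),
                           chrom_c = character(), n_anchors = integer(),
                           orientation = character())
  if (!length(hIdx) || !length(cIdx))
    return(list(pairs = emptyPairs, blocks = emptyBlocks))

  kmerSet <- function(s) {
    s <- as.character(s)
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, seq_len(n - k + 1L), seq(k, n)))
  }
  setsH <- lapply(seqs[hIdx], kmerSet)
  setsC <- lapply(seqs[cIdx], kmerSet)
  sim <- matrix(0, length(hIdx), length(cIdx))
  for (i in seq_along(hIdx)) {
    a <- setsH[[i]]
    for (j in seq_along(cIdx)) {
      b <- setsC[[j]]
      inter <- sum(a %in% b)
      un <- length(a) + length(b) - inter
      sim[i, j] <- if (un > 0) inter / un else 0
    }
  }
  bestC <- apply(sim, 1, which.max)
  bestH <- apply(sim, 2, which.max)
  anchors <- data.frame(h = integer(), c = integer(), s = numeric())
  for (i in seq_along(hIdx)) {
    j <- bestC[i]
    if (bestH[j] == i && sim[i, j] >= minSim)
      anchors <- rbind(anchors, data.frame(h = hIdx[i], c = cIdx[j],
                                           s = sim[i, j]))
  }
  if (!nrow(anchors))
    return(list(pairs = emptyPairs, blocks = emptyBlocks))

  anchors$chrH <- as.character(seqnames(spans))[anchors$h]
  anchors$chrC <- as.character(seqnames(spans))[anchors$c]
  anchors$posH <- start(spans)[anchors$h]
  anchors$posC <- start(spans)[anchors$c]

  pairsOut <- NULL; blocksOut <- NULL
  blockId <- 0L
  for (cp in unique(paste(anchors$chrH, anchors$chrC))) {
    sub <- anchors[paste(anchors$chrH, anchors$chrC) == cp, ]
    sub <- sub[order(sub$posH), ]
    cr <- rank(sub$posC, ties.method = "first")
    runStart <- 1L; dirn <- 0L
    flush <- function(from, to, dirn) {
      if (to - from + 1L < minAnchors) return()
      blockId <<- blockId + 1L
      blk <- sub[from:to, ]
      blk$block_id <- blockId
      pairsOut <<- rbind(pairsOut, blk)
      blocksOut <<- rbind(blocksOut, data.frame(
        block_id = blockId, chrom_h = blk$chrH[1], chrom_c = blk$chrC[1],
        n_anchors = nrow(blk),
        orientation = if (dirn >= 0) "same" else "reversed"))
    }
    if (nrow(sub) >= 2L) {
      for (t in 2:nrow(sub)) {
        d <- cr[t] - cr[t - 1L]
        ok <- abs(d) <= maxGap && d != 0 && (dirn == 0L || sign(d) == dirn)
        if (ok) {
          if (dirn == 0L) dirn <- sign(d)
        } else {
          flush(runStart, t - 1L, dirn)
          runStart <- t; dirn <- 0L
        }
      }
      flush(runStart, nrow(sub), dirn)
    } else flush(1L, nrow(sub), 0L)
  }
  if (is.null(pairsOut))
    return(list(pairs = emptyPairs, blocks = emptyBlocks))
  list(pairs = DataFrame(h_gene = names(spans)[pairsOut$h],
                         c_gene = names(spans)[pairsOut$c],
                         similarity = pairsOut$s,
                         block_id = pairsOut$block_id),
       blocks = DataFrame(blocksOut))
}

#' Feature density per fixed-width genomic bin
#'
#' Counts lncRNA genes, coding genes and TE intervals per physical bin
#' (100 kb by default), the circos-style density track.
#'
#' @param lncSpans,pcgSpans \code{GRanges} of spans.
#' @param te \code{GRanges} of TE intervals.
#' @param chromLengths Named integer of chromosome lengths.
#' @param binSize Bin width in bp.
#' @return \code{DataFrame}: chrom, bin_start, bin_end, n_lncrna, n_gene,
#'   n_te.
#' @export
binDensity <- function(lncSpans, pcgSpans, te, chromLengths, binSize = 1e5) {
  rows <- list()
  for (chr in names(chromLengths)) {
    starts <- seq(1L, chromLengths[[chr]], by = binSize)
    bins <- GRanges(chr, IRanges(starts,
                                 pmin(starts + binSize - 1L,
                                      chromLengths[[chr]])))
    cnt <- function(x) countOverlaps(bins, x, ignore.strand = TRUE)
    rows[[chr]] <- DataFrame(chrom = chr, bin_start = start(bins),
                             bin_end = end(bins),
                             n_lncrna = cnt(lncSpans), n_gene = cnt(pcgSpans),
                             n_te = cnt(te))
  }
  do.call(rbind, rows)
}
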