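#' Simulate the genome, annotations and ground truth
#'
#' Builds a deterministic desk-scale dataset: chromosome sequences for both
#' subgenomes (names \code{H01..}, \code{C01..}; subgenome assignment keys on
#' the first character), a reference annotation of coding genes with real
#' ORFs, an assembled-transcript annotation containing exact copies of every
#' reference transcript plus planted novel transcripts (the four positional
#' lncRNA categories, extra isoforms, and decoys that must be removed by the
#' identification cascade), transposable-element intervals, homoeologous
#' gene/lncRNA pairs in collinear order on paired H/C chromosomes, and a
#' truth table with per-feature expression means and planted
#' additive/non-additive classes.
#'
#' Independent RNG streams are derived from the master seed per artifact
#' (layout/sequences, TEs, expression truth, GO terms), so the same seed
#' always yields byte-identical files.
#'
#' @param config A \code{\link{simConfig}} object.
#' @return A list with elements \code{genome} (\code{DNAStringSet}),
#'   \code{reference} and \code{assembled} (\code{TranscriptSet}s),
#'   \code{te} (\code{GRanges}), \code{truth} (\code{DataFrame}),
#'   \code{termMap} (data.frame gene/term) and \code{config}.
#' @export
simulateGenomeAnnotation <- function(config) {
  cfg <- config
  stopifnot(is(cfg, "SimConfig"))
  chroms <- c(sprintf("H%02d", seq_len(cfg@nChromH)),
              sprintf("C%02d", seq_len(cfg@nChromC)))
  nChrom <- length(chroms)
  nSpecialGenes <- 2L * cfg@nLnc[["sense"]] + cfg@nLnc[["antisense"]] +
    cfg@nLnc[["intronic"]]
  if (nSpecialGenes > cfg@nCodingGenes)
    stop("capacity error: coding-gene budget too small for sense/antisense/",
         "intronic loci")
  if (2L * cfg@nLncHomoeologPairs > cfg@nLnc[["intergenic"]])
    stop("capacity error: homoeolog pairs exceed intergenic lncRNA budget")

  layout <- withSeed(cfg@seed + 11L, .simLayout(cfg, chroms))
  te <- withSeed(cfg@seed + 13L, .simTes(cfg, layout, chroms))
  truth <- withSeed(cfg@seed + 17L, .simExpressionTruth(cfg, layout))
  termMap <- withSeed(cfg@seed + 19L, .simGoTerms(cfg, layout, truth))

  list(genome = layout$genome, reference = layout$reference,
       assembled = layout$assembled, te = te, truth = truth,
       termMap = termMap, config = cfg)
}

# chromosome layout, sequences and both annotations
.simLayout <- function(cfg, chroms) {
  nChrom <- length(chroms)
  nPairChrom <- max(1L, min(4L, cfg@nChromC,
                            cfg@nLncHomoeologPairs %/% 6L))
  pairsPerChrom <- diff(round(seq(0, cfg@nLncHomoeologPairs,
                                  length.out = nPairChrom + 1L)))

  # global rosters, distributed round-robin over chromosomes
  rr <- function(n) if (n == 0L) integer() else rep(seq_len(nChrom),
                                                    length.out = n)
  nPlain <- cfg@nCodingGenes - 2L * cfg@nLnc[["sense"]] -
    cfg@nLnc[["antisense"]] - cfg@nLnc[["intronic"]]
  nFreeInter <- cfg@nLnc[["intergenic"]] - 2L * cfg@nLncHomoeologPairs

  entries <- list()
  addEntries <- function(kind, n, chromIdx) {
    if (n == 0L) return()
    for (j in seq_len(n)) {
      ci <- chromIdx[j]
      entries[[length(entries) + 1L]] <<-
        list(kind = kind, j = j, chrom = chroms[ci],
             key = (j - 0.5) / n)
    }
  }
  addEntries("plain_gene", nPlain, rr(nPlain))
  addEntries("sense", cfg@nLnc[["sense"]], rr(cfg@nLnc[["sense"]]))
  addEntries("antisense", cfg@nLnc[["antisense"]], rr(cfg@nLnc[["antisense"]]))
  addEntries("intronic", cfg@nLnc[["intronic"]], rr(cfg@nLnc[["intronic"]]))
  addEntries("intergenic", nFreeInter, rr(nFreeInter))
  addEntries("decoy_coding", cfg@nDecoyCoding, rr(cfg@nDecoyCoding))
  addEntries("decoy_single_exon", cfg@nDecoySingleExon,
             rr(cfg@nDecoySingleExon))
  addEntries("decoy_low_tpm", cfg@nDecoyLowTpm, rr(cfg@nDecoyLowTpm))
  # homoeologous intergenic pairs live on paired chromosomes H0k / C0k,
  # appended in identical relative order on both -> collinear by design
  pj <- 0L
  for (k in seq_len(nPairChrom)) {
    for (m in seq_len(pairsPerChrom[k])) {
      pj <- pj + 1L
      entries[[length(entries) + 1L]] <-
        list(kind = "homoeo_lnc_H", j = pj, chrom = sprintf("H%02d", k),
             key = (m - 0.5) / pairsPerChrom[k])
      entries[[length(entries) + 1L]] <-
        list(kind = "homoeo_lnc_C", j = pj, chrom = sprintf("C%02d", k),
             key = (m - 0.5) / pairsPerChrom[k])
    }
  }

  perChrom <- split(entries, vapply(entries, `[[`, "", "chrom"))
  # deterministic interleave: order loci along the chromosome by key
  perChrom <- lapply(perChrom, function(e)
    e[order(vapply(e, `[[`, 0, "key"),
            vapply(e, `[[`, "", "kind"))])

  txRec <- list()          # global per-transcript records
  lociSpans <- list()      # per chromosome: matrix of locus [start, end]
  genomeSeqs <- structure(vector("list", nChrom), names = chroms)
  geneCounter <- 0L; lncCounter <- 0L; decCounter <- 0L
  homoeoH <- list()        # pair j -> H tx record (for C-side reuse)
  plainByChrom <- list()   # chromosome -> list of plain-gene descriptors
  hPartnerGene <- character(cfg@nLncHomoeologPairs)

  for (chr in chroms) {
    chv <- sample(.bases, cfg@chromLength, TRUE, prob = .bgProb)
    cursor <- 2000L
    spans <- NULL
    # spread loci across the whole chromosome
    nLoci <- length(perChrom[[chr]] %||% list())
    avgGap <- max(400, 0.88 * (cfg@chromLength - 4000) / max(1L, nLoci) - 1300)
    gapRange <- round(c(0.5, 1.5) * avgGap)
    isC <- startsWith(chr, "C")
    k <- as.integer(substr(chr, 2, 3))
    reusePool <- if (isC && k <= cfg@nChromH)
      plainByChrom[[sprintf("H%02d", k)]] else NULL
    nReuse <- if (is.null(reusePool)) 0L
      else floor(cfg@homoeologFraction * length(reusePool))
    plainSeen <- 0L
    myPlain <- list()

    for (e in perChrom[[chr]] %||% list()) {
      locus <- switch(e$kind,
        plain_gene = {
          geneCounter <- geneCounter + 1L
          gid <- sprintf("g%s_%04d", chr, geneCounter)
          plainSeen <- plainSeen + 1L
          reuse <- if (plainSeen <= nReuse) reusePool[[plainSeen]] else NULL
          plainGeneLocus(gid, reuse = reuse,
                         mutationRate = cfg@mutationRate)
        },
        sense = {
          geneCounter <- geneCounter + 2L; lncCounter <- lncCounter + 1L
          senseLocus(sprintf("LNCG%04d", lncCounter),
                     sprintf("g%s_%04d", chr, geneCounter - 1L),
                     sprintf("g%s_%04d", chr, geneCounter))
        },
        antisense = {
          geneCounter <- geneCounter + 1L; lncCounter <- lncCounter + 1L
          antisenseLocus(sprintf("LNCG%04d", lncCounter),
                         sprintf("g%s_%04d", chr, geneCounter))
        },
        intronic = {
          geneCounter <- geneCounter + 1L; lncCounter <- lncCounter + 1L
          intronicLocus(sprintf("LNCG%04d", lncCounter),
                        sprintf("g%s_%04d", chr, geneCounter))
        },
        intergenic = {
          lncCounter <- lncCounter + 1L
          intergenicLocus(sprintf("LNCG%04d", lncCounter))
        },
        homoeo_lnc_H = {
          lncCounter <- lncCounter + 1L
          loc <- intergenicLocus(sprintf("LNCG%04d", lncCounter))
          homoeoH[[e$j]] <- loc$txs[[1L]]
          hPartnerGene[e$j] <- loc$txs[[1L]]$gene_id
          loc
        },
        homoeo_lnc_C = {
          lncCounter <- lncCounter + 1L
          intergenicLocus(sprintf("LNCG%04d", lncCounter),
                          reuse = homoeoH[[e$j]],
                          mutationRate = cfg@mutationRate)
        },
        {
          decCounter <- decCounter + 1L
          decoyLocus(sprintf("DEC%04d", decCounter), e$kind)
        })
      if (cursor + locus$width > cfg@chromLength - 2000L)
        stop("capacity error: requested features exceed genome capacity on ",
             chr)
      for (tx in locus$txs) {
        gs <- tx$exon_start + cursor - 1L
        rec <- tx
        rec$chrom <- chr
        rec$gstart <- gs
        rec$gend <- gs + tx$exon_width - 1L
        rec$pair_j <- if (e$kind %in% c("homoeo_lnc_H", "homoeo_lnc_C"))
          e$j else NA_integer_
        rec$pair_side <- if (identical(e$kind, "homoeo_lnc_H")) "H"
          else if (identical(e$kind, "homoeo_lnc_C")) "C" else NA_character_
        # plant the spliced sequence into the chromosome
        gseq <- if (tx$strand == "-")
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(tx$seq))) else tx$seq
        cw <- cumsum(tx$exon_width)
        for (i in seq_along(cw)) {
          chunk <- substr(gseq, c(1L, cw[-length(cw)] + 1L)[i], cw[i])
          chv[rec$gstart[i]:rec$gend[i]] <-
            strsplit(chunk, "", fixed = TRUE)[[1L]]
        }
        if (tx$role == "pcg") myPlain[[length(myPlain) + 1L]] <- tx
        txRec[[length(txRec) + 1L]] <- rec
      }
      spans <- rbind(spans, c(cursor, cursor + locus$width - 1L))
      cursor <- cursor + locus$width + sample(gapRange[1]:gapRange[2], 1L)
    }
    # only plain (single-gene) loci are reusable as homoeolog templates
    plainByChrom[[chr]] <- Filter(function(t) !is.null(t$cds), myPlain)
    lociSpans[[chr]] <- spans
    genomeSeqs[[chr]] <- paste(chv, collapse = "")
  }

  genome <- Biostrings::DNAStringSet(unlist(genomeSeqs))
  names(genome) <- chroms

  # extra isoforms for a subset of intergenic lncRNA genes
  lncIdx <- which(vapply(txRec, function(r)
    r$role == "lnc" && r$category == "intergenic" &&
      r$exon_width[1] >= 150L, TRUE))
  nIso <- min(cfg@nLncIsoforms, length(lncIdx))
  isoParents <- sort(sample(lncIdx, nIso))
  for (p in isoParents) {
    rec <- txRec[[p]]
    rec$tx_id <- "iso"; rec$is_isoform <- TRUE
    rec$gstart[1] <- rec$gstart[1] + 30L
    rec$exon_width[1] <- rec$exon_width[1] - 30L
    rec$seq <- NULL
    txRec[[length(txRec) + 1L]] <- rec
  }

  .assembleSets(cfg, txRec, genome, lociSpans)
}

# build reference/assembled TranscriptSets from the flat records
.assembleSets <- function(cfg, txRec, genome, lociSpans) {
  nEx <- vapply(txRec, function(r) length(r$exon_width), 0L)
  chrom <- vapply(txRec, `[[`, "", "chrom")
  strand <- vapply(txRec, `[[`, "", "strand")
  role <- vapply(txRec, `[[`, "", "role")
  refTx0 <- vapply(txRec, `[[`, "", "tx_id")
  refGene0 <- vapply(txRec, `[[`, "", "gene_id")
  isIso <- vapply(txRec, function(r) isTRUE(r$is_isoform), TRUE)
  isPcg <- role == "pcg"

  allEx <- GRanges(rep(chrom, nEx),
                   IRanges(unlist(lapply(txRec, `[[`, "gstart")),
                           unlist(lapply(txRec, `[[`, "gend"))),
                   strand = rep(strand, nEx))
  grl <- BiocGenerics::relist(allEx, IRanges::PartitioningByEnd(cumsum(nEx)))

  tid <- ifelse(isPcg, paste0("asm_", refTx0),
                paste0(refGene0, ifelse(isIso, ".2", ".1")))
  gid <- ifelse(isPcg, paste0("asmg_", refGene0), refGene0)
  names(grl) <- tid
  assembled <- TranscriptSet(grl, gid)

  refGrl <- grl[isPcg]
  names(refGrl) <- refTx0[isPcg]
  # genomic CDS per coding transcript, built as one range pool
  cdsRows <- NULL; cdsTx <- character()
  for (i in which(isPcg)) {
    r <- txRec[[i]]
    if (is.null(r$cds)) next
    m <- splicedToGenomic(r$cds[1], r$cds[2], r$gstart, r$gend,
                          r$strand == "-")
    cdsRows <- rbind(cdsRows, cbind(m, i))
    cdsTx <- c(cdsTx, rep(r$tx_id, nrow(m)))
  }
  refCds <- GRangesList()
  if (!is.null(cdsRows)) {
    cdsGr <- GRanges(chrom[cdsRows[, 3]],
                     IRanges(cdsRows[, 1], cdsRows[, 2]),
                     strand = strand[cdsRows[, 3]])
    refCds <- S4Vectors::split(cdsGr, factor(cdsTx, levels = unique(cdsTx)))
  }
  reference <- TranscriptSet(refGrl, refGene0[isPcg], cds = refCds)

  md <- data.frame(tx_id = tid, gene_id = gid,
                   ref_tx = ifelse(isPcg, refTx0, NA_character_),
                   role = role,
                   category = vapply(txRec, `[[`, "", "category"),
                   chrom = chrom, strand = strand,
                   length = vapply(txRec, function(r)
                     sum(r$exon_width), 0L),
                   n_exons = nEx,
                   pair_j = vapply(txRec, function(r)
                     r$pair_j %||% NA_integer_, 0L),
                   pair_side = vapply(txRec, function(r)
                     r$pair_side %||% NA_character_, ""),
                   is_isoform = isIso, stringsAsFactors = FALSE)
  rownames(md) <- md$tx_id
  list(genome = genome, reference = reference, assembled = assembled,
       truthBase = md, lociSpans = lociSpans, config = cfg)
}

# transposable-element intervals: a fraction of lncRNA genes get a TE
# overlapping their first exon by >= 10 bp; the remainder are dropped into
# intergenic gaps with a midpoint bias
.simTes <- function(cfg, layout, chroms) {
  md <- layout$truthBase
  lnc <- md[md$role == "lnc" & !md$is_isoform, ]
  ex1 <- unlist(exonRanges(layout$assembled)[lnc$tx_id], use.names = FALSE)
  f <- rep(seq_len(nrow(lnc)),
           lengths(exonRanges(layout$assembled)[lnc$tx_id]))
  e1start <- vapply(split(start(ex1), f), min, 0L)
  hit <- which(stats::runif(nrow(lnc)) < cfg@teDerivedFraction)
  planted <- GRanges(lnc$chrom[hit],
                     IRanges(pmax(1L, e1start[hit] - 40L),
                             e1start[hit] + 60L))
  tePlantedGene <- lnc$gene_id[hit]
  nRest <- max(0L, cfg@nTe - length(planted))
  if (nRest > 0L) {
    gapTab <- do.call(rbind, lapply(chroms, function(chr) {
      sp <- layout$lociSpans[[chr]]
      if (is.null(sp) || nrow(sp) < 2L) return(NULL)
      data.frame(chrom = chr, start = head(sp[, 2], -1L) + 20L,
                 end = sp[-1L, 1] - 20L)
    }))
    gapTab <- gapTab[gapTab$end - gapTab$start > 120, ]
    mid <- (gapTab$start + gapTab$end) / 2 / cfg@chromLength
    w <- (gapTab$end - gapTab$start) *
      stats::dbeta(mid, cfg@teMidpointBias, cfg@teMidpointBias)
    pick <- sample(nrow(gapTab), nRest, replace = TRUE, prob = w)
    tew <- pmin(sample(80:400, nRest, replace = TRUE),
                gapTab$end[pick] - gapTab$start[pick] - 10L)
    s <- gapTab$start[pick] +
      floor(stats::runif(nRest) * (gapTab$end[pick] - tew -
                                     gapTab$start[pick] + 1L))
    rest <- GRanges(gapTab$chrom[pick], IRanges(s, s + tew - 1L))
  } else rest <- GRanges()
  te <- suppressWarnings(c(planted, rest))
  names(te) <- sprintf("TE%05d", seq_along(te))
  metadata(te)$te_planted_genes <- unique(tePlantedGene)
  te
}
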