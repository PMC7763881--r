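# shared desk-scale simulation, built once per test run
.simCache <- new.env(parent = emptyenv())

smallSimConfig <- function(seed = 11L, ...)
  simConfig(seed = seed, nChromH = 3L, nChromC = 2L, chromLength = 800000L,
            nCodingGenes = 240L,
            nLnc = c(intergenic = 24L, sense = 10L, antisense = 8L,
                     intronic = 3L),
            nLncIsoforms = 6L, nDecoyCoding = 6L, nDecoySingleExon = 4L,
            nDecoyLowTpm = 4L, nTe = 120L, nLncHomoeologPairs = 12L,
            nTargetPairs = 8L, ...)

getSmallSim <- function() {
  if (is.null(.simCache$sim)) {
    cfg <- smallSimConfig()
    .simCache$sim <- simulateGenomeAnnotation(cfg)
    .simCache$counts <- simulateCounts(cfg, .simCache$sim)
  }
  list(sim = .simCache$sim, counts = .simCache$counts,
       cfg = .simCache$sim$config)
}

# build a TranscriptSet from a compact spec:
# list(list(id=, gene=, chr=, strand=, exons=rbind(c(start,end), ...)), ...)
tsFromList <- function(txs) {
  ex <- lapply(txs, function(t)
    GenomicRanges::GRanges(t$chr,
                           IRanges::IRanges(t$exons[, 1], t$exons[, 2]),
                           strand = t$strand))
  names(ex) <- vapply(txs, `[[`, "", "id")
  TranscriptSet(ex, vapply(txs, function(t) t$gene %||% t$id, ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force ORF oracle: enumerate every ATG and walk codons to a stop
bruteOrf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best <- 0L
  if (n < 6) return(best)
  for (i in seq_len(n - 2)) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i
    while (j + 2 <= n) {
      cod <- substr(s, j, j + 2)
      if (j > i && cod %in% c("TAA", "TAG", "TGA")) {
        len <- as.integer(j + 2L - i + 1L)
        if (len > best) best <- len
        break
      }
      j <- j + 3L
    }
  }
  best
}

# independent brute-force class-code oracle: scans every reference
# transcript per query, computing each relation directly on plain vectors
bruteClassCode <- function(ts, ref) {
  flat <- function(x) {
    ex <- exonRanges(x)
    ul <- unlist(ex, use.names = FALSE)
    f <- rep(seq_along(ex), lengths(ex))
    list(st = split(GenomicRanges::start(ul), f),
         en = split(GenomicRanges::end(ul), f),
         chr = as.character(GenomicRanges::seqnames(ul))[!duplicated(f)],
         str = as.character(GenomicRanges::strand(ul))[!duplicated(f)])
  }
  Q <- flat(ts); R <- flat(ref)
  out <- character(length(ts))
  for (i in seq_along(out)) {
    qs <- Q$st[[i]]; qe <- Q$en[[i]]
    qlo <- min(qs); qhi <- max(qe)
    spanOv <- exonOvSame <- exonOvOpp <- inIntron <- known <- FALSE
    for (j in seq_along(R$chr)) {
      if (Q$chr[i] != R$chr[j]) next
      rs <- R$st[[j]]; re <- R$en[[j]]
      if (qlo <= max(re) && qhi >= min(rs)) spanOv <- TRUE
      ovbp <- 0L
      for (a in seq_along(qs)) for (b in seq_along(rs)) {
        o <- min(qe[a], re[b]) - max(qs[a], rs[b]) + 1L
        if (o > 0) ovbp <- ovbp + o
      }
      sameStrand <- Q$str[i] == R$str[j]
      if (ovbp > 0 && sameStrand) exonOvSame <- TRUE
      if (ovbp > 0 && !sameStrand) exonOvOpp <- TRUE
      if (length(rs) > 1) {
        for (k in seq_len(length(rs) - 1)) {
          if (qlo >= re[k] + 1L && qhi <= rs[k + 1] - 1L) inIntron <- TRUE
        }
      }
      if (sameStrand) {
        if (length(qs) == 1 && length(rs) == 1 &&
            qs == rs && qe == re) known <- TRUE
        if (length(qs) > 1 && length(qs) == length(rs) &&
            all(qe[-length(qe)] == re[-length(re)]) &&
            all(qs[-1] == rs[-1])) known <- TRUE
      }
    }
    out[i] <- if (known) "known_match"
      else if (exonOvOpp) "x"
      else if (!spanOv) "u"
      else if (inIntron && !exonOvSame && !exonOvOpp) "i"
      else "other_overlap"
  }
  factor(out, levels = c("known_match", "x", "i", "u", "other_overlap"))
}
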