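#' Configuration for the synthetic allopolyploid dataset
#'
#' Holds every knob of the generator. Defaults describe the desk-scale
#' mirror of the study system: a two-subgenome genome of 19 chromosomes
#' (12 H + 7 C), coding genes with real ORFs drawn from a biased codon
#' usage, planted noncoding transcripts of the four positional categories
#' in roughly the proportions reported for the real transcriptome,
#' transposable-element intervals, homoeologous loci in collinear order,
#' and negative-binomially distributed counts for 4 groups x 3 replicates
#' with planted parental-difference, hybridization-activation,
#' additive/non-additive and trend structure.
#'
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nChromH = "integer", nChromC = "integer", chromLength = "integer",
  nCodingGenes = "integer",
  nLnc = "integer",              # named: intergenic, sense, antisense, intronic
  nLncIsoforms = "integer",
  nDecoyCoding = "integer", nDecoySingleExon = "integer",
  nDecoyLowTpm = "integer",
  nTe = "integer", teDerivedFraction = "numeric", teMidpointBias = "numeric",
  homoeologFraction = "numeric", nLncHomoeologPairs = "integer",
  mutationRate = "numeric",
  parentDeFraction = "numeric", speciesSpecificFraction = "numeric",
  pcgParentDeFraction = "numeric",
  nonAdditiveF1 = "numeric", nonAdditiveF1UpShare = "numeric",
  nonAdditiveS14 = "numeric",
  effectSizeRange = "numeric",
  dispersion = "numeric", librarySize = "numeric", nReplicates = "integer",
  nTargetPairs = "integer",
  baseTpmCoding = "numeric", baseTpmLnc = "numeric", tpmSdLog = "numeric",
  lowTpm = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  fr <- c(object@teDerivedFraction, object@homoeologFraction,
          object@mutationRate, object@parentDeFraction,
          object@speciesSpecificFraction, object@pcgParentDeFraction,
          object@nonAdditiveF1, object@nonAdditiveF1UpShare,
          object@nonAdditiveS14)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  cnts <- c(object@nChromH, object@nChromC, object@nCodingGenes, object@nLnc,
            object@nTe, object@nLncHomoeologPairs, object@nDecoyCoding,
            object@nDecoySingleExon, object@nDecoyLowTpm, object@nLncIsoforms)
  if (any(cnts < 0)) msg <- c(msg, "counts must be >= 0")
  if (!identical(names(object@nLnc),
                 c("intergenic", "sense", "antisense", "intronic")))
    msg <- c(msg, "nLnc must be named intergenic/sense/antisense/intronic")
  if (length(object@effectSizeRange) != 2L ||
      any(object@effectSizeRange <= 2))
    msg <- c(msg, "effectSizeRange must be two values > 2 (non-additive |log2FC| > 2)")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param seed Master seed; fully determines every artifact. Independent
#'   sub-streams are derived per artifact so regenerating one never perturbs
#'   another.
#' @param ... Slot overrides, see \code{showClass("SimConfig")}.
#' @return A validated \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L, ...) {
  defaults <- list(
    seed = 1L, nChromH = 12L, nChromC = 7L, chromLength = 2000000L,
    nCodingGenes = 1600L,
    nLnc = c(intergenic = 89L, sense = 75L, antisense = 31L, intronic = 5L),
    nLncIsoforms = 30L,
    nDecoyCoding = 20L, nDecoySingleExon = 10L, nDecoyLowTpm = 10L,
    nTe = 600L, teDerivedFraction = 0.77, teMidpointBias = 2,
    homoeologFraction = 0.2, nLncHomoeologPairs = 24L, mutationRate = 0.03,
    parentDeFraction = 0.08, speciesSpecificFraction = 0.04,
    pcgParentDeFraction = 0.03,
    nonAdditiveF1 = 0.221, nonAdditiveF1UpShare = 0.889,
    nonAdditiveS14 = 0.021,
    effectSizeRange = c(2.5, 4),
    dispersion = 0.05, librarySize = 2e6, nReplicates = 3L,
    nTargetPairs = 20L,
    baseTpmCoding = 200, baseTpmLnc = 40, tpmSdLog = 1, lowTpm = 0.05)
  args <- list(...)
  args$seed <- seed
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("unknown SimConfig parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(args)] <- args
  ints <- c("seed", "nChromH", "nChromC", "chromLength", "nCodingGenes",
            "nLncIsoforms", "nDecoyCoding", "nDecoySingleExon", "nDecoyLowTpm",
            "nTe", "nLncHomoeologPairs", "nReplicates", "nTargetPairs")
  for (s in ints) defaults[[s]] <- as.integer(defaults[[s]])
  defaults$nLnc <- structure(as.integer(defaults$nLnc),
                             names = names(defaults$nLnc))
  do.call(new, c(list("SimConfig"), defaults))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (seed", object@seed, "):",
      object@nChromH + object@nChromC, "chromosomes x", object@chromLength,
      "bp;", object@nCodingGenes, "coding genes;",
      sum(object@nLnc), "planted lncRNAs (",
      paste(names(object@nLnc), object@nLnc, sep = "=", collapse = ", "),
      ")\n")
})

# ---- sequence building blocks -----------------------------------------

.bases <- c("A", "C", "G", "T")
# AT-rich intergenic background, as in plant genomes
.bgProb <- c(A = 0.31, C = 0.19, G = 0.19, T = 0.31)

.codons <- {
  all3 <- as.vector(outer(as.vector(outer(.bases, .bases, paste0)),
                          .bases, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}
# fixed non-uniform codon usage, giving coding sequences a distinctive
# in-frame hexamer signature
.codonWeights <- {
  gc <- vapply(strsplit(.codons, ""), function(x) sum(x %in% c("G", "C")), 0)
  w <- 2^(0.8 * gc) * rep(c(1.6, 0.7, 1.1), length.out = length(.codons))
  w / sum(w)
}

randomBg <- function(n) paste(sample(.bases, n, TRUE, prob = .bgProb),
                              collapse = "")

orfSeq <- function(orfLen) {
  stopifnot(orfLen %% 3 == 0, orfLen >= 9)
  paste0("ATG",
         paste(sample(.codons, orfLen / 3 - 2, TRUE, prob = .codonWeights),
               collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

codingSeq <- function(orfLen, utr5, utr3)
  list(seq = paste0(randomBg(utr5), orfSeq(orfLen), randomBg(utr3)),
       cds = c(utr5 + 1L, utr5 + orfLen))

# noncoding sequence: intergenic composition, no ORF of >= 100 codons
noncodingSeq <- function(n) {
  repeat {
    s <- randomBg(n)
    if (findLongestOrf(s)$orf_length < 300) return(s)
  }
}

mutateSeq <- function(s, rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) ch[hit] <- sample(.bases, length(hit), TRUE)
  paste(ch, collapse = "")
}

# cut a spliced length into nEx exon widths (each >= minW); the exon count
# is reduced when the length cannot host that many
cutExons <- function(total, nEx, minW = 60L) {
  nEx <- max(1L, min(nEx, total %/% minW))
  if (nEx == 1L) return(as.integer(total))
  extra <- total - nEx * minW
  bars <- sort(sample.int(extra + 1L, nEx - 1L, replace = TRUE) - 1L)
  as.integer(minW + diff(c(0L, bars, extra)))
}

# ---- locus builders ----------------------------------------------------
# A locus is a list of transcript descriptors with coordinates local to the
# locus (1-based); `plant` order within the locus is list order, so later
# transcripts overwrite shared genomic positions (kept to UTR regions by
# construction wherever an ORF must stay intact).

.txDesc <- function(txId, geneId, strand, exonStarts, exonWidths, seq,
                    cdsSpliced = NULL, role = "pcg", category = NA_character_) {
  list(tx_id = txId, gene_id = geneId, strand = strand,
       exon_start = as.integer(exonStarts), exon_width = as.integer(exonWidths),
       seq = seq, cds = cdsSpliced, role = role, category = category)
}

plainGeneLocus <- function(geneId, reuse = NULL, mutationRate = 0.03) {
  if (!is.null(reuse)) {
    tx <- reuse
    tx$tx_id <- paste0(geneId, ".1"); tx$gene_id <- geneId
    tx$seq <- mutateSeq(tx$seq, mutationRate)
    return(list(txs = list(tx),
                width = max(tx$exon_start + tx$exon_width - 1L)))
  }
  orfLen <- 3L * sample(100:250, 1)
  utr5 <- sample(30:80, 1); utr3 <- sample(150:300, 1)
  cs <- codingSeq(orfLen, utr5, utr3)
  total <- nchar(cs$seq)
  w <- cutExons(total, sample(2:4, 1))
  nEx <- length(w)
  intr <- sample(80:300, nEx - 1L, replace = TRUE)
  starts <- cumsum(c(1L, head(w, -1L) + intr))
  strand <- sample(c("+", "-"), 1)
  list(txs = list(.txDesc(paste0(geneId, ".1"), geneId, strand, starts, w,
                          cs$seq, cs$cds)),
       width = starts[nEx] + w[nEx] - 1L)
}

# Convergent overlapping gene pair hosting a same-strand ("sense") lncRNA.
# Gene A (+) and gene B (-) overlap in their 3' UTRs; the lncRNA shares
# B's strand, overlaps B's UTR exon (sense relation) and A's UTR exon on
# the opposite strand, which is what lets it survive a u/i/x extraction.
senseLocus <- function(lncId, geneIdA, geneIdB) {
  csA <- codingSeq(300L, 30L, 270L)          # spliced 600: exons 250 + 350
  csB <- codingSeq(300L, 50L, 150L)          # spliced 500: exons 250 + 250
  lncSeq <- noncodingSeq(250L)
  txA <- .txDesc(paste0(geneIdA, ".1"), geneIdA, "+", c(1L, 351L),
                 c(250L, 350L), csA$seq, csA$cds)
  txB <- .txDesc(paste0(geneIdB, ".1"), geneIdB, "-", c(601L, 951L),
                 c(250L, 250L), csB$seq, csB$cds)
  lnc <- .txDesc(lncId, lncId, "-", c(621L, 1250L), c(120L, 130L), lncSeq,
                 role = "lnc", category = "sense")
  list(txs = list(txA, txB, lnc), width = 1379L)
}

# Gene on + with a lncRNA on - overlapping its 3' UTR exon
antisenseLocus <- function(lncId, geneId) {
  cs <- codingSeq(450L, 40L, 310L)           # spliced 800: exons 400 + 400
  lncSeq <- noncodingSeq(250L)
  tx <- .txDesc(paste0(geneId, ".1"), geneId, "+", c(1L, 501L),
                c(400L, 400L), cs$seq, cs$cds)
  lnc <- .txDesc(lncId, lncId, "-", c(611L, 950L), c(150L, 100L), lncSeq,
                 role = "lnc", category = "antisense")
  list(txs = list(tx, lnc), width = 1049L)
}

# Gene with a long intron fully containing a two-exon lncRNA
intronicLocus <- function(lncId, geneId) {
  cs <- codingSeq(450L, 30L, 120L)           # spliced 600: exons 300 + 300
  lncSeq <- noncodingSeq(350L)
  tx <- .txDesc(paste0(geneId, ".1"), geneId, "+", c(1L, 1201L),
                c(300L, 300L), cs$seq, cs$cds)
  lnc <- .txDesc(lncId, lncId, "+", c(401L, 701L), c(200L, 150L), lncSeq,
                 role = "lnc", category = "intronic")
  list(txs = list(tx, lnc), width = 1500L)
}

intergenicLocus <- function(lncId, reuse = NULL, mutationRate = 0.03) {
  if (!is.null(reuse)) {
    tx <- reuse
    tx$tx_id <- lncId; tx$gene_id <- lncId
    tx$seq <- mutateSeq(tx$seq, mutationRate)
    return(list(txs = list(tx),
                width = max(tx$exon_start + tx$exon_width - 1L)))
  }
  total <- sample(260:1100, 1)
  w <- cutExons(total, sample(2:3, 1), minW = 100L)
  nEx <- length(w)
  intr <- sample(100:300, nEx - 1L, replace = TRUE)
  starts <- cumsum(c(1L, head(w, -1L) + intr))
  tx <- .txDesc(lncId, lncId, sample(c("+", "-"), 1), starts, w,
                noncodingSeq(total), role = "lnc", category = "intergenic")
  list(txs = list(tx), width = starts[nEx] + w[nEx] - 1L)
}

decoyLocus <- function(id, kind) {
  if (kind == "decoy_coding") {
    orfLen <- 3L * sample(120:220, 1)
    cs <- codingSeq(orfLen, 40L, 120L)
    total <- nchar(cs$seq)
    w <- cutExons(total, 2L)
    starts <- c(1L, w[1] + sample(100:250, 1))
    tx <- .txDesc(id, id, sample(c("+", "-"), 1), starts, w, cs$seq,
                  cdsSpliced = NULL, role = kind, category = "intergenic")
  } else if (kind == "decoy_single_exon") {
    total <- sample(300:800, 1)
    tx <- .txDesc(id, id, sample(c("+", "-"), 1), 1L, total,
                  noncodingSeq(total), role = kind, category = "intergenic")
  } else {                                   # decoy_low_tpm
    total <- sample(260:800, 1)
    w <- cutExons(total, 2L, minW = 100L)
    starts <- c(1L, w[1] + sample(100:250, 1))
    tx <- .txDesc(id, id, sample(c("+", "-"), 1), starts, w,
                  noncodingSeq(total), role = kind, category = "intergenic")
  }
  list(txs = list(tx),
       width = max(tx$exon_start + tx$exon_width - 1L))
}
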