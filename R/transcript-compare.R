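#' Class codes of assembled transcripts relative to a reference
#'
#' Assigns each assembled transcript one of five relations to the reference
#' annotation, modelling the Cuffcompare codes the identification cascade
#' keeps: \code{known_match} (identical intron chain; for single-exon
#' transcripts, identical exon coordinates on the same strand), \code{x}
#' (>= 1 bp exon-exon overlap with a reference transcript on the opposite
#' strand), \code{i} (span entirely inside one intron of a reference
#' transcript with no exon-exon overlap with any reference transcript;
#' containment is strand-blind), \code{u} (no overlap with any reference
#' transcript span), and \code{other_overlap} for every remaining overlap.
#' Precedence when several relations hold: known_match > x > i >
#' other_overlap.
#'
#' @param ts Assembled transcripts (\code{TranscriptSet}).
#' @param ref Reference annotation (\code{TranscriptSet}).
#' @return Factor of class codes parallel to \code{txIds(ts)}, with levels
#'   \code{known_match, x, i, u, other_overlap}.
#' @export
assignClassCodes <- function(ts, ref) {
  lv <- c("known_match", "x", "i", "u", "other_overlap")
  n <- length(ts)
  if (n == 0L) return(factor(character(), levels = lv))
  sp <- txSpans(ts)
  rsp <- txSpans(ref)

  # span overlap with any reference transcript (strand-blind) -> not "u"
  spanHit <- countOverlaps(sp, rsp, ignore.strand = TRUE) > 0L

  # identical intron chain (or identical single exon) on the same strand
  isKnown <- !is.na(matchKnownTranscripts(ts, ref))

  # exon-exon overlaps, classified by relative strand
  ex <- unlist(exonRanges(ts), use.names = FALSE)
  exTx <- rep(seq_len(n), lengths(exonRanges(ts)))
  rex <- unlist(exonRanges(ref), use.names = FALSE)
  rexTx <- rep(seq_along(ref@exons), lengths(exonRanges(ref)))
  h <- findOverlaps(ex, rex, ignore.strand = TRUE)
  sameStr <- as.character(strand(ex))[S4Vectors::queryHits(h)] ==
    as.character(strand(rex))[S4Vectors::subjectHits(h)]
  hasOpp <- hasAny <- rep(FALSE, n)
  if (length(h)) {
    hasAny[unique(exTx[S4Vectors::queryHits(h)])] <- TRUE
    hasOpp[unique(exTx[S4Vectors::queryHits(h)[!sameStr]])] <- TRUE
  }

  # span containment within a single reference intron (strand-blind)
  inIntron <- countOverlaps(sp, .intronsOf(ref), type = "within",
                            ignore.strand = TRUE) > 0L

  code <- rep("other_overlap", n)
  code[!spanHit] <- "u"
  code[spanHit & inIntron & !hasAny] <- "i"
  code[hasOpp] <- "x"
  code[isKnown] <- "known_match"
  factor(code, levels = lv)
}

# all introns of a transcript set as one GRanges (optionally annotated
# with the owning gene id)
.intronsOf <- function(ts, withGene = FALSE) {
  ex <- exonRanges(ts)
  ul <- unlist(ex, use.names = FALSE)
  n <- length(ul)
  if (n < 2L) return(GRanges())
  f <- rep(seq_along(ex), lengths(ex))
  same <- f[-1L] == f[-n]
  gr <- GRanges(as.character(seqnames(ul))[-n][same],
                IRanges(end(ul)[-n][same] + 1L,
                        start(ul)[-1L][same] - 1L))
  if (withGene) mcols(gr)$gene <- geneIds(ts)[f[-n][same]]
  gr
}

# intron-chain signature used for known_match; single-exon transcripts key
# on their exact exon coordinates
.chainKey <- function(x) {
  ex <- exonRanges(x)
  vapply(seq_along(ex), function(i) {
    g <- ex[[i]]
    chr <- as.character(seqnames(g))[1]
    str <- as.character(strand(g))[1]
    if (length(g) == 1L)
      paste0(chr, str, "se:", start(g), "-", end(g))
    else
      paste0(chr, str, "ic:",
             paste(end(g)[-length(g)] + 1L, start(g)[-1L] - 1L,
                   sep = "-", collapse = ","))
  }, "")
}

#' Match assembled transcripts to identical reference transcripts
#'
#' @param ts,ref \code{TranscriptSet}s.
#' @return Character vector: for each transcript of \code{ts}, the id of a
#'   reference transcript with identical intron chain (identical exon for
#'   single-exon models), or NA.
#' @export
matchKnownTranscripts <- function(ts, ref) {
  m <- match(.chainKey(ts), .chainKey(ref))
  out <- txIds(ref)[m]
  names(out) <- txIds(ts)
  out
}

#' Extract novel long transcripts
#'
#' Keeps transcripts class-coded \code{u}, \code{i} or \code{x} whose
#' spliced length is at least \code{minLength} (200 bp by default; the
#' boundary is inclusive). Single-exon transcripts are retained here; the
#' exon-count filter belongs to the identification cascade.
#'
#' @param ts Assembled transcripts.
#' @param codes Class codes from \code{\link{assignClassCodes}} (computed
#'   when missing).
#' @param ref Reference annotation, used only when \code{codes} is missing.
#' @param minLength Minimum spliced length in bp.
#' @return A \code{TranscriptSet} of novel transcripts.
#' @export
extractNovel <- function(ts, codes = NULL, ref = NULL, minLength = 200) {
  if (is.null(codes)) {
    if (is.null(ref)) stop("either codes or ref must be supplied")
    codes <- assignClassCodes(ts, ref)
  }
  keep <- codes %in% c("u", "i", "x") & txLengths(ts) >= minLength
  ts[which(keep)]
}
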