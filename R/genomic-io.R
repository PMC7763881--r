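#' Read a GTF file into a TranscriptSet
#'
#' Exon rows sharing a \code{transcript_id} are grouped into transcript
#' models; CDS rows, when present, are attached per transcript. Coordinates
#' are kept in the native GTF convention (1-based inclusive).
#'
#' @param path Path to a GTF file.
#' @return A \code{TranscriptSet}.
#' @export
readGtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  tid <- if (is.null(gr$transcript_id)) rep(NA_character_, length(gr))
    else as.character(gr$transcript_id)
  if (anyNA(tid) || any(tid == ""))
    stop("GTF format error: missing transcript_id attribute on record(s) ",
         paste(head(which(is.na(tid) | tid == ""), 5), collapse = ", "),
         call. = FALSE)
  gid <- as.character(gr$gene_id)
  if (is.null(gr$gene_id)) gid <- tid
  gid[is.na(gid)] <- tid[is.na(gid)]
  isExon <- gr$type == "exon"
  exons <- S4Vectors::split(granges(gr)[isExon], tid[isExon])
  geneByTx <- gid[isExon][!duplicated(tid[isExon])]
  names(geneByTx) <- tid[isExon][!duplicated(tid[isExon])]
  cds <- GRangesList()
  if (any(!isExon)) {
    cds <- S4Vectors::split(granges(gr)[!isExon], tid[!isExon])
    cds <- GRangesList(lapply(cds, sort))
  }
  TranscriptSet(as.list(exons), geneIds = geneByTx[names(exons)], cds = cds)
}

#' @importFrom GenomicRanges granges
NULL

#' Write a TranscriptSet to GTF
#'
#' Round-trips with \code{\link{readGtf}}: coordinates and transcript/gene
#' ids are preserved exactly.
#'
#' @param ts A \code{TranscriptSet}.
#' @param path Output path.
#' @export
writeGtf <- function(ts, path) {
  ex <- unlist(exonRanges(ts), use.names = FALSE)
  f <- rep(seq_along(ts@exons), lengths(ts@exons))
  mcols(ex)$type <- "exon"
  mcols(ex)$transcript_id <- txIds(ts)[f]
  mcols(ex)$gene_id <- geneIds(ts)[f]
  out <- ex
  cds <- cdsRanges(ts)
  if (length(cds)) {
    cd <- unlist(cds, use.names = FALSE)
    fc <- rep(seq_along(cds), lengths(cds))
    idx <- match(names(cds), txIds(ts))
    mcols(cd)$type <- "CDS"
    mcols(cd)$transcript_id <- names(cds)[fc]
    mcols(cd)$gene_id <- geneIds(ts)[idx][fc]
    # reading-frame phase per CDS chunk, in translation order
    phase <- unlist(lapply(seq_along(cds), function(i) {
      g <- cds[[i]]
      w <- width(g)
      if (as.character(strand(g))[1] == "-") w <- rev(w)
      ph <- (3L - cumsum(c(0L, w[-length(w)])) %% 3L) %% 3L
      if (as.character(strand(g))[1] == "-") rev(ph) else ph
    }), use.names = FALSE)
    mcols(cd)$phase <- as.integer(phase)
    mcols(ex)$phase <- NA_integer_
    out <- c(ex, cd)
  }
  out <- out[order(match(out$transcript_id, txIds(ts)), start(out))]
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open on disk; the returned \code{GRanges} uses the
#' package-wide 1-based inclusive convention (the conversion is performed
#' by \code{rtracklayer}). Unstranded records keep strand \code{*}.
#'
#' @param path Path to a BED file.
#' @return A \code{GRanges}.
#' @export
readBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (any(width(gr) < 1L))
    stop("BED validation error: record(s) with start >= end: ",
         paste(head(which(width(gr) < 1L), 5), collapse = ", "), call. = FALSE)
  gr
}

#' Write intervals to BED
#' @param gr A \code{GRanges} (1-based inclusive).
#' @param path Output path.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Overlap in base pairs between two intervals
#'
#' Strand-blind overlap width; 0 for disjoint or different-chromosome
#' intervals (adjacent inclusive intervals share no base). Vectorized with
#' the usual recycling over pairs.
#'
#' @param a,b \code{GRanges} of equal length (or length 1).
#' @return Integer vector of overlap widths in bp.
#' @export
overlapBp <- function(a, b) {
  n <- max(length(a), length(b))
  ia <- rep(seq_along(a), length.out = n)
  ib <- rep(seq_along(b), length.out = n)
  same <- as.character(seqnames(a))[ia] == as.character(seqnames(b))[ib]
  ov <- pmin(end(a)[ia], end(b)[ib]) - pmax(start(a)[ia], start(b)[ib]) + 1L
  as.integer(ifelse(same, pmax(0L, ov), 0L))
}

#' Extract spliced transcript sequences from a genome
#'
#' Concatenates exon sequences in genomic order and reverse-complements
#' minus-strand transcripts.
#'
#' @param genome A named \code{DNAStringSet} of chromosome sequences.
#' @param ts A \code{TranscriptSet}.
#' @return A \code{DNAStringSet} named by transcript id.
#' @export
extractTxSeqs <- function(genome, ts) {
  ex <- exonRanges(ts)
  ul <- unlist(ex, use.names = FALSE)
  txf <- rep(seq_along(ex), lengths(ex))
  chrs <- as.character(seqnames(ul))
  missing <- setdiff(unique(chrs), names(genome))
  if (length(missing))
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  pieces <- character(length(ul))
  for (chr in unique(chrs)) {
    idx <- which(chrs == chr)
    pieces[idx] <- as.character(Biostrings::extractAt(
      genome[[chr]], IRanges(start(ul)[idx], end(ul)[idx])))
  }
  out <- Biostrings::DNAStringSet(
    vapply(split(pieces, txf), paste, "", collapse = ""))
  minus <- as.character(strand(txSpans(ts))) == "-"
  if (any(minus)) out[minus] <- Biostrings::reverseComplement(out[minus])
  names(out) <- txIds(ts)
  out
}

# Map a single interval on the spliced transcript to genomic coordinates
# (used when planting CDS annotations). `starts`/`ends` are genomic exon
# coordinates in ascending order; `s`..`e` are 1-based spliced positions.
# Returns a 2-column matrix of genomic (start, end) rows, ascending.
splicedToGenomic <- function(s, e, starts, ends, minus) {
  w <- ends - starts + 1L
  ord <- if (minus) rev(seq_along(w)) else seq_along(w)
  hi <- cumsum(w[ord])          # spliced end of each exon, transcript order
  lo <- hi - w[ord] + 1L        # spliced start
  hit <- which(hi >= s & lo <= e)
  gs <- ge <- integer(length(hit))
  for (k in seq_along(hit)) {
    j <- hit[k]; i <- ord[j]
    a <- max(s, lo[j]); b <- min(e, hi[j])   # spliced slice in this exon
    if (!minus) {
      gs[k] <- starts[i] + (a - lo[j])
      ge[k] <- starts[i] + (b - lo[j])
    } else {
      ge[k] <- ends[i] - (a - lo[j])
      gs[k] <- ends[i] - (b - lo[j])
    }
  }
  m <- cbind(gs, ge)
  m[order(m[, 1]), , drop = FALSE]
}
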