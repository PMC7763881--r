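#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom BiocGenerics width start end strand
#' @importFrom GenomicRanges GRanges GRangesList seqnames findOverlaps
#'   countOverlaps pintersect granges ranges
#' @importFrom IRanges IRanges
#' @importFrom utils head tail
#' @importFrom stats setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Transcript models as exon chains
#'
#' A \code{TranscriptSet} holds a set of transcript models, each an ordered
#' chain of exons on a single chromosome and strand, together with the
#' transcript-to-gene mapping and (for coding transcripts) CDS ranges.
#' Coordinates are 1-based inclusive throughout (GTF convention); transcript
#' length always means exonic (spliced) length.
#'
#' @slot exons A \code{GRangesList}, one element per transcript, named by
#'   transcript id; exons sorted by ascending start and non-overlapping.
#' @slot txData A \code{DataFrame} with columns \code{transcript_id} and
#'   \code{gene_id}, parallel to \code{exons}.
#' @slot cds A \code{GRangesList} of CDS ranges, named by transcript id;
#'   may cover only a subset of transcripts (non-coding ones carry none).
#'
#' @export
setClass("TranscriptSet",
  representation(exons = "GRangesList", txData = "DataFrame",
                 cds = "GRangesList"))

setValidity("TranscriptSet", function(object) {
  msg <- character()
  ex <- object@exons
  td <- object@txData
  if (length(ex) != nrow(td))
    msg <- c(msg, "exons and txData must be parallel")
  if (!all(c("transcript_id", "gene_id") %in% colnames(td)))
    msg <- c(msg, "txData needs transcript_id and gene_id columns")
  if (length(ex) && !identical(names(ex), as.character(td$transcript_id)))
    msg <- c(msg, "names(exons) must equal txData$transcript_id")
  if (any(lengths(ex) == 0L))
    msg <- c(msg, "every transcript needs at least one exon")
  if (length(ex)) {
    nchr <- lengths(unique(S4Vectors::runValue(seqnames(ex))))
    nstr <- lengths(unique(S4Vectors::runValue(strand(ex))))
    if (any(nchr != 1L))
      msg <- c(msg, sprintf("transcript(s) with exons on multiple chromosomes: %s",
                            paste(head(names(ex)[nchr != 1L], 3), collapse = ", ")))
    if (any(nstr != 1L))
      msg <- c(msg, sprintf("transcript(s) with exons on mixed strands: %s",
                            paste(head(names(ex)[nstr != 1L], 3), collapse = ", ")))
    ul <- unlist(ex, use.names = FALSE)
    f <- rep(seq_along(ex), lengths(ex))
    same <- f[-1L] == f[-length(f)]
    ok_sorted <- length(ul) < 2L ||
      all(start(ul)[-1L][same] > end(ul)[-length(f)][same])
    if (!ok_sorted)
      msg <- c(msg, "exons must be sorted ascending and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TranscriptSet
#'
#' @param exons \code{GRangesList} of exon ranges, named by transcript id.
#' @param geneIds Character vector of gene ids, parallel to \code{exons}.
#' @param cds Optional \code{GRangesList} of CDS ranges named by transcript id.
#' @return A \code{TranscriptSet}.
#' @export
TranscriptSet <- function(exons, geneIds, cds = GRangesList()) {
  if (!is(exons, "GRangesList")) exons <- GRangesList(exons, compress = TRUE)
  nms <- names(exons)
  if (length(exons)) {
    # sort exons within each transcript by ascending start (strand-blind)
    ul <- unlist(exons, use.names = FALSE)
    f <- rep(seq_along(exons), lengths(exons))
    o <- order(f, start(ul))
    exons <- BiocGenerics::relist(ul[o],
                                  IRanges::PartitioningByEnd(
                                    cumsum(lengths(exons))))
    names(exons) <- nms
  }
  td <- DataFrame(transcript_id = nms %||% character(),
                  gene_id = as.character(geneIds))
  new("TranscriptSet", exons = exons, txData = td, cds = cds)
}

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object@exons), "transcripts from",
      length(unique(object@txData$gene_id)), "genes\n")
  if (length(object@exons)) {
    chr <- unique(as.character(seqnames(unlist(object@exons, use.names = FALSE))))
    cat("  chromosomes:", paste(head(sort(chr), 8), collapse = " "),
        if (length(chr) > 8) "..." else "", "\n")
    cat("  with CDS:", length(object@cds), "transcripts\n")
  }
})

setMethod("length", "TranscriptSet", function(x) length(x@exons))

setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@exons))
  keep <- names(x@exons)[i]
  new("TranscriptSet", exons = x@exons[i], txData = x@txData[i, , drop = FALSE],
      cds = x@cds[names(x@cds) %in% keep])
})

#' Sample-annotated count matrix
#'
#' Thin \code{SummarizedExperiment} subclass for feature-by-sample read
#' counts with per-feature effective lengths (bp) and a sample design
#' mapping each library to an experimental group (\code{CC}, \code{HH},
#' \code{F1}, \code{S14}) and a replicate index.
#'
#' @export
setClass("AlloCountSet", contains = "SummarizedExperiment")

setValidity("AlloCountSet", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "needs a 'counts' assay")
  else if (any(SummarizedExperiment::assay(object, "counts") < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  rd <- SummarizedExperiment::rowData(object)
  if (!"length" %in% colnames(rd)) msg <- c(msg, "rowData needs a 'length' column")
  else if (any(rd$length <= 0)) msg <- c(msg, "feature lengths must be > 0")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("group", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData needs 'group' and 'replicate' columns")
  else if (any(is.na(cd$group)))
    msg <- c(msg, "every sample needs a group")
  if (length(msg)) msg else TRUE
})

#' Construct an AlloCountSet
#'
#' @param counts Numeric matrix of non-negative counts, features x samples.
#' @param lengths Per-feature effective lengths in bp.
#' @param group Character vector of group labels per sample.
#' @param replicate Integer replicate index per sample.
#' @return An \code{AlloCountSet}.
#' @export
AlloCountSet <- function(counts, lengths, group, replicate = NULL) {
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(group), group, FUN = seq_along)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = as.matrix(counts)),
    rowData = DataFrame(length = as.numeric(lengths)),
    colData = DataFrame(group = as.character(group),
                        replicate = as.integer(replicate),
                        row.names = colnames(counts)))
  new("AlloCountSet", se)
}

setMethod("show", "AlloCountSet", function(object) {
  cat("AlloCountSet:", nrow(object), "features x", ncol(object), "samples\n")
  cat("  groups:", paste(sprintf("%s(%d)", names(table(object$group)),
                                 table(object$group)), collapse = " "), "\n")
})
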