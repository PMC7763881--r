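#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txSpans", function(x) standardGeneric("txSpans"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txLengths", function(x) standardGeneric("txLengths"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("exonCounts", function(x) standardGeneric("exonCounts"))

#' @rdname AlloCountSet-accessors
#' @export
setGeneric("featureLengths", function(x) standardGeneric("featureLengths"))
#' @rdname AlloCountSet-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Accessors for TranscriptSet
#'
#' \code{txIds}/\code{geneIds} return the transcript and gene identifiers;
#' \code{exonRanges} and \code{cdsRanges} the underlying \code{GRangesList}s;
#' \code{txSpans} one \code{GRanges} per transcript covering min(start) to
#' max(end); \code{txLengths} the spliced (exonic) length in bp;
#' \code{exonCounts} the number of exons.
#'
#' @param x A \code{TranscriptSet}.
#' @name TranscriptSet-accessors
NULL

#' @rdname TranscriptSet-accessors
setMethod("txIds", "TranscriptSet", function(x) as.character(x@txData$transcript_id))
#' @rdname TranscriptSet-accessors
setMethod("geneIds", "TranscriptSet", function(x) as.character(x@txData$gene_id))
#' @rdname TranscriptSet-accessors
setMethod("exonRanges", "TranscriptSet", function(x) x@exons)
#' @rdname TranscriptSet-accessors
setMethod("cdsRanges", "TranscriptSet", function(x) x@cds)
#' @rdname TranscriptSet-accessors
setMethod("txSpans", "TranscriptSet", function(x) {
  ex <- x@exons
  if (!length(ex)) return(GRanges())
  ul <- unlist(ex, use.names = FALSE)
  f <- rep(seq_along(ex), lengths(ex))
  sp <- GRanges(
    seqnames = as.character(seqnames(ul))[!duplicated(f)],
    IRanges(start = vapply(split(start(ul), f), min, 0L),
            end = vapply(split(end(ul), f), max, 0L)),
    strand = as.character(strand(ul))[!duplicated(f)])
  names(sp) <- names(ex)
  sp
})
#' @rdname TranscriptSet-accessors
setMethod("txLengths", "TranscriptSet", function(x) {
  out <- vapply(width(x@exons), sum, 0L)
  names(out) <- names(x@exons)
  out
})
#' @rdname TranscriptSet-accessors
setMethod("exonCounts", "TranscriptSet", function(x) {
  out <- lengths(x@exons)
  names(out) <- names(x@exons)
  out
})

#' Accessors for AlloCountSet
#'
#' @param x An \code{AlloCountSet}.
#' @name AlloCountSet-accessors
NULL

#' @rdname AlloCountSet-accessors
setMethod("featureLengths", "AlloCountSet", function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$length, rownames(x)))
#' @rdname AlloCountSet-accessors
setMethod("sampleGroups", "AlloCountSet", function(x)
  stats::setNames(x$group, colnames(x)))

#' Extract the count assay
#' @param x An \code{AlloCountSet}.
#' @return Numeric matrix of counts.
#' @export
countsOf <- function(x) SummarizedExperiment::assay(x, "counts")
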