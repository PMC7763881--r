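#' Predict cis target genes within a genomic window
#'
#' Every protein-coding gene whose span overlaps, or lies within
#' \code{window} bp of, the lncRNA span is a potential target. Distance is
#' the span-to-span gap (0 when overlapping), signed by the coding gene's
#' position on the forward-strand axis (negative = upstream of the lncRNA
#' span).
#'
#' @param lncSpans Named \code{GRanges} of lncRNA-gene spans.
#' @param pcgSpans Named \code{GRanges} of coding-gene spans.
#' @param window Window size in bp (default 100000).
#' @return \code{DataFrame}: lncrna_gene, pcg, distance, relation.
#' @export
findCisTargets <- function(lncSpans, pcgSpans, window = 1e5) {
  h <- findOverlaps(lncSpans, pcgSpans, maxgap = window,
                    ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  ls <- start(lncSpans)[qi]; le <- end(lncSpans)[qi]
  ps <- start(pcgSpans)[si]; pe <- end(pcgSpans)[si]
  dist <- integer(length(qi))
  dist[ps > le] <- (ps - le - 1L)[ps > le]     # gap, downstream on + axis
  dist[pe < ls] <- (pe - ls + 1L)[pe < ls]     # gap, upstream: negative
  keep <- abs(dist) <= window
  rel <- ifelse(dist == 0, "overlapping",
                ifelse(dist > 0, "downstream", "upstream"))
  DataFrame(lncrna_gene = names(lncSpans)[qi][keep],
            pcg = names(pcgSpans)[si][keep],
            distance = dist[keep], relation = rel[keep])
}

#' Expression correlation of lncRNA-target pairs
#'
#' Pearson correlation of log2(TPM + 1) across all samples, with the usual
#' two-sided t-test on n - 2 degrees of freedom; a pair passes at p < 0.05.
#' Zero-variance series leave r undefined and the pair failing.
#'
#' @param pairs \code{DataFrame} from \code{\link{findCisTargets}}.
#' @param tpm TPM matrix containing both lncRNA genes and coding genes as
#'   rows.
#' @return The pairs with added pearson_r, r_pvalue, passes.
#' @export
correlatePairs <- function(pairs, tpm) {
  lt <- log2(tpm + 1)
  n <- ncol(lt)
  r <- p <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$lncrna_gene[i]; b <- pairs$pcg[i]
    if (!(a %in% rownames(lt)) || !(b %in% rownames(lt))) next
    x <- lt[a, ]; y <- lt[b, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r[i] <- stats::cor(x, y)
    if (abs(r[i]) >= 1) { p[i] <- 0; next }
    tt <- r[i] * sqrt((n - 2) / (1 - r[i]^2))
    p[i] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  pairs$pearson_r <- r
  pairs$r_pvalue <- p
  pairs$passes <- !is.na(p) & p < 0.05
  pairs
}

#' Hypergeometric term enrichment of target genes
#'
#' Upper-tail hypergeometric test per term: with N background genes, K of
#' them carrying the term, and n targets of which k carry it,
#' p = P(X >= k). BH correction across terms; results sorted by p with the
#' top 10 terms at p < 0.05 flagged.
#'
#' @param targets Character vector of target gene ids (subset of
#'   background).
#' @param background Character vector of background gene ids.
#' @param termMap data.frame with columns \code{gene} and \code{term}.
#' @return \code{DataFrame}: term, k, K, n, N, p, padj, top.
#' @export
hypergeomEnrich <- function(targets, background, termMap) {
  targets <- unique(targets); background <- unique(background)
  if (!length(targets)) stop("empty target set")
  if (!all(targets %in% background))
    stop("targets must be a subset of the background")
  termMap <- termMap[termMap$gene %in% background, , drop = FALSE]
  N <- length(background); n <- length(targets)
  terms <- unique(termMap$term)
  K <- vapply(terms, function(t)
    length(unique(termMap$gene[termMap$term == t])), 0L)
  k <- vapply(terms, function(t)
    sum(targets %in% termMap$gene[termMap$term == t]), 0L)
  p <- unname(stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE))
  padj <- bhAdjust(p)
  o <- order(p, terms)
  res <- DataFrame(term = terms[o], k = unname(k)[o], K = unname(K)[o],
                   n = n, N = N, p = p[o], padj = padj[o])
  res$top <- seq_len(nrow(res)) <= 10 & res$p < 0.05
  res
}
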