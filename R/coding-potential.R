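# Fickett (1982) TESTCODE lookup tables, as used by CPAT-style scorers.
# Probability rows are ordered by ascending parameter bin; position bins are
# [0,1.1), [1.1,1.2), ..., [1.8,1.9), [1.9,Inf); content bins are [0,0.17),
# [0.17,0.19), ..., [0.31,0.33), [0.33,1].
.fickett <- list(
  posBreaks = c(1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9),
  posProb = rbind(
    A = c(0.22, 0.20, 0.34, 0.45, 0.68, 0.58, 0.93, 0.84, 0.68, 0.94),
    C = c(0.23, 0.30, 0.33, 0.51, 0.48, 0.66, 0.81, 0.70, 0.70, 0.80),
    G = c(0.08, 0.08, 0.16, 0.27, 0.48, 0.53, 0.64, 0.74, 0.88, 0.90),
    T = c(0.09, 0.09, 0.20, 0.54, 0.44, 0.69, 0.68, 0.91, 0.97, 0.97)),
  posWeight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
  contBreaks = c(0.17, 0.19, 0.21, 0.23, 0.25, 0.27, 0.29, 0.31, 0.33),
  contProb = rbind(
    A = c(0.21, 0.81, 0.65, 0.67, 0.49, 0.62, 0.55, 0.44, 0.49, 0.28),
    C = c(0.31, 0.39, 0.44, 0.43, 0.59, 0.59, 0.64, 0.51, 0.64, 0.82),
    G = c(0.29, 0.33, 0.41, 0.41, 0.73, 0.64, 0.64, 0.47, 0.54, 0.40),
    T = c(0.58, 0.51, 0.69, 0.56, 0.75, 0.55, 0.40, 0.39, 0.24, 0.28)),
  contWeight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14))

#' Longest open reading frame on the forward strand
#'
#' Scans all three forward frames for the longest ATG..{TAA,TAG,TGA} open
#' reading frame; the reported length includes the stop codon. Assembled
#' transcripts are already stranded, so the reverse strand is not searched.
#'
#' @param seqs Character vector or \code{DNAStringSet}.
#' @return A data.frame with \code{orf_length} (0 when no ORF), \code{frame}
#'   (0-based, NA when no ORF) and \code{start} (1-based position of the A of
#'   ATG, NA when no ORF).
#' @export
findLongestOrf <- function(seqs) {
  seqs <- as.character(seqs)
  out <- data.frame(orf_length = integer(length(seqs)),
                    frame = NA_integer_, start = NA_integer_)
  for (i in seq_along(seqs)) {
    s <- toupper(seqs[i])
    if (!nzchar(s)) next
    st <- gregexpr("(?=ATG)", s, perl = TRUE)[[1L]]
    sp <- gregexpr("(?=TAA|TAG|TGA)", s, perl = TRUE)[[1L]]
    if (st[1L] == -1L || sp[1L] == -1L) next
    best <- 0L; bestf <- NA_integer_; bests <- NA_integer_
    for (f in 0:2) {
      stf <- st[(st - 1L) %% 3L == f]
      spf <- sp[(sp - 1L) %% 3L == f]
      spf <- spf[spf + 2L <= nchar(s)]
      if (!length(stf) || !length(spf)) next
      # first in-frame stop at or beyond start+3
      j <- findInterval(stf + 2L, spf) + 1L
      ok <- j <= length(spf)
      if (!any(ok)) next
      len <- spf[j[ok]] - stf[ok] + 3L
      k <- which.max(len)
      if (len[k] > best) { best <- len[k]; bestf <- f; bests <- stf[ok][k] }
    }
    out$orf_length[i] <- best
    out$frame[i] <- bestf
    out$start[i] <- bests
  }
  rownames(out) <- names(seqs)
  out
}

#' Fickett TESTCODE statistic
#'
#' Combines four codon-position bias parameters (for each base, the maximal
#' over minimal-plus-one count across the three codon positions) and four
#' base-content parameters through the published lookup tables. Coding
#' sequences show strong period-3 position bias and score high.
#'
#' @param seqs Character vector or \code{DNAStringSet}; each at least 200 nt.
#' @return Numeric scores.
#' @export
fickettScore <- function(seqs) {
  seqs <- as.character(seqs)
  if (any(nchar(seqs) < 200))
    stop("Fickett score undefined for sequences shorter than 200 nt")
  tb <- .fickett
  vapply(seqs, function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    phase <- (seq_along(ch) - 1L) %% 3L
    score <- 0
    n <- length(ch)
    for (b in c("A", "C", "G", "T")) {
      cnt <- c(sum(ch == b & phase == 0L), sum(ch == b & phase == 1L),
               sum(ch == b & phase == 2L))
      posPar <- max(cnt) / (min(cnt) + 1)
      contPar <- sum(cnt) / n
      pi <- findInterval(posPar, tb$posBreaks) + 1L
      ci <- findInterval(contPar, tb$contBreaks) + 1L
      score <- score + tb$posProb[b, pi] * tb$posWeight[b] +
        tb$contProb[b, ci] * tb$contWeight[b]
    }
    score
  }, 0, USE.NAMES = FALSE)
}

#' Train an in-frame hexamer usage table
#'
#' Counts in-frame (step 3) hexamers over a coding and a noncoding training
#' set, applies add-one smoothing, and normalizes each model to sum to one.
#'
#' @param codingSeqs,noncodingSeqs \code{DNAStringSet} or character vectors;
#'   at least 10 sequences per class.
#' @return A \code{hexamerTable}: list with \code{coding} and \code{noncoding}
#'   frequency vectors over the 4096 hexamers and their \code{logratio}.
#' @export
trainHexamerTable <- function(codingSeqs, noncodingSeqs) {
  if (length(codingSeqs) < 10L || length(noncodingSeqs) < 10L)
    stop("hexamer training needs at least 10 sequences per class")
  cnt <- function(x) {
    x <- Biostrings::DNAStringSet(x)
    x <- x[width(x) >= 6L]
    if (!length(x)) stop("hexamer training set empty after length filter")
    colSums(Biostrings::oligonucleotideFrequency(x, 6L, step = 3L))
  }
  kc <- cnt(codingSeqs) + 1
  kn <- cnt(noncodingSeqs) + 1
  out <- list(coding = kc / sum(kc), noncoding = kn / sum(kn))
  out$logratio <- log(out$coding / out$noncoding)
  class(out) <- "hexamerTable"
  out
}

#' Hexamer usage bias of a sequence
#'
#' Mean log-ratio of coding over noncoding hexamer frequency across the
#' in-frame hexamers of the longest ORF (whole sequence in frame 0 when the
#' sequence has no ORF).
#'
#' @param seqs Character vector or \code{DNAStringSet}.
#' @param table A \code{hexamerTable} from \code{\link{trainHexamerTable}}.
#' @return Numeric bias scores (0 for sequences shorter than 6 nt).
#' @export
hexamerBias <- function(seqs, table) {
  seqs <- as.character(seqs)
  orf <- findLongestOrf(seqs)
  vapply(seq_along(seqs), function(i) {
    s <- toupper(seqs[i])
    if (orf$orf_length[i] > 0)
      s <- substr(s, orf$start[i], orf$start[i] + orf$orf_length[i] - 1L)
    if (nchar(s) < 6L) return(0)
    k <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s), 6L,
                                              step = 3L)
    m <- sum(k)
    if (m == 0) return(0)
    sum(k * table$logratio[names(k)]) / m
  }, 0)
}

#' Fit the logistic coding-potential model
#'
#' Logistic regression (fitted by iteratively reweighted least squares via
#' \code{stats::glm}) of coding status on ORF length, ORF coverage, Fickett
#' score and hexamer bias; the predicted probability plays the role of a
#' CPAT-style coding probability compared against the 0.36 cutoff.
#'
#' @param features data.frame with columns \code{orf_length},
#'   \code{orf_coverage}, \code{fickett}, \code{hexamer}.
#' @param labels Logical or 0/1 vector; TRUE/1 = coding.
#' @return A \code{codingModel} (coefficient vector wrapper).
#' @export
trainCodingModel <- function(features, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("coding-model training error: labels contain a single class")
  df <- data.frame(y = labels, features[, c("orf_length", "orf_coverage",
                                            "fickett", "hexamer")])
  fit <- suppressWarnings(stats::glm(y ~ orf_length + orf_coverage + fickett +
                                       hexamer, data = df, family = stats::binomial()))
  structure(list(coef = stats::coef(fit)), class = "codingModel")
}

#' Coding probability under a fitted model
#' @param model A \code{codingModel}.
#' @param features data.frame as in \code{\link{trainCodingModel}}.
#' @return Probabilities in [0, 1].
#' @export
codingProbability <- function(model, features) {
  X <- cbind(1, as.matrix(features[, c("orf_length", "orf_coverage",
                                       "fickett", "hexamer")]))
  co <- model$coef
  co[is.na(co)] <- 0
  as.numeric(stats::plogis(X %*% co))
}

#' Consensus noncoding filter
#'
#' A transcript is called noncoding when every supplied score is strictly
#' below its tool threshold (set-intersection rule over tools; a score equal
#' to its threshold, e.g. a CPAT-style probability of exactly 0.36, is
#' coding).
#'
#' @param scores data.frame with one column per tool (e.g. \code{CPAT},
#'   \code{CPC2}, \code{PLEK}, \code{CNCI}).
#' @param thresholds Named numeric vector; default
#'   \code{c(CPC2 = 0, PLEK = 0, CNCI = 0, CPAT = 0.36)}.
#' @return Logical vector, TRUE = noncoding.
#' @export
consensusNoncoding <- function(scores,
                               thresholds = c(CPC2 = 0, PLEK = 0, CNCI = 0,
                                              CPAT = 0.36)) {
  scores <- as.data.frame(scores)
  miss <- setdiff(names(thresholds), colnames(scores))
  if (length(miss))
    stop("consensus error: missing required tool score(s): ",
         paste(miss, collapse = ", "))
  ok <- rep(TRUE, nrow(scores))
  for (tool in names(thresholds)) {
    v <- scores[[tool]]
    if (anyNA(v))
      stop("consensus error: NA score(s) for tool ", tool)
    ok <- ok & (v < thresholds[[tool]])
  }
  ok
}
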