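#' TPM normalization
#'
#' Counts are divided by feature length in kb and the resulting rates
#' rescaled so each sample sums to one million (transcripts per million).
#'
#' @param x An \code{\link{AlloCountSet}} or a count matrix (then
#'   \code{lengths} must be given).
#' @param lengths Feature lengths in bp when \code{x} is a matrix.
#' @return Matrix of TPM values, same dimensions as the counts.
#' @export
computeTpm <- function(x, lengths = NULL) {
  if (is(x, "AlloCountSet")) {
    m <- countsOf(x); lengths <- featureLengths(x)
  } else m <- as.matrix(x)
  if (is.null(lengths)) stop("feature lengths required")
  rate <- m / (lengths / 1000)
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("normalization error: all-zero sample(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  t(t(rate) / tot) * 1e6
}

#' Per-group means of an expression matrix
#' @param m Features x samples matrix.
#' @param groups Group label per sample.
#' @return Features x groups matrix of means.
#' @export
groupMeans <- function(m, groups) {
  gs <- unique(groups)
  out <- vapply(gs, function(g)
    rowMeans(m[, groups == g, drop = FALSE]), numeric(nrow(m)))
  colnames(out) <- gs
  out
}

#' Within-group replicate correlation
#'
#' Mean pairwise Pearson correlation of log2(TPM + 1) between the
#' replicates of each group. Pairs where either replicate has zero
#' variance are undefined and excluded from the mean.
#'
#' @param tpm TPM matrix.
#' @param groups Group label per sample.
#' @return Named numeric: mean r per group (NA when no defined pair).
#' @export
replicateCorrelation <- function(tpm, groups) {
  lt <- log2(tpm + 1)
  vapply(unique(groups), function(g) {
    cols <- which(groups == g)
    if (length(cols) < 2) return(NA_real_)
    rs <- c()
    for (i in seq_along(cols)[-length(cols)])
      for (j in seq((i + 1), length(cols))) {
        a <- lt[, cols[i]]; b <- lt[, cols[j]]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) next
        rs <- c(rs, stats::cor(a, b))
      }
    if (length(rs)) mean(rs) else NA_real_
  }, 0)
}

#' Mid-parent value pseudo-replicates
#'
#' Pairs parental replicates by replicate index and averages them:
#' pseudo-replicate i is (CC_i + HH_i) / 2. For counts, values are rounded
#' half-up to integers so they remain usable by the count-based test.
#'
#' @param m Features x samples matrix (counts or TPM).
#' @param groups Group label per sample.
#' @param parents The two parental group labels (default CC and HH).
#' @param type \code{"count"} (round half-up) or \code{"tpm"} (no rounding).
#' @return Matrix with one MPV pseudo-replicate column per replicate pair,
#'   named \code{MPV_1..n}.
#' @export
midParent <- function(m, groups, parents = c("CC", "HH"), type = "count") {
  a <- which(groups == parents[1]); b <- which(groups == parents[2])
  if (length(a) == 0 || length(b) == 0)
    stop("pairing error: parental group(s) absent")
  if (length(a) != length(b))
    stop("pairing error: unequal replicate numbers (",
         length(a), " vs ", length(b), ")")
  mp <- (m[, a, drop = FALSE] + m[, b, drop = FALSE]) / 2
  if (type == "count") mp <- roundHalfUp(mp)
  colnames(mp) <- paste0("MPV_", seq_along(a))
  mp
}
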