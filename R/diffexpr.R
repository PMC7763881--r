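#' Median-of-ratios size factors
#'
#' For each sample, the median across features of the ratio between the
#' feature's count and its geometric mean over samples, computed over
#' features with nonzero counts everywhere. When no such feature exists
#' the total-count ratio is used instead, with a warning.
#'
#' @param m Count matrix, features x samples.
#' @return Numeric size factors, one per sample.
#' @export
medianRatioSizeFactors <- function(m) {
  m <- as.matrix(m)
  ok <- rowSums(m > 0) == ncol(m)
  if (!any(ok)) {
    warning("no feature with nonzero counts in all samples; ",
            "falling back to total-count ratios")
    sf <- colSums(m)
    return(sf / exp(mean(log(sf))))
  }
  lg <- log(m[ok, , drop = FALSE])
  gm <- rowMeans(lg)
  apply(exp(lg - gm), 2, stats::median)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \code{padj_(i) = min_{j >= rank(i)} p_(j) * m / j}, capped at 1.
#' NA p-values are excluded from m and stay NA.
#'
#' @param p Numeric p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  m <- length(idx)
  if (m == 0) return(out)
  o <- order(p[idx])
  adj <- pmin(1, rev(cummin(rev(p[idx][o] * m / seq_len(m)))))
  out[idx[o]] <- adj
  out
}

#' Negative-binomial Wald test for a pairwise contrast
#'
#' A deliberately compact NB test: counts are normalized by
#' median-of-ratios size factors; per-feature dispersion is estimated by
#' method-of-moments on the normalized counts and shrunk halfway toward a
#' fitted mean-dispersion trend (a + b / mean); the Wald statistic is the
#' log2 fold change of normalized group means (pseudo-count 0.5) over its
#' delta-method standard error, with a two-sided normal p-value,
#' Benjamini-Hochberg correction across features, and calls at the
#' configured thresholds (both padj < alpha and |log2FC| > lfcMin are
#' required). Per-feature dispersions below the trend are raised to the
#' trend: with 3 replicates per side the method-of-moments estimate is
#' extremely noisy and its downward excursions would otherwise inflate the
#' Wald statistic. Features with zero counts in both groups get NA
#' p-values and are excluded from the correction.
#'
#' @param m Count matrix (features x samples).
#' @param groups Group label per sample.
#' @param contrast Character of length 2, \code{c(A, B)}; positive log2FC
#'   means higher in A.
#' @param alpha Adjusted-p threshold (default 1e-4).
#' @param lfcMin Absolute log2 fold-change threshold (default 2).
#' @param sizeFactors Optional precomputed size factors for the used
#'   samples.
#' @return \code{DataFrame} with feature, base_mean, log2FC, wald_p, padj,
#'   call (\code{up_in_A}/\code{down_in_A}/\code{ns}) and dispersion.
#' @export
nbWaldTest <- function(m, groups, contrast, alpha = 1e-4, lfcMin = 2,
                       sizeFactors = NULL) {
  stopifnot(length(contrast) == 2)
  if (!all(contrast %in% groups))
    stop("design error: contrast group(s) absent: ",
         paste(setdiff(contrast, groups), collapse = ", "))
  sel <- groups %in% contrast
  m <- as.matrix(m)[, sel, drop = FALSE]
  g <- groups[sel]
  if (min(table(g)) < 2) stop("need at least 2 replicates per side")
  sf <- sizeFactors %||% medianRatioSizeFactors(m)
  nm <- t(t(m) / sf)
  ia <- g == contrast[1]; ib <- g == contrast[2]
  nA <- sum(ia); nB <- sum(ib)
  meanA <- rowMeans(nm[, ia, drop = FALSE])
  meanB <- rowMeans(nm[, ib, drop = FALSE])
  varA <- apply(nm[, ia, drop = FALSE], 1, stats::var)
  varB <- apply(nm[, ib, drop = FALSE], 1, stats::var)
  baseMean <- (meanA + meanB) / 2

  # method-of-moments dispersion, pooled over both groups
  mom <- function(mu, v) ifelse(mu > 0, pmax(0, (v - mu) / mu^2), NA_real_)
  aA <- mom(meanA, varA); aB <- mom(meanB, varB)
  wA <- ifelse(is.na(aA), 0, nA - 1); wB <- ifelse(is.na(aB), 0, nB - 1)
  aHat <- ifelse(wA + wB > 0,
                 (ifelse(is.na(aA), 0, aA) * wA +
                    ifelse(is.na(aB), 0, aB) * wB) / pmax(1, wA + wB),
                 NA_real_)
  # mean-dispersion trend: alpha(mu) = a + b / mu
  usable <- which(!is.na(aHat) & baseMean > 0)
  ibm <- 1 / baseMean[usable]
  if (length(usable) >= 10 &&
      stats::sd(ibm) / mean(ibm) >= 0.1) {
    fit <- stats::lm(aHat[usable] ~ ibm)
    co <- stats::coef(fit)
    co[is.na(co)] <- 0
    aTrend <- pmax(1e-8, co[1] + co[2] / pmax(baseMean, 1e-8))
  } else if (length(usable) >= 10) {
    # means nearly coincide: the 1/mean regressor is uninformative and its
    # extrapolation unstable, so use the pooled mean dispersion
    aTrend <- rep(max(1e-8, mean(aHat[usable])), length(aHat))
  } else {
    aTrend <- rep(max(1e-8, stats::median(aHat, na.rm = TRUE)), length(aHat))
    aTrend[is.na(aTrend)] <- 0.1
  }
  # below-trend method-of-moments values are dominated by sampling noise
  # with few replicates; the trend acts as a lower bound after shrinkage
  disp <- ifelse(is.na(aHat), aTrend,
                 pmax(0.5 * aHat + 0.5 * aTrend, aTrend))

  lfc <- log2((meanA + 0.5) / (meanB + 0.5))
  vA <- (meanA + disp * meanA^2) / nA
  vB <- (meanB + disp * meanB^2) / nB
  se <- sqrt(vA / (meanA + 0.5)^2 + vB / (meanB + 0.5)^2) / log(2)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  p[meanA == 0 & meanB == 0] <- NA
  padj <- bhAdjust(p)
  call <- rep("ns", nrow(m))
  sig <- !is.na(padj) & padj < alpha
  call[sig & lfc > lfcMin] <- "up_in_A"
  call[sig & lfc < -lfcMin] <- "down_in_A"
  DataFrame(feature = rownames(m), contrast = paste(contrast, collapse = "-"),
            base_mean = baseMean, log2FC = lfc, wald_p = p, padj = padj,
            call = call, dispersion = disp, row.names = rownames(m))
}

#' Additivity classification against the mid-parent value
#'
#' Maps the DE call of a progeny-vs-MPV contrast to
#' \code{nonadditive_up} / \code{nonadditive_down} / \code{additive}.
#'
#' @param de Result of \code{\link{nbWaldTest}} for (progeny, MPV).
#' @return \code{DataFrame} with feature and class.
#' @export
classifyAdditivity <- function(de) {
  cls <- c(up_in_A = "nonadditive_up", down_in_A = "nonadditive_down",
           ns = "additive")[de$call]
  DataFrame(feature = de$feature, class = unname(cls),
            row.names = rownames(de))
}

#' Species-specific expression flags
#'
#' A feature is A-specific for a contrast (A, B) when its mean TPM in A
#' exceeds \code{tpmMin} and every replicate count in B is exactly zero
#' (and symmetrically). Species-specific expression is treated as a kind
#' of differential expression and merged into the DE calls.
#'
#' @param counts Count matrix.
#' @param tpm Matching TPM matrix.
#' @param groups Group label per sample.
#' @param contrast Character of length 2.
#' @param tpmMin Expression threshold on the expressed side (default 0.3).
#' @return Factor with levels none/A_only/B_only.
#' @export
detectSpeciesSpecific <- function(counts, tpm, groups, contrast,
                                  tpmMin = 0.3) {
  ia <- groups == contrast[1]; ib <- groups == contrast[2]
  mA <- rowMeans(tpm[, ia, drop = FALSE])
  mB <- rowMeans(tpm[, ib, drop = FALSE])
  zA <- rowSums(counts[, ia, drop = FALSE] > 0) == 0
  zB <- rowSums(counts[, ib, drop = FALSE] > 0) == 0
  out <- rep("none", nrow(counts))
  out[mA > tpmMin & zB] <- "A_only"
  out[mB > tpmMin & zA] <- "B_only"
  factor(out, levels = c("none", "A_only", "B_only"))
}

#' Merge species-specific flags into DE calls
#'
#' Features flagged A_only/B_only become up_in_A/down_in_A when the Wald
#' test did not already call them.
#'
#' @param de Result of \code{\link{nbWaldTest}}.
#' @param flags Result of \code{\link{detectSpeciesSpecific}} on the same
#'   features/contrast.
#' @return The DE \code{DataFrame} with updated calls and a
#'   \code{species_specific} column.
#' @export
mergeSpecificCalls <- function(de, flags) {
  de$species_specific <- as.character(flags)
  up <- flags == "A_only" & de$call == "ns"
  dn <- flags == "B_only" & de$call == "ns"
  de$call[up] <- "up_in_A"
  de$call[dn] <- "down_in_A"
  de
}
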