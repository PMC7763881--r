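#' Enumerate model expression profiles
#'
#' All unit-change trajectories over T ordered conditions with per-step
#' change in \{-c, ..., +c\}, in lexicographic order (most negative first),
#' numbered 0..(2c+1)^(T-1) - 1. Profile values are cumulative sums
#' starting at 0; the all-flat profile is always included (id
#' ((2c+1)^(T-1) - 1) / 2).
#'
#' @param T Number of conditions (default 3: MPV, F1, S14).
#' @param c Maximum unit change per step (default 2).
#' @return List with \code{changes} (profiles x (T-1) matrix),
#'   \code{values} (profiles x T matrix) and \code{profile_id}.
#' @export
enumerateProfiles <- function(T = 3L, c = 2L) {
  stopifnot(T >= 2L, c >= 1L)
  steps <- seq(-c, c)
  changes <- as.matrix(expand.grid(rep(list(steps), T - 1L)))
  dimnames(changes) <- NULL
  ord <- do.call(order, as.data.frame(changes))
  changes <- changes[ord, , drop = FALSE]
  values <- cbind(0L, t(apply(changes, 1L, cumsum)))
  if (T == 2L) values <- cbind(0L, changes)  # apply() would drop dims
  list(profile_id = seq_len(nrow(changes)) - 1L,
       changes = changes, values = values)
}

#' Assign genes to their best-matching model profile
#'
#' Each gene's series (mean log2(TPM+1) over the ordered conditions) is
#' re-expressed as differences from the first condition and assigned to
#' the profile with the highest Pearson correlation to the profile values.
#' Zero-variance series go to the flat profile; ties break to the lowest
#' profile id.
#'
#' @param series Genes x T matrix.
#' @param profiles From \code{\link{enumerateProfiles}}.
#' @return Integer vector of profile ids, named by gene.
#' @export
assignProfiles <- function(series, profiles) {
  series <- as.matrix(series)
  stopifnot(ncol(series) == ncol(profiles$values))
  d <- series - series[, 1L]
  flatId <- profiles$profile_id[rowSums(abs(profiles$changes)) == 0]
  pv <- t(profiles$values)
  # correlation of each gene's difference series with each profile
  suppressWarnings(cc <- stats::cor(t(d), pv))
  cc[is.na(cc)] <- -Inf
  best <- apply(cc, 1L, function(r) which(r == max(r))[1L]) # lowest id wins
  ids <- profiles$profile_id[best]
  zeroVar <- apply(d, 1L, function(x) stats::sd(x) == 0)
  ids[zeroVar] <- flatId
  names(ids) <- rownames(series)
  ids
}

#' Permutation significance of profile memberships
#'
#' For each permutation round, every gene's T values are independently
#' shuffled and genes reassigned; the expected assignment fraction per
#' profile is the mean over rounds, and the p-value the binomial upper
#' tail of the observed count. BH correction across profiles; significant
#' profiles have padj < 0.05.
#'
#' @param series Genes x T matrix (as in \code{\link{assignProfiles}}).
#' @param profiles From \code{\link{enumerateProfiles}}.
#' @param nPerm Number of permutation rounds (default 1000).
#' @param seed RNG seed for the permutations.
#' @return \code{DataFrame}: profile_id, n_assigned, expected, p, padj,
#'   significant.
#' @export
profileSignificance <- function(series, profiles, nPerm = 1000L, seed = 1L) {
  series <- as.matrix(series)
  T <- ncol(series)
  stopifnot(T >= 2L)
  n <- nrow(series)
  obs <- assignProfiles(series, profiles)
  nP <- length(profiles$profile_id)
  obsCount <- tabulate(obs + 1L, nbins = nP)
  piSum <- numeric(nP)
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      perm <- series
      for (i in seq_len(n)) perm[i, ] <- perm[i, sample.int(T)]
      pa <- assignProfiles(perm, profiles)
      piSum <- piSum + tabulate(pa + 1L, nbins = nP) / n
    }
  })
  piHat <- piSum / nPerm
  p <- stats::pbinom(obsCount - 1L, n, piHat, lower.tail = FALSE)
  padj <- bhAdjust(p)
  DataFrame(profile_id = profiles$profile_id, n_assigned = obsCount,
            expected = piHat * n, p = p, padj = padj,
            significant = padj < 0.05)
}

#' Group significant profiles into clusters
#'
#' Single-linkage grouping: significant profiles whose value vectors have
#' Pearson correlation >= \code{minCor} end up in the same cluster
#' (transitively). The flat profile has no defined correlation and always
#' forms its own cluster when significant.
#'
#' @param profiles From \code{\link{enumerateProfiles}}.
#' @param significant Logical vector (or ids) of significant profiles.
#' @param minCor Correlation threshold (default 0.7).
#' @return Integer cluster ids named by profile id (NA for non-significant
#'   profiles).
#' @export
clusterProfiles <- function(profiles, significant, minCor = 0.7) {
  ids <- profiles$profile_id
  if (is.logical(significant)) significant <- ids[significant]
  out <- rep(NA_integer_, length(ids))
  names(out) <- ids
  sig <- which(ids %in% significant)
  if (!length(sig)) return(out)
  suppressWarnings(cm <- stats::cor(t(profiles$values[sig, , drop = FALSE])))
  cm[is.na(cm)] <- -Inf
  # connected components over edges r >= minCor (single linkage)
  comp <- rep(0L, length(sig))
  cur <- 0L
  for (s in seq_along(sig)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cur
      nb <- which(cm[v, ] >= minCor & comp == 0L)
      queue <- c(queue, nb)
    }
  }
  out[sig] <- comp
  out
}
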