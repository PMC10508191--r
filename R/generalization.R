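# Discovery-to-replication generalization: error-adjusted correlation of
# effect estimates and sign-concordance binomial tests.

#' Pair discovery and replication effects at nominally significant hits
#'
#' Selects (inversion, phenotype) pairs with discovery p below `pCut`
#' (selection uses discovery p only) and joins the replication estimates.
#'
#' @param discovery,replication association data.frames (as returned by
#'   [jointInversionRegression()]) sharing `inversionId`/`phenotypeId` keys.
#' @param pCut discovery significance cut (default 0.05).
#' @return data.frame with columns `inversionId`, `phenotypeId`, `betaD`,
#'   `seD`, `pD`, `betaR`, `seR`, `pR`.
#' @export
selectPairs <- function(discovery, replication, pCut = 0.05) {
  keep <- discovery[discovery$p < pCut, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no discovery pairs below the significance cut")
  key <- function(d) paste(d$inversionId, d$phenotypeId, sep = "\r")
  idx <- match(key(keep), key(replication))
  if (anyNA(idx)) stop("replication results missing for some selected pairs")
  data.frame(inversionId = keep$inversionId, phenotypeId = keep$phenotypeId,
             betaD = keep$beta, seD = keep$se, pD = keep$p,
             betaR = replication$beta[idx], seR = replication$se[idx],
             pR = replication$p[idx], stringsAsFactors = FALSE)
}

#' Correlation of effect estimates across cohorts, adjusted for estimation
#' error
#'
#' `rRaw` is the Pearson correlation of the paired beta estimates with its
#' two-sided t-distribution p-value. Because both estimates carry sampling
#' error, `rRaw` is attenuated relative to the correlation of the true
#' effects; the adjusted estimate divides the between-cohort covariance by
#' the error-corrected standard deviations,
#' `cov(bD, bR) / sqrt((var(bD) - mean(seD^2)) * (var(bR) - mean(seR^2)))`,
#' clamped to `[-1, 1]`. When a corrected variance is non-positive the
#' adjusted value is undefined and flagged.
#'
#' @param pairs paired effect table from [selectPairs()].
#' @return A list: `rRaw`, `rAdjusted` (NA when undefined), `rP`,
#'   `adjustedDefined`, `nPairs`.
#' @export
betaCorrelation <- function(pairs) {
  n <- nrow(pairs)
  if (n < 3L) stop("need at least 3 pairs to correlate effects")
  rRaw <- stats::cor(pairs$betaD, pairs$betaR)
  tt <- stats::cor.test(pairs$betaD, pairs$betaR)
  vD <- stats::var(pairs$betaD) - mean(pairs$seD^2)
  vR <- stats::var(pairs$betaR) - mean(pairs$seR^2)
  defined <- vD > 0 && vR > 0
  rAdj <- if (defined) {
    max(-1, min(1, stats::cov(pairs$betaD, pairs$betaR) / sqrt(vD * vR)))
  } else NA_real_
  list(rRaw = rRaw, rAdjusted = rAdj, rP = tt$p.value,
       adjustedDefined = defined, nPairs = n)
}

#' Sign concordance of effect directions with a binomial test
#'
#' Counts pairs whose discovery and replication betas agree in sign (an
#' exactly zero beta counts as discordant) and tests the concordance rate
#' against 0.5 with an exact binomial tail, by default one-sided:
#' `P(X >= k | n, 0.5)`.
#'
#' @param pairs paired effect table from [selectPairs()].
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A list: `concordance`, `binomP`, `k`, `n`.
#' @export
signConcordance <- function(pairs, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- nrow(pairs)
  if (n < 1L) stop("need at least one pair")
  agree <- sign(pairs$betaD) == sign(pairs$betaR) &
    pairs$betaD != 0 & pairs$betaR != 0
  k <- sum(agree)
  p <- stats::binom.test(k, n, p = 0.5, alternative = alternative)$p.value
  list(concordance = k / n, binomP = p, k = k, n = n)
}
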