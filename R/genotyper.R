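# Similarity-score inversion genotyping: reference genotype-frequency model,
# LD-weighted scores H_k per inversion-genotype group, QC rules, tag-SNP
# fallback, and cross-method concordance.

GROUPS <- c("NN", "NI", "II")

# Hardy-Weinberg goodness of fit (1 df) from genotype counts (n0, n1, n2)
# against expectations at the estimated allele frequency.
.hweChisq <- function(counts) {
  n <- sum(counts)
  p <- (counts[2] + 2 * counts[3]) / (2 * n)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (any(expd == 0)) {
    # allele fixed: observed necessarily matches expectation
    return(list(stat = 0, p = 1, freq = p))
  }
  stat <- sum((counts - expd)^2 / expd)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       freq = p)
}

#' Build the similarity-score reference model from a phased panel
#'
#' Groups reference individuals by inversion genotype (number of inverted
#' haplotypes: NN = 0, NI = 1, II = 2) and tabulates, for every SNP, the raw
#' empirical frequency of each diploid genotype within each group (no
#' smoothing; a group with zero reference individuals gets a uniform table
#' and its count records 0). Per-SNP weights are the squared Pearson
#' correlation, across haplotypes, between the alternate-allele indicator
#' and the inverted-orientation indicator.
#'
#' @param panel a [HaplotypePanel-class] with orientation labels.
#' @param inversionId locus label stored in the model.
#' @param smoothing pseudocount added to every genotype count within a group
#'   before normalization (default 0: raw empirical frequencies, so a
#'   genotype unseen in a group contributes exactly 0 to its score).
#' @return A [ReferenceModel-class].
#' @export
buildReference <- function(panel, inversionId = "inv1", smoothing = 0) {
  stopifnot(is(panel, "HaplotypePanel"))
  orient <- panel@orientation
  if (length(unique(orient)) < 2L)
    stop("degenerate panel: all haplotypes share one orientation")
  H <- panel@haplotypes
  L <- ncol(H)
  nInd <- nrow(H) / 2L
  iA <- seq(1L, 2L * nInd, by = 2L)
  iB <- iA + 1L
  geno <- H[iA, , drop = FALSE] + H[iB, , drop = FALSE]      # nInd x L
  invCount <- (orient[iA] == "I") + (orient[iB] == "I")      # 0/1/2
  group <- factor(GROUPS[invCount + 1L], levels = GROUPS)

  freqs <- array(1 / 3, dim = c(L, 3, 3),
                 dimnames = list(panel@snpMeta$id, c("0", "1", "2"), GROUPS))
  counts <- stats::setNames(as.integer(table(group)), GROUPS)
  for (k in seq_along(GROUPS)) {
    idx <- which(group == GROUPS[k])
    if (length(idx) == 0L) next
    for (s in 0:2)
      freqs[, s + 1L, k] <- (colSums(geno[idx, , drop = FALSE] == s) +
                               smoothing) / (length(idx) + 3 * smoothing)
  }

  z <- as.numeric(orient == "I")
  w <- apply(H, 2, function(col) {
    if (stats::sd(col) == 0) return(0)
    stats::cor(col, z)^2
  })
  new("ReferenceModel",
      inversionId = inversionId,
      snpMeta = panel@snpMeta,
      freqs = freqs,
      weights = unname(w),
      groupCounts = counts)
}

#' Similarity scores of one sample against a reference model
#'
#' For each inversion-genotype group k, computes the LD-weighted similarity
#' \deqn{H_k = \frac{\sum_{i} \sum_{s \in \{0,1,2\}} P_i(s)\, f_{k,i}(s)\,
#' \rho_i^2}{\sum_{i} p_i^2}}
#' over the SNPs shared between the sample and the reference and not masked
#' missing, where `P_i` is the sample's genotype posterior at SNP i and
#' `p_i = max_s P_i(s)` its certainty. SNPs missing in the sample enter
#' neither numerator nor denominator.
#'
#' @param post L x 3 matrix of genotype posteriors (rows may be all-NA for
#'   missing SNPs), with rows aligned to the model's SNPs, or a
#'   [CohortGenotypes-class] together with `sample`.
#' @param ref a [ReferenceModel-class].
#' @param sample sample index when `post` is a cohort object.
#' @param normalization denominator of the score: `"certainty"` (the
#'   standard `sum(p_i^2)`) or `"weighted"` (`sum(p_i * rho_i^2)`, which
#'   bounds every score by 1 even when low-weight SNPs dominate).
#' @return Named numeric of length 3 (`NN`, `NI`, `II`) with attribute
#'   `nSnpsUsed`.
#' @export
scoreSample <- function(post, ref, sample = NULL,
                        normalization = c("certainty", "weighted")) {
  normalization <- match.arg(normalization)
  stopifnot(is(ref, "ReferenceModel"))
  if (is(post, "CohortGenotypes")) {
    stopifnot(!is.null(sample))
    miss <- post@missing[sample, ]
    post <- post@posteriors[sample, , , drop = TRUE]
    post[miss, ] <- NA_real_
  }
  post <- as.matrix(post)
  if (nrow(post) != nSnps(ref))
    stop("posterior rows must align with reference SNPs")
  used <- stats::complete.cases(post)
  if (!any(used))
    stop("no usable SNPs shared between sample and reference")
  P <- post[used, , drop = FALSE]
  w <- ref@weights[used]
  pmax_i <- apply(P, 1, max)
  denom <- switch(normalization,
                  certainty = sum(pmax_i^2),
                  weighted = sum(pmax_i * w))
  scores <- vapply(seq_along(GROUPS), function(k) {
    Fk <- ref@freqs[used, , k, drop = FALSE][, , 1, drop = FALSE]
    dim(Fk) <- dim(P)
    sum(w * rowSums(P * Fk)) / denom
  }, numeric(1))
  names(scores) <- GROUPS
  attr(scores, "nSnpsUsed") <- sum(used)
  scores
}

#' Call an inversion genotype from similarity scores with QC
#'
#' The call is the group with the maximum score, accepted only when at least
#' `minSnps` SNPs entered the score and the top score exceeds the runner-up
#' by at least `minDiff`; an exact tie on the top score is a no-call. Failed
#' QC yields a missing genotype and dosage with per-criterion flags.
#'
#' @param scores named numeric of the three group scores (from
#'   [scoreSample()]).
#' @param nSnpsUsed number of SNPs that entered the score (taken from the
#'   `scores` attribute when omitted).
#' @param minSnps minimum SNP call rate (default 15).
#' @param minDiff minimum top-minus-second score difference (default 0.1).
#' @return One-row data.frame: `HNN`, `HNI`, `HII`, `genotype` (NA when not
#'   callable), `dosage`, `nSnpsUsed`, `scoreDiff`, `qcPass`, and flags
#'   `failCallRate`, `failScoreDiff`, `failTie`.
#' @export
callGenotype <- function(scores, nSnpsUsed = attr(scores, "nSnpsUsed"),
                         minSnps = 15L, minDiff = 0.1) {
  stopifnot(length(scores) == 3L, all(is.finite(scores)))
  ord <- order(scores, decreasing = TRUE)
  diff <- scores[ord[1]] - scores[ord[2]]
  tie <- diff == 0
  failCallRate <- nSnpsUsed < minSnps
  failScoreDiff <- diff < minDiff
  pass <- !failCallRate && !failScoreDiff && !tie
  geno <- if (pass) GROUPS[ord[1]] else NA_character_
  data.frame(
    HNN = unname(scores["NN"]), HNI = unname(scores["NI"]),
    HII = unname(scores["II"]),
    genotype = geno,
    dosage = if (pass) ord[1] - 1L else NA_integer_,
    nSnpsUsed = as.integer(nSnpsUsed),
    scoreDiff = unname(diff),
    qcPass = pass,
    failCallRate = failCallRate,
    failScoreDiff = failScoreDiff,
    failTie = tie,
    stringsAsFactors = FALSE
  )
}

#' Call inversion genotypes for a whole cohort
#'
#' @param cohort a [CohortGenotypes-class].
#' @param ref a [ReferenceModel-class].
#' @param minSnps,minDiff QC thresholds, see [callGenotype()].
#' @param normalization score denominator, see [scoreSample()].
#' @return A list: `calls` (data.frame, one row per sample with `sampleId`
#'   first) and `callability` (fraction of samples passing QC).
#' @export
callCohort <- function(cohort, ref, minSnps = 15L, minDiff = 0.1,
                       normalization = "certainty") {
  stopifnot(is(cohort, "CohortGenotypes"))
  n <- dim(cohort@posteriors)[1]
  if (n == 0L) stop("empty cohort")
  rows <- lapply(seq_len(n), function(j) {
    sc <- scoreSample(cohort, ref, sample = j, normalization = normalization)
    callGenotype(sc, minSnps = minSnps, minDiff = minDiff)
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  calls <- cbind(sampleId = cohort@sampleIds, calls,
                 stringsAsFactors = FALSE)
  list(calls = calls, callability = mean(calls$qcPass))
}

#' Tag-SNP rule constructor
#'
#' A tag SNP is a SNP whose alleles are in high LD (haplotype r^2 above
#' `minR2`) with the inversion orientation, so the inversion genotype can be
#' read off the SNP genotype.
#'
#' @param inversionId locus label.
#' @param snpId the tag SNP identifier.
#' @param invertedAllele which allele is phased with the inverted
#'   orientation: `"alt"` or `"ref"`.
#' @param minR2 the LD threshold the rule was selected at (default 0.9).
#' @param r2 optionally, the observed haplotype r^2.
#' @return A one-row data.frame rule.
#' @export
tagSnpRule <- function(inversionId, snpId, invertedAllele,
                       minR2 = 0.9, r2 = NA_real_) {
  stopifnot(minR2 > 0, minR2 <= 1,
            invertedAllele %in% c("ref", "alt"))
  data.frame(inversionId = inversionId, snpId = snpId,
             invertedAllele = invertedAllele, minR2 = minR2, r2 = r2,
             stringsAsFactors = FALSE)
}

#' Select tag SNPs from a phased panel
#'
#' Screens every panel SNP for haplotype r^2 with the inversion orientation
#' and returns rules for those at or above `minR2`, sorted by descending
#' r^2, each annotated with the allele phased with the inverted orientation.
#'
#' @param panel a [HaplotypePanel-class].
#' @param minR2 LD threshold (default 0.9).
#' @param inversionId locus label copied into the rules.
#' @return A data.frame of tag-SNP rules (possibly zero rows).
#' @export
selectTagSnps <- function(panel, minR2 = 0.9, inversionId = "inv1") {
  stopifnot(is(panel, "HaplotypePanel"))
  z <- as.numeric(panel@orientation == "I")
  H <- panel@haplotypes
  r <- apply(H, 2, function(col) {
    if (stats::sd(col) == 0 || stats::sd(z) == 0) return(0)
    stats::cor(col, z)
  })
  keep <- which(r^2 >= minR2)
  if (length(keep) == 0L)
    return(data.frame(inversionId = character(0), snpId = character(0),
                      invertedAllele = character(0), minR2 = numeric(0),
                      r2 = numeric(0), stringsAsFactors = FALSE))
  keep <- keep[order(r[keep]^2, decreasing = TRUE)]
  do.call(rbind, lapply(keep, function(i) {
    tagSnpRule(inversionId, panel@snpMeta$id[i],
               invertedAllele = if (r[i] > 0) "alt" else "ref",
               minR2 = minR2, r2 = r[i]^2)
  }))
}

#' Call inversion genotypes from a single tag SNP
#'
#' The call is the posterior-argmax genotype at the tag SNP, re-expressed as
#' the dosage of the inverted-phased allele and mapped 0 to NN, 1 to NI,
#' 2 to II. Samples missing the tag SNP are uncalled.
#'
#' @param cohort a [CohortGenotypes-class].
#' @param rule a one-row tag-SNP rule (see [tagSnpRule()]).
#' @return Character vector of genotypes (`NA` where uncalled), named by
#'   sample id.
#' @export
callByTagSnp <- function(cohort, rule) {
  stopifnot(is(cohort, "CohortGenotypes"), nrow(rule) == 1L)
  i <- match(rule$snpId, cohort@snpMeta$id)
  n <- dim(cohort@posteriors)[1]
  out <- rep(NA_character_, n)
  names(out) <- cohort@sampleIds
  if (is.na(i)) {
    warning("tag SNP ", rule$snpId, " not present in cohort data; all calls missing")
    return(out)
  }
  P <- cohort@posteriors[, i, , drop = TRUE]
  if (is.null(dim(P))) P <- matrix(P, nrow = n)
  altDosage <- max.col(P, ties.method = "first") - 1L
  invDosage <- if (rule$invertedAllele == "alt") altDosage else 2L - altDosage
  callable <- !cohort@missing[, i]
  out[callable] <- GROUPS[invDosage[callable] + 1L]
  out
}

#' Concordance between two genotype call sets
#'
#' @param callsA,callsB either call data.frames from [callCohort()] (columns
#'   `sampleId`, `genotype`) or named character vectors of genotypes.
#' @return A list: `accuracy` (fraction identical among samples called by
#'   both) and `nCompared`.
#' @export
methodConcordance <- function(callsA, callsB) {
  asVec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$genotype, x$sampleId) else x
  }
  a <- asVec(callsA)
  b <- asVec(callsB)
  ids <- intersect(names(a), names(b))
  a <- a[ids]; b <- b[ids]
  both <- !is.na(a) & !is.na(b)
  if (!any(both)) stop("no samples called by both methods; accuracy undefined")
  list(accuracy = mean(a[both] == b[both]), nCompared = sum(both))
}

#' Allele frequency and Hardy-Weinberg check of a call set
#'
#' @param calls call data.frame from [callCohort()].
#' @return A list: `invAlleleFreq`, `hweP` (1-df chi-square goodness of fit
#'   against Hardy-Weinberg expectations at the estimated frequency), and
#'   `genotypeCounts` (named NN/NI/II).
#' @export
genotypeSummary <- function(calls) {
  g <- calls$genotype[calls$qcPass]
  if (length(g) == 0L) stop("no QC-passing calls")
  counts <- stats::setNames(
    vapply(GROUPS, function(k) sum(g == k), integer(1)), GROUPS)
  hwe <- .hweChisq(counts)
  list(invAlleleFreq = unname(hwe$freq), hweP = unname(hwe$p),
       genotypeCounts = counts)
}
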