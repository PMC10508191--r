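# Independent oracles and hand-built fixtures shared across test files.

# Naive similarity-score oracle: explicit double loop over SNPs and
# genotypes, independent of the vectorized implementation.
naiveScores <- function(post, freqs, weights) {
  groups <- c("NN", "NI", "II")
  L <- nrow(post)
  used <- which(stats::complete.cases(post))
  denom <- 0
  for (i in used) denom <- denom + max(post[i, ])^2
  out <- numeric(3)
  for (k in 1:3) {
    num <- 0
    for (i in used) {
      for (s in 1:3) num <- num + post[i, s] * freqs[i, s, k] * weights[i]
    }
    out[k] <- num / denom
  }
  names(out) <- groups
  out
}

# Brute-force squared correlation between a haplotype column and the
# inverted-orientation indicator.
bruteR2 <- function(hapCol, orient) {
  z <- as.numeric(orient == "I")
  if (stats::sd(hapCol) == 0) return(0)
  stats::cor(hapCol, z)^2
}

# Hand-built 6-individual, 3-SNP panel: 3 NN, 2 NI, 1 II.
# SNP1 is a perfect tag (alt on exactly the I haplotypes), SNP2 is weakly
# informative, SNP3 carries no orientation information.
handPanel <- function() {
  H <- rbind(
    c(0, 0, 1), c(0, 1, 0),   # individual 1, NI/NI
    c(0, 0, 0), c(0, 0, 1),   # individual 2, NI/NI
    c(0, 1, 1), c(0, 0, 0),   # individual 3, NI/NI
    c(1, 1, 0), c(0, 0, 1),   # individual 4, I/NI
    c(1, 0, 1), c(0, 1, 0),   # individual 5, I/NI
    c(1, 1, 1), c(1, 1, 0)    # individual 6, I/I
  )
  storage.mode(H) <- "integer"
  orient <- c("NI", "NI", "NI", "NI", "NI", "NI",
              "I", "NI", "I", "NI", "I", "I")
  new("HaplotypePanel",
      snpMeta = data.frame(id = c("s1", "s2", "s3"), chrom = "1",
                           pos = c(100L, 200L, 300L), ref = "A", alt = "G",
                           stringsAsFactors = FALSE),
      haplotypes = H, orientation = orient, familyFreqs = NULL)
}

# Brute-force genotype-frequency tables for a panel: counts per inversion
# group, divided by group size.
bruteFreqs <- function(panel) {
  H <- haplotypes(panel)
  orient <- orientation(panel)
  nInd <- nrow(H) / 2
  groups <- c("NN", "NI", "II")
  geno <- H[seq(1, 2 * nInd, 2), , drop = FALSE] +
    H[seq(2, 2 * nInd, 2), , drop = FALSE]
  invCount <- (orient[seq(1, 2 * nInd, 2)] == "I") +
    (orient[seq(2, 2 * nInd, 2)] == "I")
  f <- array(1 / 3, dim = c(ncol(H), 3, 3))
  for (k in 1:3) {
    idx <- which(invCount == k - 1)
    if (!length(idx)) next
    for (i in seq_len(ncol(H))) for (s in 0:2)
      f[i, s + 1, k] <- mean(geno[idx, i] == s)
  }
  f
}

# A cohort posterior matrix for a single sample from hard genotypes with
# given certainty.
posteriorFromGenotypes <- function(g, certainty = 1) {
  P <- matrix((1 - certainty) / 2, length(g), 3)
  for (j in seq_along(g)) P[j, g[j] + 1] <- certainty
  P
}

# Random posterior fixture: L SNPs, rows normalized, optional missing rows.
randomPosterior <- function(L, nMissing = 0) {
  P <- matrix(stats::runif(L * 3), L, 3)
  P <- P / rowSums(P)
  if (nMissing > 0) P[sample(L, nMissing), ] <- NA_real_
  P
}

# Random reference model with valid frequency tables and weights.
randomModel <- function(L) {
  f <- array(stats::runif(L * 3 * 3), dim = c(L, 3, 3))
  for (k in 1:3) f[, , k] <- f[, , k] / rowSums(f[, , k])
  new("ReferenceModel",
      inversionId = "rand",
      snpMeta = data.frame(id = sprintf("s%d", 1:L), chrom = "1",
                           pos = seq_len(L) * 10L, ref = "A", alt = "G",
                           stringsAsFactors = FALSE),
      freqs = f,
      weights = stats::runif(L),
      groupCounts = c(NN = 5L, NI = 5L, II = 5L))
}

genotypeLabels <- function(dosage) c("NN", "NI", "II")[dosage + 1L]
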