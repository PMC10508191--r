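# Association pipeline: genotype/sample QC, GRM relatedness pruning,
# covariate + global-measure residualization, rank-based inverse normal
# transformation, joint additive regression on inversion dosages, X-linked
# dosage-compensation codings, effective number of independent tests, and
# SNP-conditional adjustment.

#' SNP and sample quality control
#'
#' Applies, in order: removal of individuals with more than `maxIndivMiss`
#' missing SNPs, then of SNPs with more than `maxSnpMiss` missingness,
#' failing the Hardy-Weinberg test at `hweP`, or with minor allele frequency
#' below `minMaf`.
#'
#' @param G genotype matrix (individuals x SNPs, dosages 0/1/2, `NA`
#'   missing).
#' @param maxIndivMiss maximum per-individual missing fraction (default 0.10).
#' @param maxSnpMiss maximum per-SNP missing fraction (default 0.05).
#' @param hweP Hardy-Weinberg p-value threshold (default 1e-6).
#' @param minMaf minor-allele-frequency threshold (default 0.01).
#' @return A list: `genotypes` (filtered matrix) and `report` (named counts
#'   removed per criterion, in application order).
#' @export
snpSampleQC <- function(G, maxIndivMiss = 0.10, maxSnpMiss = 0.05,
                        hweP = 1e-6, minMaf = 0.01) {
  G <- as.matrix(G)
  indivMiss <- rowMeans(is.na(G))
  dropIndiv <- indivMiss > maxIndivMiss
  G <- G[!dropIndiv, , drop = FALSE]

  snpMiss <- colMeans(is.na(G))
  dropMiss <- snpMiss > maxSnpMiss
  G1 <- G[, !dropMiss, drop = FALSE]

  hwePvals <- apply(G1, 2, function(g) {
    g <- g[!is.na(g)]
    .hweChisq(c(sum(g == 0), sum(g == 1), sum(g == 2)))$p
  })
  dropHwe <- hwePvals < hweP
  G2 <- G1[, !dropHwe, drop = FALSE]

  p <- colMeans(G2, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  dropMaf <- maf < minMaf
  G3 <- G2[, !dropMaf, drop = FALSE]

  if (ncol(G3) == 0L) stop("all SNPs removed by QC")
  list(genotypes = G3,
       report = c(individualsMissing = sum(dropIndiv),
                  snpsMissing = sum(dropMiss),
                  snpsHwe = sum(dropHwe),
                  snpsMaf = sum(dropMaf)))
}

#' Genetic relationship matrix
#'
#' Standard allele-frequency-standardized GRM:
#' \deqn{A_{jk} = \frac{1}{M} \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
#' {2 p_i (1 - p_i)}}
#' over the M polymorphic SNPs.
#'
#' @param X dosage matrix (individuals x SNPs, no missing values).
#' @param freqs optional per-SNP allele frequencies; estimated from `X` when
#'   omitted.
#' @return Symmetric relatedness matrix.
#' @export
computeGRM <- function(X, freqs = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("GRM needs at least two individuals")
  if (is.null(freqs)) freqs <- colMeans(X) / 2
  usable <- freqs > 0 & freqs < 1
  if (!any(usable)) stop("no polymorphic SNPs; GRM undefined")
  X <- X[, usable, drop = FALSE]
  p <- freqs[usable]
  Z <- sweep(X, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  tcrossprod(Z) / ncol(Z)
}

#' Prune related individuals from a GRM
#'
#' Greedy pruning: while any off-diagonal relatedness exceeds `threshold`,
#' remove the individual participating in the most such pairs (ties broken
#' toward the larger index) and re-examine. Removing one member of each
#' related pair leaves a set with no relatedness above the threshold.
#'
#' @param grm square symmetric relatedness matrix.
#' @param threshold relatedness cutoff (default 0.1, roughly third cousins).
#' @return A list: `retained` (indices kept) and `removed` (indices removed,
#'   in removal order).
#' @export
relatednessFilter <- function(grm, threshold = 0.1) {
  grm <- as.matrix(grm)
  stopifnot(nrow(grm) == ncol(grm))
  active <- seq_len(nrow(grm))
  removed <- integer(0)
  A <- grm
  diag(A) <- 0
  repeat {
    over <- A[active, active, drop = FALSE] > threshold
    deg <- rowSums(over)
    if (!any(deg > 0)) break
    worst <- which(deg == max(deg))
    victim <- active[worst[length(worst)]]   # tie -> larger sample index
    removed <- c(removed, victim)
    active <- setdiff(active, victim)
  }
  list(retained = active, removed = removed)
}

# OLS residuals of each column of Y on design X (with intercept); errors on
# rank deficiency, naming the offending columns.
.residualize <- function(Y, X) {
  X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Y - X %*% qr.coef(qrX, Y)
}

#' Residualize phenotypes on covariates (and optionally global measures)
#'
#' Regresses every phenotype on the covariates (categorical covariates enter
#' as indicator contrasts) and returns the ordinary-least-squares residuals.
#' With `adjustGlobal = TRUE`, each phenotype's mapped global measure (e.g.
#' total surface area for regional areas) is included in its design, so
#' downstream effects are specific to the region rather than to global size.
#'
#' @param pheno a [PhenotypeTable-class].
#' @param adjustGlobal also regress out each phenotype's global measure.
#' @return Residual matrix, samples x phenotypes.
#' @export
preresidualize <- function(pheno, adjustGlobal = FALSE) {
  stopifnot(is(pheno, "PhenotypeTable"))
  X <- stats::model.matrix(~ ., data = pheno@covariates)[, -1, drop = FALSE]
  Y <- pheno@phenotypes
  if (!adjustGlobal) return(.residualize(Y, X))
  out <- Y
  for (j in seq_len(ncol(Y))) {
    gcol <- pheno@globalMap[colnames(Y)[j]]
    Xj <- cbind(X, global = pheno@globals[, gcol])
    out[, j] <- .residualize(Y[, j, drop = FALSE], Xj)
  }
  out
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their Blom-offset ranks,
#' `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties. The
#' output has a standard-normal marginal and preserves the input's weak
#' ordering.
#'
#' @param v numeric vector, `n >= 3`, not all equal.
#' @return Transformed vector.
#' @export
rankINT <- function(v) {
  if (anyNA(v)) stop("rankINT() requires complete values")
  n <- length(v)
  if (n < 3L) stop("rankINT() needs at least 3 values")
  if (length(unique(v)) == 1L)
    stop("all values identical; no ordering information to transform")
  stats::qnorm((rank(v, ties.method = "average") - 3 / 8) / (n + 1 / 4))
}

#' X-linked dosage-compensation coding
#'
#' Females are always coded by inverted-allele dosage `{0, 1, 2}`. Males are
#' hemizygous; under full dosage compensation (X-inactivation equalizes
#' expression) a male carrier counts like a homozygote (`{0, 2}`), under no
#' compensation like a heterozygote (`{0, 1}`).
#'
#' @param genotypes character genotypes: `NN`/`NI`/`II` (male hemizygotes may
#'   be given as `NN`/`II` or as `N`/`I`); `NA` allowed.
#' @param sex integer vector, 0 female / 1 male.
#' @param mode `"full_dc"` or `"no_dc"`.
#' @return Numeric dosage vector.
#' @export
dcCoding <- function(genotypes, sex, mode = c("full_dc", "no_dc")) {
  mode <- match.arg(mode)
  stopifnot(length(genotypes) == length(sex))
  female <- c(NN = 0, NI = 1, II = 2)
  out <- rep(NA_real_, length(genotypes))
  isF <- sex == 0L
  out[isF] <- female[genotypes[isF]]
  gM <- genotypes[!isF]
  if (any(gM %in% "NI", na.rm = TRUE))
    stop("male heterozygote encountered; males must be hemizygous on X")
  carrier <- gM %in% c("II", "I")
  nonc <- gM %in% c("NN", "N")
  dos <- rep(NA_real_, length(gM))
  dos[nonc] <- 0
  dos[carrier] <- if (mode == "full_dc") 2 else 1
  out[!isF] <- dos
  out
}

#' Joint additive regression of phenotypes on all inversion dosages
#'
#' Fits, per phenotype, one ordinary-least-squares model with every
#' inversion dosage as a simultaneous predictor (plus intercept). Reports,
#' per inversion, the additive effect per inverted allele with its standard
#' error, two-sided t-test p-value, and the incremental variance explained
#' `R^2(full) - R^2(full minus that inversion)`.
#'
#' @param Y phenotype matrix (typically residualized and INT-transformed),
#'   samples x phenotypes.
#' @param D dosage matrix, samples x inversions; additive coding.
#' @return data.frame with one row per inversion x phenotype: `inversionId`,
#'   `phenotypeId`, `beta`, `se`, `t`, `p`, `incrementalR2`, `n`.
#' @export
jointInversionRegression <- function(Y, D) {
  Y <- as.matrix(Y)
  D <- as.matrix(D)
  n <- nrow(Y)
  M <- ncol(D)
  if (n != nrow(D)) stop("Y and D must have the same number of rows")
  if (n <= M + 1L) stop("need n > number of inversions + 1")
  if (is.null(colnames(D))) colnames(D) <- sprintf("inv%d", seq_len(M))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("pheno%02d", seq_len(ncol(Y)))
  X <- cbind(`(Intercept)` = 1, D)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    C <- abs(stats::cor(D))
    diag(C) <- 0
    pair <- which(C == max(C), arr.ind = TRUE)[1, ]
    stop("collinear inversion dosage columns: ",
         colnames(D)[pair[1]], " and ", colnames(D)[pair[2]])
  }
  XtXinv <- chol2inv(qr.R(qrX))
  coefs <- qr.coef(qrX, Y)
  resid <- Y - X %*% coefs
  dfRes <- n - ncol(X)
  out <- vector("list", ncol(Y))
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    tss <- sum((y - mean(y))^2)
    rssFull <- sum(resid[, j]^2)
    sigma2 <- rssFull / dfRes
    se <- sqrt(sigma2 * diag(XtXinv))[-1]
    beta <- coefs[-1, j]
    tval <- beta / se
    pval <- 2 * stats::pt(abs(tval), dfRes, lower.tail = FALSE)
    incR2 <- vapply(seq_len(M), function(m) {
      Xm <- X[, -(m + 1L), drop = FALSE]
      rssDrop <- sum(qr.resid(qr(Xm), y)^2)
      (rssDrop - rssFull) / tss
    }, numeric(1))
    out[[j]] <- data.frame(inversionId = colnames(D),
                           phenotypeId = colnames(Y)[j],
                           beta = unname(beta), se = unname(se),
                           t = unname(tval), p = unname(pval),
                           incrementalR2 = incR2, n = n,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Effective number of independent phenotypes by spectral decomposition
#'
#' Eigen-decomposes the phenotype correlation matrix and estimates the
#' effective number of independent tests. The default estimator counts
#' `1(lambda_i >= 1) + (lambda_i - floor(lambda_i))` per eigenvalue
#' (Li-Ji); `method = "nyholt"` uses
#' `1 + (M - 1) * (1 - var(lambda) / M)`. The multiple-testing threshold is
#' `alpha / t_e`.
#'
#' @param R phenotype correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite within tolerance 1e-8).
#' @param alpha family-wise error rate (default 0.05).
#' @param method `"liji"` (default) or `"nyholt"`.
#' @return A list: `tE`, `eigenvalues`, `alpha`, `bonferroniThreshold`.
#' @export
effectiveTests <- function(R, alpha = 0.05, method = c("liji", "nyholt")) {
  method <- match.arg(method)
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8)
    stop("correlation matrix must be symmetric with unit diagonal")
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(lambda) < -1e-8) stop("correlation matrix is not positive semi-definite")
  lambda <- pmax(lambda, 0)
  M <- length(lambda)
  # round before the integer/fractional split so an eigenvalue within 1e-10
  # of an integer (numerical noise) does not flip its floor()
  lamR <- round(lambda, 10)
  tE <- switch(method,
    liji = sum(as.numeric(lamR >= 1) + (lamR - floor(lamR))),
    nyholt = 1 + (M - 1) * (1 - stats::var(lambda) / M))
  list(tE = tE, eigenvalues = lambda, alpha = alpha,
       bonferroniThreshold = alpha / tE)
}

#' Significance tier of an association p-value
#'
#' @param p numeric p-values in `(0, 1]`.
#' @param multiplicity result of [effectiveTests()] (supplies
#'   `alpha / t_e`).
#' @param gwAlpha genome-wide significance level (default 5e-8).
#' @return Character vector: `"genome_wide"`, `"bonferroni"`, `"nominal"` or
#'   `"none"`.
#' @export
significanceTiers <- function(p, multiplicity, gwAlpha = 5e-8) {
  stopifnot(all(p > 0 & p <= 1))
  thr <- multiplicity$bonferroniThreshold
  ifelse(p < gwAlpha, "genome_wide",
         ifelse(p < thr, "bonferroni",
                ifelse(p < 0.05, "nominal", "none")))
}

# p-value of the last column of design X (plus intercept) in an OLS of y.
.lastPredictorP <- function(y, X) {
  X <- cbind(1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) return(NA_real_)
  coefs <- qr.coef(qrX, y)
  rss <- sum(qr.resid(qrX, y)^2)
  dfRes <- length(y) - ncol(X)
  se <- sqrt(rss / dfRes * diag(chol2inv(qr.R(qrX))))
  2 * stats::pt(abs(coefs[ncol(X)] / se[ncol(X)]), dfRes, lower.tail = FALSE)
}

.singleFit <- function(y, X, focus) {
  X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  coefs <- qr.coef(qrX, y)
  rss <- sum(qr.resid(qrX, y)^2)
  dfRes <- length(y) - ncol(X)
  se <- sqrt(rss / dfRes * diag(chol2inv(qr.R(qrX))))
  k <- match(focus, colnames(X))
  tval <- coefs[k] / se[k]
  data.frame(beta = unname(coefs[k]), se = unname(se[k]), t = unname(tval),
             p = 2 * stats::pt(abs(tval), dfRes, lower.tail = FALSE),
             n = length(y))
}

#' SNP-conditional adjustment of an inversion association
#'
#' Forward stepwise selection on individual-level data: iteratively adds the
#' candidate region SNP with the smallest conditional p-value (given the
#' SNPs already selected) while that p-value is below `selectP`, skipping
#' candidates whose r^2 with the already-selected predictors exceeds 0.99,
#' up to `maxSteps` SNPs. The inversion association is then refit with the
#' selected SNP dosages as covariates; if a high-LD SNP carries the same
#' signal as the inversion, the conditional association is absorbed.
#'
#' @param y phenotype vector (residualized / transformed).
#' @param invDosage inversion dosage vector.
#' @param snpDosages matrix of candidate SNP dosages from the inversion
#'   region (columns named).
#' @param selectP stepwise inclusion threshold (default 5e-8).
#' @param maxSteps maximum SNPs selected (default 20).
#' @return A list: `selected` (SNP column names, possibly empty),
#'   `conditional` and `unconditional` one-row association data.frames for
#'   the inversion.
#' @export
conditionalAdjustment <- function(y, invDosage, snpDosages,
                                  selectP = 5e-8, maxSteps = 20L) {
  snpDosages <- as.matrix(snpDosages)
  if (is.null(colnames(snpDosages)))
    colnames(snpDosages) <- sprintf("snp%d", seq_len(ncol(snpDosages)))
  if (nrow(snpDosages) != length(y) || length(invDosage) != length(y))
    stop("y, invDosage and snpDosages must align")
  selected <- character(0)
  remaining <- colnames(snpDosages)
  while (length(selected) < maxSteps && length(remaining) > 0L) {
    Xsel <- snpDosages[, selected, drop = FALSE]
    ps <- vapply(remaining, function(s) {
      cand <- snpDosages[, s]
      if (length(selected)) {
        tss <- sum((cand - mean(cand))^2)
        rss <- sum(stats::lm.fit(cbind(1, Xsel), cand)$residuals^2)
        if (tss == 0 || 1 - rss / tss > 0.99) return(NA_real_)  # collinearity guard
      }
      .lastPredictorP(y, cbind(Xsel, cand))
    }, numeric(1))
    if (all(is.na(ps)) || min(ps, na.rm = TRUE) >= selectP) break
    best <- remaining[which.min(ps)]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  uncond <- .singleFit(y, cbind(inversion = invDosage), "inversion")
  cond <- if (length(selected)) {
    .singleFit(y, cbind(inversion = invDosage,
                        snpDosages[, selected, drop = FALSE]), "inversion")
  } else uncond
  list(selected = selected, conditional = cond, unconditional = uncond)
}
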