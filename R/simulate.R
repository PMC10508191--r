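# Synthetic-data generator: two haplotype families (inverted / non-inverted)
# with suppressed recombination between orientations modelled as
# family-specific per-SNP allele frequencies; sites independent within a
# family, inversions independent of each other.

# Per-region family allele frequencies are a deterministic function of
# (seed, region) so a panel and a cohort simulated from the same config share
# the same underlying frequencies without sharing haplotypes.
.regionFamilyFreqs <- function(config, region = 1L) {
  set.seed(config@seed + 7919L * region)
  L <- config@nSnps
  base <- stats::runif(L, 0.05, 0.95)
  d <- config@divergence
  fI <- pmin(pmax(base + d, 0.01), 0.99)
  fNI <- pmin(pmax(base - d, 0.01), 0.99)
  if (config@plantPerfectTag) {
    fI[1] <- 1
    fNI[1] <- 0
  }
  data.frame(freqI = fI, freqNI = fNI)
}

.regionSnpMeta <- function(config, region = 1L) {
  L <- config@nSnps
  data.frame(
    id = sprintf("inv%d_snp%03d", region, seq_len(L)),
    chrom = if (config@xLinked[region]) "chrX" else as.character(region),
    pos = 1000L + 100L * seq_len(L),
    ref = "A", alt = "G",
    stringsAsFactors = FALSE
  )
}

#' Simulate a phased, orientation-labelled reference panel
#'
#' Draws each haplotype's orientation Bernoulli(q), then draws alleles
#' independently per SNP from the haplotype family's allele frequency:
#' `clip(pi_i + delta, 0.01, 0.99)` on inverted haplotypes and
#' `clip(pi_i - delta, 0.01, 0.99)` on non-inverted ones, with the base
#' frequency `pi_i ~ Uniform(0.05, 0.95)`. Haplotypes are paired
#' consecutively into diploid individuals.
#'
#' @param config a [SimulationConfig-class].
#' @param region which inversion region to simulate (1-based index).
#' @return A [HaplotypePanel-class]; the generator's true family frequencies
#'   are kept in the `familyFreqs` slot for downstream cohort simulation.
#' @export
simulateReferencePanel <- function(config, region = 1L) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  ff <- .regionFamilyFreqs(config, region)
  set.seed(config@seed + 7919L * region + 1L)
  nHap <- 2L * config@nRefIndividuals
  L <- config@nSnps
  orient <- ifelse(stats::runif(nHap) < config@invFreq, "I", "NI")
  p <- ifelse(orient == "I", 1, 0)
  H <- matrix(0L, nHap, L)
  for (i in seq_len(L)) {
    f <- ifelse(orient == "I", ff$freqI[i], ff$freqNI[i])
    H[, i] <- as.integer(stats::runif(nHap) < f)
  }
  new("HaplotypePanel",
      snpMeta = .regionSnpMeta(config, region),
      haplotypes = H,
      orientation = orient,
      familyFreqs = ff)
}

.drawCertainty <- function(model, n) {
  switch(model$type,
    fixed = rep(model$value, n),
    uniform = stats::runif(n, model$min, model$max),
    stop("unknown certainty model type: ", model$type))
}

# Perturb genotype to an adjacent dosage: 0 -> 1, 2 -> 1, 1 -> 0 or 2.
.perturbAdjacent <- function(g) {
  out <- g
  het <- g == 1L
  out[g == 0L] <- 1L
  out[g == 2L] <- 1L
  out[het] <- ifelse(stats::runif(sum(het)) < 0.5, 0L, 2L)
  out
}

#' Simulate an imputed study cohort with known inversion genotypes
#'
#' Each individual's true inversion genotype comes from two independent
#' Bernoulli(q) haplotype draws (one for males at X-linked loci). Observed
#' SNP genotypes are drawn from the family allele frequencies given the true
#' orientation of each haplotype, miscalled to an adjacent dosage with
#' probability `genotypeErrorRate`, and wrapped in a posterior placing the
#' drawn certainty `p_i` on the observed genotype and `(1 - p_i)/2` on each
#' of the other two.
#'
#' @param config a [SimulationConfig-class].
#' @param panel optional [HaplotypePanel-class] simulated from the same
#'   config; its true family frequencies are reused so that cohort and panel
#'   describe the same locus. When `NULL`, frequencies are regenerated
#'   deterministically from the seed (identical to the panel's).
#' @return A list with `regions` (one [CohortGenotypes-class] per inversion),
#'   `truth` (n x nInversions matrix of true inverted-allele dosages; males
#'   at X-linked loci carry 0/1), and `sex` (0 female, 1 male).
#' @export
simulateCohort <- function(config, panel = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@nStudy
  M <- config@nInversions
  set.seed(config@seed + 104729L)
  sex <- as.integer(stats::runif(n) < config@sexRatio)
  truth <- matrix(0L, n, M)
  regions <- vector("list", M)
  for (m in seq_len(M)) {
    ff <- if (!is.null(panel) && m == 1L && !is.null(panel@familyFreqs))
      panel@familyFreqs else .regionFamilyFreqs(config, m)
    set.seed(config@seed + 104729L + 31L * m)
    L <- config@nSnps
    q <- config@invFreq
    haploid <- config@xLinked[m] & sex == 1L
    hapA <- as.integer(stats::runif(n) < q)
    hapB <- as.integer(stats::runif(n) < q)
    dosage <- ifelse(haploid, hapA, hapA + hapB)
    truth[, m] <- dosage
    post <- array(0, dim = c(n, L, 3))
    miss <- matrix(FALSE, n, L)
    for (i in seq_len(L)) {
      aA <- as.integer(stats::runif(n) < ifelse(hapA == 1L, ff$freqI[i], ff$freqNI[i]))
      aB <- as.integer(stats::runif(n) < ifelse(hapB == 1L, ff$freqI[i], ff$freqNI[i]))
      g <- ifelse(haploid, 2L * aA, aA + aB)
      err <- stats::runif(n) < config@genotypeErrorRate
      g[err] <- .perturbAdjacent(g[err])
      p <- .drawCertainty(config@certaintyModel, n)
      rest <- (1 - p) / 2
      for (s in 0:2) post[, i, s + 1L] <- ifelse(g == s, p, rest)
    }
    regions[[m]] <- new("CohortGenotypes",
                        posteriors = post,
                        missing = miss,
                        sampleIds = sprintf("S%05d", seq_len(n)),
                        snpMeta = .regionSnpMeta(config, m),
                        sex = sex)
  }
  list(regions = regions, truth = truth, sex = sex)
}

# PSD square root of a correlation matrix via eigendecomposition (tolerates
# semi-definite targets, unlike chol()).
.corrSqrt <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate phenotypes with additive inversion effects
#'
#' Generates regional phenotypes `y_j = sum_m beta[m, j] * dosage_m +
#' gamma_age * age + gamma_sex * sex + globalWeight * g + e`, with noise `e`
#' multivariate normal matching the configured phenotype correlation matrix
#' (unit variances), a standard-normal global measure `g`, and covariates
#' (age, sex, scanner site, a scan-quality proxy, a diagnosis flag). For
#' X-linked inversions, male dosage contributions follow the generative
#' dosage-compensation mode: under `"full_dc"` a hemizygous carrier
#' contributes like a homozygote (dosage 2), under `"no_dc"` like a
#' heterozygote (dosage 1).
#'
#' @param truthDosages n x nInversions matrix of inverted-allele dosages
#'   (males at X-linked loci coded 0/1).
#' @param config a [SimulationConfig-class].
#' @param sex integer vector (0 female, 1 male); defaults to all female.
#' @param dcMode generative dosage-compensation mode for X-linked loci.
#' @return A [PhenotypeTable-class].
#' @export
simulatePhenotypes <- function(truthDosages, config, sex = NULL,
                               dcMode = c("full_dc", "no_dc")) {
  stopifnot(is(config, "SimulationConfig"))
  dcMode <- match.arg(dcMode)
  truthDosages <- as.matrix(truthDosages)
  if (ncol(truthDosages) != config@nInversions)
    stop("truthDosages must have one column per configured inversion")
  if (ncol(config@betas) != config@nPhenotypes)
    stop("betas dimension does not match nPhenotypes")
  n <- nrow(truthDosages)
  if (is.null(sex)) sex <- integer(n) else stopifnot(length(sex) == n)
  set.seed(config@seed + 224737L)
  J <- config@nPhenotypes
  D <- truthDosages
  for (m in which(config@xLinked)) {
    male <- sex == 1L
    D[male, m] <- if (dcMode == "full_dc") 2L * truthDosages[male, m]
                  else truthDosages[male, m]
  }
  age <- stats::rnorm(n, 55, 7.5)
  site <- factor(sample(c("siteA", "siteB", "siteC"), n, replace = TRUE))
  quality <- stats::rnorm(n)
  diagnosis <- as.integer(stats::runif(n) < 0.05)
  g <- stats::rnorm(n)
  E <- matrix(stats::rnorm(n * J), n, J) %*% .corrSqrt(config@phenotypeCorr)
  Y <- D %*% config@betas +
    config@covariateEffects["age"] * (age - 55) +
    config@covariateEffects["sex"] * sex +
    config@globalWeight * g + E
  colnames(Y) <- sprintf("pheno%02d", seq_len(J))
  globals <- matrix(g, n, 1, dimnames = list(NULL, "globalMeasure"))
  map <- stats::setNames(rep("globalMeasure", J), colnames(Y))
  new("PhenotypeTable",
      sampleIds = sprintf("S%05d", seq_len(n)),
      phenotypes = Y,
      covariates = data.frame(age = age, sex = sex, site = site,
                              quality = quality, diagnosis = diagnosis),
      globals = globals,
      globalMap = map)
}

#' Simulate matched discovery and replication cohorts
#'
#' True per-(inversion, phenotype) effects for the two cohorts are drawn
#' jointly from a bivariate normal with correlation `betaCorr` and standard
#' deviation `betaSd`; genotypes and phenotypes are then simulated
#' independently per cohort with those effects.
#'
#' @param config a [SimulationConfig-class] (applies to both cohorts).
#' @param betaCorr correlation of true effects across cohorts, in `[-1, 1]`.
#' @param betaSd standard deviation of the true effects.
#' @return A list with `discovery` and `replication` (each the value of
#'   [simulateCohort()] plus a `phenotypes` element) and `trueBetas`
#'   (list of the two effect matrices).
#' @export
simulateTwoCohorts <- function(config, betaCorr, betaSd = 0.1) {
  stopifnot(is(config, "SimulationConfig"))
  if (betaCorr < -1 || betaCorr > 1)
    stop("betaCorr must lie in [-1, 1]")
  set.seed(config@seed + 350377L)
  M <- config@nInversions
  J <- config@nPhenotypes
  z1 <- stats::rnorm(M * J)
  z2 <- betaCorr * z1 + sqrt(1 - betaCorr^2) * stats::rnorm(M * J)
  bD <- matrix(betaSd * z1, M, J)
  bR <- matrix(betaSd * z2, M, J)

  mkCohort <- function(betas, offset) {
    cfg <- config
    cfg@betas <- betas
    cfg@seed <- config@seed + offset
    sim <- simulateCohort(cfg)
    sim$phenotypes <- simulatePhenotypes(sim$truth, cfg, sex = sim$sex)
    sim
  }
  list(discovery = mkCohort(bD, 11L),
       replication = mkCohort(bR, 23L),
       trueBetas = list(discovery = bD, replication = bR))
}
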