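#' @import methods
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Simulation configuration for synthetic inversion cohorts
#'
#' Bundles every parameter of the synthetic-data generator: the reference
#' panel size, the study cohort size, the inversion allele frequency, the
#' per-SNP allele-frequency divergence between the inverted (I) and
#' non-inverted (NI) haplotype families, the genotype error rate, the
#' imputation-certainty model, and the phenotype-generating model
#' (per-inversion additive effects, covariate effects, a global-size
#' component and a target inter-phenotype correlation matrix).
#'
#' @slot seed integer seed; all generator randomness derives from it.
#' @slot nRefIndividuals number of diploid reference-panel individuals.
#' @slot nStudy number of study-cohort individuals.
#' @slot nSnps number of SNPs per inversion region (L).
#' @slot invFreq population frequency q of the inverted allele.
#' @slot divergence per-SNP allele-frequency separation delta between the two
#'   haplotype families, in `[0, 0.5]`.
#' @slot genotypeErrorRate probability epsilon that an observed SNP genotype
#'   is perturbed to an adjacent dosage value.
#' @slot certaintyModel list describing the per-SNP imputation certainty
#'   distribution: `list(type = "fixed", value = p)` or
#'   `list(type = "uniform", min = a, max = b)` with support in (1/3, 1].
#' @slot nInversions number of independently simulated inversion loci.
#' @slot nPhenotypes number of regional phenotypes.
#' @slot betas nInversions x nPhenotypes matrix of additive effects
#'   (phenotype units per inverted allele).
#' @slot phenotypeCorr target correlation matrix of the phenotype noise.
#' @slot globalWeight loading of the global measure on every regional
#'   phenotype.
#' @slot covariateEffects named numeric, effects of `age` and `sex` on every
#'   phenotype.
#' @slot xLinked logical per inversion; X-linked loci give males a single
#'   haplotype.
#' @slot sexRatio probability that an individual is male.
#' @slot plantPerfectTag if TRUE the first SNP of each region is fixed for
#'   the alternate allele on I haplotypes and the reference allele on NI
#'   haplotypes (a perfect tag SNP, haplotype r^2 = 1 with orientation).
#'
#' @seealso [simConfig()] for the user-facing constructor with defaults.
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nRefIndividuals = "integer",
    nStudy = "integer",
    nSnps = "integer",
    invFreq = "numeric",
    divergence = "numeric",
    genotypeErrorRate = "numeric",
    certaintyModel = "list",
    nInversions = "integer",
    nPhenotypes = "integer",
    betas = "matrix",
    phenotypeCorr = "matrix",
    globalWeight = "numeric",
    covariateEffects = "numeric",
    xLinked = "logical",
    sexRatio = "numeric",
    plantPerfectTag = "logical"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  probs <- c(invFreq = object@invFreq, eps = object@genotypeErrorRate,
             sexRatio = object@sexRatio)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "invFreq, genotypeErrorRate and sexRatio must lie in [0, 1]")
  if (object@divergence < 0 || object@divergence > 0.5)
    msg <- c(msg, "divergence must lie in [0, 0.5]")
  if (any(c(object@nRefIndividuals, object@nStudy, object@nSnps,
            object@nInversions, object@nPhenotypes) < 1L))
    msg <- c(msg, "counts (individuals, SNPs, inversions, phenotypes) must be positive")
  if (!identical(dim(object@betas),
                 c(object@nInversions, object@nPhenotypes)))
    msg <- c(msg, "betas must be an nInversions x nPhenotypes matrix")
  R <- object@phenotypeCorr
  if (!identical(dim(R), c(object@nPhenotypes, object@nPhenotypes))) {
    msg <- c(msg, "phenotypeCorr must be nPhenotypes x nPhenotypes")
  } else {
    if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8)
      msg <- c(msg, "phenotypeCorr must be symmetric with unit diagonal")
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      msg <- c(msg, "phenotypeCorr must be positive semi-definite")
  }
  if (length(object@xLinked) != object@nInversions)
    msg <- c(msg, "xLinked must have one flag per inversion")
  if (!object@certaintyModel$type %in% c("fixed", "uniform"))
    msg <- c(msg, "certaintyModel$type must be 'fixed' or 'uniform'")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimulationConfig-class]
#'
#' Defaults describe a single autosomal 17q21.31-like locus: inverted-allele
#' frequency 0.20, strong family divergence, 30 SNPs, clean genotypes with
#' full imputation certainty, and one phenotype with no planted effect.
#'
#' @param seed integer seed.
#' @param nRefIndividuals reference-panel diploids (default 500, emulating a
#'   ~500-individual phased European reference panel).
#' @param nStudy study-cohort individuals.
#' @param nSnps SNPs per inversion region.
#' @param invFreq inverted-allele frequency q.
#' @param divergence per-SNP family allele-frequency separation.
#' @param genotypeErrorRate per-SNP genotype miscall probability.
#' @param certaintyModel imputation-certainty distribution spec.
#' @param nInversions number of inversion loci.
#' @param nPhenotypes number of regional phenotypes.
#' @param betas effect matrix (recycled scalar allowed).
#' @param phenotypeCorr target noise correlation matrix (default identity).
#' @param globalWeight loading of the global measure.
#' @param covariateEffects named numeric `c(age = , sex = )`.
#' @param xLinked logical per inversion.
#' @param sexRatio probability male.
#' @param plantPerfectTag plant a perfect tag SNP as SNP 1 of each region.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nStudy = 200)
#' panel <- simulateReferencePanel(cfg)
#' @export
simConfig <- function(seed = 1L,
                      nRefIndividuals = 500L,
                      nStudy = 1000L,
                      nSnps = 30L,
                      invFreq = 0.2,
                      divergence = 0.45,
                      genotypeErrorRate = 0,
                      certaintyModel = list(type = "fixed", value = 1),
                      nInversions = 1L,
                      nPhenotypes = 1L,
                      betas = 0,
                      phenotypeCorr = diag(nPhenotypes),
                      globalWeight = 0,
                      covariateEffects = c(age = 0.02, sex = 0.1),
                      xLinked = rep(FALSE, nInversions),
                      sexRatio = 0.5,
                      plantPerfectTag = FALSE) {
  if (!is.matrix(betas))
    betas <- matrix(betas, nrow = nInversions, ncol = nPhenotypes)
  new("SimulationConfig",
      seed = as.integer(seed),
      nRefIndividuals = as.integer(nRefIndividuals),
      nStudy = as.integer(nStudy),
      nSnps = as.integer(nSnps),
      invFreq = invFreq,
      divergence = divergence,
      genotypeErrorRate = genotypeErrorRate,
      certaintyModel = certaintyModel,
      nInversions = as.integer(nInversions),
      nPhenotypes = as.integer(nPhenotypes),
      betas = betas,
      phenotypeCorr = phenotypeCorr,
      globalWeight = globalWeight,
      covariateEffects = covariateEffects,
      xLinked = xLinked,
      sexRatio = sexRatio,
      plantPerfectTag = plantPerfectTag)
}

#' Phased reference haplotype panel for one inversion region
#'
#' Holds a binary haplotype matrix (rows are haplotypes, columns are SNPs;
#' entries are alternate-allele indicators), one orientation label per
#' haplotype (`"I"` inverted, `"NI"` non-inverted), and SNP metadata.
#' Haplotypes `2k - 1` and `2k` belong to diploid individual `k`.
#'
#' @slot snpMeta data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`;
#'   positions strictly increasing.
#' @slot haplotypes integer matrix in `{0, 1}`, `2 * n individuals` rows.
#' @slot orientation character vector, one of `"I"`/`"NI"` per haplotype.
#' @slot familyFreqs generator truth (per-SNP alternate-allele frequency in
#'   each family) when the panel was simulated; `NULL` for panels read from
#'   files.
#' @export
setClass("HaplotypePanel",
  representation(
    snpMeta = "data.frame",
    haplotypes = "matrix",
    orientation = "character",
    familyFreqs = "data.frameOrNULL"
  )
)

setValidity("HaplotypePanel", function(object) {
  msg <- character(0)
  H <- object@haplotypes
  if (!all(H %in% c(0L, 1L)))
    msg <- c(msg, "haplotype matrix entries must be 0/1")
  if (nrow(H) %% 2L != 0L)
    msg <- c(msg, "haplotype count must be even (diploid pairing)")
  if (length(object@orientation) != nrow(H))
    msg <- c(msg, "one orientation label required per haplotype")
  if (!all(object@orientation %in% c("I", "NI")))
    msg <- c(msg, "orientation labels must be 'I' or 'NI'")
  if (ncol(H) != nrow(object@snpMeta))
    msg <- c(msg, "snpMeta rows must match haplotype matrix columns")
  if (is.unsorted(object@snpMeta$pos, strictly = TRUE))
    msg <- c(msg, "SNP positions must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Per-sample SNP genotype posteriors for one inversion region
#'
#' The cohort-level container consumed by the genotyper: for every sample and
#' region SNP, a posterior probability vector over the diploid genotypes
#' `{0, 1, 2}` (alternate-allele dosage), plus a missingness mask. Posteriors
#' at non-missing SNPs sum to 1.
#'
#' @slot posteriors numeric array `n samples x L SNPs x 3 genotypes`.
#' @slot missing logical matrix `n x L`; TRUE where the sample has no usable
#'   genotype at that SNP.
#' @slot sampleIds character sample identifiers.
#' @slot snpMeta data.frame of SNP metadata (as in [HaplotypePanel-class]).
#' @slot sex integer vector (0 female, 1 male), or length 0 when unknown.
#' @export
setClass("CohortGenotypes",
  representation(
    posteriors = "array",
    missing = "matrix",
    sampleIds = "character",
    snpMeta = "data.frame",
    sex = "integer"
  )
)

setValidity("CohortGenotypes", function(object) {
  msg <- character(0)
  d <- dim(object@posteriors)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "posteriors must be an n x L x 3 array")
  if (!identical(dim(object@missing), d[1:2]))
    msg <- c(msg, "missing mask must be n x L")
  if (length(object@sampleIds) != d[1])
    msg <- c(msg, "one sample id per posterior row")
  if (nrow(object@snpMeta) != d[2])
    msg <- c(msg, "snpMeta rows must match SNP dimension")
  if (length(object@sex) && length(object@sex) != d[1])
    msg <- c(msg, "sex must be empty or one value per sample")
  ok <- !object@missing
  if (any(ok)) {
    sums <- apply(object@posteriors, c(1, 2), sum)[ok]
    if (max(abs(sums - 1)) > 1e-6)
      msg <- c(msg, "non-missing posterior vectors must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Reference model for similarity-score inversion genotyping
#'
#' Pre-computed from a phased, orientation-labelled reference panel: the
#' empirical frequency `f[k, i](s)` of each diploid SNP genotype
#' `s in {0, 1, 2}` within each inversion-genotype group `k in {NN, NI, II}`,
#' and a per-SNP weight `rho_i^2`, the squared haplotype correlation between
#' the SNP's alternate allele and the inverted orientation.
#'
#' @slot inversionId locus label, e.g. `"17q21.31"`.
#' @slot snpMeta SNP metadata data.frame.
#' @slot freqs numeric array `L x 3 genotypes x 3 groups`; each frequency row
#'   sums to 1 for groups with at least one reference individual.
#' @slot weights numeric vector of per-SNP rho^2 in `[0, 1]`.
#' @slot groupCounts named integer, reference individuals per group; groups
#'   with zero individuals carry a uniform (uninformative) frequency table.
#' @export
setClass("ReferenceModel",
  representation(
    inversionId = "character",
    snpMeta = "data.frame",
    freqs = "array",
    weights = "numeric",
    groupCounts = "integer"
  )
)

setValidity("ReferenceModel", function(object) {
  msg <- character(0)
  d <- dim(object@freqs)
  if (length(d) != 3L || d[2] != 3L || d[3] != 3L)
    msg <- c(msg, "freqs must be L x 3 x 3")
  if (length(object@weights) != d[1])
    msg <- c(msg, "one weight per SNP")
  if (any(object@weights < -1e-12 | object@weights > 1 + 1e-12))
    msg <- c(msg, "weights must lie in [0, 1]")
  if (!identical(names(object@groupCounts), c("NN", "NI", "II")))
    msg <- c(msg, "groupCounts must be named NN, NI, II")
  for (k in which(object@groupCounts > 0L)) {
    m <- object@freqs[, , k, drop = FALSE]
    dim(m) <- dim(object@freqs)[1:2]
    rs <- rowSums(m)
    if (length(rs) && max(abs(rs - 1)) > 1e-9) {
      msg <- c(msg, sprintf("frequency rows for group %s must sum to 1",
                            names(object@groupCounts)[k]))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Phenotypes, covariates and global measures for association analysis
#'
#' @slot sampleIds character.
#' @slot phenotypes numeric matrix, samples x phenotypes, real units.
#' @slot covariates data.frame aligned to samples (e.g. `age`, `sex`, `site`,
#'   a scan-quality proxy, a diagnosis flag); `site` may be a factor and
#'   enters models as indicator contrasts.
#' @slot globals numeric matrix of global measures (e.g. total surface area).
#' @slot globalMap named character mapping each phenotype column to the
#'   global-measure column regressed out when `adjustGlobal = TRUE`.
#' @export
setClass("PhenotypeTable",
  representation(
    sampleIds = "character",
    phenotypes = "matrix",
    covariates = "data.frame",
    globals = "matrix",
    globalMap = "character"
  )
)

setValidity("PhenotypeTable", function(object) {
  msg <- character(0)
  n <- length(object@sampleIds)
  if (nrow(object@phenotypes) != n || nrow(object@covariates) != n ||
      nrow(object@globals) != n)
    msg <- c(msg, "phenotypes, covariates and globals must align to sampleIds")
  v <- apply(object@phenotypes, 2, stats::var)
  if (any(!is.na(v) & v == 0))
    msg <- c(msg, "phenotype columns must not be constant")
  if (length(object@globalMap) &&
      !all(object@globalMap %in% colnames(object@globals)))
    msg <- c(msg, "globalMap must reference columns of globals")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      sprintf("%d ref individuals, %d study, L = %d SNPs",
              object@nRefIndividuals, object@nStudy, object@nSnps), "\n")
  cat(sprintf("  q = %.3f, divergence = %.2f, error rate = %.3f, seed = %d\n",
              object@invFreq, object@divergence, object@genotypeErrorRate,
              object@seed))
  cat(sprintf("  %d inversion(s), %d phenotype(s)\n",
              object@nInversions, object@nPhenotypes))
})

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d haplotypes (%d I / %d NI) x %d SNPs\n",
              nrow(object@haplotypes), sum(object@orientation == "I"),
              sum(object@orientation == "NI"), ncol(object@haplotypes)))
})

setMethod("show", "CohortGenotypes", function(object) {
  cat(sprintf("CohortGenotypes: %d samples x %d SNPs (%.1f%% missing)\n",
              dim(object@posteriors)[1], dim(object@posteriors)[2],
              100 * mean(object@missing)))
})

setMethod("show", "ReferenceModel", function(object) {
  cat(sprintf("ReferenceModel '%s': %d SNPs; group counts NN=%d NI=%d II=%d\n",
              object@inversionId, nrow(object@snpMeta),
              object@groupCounts["NN"], object@groupCounts["NI"],
              object@groupCounts["II"]))
  cat(sprintf("  mean rho^2 = %.3f, max = %.3f\n",
              mean(object@weights), max(object@weights)))
})

setMethod("show", "PhenotypeTable", function(object) {
  cat(sprintf("PhenotypeTable: %d samples, %d phenotypes, %d covariates, %d globals\n",
              length(object@sampleIds), ncol(object@phenotypes),
              ncol(object@covariates), ncol(object@globals)))
})

#' @describeIn HaplotypePanel-class number of SNPs in the region
#' @param panel,object a panel, cohort or model object
#' @export
nSnps <- function(object) {
  if (is(object, "HaplotypePanel")) return(ncol(object@haplotypes))
  if (is(object, "CohortGenotypes")) return(dim(object@posteriors)[2])
  if (is(object, "ReferenceModel")) return(dim(object@freqs)[1])
  stop("nSnps() not defined for class ", class(object))
}

#' Accessors for panel, cohort and model objects
#'
#' Small read-only accessors: `haplotypes()`, `orientation()`, `snpMeta()`,
#' `posteriors()`, `sampleIds()`, `weights()` (per-SNP rho^2),
#' `genotypeFreqs()` (the L x 3 x 3 frequency array) and `groupCounts()`.
#'
#' @param object the S4 object to inspect.
#' @name accessors
NULL

#' @rdname accessors
#' @export
haplotypes <- function(object) object@haplotypes

#' @rdname accessors
#' @export
orientation <- function(object) object@orientation

#' @rdname accessors
#' @export
snpMeta <- function(object) object@snpMeta

#' @rdname accessors
#' @export
posteriors <- function(object) object@posteriors

#' @rdname accessors
#' @export
sampleIds <- function(object) object@sampleIds

#' @rdname accessors
#' @export
snpWeights <- function(object) object@weights

#' @rdname accessors
#' @export
genotypeFreqs <- function(object) object@freqs

#' @rdname accessors
#' @export
groupCounts <- function(object) object@groupCounts

#' @rdname accessors
#' @export
phenotypes <- function(object) object@phenotypes

#' @rdname accessors
#' @export
covariates <- function(object) object@covariates

#' @rdname accessors
#' @export
globalMeasures <- function(object) object@globals
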