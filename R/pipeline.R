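# End-to-end orchestration: simulate (optional) -> build reference -> call ->
# associate -> (optional) generalize, with all artifacts written to disk.

#' Build a pipeline run configuration
#'
#' Collects input paths (or a simulation config), QC thresholds and output
#' location for [runPipeline()]. Thresholds default to the standard values:
#' at least 15 SNPs and a score difference of 0.1 for a call; 10%/5%
#' individual/SNP missingness, Hardy-Weinberg p 1e-6 and MAF 0.01 for
#' genotype QC; relatedness 0.1; alpha 0.05 and genome-wide alpha 5e-8.
#'
#' @param simulation a [SimulationConfig-class] to generate inputs, or
#'   `NULL` to read them from files.
#' @param genotypesVcf,referenceVcf,orientationTsv,referenceModelJson input
#'   paths used when `simulation` is `NULL` (either a phased panel or a
#'   pre-built JSON model).
#' @param outDir output directory (created if needed).
#' @param minSnps,minDiff inversion-call QC thresholds.
#' @param alpha,gwAlpha significance levels.
#' @param relatednessThreshold GRM pruning cutoff.
#' @param adjustGlobal residualize regional phenotypes on their global
#'   measure.
#' @param generalize also simulate a replication cohort and compute
#'   generalization statistics (simulation mode only).
#' @param betaCorr true cross-cohort effect correlation used when
#'   `generalize = TRUE`.
#' @param verbose print stage messages.
#' @return A named list, validated.
#' @export
runConfig <- function(simulation = NULL,
                      genotypesVcf = NULL, referenceVcf = NULL,
                      orientationTsv = NULL, referenceModelJson = NULL,
                      outDir = tempfile("invTyper_run_"),
                      minSnps = 15L, minDiff = 0.1,
                      alpha = 0.05, gwAlpha = 5e-8,
                      relatednessThreshold = 0.1,
                      adjustGlobal = FALSE,
                      generalize = FALSE, betaCorr = 0.8,
                      verbose = FALSE) {
  stopifnot(minSnps >= 1, minDiff >= 0, alpha > 0, alpha < 1, gwAlpha > 0)
  if (is.null(simulation) && is.null(genotypesVcf))
    stop("either a simulation config or genotype inputs are required")
  list(simulation = simulation, genotypesVcf = genotypesVcf,
       referenceVcf = referenceVcf, orientationTsv = orientationTsv,
       referenceModelJson = referenceModelJson, outDir = outDir,
       minSnps = as.integer(minSnps), minDiff = minDiff, alpha = alpha,
       gwAlpha = gwAlpha, relatednessThreshold = relatednessThreshold,
       adjustGlobal = adjustGlobal, generalize = generalize,
       betaCorr = betaCorr, verbose = verbose)
}

.stageMsg <- function(cfg, ...) if (isTRUE(cfg$verbose)) message("[invTyper] ", ...)

#' Run the full inversion genotyping and association pipeline
#'
#' Executes the stages in order and writes: `calls.tsv` (per sample and
#' inversion: scores, genotype, dosage, QC flags), `association.tsv`
#' (per inversion and phenotype: beta, se, t, p, incremental R^2, tier),
#' `multiplicity.json` (effective number of tests, eigenvalues, threshold),
#' optionally `generalization.json`, and `run.log` recording the seed,
#' package/R versions and every threshold. Outputs are deterministic given
#' the simulation seed.
#'
#' @param cfg configuration from [runConfig()].
#' @return Invisibly, a list with the in-memory results (`calls`,
#'   `association`, `multiplicity`, `generalization`, `outDir`).
#' @export
runPipeline <- function(cfg) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  simCfg <- cfg$simulation

  if (!is.null(simCfg)) {
    .stageMsg(cfg, "simulating reference panel(s) and cohort")
    panels <- lapply(seq_len(simCfg@nInversions), function(m)
      simulateReferencePanel(simCfg, region = m))
    sim <- simulateCohort(simCfg, panel = panels[[1]])
    regions <- sim$regions
    pheno <- simulatePhenotypes(sim$truth, simCfg, sex = sim$sex)
    refs <- lapply(seq_along(panels), function(m)
      buildReference(panels[[m]], inversionId = sprintf("inv%d", m)))
  } else {
    .stageMsg(cfg, "reading genotypes and reference")
    regions <- list(readGenotypeRegion(cfg$genotypesVcf))
    refs <- list(
      if (!is.null(cfg$referenceModelJson))
        deserializeReferenceModel(cfg$referenceModelJson)
      else buildReference(readReferencePanel(cfg$referenceVcf,
                                             cfg$orientationTsv)))
    pheno <- NULL
  }

  .stageMsg(cfg, "calling inversion genotypes")
  callList <- lapply(seq_along(regions), function(m) {
    cc <- callCohort(regions[[m]], refs[[m]],
                     minSnps = cfg$minSnps, minDiff = cfg$minDiff)
    cbind(inversionId = refs[[m]]@inversionId, cc$calls,
          stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, callList)
  utils::write.table(calls, file.path(cfg$outDir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  association <- NULL
  multiplicity <- NULL
  if (!is.null(pheno)) {
    D <- do.call(cbind, lapply(callList, function(x) x$dosage))
    colnames(D) <- vapply(refs, function(r) r@inversionId, character(1))
    callable <- colMeans(!is.na(D)) > 0
    if (!any(callable))
      stop("association stage: no callable inversion")
    D <- D[, callable, drop = FALSE]
    complete <- stats::complete.cases(D)
    .stageMsg(cfg, "associating (", sum(complete), " samples)")
    Yres <- preresidualize(pheno, adjustGlobal = cfg$adjustGlobal)[complete, ,
                                                                   drop = FALSE]
    Yint <- apply(Yres, 2, rankINT)
    mult <- effectiveTests(stats::cor(Yint), alpha = cfg$alpha)
    assoc <- jointInversionRegression(Yint, D[complete, , drop = FALSE])
    assoc$tier <- significanceTiers(assoc$p, mult, gwAlpha = cfg$gwAlpha)
    utils::write.table(assoc, file.path(cfg$outDir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(tE = mult$tE, eigenvalues = mult$eigenvalues,
           alpha = mult$alpha, bonferroniThreshold = mult$bonferroniThreshold),
      file.path(cfg$outDir, "multiplicity.json"),
      auto_unbox = TRUE, digits = NA)
    association <- assoc
    multiplicity <- mult
  }

  generalization <- NULL
  if (isTRUE(cfg$generalize) && !is.null(simCfg)) {
    .stageMsg(cfg, "generalization analysis")
    two <- simulateTwoCohorts(simCfg, betaCorr = cfg$betaCorr)
    fitOne <- function(side) {
      Yr <- preresidualize(side$phenotypes)
      jointInversionRegression(apply(Yr, 2, rankINT), side$truth)
    }
    disc <- fitOne(two$discovery)
    repl <- fitOne(two$replication)
    gen <- tryCatch({
      pairs <- selectPairs(disc, repl)
      c(betaCorrelation(pairs)[c("rRaw", "rAdjusted", "rP")],
        signConcordance(pairs)[c("concordance", "binomP", "n")])
    }, error = function(e) list(error = conditionMessage(e)))
    jsonlite::write_json(gen, file.path(cfg$outDir, "generalization.json"),
                         auto_unbox = TRUE, digits = NA)
    generalization <- gen
  }

  log <- c(
    sprintf("invTyper %s on R %s", as.character(utils::packageVersion("invTyper")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %s", if (!is.null(simCfg)) simCfg@seed else "NA"),
    sprintf("minSnps: %d", cfg$minSnps),
    sprintf("minDiff: %g", cfg$minDiff),
    sprintf("alpha: %g", cfg$alpha),
    sprintf("gwAlpha: %g", cfg$gwAlpha),
    sprintf("relatednessThreshold: %g", cfg$relatednessThreshold),
    sprintf("adjustGlobal: %s", cfg$adjustGlobal))
  writeLines(log, file.path(cfg$outDir, "run.log"))

  invisible(list(calls = calls, association = association,
                 multiplicity = multiplicity,
                 generalization = generalization, outDir = cfg$outDir))
}
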