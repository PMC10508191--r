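# Readers and writers for the standard formats: study genotypes as VCF with
# GT + GP fields, phased reference panels as VCF plus an orientation table,
# phenotype/covariate TSVs, and the reference model as versioned JSON.

REFMODEL_SCHEMA <- "invTyper-refmodel-1"

.parseRegion <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("region must be 'chrom:start-end' (1-based inclusive)")
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Read study genotypes from a VCF into a cohort container
#'
#' Builds per-sample genotype posteriors: from the `GP` genotype-probability
#' field when present, else from the `DS` dosage field (mass on the two
#' nearest genotypes), else point masses on the hard `GT` call. Missing or
#' half-missing genotypes are masked missing; multi-allelic sites are
#' skipped with a warning.
#'
#' @param path VCF file (plain or bgzipped).
#' @param region optional `"chrom:start-end"` (1-based inclusive) filter.
#' @return A [CohortGenotypes-class].
#' @export
readGenotypeRegion <- function(path, region = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    r <- .parseRegion(region)
    pos <- as.integer(fix[, "POS"])
    keep <- fix[, "CHROM"] == r$chrom & pos >= r$start & pos <= r$end
    if (!any(keep)) stop("region ", region, " contains no records")
  }
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi & keep))
    warning(sum(multi & keep), " multi-allelic site(s) skipped")
  keep <- keep & !multi
  if (!any(keep)) stop("no usable biallelic records")
  vcf@fix <- fix[keep, , drop = FALSE]
  vcf@gt <- vcf@gt[keep, , drop = FALSE]

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gp <- tryCatch(vcfR::extract.gt(vcf, element = "GP"),
                 error = function(e) NULL)
  ds <- tryCatch(vcfR::extract.gt(vcf, element = "DS"),
                 error = function(e) NULL)
  L <- nrow(gt)
  n <- ncol(gt)
  post <- array(0, dim = c(n, L, 3))
  miss <- matrix(FALSE, n, L)
  gtDosage <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(a, function(al) {
      if (length(al) != 2L || any(al == ".") || anyNA(al)) return(NA_integer_)
      sum(as.integer(al))
    }, integer(1))
  }
  for (i in seq_len(L)) {
    d <- gtDosage(gt[i, ])
    pI <- matrix(NA_real_, n, 3)
    if (!is.null(gp) && !all(is.na(gp[i, ]))) {
      sp <- strsplit(gp[i, ], ",", fixed = TRUE)
      for (j in seq_len(n)) {
        v <- suppressWarnings(as.numeric(sp[[j]]))
        if (length(v) == 3L && !anyNA(v)) pI[j, ] <- v / sum(v)
      }
    } else if (!is.null(ds) && !all(is.na(ds[i, ]))) {
      dsv <- suppressWarnings(as.numeric(ds[i, ]))
      for (j in seq_len(n)) {
        x <- dsv[j]
        if (!is.na(x)) {
          x <- min(max(x, 0), 2)
          lo <- floor(x)
          frac <- x - lo
          v <- numeric(3)
          v[lo + 1] <- 1 - frac
          if (lo < 2) v[lo + 2] <- frac
          pI[j, ] <- v
        }
      }
    }
    hard <- which(is.na(pI[, 1]) & !is.na(d))
    for (j in hard) {
      v <- numeric(3)
      v[d[j] + 1L] <- 1
      pI[j, ] <- v
    }
    bad <- is.na(pI[, 1])
    miss[, i] <- bad
    pI[bad, ] <- 0
    post[, i, ] <- pI
  }
  new("CohortGenotypes",
      posteriors = post, missing = miss,
      sampleIds = colnames(gt),
      snpMeta = data.frame(id = ifelse(is.na(vcf@fix[, "ID"]) | vcf@fix[, "ID"] == ".",
                                       paste0(vcf@fix[, "CHROM"], ":", vcf@fix[, "POS"]),
                                       vcf@fix[, "ID"]),
                           chrom = vcf@fix[, "CHROM"],
                           pos = as.integer(vcf@fix[, "POS"]),
                           ref = vcf@fix[, "REF"], alt = vcf@fix[, "ALT"],
                           stringsAsFactors = FALSE),
      sex = integer(0))
}

#' Write a cohort to VCF with GT and GP fields
#'
#' @param cohort a [CohortGenotypes-class].
#' @param path output path (plain-text VCF).
#' @return `path`, invisibly.
#' @export
writeCohortVCF <- function(cohort, path) {
  stopifnot(is(cohort, "CohortGenotypes"))
  sm <- cohort@snpMeta
  n <- dim(cohort@posteriors)[1]
  L <- dim(cohort@posteriors)[2]
  gtStr <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype posterior probabilities\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort@sampleIds), collapse = "\t"))
  body <- vapply(seq_len(L), function(i) {
    P <- matrix(cohort@posteriors[, i, ], nrow = n)
    g <- max.col(P, ties.method = "first")
    cells <- vapply(seq_len(n), function(j) {
      if (cohort@missing[j, i]) return("./.:.")
      sprintf("%s:%.6f,%.6f,%.6f", gtStr[g[j]], P[j, 1], P[j, 2], P[j, 3])
    }, character(1))
    paste(c(sm$chrom[i], sm$pos[i], sm$id[i], sm$ref[i], sm$alt[i],
            ".", "PASS", ".", "GT:GP", cells), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a phased reference panel and its orientation table
#'
#' The VCF must be phased (`|` separators); the orientation TSV maps every
#' haplotype (`sample`, `haplotype` index 1/2) to `I` or `NI`.
#'
#' @param vcfPath phased VCF.
#' @param orientationPath TSV with columns `sample`, `haplotype`,
#'   `orientation`.
#' @return A [HaplotypePanel-class].
#' @export
readReferencePanel <- function(vcfPath, orientationPath) {
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  unphased <- grepl("/", gt, fixed = TRUE)
  dim(unphased) <- dim(gt)
  if (any(unphased)) {
    bad <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype at record ", rownames(gt)[bad[1]],
         " sample ", colnames(gt)[bad[2]])
  }
  samples <- colnames(gt)
  L <- nrow(gt)
  H <- matrix(0L, 2L * length(samples), L)
  for (j in seq_along(samples)) {
    al <- strsplit(gt[, j], "|", fixed = TRUE)
    a1 <- vapply(al, `[`, character(1), 1)
    a2 <- vapply(al, `[`, character(1), 2)
    H[2L * j - 1L, ] <- as.integer(a1)
    H[2L * j, ] <- as.integer(a2)
  }
  ori <- utils::read.delim(orientationPath, stringsAsFactors = FALSE)
  key <- paste(ori$sample, ori$haplotype)
  want <- paste(rep(samples, each = 2L), rep(1:2, length(samples)))
  idx <- match(want, key)
  if (anyNA(idx))
    stop("orientation missing for haplotype(s): ",
         paste(utils::head(want[is.na(idx)], 3), collapse = "; "))
  orient <- ori$orientation[idx]
  new("HaplotypePanel",
      snpMeta = data.frame(id = ifelse(is.na(vcf@fix[, "ID"]) | vcf@fix[, "ID"] == ".",
                                       paste0(vcf@fix[, "CHROM"], ":", vcf@fix[, "POS"]),
                                       vcf@fix[, "ID"]),
                           chrom = vcf@fix[, "CHROM"],
                           pos = as.integer(vcf@fix[, "POS"]),
                           ref = vcf@fix[, "REF"], alt = vcf@fix[, "ALT"],
                           stringsAsFactors = FALSE),
      haplotypes = H,
      orientation = orient,
      familyFreqs = NULL)
}

#' Write a haplotype panel as phased VCF plus orientation TSV
#'
#' @param panel a [HaplotypePanel-class].
#' @param vcfPath,orientationPath output paths.
#' @return `vcfPath`, invisibly.
#' @export
writeReferencePanel <- function(panel, vcfPath, orientationPath) {
  stopifnot(is(panel, "HaplotypePanel"))
  H <- panel@haplotypes
  nInd <- nrow(H) / 2L
  samples <- sprintf("REF%04d", seq_len(nInd))
  sm <- panel@snpMeta
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(ncol(H)), function(i) {
    cells <- sprintf("%d|%d", H[seq(1, 2 * nInd, 2), i], H[seq(2, 2 * nInd, 2), i])
    paste(c(sm$chrom[i], sm$pos[i], sm$id[i], sm$ref[i], sm$alt[i],
            ".", "PASS", ".", "GT", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcfPath)
  ori <- data.frame(sample = rep(samples, each = 2L),
                    haplotype = rep(1:2, nInd),
                    orientation = panel@orientation)
  utils::write.table(ori, orientationPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(vcfPath)
}

#' Serialize a reference model to versioned JSON
#'
#' @param model a [ReferenceModel-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
serializeReferenceModel <- function(model, path) {
  stopifnot(is(model, "ReferenceModel"))
  doc <- list(
    schema = REFMODEL_SCHEMA,
    inversionId = model@inversionId,
    snpMeta = model@snpMeta,
    groupCounts = as.list(model@groupCounts),
    weights = model@weights,
    freqs = stats::setNames(lapply(seq_along(GROUPS), function(k) {
      m <- model@freqs[, , k, drop = FALSE]
      dim(m) <- dim(model@freqs)[1:2]
      m
    }), GROUPS)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deserialize a reference model from JSON
#'
#' @param path JSON written by [serializeReferenceModel()].
#' @return A [ReferenceModel-class].
#' @export
deserializeReferenceModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || doc$schema != REFMODEL_SCHEMA)
    stop("unsupported reference-model schema: ",
         if (is.null(doc$schema)) "(none)" else doc$schema)
  L <- length(doc$weights)
  freqs <- array(NA_real_, dim = c(L, 3, 3),
                 dimnames = list(doc$snpMeta$id, c("0", "1", "2"), GROUPS))
  for (k in GROUPS) freqs[, , k] <- as.matrix(doc$freqs[[k]])
  new("ReferenceModel",
      inversionId = doc$inversionId,
      snpMeta = as.data.frame(doc$snpMeta),
      freqs = freqs,
      weights = as.numeric(doc$weights),
      groupCounts = stats::setNames(as.integer(unlist(doc$groupCounts[GROUPS])),
                                    GROUPS))
}

#' Write a phenotype table (phenotypes, covariates, globals) to TSV
#'
#' @param pheno a [PhenotypeTable-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePhenotypeTSV <- function(pheno, path) {
  stopifnot(is(pheno, "PhenotypeTable"))
  df <- data.frame(sampleId = pheno@sampleIds, pheno@covariates,
                   pheno@globals, pheno@phenotypes,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
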