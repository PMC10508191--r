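test_that("reference model matches hand-computed frequency and LD tables", {
  panel <- handPanel()
  ref <- buildReference(panel, "hand")
  f <- genotypeFreqs(ref)
  # SNP1: perfect tag. individuals: NN group genotypes (0,0,0), NI (1,1), II (2)
  expect_equal(unname(f[1, , "NN"]), c(1, 0, 0))
  expect_equal(unname(f[1, , "NI"]), c(0, 1, 0))
  expect_equal(unname(f[1, , "II"]), c(0, 0, 1))
  # SNP2: NN genotypes (1,0,1) -> (1/3, 2/3, 0)
  expect_equal(unname(f[2, , "NN"]), c(1 / 3, 2 / 3, 0))
  expect_equal(unname(f[2, , "NI"]), c(0, 1, 0))
  expect_equal(unname(f[2, , "II"]), c(0, 0, 1))
  # SNP3: everyone heterozygous
  for (k in c("NN", "NI", "II"))
    expect_equal(unname(f[3, , k]), c(0, 1, 0))
  # weights: perfect tag, weak, uninformative — against brute-force r^2
  H <- haplotypes(panel)
  expected <- vapply(1:3, function(i) bruteR2(H[, i], orientation(panel)),
                     numeric(1))
  expect_equal(snpWeights(ref), expected, tolerance = 1e-12)
  expect_equal(snpWeights(ref)[1], 1)
  expect_equal(snpWeights(ref)[3], 0)
  expect_identical(groupCounts(ref), c(NN = 3L, NI = 2L, II = 1L))
})

test_that("reference model is empirical-frequency exact on simulated panels", {
  cfg <- simConfig(seed = 101, nRefIndividuals = 60, nSnps = 12)
  panel <- simulateReferencePanel(cfg)
  ref <- buildReference(panel)
  expect_equal(genotypeFreqs(ref), bruteFreqs(panel),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("pseudocount smoothing redistributes mass but defaults to off", {
  panel <- handPanel()
  raw <- buildReference(panel)
  sm <- buildReference(panel, smoothing = 1)
  f <- genotypeFreqs(sm)
  # rows still normalize, and no genotype has exactly zero frequency
  for (k in c("NN", "NI", "II")) {
    expect_equal(unname(rowSums(f[, , k])), rep(1, 3), tolerance = 1e-12)
    expect_true(all(f[, , k] > 0))
  }
  # smoothed NN count for SNP1 genotype 0: (3 + 1) / (3 + 3)
  expect_equal(unname(f[1, 1, "NN"]), 4 / 6)
  # default remains the raw empirical table
  expect_equal(unname(genotypeFreqs(raw)[1, , "NN"]), c(1, 0, 0))
})

test_that("the weighted normalization rescales scores by the same factor", {
  set.seed(105)
  model <- randomModel(12)
  post <- randomPosterior(12)
  std <- scoreSample(post, model)
  alt <- scoreSample(post, model, normalization = "weighted")
  pm <- apply(post, 1, max)
  ratio <- sum(pm^2) / sum(pm * snpWeights(model))
  expect_equal(as.numeric(alt), as.numeric(std) * ratio, tolerance = 1e-12)
  # with certainty 1 the weighted form bounds every score by 1
  post1 <- posteriorFromGenotypes(sample(0:2, 12, replace = TRUE))
  expect_true(all(scoreSample(post1, model, normalization = "weighted") <= 1 + 1e-12))
})

test_that("panels without divergence give near-zero weights", {
  cfg <- simConfig(seed = 103, nRefIndividuals = 400, divergence = 0)
  ref <- buildReference(simulateReferencePanel(cfg))
  expect_true(all(snpWeights(ref) < 9 / (2 * 400)))
})

test_that("single-orientation panels are rejected as degenerate", {
  panel <- handPanel()
  panel@orientation <- rep("NI", 12)
  expect_error(buildReference(panel), "degenerate")
})

test_that("similarity scores equal the naive double-loop oracle", {
  set.seed(202)
  for (rep in 1:100) {
    L <- sample(3:25, 1)
    model <- randomModel(L)
    post <- randomPosterior(L, nMissing = sample(0:(L - 2), 1))
    got <- scoreSample(post, model)
    want <- naiveScores(post, genotypeFreqs(model), snpWeights(model))
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
    expect_equal(attr(got, "nSnpsUsed"), sum(stats::complete.cases(post)))
  }
})

test_that("score edge cases: perfect match and uninformative reference", {
  L <- 10
  model <- randomModel(L)
  # point masses on the genotype that group NN says is certain, weights 1
  model@freqs[, , 1] <- 0
  model@freqs[, 1, 1] <- 1            # NN: genotype 0 certain at every SNP
  model@weights <- rep(1, L)
  post <- posteriorFromGenotypes(rep(0L, L), certainty = 1)
  sc <- scoreSample(post, model)
  expect_equal(unname(sc["NN"]), 1)
  # uniform reference: all groups tie at 1/3 (weights 1, certainty 1)
  uni <- model
  for (k in 1:3) uni@freqs[, , k] <- 1 / 3
  scU <- scoreSample(post, uni)
  expect_equal(as.numeric(scU), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("scores are invariant to SNP order and bounded with certainty 1", {
  set.seed(203)
  L <- 15
  model <- randomModel(L)
  post <- posteriorFromGenotypes(sample(0:2, L, replace = TRUE))
  sc <- scoreSample(post, model)
  expect_true(all(sc >= 0 & sc <= 1))
  perm <- sample(L)
  modelP <- model
  modelP@freqs <- model@freqs[perm, , , drop = FALSE]
  modelP@weights <- model@weights[perm]
  modelP@snpMeta <- model@snpMeta[perm, ]
  expect_equal(as.numeric(scoreSample(post[perm, ], modelP)),
               as.numeric(sc), tolerance = 1e-12)
})

test_that("a zero-weight SNP contributes nothing to the numerator but stays in the denominator", {
  set.seed(204)
  L <- 8
  model <- randomModel(L)
  model@weights[4] <- 0
  post <- randomPosterior(L)
  scWith <- scoreSample(post, model)
  postMasked <- post
  postMasked[4, ] <- NA_real_
  scWithout <- scoreSample(postMasked, model)
  denomWith <- sum(apply(post, 1, max)^2)
  denomWithout <- sum(apply(post[-4, ], 1, max)^2)
  # numerators agree exactly; scores differ only through the denominator
  expect_equal(as.numeric(scWith) * denomWith,
               as.numeric(scWithout) * denomWithout, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(as.numeric(scWith), as.numeric(scWithout))))
})

test_that("genotype calling applies call-rate, score-difference and tie QC", {
  pass <- callGenotype(c(NN = 0.9, NI = 0.5, II = 0.3), nSnpsUsed = 20)
  expect_true(pass$qcPass)
  expect_identical(pass$genotype, "NN")
  expect_identical(pass$dosage, 0L)
  expect_equal(pass$scoreDiff, 0.4)

  diffFail <- callGenotype(c(NN = 0.9, NI = 0.85, II = 0.1), nSnpsUsed = 20)
  expect_false(diffFail$qcPass)
  expect_true(diffFail$failScoreDiff)
  expect_true(is.na(diffFail$genotype))

  rateFail <- callGenotype(c(NN = 0.9, NI = 0.5, II = 0.3), nSnpsUsed = 10)
  expect_false(rateFail$qcPass)
  expect_true(rateFail$failCallRate)

  tie <- callGenotype(c(NN = 0.6, NI = 0.6, II = 0.2), nSnpsUsed = 20,
                      minDiff = 0)
  expect_false(tie$qcPass)
  expect_true(tie$failTie)
})

test_that("clean cohorts are fully callable and recover simulated truth", {
  cfg <- simConfig(seed = 301, nStudy = 400, nRefIndividuals = 300,
                   divergence = 0.49, genotypeErrorRate = 0)
  panel <- simulateReferencePanel(cfg)
  ref <- buildReference(panel)
  sim <- simulateCohort(cfg, panel)
  cc <- callCohort(sim$regions[[1]], ref)
  expect_equal(cc$callability, 1.0)
  expect_identical(cc$calls$genotype, genotypeLabels(sim$truth[, 1]))
})

test_that("short panels fail the call-rate criterion; empty cohorts error", {
  cfg <- simConfig(seed = 303, nStudy = 30, nSnps = 10, divergence = 0.49)
  panel <- simulateReferencePanel(cfg)
  sim <- simulateCohort(cfg, panel)
  cc <- callCohort(sim$regions[[1]], buildReference(panel))
  expect_equal(cc$callability, 0)
  expect_true(all(cc$calls$failCallRate))
  empty <- sim$regions[[1]]
  empty@posteriors <- empty@posteriors[0, , , drop = FALSE]
  empty@missing <- empty@missing[0, , drop = FALSE]
  empty@sampleIds <- character(0)
  empty@sex <- integer(0)
  expect_error(callCohort(empty, buildReference(panel)), "empty cohort")
})

test_that("tag-SNP selection finds planted high-LD SNPs and sorts by r^2", {
  cfg <- simConfig(seed = 305, divergence = 0.49, plantPerfectTag = TRUE)
  panel <- simulateReferencePanel(cfg)
  rules <- selectTagSnps(panel)
  expect_gt(nrow(rules), 0)
  expect_equal(rules$r2[1], 1)
  expect_identical(rules$snpId[1], snpMeta(panel)$id[1])
  expect_true(all(diff(rules$r2) <= 0))
  expect_true(all(rules$r2 >= 0.9))
  # no divergence -> no tags
  flat <- simulateReferencePanel(simConfig(seed = 305, divergence = 0))
  expect_equal(nrow(selectTagSnps(flat)), 0)
})

test_that("tag-SNP calls map inverted-allele dosage to genotype", {
  cfg <- simConfig(seed = 307, nStudy = 500, divergence = 0.49,
                   plantPerfectTag = TRUE, genotypeErrorRate = 0)
  panel <- simulateReferencePanel(cfg)
  sim <- simulateCohort(cfg, panel)
  rules <- selectTagSnps(panel)
  tag <- callByTagSnp(sim$regions[[1]], rules[1, ])
  # perfect tag, no error: tag calls equal simulated truth
  expect_identical(unname(tag), genotypeLabels(sim$truth[, 1]))
  # and equal score-based calls
  cc <- callCohort(sim$regions[[1]], buildReference(panel))
  conc <- methodConcordance(cc$calls, tag)
  expect_equal(conc$accuracy, 1.0)
  # missing tag SNP -> all missing, with a warning
  bogus <- tagSnpRule("inv1", "nonexistent", "alt")
  expect_warning(tagNA <- callByTagSnp(sim$regions[[1]], bogus), "not present")
  expect_true(all(is.na(tagNA)))
})

test_that("concordance handles error injection and empty overlap", {
  a <- c(S1 = "NN", S2 = "NI", S3 = "II", S4 = NA)
  expect_equal(methodConcordance(a, a)$accuracy, 1.0)
  b <- c(S1 = "NN", S2 = "NN", S3 = "II", S4 = "NN")
  got <- methodConcordance(a, b)
  expect_equal(got$accuracy, 2 / 3)
  expect_equal(got$nCompared, 3)
  allMissing <- c(S1 = NA_character_, S2 = NA_character_)
  expect_error(methodConcordance(a[1:2], allMissing), "undefined")
})

test_that("genotyping degrades monotonically with genotype error", {
  accs <- vapply(c(0, 0.02, 0.05, 0.1), function(eps) {
    cfg <- simConfig(seed = 311, nStudy = 300, divergence = 0.49,
                     genotypeErrorRate = eps, plantPerfectTag = TRUE)
    panel <- simulateReferencePanel(cfg)
    sim <- simulateCohort(cfg, panel)
    cc <- callCohort(sim$regions[[1]], buildReference(panel))
    ok <- cc$calls$qcPass
    mean(cc$calls$genotype[ok] == genotypeLabels(sim$truth[ok, 1]))
  }, numeric(1))
  expect_true(all(diff(accs) <= 1e-9))
})

test_that("genotype summary computes allele frequency and HWE", {
  mkCalls <- function(nNN, nNI, nII) {
    data.frame(genotype = rep(c("NN", "NI", "II"), c(nNN, nNI, nII)),
               qcPass = TRUE, stringsAsFactors = FALSE)
  }
  hw <- genotypeSummary(mkCalls(640, 320, 40))
  expect_equal(hw$invAlleleFreq, 0.2)
  expect_gt(hw$hweP, 0.9)
  bad <- genotypeSummary(mkCalls(500, 0, 500))
  expect_equal(bad$invAlleleFreq, 0.5)
  expect_lt(bad$hweP, 1e-10)
  expect_error(genotypeSummary(data.frame(genotype = "NN", qcPass = FALSE)),
               "no QC-passing")
})
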