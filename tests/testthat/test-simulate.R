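test_that("config validation rejects out-of-range parameters", {
  expect_error(simConfig(maf = 0.6), "maf")
  expect_error(simConfig(nCases = 0), "nCases")
  expect_error(simConfig(oddsRatio = -1), "oddsRatio")
  expect_error(simConfig(certainty = 0.2), "certainty")
  expect_error(simConfig(trueAltFraction = 1), "trueAltFraction")
  expect_error(simConfig(refBias = 0.5), "refBias")
  expect_error(simConfig(nCorrelated = 10, nGenes = 10), "nCorrelated")
  expect_error(simConfig(deOverlap = 200, nDe = 150), "deOverlap")
  expect_error(simConfig(flankLen = 50, rssOffset = 30), "flank too short")
  expect_error(simConfig(peakTssWithinFrac = 1.2), "peakTssWithinFrac")
})

test_that("generators are pure functions of the config seed", {
  cfg <- simConfig(seed = 99, nCases = 50L, nControls = 50L)
  expect_identical(simulateCaseControl(cfg, panel = TRUE),
    simulateCaseControl(cfg, panel = TRUE))
  cfgC <- simConfig(seed = 99, nGenes = 100L, nCorrelated = 10L,
    nDe = 10L, deOverlap = 2L, nSamplesCohort = 20L)
  a <- simulateExpressionCohort(cfgC)
  b <- simulateExpressionCohort(cfgC)
  expect_identical(tpm(a$te), tpm(b$te))
  expect_identical(simulateBreakpointLocus(cfg)$seq,
    simulateBreakpointLocus(cfg)$seq)
  expect_identical(simulateAllelicReads(cfg)$reads,
    simulateAllelicReads(cfg)$reads)
})

test_that("case/control allele frequencies follow the configured odds ratio", {
  # null effect: equal frequencies in expectation
  cfg0 <- simConfig(seed = 7, oddsRatio = 1, nCases = 20000L, nControls = 20000L)
  cc0 <- simulateCaseControl(cfg0)
  expect_equal(cc0$truth$caseFreq, cfg0$maf)
  calls <- hardCalls(cc0$genotypes)[, 1]
  fCase <- mean(calls[cc0$phenotype]) / 2
  fCtrl <- mean(calls[!cc0$phenotype]) / 2
  expect_lt(abs(fCase - fCtrl), 0.02)
  expect_lt(abs(fCtrl - 0.3), 0.02)

  # allele-scale odds ratio reproduced in truth
  cfg <- simConfig(seed = 7)
  cc <- simulateCaseControl(cfg)
  f <- cfg$maf
  expect_equal(cc$truth$caseFreq / (1 - cc$truth$caseFreq) / (f / (1 - f)),
    1.45, tolerance = 1e-12)
})

test_that("genotypes are Hardy-Weinberg within each phenotype group", {
  cfg <- simConfig(seed = 13, nCases = 30000L, nControls = 30000L)
  cc <- simulateCaseControl(cfg)
  calls <- hardCalls(cc$genotypes)[, 1]
  for (grp in list(cc$phenotype, !cc$phenotype)) {
    g <- calls[grp]
    f <- mean(g) / 2
    expect_lt(abs(mean(g == 2) - f^2), 0.01)
    expect_lt(abs(mean(g == 1) - 2 * f * (1 - f)), 0.01)
  }
})

test_that("simulated posteriors are valid triples with the stated concentration", {
  gt <- GenotypeTable(matrix(c(0L, 1L, 2L, 1L), 2, 2))
  post <- simulatePosteriors(gt, 0.9)
  gp <- posteriorProbs(post)
  expect_true(all(abs(apply(gp, c(1, 2), sum) - 1) < 1e-12))
  expect_equal(gp[1, 1, 1], 0.9) # mass on the true call
  expect_equal(gp[1, 1, 2], 0.05)
  expect_error(simulatePosteriors(gt, 0.2), "certainty")
  # full certainty: every INFO score is 1
  expect_true(all(infoFilter(simulatePosteriors(gt, 1))$scores == 1))
  # half certainty: informative variant scores below 1
  half <- infoFilter(simulatePosteriors(gt, 0.5))
  expect_true(all(half$scores < 1))
})

test_that("eQTL generator plants a dosage-monotone effect", {
  cfg <- simConfig(seed = 3, exprNoiseSd = 0)
  sim <- simulateEqtl(c(0L, 1L, 2L, 0L, 2L), simConfig(seed = 3,
    exprNoiseSd = 0, foldPerRiskHomozygote = 4, nondisomicFrac = 0))
  vals <- tpm(sim$te)[1, ]
  g <- sim$genotype
  # noiseless: exact dosage-monotone group means, hom ratio = fold
  expect_equal(mean(vals[g == 2]) / mean(vals[g == 0]), 4, tolerance = 1e-9)
  expect_equal(mean(vals[g == 1]) / mean(vals[g == 0]), 2, tolerance = 1e-9)
  expect_error(simulateEqtl(integer(0), cfg), "empty")
})

test_that("expression cohort plants the driver, targets and DE overlap", {
  cfg <- simConfig(seed = 21, nGenes = 500L, nCorrelated = 25L,
    nDe = 40L, deOverlap = 10L, nSamplesCohort = 117L, targetRho = 0.9)
  sim <- simulateExpressionCohort(cfg)
  expect_equal(sum(rownames(tpm(sim$te)) == cfg$driver), 1)
  expect_length(sim$truth$correlated, 25)
  expect_length(sim$truth$de, 40)
  expect_length(sim$truth$overlap, 10)
  # strongly correlated targets are all captured at the stringent cut
  corr <- spearmanToDriver(sim$te, cfg$driver)
  got <- correlatedGeneSet(corr, 5e-4, cfg$driver)
  expect_true(all(sim$truth$correlated %in% got))
  # and they head the |rho| ranking
  ord <- corr$gene[order(-abs(corr$rho))]
  expect_true(all(sim$truth$correlated %in% ord[seq_len(30)]))
})

test_that("translocated cases are appended, flagged and planted at the target", {
  cfg <- simConfig(seed = 31, nGenes = 200L, nCorrelated = 10L, nDe = 10L,
    deOverlap = 2L, nSamplesCohort = 50L)
  cohort <- simulateExpressionCohort(cfg)
  tx <- simulateTranslocatedCases(cohort$te, cfg)
  fl <- as.logical(colData(tx$te)$translocated)
  expect_equal(sum(fl), 2)
  expect_identical(colnames(tpm(tx$te))[fl], tx$truth$cases)
  expect_false(any(fl[seq_len(50)])) # flags only on appended cases
  # planted exactly: cohort mean + z * cohort SD on the TPM scale
  z <- translocationZscore(tx$te, cfg$driver)
  expect_equal(unname(z$z), rep(4.6, 2), tolerance = 1e-9)
})

test_that("peak/TSS layout hits the configured proximal fraction exactly", {
  for (frac in c(0, 0.5, 1)) {
    cfg <- simConfig(seed = 41, nPeaks = 200L, peakTssWithinFrac = frac,
      chromLen = 2e6)
    sim <- simulatePeaksTss(cfg)
    got <- assignPeaksToTss(sim$peaks, sim$tss, cfg$tssWindow)
    expect_setequal(unique(got$gene), sim$truth$within)
    expect_length(sim$truth$within, round(frac * 200))
    # brute-force distance check
    want <- bruteAssign(sim$peaks, sim$tss, cfg$tssWindow)
    expect_setequal(unique(want$gene), sim$truth$within)
  }
})
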