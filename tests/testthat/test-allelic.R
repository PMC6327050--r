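test_that("reference masking replaces exactly the listed positions", {
  expect_identical(maskReference("ACGT", 2), "ANGT")
  expect_identical(maskReference("ACGT", integer(0)), "ACGT")
  expect_identical(maskReference("ACGT", c(1, 4)), "NCGN")
  expect_error(maskReference("ACGT", 5), "5")
})

test_that("allelic read counting tallies by base with quality filters", {
  site <- list(site = "rs1", chrom = "chr14", pos = 100, ref = "A", alt = "G")
  pile <- data.frame(chrom = "chr14", pos = 100,
    base = c(rep("A", 7), rep("G", 3), "N"),
    baseq = c(rep(30, 10), 30), mapq = rep(60, 11))
  ac <- countAllelicReads(pile, site)
  expect_identical(ac@kRef, 7L)
  expect_identical(ac@kAlt, 3L)
  expect_identical(ac@kOther, 1L) # the N read

  # low base quality moves a read to kOther; low MAPQ removes it entirely
  pile$baseq[1] <- 5
  pile$mapq[2] <- 10
  ac2 <- countAllelicReads(pile, site)
  expect_identical(ac2@kRef, 5L)
  expect_identical(ac2@kOther, 2L)

  empty <- countAllelicReads(pile[0, ], site)
  expect_identical(empty@flag, "uncovered")
  expect_identical(empty@kRef + empty@kAlt, 0L)
})

test_that("minlike binomial p matches pmf enumeration on the worked cases", {
  expect_equal(binomialBiasTest(5, 10)$p, 1) # modal outcome
  expect_equal(binomialBiasTest(9, 10)$p, 22 / 1024, tolerance = 1e-12)
  expect_equal(binomialBiasTest(0, 1, p0 = 0.5)$p, 1)
  zero <- binomialBiasTest(0, 0)
  expect_true(is.na(zero$p))
  expect_identical(zero$flag, "no-reads")
})

test_that("minlike p agrees with binom.test across random cases", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(binomialBiasTest(k, n, p0)$p,
      binom.test(k, n, p0)$p.value, tolerance = 1e-9)
  }
})

test_that("central and one-sided alternatives behave as documented", {
  expect_equal(binomialBiasTest(9, 10, alternative = "greater")$p,
    pbinom(8, 10, 0.5, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(binomialBiasTest(9, 10, alternative = "less")$p,
    pbinom(9, 10, 0.5), tolerance = 1e-12)
  cent <- binomialBiasTest(9, 10, alternative = "central")$p
  expect_equal(cent, min(1, 2 * pbinom(8, 10, 0.5, lower.tail = FALSE)),
    tolerance = 1e-12)
  # mid-p is smaller than the exact p but non-negative
  mid <- binomialBiasTest(9, 10, midp = TRUE)$p
  expect_lt(mid, 22 / 1024)
  expect_gte(mid, 0)
})

test_that("the input-DNA gate labels only assay-specific imbalance", {
  a <- AllelicCount("rs1", 35, 15, assay = "H3K27ac")
  i <- AllelicCount("rs1", 25, 25, assay = "input")
  res <- pairedBiasAssessment(a, i)
  expect_true(res$alleleSpecific)
  expect_lt(res$assay$p, 0.05)
  expect_gte(res$input$p, 0.05)

  # balanced assay: no label
  expect_false(pairedBiasAssessment(
    AllelicCount("rs1", 25, 25), AllelicCount("rs1", 25, 25))$alleleSpecific)
  # input artefact: both skewed, no label
  expect_false(pairedBiasAssessment(
    AllelicCount("rs1", 35, 15), AllelicCount("rs1", 36, 14))$alleleSpecific)
  expect_error(pairedBiasAssessment(a,
    AllelicCount("rs2", 25, 25)), "different sites")
})

test_that("reference bias shifts retained counts and masking removes it", {
  # closed form: f=0.5, bias 2 gives retained alt fraction 1/3
  afUn <- afMa <- numeric(100)
  for (i in 1:100) {
    cfg <- simConfig(seed = 500 + i, trueAltFraction = 0.5, refBias = 2)
    sim <- simulateAllelicReads(cfg)
    afUn[i] <- sim$unmasked@kAlt / (sim$unmasked@kRef + sim$unmasked@kAlt)
    afMa[i] <- sim$masked@kAlt / (sim$masked@kRef + sim$masked@kAlt)
  }
  expect_lt(abs(mean(afUn) - 1 / 3), 0.02)
  expect_lt(abs(mean(afMa) - 0.5), 0.02)
  # per-replicate: masking moves the estimate toward truth in >= 95% of runs
  closer <- abs(afMa - 0.5) <= abs(afUn - 0.5)
  expect_gte(mean(closer), 0.95)
})

test_that("bias at a non-maskable site is not modelled as removable", {
  cfg <- simConfig(seed = 77, trueAltFraction = 0.5, refBias = 2)
  sim <- simulateAllelicReads(cfg, maskable = FALSE)
  expect_identical(sim$unmasked@kAlt, sim$masked@kAlt)
})
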