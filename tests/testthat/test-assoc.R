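test_that("allelic association recovers the 2x2 cross-product odds ratio", {
  # cases carry 60 risk / 40 other alleles, controls 40 / 60
  g <- c(rep(2L, 20), rep(1L, 20), rep(0L, 10), rep(2L, 10), rep(1L, 20), rep(0L, 20))
  ph <- rep(c(TRUE, FALSE), each = 50)
  res <- allelicAssociation(g, ph)
  expect_equal(res$or, (60 * 60) / (40 * 40))
  expect_equal(res$se, sqrt(1 / 60 + 1 / 40 + 1 / 40 + 1 / 60))

  # identical allele frequencies: OR 1, p 1
  null <- allelicAssociation(c(g[1:50], g[1:50]), ph)
  expect_equal(null$or, 1)
  expect_equal(null$p, 1)
})

test_that("zero cells get the Haldane-Anscombe correction, monomorphics are flagged", {
  g <- c(rep(2L, 5), rep(1L, 5)) # cases all hom-risk: zero 'other' cell
  ph <- rep(c(TRUE, FALSE), each = 5)
  res <- allelicAssociation(g, ph)
  expect_identical(res$flag, "corrected")
  expect_equal(res$or, (10.5 * 5.5) / (0.5 * 5.5)) # corrected cross-product
  expect_true(is.finite(res$or))

  mono <- allelicAssociation(rep(0L, 10), ph)
  expect_identical(mono$flag, "monomorphic")
  expect_true(is.na(mono$or))
})

test_that("fixed-effect meta matches the hand formula and the identity case", {
  m <- fixedEffectMeta(c(0.5, 0.3), c(0.1, 0.2)) # weights 100, 25
  expect_equal(m$beta, 0.46, tolerance = 1e-12)
  expect_equal(m$se, 1 / sqrt(125), tolerance = 1e-12)
  expect_equal(m$Q, 0.8, tolerance = 1e-12)
  expect_equal(m$pHet, pchisq(0.8, 1, lower.tail = FALSE), tolerance = 1e-12)

  one <- fixedEffectMeta(0.4, 0.15)
  expect_equal(one$beta, 0.4)
  expect_equal(one$se, 0.15)
  expect_equal(one$Q, 0)
  expect_equal(one$pHet, 1) # df-0 convention

  same <- fixedEffectMeta(rep(0.2, 4), rep(0.1, 4))
  expect_equal(same$Q, 0)
  expect_equal(same$pHet, 1)
})

test_that("meta of k identical copies keeps beta and scales se by 1/sqrt(k)", {
  for (k in c(2, 3, 7)) {
    m <- fixedEffectMeta(rep(0.37, k), rep(0.12, k))
    expect_equal(m$beta, 0.37)
    expect_equal(m$se, 0.12 / sqrt(k), tolerance = 1e-12)
  }
})

test_that("meta agrees with an established fixed-effect implementation", {
  skip_if_not_installed("metafor")
  set.seed(11)
  for (i in 1:5) {
    b <- rnorm(4)
    s <- runif(4, 0.05, 0.3)
    m <- fixedEffectMeta(b, s)
    r <- metafor::rma(yi = b, sei = s, method = "FE")
    expect_equal(m$beta, as.numeric(r$beta), tolerance = 1e-8)
    expect_equal(m$se, r$se, tolerance = 1e-8)
    expect_equal(m$Q, r$QE, tolerance = 1e-8)
  }
})

test_that("INFO score matches the ratio formula and its conventions", {
  # point-mass triples carry full information
  expect_equal(infoScore(rbind(c(1, 0, 0), c(0, 0, 1)))$info, 1)
  # two-sample hand computation: theta 0.375, info 1 - 0.25/0.9375 = 11/15
  res <- infoScore(rbind(c(0.5, 0.5, 0), c(0, 1, 0)))
  expect_equal(res$theta, 0.375, tolerance = 1e-12)
  expect_equal(res$info, 11 / 15, tolerance = 1e-12)
  # monomorphic convention
  expect_equal(infoScore(rbind(c(1, 0, 0), c(1, 0, 0)))$info, 1)
  expect_error(infoScore(rbind(c(0.5, 0.2, 0.2))), "sum to 1")
})

test_that("INFO equals an independent per-sample implementation on random tables", {
  set.seed(71)
  for (i in 1:1000) {
    n <- sample(2:20, 1)
    raw <- matrix(runif(3 * n), n, 3)
    gp <- raw / rowSums(raw)
    got <- infoScore(gp)$info
    # independent route: explicit per-sample loop over the variance terms
    num <- 0
    esum <- 0
    for (s in seq_len(n)) {
      e <- gp[s, 2] + 2 * gp[s, 3]
      f <- gp[s, 2] + 4 * gp[s, 3]
      num <- num + (f - e^2)
      esum <- esum + e
    }
    th <- esum / (2 * n)
    want <- if (th <= 0 || th >= 1) 1 else
      min(max(1 - num / (2 * n * th * (1 - th)), 0), 1)
    expect_lt(abs(got - want), 1e-10)
  }
})

test_that("INFO filtering drops exactly the variants below threshold", {
  calls <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L), 3, 2,
    dimnames = list(paste0("s", 1:3), c("good", "poor")))
  gt <- simulatePosteriors(GenotypeTable(calls), certainty = 1)
  expect_equal(unname(infoFilter(gt)$scores), c(1, 1))
  gt2 <- simulatePosteriors(GenotypeTable(calls), certainty = 0.5)
  sc <- infoFilter(gt2, infoMin = 0.8)
  expect_true(all(sc$scores < 1))
  expect_identical(sc$keep, names(sc$scores)[sc$scores >= 0.8])
})

test_that("dosage r2 is 1 for identical and complementary coding, NA for constants", {
  a <- c(0, 1, 2, 1, 0, 2)
  expect_equal(ldR2(a, a), 1)
  expect_equal(ldR2(a, 2 - a), 1)
  expect_true(is.na(ldR2(a, rep(1, 6))))
})

test_that("independent variants have near-zero r2", {
  set.seed(5)
  r2 <- replicate(100, ldR2(rbinom(1000, 2, 0.3), rbinom(1000, 2, 0.3)))
  expect_gte(mean(r2 < 0.02), 0.95)
})

test_that("LD block capture returns exactly the planted proxies", {
  cfg <- simConfig(seed = 3, nCases = 500L, nControls = 500L)
  cc <- simulateCaseControl(cfg, panel = TRUE)
  cap <- ldBlockCapture(cc$genotypes, "rs_lead")
  expect_setequal(cap$captured, cc$truth$proxies)
  expect_equal(cap$fraction, 1)
  # brute-force equivalence on the same instance
  expect_setequal(cap$captured,
    bruteBlock(dosages(cc$genotypes), "rs_lead", 0.4, 0.01))
  # vacuous capture with the lead alone
  solo <- GenotypeTable(matrix(c(0L, 1L, 2L, 1L), 4, 1,
    dimnames = list(paste0("s", 1:4), "rs_lead")))
  expect_equal(ldBlockCapture(solo, "rs_lead")$fraction, 1)
})

test_that("the MAF gate excludes a perfectly correlated low-frequency proxy", {
  lead <- c(rep(2L, 10), rep(1L, 20), rep(0L, 70))
  calls <- cbind(rs_lead = lead, proxy_low = lead)
  rownames(calls) <- paste0("s", 1:100)
  gt <- GenotypeTable(calls)
  expect_identical(ldBlockCapture(gt, "rs_lead", mafMin = 0.01)$captured, "proxy_low")
  expect_length(ldBlockCapture(gt, "rs_lead", mafMin = 0.3)$captured, 0)
})

test_that("conditional association flags degenerate covariates and reduces cleanly", {
  set.seed(9)
  g <- rbinom(400, 2, 0.3)
  ph <- rbinom(400, 1, plogis(-0.5 + 0.4 * g))
  # identical covariate: collinear
  expect_identical(conditionalAssociation(g, ph, g)$flag, "collinear")
  # all-zero covariate reduces to the unconditional LRT
  res <- conditionalAssociation(g, ph, rep(0, 400))
  f0 <- glm(ph ~ 1, family = binomial())
  f1 <- glm(ph ~ g, family = binomial())
  expect_equal(res$p, pchisq(f0$deviance - f1$deviance, 1, lower.tail = FALSE),
    tolerance = 1e-10)
})
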