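mkTe <- function(mat) TpmExperiment(mat)

test_that("Spearman-to-driver matches rank correlation by hand", {
  mat <- rbind(drv = c(1, 2, 3), g1 = c(3, 1, 2), g2 = c(1, 4, 9),
    g3 = c(5, 5, 5))
  res <- spearmanToDriver(mkTe(mat), "drv")
  expect_equal(res$rho[res$gene == "g1"], -0.5, tolerance = 1e-12)
  # monotone transform of the driver: rho 1, flagged exact-monotone
  expect_equal(res$rho[res$gene == "g2"], 1)
  expect_identical(res$flag[res$gene == "g2"], "exact-monotone")
  expect_equal(res$p[res$gene == "g2"], 0)
  expect_equal(res$rho[res$gene == "drv"], 1) # driver vs itself
  expect_identical(res$flag[res$gene == "g3"], "constant")
  expect_true(is.na(res$rho[res$gene == "g3"]))
})

test_that("Spearman rho is invariant under exponentiating either variable", {
  set.seed(6)
  mat <- matrix(rexp(5 * 20), 5, 20,
    dimnames = list(paste0("g", 1:5), NULL))
  a <- spearmanToDriver(mkTe(mat), "g1")
  b <- spearmanToDriver(mkTe(exp(mat)), "g1")
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
})

test_that("correlated gene set applies a strict threshold and excludes the driver", {
  corr <- data.frame(gene = c("d", "a", "b", "c"),
    p = c(0, 1e-5, 5e-4, 0.2))
  expect_setequal(correlatedGeneSet(corr, 5e-4, driver = "d"), "a") # strict <
  expect_setequal(correlatedGeneSet(corr, 1.0, driver = "d"), c("a", "b", "c"))
})

test_that("overlap enrichment matches exact tail enumeration", {
  u <- paste0("g", 1:100)
  res <- overlapBinomial(u, u[1:10], u[6:15])
  expect_equal(res$overlap, 5)
  expect_equal(res$expected, 1)
  expect_equal(res$p, upperTailEnum(5, 10, 0.1), tolerance = 1e-12)

  # A = universe: success probability 1, p = 1
  expect_equal(overlapBinomial(u, u, u[1:10])$p, 1)
  # zero overlap spans the whole support
  expect_equal(overlapBinomial(u, u[1:10], u[90:99])$p, 1)
  expect_error(overlapBinomial(u[1:50], u[45:55], u[1:5]), "outside the universe")

  hyp <- overlapBinomial(u, u[1:10], u[6:15], model = "hypergeometric")
  expect_equal(hyp$p, phyper(4, 10, 90, 10, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("binomial overlap p sits near the Monte-Carlo resampling estimate", {
  set.seed(33)
  u <- paste0("g", 1:200)
  A <- u[1:10]
  B <- u[c(1:2, 100:109)] # overlap 2
  res <- overlapBinomial(u, A, B)
  draws <- replicate(10000, length(intersect(sample(u, length(B)), A)) >= res$overlap)
  pMc <- mean(draws)
  se <- sqrt(pMc * (1 - pMc) / 10000)
  # binomial null approximates the without-replacement draw at this density
  expect_lt(abs(res$p - pMc), 3 * se + 0.01)
})

test_that("top DE genes rank by adjusted p with the stated tie-breaks", {
  de <- data.frame(gene = c("b", "a", "c", "d"),
    padj = c(0.01, 0.01, 0.001, 0.5),
    log2FC = c(2, -3, 1, 4))
  expect_identical(topDeGenes(de, 3), c("c", "a", "b")) # |lfc| beats name
  expect_identical(topDeGenes(de, 4), c("c", "a", "b", "d"))
  expect_warning(all4 <- topDeGenes(de, 10), "returning all")
  expect_length(all4, 4)
  # equal padj and |lfc|: lexicographic gene id
  tie <- data.frame(gene = c("z", "y"), padj = c(0.1, 0.1), log2FC = c(1, -1))
  expect_identical(topDeGenes(tie, 1), "y")
})

test_that("translocation Z uses the non-flagged cohort with sample SD", {
  mat <- matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("drv", paste0("s", 1:4)))
  te <- TpmExperiment(mat, data.frame(translocated = c(FALSE, FALSE, FALSE, TRUE)))
  res <- translocationZscore(te, "drv")
  expect_equal(unname(res$z), 2) # (4 - 2) / 1
  expect_equal(res$meanZ, 2)
  expect_equal(res$nCohort, 3)

  # case at the cohort mean scores zero
  mat2 <- matrix(c(1, 2, 3, 2), 1, 4, dimnames = list("drv", paste0("s", 1:4)))
  te2 <- TpmExperiment(mat2, data.frame(translocated = c(FALSE, FALSE, FALSE, TRUE)))
  expect_equal(unname(translocationZscore(te2, "drv")$z), 0)

  # constant cohort is flagged undefined
  mat3 <- matrix(c(2, 2, 2, 9), 1, 4, dimnames = list("drv", paste0("s", 1:4)))
  te3 <- TpmExperiment(mat3, data.frame(translocated = c(FALSE, FALSE, FALSE, TRUE)))
  expect_identical(translocationZscore(te3, "drv")$flag, "zero-sd")
})

test_that("a cohort-drawn case has Z of mean ~0 and SD ~1", {
  set.seed(44)
  zs <- replicate(1000, {
    vals <- matrix(c(rnorm(30, 50, 5), rnorm(1, 50, 5)), 1, 31,
      dimnames = list("drv", paste0("s", 1:31)))
    te <- TpmExperiment(pmax(vals, 0),
      data.frame(translocated = c(rep(FALSE, 30), TRUE)))
    translocationZscore(te, "drv")$meanZ
  })
  expect_lt(abs(mean(zs)), 0.1)
  expect_lt(abs(sd(zs) - 1), 0.15)
})
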