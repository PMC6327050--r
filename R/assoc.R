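#' Case/control allelic association for one biallelic variant
#'
#' Tests association between a variant and disease status on the allele
#' scale: alleles are cross-tabulated as a 2x2 table (risk vs other allele
#' by case vs control) and the odds ratio is the cross-product, with a Woolf
#' standard error on the log scale and a normal-approximation two-sided
#' p-value.  Any zero cell triggers the Haldane-Anscombe correction (0.5
#' added to every cell).  A monomorphic variant yields a flagged result with
#' `NA` odds ratio rather than an error.
#'
#' @param genotypes a [GenotypeTable-class], or an integer vector of hard
#'   calls (0/1/2 copies of the risk allele) aligned with `phenotype`.
#' @param phenotype logical or 0/1 vector; `TRUE`/1 = case.
#' @param variant variant id (required when `genotypes` is a table with
#'   several variants).
#' @return list with `variant`, `or`, `beta`, `se`, `p`, `maf`, the 2x2
#'   allele count `table`, and `flag` (`"monomorphic"` or `"corrected"`
#'   when applicable).
#' @examples
#' # 60/40 risk/other alleles in cases vs 40/60 in controls: OR 2.25
#' g <- c(rep(2, 20), rep(1, 20), rep(0, 10), rep(2, 10), rep(1, 20), rep(0, 20))
#' allelicAssociation(g, rep(c(1, 0), each = 50))$or
#' @export
allelicAssociation <- function(genotypes, phenotype, variant = NULL) {
  if (is(genotypes, "GenotypeTable")) {
    if (is.null(variant)) {
      if (ncol(hardCalls(genotypes)) != 1L) {
        stop("specify 'variant' when the table holds several variants")
      }
      variant <- variantIds(genotypes)[1]
    }
    calls <- hardCalls(genotypes)[, variant]
  } else {
    calls <- as.integer(genotypes)
    if (is.null(variant)) variant <- "variant"
  }
  pheno <- as.logical(phenotype)
  keep <- !is.na(calls) & !is.na(pheno)
  calls <- calls[keep]
  pheno <- pheno[keep]
  if (sum(pheno) == 0L || sum(!pheno) == 0L) {
    stop("need at least one case and one control")
  }
  a <- sum(calls[pheno]) # risk alleles, cases
  b <- 2 * sum(pheno) - a # other alleles, cases
  c <- sum(calls[!pheno]) # risk alleles, controls
  d <- 2 * sum(!pheno) - c
  tab <- matrix(c(a, b, c, d), 2, 2,
    dimnames = list(c("risk", "other"), c("case", "control")))
  maf <- (a + c) / (2 * length(calls))
  maf <- min(maf, 1 - maf)
  if ((a + c) == 0L || (b + d) == 0L) {
    return(list(variant = variant, or = NA_real_, beta = NA_real_,
      se = NA_real_, p = NA_real_, maf = maf, table = tab,
      flag = "monomorphic"))
  }
  flag <- character(0)
  if (any(tab == 0)) {
    tab2 <- tab + 0.5
    flag <- "corrected"
  } else {
    tab2 <- tab
  }
  beta <- log((tab2[1, 1] * tab2[2, 2]) / (tab2[1, 2] * tab2[2, 1]))
  se <- sqrt(sum(1 / tab2))
  p <- 2 * pnorm(-abs(beta) / se)
  list(variant = variant, or = exp(beta), beta = beta, se = se, p = p,
    maf = maf, table = tab, flag = flag)
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools per-study log odds ratios with weights \eqn{w_i = 1/se_i^2}.  The
#' pooled standard error is \eqn{1/\sqrt{\sum w_i}}; heterogeneity is
#' summarized by Cochran's \eqn{Q = \sum w_i (\beta_i - \hat\beta)^2} with a
#' chi-square p-value on \eqn{k-1} degrees of freedom.  With a single study
#' the pooled estimate is the input and the heterogeneity p is 1 by
#' convention.
#'
#' @param beta numeric vector of per-study log odds ratios.
#' @param se matching vector of standard errors (all > 0).
#' @return list with `beta`, `se`, `or`, `p` (pooled), `Q`, `pHet`, `k`,
#'   and the `weights` used.
#' @examples
#' fixedEffectMeta(c(0.5, 0.3), c(0.1, 0.2)) # pooled beta 0.46, Q 0.8
#' @export
fixedEffectMeta <- function(beta, se) {
  if (length(beta) == 0L) stop("at least one study is required")
  if (length(beta) != length(se)) stop("'beta' and 'se' lengths differ")
  if (any(!is.finite(se)) || any(se <= 0)) stop("all 'se' must be positive")
  w <- 1 / se^2
  k <- length(beta)
  pooled <- sum(w * beta) / sum(w)
  pooledSe <- 1 / sqrt(sum(w))
  Q <- sum(w * (beta - pooled)^2)
  pHet <- if (k > 1L) pchisq(Q, df = k - 1L, lower.tail = FALSE) else 1
  list(beta = pooled, se = pooledSe, or = exp(pooled),
    p = 2 * pnorm(-abs(pooled) / pooledSe),
    Q = Q, pHet = pHet, k = k, weights = w)
}

#' Imputation INFO score from genotype posterior probabilities
#'
#' Measures the information an imputed variant's posterior triples retain
#' about its allele frequency.  With per-sample expected dosage
#' \eqn{e_i = p_{i1} + 2 p_{i2}} and second moment \eqn{f_i = p_{i1} + 4
#' p_{i2}}, the score is \eqn{1 - \sum_i (f_i - e_i^2) / (2N \hat\theta (1 -
#' \hat\theta))} where \eqn{\hat\theta = \sum_i e_i / 2N}.  Point-mass
#' triples give a score of 1, as does a monomorphic variant (by convention).
#' The score is clipped to [0, 1].
#'
#' @param gp an `n x 3` matrix of per-sample posterior triples (p0, p1, p2)
#'   for one variant, each row summing to 1 within 1e-6.
#' @return list with `theta` (estimated allele frequency), `info`, and the
#'   per-sample `e` and `f` components.
#' @examples
#' infoScore(rbind(c(0.5, 0.5, 0), c(0, 1, 0)))$info # ~0.7333
#' @export
infoScore <- function(gp) {
  gp <- as.matrix(gp)
  if (ncol(gp) != 3L) stop("'gp' must have three columns (p0, p1, p2)")
  if (nrow(gp) == 0L) stop("'gp' must have at least one sample")
  sums <- rowSums(gp)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("posterior triples must sum to 1 within 1e-6 (rows: ",
      paste(which(abs(sums - 1) > 1e-6), collapse = ", "), ")")
  }
  e <- gp[, 2] + 2 * gp[, 3]
  f <- gp[, 2] + 4 * gp[, 3]
  n <- nrow(gp)
  theta <- sum(e) / (2 * n)
  if (theta <= 0 || theta >= 1) {
    info <- 1
  } else {
    info <- 1 - sum(f - e^2) / (2 * n * theta * (1 - theta))
    info <- min(max(info, 0), 1)
  }
  list(theta = theta, info = info, e = e, f = f)
}

#' Filter variants by INFO score
#'
#' @param gt a [GenotypeTable-class] with posterior probabilities.
#' @param infoMin minimum INFO score retained (default 0.8); variants with
#'   `info < infoMin` are dropped.
#' @return list with `scores` (named numeric per variant) and `keep`
#'   (character vector of retained variant ids).
#' @export
infoFilter <- function(gt, infoMin = 0.8) {
  stopifnot(is(gt, "GenotypeTable"))
  gp <- posteriorProbs(gt)
  scores <- vapply(seq_len(dim(gp)[2]), function(v) {
    infoScore(gp[, v, , drop = TRUE])$info
  }, numeric(1))
  names(scores) <- variantIds(gt)
  list(scores = scores, keep = names(scores)[scores >= infoMin])
}

#' Pairwise LD as squared dosage correlation
#'
#' Composite linkage disequilibrium between two variants, computed as the
#' squared Pearson correlation of their dosage vectors (phase-free).
#'
#' @param a,b equal-length numeric dosage vectors.
#' @return squared correlation in [0, 1]; `NA` (flagged undefined) when
#'   either vector is constant.
#' @examples
#' ldR2(c(0, 1, 2, 1), 2 - c(0, 1, 2, 1)) # 1: affine recoding
#' @export
ldR2 <- function(a, b) {
  if (length(a) != length(b)) stop("dosage vectors must have equal length")
  keep <- complete.cases(a, b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) < 2L || sd(a) == 0 || sd(b) == 0) {
    return(NA_real_)
  }
  cor(a, b)^2
}

#' Capture the LD block around a lead variant
#'
#' Returns the proxies of a lead variant: variants whose minor allele
#' frequency exceeds `mafMin` and whose dosage r-squared with the lead is at
#' least `r2Min`.  The capture fraction is the share of that block present
#' in `available` (the variants with usable data; defaults to all), which is
#' 1 (vacuous) for an empty block.
#'
#' @param gt a [GenotypeTable-class].
#' @param lead lead variant id (must be present).
#' @param r2Min,mafMin thresholds; r2 inclusive (`>=`), MAF exclusive (`>`).
#' @param available optional character vector of variant ids with data.
#' @return list with `captured` (proxy ids in the block, lead excluded),
#'   `block` (all qualifying proxies), `fraction`, and the per-variant
#'   `r2` and `maf` used.
#' @export
ldBlockCapture <- function(gt, lead, r2Min = 0.4, mafMin = 0.01,
                           available = NULL) {
  stopifnot(is(gt, "GenotypeTable"))
  ids <- variantIds(gt)
  if (!lead %in% ids) stop("lead variant '", lead, "' not in table")
  dos <- dosages(gt)
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  r2 <- vapply(ids, function(v) {
    if (v == lead) 1 else ldR2(dos[, lead], dos[, v])
  }, numeric(1))
  others <- setdiff(ids, lead)
  block <- others[maf[others] > mafMin & !is.na(r2[others]) & r2[others] >= r2Min]
  if (is.null(available)) available <- ids
  captured <- intersect(block, available)
  fraction <- if (length(block)) length(captured) / length(block) else 1
  list(captured = captured, block = block, fraction = fraction,
    r2 = r2, maf = maf)
}

#' Conditional association via logistic likelihood-ratio test
#'
#' Tests whether a variant carries association signal beyond a conditioning
#' dosage, comparing logistic models `phenotype ~ covariate` and `phenotype
#' ~ covariate + dosage` by likelihood ratio (1 df).  A constant covariate
#' reduces to the unconditional test.  Near-collinear test/covariate pairs
#' (|r| > 0.999) are flagged and return an `NA` p-value, as do fits that do
#' not converge.
#'
#' @param dosage numeric dosage vector of the variant under test.
#' @param phenotype logical or 0/1 case indicator.
#' @param covariate numeric dosage of the conditioning variant.
#' @return list with `p`, `lrt` (the deviance difference), and `flag`
#'   (`"collinear"` / `"nonconverged"` when applicable).
#' @export
conditionalAssociation <- function(dosage, phenotype, covariate) {
  pheno <- as.integer(as.logical(phenotype))
  if (length(dosage) != length(pheno) || length(covariate) != length(pheno)) {
    stop("'dosage', 'phenotype' and 'covariate' must be aligned")
  }
  if (sd(dosage) == 0) {
    return(list(p = NA_real_, lrt = NA_real_, flag = "constant-test-variant"))
  }
  constCov <- sd(covariate) == 0
  if (!constCov && abs(cor(dosage, covariate)) > 0.999) {
    return(list(p = NA_real_, lrt = NA_real_, flag = "collinear"))
  }
  fit0 <- if (constCov) {
    glm(pheno ~ 1, family = binomial())
  } else {
    glm(pheno ~ covariate, family = binomial())
  }
  fit1 <- if (constCov) {
    glm(pheno ~ dosage, family = binomial())
  } else {
    glm(pheno ~ covariate + dosage, family = binomial())
  }
  if (!fit0$converged || !fit1$converged) {
    return(list(p = NA_real_, lrt = NA_real_, flag = "nonconverged"))
  }
  lrt <- fit0$deviance - fit1$deviance
  list(p = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
    lrt = lrt, flag = character(0))
}
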