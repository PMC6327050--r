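#' Simulation configuration with study-scale defaults
#'
#' Builds the validated parameter list every generator consumes.  Defaults
#' reproduce the dimensions of the study the pipeline is modelled on: two
#' case/control series (824/5200 and 834/2024) with a risk-allele odds
#' ratio of 1.45 at MAF 0.3; a 60-blast expression panel of which 44 are
#' chr14-disomic, with a 1.8-fold risk-homozygote eQTL; an allelic ChIP
#' readout at depth 100; a 117-case expression cohort with a driver gene,
#' 150 correlated targets and a 150-gene knockdown DE set; 2 translocated
#' cases at outlier effect 4.6 SD; 313 peaks of which 83/313 of genes have
#' a TSS within 1 kb; and breakpoint flanks with planted RSS elements.
#'
#' @param seed integer RNG seed; every generator is a pure function of the
#'   config including this seed.
#' @param nCases,nControls,nCases2,nControls2 case/control sizes of the two
#'   association series.
#' @param maf risk-allele frequency in controls, in (0, 0.5].
#' @param oddsRatio per-allele odds ratio (> 0) applied on the allele scale.
#' @param nProxies,nIndependents,proxyFlip LD panel layout: proxies are
#'   lead copies with per-allele flip probability `proxyFlip`.
#' @param certainty posterior mass placed on the true genotype when
#'   simulating imputation posteriors, in (1/3, 1].
#' @param nSamplesExpr,nondisomicFrac eQTL panel size and fraction of
#'   samples with non-disomic chr14.
#' @param foldPerRiskHomozygote,exprNoiseSd,baselineTpm eQTL effect (fold
#'   between homozygote groups, > 0), log-scale noise SD, baseline TPM.
#' @param depth,trueAltFraction,refBias,inputAltFraction allelic-read
#'   model: site depth, true alternate fraction in (0, 1), multiplicative
#'   reference-read retention advantage (>= 1), input-DNA alt fraction.
#' @param nGenes,nSamplesCohort,driver,nCorrelated,targetRho,nDe,deOverlap
#'   expression-cohort model: gene/sample counts, driver id, planted
#'   correlated-target count and correlation magnitude in (0, 1), DE-set
#'   size and its overlap with the correlated set.
#' @param nTranslocated,targetZ translocated-case count and planted outlier
#'   effect in cohort SD units (>= 0).
#' @param flankLen,plantRss,heptamerOnly,rssSpacer,rssOffset breakpoint
#'   locus model: flank length (>= 50), whether to plant an RSS, whether to
#'   plant the heptamer without its nonamer, spacer class, offset of the
#'   heptamer start downstream of the breakpoint.
#' @param nPeaks,peakTssWithinFrac,chromLen,tssWindow peak/TSS layout:
#'   peak count, fraction of genes with a TSS within `tssWindow` of a peak
#'   (in [0, 1]), chromosome length.
#' @return a validated list of class `"simConfig"`.
#' @export
simConfig <- function(seed = 1L,
                      nCases = 824L, nControls = 5200L,
                      nCases2 = 834L, nControls2 = 2024L,
                      maf = 0.3, oddsRatio = 1.45,
                      nProxies = 5L, nIndependents = 5L, proxyFlip = 0.05,
                      certainty = 0.98,
                      nSamplesExpr = 60L, nondisomicFrac = 16 / 60,
                      foldPerRiskHomozygote = 1.8, exprNoiseSd = 0.5,
                      baselineTpm = 50,
                      depth = 100L, trueAltFraction = 0.65, refBias = 1.5,
                      inputAltFraction = 0.5,
                      nGenes = 2000L, nSamplesCohort = 117L,
                      driver = "CEBPE", nCorrelated = 150L, targetRho = 0.6,
                      nDe = 150L, deOverlap = 30L,
                      nTranslocated = 2L, targetZ = 4.6,
                      flankLen = 300L, plantRss = TRUE, heptamerOnly = TRUE,
                      rssSpacer = 12L, rssOffset = 25L,
                      nPeaks = 313L, peakTssWithinFrac = 83 / 313,
                      chromLen = 3e6, tssWindow = 1000L) {
  cfg <- as.list(environment())
  counts <- c("nCases", "nControls", "nCases2", "nControls2", "nSamplesExpr",
    "depth", "nGenes", "nSamplesCohort", "nPeaks")
  for (nm in counts) {
    if (cfg[[nm]] < 1) stop("invalid config: '", nm, "' must be positive")
  }
  if (maf <= 0 || maf > 0.5) stop("invalid config: 'maf' must lie in (0, 0.5]")
  if (oddsRatio <= 0) stop("invalid config: 'oddsRatio' must be > 0")
  if (certainty <= 1 / 3 || certainty > 1) {
    stop("invalid config: 'certainty' must lie in (1/3, 1]")
  }
  if (foldPerRiskHomozygote <= 0) {
    stop("invalid config: 'foldPerRiskHomozygote' must be > 0")
  }
  if (trueAltFraction <= 0 || trueAltFraction >= 1) {
    stop("invalid config: 'trueAltFraction' must lie in (0, 1)")
  }
  if (refBias < 1) stop("invalid config: 'refBias' must be >= 1")
  if (targetRho < 0 || targetRho >= 1) {
    stop("invalid config: 'targetRho' must lie in [0, 1)")
  }
  if (nCorrelated >= nGenes) stop("invalid config: 'nCorrelated' must be < 'nGenes'")
  if (deOverlap > nCorrelated || deOverlap > nDe) {
    stop("invalid config: 'deOverlap' exceeds a set size")
  }
  if (targetZ < 0) stop("invalid config: 'targetZ' must be >= 0")
  if (flankLen < 50) stop("invalid config: 'flankLen' must be >= 50")
  if (plantRss) {
    need <- nchar(RSS_HEPTAMER) + rssSpacer + 1 + nchar(RSS_NONAMER) + rssOffset
    if (flankLen < need) {
      stop("invalid config: flank too short to contain the planted RSS")
    }
  }
  if (peakTssWithinFrac < 0 || peakTssWithinFrac > 1) {
    stop("invalid config: 'peakTssWithinFrac' must lie in [0, 1]")
  }
  if (chromLen < (nPeaks + 1) * (400 + 4 * tssWindow + 10)) {
    stop("invalid config: 'chromLen' too small to place ", nPeaks, " peaks")
  }
  structure(cfg, class = "simConfig")
}

#' @export
print.simConfig <- function(x, ...) {
  cat("simConfig (seed ", x$seed, "): ", length(x), " parameters\n", sep = "")
  invisible(x)
}

# Per-generator seed streams, derived from the config seed so that each
# dataset is reproducible in isolation.  Offsets stay small to keep derived
# seeds within 32-bit integer range.
.simSeed <- function(config, offset) {
  set.seed((config$seed %% 2000000000L) + offset)
}

#' Simulate case/control genotypes at a risk locus
#'
#' Draws Hardy-Weinberg genotypes for a lead risk variant at control
#' frequency `maf`, with the case-allele frequency implied by the per-allele
#' odds ratio on the allele scale, \eqn{f_{case} = OR f / (1 - f + OR f)}.
#' Optionally adds an LD panel: proxy variants generated by copying lead
#' alleles with flip probability `proxyFlip`, and independent variants at
#' the same frequency.
#'
#' @param config a [simConfig()].
#' @param study 1 or 2, selecting the case/control sizes of the first or
#'   second series.
#' @param panel also generate the proxy/independent variant panel
#'   (default FALSE: lead only).
#' @return list with `genotypes` ([GenotypeTable-class], lead variant
#'   `"rs_lead"`), `phenotype` (logical), and `truth` (true OR, control
#'   MAF, case allele frequency, proxy/independent ids).
#' @export
simulateCaseControl <- function(config, study = 1L, panel = FALSE) {
  .simSeed(config, 11L + study)
  nCase <- if (study == 1L) config$nCases else config$nCases2
  nCtrl <- if (study == 1L) config$nControls else config$nControls2
  f <- config$maf
  fCase <- config$oddsRatio * f / (1 - f + config$oddsRatio * f)
  n <- nCase + nCtrl
  pheno <- c(rep(TRUE, nCase), rep(FALSE, nCtrl))
  freq <- ifelse(pheno, fCase, f)
  # per-allele draws so proxies can be derived allele-wise
  a1 <- rbinom(n, 1, freq)
  a2 <- rbinom(n, 1, freq)
  calls <- matrix(a1 + a2, ncol = 1)
  ids <- "rs_lead"
  proxies <- character(0)
  independents <- character(0)
  if (panel) {
    flip <- function(a) abs(a - rbinom(n, 1, config$proxyFlip))
    for (i in seq_len(config$nProxies)) {
      calls <- cbind(calls, flip(a1) + flip(a2))
      proxies <- c(proxies, paste0("proxy", i))
    }
    for (i in seq_len(config$nIndependents)) {
      calls <- cbind(calls, rbinom(n, 2, f))
      independents <- c(independents, paste0("indep", i))
    }
    ids <- c(ids, proxies, independents)
  }
  colnames(calls) <- ids
  rownames(calls) <- paste0(ifelse(pheno, "case", "ctrl"), seq_len(n))
  list(genotypes = GenotypeTable(calls), phenotype = pheno,
    truth = list(oddsRatio = config$oddsRatio, maf = f, caseFreq = fCase,
      proxies = proxies, independents = independents, seed = config$seed))
}

#' Simulate imputation posterior probabilities for hard calls
#'
#' Places posterior mass `certainty` on each sample's true genotype and
#' splits the remainder evenly over the other two classes, emulating an
#' imperfectly imputed variant whose INFO score falls as `certainty` drops.
#'
#' @param gt a [GenotypeTable-class] of hard calls.
#' @param certainty mass on the true genotype, in (1/3, 1].
#' @return a [GenotypeTable-class] carrying a posterior array and dosages
#'   recomputed as expected dosages.
#' @export
simulatePosteriors <- function(gt, certainty) {
  stopifnot(is(gt, "GenotypeTable"))
  if (certainty <= 1 / 3 || certainty > 1) {
    stop("invalid config: 'certainty' must lie in (1/3, 1]")
  }
  calls <- hardCalls(gt)
  n <- nrow(calls)
  v <- ncol(calls)
  gp <- array((1 - certainty) / 2, dim = c(n, v, 3))
  for (g in 0:2) {
    idx <- which(calls == g)
    gp[cbind(arrayInd(idx, dim(calls)), g + 1L)] <- certainty
  }
  e <- gp[, , 2, drop = FALSE] + 2 * gp[, , 3, drop = FALSE]
  dosage <- matrix(e, n, v, dimnames = dimnames(calls))
  GenotypeTable(calls, dosage = dosage, gp = gp)
}

#' Simulate a genotype-stratified expression panel
#'
#' Log-normal TPM with a per-dosage additive effect on the log scale:
#' \eqn{\log y = \log(\mathrm{baseline}) + g \cdot \log(\mathrm{fold}) / 2 +
#' \epsilon}, so risk homozygotes differ from non-risk homozygotes by the
#' configured fold.  A configured fraction of samples is marked non-disomic
#' for the chromosome (copy number 1 or 3) with expression perturbed by the
#' copy ratio, emulating the confounding the disomy restriction removes.
#'
#' @param genotype integer risk-allele dosage vector, one per sample (its
#'   length overrides `config$nSamplesExpr`).
#' @param config a [simConfig()].
#' @return list with `te` ([TpmExperiment-class] of gene `driver` with
#'   `copy_number` metadata), `genotype` (named), and `truth` (fold,
#'   disomic sample ids).
#' @export
simulateEqtl <- function(genotype, config) {
  if (length(genotype) == 0L) stop("empty genotype table")
  .simSeed(config, 21L)
  n <- length(genotype)
  samples <- paste0("blast", seq_len(n))
  nNon <- round(config$nondisomicFrac * n)
  cn <- rep(2L, n)
  if (nNon > 0) {
    nonIdx <- sample(n, nNon)
    cn[nonIdx] <- sample(c(1L, 3L), nNon, replace = TRUE)
  }
  logTpm <- log(config$baselineTpm) +
    genotype * log(config$foldPerRiskHomozygote) / 2 +
    rnorm(n, 0, config$exprNoiseSd) +
    log(cn / 2)
  mat <- matrix(exp(logTpm), nrow = 1,
    dimnames = list(config$driver, samples))
  te <- TpmExperiment(mat, data.frame(copy_number = cn))
  list(te = te, genotype = setNames(as.integer(genotype), samples),
    truth = list(fold = config$foldPerRiskHomozygote,
      disomic = samples[cn == 2L], seed = config$seed))
}

#' Simulate allelic reads at a heterozygous site
#'
#' Generates per-read allele calls at the configured depth with true
#' alternate fraction `trueAltFraction`, then applies reference-mapping
#' bias as a read-retention filter: when the site is "maskable" (a known
#' common variant) and the reference has *not* been N-masked, each
#' alternate-allele read survives mapping with probability `1/refBias`
#' while reference reads always survive, giving a retained alternate
#' fraction of \eqn{f / (f + (1-f)\,\mathrm{refBias})}.  Masking the site
#' removes the penalty, so the masked counts are the unbiased ones.
#'
#' @param config a [simConfig()].
#' @param assay assay label.
#' @param altFraction overrides `config$trueAltFraction` when given.
#' @param maskable whether the site's bias is removable by masking
#'   (default TRUE).
#' @param streamOffset small integer distinguishing independent draws from
#'   one config (e.g. assay vs input control).
#' @return list with `reads` (data.frame: read, allele, survivesBias),
#'   `masked` and `unmasked` [AllelicCount-class] tallies, and `truth`.
#' @export
simulateAllelicReads <- function(config, assay = "H3K27ac",
                                 altFraction = NULL, maskable = TRUE,
                                 streamOffset = 0L) {
  .simSeed(config, 31L + streamOffset)
  f <- if (is.null(altFraction)) config$trueAltFraction else altFraction
  depth <- config$depth
  allele <- ifelse(runif(depth) < f, "alt", "ref")
  survives <- ifelse(allele == "ref", TRUE, runif(depth) < 1 / config$refBias)
  if (!maskable) survives <- rep(TRUE, depth) # bias only acts at known SNPs
  reads <- data.frame(read = paste0("r", seq_len(depth)), allele = allele,
    survivesBias = survives)
  tally <- function(keep) {
    AllelicCount("site1", sum(allele[keep] == "ref"),
      sum(allele[keep] == "alt"), 0L, assay = assay)
  }
  list(reads = reads,
    masked = tally(rep(TRUE, depth)),
    unmasked = tally(survives),
    truth = list(altFraction = f, refBias = config$refBias,
      maskable = maskable,
      expectedBiasedFraction = f / (f + (1 - f) * config$refBias),
      seed = config$seed))
}

#' Simulate an expression cohort with a driver-correlated program
#'
#' Builds a genes x samples TPM matrix in which one driver gene and
#' `nCorrelated` target genes share a latent factor at correlation
#' magnitude `targetRho` (log scale), all remaining genes are independent,
#' and a DE gene list is planted with a configured overlap with the
#' correlated set.
#'
#' @param config a [simConfig()].
#' @return list with `te` ([TpmExperiment-class]), `deTable` (data.frame
#'   gene/padj/log2FC ranking the planted DE set first), and `truth`
#'   (correlated gene ids, DE ids, overlap ids, rho).
#' @export
simulateExpressionCohort <- function(config) {
  .simSeed(config, 41L)
  nG <- config$nGenes
  nS <- config$nSamplesCohort
  rho <- config$targetRho
  genes <- c(config$driver, paste0("gene", seq_len(nG - 1L)))
  corrGenes <- genes[1L + seq_len(config$nCorrelated)]
  latent <- rnorm(nS)
  logX <- matrix(rnorm(nG * nS), nG, nS, dimnames = list(genes, paste0("case", seq_len(nS))))
  logX[config$driver, ] <- latent
  if (config$nCorrelated > 0) {
    noise <- matrix(rnorm(config$nCorrelated * nS), config$nCorrelated, nS)
    logX[corrGenes, ] <- rho * matrix(latent, config$nCorrelated, nS, byrow = TRUE) +
      sqrt(1 - rho^2) * noise
  }
  tpmMat <- exp(log(config$baselineTpm) + logX)
  te <- TpmExperiment(tpmMat, data.frame(translocated = rep(FALSE, nS)))
  nonCorr <- setdiff(genes[-1], corrGenes)
  if (length(nonCorr) < config$nDe - config$deOverlap) {
    stop("invalid config: too few uncorrelated genes for the DE set")
  }
  deGenes <- c(corrGenes[seq_len(config$deOverlap)],
    nonCorr[seq_len(config$nDe - config$deOverlap)])
  other <- setdiff(genes, c(deGenes, config$driver))
  deTable <- data.frame(
    gene = c(deGenes, other),
    padj = c(runif(length(deGenes), 1e-10, 1e-4),
      runif(length(other), 0.2, 1)),
    log2FC = c(rnorm(length(deGenes), 2, 0.5), rnorm(length(other), 0, 0.2)))
  list(te = te, deTable = deTable,
    truth = list(driver = config$driver, correlated = corrGenes,
      de = deGenes, overlap = intersect(deGenes, corrGenes),
      rho = rho, seed = config$seed))
}

#' Append translocated outlier cases to a cohort
#'
#' Adds `nTranslocated` flagged cases whose driver-gene TPM equals the
#' cohort mean plus `targetZ` cohort standard deviations (TPM scale); all
#' other genes are drawn from each gene's cohort log-normal model.
#'
#' @param te cohort [TpmExperiment-class] (non-translocated).
#' @param config a [simConfig()].
#' @return list with `te` (cohort plus flagged cases) and `truth`
#'   (appended ids, planted z).
#' @export
simulateTranslocatedCases <- function(te, config) {
  stopifnot(is(te, "TpmExperiment"))
  if (ncol(tpm(te)) == 0L) stop("empty cohort")
  .simSeed(config, 51L)
  mat <- tpm(te)
  k <- config$nTranslocated
  lm0 <- apply(log(pmax(mat, 1e-8)), 1, mean)
  ls0 <- apply(log(pmax(mat, 1e-8)), 1, sd)
  newCols <- vapply(seq_len(k), function(i) {
    exp(rnorm(nrow(mat), lm0, ls0))
  }, numeric(nrow(mat)))
  dimnames(newCols) <- list(rownames(mat), paste0("transloc", seq_len(k)))
  drv <- config$driver
  newCols[drv, ] <- mean(mat[drv, ]) + config$targetZ * sd(mat[drv, ])
  full <- cbind(mat, newCols)
  translocated <- c(rep(FALSE, ncol(mat)), rep(TRUE, k))
  te2 <- TpmExperiment(full, data.frame(translocated = translocated))
  list(te = te2,
    truth = list(cases = colnames(newCols), targetZ = config$targetZ,
      seed = config$seed))
}

#' Simulate a breakpoint locus with optional planted RSS
#'
#' Generates a random background sequence of `2 * flankLen + 1` bases with
#' the breakpoint at the centre.  When `plantRss` is set, a heptamer is
#' planted downstream of the breakpoint at `rssOffset`, followed (unless
#' `heptamerOnly`) by the configured spacer and the nonamer, i.e. a full
#' 12- or 23-RSS.
#'
#' @param config a [simConfig()].
#' @param name locus name recorded in the truth.
#' @return list with `seq` (character), `breakpoint` (1-based centre
#'   position), and `truth` (planted element start positions, or NULL).
#' @export
simulateBreakpointLocus <- function(config, name = "bp1") {
  .simSeed(config, 61L + utf8ToInt(substr(name, nchar(name), nchar(name))))
  L <- 2L * config$flankLen + 1L
  seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  bp <- config$flankLen + 1L
  truth <- NULL
  if (config$plantRss) {
    hep <- strsplit(RSS_HEPTAMER, "")[[1]]
    hepStart <- bp + config$rssOffset
    seq[hepStart:(hepStart + length(hep) - 1L)] <- hep
    nonStart <- NA_integer_
    if (!config$heptamerOnly) {
      non <- strsplit(RSS_NONAMER, "")[[1]]
      nonStart <- hepStart + length(hep) + config$rssSpacer
      seq[nonStart:(nonStart + length(non) - 1L)] <- non
    } else {
      # scrub chance nonamers at every spacer-consistent offset (both
      # classes, generous slack) so the planted element really is
      # heptamer-only even under a 1-mismatch nonamer budget
      nonBases <- strsplit(RSS_NONAMER, "")[[1]]
      for (sp in c(12L, 23L)) {
        for (d in (sp - 2L):(sp + 2L)) {
          ns <- hepStart + length(hep) + d
          if (ns >= 1L && ns + length(nonBases) - 1L <= L) {
            for (k in 1:2) { # two forced mismatches beat a 1-mismatch budget
              cur <- seq[ns + k - 1L]
              seq[ns + k - 1L] <- setdiff(c("G", "T"), c(cur, nonBases[k]))[1]
            }
          }
        }
      }
    }
    truth <- list(heptamerStart = hepStart, nonamerStart = nonStart,
      spacer = if (config$heptamerOnly) NA_integer_ else config$rssSpacer,
      offset = config$rssOffset)
  }
  list(seq = paste(seq, collapse = ""), breakpoint = bp,
    truth = c(list(name = name, seed = config$seed), truth))
}

#' Simulate peaks and TSS with a controlled proximal fraction
#'
#' Places `nPeaks` peaks on a chromosome and one TSS per gene so that a
#' `peakTssWithinFrac` share of genes lies within `tssWindow` bp of some
#' peak and the remainder lies strictly farther than `tssWindow` from every
#' peak.  Peaks are laid on a widely spaced grid so distances are
#' unambiguous.
#'
#' @param config a [simConfig()]; `nGenesTss` genes are taken equal to
#'   `nPeaks` (one candidate gene per peak).
#' @return list with `peaks` ([GenomicRanges::GRanges-class]), `tss`
#'   (data.frame gene/chrom/pos/strand), and `truth` (gene ids placed
#'   within the window).
#' @export
simulatePeaksTss <- function(config) {
  .simSeed(config, 71L)
  nP <- config$nPeaks
  w <- config$tssWindow
  spacing <- as.integer(floor(config$chromLen / (nP + 1)))
  starts <- spacing * seq_len(nP)
  peakWidth <- 400L
  peaks <- GRanges("chr14", IRanges(starts, width = peakWidth),
    name = paste0("peak", seq_len(nP)))
  names(peaks) <- peaks$name
  nGenes <- nP
  nNear <- round(config$peakTssWithinFrac * nGenes)
  nearIdx <- if (nNear > 0) sort(sample(nGenes, nNear)) else integer(0)
  pos <- integer(nGenes)
  for (i in seq_len(nGenes)) {
    if (i %in% nearIdx) {
      # within [0, w] of the peak's end, inclusive
      pos[i] <- end(peaks)[i] + sample(0:w, 1)
    } else {
      # beyond the window from its own peak and > 2w from the next
      pos[i] <- end(peaks)[i] + w + 1L + sample(seq_len(spacing - peakWidth - 4L * w), 1)
    }
  }
  tss <- data.frame(gene = paste0("tssgene", seq_len(nGenes)), chrom = "chr14",
    pos = pos, strand = "+")
  list(peaks = peaks, tss = tss,
    truth = list(within = tss$gene[nearIdx], seed = config$seed))
}
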