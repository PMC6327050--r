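#' Default analysis thresholds for a pipeline run
#'
#' @param infoMin minimum imputation INFO score retained.
#' @param r2Min,mafMin LD-block capture thresholds.
#' @param tssWindow peak-to-TSS assignment window in bp.
#' @param corrP driver-correlation p-value cutoff.
#' @param topK DE genes taken forward into the overlap test.
#' @param alpha significance level for the allelic-imbalance gate.
#' @param hicThreshold minimum Hi-C contact value declaring a link (the
#'   study-design choice this parameter encodes has no canonical value; it
#'   must always be stated with the results).
#' @param rssWindow breakpoint-to-RSS proximity window in bp.
#' @return named list of parameters.
#' @export
pipelineParams <- function(infoMin = 0.8, r2Min = 0.4, mafMin = 0.01,
                           tssWindow = 1000, corrP = 5e-4, topK = 150,
                           alpha = 0.05, hicThreshold = 5, rssWindow = 50) {
  as.list(environment())
}

.logLine <- function(con, ...) {
  writeLines(paste0(format(Sys.time(), "%H:%M:%OS2"), " | ", ...), con)
}

#' Run the integrative fine-mapping pipeline end to end
#'
#' Orchestrates the analysis stages on synthetic inputs with known truth
#' (`simulate = TRUE`): association + meta-analysis + INFO filter + LD
#' capture + conditional analysis (`assoc`), disomy-restricted eQTL
#' (`eqtl`), allele-specific ChIP imbalance with masking and input control
#' (`ase`), ChIP-qPCR quantitation (`chipq`), peak/TSS/Hi-C/motif
#' annotation (`annotate`), correlated gene programs and translocation
#' outliers (`programs`), and breakpoint RSS classification
#' (`breakpoints`).  Inputs are written to `<outDir>/inputs`, read back
#' through the package's parsers, and each stage's outputs land in its own
#' subdirectory.  The run writes a resolved configuration
#' (`resolved_config.json`), a timing log (`run.log`) and a deterministic
#' summary (`summary.json`) that contains no timestamps, so identical
#' seeds reproduce it byte for byte.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed driving every simulated input.
#' @param config a [simConfig()]; defaults to `simConfig(seed = seed)`.
#' @param params a [pipelineParams()] list of analysis thresholds.
#' @param stages subset of stages to run, in dependency order.
#' @param simulate generate inputs (currently the only supported source;
#'   pre-existing files in `<outDir>/inputs` are reused when FALSE).
#' @return (invisibly) the summary list; side effect: files under
#'   `outDir`.
#' @export
runPipeline <- function(outDir, seed = 1L, config = simConfig(seed = seed),
                        params = pipelineParams(),
                        stages = c("assoc", "eqtl", "ase", "chipq",
                          "annotate", "programs", "breakpoints"),
                        simulate = TRUE) {
  if (length(stages)) stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inDir <- file.path(outDir, "inputs")
  dir.create(inDir, showWarnings = FALSE)
  log <- file(file.path(outDir, "run.log"), "w")
  on.exit(close(log), add = TRUE)
  write_json(list(seed = seed, config = unclass(config), params = params,
    version = as.character(packageVersion("regfine"))),
    file.path(outDir, "resolved_config.json"), auto_unbox = TRUE, digits = NA)
  summary <- list(seed = seed,
    version = as.character(packageVersion("regfine")))

  runStage <- function(name, fun) {
    t0 <- Sys.time()
    .logLine(log, "stage ", name, " started")
    res <- tryCatch(fun(), error = function(e) {
      .logLine(log, "stage ", name, " FAILED: ", conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    .logLine(log, "stage ", name, " finished in ",
      sprintf("%.2fs", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  if (simulate) {
    summary$inputs <- runStage("simulate", function() {
      cc <- simulateCaseControl(config, study = 1L, panel = TRUE)
      gtPost <- simulatePosteriors(cc$genotypes, config$certainty)
      writeGenotypeTsv(gtPost, file.path(inDir, "genotypes_study1.tsv"))
      write.table(data.frame(sample = sampleIds(cc$genotypes),
        status = as.integer(cc$phenotype)),
        file.path(inDir, "phenotype_study1.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      pt <- simulatePeaksTss(config)
      writePeaksBed(pt$peaks, file.path(inDir, "peaks.bed"))
      writeTssTsv(pt$tss, file.path(inDir, "tss.tsv"))
      # planted contact between the first peak and the first TSS
      res <- 5000
      b1 <- floor((start(pt$peaks)[1] - 1) / res)
      b2 <- floor((pt$tss$pos[1] - 1) / res)
      cm <- ContactMap(data.frame(
        bin_i = c(b1, b1 + 40), bin_j = c(b2, b1 + 80),
        value = c(10, 1)), "chr14", res)
      writeContactsTsv(cm, file.path(inDir, "contacts.tsv"))
      bp1 <- simulateBreakpointLocus(config, "bp1")
      bp2 <- simulateBreakpointLocus(config, "bp2")
      seqs <- DNAStringSet(c(bp1 = bp1$seq, bp2 = bp2$seq))
      writeXStringSet(seqs, file.path(inDir, "breakpoint_loci.fa"))
      write.table(data.frame(name = c("bp1", "bp2"), chrom = c("bp1", "bp2"),
        pos = c(bp1$breakpoint, bp2$breakpoint), orientation = "downstream"),
        file.path(inDir, "breakpoints.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_json(list(caseControl = cc$truth, peaksTss = pt$truth,
        bp1 = bp1$truth, bp2 = bp2$truth),
        file.path(inDir, "truth.json"), auto_unbox = TRUE, digits = NA)
      list(nSamplesStudy1 = nrow(hardCalls(cc$genotypes)),
        nVariants = ncol(hardCalls(cc$genotypes)),
        nPeaks = length(pt$peaks), nTss = nrow(pt$tss))
    })
  }

  if ("assoc" %in% stages) {
    summary$assoc <- runStage("assoc", function() {
      dir.create(file.path(outDir, "assoc"), showWarnings = FALSE)
      gt <- readGenotypeTsv(file.path(inDir, "genotypes_study1.tsv"))
      ph <- read.delim(file.path(inDir, "phenotype_study1.tsv"))
      pheno <- as.logical(ph$status[match(sampleIds(gt), ph$sample)])
      info <- infoFilter(gt, params$infoMin)
      a1 <- allelicAssociation(gt, pheno, "rs_lead")
      cc2 <- simulateCaseControl(config, study = 2L, panel = FALSE)
      a2 <- allelicAssociation(cc2$genotypes, cc2$phenotype, "rs_lead")
      meta <- fixedEffectMeta(c(a1$beta, a2$beta), c(a1$se, a2$se))
      cap <- ldBlockCapture(gt, "rs_lead", params$r2Min, params$mafMin,
        available = info$keep)
      cond <- conditionalAssociation(dosages(gt)[, "proxy1"], pheno,
        dosages(gt)[, "rs_lead"])
      tab <- data.frame(variant = variantIds(gt), info = info$scores,
        maf = cap$maf, r2_lead = cap$r2,
        captured = variantIds(gt) %in% cap$captured)
      write.table(tab, file.path(outDir, "assoc", "variants.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      list(leadOr = a1$or, leadP = a1$p, study2Or = a2$or,
        metaOr = meta$or, metaP = meta$p, metaQ = meta$Q,
        metaPHet = meta$pHet, nInfoPass = length(info$keep),
        captureFraction = cap$fraction, nCaptured = length(cap$captured),
        conditionalProxyP = cond$p)
    })
  }

  if ("eqtl" %in% stages) {
    summary$eqtl <- runStage("eqtl", function() {
      dir.create(file.path(outDir, "eqtl"), showWarnings = FALSE)
      .simSeed(config, 19L)
      g <- rbinom(config$nSamplesExpr, 2, config$maf)
      sim <- simulateEqtl(g, config)
      writeExpressionTsv(sim$te, file.path(inDir, "expression_eqtl.tsv"))
      te <- readExpressionTsv(file.path(inDir, "expression_eqtl.tsv"))
      res <- eqtlTest(te, config$driver, sim$genotype)
      out <- data.frame(gene = config$driver, H = res$kw$H, p = res$kw$p,
        fold = res$fold$fold, n = res$kw$n)
      write.table(out, file.path(outDir, "eqtl", "eqtl.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      list(nDisomic = length(res$samples), kwH = res$kw$H, kwP = res$kw$p,
        fold = res$fold$fold)
    })
  }

  if ("ase" %in% stages) {
    summary$ase <- runStage("ase", function() {
      dir.create(file.path(outDir, "ase"), showWarnings = FALSE)
      assay <- simulateAllelicReads(config, "H3K27ac")
      input <- simulateAllelicReads(config, "input",
        altFraction = config$inputAltFraction, streamOffset = 1L)
      # analysis proper runs on the N-masked alignment (bias removed)
      pa <- pairedBiasAssessment(assay$masked, input$masked,
        alpha = params$alpha)
      nUn <- assay$unmasked@kRef + assay$unmasked@kAlt
      nMa <- assay$masked@kRef + assay$masked@kAlt
      out <- data.frame(
        assay = c("H3K27ac", "input"),
        k_ref = c(assay$masked@kRef, input$masked@kRef),
        k_alt = c(assay$masked@kAlt, input$masked@kAlt),
        p = c(pa$assay$p, pa$input$p))
      write.table(out, file.path(outDir, "ase", "allelic_counts.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      list(assayAltFraction = pa$assay$altFraction, assayP = pa$assay$p,
        inputP = pa$input$p, alleleSpecific = pa$alleleSpecific,
        unmaskedAltFraction = assay$unmasked@kAlt / nUn,
        maskedAltFraction = assay$masked@kAlt / nMa)
    })
  }

  if ("chipq" %in% stages) {
    summary$chipq <- runStage("chipq", function() {
      dir.create(file.path(outDir, "chipq"), showWarnings = FALSE)
      .simSeed(config, 81L)
      qty <- 5^(4:0) # fivefold serial dilutions
      cq <- 20 - log2(qty) + rnorm(length(qty), 0, 0.05)
      curve <- standardCurveFit(qty, cq)
      piTarget <- percentInput(interpolateQuantity(curve, 24.0),
        interpolateQuantity(curve, 20.0), inputFraction = 0.1)
      piIgg <- percentInput(interpolateQuantity(curve, 27.0),
        interpolateQuantity(curve, 20.0), inputFraction = 0.1)
      fe <- foldEnrichment(piTarget, piIgg)
      prefTruth <- 300
      cqMatched <- curve$intercept + curve$slope * log10(prefTruth)
      cqMismatched <- curve$intercept + curve$slope * log10(1)
      pref <- allelePreference(curve, cqMatched, cqMismatched)
      tt <- replicateTTest(c(0.52, 0.61, 0.55), c(0.35, 0.41, 0.38))
      out <- data.frame(slope = curve$slope, efficiency = curve$efficiency,
        pct_input_target = piTarget, pct_input_igg = piIgg,
        fold_enrichment = fe, allele_preference = pref$preference)
      write.table(out, file.path(outDir, "chipq", "quant.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      list(slope = curve$slope, efficiency = curve$efficiency,
        pctInputTarget = piTarget, pctInputIgg = piIgg,
        foldEnrichment = fe, allelePreference = pref$preference,
        replicateP = tt$p)
    })
  }

  if ("annotate" %in% stages) {
    summary$annotate <- runStage("annotate", function() {
      dir.create(file.path(outDir, "annotate"), showWarnings = FALSE)
      peaks <- readPeaksBed(file.path(inDir, "peaks.bed"))
      tss <- readTssTsv(file.path(inDir, "tss.tsv"))
      assigned <- assignPeaksToTss(peaks, tss, params$tssWindow)
      write.table(assigned, file.path(outDir, "annotate", "peak_tss.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      cm <- readContactsTsv(file.path(inDir, "contacts.tsv"))
      link <- hicLink(cm,
        GRanges("chr14", IRanges(start(peaks)[1], end(peaks)[1])),
        GRanges("chr14", IRanges(tss$pos[1], width = 1)),
        threshold = params$hicThreshold)
      .simSeed(config, 91L)
      promoter <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
        collapse = "")
      promoter <- paste0(substr(promoter, 1, 500), "TTGCGCAA",
        substr(promoter, 509, 2000))
      hits <- motifScan(promoter, "TTGCGCAA")
      list(nAssignedGenes = length(unique(assigned$gene)),
        hicLinked = link$linked, hicValue = link$value,
        motifHits = nrow(hits), motifFirstPos = if (nrow(hits)) hits$start[1] else NA)
    })
  }

  if ("programs" %in% stages) {
    summary$programs <- runStage("programs", function() {
      dir.create(file.path(outDir, "programs"), showWarnings = FALSE)
      cohort <- simulateExpressionCohort(config)
      withTx <- simulateTranslocatedCases(cohort$te, config)
      writeExpressionTsv(withTx$te, file.path(inDir, "expression_cohort.tsv"))
      write.table(cohort$deTable, file.path(inDir, "de_table.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      te <- readExpressionTsv(file.path(inDir, "expression_cohort.tsv"))
      blasts <- te[, !as.logical(colData(te)$translocated)]
      blasts <- TpmExperiment(assay(blasts, "tpm"))
      corr <- spearmanToDriver(blasts, config$driver)
      corrSet <- correlatedGeneSet(corr, params$corrP, config$driver)
      de <- read.delim(file.path(inDir, "de_table.tsv"))
      deSet <- topDeGenes(de, params$topK)
      universe <- setdiff(rownames(tpm(te)), config$driver)
      ov <- overlapBinomial(universe, corrSet, deSet)
      z <- translocationZscore(te, config$driver)
      write.table(corr, file.path(outDir, "programs", "driver_correlation.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_json(ov, file.path(outDir, "programs", "overlap.json"),
        auto_unbox = TRUE, digits = NA)
      list(nCorrelated = length(corrSet), overlap = ov$overlap,
        overlapExpected = ov$expected, overlapP = ov$p,
        meanZ = z$meanZ, nTranslocated = length(z$z))
    })
  }

  if ("breakpoints" %in% stages) {
    summary$breakpoints <- runStage("breakpoints", function() {
      dir.create(file.path(outDir, "breakpoints"), showWarnings = FALSE)
      seqs <- readDNAStringSet(file.path(inDir, "breakpoint_loci.fa"))
      bps <- read.delim(file.path(inDir, "breakpoints.tsv"))
      res <- lapply(seq_len(nrow(bps)), function(i) {
        s <- as.character(seqs[[bps$name[i]]])
        hits <- rssScan(s)
        cls <- classifyBreakpoint(hits, bps$pos[i], params$rssWindow)
        list(name = bps$name[i], category = cls$category,
          nearestDistance = cls$nearestDistance, nHits = nrow(hits))
      })
      out <- do.call(rbind, lapply(res, as.data.frame))
      write.table(out, file.path(outDir, "breakpoints", "classification.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      setNames(lapply(res, function(r) r[c("category", "nearestDistance", "nHits")]),
        vapply(res, `[[`, character(1), "name"))
    })
  }

  write_json(summary, file.path(outDir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(summary)
}
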