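#' Spearman correlation of every gene with a driver gene
#'
#' Rank correlation (average-rank ties) of each gene's expression with the
#' driver across samples, with the usual t approximation for the two-sided
#' p-value, \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of
#' freedom.  Perfectly monotone genes (|rho| = 1) are flagged
#' `exact-monotone` with p = 0; constant genes are flagged undefined.
#'
#' @param te a [TpmExperiment-class] or genes x samples matrix.
#' @param driver driver gene id (must be a row).
#' @return data.frame with `gene`, `rho`, `p`, `n`, `flag`.
#' @export
spearmanToDriver <- function(te, driver) {
  mat <- if (is(te, "TpmExperiment")) tpm(te) else as.matrix(te)
  if (!driver %in% rownames(mat)) stop("driver '", driver, "' not in matrix")
  n <- ncol(mat)
  if (n < 3L) stop("need at least 3 samples")
  rd <- rank(mat[driver, ])
  ranks <- t(apply(mat, 1, rank))
  sds <- apply(ranks, 1, sd)
  rho <- rep(NA_real_, nrow(mat))
  ok <- sds > 0 & sd(rd) > 0
  rho[ok] <- as.numeric(cor(rd, t(ranks[ok, , drop = FALSE])))
  p <- rep(NA_real_, nrow(mat))
  flag <- ifelse(ok, "", "constant")
  mono <- ok & abs(rho) >= 1 - 1e-12
  flag[mono] <- "exact-monotone"
  p[mono] <- 0
  mid <- ok & !mono
  tstat <- rho[mid] * sqrt((n - 2) / (1 - rho[mid]^2))
  p[mid] <- 2 * pt(-abs(tstat), df = n - 2)
  data.frame(gene = rownames(mat), rho = rho, p = p, n = n, flag = flag,
    row.names = NULL)
}

#' Select the driver-correlated gene set
#'
#' @param corr result of [spearmanToDriver()].
#' @param pThreshold strict upper bound on the (optionally adjusted)
#'   p-value (default 5e-4).
#' @param driver driver gene id, always excluded from the set.
#' @param adjust multiple-testing adjustment passed to
#'   [stats::p.adjust()] (default `"none"`).
#' @return character vector of gene ids.
#' @export
correlatedGeneSet <- function(corr, pThreshold = 5e-4, driver = NULL,
                              adjust = "none") {
  p <- p.adjust(corr$p, method = adjust)
  genes <- corr$gene[!is.na(p) & p < pThreshold]
  if (!is.null(driver)) genes <- setdiff(genes, driver)
  genes
}

#' Binomial overlap enrichment between two gene sets
#'
#' Tests whether two gene sets drawn from a common universe overlap more
#' than chance: with universe size \eqn{N}, set sizes \eqn{|A|} and
#' \eqn{|B|} and observed overlap \eqn{x}, the upper-tail p-value is
#' \eqn{P(X \ge x)} for \eqn{X \sim \mathrm{Binomial}(|B|, |A|/N)}.  A
#' hypergeometric (sampling-without-replacement) alternative is offered for
#' comparison.  Membership is computed on deduplicated identifiers, and
#' both sets must be subsets of the universe.
#'
#' @param universe character vector defining the gene universe.
#' @param setA,setB gene sets (subsets of `universe`).
#' @param model `"binomial"` (default) or `"hypergeometric"`.
#' @return list with `N`, `sizeA`, `sizeB`, `overlap`, `expected`
#'   (`|B| |A| / N`), `p`, and `model`.
#' @examples
#' u <- paste0("g", 1:100)
#' overlapBinomial(u, u[1:10], u[6:15])$p # P(X >= 5), X ~ Bin(10, 0.1)
#' @export
overlapBinomial <- function(universe, setA, setB,
                            model = c("binomial", "hypergeometric")) {
  model <- match.arg(model)
  universe <- unique(universe)
  setA <- unique(setA)
  setB <- unique(setB)
  offA <- setdiff(setA, universe)
  offB <- setdiff(setB, universe)
  if (length(offA) || length(offB)) {
    stop("set members outside the universe: ",
      paste(head(c(offA, offB), 10), collapse = ", "))
  }
  N <- length(universe)
  x <- length(intersect(setA, setB))
  p <- if (model == "binomial") {
    pbinom(x - 1, size = length(setB), prob = length(setA) / N,
      lower.tail = FALSE)
  } else {
    phyper(x - 1, m = length(setA), n = N - length(setA), k = length(setB),
      lower.tail = FALSE)
  }
  list(N = N, sizeA = length(setA), sizeB = length(setB), overlap = x,
    expected = length(setB) * length(setA) / N, p = p, model = model)
}

#' Top differentially expressed genes from a DE table
#'
#' Ranks genes by ascending adjusted p-value, breaking ties by descending
#' absolute log fold change and then lexicographic gene id, and returns the
#' first `k`.
#'
#' @param de data.frame of DE results.
#' @param k number of genes to return (default 150); if `k` exceeds the
#'   table size, the whole table is returned with a warning.
#' @param geneCol,pCol,lfcCol column names (defaults `"gene"`, `"padj"`,
#'   `"log2FC"`).
#' @return character vector of gene ids.
#' @export
topDeGenes <- function(de, k = 150, geneCol = "gene", pCol = "padj",
                       lfcCol = "log2FC") {
  need <- c(geneCol, pCol, lfcCol)
  if (!all(need %in% names(de))) {
    stop("DE table lacks column(s): ", paste(setdiff(need, names(de)), collapse = ", "))
  }
  if (k > nrow(de)) {
    warning("k = ", k, " exceeds table size ", nrow(de), "; returning all genes")
    k <- nrow(de)
  }
  ord <- order(de[[pCol]], -abs(de[[lfcCol]]), de[[geneCol]])
  as.character(de[[geneCol]][ord][seq_len(k)])
}

#' Outlier expression Z-scores for translocated cases
#'
#' Quantifies driver over-expression in translocation-carrying cases
#' against the rest of the cohort: per flagged case,
#' \eqn{z = (x - \bar x_{cohort}) / s_{cohort}} where the mean and sample
#' standard deviation (denominator n-1) are computed over non-translocated
#' cases only, on the TPM scale.
#'
#' @param te a [TpmExperiment-class] whose `colData` has a logical
#'   `translocated` column.
#' @param gene gene id.
#' @return list with per-case `z` (named), `meanZ`, cohort `mean`, `sd`,
#'   `nCohort`, and `flag` (`"zero-sd"` with `NA` z when the cohort is
#'   constant).
#' @export
translocationZscore <- function(te, gene) {
  stopifnot(is(te, "TpmExperiment"))
  if (!"translocated" %in% names(colData(te))) {
    stop("colData lacks a 'translocated' column")
  }
  if (!gene %in% rownames(tpm(te))) stop("gene '", gene, "' not in matrix")
  fl <- as.logical(colData(te)$translocated)
  if (sum(!fl) < 2L) stop("need >= 2 non-translocated cohort cases")
  vals <- tpm(te)[gene, ]
  m <- mean(vals[!fl])
  s <- sd(vals[!fl])
  if (s == 0) {
    return(list(z = setNames(rep(NA_real_, sum(fl)), names(vals)[fl]),
      meanZ = NA_real_, mean = m, sd = s, nCohort = sum(!fl),
      flag = "zero-sd"))
  }
  z <- (vals[fl] - m) / s
  list(z = z, meanZ = if (length(z)) mean(z) else NA_real_,
    mean = m, sd = s, nCohort = sum(!fl), flag = character(0))
}
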