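#' Restrict samples to chromosome-disomic cases
#'
#' eQTL testing at a locus is confounded by somatic copy-number change, so
#' samples are restricted to those carrying exactly two copies of the
#' chromosome of interest.
#'
#' @param samples character vector of sample ids.
#' @param copyNumber named (or aligned) integer vector of copy-number calls
#'   for the chromosome.
#' @param onMissing what to do with samples lacking a call: `"exclude"`
#'   (default) or `"error"`.
#' @return character vector of retained sample ids.
#' @examples
#' disomyFilter(c("a", "b", "c", "d"), c(2, 2, 3, 1))
#' @export
disomyFilter <- function(samples, copyNumber, onMissing = c("exclude", "error")) {
  onMissing <- match.arg(onMissing)
  if (!is.null(names(copyNumber))) {
    cn <- copyNumber[samples]
  } else {
    if (length(copyNumber) != length(samples)) {
      stop("'copyNumber' must be named or aligned with 'samples'")
    }
    cn <- copyNumber
  }
  if (any(is.na(cn)) && onMissing == "error") {
    stop("missing copy-number call for sample(s): ",
      paste(samples[is.na(cn)], collapse = ", "))
  }
  samples[!is.na(cn) & cn == 2]
}

#' Kruskal-Wallis test of expression across genotype groups
#'
#' Rank-based test of equal expression distributions across genotype
#' classes, using average ranks for ties and the tie-corrected statistic
#' \deqn{H = \frac{12}{N(N+1)} \sum_g n_g (\bar R_g - \tfrac{N+1}{2})^2
#'   \Big/ \Big(1 - \tfrac{\sum (t^3 - t)}{N^3 - N}\Big)}
#' with a chi-square p-value on (groups - 1) degrees of freedom.  All-equal
#' observations are a degenerate case returning H = 0, p = 1.  The test is
#' delegated to [stats::kruskal.test()].
#'
#' @param values numeric expression values (e.g. TPM).
#' @param genotype grouping factor/vector (e.g. 0/1/2 risk-allele dosage).
#' @return list with `H`, `p`, `df`, `n`, per-group sizes `groupSizes` and
#'   mean ranks `meanRanks`.
#' @examples
#' kruskalByGenotype(1:6, rep(0:2, each = 2)) # H = 32/7
#' @export
kruskalByGenotype <- function(values, genotype) {
  keep <- !is.na(values) & !is.na(genotype)
  values <- values[keep]
  g <- factor(genotype[keep])
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least two non-empty genotype groups")
  if (length(values) < 3L) stop("need at least three observations")
  rk <- rank(values)
  groupSizes <- table(g)
  meanRanks <- tapply(rk, g, mean)
  if (diff(range(values)) == 0) {
    return(list(H = 0, p = 1, df = nlevels(g) - 1L,
      n = length(values), groupSizes = groupSizes, meanRanks = meanRanks))
  }
  kt <- kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value,
    df = unname(kt$parameter), n = length(values),
    groupSizes = groupSizes, meanRanks = meanRanks)
}

#' Fold change between homozygote genotype groups
#'
#' Expression fold change of risk-allele homozygotes over non-risk
#' homozygotes, the effect size usually quoted alongside a genotype-stratified
#' eQTL test.  Mean type is configurable; arithmetic is the default.
#'
#' @param values numeric expression values (positive for geometric means).
#' @param genotype risk-allele dosage (0/1/2) aligned with `values`.
#' @param mean `"arithmetic"` (default) or `"geometric"`.
#' @return list with `fold`, per-group `means` and `sizes`, and `flag`
#'   (`"empty-homozygote-group"` with `NA` fold when one group is absent).
#' @examples
#' homozygoteFoldChange(c(10, 20, 5, 10), c(2, 2, 0, 0))$fold # 2
#' @export
homozygoteFoldChange <- function(values, genotype,
                                 mean = c("arithmetic", "geometric")) {
  mean <- match.arg(mean)
  keep <- !is.na(values) & !is.na(genotype)
  values <- values[keep]
  genotype <- genotype[keep]
  hi <- values[genotype == 2]
  lo <- values[genotype == 0]
  sizes <- c(hom_risk = length(hi), het = sum(genotype == 1), hom_nonrisk = length(lo))
  if (!length(hi) || !length(lo)) {
    return(list(fold = NA_real_, means = c(NA_real_, NA_real_),
      sizes = sizes, flag = "empty-homozygote-group"))
  }
  avg <- function(x) if (mean == "arithmetic") base::mean(x) else exp(base::mean(log(x)))
  m <- c(hom_risk = avg(hi), hom_nonrisk = avg(lo))
  list(fold = m[["hom_risk"]] / m[["hom_nonrisk"]], means = m, sizes = sizes,
    flag = character(0))
}

#' Genotype-stratified eQTL test for one gene
#'
#' Convenience wrapper combining the disomy restriction, the Kruskal-Wallis
#' test and the homozygote fold change for a single gene.
#'
#' @param te a [TpmExperiment-class] whose `colData` has a `copy_number`
#'   column.
#' @param gene gene id (row of the TPM assay).
#' @param genotype named risk-allele dosage vector covering the samples.
#' @param restrictDisomic apply the copy-number == 2 restriction (default
#'   TRUE).
#' @return list with `kw` (see [kruskalByGenotype()]), `fold` (see
#'   [homozygoteFoldChange()]), and `samples` used.
#' @export
eqtlTest <- function(te, gene, genotype, restrictDisomic = TRUE) {
  stopifnot(is(te, "TpmExperiment"))
  if (!gene %in% rownames(tpm(te))) stop("gene '", gene, "' not in matrix")
  samples <- colnames(tpm(te))
  if (restrictDisomic) {
    if (!"copy_number" %in% names(colData(te))) {
      stop("colData lacks a 'copy_number' column")
    }
    cn <- setNames(colData(te)$copy_number, samples)
    samples <- disomyFilter(samples, cn)
  }
  vals <- tpm(te)[gene, samples]
  g <- genotype[samples]
  list(kw = kruskalByGenotype(vals, g),
    fold = homozygoteFoldChange(vals, g), samples = samples)
}
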