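#' Mask variant positions in a reference sequence with N
#'
#' Replaces the base at each listed position with `N`, the standard remedy
#' for reference-mapping bias in allele-specific read counting: once common
#' variant positions carry no reference base, reads from either allele pay
#' the same mismatch penalty and map with equal efficiency.
#'
#' @param sequence a [Biostrings::DNAString-class] or character scalar.
#' @param positions integer vector of 1-based positions to mask.
#' @return the masked sequence, same class and length as the input.
#' @examples
#' as.character(maskReference("ACGT", 2)) # "ANGT"
#' @export
maskReference <- function(sequence, positions) {
  wasChar <- is.character(sequence)
  seq <- if (wasChar) DNAString(sequence) else sequence
  positions <- as.integer(positions)
  if (length(positions)) {
    bad <- positions < 1L | positions > length(seq)
    if (any(bad)) {
      stop("position(s) out of bounds for a length-", length(seq),
        " sequence: ", paste(positions[bad], collapse = ", "))
    }
    seq <- replaceLetterAt(seq, positions, rep.int("N", length(positions)))
  }
  if (wasChar) as.character(seq) else seq
}

#' Count allelic reads at a heterozygous site
#'
#' Tallies pileup records at a biallelic site into reference / alternate /
#' other counts.  Reads with mapping quality below `mapqMin` are discarded;
#' bases below `baseQualityMin` or matching neither allele fall into
#' `kOther`.
#'
#' @param pileup data.frame with columns `chrom`, `pos` (1-based), `base`,
#'   and optionally `baseq`, `mapq`.
#' @param site list or one-row data.frame with `site`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param baseQualityMin minimum base quality counted toward an allele
#'   (default 20).
#' @param mapqMin minimum mapping quality for a read to be used at all
#'   (default 30).
#' @param assay assay label stored in the result.
#' @return an [AllelicCount-class]; a site with no usable reads is returned
#'   with zero tallies and flag `"uncovered"`.
#' @export
countAllelicReads <- function(pileup, site, baseQualityMin = 20,
                              mapqMin = 30, assay = "assay") {
  stopifnot(all(c("chrom", "pos", "base") %in% names(pileup)))
  rows <- pileup$chrom == site$chrom & pileup$pos == site$pos
  if ("mapq" %in% names(pileup)) rows <- rows & pileup$mapq >= mapqMin
  px <- pileup[rows, , drop = FALSE]
  if (nrow(px) == 0L) {
    return(AllelicCount(site$site, 0L, 0L, 0L, site$chrom, site$pos,
      site$ref, site$alt, assay, flag = "uncovered"))
  }
  base <- toupper(px$base)
  lowq <- if ("baseq" %in% names(px)) px$baseq < baseQualityMin else rep(FALSE, nrow(px))
  kRef <- sum(!lowq & base == toupper(site$ref))
  kAlt <- sum(!lowq & base == toupper(site$alt))
  kOther <- nrow(px) - kRef - kAlt
  AllelicCount(site$site, kRef, kAlt, kOther, site$chrom, site$pos,
    site$ref, site$alt, assay)
}

#' Exact binomial test of allelic imbalance
#'
#' Tests whether the alternate-allele read fraction at a heterozygous site
#' departs from a null proportion `p0` (0.5 for an unbiased assay).  The
#' two-sided p-value uses the minimum-likelihood ("minlike") construction:
#' the sum of probabilities of all outcomes whose binomial probability does
#' not exceed that of the observed count.  A central two-sided option
#' (twice the smaller tail, capped at 1), one-sided alternatives, and a
#' mid-p variant (half weight on outcomes exactly as likely/extreme as the
#' observation) are also available.
#'
#' @param kAlt observed alternate-allele reads, or an
#'   [AllelicCount-class] (in which case `n` is taken from it).
#' @param n total informative reads (`kRef + kAlt`).
#' @param p0 null alternate fraction in (0, 1).
#' @param alternative `"minlike"` (default), `"central"`, `"less"`,
#'   `"greater"`.
#' @param midp use the mid-p variant (default FALSE).
#' @return list with `site` (if known), `k`, `n`, `altFraction`, the
#'   `enrichment` ratio altFraction/(1 - altFraction), `p`, `alternative`,
#'   and `flag` (`"no-reads"` with `NA` p when n = 0).
#' @examples
#' binomialBiasTest(9, 10)$p # 22/1024
#' @export
binomialBiasTest <- function(kAlt, n = NULL, p0 = 0.5,
                             alternative = c("minlike", "central", "less", "greater"),
                             midp = FALSE) {
  alternative <- match.arg(alternative)
  site <- NA_character_
  if (is(kAlt, "AllelicCount")) {
    site <- kAlt@site
    n <- kAlt@kRef + kAlt@kAlt
    kAlt <- kAlt@kAlt
  }
  if (is.null(n)) stop("'n' is required")
  if (p0 <= 0 || p0 >= 1) stop("'p0' must lie strictly in (0, 1)")
  if (kAlt < 0 || kAlt > n) stop("'kAlt' must lie in [0, n]")
  af <- if (n > 0) kAlt / n else NA_real_
  if (n == 0L) {
    return(list(site = site, k = kAlt, n = n, altFraction = af,
      enrichment = NA_real_, p = NA_real_, alternative = alternative,
      flag = "no-reads"))
  }
  d <- dbinom(0:n, n, p0)
  dObs <- d[kAlt + 1]
  relEps <- 1 + 1e-7
  p <- switch(alternative,
    minlike = {
      if (midp) {
        strictly <- d < dObs / relEps
        asLikely <- !strictly & d <= dObs * relEps
        sum(d[strictly]) + 0.5 * sum(d[asLikely])
      } else {
        sum(d[d <= dObs * relEps])
      }
    },
    central = {
      lo <- pbinom(kAlt, n, p0)
      hi <- pbinom(kAlt - 1, n, p0, lower.tail = FALSE)
      if (midp) {
        lo <- lo - 0.5 * dObs
        hi <- hi - 0.5 * dObs
      }
      min(1, 2 * min(lo, hi))
    },
    less = pbinom(kAlt, n, p0) - if (midp) 0.5 * dObs else 0,
    greater = pbinom(kAlt - 1, n, p0, lower.tail = FALSE) - if (midp) 0.5 * dObs else 0
  )
  list(site = site, k = kAlt, n = n, altFraction = af,
    enrichment = if (af < 1) af / (1 - af) else Inf,
    p = min(1, max(p, 0)), alternative = alternative, flag = character(0))
}

#' Allelic imbalance with an input-DNA control
#'
#' A site shows credible allele-specific signal only when the assay reads
#' are imbalanced *and* the input (pre-immunoprecipitation) DNA is not:
#' imbalance present in the input points to a mapping or copy-number
#' artefact rather than differential chromatin signal.
#'
#' @param assayCount,inputCount [AllelicCount-class] objects at the same
#'   site.
#' @param p0 null alternate fraction (default 0.5).
#' @param alpha significance level applied to both tests (default 0.05).
#' @param ... passed to [binomialBiasTest()].
#' @return list with `assay` and `input` test results, and `alleleSpecific`
#'   (TRUE iff assay p < alpha and input p >= alpha).
#' @examples
#' a <- AllelicCount("rs1", kRef = 35, kAlt = 15, assay = "H3K27ac")
#' i <- AllelicCount("rs1", kRef = 25, kAlt = 25, assay = "input")
#' pairedBiasAssessment(a, i)$alleleSpecific
#' @export
pairedBiasAssessment <- function(assayCount, inputCount, p0 = 0.5,
                                 alpha = 0.05, ...) {
  if (assayCount@site != inputCount@site) {
    stop("assay and input counts describe different sites")
  }
  ta <- binomialBiasTest(assayCount, p0 = p0, ...)
  ti <- binomialBiasTest(inputCount, p0 = p0, ...)
  ok <- !is.na(ta$p) && !is.na(ti$p) && ta$p < alpha && ti$p >= alpha
  list(assay = ta, input = ti, alleleSpecific = ok, alpha = alpha)
}
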