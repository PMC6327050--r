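#' Fit a qPCR standard curve
#'
#' Least-squares fit of quantification cycle (Cq) on log10 template
#' quantity across a serial dilution series.  A valid curve has a negative
#' slope; amplification efficiency is \eqn{10^{-1/\mathrm{slope}}} (2 for
#' perfect doubling chemistry, slope about -3.32).
#'
#' @param quantity strictly positive template quantities (>= 3 distinct
#'   points).
#' @param cq matching Cq values.
#' @return list with `slope`, `intercept`, `efficiency`, `r2`, and `valid`
#'   (FALSE, with flag `"invalid-curve"`, when the slope is >= 0).
#' @examples
#' q <- 5^(0:4)
#' standardCurveFit(q, 30 - log2(q))$efficiency # 2
#' @export
standardCurveFit <- function(quantity, cq) {
  if (length(quantity) != length(cq)) stop("inputs must be aligned")
  if (length(unique(quantity)) < 3L) stop("need >= 3 distinct dilution points")
  if (any(quantity <= 0)) stop("quantities must be strictly positive")
  fit <- lm(cq ~ log10(quantity))
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  valid <- is.finite(slope) && slope < 0
  tss <- sum((cq - mean(cq))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else NA_real_
  list(slope = slope, intercept = intercept,
    efficiency = if (valid) 10^(-1 / slope) else NA_real_,
    r2 = r2, valid = valid,
    flag = if (valid) character(0) else "invalid-curve")
}

#' Interpolate a template quantity from a fitted standard curve
#'
#' @param curve result of [standardCurveFit()].
#' @param cq Cq value(s) to interpolate.
#' @return template quantity on the scale of the dilution series.
#' @export
interpolateQuantity <- function(curve, cq) {
  if (!isTRUE(curve$valid)) stop("cannot interpolate on an invalid curve")
  10^((cq - curve$intercept) / curve$slope)
}

#' Percent input normalisation for ChIP-qPCR
#'
#' Expresses immunoprecipitated signal as a percentage of total chromatin,
#' correcting for the fraction of chromatin the input aliquot represents:
#' `100 * ip / (input / inputFraction)`.
#'
#' @param ip interpolated IP quantity (> 0).
#' @param input interpolated input quantity.
#' @param inputFraction fraction of chromatin in the input aliquot, in
#'   (0, 1] (1 = input measured on the full amount).
#' @return percent of input; `NA` flagged when input is zero.
#' @examples
#' percentInput(2, 2, inputFraction = 0.01) # 2
#' @export
percentInput <- function(ip, input, inputFraction = 1) {
  if (inputFraction <= 0 || inputFraction > 1) {
    stop("'inputFraction' must lie in (0, 1]")
  }
  if (input <= 0) {
    return(structure(NA_real_, flag = "zero-input"))
  }
  100 * ip / (input / inputFraction)
}

#' Fold enrichment over a nonspecific-antibody control
#'
#' @param target percent input of the specific antibody.
#' @param control percent input of the IgG (nonspecific) control.
#' @return `target / control`; `NA` flagged when the control is zero.
#' @export
foldEnrichment <- function(target, control) {
  if (is.na(control) || control <= 0) {
    return(structure(NA_real_, flag = "zero-control"))
  }
  target / control
}

#' Allele preference of an allele-specific primer pair
#'
#' Quantifies how strongly an allele-specific qPCR primer prefers its
#' matched template over the mismatched one, by interpolating both Cq
#' values through a fitted standard curve and taking the quantity ratio.  A
#' mismatched template that never amplifies (Cq at the cycling ceiling) is
#' censored: the preference is reported as a lower bound.
#'
#' @param curve result of [standardCurveFit()].
#' @param cqMatched,cqMismatched Cq on matched / mismatched template.
#' @param cqCeiling optional cycle ceiling; `cqMismatched >= cqCeiling`
#'   marks the measurement censored.
#' @return list with `preference` (matched/mismatched quantity ratio),
#'   `censored`, and `flag`.
#' @export
allelePreference <- function(curve, cqMatched, cqMismatched, cqCeiling = NULL) {
  qm <- interpolateQuantity(curve, cqMatched)
  qx <- interpolateQuantity(curve, cqMismatched)
  censored <- !is.null(cqCeiling) && cqMismatched >= cqCeiling
  list(preference = qm / qx, censored = censored,
    flag = if (censored) "mismatched-template-censored" else character(0))
}

#' Replicate comparison by t-test
#'
#' Welch's two-sided t-test (default) or a paired t-test for matched
#' replicates, via [stats::t.test()].  Two degenerate zero-variance groups
#' with equal means return p = 1 by convention (p = 0 if the means differ).
#'
#' @param a,b numeric replicate values (>= 2 each).
#' @param paired match replicates pairwise (default FALSE).
#' @return list with `t`, `df`, `p`, and `flag`.
#' @examples
#' replicateTTest(1:3, 4:6)$p # ~0.0214
#' @export
replicateTTest <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  degenerate <- if (paired) sd(a - b) == 0 else (sd(a) == 0 && sd(b) == 0)
  if (degenerate) {
    equal <- if (paired) all(a == b) else mean(a) == mean(b)
    return(list(t = if (equal) 0 else Inf, df = NA_real_,
      p = if (equal) 1 else 0, flag = "degenerate"))
  }
  tt <- t.test(a, b, paired = paired)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, flag = character(0))
}
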