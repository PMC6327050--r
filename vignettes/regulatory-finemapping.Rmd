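---
title: "Methods: integrative regulatory fine-mapping with regfine"
author: "regfine authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative regulatory fine-mapping with regfine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regfine)
```

# Overview

`regfine` chains the analyses needed to move from a GWAS hit in a
regulatory element to a mechanistic account: association and LD structure,
a copy-number-restricted eQTL, allele-specific chromatin signal, qPCR
quantitation, enhancer–promoter linking, downstream gene programs, and the
recombination-signal scan that asks whether a translocation was
RAG-mediated.  This vignette records the statistical models, the
parameters that matter, the design decisions taken where several defensible
choices existed, and what the synthetic-data tests do and do not establish.

# Association and fine-mapping

**Allelic association.** The base test is the 2×2 allele-count table
(risk/other allele × case/control).  The odds ratio is the cross-product,
the log-OR standard error is Woolf's \(\sqrt{1/a + 1/b + 1/c + 1/d}\), and
the two-sided p comes from the normal approximation.  Any zero cell
triggers the Haldane–Anscombe correction (0.5 to every cell);
monomorphic variants return a flagged `NA` rather than an error.  We chose
the allele-count test over a genotypic logistic model because it matches
per-allele OR reporting and is closed-form, hence checkable against a hand
oracle; logistic regression appears only in the conditional analysis,
where a covariate is unavoidable.

**Meta-analysis.** Fixed-effect inverse-variance pooling with weights
\(w_i = 1/se_i^2\); heterogeneity by Cochran's
\(Q = \sum w_i(\beta_i - \hat\beta)^2\) on \(k-1\) df.  With a single
study \(p_{het} = 1\) by convention (vacuous homogeneity).

**INFO score.** For posterior triples \((p_{i0}, p_{i1}, p_{i2})\), with
\(e_i = p_{i1} + 2p_{i2}\) and \(f_i = p_{i1} + 4p_{i2}\),
\[
\mathrm{INFO} = 1 - \frac{\sum_i (f_i - e_i^2)}
  {2N\,\hat\theta(1-\hat\theta)}, \qquad
\hat\theta = \frac{\sum_i e_i}{2N}.
\]
Point-mass posteriors give 1; monomorphic variants return 1 by convention;
sampling noise can push the ratio marginally outside \([0,1]\), so it is
clipped.  The default retention threshold is 0.8.

**LD and capture.** \(r^2\) is the squared Pearson correlation of dosage
vectors — the phase-free composite-LD surrogate, since phased haplotypes
are not part of the inputs.  The block around a lead variant is every
variant with MAF > 0.01 (strict) and \(r^2 \ge 0.4\) (inclusive); the
capture fraction is the share of that block present among variants with
usable data.  Note an arithmetic constraint worth knowing: a variant at
MAF 0.005 cannot reach \(r^2 \ge 0.4\) with a MAF-0.3 lead (the frequency
mismatch caps \(r^2\) near 0.01), so in practice the MAF gate acts on
borderline-frequency proxies, which is how the tests exercise it.

**Conditional analysis.** Likelihood-ratio test between logistic models
`pheno ~ covariate` and `pheno ~ covariate + dosage` (1 df).  A constant
covariate reduces to the unconditional test; |r| > 0.999 between test and
conditioning dosage is flagged collinear rather than fit.

# Copy-number-restricted eQTL

Somatic aneuploidy moves expression for reasons unrelated to genotype, so
the panel is first restricted to samples carrying exactly two copies of
the chromosome (`disomyFilter`; missing calls excluded by default,
configurable to error).  The test is the tie-corrected Kruskal–Wallis
statistic across genotype classes (delegated to `stats::kruskal.test`),
with H = 0, p = 1 for degenerate all-equal data.  The effect size is the
fold change between homozygote group means.  Because a single reported
fold could equally be homozygote-contrast or per-allele, we define it as
risk-homozygote mean over non-risk-homozygote mean — an interpretation,
recorded here, not a claim about any particular study — with the mean type
configurable (arithmetic default, geometric available); with log-normal
expression and genotype-independent noise the arithmetic-mean ratio is an
unbiased estimate of the planted fold.

# Allele-specific chromatin signal

Reads from the non-reference allele carry an extra mismatch against the
reference and are lost in alignment at a higher rate — reference-mapping
bias.  The remedy is to replace common variant positions with `N` in the
reference before alignment; `maskReference` implements the edit and the
generator models the bias as a multiplicative read-retention advantage
(`refBias` ≥ 1): an alternate-allele read survives with probability
1/refBias at an unmasked known-variant site, giving a retained alternate
fraction \(f/(f + (1-f)\,b)\).  Masking removes the penalty entirely in
this model; the acceptance tests verify ≥ 90% of the induced shift in the
alternate-fraction estimate disappears, and that bias at sites *not* in
the masked set is, correctly, untouched.

Counting applies MAPQ ≥ 30 (read-level) and base quality ≥ 20
(base-level, falling into `k_other`) by default; the MAPQ threshold
mirrors standard ChIP-seq practice, the base-quality floor is our choice.

**Imbalance testing.** Exact binomial test of \(k_{alt}\) of \(n\) reads
against \(p_0 = 0.5\).  The two-sided default is the minimum-likelihood
("minlike") construction — sum the probabilities of all outcomes no more
likely than the observed one — because it is the common exact-test default
and reproduces `binom.test`; the central (2·min-tail, capped at 1) and
one-sided alternatives are exposed, as is a mid-p variant, since discrete
tests are conservative and mid-p is the standard remedy when calibration
matters more than strict level control.  A site is labelled
allele-specific only when the assay p is below α *and* the paired
input-DNA p is not (same α both sides, 0.05 default): input imbalance
means the site's apparent signal is an artefact of mapping or copy number,
not chromatin.

# ChIP-qPCR quantitation

Cq is regressed on \(\log_{10}\)(quantity) over a serial dilution series
(fivefold by convention); amplification efficiency is \(10^{-1/slope}\)
(2 for perfect doubling, slope ≈ −3.32).  Non-negative slopes flag the
curve invalid.  Percent input is \(100\,q_{IP}/(q_{input}/\phi)\) where
\(\phi\) is the chromatin fraction the input aliquot represents; fold
enrichment is the percent-input ratio against the IgG control; both are
invariant to common multiplicative rescaling of all quantities.
Allele-specific primers are validated by interpolating matched and
mismatched templates through the fitted curve; a mismatched template
pinned at the cycle ceiling reports a censored lower bound.  Replicates
compare by Welch's t-test (paired available); two zero-variance groups
with equal means give p = 1 by convention.

# Regulome annotation

**Peak→TSS.** A gene is assigned when the distance from its TSS position
to the nearest peak edge (0 inside) is ≤ the window, inclusive, 1 kb by
default.  "Within 1 kb" has no canonical edge convention; inclusive is
ours, and the brute-force property test pins it down.  TSS strand is
ignored — the position *is* the TSS.

**Hi-C linking.** Intervals map to fixed bins by
\(\lfloor \text{pos}_{0\text{-based}}/\text{resolution} \rfloor\); two
intervals are linked when the maximum normalized contact over the bin
cross-product reaches the threshold, and same-bin pairs are linked by
convention (sub-resolution distance).  The contact threshold has no
canonical value — it depends on the normalization and depth of the map —
so it is a required parameter, recorded with the results, not a default.

**Motif scanning.** IUPAC-aware Hamming matching on both strands via
`Biostrings::matchPattern`, with palindromic double-hits collapsed to one
record of strand `"both"`.  Consensus/mismatch matching only; position
weight matrices are out of scope.

# Expression programs

Spearman correlation (average-rank ties, t approximation on \(n-2\) df)
of every gene against the driver; the correlated set takes p strictly
below 5×10⁻⁴, driver excluded, unadjusted by default with `p.adjust`
methods exposed — whether to adjust before such a cut is a judgment call,
and the threshold's origin suggests an unadjusted screen.  The floor on
cohort size is 3 samples (the t approximation's df = 1 limit).

Overlap enrichment uses the upper-tail binomial \(P(X \ge x)\),
\(X \sim \mathrm{Bin}(|B|, |A|/N)\) — the "binomial p" convention — with
the hypergeometric (without-replacement) model available for comparison;
at program scale (small sets, large universe) the two agree closely.  The
universe must be stated explicitly: we define it as the genes present in
the expression table (driver excluded), recorded in the output metadata,
because enrichment p-values are meaningless without a reproducible
universe.  DE tables rank by ascending adjusted p, ties broken by
descending |log2FC| then gene id, top 150 by default.

Translocation outliers score as \(z = (x - \bar{x})/s\) against the mean
and *sample* SD (n−1; the conservative small-cohort choice) of
non-translocated cases, on the TPM scale, averaged over flagged cases.

# The synthetic-data generators

Every generator is a pure function of `simConfig()` including its seed
(per-generator derived streams, recorded in the truth output), so a
config reproduces its datasets byte for byte.  Defaults are the
motivating study's dimensions: series of 824/5200 and 834/2024 at OR
1.45 and MAF 0.3; a 60-blast panel with 44 disomic and a 1.8-fold eQTL;
allelic depth 100; a 117-case cohort with a driver, 150 correlated
targets and a 150-gene DE set; two translocated cases at 4.6 SD; 313
peaks with 83/313 of genes TSS-proximal.

Model choices: case/control genotypes are Hardy–Weinberg within group
with the case allele frequency implied by the odds ratio on the allele
scale; expression is log-normal (positive support matching TPM — an
assumption, the noise model of blast expression not being otherwise
pinned down) with additive per-dosage genotype effects on the log scale
and copy-ratio shifts for non-disomic samples; reference bias is a
multiplicative read-retention advantage (matching the mechanism N-masking
corrects); correlated targets share a latent factor with the driver at
the configured magnitude; translocated cases plant the driver
*deterministically* at cohort mean + z·SD while drawing all other genes
from the per-gene cohort model; breakpoint loci are uniform-random
sequence with the RSS elements planted at recorded offsets (and, for
heptamer-only planting, chance nonamers actively scrubbed from all
spacer-consistent offsets so the classification truth is unambiguous);
peaks sit on a wide grid with TSS placed inside or strictly outside the
window so the proximal fraction is exact, not approximate.

What the generators do *not* emulate — and hence what green tests do not
establish about real data: population structure and imputation error
beyond the symmetric posterior-flattening model; linked untyped causal
variants; overdispersed (beta-binomial) allelic counts from PCR
duplicates; correlated gene–gene structure beyond one latent factor;
Hi-C distance decay; sequence composition bias.  Calibration and
recovery results transfer to real data only insofar as these features are
negligible for the statistic in question.

## Calibration and recovery

Under each null (OR = 1, fold = 1, balanced unbiased allelic reads,
ρ = 0, z = 0) the corresponding downstream p-values pass a
Kolmogorov–Smirnov uniformity test at α = 0.01 over 200 replicates.  Two
subtleties: the allelic-imbalance null uses the mid-p variant (the exact
minlike p is conservative on a depth-100 lattice), and the z = 0 null is
checked through the cohort-model draw of the appended case via a
randomized rank-PIT — the planted driver value at z = 0 is exactly the
cohort mean by the model's definition, so the driver's z is identically 0
there, and TPM's skewness makes a normal tail the wrong reference for a
cohort-drawn value anyway.

Planted effects are recovered within stated tolerances (OR 1.45 within
10% at 5000/5000; fold 1.8 within 25% at n = 44 — dominated by the
~4-sample risk-homozygote group; biased alternate fraction at the closed
form 1/3; 300-fold primer preference within 1%; mean Z 4.6 within 15%),
each as a mean over 20 seeds.  Exact tests are verified against full pmf
enumeration for all n ≤ 30; peak assignment and LD capture against
all-pairs brute force; the RSS scanner against planted motifs in 100/100
seeds and a \(2(L-6)/4^7\) background-rate Poisson band.

## Problem sizes in the shipped tests

The test suite scales simulations to what the properties need, not to the
full study dimensions: calibration runs use 200 replicates of
small-to-moderate cohorts (300/300 association, 44-blast eQTL, depth-100
counts, 117-sample correlation), recovery runs use 20 seeds, and
brute-force equivalence uses random instances up to a few hundred
intervals/variants.  The pipeline demo in the acceptance script runs the
full default dimensions once.

# Numerical conventions and degenerate inputs

1-based coordinates for sites and sequences (VCF/Biostrings convention),
1-based closed intervals in `GRanges`, 0-based half-open only at the BED
boundary, conversions centralized in the IO layer.  Flagged-`NA` returns,
rather than exceptions, for statistically undefined cases (monomorphic
association, constant-vector r², empty homozygote groups, zero-SD
cohorts, zero-input qPCR); hard errors for malformed inputs (posteriors
not summing to 1, out-of-bounds mask positions, invalid IUPAC codes or
bases, sets outside the universe).  Ties use average ranks everywhere.

# On the RSS elements

The recombination-signal defaults are the canonical V(D)J heptamer
`CACAGTG` and nonamer `ACAAAAACC` with 12/23 bp spacers ± 1, supplied as
configurable values.  Descriptions of RAG motifs occasionally say
"hexamer" where the canonical element is the seven-base heptamer; the
scanner uses the canonical elements and exposes them as parameters rather
than guessing at a six-base variant.  Mismatch budgets default to 0 for
the heptamer (its conservation is functionally strict) and 1 for the
nonamer — our choice, configurable.

# Known limitations

No beta-binomial overdispersion in imbalance testing; no PWM scoring; no
loop-calling statistics on Hi-C (threshold linking only); the binomial
overlap ignores gene-length and expression-level selection biases; the
conditional analysis assumes an additive dosage effect; the pipeline's
non-simulated input path expects the package's own TSV conventions rather
than arbitrary external formats (VCF/BAM ingestion is limited to what the
IO layer documents).
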