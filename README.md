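# regfine

Integrative regulatory fine-mapping of a GWAS risk locus, in R.

Genome-wide association studies often land on a common variant in a
regulatory element — a promoter SNP, say — and leave open the hard part:
which allele changes which molecular readout, and through which target
gene.  `regfine` implements, as one tested toolkit, the chain of analyses
used to close that gap at a leukemia risk locus sitting in the promoter of
a transcription factor gene:

1. **Association & fine-mapping** — per-variant case/control allelic
   association (2×2 allele-count odds ratio with Woolf SE), inverse-variance
   fixed-effect meta-analysis with Cochran's *Q* heterogeneity, imputation
   INFO-score filtering, LD-block capture at dosage *r²* ≥ 0.4 and MAF >
   0.01, and conditional logistic likelihood-ratio analysis.
2. **eQTL** — copy-number-restricted (disomic-only) Kruskal–Wallis testing
   of expression by genotype, with the homozygote fold change as effect size.
3. **Allele-specific chromatin signal** — common-variant N-masking of the
   reference, allelic read counting with MAPQ/base-quality filters, exact
   ("minlike") two-sided binomial imbalance tests, and an input-DNA control
   gate: a site counts as allele-specific only when the assay is imbalanced
   and the input is not.
4. **ChIP-qPCR quantitation** — standard-curve fits on serial dilutions
   (efficiency = 10^(−1/slope)), percent input, fold enrichment over IgG,
   allele-specific-primer preference checks, and replicate Welch t-tests.
5. **Regulome annotation** — peak-to-TSS assignment within a 1 kb window,
   Hi-C contact linking of peaks to promoters at binned resolution, and
   IUPAC consensus motif scanning (e.g. the C/EBP site `TTGCGCAA`).
6. **Expression programs** — Spearman correlation of every gene with a
   driver gene, correlated-set selection at *P* < 5×10⁻⁴, binomial overlap
   enrichment against knockdown DE sets (p = P(X ≥ x), X ~ Bin(|B|, |A|/N)),
   and translocation outlier Z-scores against the non-translocated cohort.
7. **Breakpoints** — flank extraction around translocation breakpoints and
   recombination-signal-sequence (RSS) scanning: consensus heptamer
   `CACAGTG` and nonamer `ACAAAAACC` with 12/23 bp spacers, classifying
   each breakpoint as full-RSS-proximal, heptamer-only-proximal, or no-RSS.

Every input the pipeline consumes can be generated synthetically with known
ground truth (`simConfig()` + the `simulate*()` family), so the whole chain
is testable end to end without any external data.  Defaults mirror the
motivating study's dimensions: two case/control series (824/5200,
834/2024) at OR 1.45, 44 disomic blasts with a 1.8-fold eQTL, a 117-case
expression cohort, two translocated cases at 4.6 SD, 313 peaks with 83
TSS-proximal genes.

## Worked example

```r
library(regfine)
cfg <- simConfig(seed = 7)

# association + meta-analysis of the two simulated series
cc  <- simulateCaseControl(cfg)
a1  <- allelicAssociation(cc$genotypes, cc$phenotype, "rs_lead")
cc2 <- simulateCaseControl(cfg, study = 2)
a2  <- allelicAssociation(cc2$genotypes, cc2$phenotype, "rs_lead")
m   <- fixedEffectMeta(c(a1$beta, a2$beta), c(a1$se, a2$se))

# disomy-restricted eQTL on a 60-blast panel (44 disomic)
set.seed(19); g <- rbinom(cfg$nSamplesExpr, 2, cfg$maf)
eq  <- simulateEqtl(g, cfg)
res <- eqtlTest(eq$te, "CEBPE", eq$genotype)

# allele-specific ChIP signal with an input-DNA control
pa <- pairedBiasAssessment(
  simulateAllelicReads(cfg)$masked,
  simulateAllelicReads(cfg, "input", altFraction = 0.5, streamOffset = 1)$masked)
```

This prints, via the obvious `sprintf()` calls:

```
lead OR = 1.50 (p = 1.68e-13)
meta OR = 1.50 (p = 1.14e-23), Q = 0.014, p_het = 0.90
disomic n = 44, KW H = 7.92, p = 0.019, fold = 2.43
assay alt fraction = 0.63 (binomial p = 0.012), input p = 0.13 -> allele-specific: TRUE
```

Read: the simulated risk allele (true OR 1.45) is recovered at OR 1.50
with no between-study heterogeneity; restricted to the 44 disomic blasts
its risk-homozygotes express the target ~2.4-fold higher (planted: 1.8,
one 4-sample homozygote group — small-n noise); and the assay reads are
significantly imbalanced toward one allele while the input DNA is not, the
signature of genuine allele-specific chromatin signal.

The full pipeline, with per-stage outputs, a resolved config, a log, and a
deterministic `summary.json`:

```r
runPipeline("my_run", seed = 7)
```

or from a shell: `inst/scripts/regfine run --simulate --seed 7 --out my_run`.

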