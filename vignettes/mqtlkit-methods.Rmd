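---
title: "mqtlkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mqtlkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
statistical models, the parameters that matter, what the synthetic data can
and cannot stand in for, and the places where the design was genuinely open
and a choice had to be made.

## The two-stage association scan

The phenotype of every scan is the *normalized* methylation value: β-values
are mapped through the logistic link to the logit (log-odds) scale and
covariate effects — chip, position on chip, sex, age, age², and the
sex-by-age interactions — are removed by linear regression per probe
(`normalizeMethylation()`). We deliberately residualize linearly on the link
scale rather than taking residuals from a quasi-binomial response-scale fit:
link-scale linear residuals are *exactly* orthogonal to every covariate
column (the property association testing needs; asserted at 1e-8 in the
tests), and the intercept-only case reduces to centred logits. β-values of
exactly 0 or 1 are clipped to `[1e-6, 1 - 1e-6]` and counted. Sub-cohorts
can be normalized separately (a `group` column) and recombined, mirroring
designs in which one cohort is itself a pair of birth cohorts.

Outliers follow a 5-IQR rule with type-7 (linear-interpolation) quartiles —
the quartile method is not canonical and had to be fixed for
reproducibility. Two handling modes mirror two cohort conventions: set the
measurement missing (`"remove"`), or leave the value but restrict the probe
to common SNPs (MAF > 0.05, `"restrict_maf"`), the idea being that a rare
genotype plus an outlying measurement manufactures association. With zero
IQR the fences collapse onto the quartiles and any different value is
flagged; this degenerate case is reported.

Association itself (`assocTest()`) is simple linear regression of the
normalized phenotype on additive dosage: slope, SE, two-sided t-test p, and
r² (fraction of phenotype variance explained). The unit tests hold it to a
hand-coded normal-equations oracle at 1e-10. Family structure is *not*
modelled: the synthetic cohorts are unrelated, and a mixed model can be
slotted in behind the same contract later. Pairs with fewer than 10 complete
observations or zero dosage variance are skipped and counted.

The scan thresholds are the stringent two-cohort design, all configurable in
`scanConfig()`:

| parameter | default | role |
|---|---|---|
| `cisWindowBp` | 2,000,000 | cis window, per side of the CpG |
| `cisDiscoveryP` | 1e-11 | cis discovery (best SNP per probe) |
| `cisReplicationP` | 1e-6 | cis replication in the other cohort |
| `transStage1P` | 1e-7 | stage-1 trigger on genotyped SNPs |
| `transDiscoveryP` | 1e-13 | trans discovery |
| `transReplicationP` | 1e-5 | trans replication |

A trans SNP is any SNP outside the cis window — the window spans 4 Mbp in
total (2 Mbp per side), so a same-chromosome SNP 3 Mbp from the CpG is
trans-eligible, and cis/trans is a partition of retained records. Stage 2 of
the trans scan re-analyses only the triggering chromosome/probe pair (not
genome-wide), emulating the computational design that motivates the two
stages. Ties in p are broken by chromosome, then lower genomic position.
Replication requires beating the class threshold *and* sign agreement after
allele alignment (swapped ref/alt flips the replication sign; unambiguous
strand flips are reconciled; irreconcilable alleles are dropped and counted
separately from failed replication). When both discovery directions
replicate a probe at different SNPs, the SNP with the smaller
Fisher-combined p (−2(ln p₁ + ln p₂), 4 df) is kept.

The headline variance-explained summary averages r² over *all* probes,
counting zero for probes without an mQTL — the honest denominator when
asking how much methylation heritability the mapped QTL explain.

## LD scores and the heritability partition

The LD score of SNP j is `L_j = 1 + Σ r² − n/N` over the n other SNPs
within ±500 kb (window 1 Mbp), with N the reference-panel sample size. Two
reading choices are ours: the window sum *excludes* the target (the leading
1 is the self term, so an isolated SNP scores exactly 1 — the equation's
structure supports this but does not force it), and a SNP exactly at the
window edge is included. r² is the squared Pearson correlation of dosage
vectors (composite LD; no phasing). Stratification splits each score into an
mQTL component and a rest-of-genome component, each with its own membership
indicator and its own `− n_c/N` correction — the natural extension of the
unstratified form — so the components add to the total exactly (asserted at
1e-9 in the class validity). The pairwise structure is kept as a sparse
matrix so the stratification can be recomputed for any SNP set in two
sparse matrix-vector products (`stratifyLdScores()`), which is what makes
resampling nulls affordable.

The partition regresses GWAS χ² on the two score columns with a free
intercept, by *unweighted* OLS — no heteroskedasticity weights and no
block-jackknife: inference for the quantity of interest comes from the
resampling null, not from regression SEs (which are reported but
advisory). Slopes convert to heritability as `h²_c = β_c M_c / N`, with N
= cases + controls for case-control traits. Negative component estimates
are reported as-is with a warning, never truncated; an optional region mask
(e.g. the HLA block) drops SNPs before fitting.

## The matched resampling null

The mQTL SNP set is first greedily LD-pruned in significance order so no
retained pair within 1 Mbp exceeds r² = 0.8 (distal pairs are treated as
unlinked); this makes its LD structure comparable to a random MAF-matched
draw. Null sets replicate the target's composition exactly per stratum:
MAF bins of width 0.05 (`[0, 0.05), …, [0.45, 0.5]`, the last bin closed),
optionally jointly with annotation category — joint matching is the
stricter reading of "matched by frequency and annotation" and is the
default; marginal matching is available via the flag. Sampling is without
replacement within a set, independent across sets, deterministic under the
seed.

The test statistic is the mQTL heritability share, recomputed per set by
restratifying the LD scores and refitting the partition. For resampling we
use the signed ratio `h²_mQTL / (h²_mQTL + h²_G)`: under a pure-noise null
both components can be estimated negative, and the flagged "undefined"
proportion would break exchangeability of ranks; the signed ratio is
defined for every resample and the empirical p depends only on ranks.
Reported alongside are the one-sided upper-tail normal approximation
`z = (obs − mean_null)/sd_null` and the empirical `(r + 1)/(B + 1)`. The
null *SD* (not the SD of the mean) is the scale of that z — the
interpretation consistent with reference tables of this test, where an
observed 0.330 against 0.083 (0.040) gives z ≈ 6.2 and p in the 1e-10
decade. B defaults to 199 (the reference analyses do not state one);
below B = 20 the normal approximation is suppressed.

## Annotation, overlap, and genome distribution

Positional annotation is ANNOVAR-style with a fixed precedence: Exonic >
UTR5 > UTR3 > ncRNA-exonic > Intronic > ncRNA-intronic > Upstream >
Downstream > Intergenic. Upstream/downstream are measured from transcript
bounds, strand-aware (Upstream is the 5′ side), default distance 2 Mbp to
align with the cis window — tests also exercise the conventional 1 kb to
show the sensitivity, without asserting reference values against it.
Category enrichment is a per-category 2×2 Pearson χ² (Fisher's exact test
when an expected count drops below 5, recorded per row), Bonferroni across
categories.

Probe-SNP overlap flags are pure interval geometry, independent of scan
results: a variant inside the probe's binding interval, or inside the 2-bp
CpG dinucleotide. The binding interval defaults to the 50 bp ending at the
CpG — array-typical, configurable, and explicitly input metadata since no
universal definition exists. The accounting compares the flagged fraction
among cis-mQTL probes with the background fraction among mQTL-free probes;
the difference bounds the share of cis signal attributable to
genotype-specific measurement error. Flagged mQTL are reported, never
removed downstream.

Subtelomeric analysis uses the exact fraction `2·margin·n_chroms / Σ
lengths` (both ends of every autosome; 1 Mbp margins on the bundled GRCh37
autosomes give 1.53%) and a one-sided exact binomial test. Sex chromosomes
are excluded throughout. Per-chromosome counts are compared against
expectations proportional to gene counts (length-proportional available),
with Pearson residuals and a χ² goodness of fit.

Effect-size comparison between mQTL and GWAS takes absolute values *before*
scaling by `√(2f(1−f))` (absolute values because methylation direction is
not comparable across loci; the order matters only for the sign). A caveat
the tests document: scaling both vectors by the same per-SNP factor induces
a small positive correlation even for independent effects (~0.06 at
n = 1000), so "no correlation" findings should be read against that
baseline, not against zero. Strand-ambiguous (A/T, C/G) SNPs are dropped
and counted.

## What the synthetic data emulates — and what it does not

`simConfig()` defaults describe the study the package targets: two cohorts
of unrelated individuals (614 and 1366 samples), post-QC common SNPs (MAF
0.05–0.5), ~10% of SNPs directly genotyped (the rest standing in for
imputed SNPs), logit-scale methylation noise of variance 1 with covariate
effect SDs of 0.05–0.3, and local LD on a 50 kb scale. The toy genome is
three autosomes totalling 160 Mbp with one gene per 150 kb — sized so that
a full two-cohort run takes seconds, not hours; the test suite uses smaller
panels still (stated per test: cohorts of 50–1000, panels of 40–1500 SNPs,
the partition recovery at 20,000 synthetic score rows).

Genotypes come from a mosaic-of-founder-haplotypes model: 32 founders whose
alt-allele carriers form a contiguous arc on a founder ring, the arc offset
re-randomized between adjacent SNPs with probability `1 − exp(−d/λ)`; sample
haplotypes then mosaic across founders at the same rate. This yields blocky
r² decaying on the λ scale with exact founder allele frequencies — enough
structure for LD-score, pruning and two-stage-scan logic to be exercised
honestly. It does *not* reproduce human allele-frequency spectra,
recombination hotspots, or population structure. Methylation is inverse
logit of baseline + genetics + covariates + Gaussian noise: planted variance
fractions are calibrated against the *realized* non-genetic variance of each
probe, so recovery tests measure estimation error, not simulation error.
β-value artefacts of real arrays (probe chemistry differences, detection
failure patterns, cell-composition variation beyond supplied covariates)
are not modelled — passing tests show the pipeline's statistics behave as
designed, not that real-data preprocessing is solved. GWAS statistics are
simulated at the χ² level (scaled central χ²₁ matching the stratified
expectation), not from an individual-level liability model: sufficient for
testing the regression and the null machinery, silent on fine-grained
polygenicity.

## Numerical conventions and degenerate inputs

Coordinates are 1-based inclusive everywhere (VCF/GFF3 convention); BED
input is converted on read. Hardy-Weinberg QC is a 1-df Pearson χ² on
rounded hard calls (the threshold convention names no statistic; Pearson is
the simplest defensible choice), with monomorphic SNPs untestable and
retained by MAF filtering instead. Probes with no SNP in their window,
SNPs missing from the replication panel, monomorphic dosages, empty record
lists, zero-IQR distributions and zero-denominator proportions are all
signalled (NA plus a count or warning) rather than silently dropped —
every filter logs in/out counts retrievable from `metadata()`/attributes.
Determinism: every generator takes an explicit seed and restores the
caller's RNG state; fixed seed means byte-identical output.

## Known limitations

* No family-based association (the major difference from mixed-model
  pipelines); unrelated-sample OLS is the contract.
* No winner's-curse correction of discovery effect sizes, and no
  conditional/secondary-signal mapping.
* LD pruning and LD scores use composite (dosage) LD from the supplied
  reference, not phased haplotypes.
* The null-set machinery assumes every target stratum has enough pool
  candidates; thin strata are an error by design, not a silent fallback.
* IDAT parsing, background correction, imputation and phasing are out of
  scope: inputs are post-QC dosages and background-corrected β-values.
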