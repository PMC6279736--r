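#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   findOverlaps strand
#' @importFrom GenomeInfoDb seqlevels seqnames
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   rowData colData assay<- rowData<- colData<-
NULL

#' Simulation configuration
#'
#' Holds every parameter of the synthetic two-cohort study: cohort sizes,
#' SNP/probe panel sizes, a toy autosome-only genome, the local-LD scale of
#' the mosaic-haplotype genotype model, the planted cis/trans mQTL
#' architecture, covariate structure of the methylation model, and the seed.
#' Use [simConfig()] to construct one; defaults mirror the two-cohort
#' whole-blood study design (n = 614 and n = 1366).
#'
#' @slot nIndividuals Named integer vector, samples per cohort.
#' @slot nSnps,nProbes Panel sizes.
#' @slot chromLengths Named numeric, chromosome lengths in bp (autosomes).
#' @slot ldDecayBp Distance scale (bp) over which haplotype-mosaic LD decays.
#' @slot mafRange Length-2 numeric in (0, 0.5]: range of simulated MAFs.
#' @slot cisEffects,transEffects data.frames with columns `probe`, `snp`
#'   (panel indices) and `varFrac` (fraction of methylation variance
#'   explained by the SNP).
#' @slot covariateEffects Named numeric: per-covariate effect SDs on the
#'   logit-methylation scale (chip, position, sex, age, age2, sex_age,
#'   sex_age2).
#' @slot noiseVar Residual variance on the logit scale.
#' @slot genotypedFraction Fraction of SNPs flagged as directly genotyped
#'   (the remainder emulate imputed SNPs).
#' @slot nGenes Number of genes in the toy gene model.
#' @slot seed Integer seed; fixed seed gives byte-identical output.
#' @export
setClass("SimConfig", representation(
  nIndividuals = "integer",
  nSnps = "integer",
  nProbes = "integer",
  chromLengths = "numeric",
  ldDecayBp = "numeric",
  mafRange = "numeric",
  cisEffects = "data.frame",
  transEffects = "data.frame",
  covariateEffects = "numeric",
  noiseVar = "numeric",
  genotypedFraction = "numeric",
  nGenes = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (any(object@nIndividuals < 2)) msg <- c(msg, "need >= 2 individuals per cohort")
  if (object@nSnps < 1 || object@nProbes < 0) msg <- c(msg, "invalid panel sizes")
  if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0))
    msg <- c(msg, "chromLengths must be named and positive")
  if (length(object@mafRange) != 2 || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must lie within (0, 0.5]")
  for (eff in list(object@cisEffects, object@transEffects)) {
    if (nrow(eff)) {
      if (!all(c("probe", "snp", "varFrac") %in% names(eff)))
        msg <- c(msg, "effect grids need columns probe, snp, varFrac")
      else if (any(eff$varFrac < 0 | eff$varFrac >= 1))
        msg <- c(msg, "variance fractions must lie in [0, 1)")
    }
  }
  both <- rbind(object@cisEffects, object@transEffects)
  if (nrow(both)) {
    tot <- tapply(both$varFrac, both$probe, sum)
    if (any(tot >= 1)) msg <- c(msg, "per-probe planted variance must be < 1")
  }
  if (object@noiseVar <= 0) msg <- c(msg, "noiseVar must be positive")
  if (object@genotypedFraction <= 0 || object@genotypedFraction > 1)
    msg <- c(msg, "genotypedFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Genotype matrix with SNP metadata
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] holding an additive
#' dosage assay (SNPs in rows, samples in columns, values in \[0, 2\] or NA)
#' with per-SNP metadata in `rowRanges`: alleles, minor allele frequency and
#' a genotyped-vs-imputed flag. Construct with [GenotypeMatrix()] or
#' [readVcfDosage()].
#'
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- assay(object, "dosage")
  rng <- suppressWarnings(range(d, na.rm = TRUE))
  if (nrow(object) && ncol(object) && is.finite(rng[1]) &&
      (rng[1] < 0 || rng[2] > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  need <- c("ref", "alt", "maf", "genotyped")
  if (!all(need %in% names(rowData(object))))
    msg <- c(msg, paste("rowData needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate SNP ids")
  if (length(msg)) msg else TRUE
})

#' Methylation beta-value matrix with probe metadata
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose `beta` assay
#' holds methylation beta-values (probes in rows, samples in columns, values
#' in \[0, 1\] or NA). `rowRanges` is the probe binding-region interval;
#' `rowData` carries the CpG position (`cpg_pos`, 1-based position of the
#' CpG cytosine), a CpG-site flag (`is_cpg`), a multi-mapping flag and the
#' outlier-handling flag `restrict_maf`. A `normalized` assay is added by
#' [normalizeMethylation()].
#'
#' @export
setClass("MethylationMatrix", contains = "RangedSummarizedExperiment")

setValidity("MethylationMatrix", function(object) {
  msg <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    return("assay 'beta' is required")
  b <- assay(object, "beta")
  rng <- suppressWarnings(range(b, na.rm = TRUE))
  if (nrow(object) && ncol(object) && is.finite(rng[1]) &&
      (rng[1] < 0 || rng[2] > 1))
    msg <- c(msg, "beta values must lie in [0, 1]")
  if (!all(c("cpg_pos", "is_cpg") %in% names(rowData(object))))
    msg <- c(msg, "rowData needs columns cpg_pos, is_cpg")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate probe ids")
  ok <- start(object) <= rowData(object)$cpg_pos + 1L &
    end(object) + 1L >= rowData(object)$cpg_pos
  if (nrow(object) && !all(ok, na.rm = TRUE))
    msg <- c(msg, "probe interval must contain or abut its CpG position")
  if (length(msg)) msg else TRUE
})

#' Gene model
#'
#' Transcript structures for a (toy or real) genome: a transcript-level
#' `GRanges` with coding flags and CDS bounds, plus an exon `GRangesList`
#' parallel to it. Built by [simulateGeneModel()], [readGeneModelGff3()] or
#' [readGeneModelBed()].
#'
#' @slot transcripts GRanges with mcols `tx_id`, `gene_id`, `coding`,
#'   `cds_start`, `cds_end` (NA for non-coding).
#' @slot exons GRangesList named by `tx_id`; exons sorted, non-overlapping.
#' @export
setClass("GeneModel", representation(
  transcripts = "GRanges",
  exons = "GRangesList"
))

setValidity("GeneModel", function(object) {
  tx <- object@transcripts
  ex <- object@exons
  msg <- character()
  if (length(tx) != length(ex)) return("transcripts and exons differ in length")
  if (length(tx) == 0) return(TRUE)
  if (!identical(as.character(mcols(tx)$tx_id), names(ex)))
    msg <- c(msg, "exons must be named by tx_id in transcript order")
  exs <- unlist(ex, use.names = FALSE)
  txrep <- rep(seq_along(tx), lengths(ex))
  if (any(start(exs) < start(tx)[txrep]) || any(end(exs) > end(tx)[txrep]))
    msg <- c(msg, "exons must lie within transcript bounds")
  coding <- mcols(tx)$coding
  cs <- mcols(tx)$cds_start; ce <- mcols(tx)$cds_end
  bad <- coding & (is.na(cs) | is.na(ce) | cs < start(tx) | ce > end(tx) | cs > ce)
  if (any(bad)) msg <- c(msg, "coding transcripts need CDS within tx bounds")
  if (length(msg)) msg else TRUE
})

#' Stratified LD score table
#'
#' Per-SNP LD scores `L = 1 + sum(r^2) - n/N` over a window centred on each
#' SNP, stratified into an mQTL component and a rest-of-genome component
#' that add exactly to the total. The pairwise r-squared structure is
#' retained so the stratification can be recomputed cheaply for any other
#' SNP set (used by the resampling null). Built by [ldScores()]; restratify
#' with [stratifyLdScores()].
#'
#' @slot table data.frame: snp_id, chrom, pos, maf, L_total, L_mqtl, L_G,
#'   n_window.
#' @slot r2 Sparse symmetric matrix of within-window pairwise r-squared
#'   values (diagonal zero).
#' @slot adj Sparse pattern of window adjacency (1 where a pair is within
#'   the window).
#' @slot nRef Sample size of the reference genotypes used for r-squared.
#' @slot windowBp Full window width in bp (SNPs within half this distance
#'   are neighbours).
#' @slot mqtlIds Character vector of SNP ids in the mQTL component.
#' @export
setClass("LDScoreTable", representation(
  table = "data.frame",
  r2 = "ANY",
  adj = "ANY",
  nRef = "integer",
  windowBp = "numeric",
  mqtlIds = "character"
))

setValidity("LDScoreTable", function(object) {
  tb <- object@table
  need <- c("snp_id", "chrom", "pos", "maf", "L_total", "L_mqtl", "L_G", "n_window")
  if (!all(need %in% names(tb)))
    return(paste("table needs columns:", paste(need, collapse = ", ")))
  if (max(abs(tb$L_mqtl + tb$L_G - tb$L_total)) > 1e-9)
    return("stratified components must add to the total LD score")
  TRUE
})

#' Heritability partition fit
#'
#' Result of regressing GWAS chi-square statistics on stratified LD scores
#' and converting the slopes to heritability components: `h2_c =
#' slope_c * M_c / N`. See [fitPartition()].
#'
#' @slot alpha Regression intercept.
#' @slot beta Named slopes (mQTL, G).
#' @slot se Named OLS standard errors of the slopes.
#' @slot M Named SNP counts per component.
#' @slot nGwas GWAS sample size (cases + controls for case-control traits).
#' @slot h2 Named heritability components.
#' @slot proportion Share of explained heritability attributable to mQTL.
#' @slot nSnpsUsed Number of SNPs entering the regression.
#' @export
setClass("PartitionFit", representation(
  alpha = "numeric",
  beta = "numeric",
  se = "numeric",
  M = "numeric",
  nGwas = "numeric",
  h2 = "numeric",
  proportion = "numeric",
  nSnpsUsed = "integer"
))

#' Resampling-null enrichment test result
#'
#' Observed statistic (the mQTL heritability proportion, or any user
#' statistic) against its distribution over matched null SNP sets. The
#' null SD plays the role of the "S.E." in classic tables of this test;
#' the one-sided normal p is supplemented by the empirical
#' `(r + 1) / (B + 1)` p-value. See [enrichmentTest()].
#'
#' @slot observed Observed statistic.
#' @slot nullValues Statistic on each of the B null sets.
#' @slot nullMean,nullSd Moments of the null distribution.
#' @slot zScore Normal-approximation z.
#' @slot pNormal One-sided upper-tail normal p (NA when B < 20).
#' @slot pEmpirical Empirical p, (r + 1) / (B + 1).
#' @slot B Number of null sets.
#' @export
setClass("NullTestResult", representation(
  observed = "numeric",
  nullValues = "numeric",
  nullMean = "numeric",
  nullSd = "numeric",
  zScore = "numeric",
  pNormal = "numeric",
  pEmpirical = "numeric",
  B = "integer"
))
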