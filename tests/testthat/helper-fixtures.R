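## Shared fixtures, built lazily once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## Small two-cohort study with planted cis and trans effects; the trans SNP
## is chosen among the genotyped panel SNPs so stage 1 can see it.
small_study <- function() fixture("small_study", function() {
  base <- simConfig(nIndividuals = c(A = 250, B = 250), nSnps = 300,
                    nProbes = 15, chromLengths = c(`1` = 1.5e7, `2` = 1.5e7),
                    seed = 101)
  g0 <- simulateGenotypes(base, "A")
  geno_snps <- which(snpInfo(g0)$genotyped)
  trans_snp <- geno_snps[length(geno_snps)]          # on chrom 2
  cfg <- simConfig(nIndividuals = c(A = 250, B = 250), nSnps = 300,
                   nProbes = 15, chromLengths = c(`1` = 1.5e7, `2` = 1.5e7),
                   cisEffects = data.frame(probe = 1:2, snp = c(20, 120),
                                           varFrac = c(0.45, 0.35)),
                   transEffects = data.frame(probe = 3, snp = trans_snp,
                                             varFrac = 0.35),
                   seed = 101)
  gA <- simulateGenotypes(cfg, "A")
  gB <- simulateGenotypes(cfg, "B")
  sA <- simulateMethylation(gA, cfg)
  sB <- simulateMethylation(gB, cfg)
  list(cfg = cfg, gA = gA, gB = gB,
       mA = normalizeMethylation(sA$meth), mB = normalizeMethylation(sB$meth),
       truthA = sA$truth, truthB = sB$truth)
})

## Construct a MethylationMatrix directly from a logit-scale phenotype
## matrix (probes x samples).
meth_from_logit <- function(lgt, chrom = "1",
                            cpg_pos = seq(1e5, by = 1e5,
                                          length.out = nrow(lgt))) {
  MethylationMatrix(plogis(lgt),
                    data.frame(probe_id = sprintf("p%03d", seq_len(nrow(lgt))),
                               chrom = chrom, cpg_pos = cpg_pos),
                    sampleIds = sprintf("s%03d", seq_len(ncol(lgt))))
}

## Construct a GenotypeMatrix from a dosage matrix (SNPs x samples).
geno_from_dosage <- function(d, chrom = "1",
                             pos = seq(1e5, by = 1e5, length.out = nrow(d)),
                             genotyped = TRUE) {
  GenotypeMatrix(d,
                 data.frame(snp_id = sprintf("rs%03d", seq_len(nrow(d))),
                            chrom = chrom, pos = pos, ref = "A", alt = "G",
                            genotyped = genotyped),
                 sampleIds = sprintf("s%03d", seq_len(ncol(d))))
}

## Two-transcript fixture used by annotation precedence tests:
## gene A (coding, + strand) with a UTR5 that overlaps an intron of
## gene B (coding, + strand).
two_tx_model <- function() {
  tx <- GenomicRanges::GRanges(
    "1", IRanges::IRanges(c(1000, 500), c(3000, 6000)), strand = "+",
    tx_id = c("txA", "txB"), gene_id = c("gA", "gB"),
    coding = c(TRUE, TRUE), cds_start = c(1500L, 600L),
    cds_end = c(2800L, 5800L))
  names(tx) <- tx$tx_id
  ex <- GenomicRanges::GRangesList(
    txA = GenomicRanges::GRanges("1", IRanges::IRanges(1000, 3000),
                                 strand = "+"),
    txB = GenomicRanges::GRanges("1", IRanges::IRanges(c(500, 5000),
                                                       c(800, 6000)),
                                 strand = "+"))
  GeneModel(tx, ex)
}
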