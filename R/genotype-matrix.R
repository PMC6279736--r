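#' Construct a GenotypeMatrix
#'
#' @param dosage Numeric matrix, SNPs x samples, additive alt-allele dosages
#'   in \[0, 2\] (hard calls 0/1/2 or fractional imputed dosages); NA for
#'   missing genotypes.
#' @param snpInfo data.frame with one row per SNP: `snp_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, and optionally `genotyped` (logical, default
#'   TRUE). MAF is always recomputed from the dosages.
#' @param sampleIds Character vector of sample names; defaults to the dosage
#'   column names.
#' @return A [GenotypeMatrix-class] with SNPs sorted by chromosome and
#'   position.
#' @examples
#' d <- matrix(c(0, 1, 2, 1, 1, 0), nrow = 2, byrow = TRUE)
#' si <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1", pos = c(100, 200),
#'                  ref = "A", alt = "G")
#' g <- GenotypeMatrix(d, si, sampleIds = c("s1", "s2", "s3"))
#' snpInfo(g)$maf
#' @export
GenotypeMatrix <- function(dosage, snpInfo, sampleIds = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  .assert(nrow(dosage) == nrow(snpInfo), "dosage rows (%d) != snpInfo rows (%d)",
          nrow(dosage), nrow(snpInfo))
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  .assert(all(need %in% names(snpInfo)), "snpInfo needs columns: %s",
          paste(need, collapse = ", "))
  if (is.null(sampleIds)) sampleIds <- paste0("sample_", seq_len(ncol(dosage)))
  if (is.null(snpInfo$genotyped)) snpInfo$genotyped <- TRUE
  ## canonical order: chrom (as given levels), then position
  chrom <- as.character(snpInfo$chrom)
  o <- order(match(chrom, unique(chrom)), snpInfo$pos)
  dosage <- dosage[o, , drop = FALSE]
  snpInfo <- snpInfo[o, , drop = FALSE]
  af <- rowMeans(dosage, na.rm = TRUE) / 2
  gr <- GRanges(as.character(snpInfo$chrom),
                IRanges(snpInfo$pos, width = 1L),
                ref = as.character(snpInfo$ref),
                alt = as.character(snpInfo$alt),
                maf = pmin(af, 1 - af),
                genotyped = as.logical(snpInfo$genotyped))
  names(gr) <- as.character(snpInfo$snp_id)
  dimnames(dosage) <- list(names(gr), sampleIds)
  new("GenotypeMatrix", SummarizedExperiment(
    assays = SimpleList(dosage = dosage), rowRanges = gr))
}

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) assay(x, "dosage"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("snpInfo", "GenotypeMatrix", function(x) {
  data.frame(snp_id = rownames(x),
             chrom = as.character(seqnames(x)),
             pos = start(x),
             ref = rowData(x)$ref,
             alt = rowData(x)$alt,
             maf = rowData(x)$maf,
             genotyped = rowData(x)$genotyped,
             row.names = NULL)
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) colnames(x))

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d SNPs x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  chromosomes: %s\n",
              paste(seqlevels(object), collapse = ", ")))
  cat(sprintf("  genotyped SNPs: %d; MAF range: %.3f-%.3f\n",
              sum(rowData(object)$genotyped),
              min(rowData(object)$maf), max(rowData(object)$maf)))
})

#' Genotype quality control
#'
#' Removes SNPs with minor allele frequency below `mafMin` and SNPs whose
#' genotype counts deviate from Hardy-Weinberg equilibrium at `hwePMin`,
#' the standard post-imputation filters. The HWE test is a 1-df Pearson
#' chi-square on (hom-ref, het, hom-alt) counts; fractional dosages are
#' rounded to hard calls for the HWE test only. Idempotent. The counts of
#' SNPs removed per reason are attached as `metadata(x)$qc_counts`.
#'
#' @param geno A [GenotypeMatrix-class].
#' @param mafMin Minimum minor allele frequency (default 0.05).
#' @param hwePMin Minimum HWE p-value (default 1e-6).
#' @return The filtered `GenotypeMatrix`.
#' @export
applyGenotypeQC <- function(geno, mafMin = 0.05, hwePMin = 1e-6) {
  maf <- rowData(geno)$maf
  hwep <- hweChisqP(dosages(geno))
  keep <- maf >= mafMin & (is.na(hwep) | hwep >= hwePMin)
  out <- geno[keep, ]
  counts <- list(n_in = nrow(geno),
                 removed_maf = sum(maf < mafMin),
                 removed_hwe = sum(maf >= mafMin & !is.na(hwep) & hwep < hwePMin),
                 n_out = nrow(out))
  .log_counts("genotype-qc", counts)
  metadata(out)$qc_counts <- counts
  out
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' 1-df Pearson chi-square of observed genotype counts against
#' Hardy-Weinberg expectations, per SNP. Dosages are rounded to hard calls;
#' monomorphic SNPs return NA (the test is undefined).
#'
#' @param dosage Numeric matrix (SNPs x samples) or vector of dosages in
#'   \[0, 2\].
#' @return Numeric vector of p-values, one per SNP.
#' @examples
#' hweChisqP(c(rep(0, 25), rep(1, 50), rep(2, 25)))  # exact HWE: p = 1
#' @export
hweChisqP <- function(dosage) {
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1)
  g <- round(dosage)
  n0 <- rowSums(g == 0, na.rm = TRUE)
  n1 <- rowSums(g == 1, na.rm = TRUE)
  n2 <- rowSums(g == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2; e1 <- 2 * n * p * q; e2 <- n * p^2
  chi2 <- ifelse(p == 0 | q == 0, NA_real_,
                 (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}
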