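#' Read genotypes from a VCF
#'
#' Parses GT (or DS, when present) fields into additive alt-allele dosages.
#' Missing genotypes (`./.`) become NA; MAF is computed from the observed
#' dosages. SNPs are flagged genotyped unless an `IMPUTED` INFO flag is
#' present.
#'
#' @param path VCF file (plain or bgzipped).
#' @return A [GenotypeMatrix-class].
#' @export
readVcfDosage <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  gmat <- VariantAnnotation::geno(v)
  if ("DS" %in% names(gmat)) {
    dosage <- gmat$DS
    storage.mode(dosage) <- "numeric"
  } else {
    .assert("GT" %in% names(gmat), "VCF has neither GT nor DS")
    gt <- gmat$GT
    dosage <- matrix(.gt_to_dosage(gt), nrow(gt), ncol(gt),
                     dimnames = dimnames(gt))
  }
  alt <- vapply(rr$ALT, function(a) as.character(a[1]), character(1))
  imputed <- if ("IMPUTED" %in% names(VariantAnnotation::info(v)))
    VariantAnnotation::info(v)$IMPUTED else rep(FALSE, length(rr))
  GenotypeMatrix(dosage,
                 data.frame(snp_id = names(rr),
                            chrom = as.character(seqnames(rr)),
                            pos = start(rr),
                            ref = as.character(rr$REF), alt = alt,
                            genotyped = !imputed),
                 sampleIds = colnames(dosage))
}

.gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  d <- (a1 == "1") + (a2 == "1")
  d[a1 == "." | a2 == "."] <- NA_real_
  d
}

#' Write a GenotypeMatrix as VCF
#'
#' Hard-call dosages are written as GT fields (fractional dosages are
#' rounded for GT and preserved exactly in a DS field); imputed SNPs carry
#' an `IMPUTED` INFO flag.
#'
#' @param geno A [GenotypeMatrix-class].
#' @param path Output path ('.vcf').
#' @return `path`, invisibly.
#' @export
writeVcfDosage <- function(geno, path) {
  d <- dosages(geno)
  si <- snpInfo(geno)
  hard <- round(d)
  fractional <- any(abs(d - hard) > 1e-9, na.rm = TRUE)
  gt <- matrix(c("0/0", "0/1", "1/1")[hard + 1], nrow(d), ncol(d))
  gt[is.na(hard)] <- "./."
  dimnames(gt) <- dimnames(d)
  gr <- GRanges(si$chrom, IRanges(si$pos, width = 1L))
  names(gr) <- si$snp_id
  hdr <- VariantAnnotation::VCFHeader(samples = colnames(d))
  gdf <- DataFrame(Number = "1", Type = "String", Description = "Genotype",
                   row.names = "GT")
  genolist <- SimpleList(GT = gt)
  if (fractional) {
    gdf <- rbind(gdf, DataFrame(Number = "1", Type = "Float",
                                Description = "Dosage", row.names = "DS"))
    genolist$DS <- d
  }
  VariantAnnotation::geno(hdr) <- gdf
  VariantAnnotation::info(hdr) <- DataFrame(
    Number = "0", Type = "Flag", Description = "Imputed SNP",
    row.names = "IMPUTED")
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
  v <- VariantAnnotation::VCF(
    rowRanges = gr,
    colData = DataFrame(Samples = seq_len(ncol(d)), row.names = colnames(d)),
    fixed = DataFrame(REF = Biostrings::DNAStringSet(si$ref),
                      ALT = Biostrings::DNAStringSetList(as.list(si$alt)),
                      QUAL = rep(NA_real_, nrow(d)),
                      FILTER = rep("PASS", nrow(d))),
    info = DataFrame(IMPUTED = !si$genotyped),
    geno = genolist)
  metadata(v)$header <- hdr
  VariantAnnotation::writeVcf(v, path)
  invisible(path)
}

#' Read / write a methylation matrix as TSV
#'
#' Layout: columns `probe_id`, `chrom`, `cpg_pos`, `probe_start`,
#' `probe_end`, then one beta column per sample.
#'
#' @param meth A [MethylationMatrix-class].
#' @param path File path.
#' @return `readMethylationTsv` returns a [MethylationMatrix-class];
#'   `writeMethylationTsv` returns `path` invisibly.
#' @export
writeMethylationTsv <- function(meth, path) {
  pi <- probeInfo(meth)
  dt <- data.table::data.table(
    probe_id = pi$probe_id, chrom = pi$chrom, cpg_pos = pi$cpg_pos,
    probe_start = pi$probe_start, probe_end = pi$probe_end)
  dt <- cbind(dt, data.table::as.data.table(betas(meth)))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname writeMethylationTsv
#' @export
readMethylationTsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  meta_cols <- c("probe_id", "chrom", "cpg_pos", "probe_start", "probe_end")
  .assert(all(c("probe_id", "chrom", "cpg_pos") %in% names(dt)),
          "methylation TSV needs probe_id, chrom, cpg_pos columns")
  meta_cols <- intersect(meta_cols, names(dt))
  b <- as.matrix(dt[, setdiff(names(dt), meta_cols), with = FALSE])
  MethylationMatrix(b, as.data.frame(dt[, meta_cols, with = FALSE]),
                    sampleIds = colnames(b))
}

#' Read GWAS summary statistics
#'
#' Accepts TSVs with at least a SNP id column plus effect/SE, odds-ratio/SE
#' or p-value columns. Odds ratios are converted to the log scale; the
#' chi-square statistic is filled from `(effect / se)^2` when both are
#' present, otherwise from the inverse chi-square CDF of the p-value.
#'
#' @param path TSV file.
#' @param effectColumn Name of the effect column; `"OR"` (or a column named
#'   `or`/`OR`) triggers log conversion. Default auto-detects `effect`,
#'   `beta`, `b`, `OR`, `or`, `log_odds`.
#' @return data.frame: snp_id, a1, a2, freq, effect, se, p, chi2, n.
#' @export
readSumstats <- function(path, effectColumn = NULL) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t"))
  nm <- names(dt)
  pick <- function(cands) { i <- match(tolower(cands), tolower(nm))
                            nm[i[!is.na(i)]][1] }
  idcol <- pick(c("snp_id", "snp", "rsid", "id", "markername"))
  .assert(!is.na(idcol) && length(idcol) == 1, "missing required column: snp id")
  if (is.null(effectColumn))
    effectColumn <- pick(c("effect", "beta", "b", "log_odds", "or"))
  is_or <- !is.na(effectColumn) && tolower(effectColumn) == "or"
  secol <- pick(c("se", "stderr", "standard_error"))
  pcol <- pick(c("p", "pval", "p_value", "pvalue"))
  ncol_ <- pick(c("n", "samplesize", "n_total"))
  out <- data.frame(snp_id = as.character(dt[[idcol]]))
  a1c <- pick(c("a1", "allele1", "effect_allele"))
  a2c <- pick(c("a2", "allele2", "other_allele"))
  out$a1 <- if (!is.na(a1c)) toupper(dt[[a1c]]) else NA_character_
  out$a2 <- if (!is.na(a2c)) toupper(dt[[a2c]]) else NA_character_
  fc <- pick(c("freq", "maf", "eaf", "frq"))
  out$freq <- if (!is.na(fc)) dt[[fc]] else NA_real_
  out$effect <- if (!is.na(effectColumn)) {
    if (is_or) log(dt[[effectColumn]]) else dt[[effectColumn]]
  } else NA_real_
  out$se <- if (!is.na(secol)) dt[[secol]] else NA_real_
  out$p <- if (!is.na(pcol)) dt[[pcol]] else NA_real_
  out$chi2 <- ifelse(!is.na(out$effect) & !is.na(out$se),
                     (out$effect / out$se)^2,
                     stats::qchisq(out$p, df = 1, lower.tail = FALSE))
  .assert(!all(is.na(out$chi2)),
          "missing required column: need effect+se or p to form chi-square")
  out$p[is.na(out$p)] <- stats::pchisq(out$chi2[is.na(out$p)], 1,
                                       lower.tail = FALSE)
  out$n <- if (!is.na(ncol_)) dt[[ncol_]] else NA_real_
  out
}

#' @rdname readSumstats
#' @param sumstats Summary-statistics data.frame.
#' @export
writeSumstats <- function(sumstats, path) {
  data.table::fwrite(data.table::as.data.table(sumstats), path, sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(path)
}

#' Write an mQTL record table
#'
#' Fixed column order compatible with a supplementary-table export:
#' probe_id, probe_chrom, cpg_pos, snp_id, snp_chrom, snp_pos, a1, a2, maf,
#' beta, se, p, r2, class, rep_beta, rep_p, same_dir.
#'
#' @param records mQTL record data.frame (from [cisScan()] /
#'   [replicateMqtl()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeMqtlTable <- function(records, path) {
  cols <- c("probe_id", "probe_chrom", "cpg_pos", "snp_id", "snp_chrom",
            "snp_pos", "a1", "a2", "maf", "beta", "se", "p", "r2", "class",
            "rep_beta", "rep_p", "same_dir")
  for (cc in setdiff(cols, names(records))) records[[cc]] <- NA
  data.table::fwrite(data.table::as.data.table(records[, cols]), path,
                     sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
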