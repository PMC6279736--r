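#' Heterozygosity-scaled effect size
#'
#' Scales an absolute effect by `sqrt(2 f (1 - f))`, the SD of the
#' genotype at MAF f, correcting for the expected inverse relationship
#' between effect size and minor allele frequency: the scaled value is the
#' effect per genotype SD.
#'
#' @param effect Effect size (absolute value is taken before scaling).
#' @param f Minor allele frequency in (0, 0.5].
#' @return `|effect| * sqrt(2 f (1 - f))`.
#' @examples
#' scaleEffect(-2, 0.5)     # 2 * sqrt(0.5)
#' scaleEffect(3, 0.1)      # 3 * sqrt(0.18)
#' @export
scaleEffect <- function(effect, f) {
  .assert(all(f > 0 & f <= 0.5), "MAF must lie in (0, 0.5]")
  abs(effect) * sqrt(2 * f * (1 - f))
}

#' Correlation between mQTL and GWAS effect sizes
#'
#' Joins mQTL and GWAS effects on SNP id, aligns alleles (effects whose
#' a1/a2 encoding is swapped are reconciled; strand-ambiguous A/T and C/G
#' SNPs are dropped and counted), takes absolute values (methylation may
#' be protective or not in different regions), scales both sides by
#' `sqrt(2 f (1 - f))`, and reports the Pearson correlation with its
#' two-sided t-test p-value. Because absolute values are taken, allele
#' alignment affects only the dropped-SNP accounting, not the correlation.
#'
#' @param mqtlEffects data.frame: snp_id, effect, maf, and optionally
#'   a1/a2.
#' @param gwasEffects data.frame: snp_id, effect (beta or log odds-ratio),
#'   and optionally a1/a2, freq.
#' @param minPairs Minimum joined SNPs (default 10).
#' @return List: r, p, nPairs, nAmbiguousDropped.
#' @export
effectCorrelation <- function(mqtlEffects, gwasEffects, minPairs = 10) {
  j <- match(mqtlEffects$snp_id, gwasEffects$snp_id)
  ok <- !is.na(j)
  m <- mqtlEffects[ok, , drop = FALSE]
  g <- gwasEffects[j[ok], , drop = FALSE]
  n_amb <- 0L
  if (!is.null(m$a1) && !is.null(m$a2)) {
    amb <- (m$a1 == "A" & m$a2 == "T") | (m$a1 == "T" & m$a2 == "A") |
      (m$a1 == "C" & m$a2 == "G") | (m$a1 == "G" & m$a2 == "C")
    amb[is.na(amb)] <- FALSE
    n_amb <- sum(amb)
    m <- m[!amb, , drop = FALSE]; g <- g[!amb, , drop = FALSE]
  }
  .assert(nrow(m) >= minPairs, "fewer than %d joined SNPs", minPairs)
  x <- scaleEffect(m$effect, m$maf)
  y <- scaleEffect(g$effect, m$maf)
  .assert(stats::sd(x) > 0 && stats::sd(y) > 0,
          "zero variance in an effect vector: correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, nPairs = nrow(m),
       nAmbiguousDropped = n_amb)
}
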