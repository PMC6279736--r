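#' Partition trait heritability into mQTL and rest-of-genome components
#'
#' Ordinary least squares of per-SNP GWAS chi-square statistics on the two
#' stratified LD score columns (with a free intercept):
#' `chi2_j = alpha + b_mQTL * L_j,mQTL + b_G * L_j,G`. Each slope is
#' converted to a heritability component as `h2_c = b_c * M_c / N`, where
#' `M_c` is the SNP count of the component and N the GWAS sample size
#' (cases + controls for case-control traits). The regression is
#' unweighted; inference for the mQTL proportion comes from the matched
#' resampling null ([enrichmentTest()]), not from the OLS standard errors
#' (which are nevertheless reported).
#'
#' @param sumstats Summary-statistics data.frame (needs `snp_id` and
#'   `chi2`; see [readSumstats()]).
#' @param ldscores An [LDScoreTable-class].
#' @param nGwas GWAS sample size; defaults to the median of the `n` column.
#' @param excludeRegion Optional region mask `"chrom:start-end"` (e.g. the
#'   HLA region `"6:25000000-35000000"`) removed from the regression.
#' @return A [PartitionFit-class].
#' @export
fitPartition <- function(sumstats, ldscores, nGwas = NULL,
                         excludeRegion = NULL) {
  tb <- ldTable(ldscores)
  j <- match(tb$snp_id, sumstats$snp_id)
  keep <- !is.na(j)
  tb <- tb[keep, ]; j <- j[keep]
  chi2 <- sumstats$chi2[j]
  if (!is.null(excludeRegion)) {
    mask <- .parse_region(excludeRegion)
    drop <- tb$chrom == mask$chrom & tb$pos >= mask$start & tb$pos <= mask$end
    tb <- tb[!drop, ]; chi2 <- chi2[!drop]
  }
  .assert(nrow(tb) >= 100, "need at least 100 SNPs to fit the partition")
  if (is.null(nGwas)) nGwas <- stats::median(sumstats$n[j], na.rm = TRUE)
  X <- cbind(1, mqtl = tb$L_mqtl, G = tb$L_G)
  qrx <- qr(X)
  .assert(qrx$rank == 3L, "collinear LD-score columns: fit aborted")
  fit <- stats::lm.fit(X, chi2)
  coefs <- fit$coefficients
  sigma2 <- sum(fit$residuals^2) / (nrow(tb) - 3)
  vc <- chol2inv(qr.R(qrx)) * sigma2
  se <- sqrt(diag(vc))[2:3]
  M <- c(mQTL = sum(tb$snp_id %in% ldscores@mqtlIds),
         G = sum(!tb$snp_id %in% ldscores@mqtlIds))
  h2 <- c(mQTL = unname(coefs[2]) * M[["mQTL"]] / nGwas,
          G = unname(coefs[3]) * M[["G"]] / nGwas)
  prop <- .h2_proportion(h2)
  new("PartitionFit", alpha = unname(coefs[1]),
      beta = c(mQTL = unname(coefs[2]), G = unname(coefs[3])),
      se = c(mQTL = se[1], G = se[2]),
      M = M, nGwas = as.numeric(nGwas), h2 = h2, proportion = prop,
      nSnpsUsed = nrow(tb))
}

.parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  .assert(length(m) == 4, "region must be 'chrom:start-end'")
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

.h2_proportion <- function(h2) {
  tot <- sum(h2)
  if (all(h2 <= 0)) { warning("both components <= 0: proportion undefined")
                      return(NA_real_) }
  if (any(h2 < 0))
    warning("negative heritability component estimate propagated as-is")
  unname(h2[["mQTL"]] / tot)
}

#' Proportion of explained heritability attributable to mQTL
#'
#' `h2_mQTL / (h2_mQTL + h2_G)`. Negative component estimates are
#' propagated as-is (with a warning); both components non-positive is
#' undefined (NA with a warning).
#'
#' @param fit A [PartitionFit-class].
#' @return Numeric proportion.
#' @export
proportionOfHeritability <- function(fit) .h2_proportion(fit@h2)

#' Heritability from a partition slope
#'
#' The per-component conversion `h2 = slope * M / N`.
#'
#' @param beta LD-score regression slope of the component.
#' @param M Number of SNPs in the component.
#' @param nGwas GWAS sample size.
#' @return Heritability attributable to the component.
#' @examples
#' h2FromSlope(0.002, 1000, 10000)  # 2e-4
#' @export
h2FromSlope <- function(beta, M, nGwas) beta * M / nGwas

setMethod("show", "PartitionFit", function(object) {
  cat(sprintf("PartitionFit on %d SNPs (M_mQTL = %d, M_G = %d, N = %g)\n",
              object@nSnpsUsed, object@M[["mQTL"]], object@M[["G"]],
              object@nGwas))
  cat(sprintf("  alpha = %.4f; slopes: mQTL %.3e (SE %.1e), G %.3e (SE %.1e)\n",
              object@alpha, object@beta[["mQTL"]], object@se[["mQTL"]],
              object@beta[["G"]], object@se[["G"]]))
  cat(sprintf("  h2: mQTL %.4f, G %.4f; mQTL proportion = %.3f\n",
              object@h2[["mQTL"]], object@h2[["G"]], object@proportion))
})
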