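#' Genome fraction covered by subtelomeric regions
#'
#' `(2 * margin * n_chroms) / sum(lengths)`: both ends of every
#' chromosome are counted. With the bundled GRCh37 autosome lengths and a
#' 1 Mbp margin this is 0.0153 (1.53% of the autosomal genome).
#'
#' @param marginBp Subtelomeric margin (default 1 Mbp).
#' @param chromLengths Named chromosome lengths; defaults to
#'   [grch37AutosomeLengths()].
#' @return Fraction in \[0, 1\].
#' @examples
#' subtelomericFraction()                          # 0.0153
#' subtelomericFraction(1e6, c(`1` = 1e7))         # 0.2
#' @export
subtelomericFraction <- function(marginBp = 1e6,
                                 chromLengths = grch37AutosomeLengths()) {
  .assert(all(chromLengths > 0), "chromosome lengths must be positive")
  .assert(marginBp < min(chromLengths) / 2,
          "margin must be smaller than half the shortest chromosome")
  2 * marginBp * length(chromLengths) / sum(chromLengths)
}

#' Subtelomeric enrichment of positions
#'
#' Fraction of positions lying within `marginBp` of either end of their
#' chromosome, with a one-sided exact binomial test against the genome
#' fraction expected under uniform placement.
#'
#' @param chrom,pos Position vectors (chromosomes must appear in
#'   `chromLengths`).
#' @param marginBp Subtelomeric margin (default 1 Mbp).
#' @param chromLengths Named chromosome lengths; defaults to
#'   [grch37AutosomeLengths()].
#' @return List: `observedFraction`, `expectedFraction`, `nSubtelomeric`,
#'   `n`, `p` (one-sided, greater).
#' @export
subtelomericEnrichment <- function(chrom, pos, marginBp = 1e6,
                                   chromLengths = grch37AutosomeLengths()) {
  .assert(length(pos) > 0, "empty position list")
  chrom <- as.character(chrom)
  .assert(all(chrom %in% names(chromLengths)), "positions on unknown chromosomes")
  len <- chromLengths[chrom]
  sub <- pos <= marginBp | pos > len - marginBp
  expected <- subtelomericFraction(marginBp, chromLengths)
  bt <- stats::binom.test(sum(sub), length(sub), p = expected,
                          alternative = "greater")
  list(observedFraction = mean(sub), expectedFraction = expected,
       nSubtelomeric = sum(sub), n = length(sub), p = bt$p.value)
}

#' Per-chromosome distribution of trans mQTL SNPs
#'
#' Observed SNP counts per chromosome against expectations proportional to
#' per-chromosome gene counts (or chromosome length with
#' `expect = "length"`), with Pearson residuals, a chi-square
#' goodness-of-fit test, and the gene-count/SNP-count correlation with and
#' without flagged outlier chromosomes.
#'
#' @param chrom Chromosome of each SNP.
#' @param geneCounts Named per-chromosome gene counts.
#' @param chromLengths Optional named lengths (required for
#'   `expect = "length"`).
#' @param expect `"genes"` (default) or `"length"`.
#' @param outliers Chromosomes excluded from the reported correlation
#'   (e.g. those with visibly inflated counts).
#' @return List: `table` (chrom, observed, expected, pearson_resid),
#'   `chisq_p`, `correlation`, `correlationExclOutliers`.
#' @export
perChromosomeDistribution <- function(chrom, geneCounts,
                                      chromLengths = NULL,
                                      expect = c("genes", "length"),
                                      outliers = character()) {
  expect <- match.arg(expect)
  chroms <- names(geneCounts)
  obs <- table(factor(as.character(chrom), levels = chroms))
  w <- if (expect == "genes") geneCounts else {
    .assert(!is.null(chromLengths), "chromLengths required for expect='length'")
    chromLengths[chroms]
  }
  exp_counts <- sum(obs) * w / sum(w)
  resid <- (as.numeric(obs) - exp_counts) / sqrt(exp_counts)
  chisq <- sum(resid^2)
  p <- stats::pchisq(chisq, df = length(chroms) - 1, lower.tail = FALSE)
  keep <- !chroms %in% outliers
  corr <- stats::cor(as.numeric(obs), as.numeric(geneCounts))
  corr_ex <- if (sum(keep) >= 3)
    stats::cor(as.numeric(obs)[keep], as.numeric(geneCounts)[keep])
  else NA_real_
  list(table = data.frame(chrom = chroms, observed = as.numeric(obs),
                          expected = as.numeric(exp_counts),
                          pearson_resid = resid),
       chisq = chisq, chisq_p = p, correlation = corr,
       correlationExclOutliers = corr_ex)
}
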