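#' Scan configuration
#'
#' Windows and significance thresholds of the two-stage cis/trans mQTL
#' scan. Defaults are the stringent two-cohort design: cis discovery at
#' p < 1e-11 within +/-2 Mbp of the CpG, cis replication at p < 1e-6;
#' trans stage 1 (genotyped SNPs) triggers at p < 1e-7, trans discovery at
#' p < 1e-13, trans replication at p < 1e-5; replication additionally
#' requires the same direction of effect.
#'
#' @param cisWindowBp Cis window half-width in bp (2 Mbp per side).
#' @param cisDiscoveryP,cisReplicationP Cis thresholds.
#' @param transStage1P,transDiscoveryP,transReplicationP Trans thresholds.
#' @param requireSameDirection Require sign agreement at replication.
#' @param mafRestrictThreshold MAF floor used for probes flagged
#'   `restrict_maf`.
#' @return A list of class `ScanConfig`.
#' @export
scanConfig <- function(cisWindowBp = 2e6, cisDiscoveryP = 1e-11,
                       cisReplicationP = 1e-6, transStage1P = 1e-7,
                       transDiscoveryP = 1e-13, transReplicationP = 1e-5,
                       requireSameDirection = TRUE,
                       mafRestrictThreshold = 0.05) {
  ps <- c(cisDiscoveryP, cisReplicationP, transStage1P, transDiscoveryP,
          transReplicationP)
  .assert(all(ps > 0 & ps < 1), "p thresholds must lie in (0, 1)")
  .assert(cisWindowBp > 0, "window must be positive")
  structure(list(cisWindowBp = cisWindowBp, cisDiscoveryP = cisDiscoveryP,
                 cisReplicationP = cisReplicationP,
                 transStage1P = transStage1P,
                 transDiscoveryP = transDiscoveryP,
                 transReplicationP = transReplicationP,
                 requireSameDirection = requireSameDirection,
                 mafRestrictThreshold = mafRestrictThreshold),
            class = "ScanConfig")
}

#' Single SNP-probe association test
#'
#' Simple linear regression of the (normalized) methylation phenotype on
#' the additive dosage: slope, its standard error, the two-sided t-test
#' p-value, and the squared sample correlation (the fraction of phenotype
#' variance explained by the SNP). Pairs with fewer than 10 complete
#' observations or zero dosage variance return NA (the pair is skipped by
#' the scans and counted).
#'
#' @param dosage Numeric dosage vector.
#' @param phenotype Numeric phenotype vector, same length.
#' @return Named numeric vector: effect, se, p, r2, n.
#' @examples
#' set.seed(1)
#' d <- rbinom(50, 2, 0.3)
#' assocTest(d, 2 * d + rnorm(50))
#' @export
assocTest <- function(dosage, phenotype) {
  ok <- !is.na(dosage) & !is.na(phenotype)
  n <- sum(ok)
  if (n < 10) return(c(effect = NA, se = NA, p = NA, r2 = NA, n = n))
  x <- dosage[ok]; y <- phenotype[ok]
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(c(effect = NA, se = NA, p = NA, r2 = NA, n = n))
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  beta <- sxy / sxx
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else NA_real_
  sigma2 <- (syy - beta * sxy) / (n - 2)
  se <- sqrt(pmax(sigma2, 0) / sxx)
  tstat <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  c(effect = beta, se = se, p = p, r2 = r2, n = n)
}

## Vectorized association of one phenotype against many SNPs (rows of D).
## Falls back to the scalar path when dosages contain NA.
.bulk_assoc <- function(D, y) {
  ok <- !is.na(y)
  y <- y[ok]; D <- D[, ok, drop = FALSE]
  if (anyNA(D)) {
    out <- t(apply(D, 1, assocTest, phenotype = y))
    return(data.frame(effect = out[, 1], se = out[, 2], p = out[, 3],
                      r2 = out[, 4]))
  }
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  Dm <- D - rowMeans(D)
  sxx <- rowSums(Dm^2)
  sxy <- as.numeric(Dm %*% yc)
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  r2 <- ifelse(sxx > 0 & syy > 0, sxy^2 / (sxx * syy), NA_real_)
  sigma2 <- pmax((syy - beta * sxy) / (n - 2), 0)
  se <- sqrt(sigma2 / sxx)
  tstat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  p <- ifelse(is.na(beta) | n < 10, NA_real_,
              2 * stats::pt(-abs(tstat), df = n - 2))
  data.frame(effect = beta, se = se, p = p, r2 = r2)
}

## Best SNP among candidates: smallest p; ties by chromosome then position.
.pick_best <- function(stats, si, idx) {
  p <- stats$p[idx]
  if (all(is.na(p))) return(NA_integer_)
  best_p <- min(p, na.rm = TRUE)
  cand <- idx[which(!is.na(p) & p == best_p)]
  cand[order(match(si$chrom[cand], unique(si$chrom)), si$pos[cand])][1]
}

.mqtl_record <- function(probe, si, j, st, class, cohort) {
  data.frame(probe_id = probe$probe_id, probe_chrom = probe$chrom,
             cpg_pos = probe$cpg_pos,
             snp_id = si$snp_id[j], snp_chrom = si$chrom[j],
             snp_pos = si$pos[j], a1 = si$ref[j], a2 = si$alt[j],
             maf = si$maf[j],
             beta = st$effect, se = st$se, p = st$p, r2 = st$r2,
             class = class, cohort = cohort,
             rep_beta = NA_real_, rep_p = NA_real_, rep_r2 = NA_real_,
             same_dir = NA)
}

.empty_records <- function() {
  data.frame(probe_id = character(), probe_chrom = character(),
             cpg_pos = integer(), snp_id = character(),
             snp_chrom = character(), snp_pos = integer(),
             a1 = character(), a2 = character(), maf = numeric(),
             beta = numeric(), se = numeric(), p = numeric(),
             r2 = numeric(), class = character(), cohort = character(),
             rep_beta = numeric(), rep_p = numeric(), rep_r2 = numeric(),
             same_dir = logical())
}

#' Cis mQTL scan
#'
#' For every probe, tests all SNPs within `cisWindowBp` of the CpG site on
#' the same chromosome and retains the single most significant SNP when its
#' p-value beats `cisDiscoveryP` (only the best SNP per probe is
#' considered). Probes flagged `restrict_maf` are tested only against SNPs
#' with MAF above `mafRestrictThreshold`. Ties in p are broken by
#' chromosome, then genomic position. The returned records carry
#' `attr(, "counts")` with probes tested / without candidate SNPs /
#' significant.
#'
#' @param geno A [GenotypeMatrix-class].
#' @param meth A [MethylationMatrix-class] (normalized assay used when
#'   present).
#' @param config A [scanConfig()].
#' @return data.frame of mQTL records (class `"cis"`).
#' @export
cisScan <- function(geno, meth, config = scanConfig()) {
  si <- snpInfo(geno)
  pi <- probeInfo(meth)
  pheno <- .phenotypes(meth)
  D <- dosages(geno)
  cohort <- metadata(geno)$cohort %||% "discovery"
  recs <- list(); n_nosnp <- 0L
  by_chrom <- split(seq_len(nrow(si)), si$chrom)
  for (i in seq_len(nrow(pi))) {
    idx <- by_chrom[[pi$chrom[i]]]
    idx <- idx[abs(si$pos[idx] - pi$cpg_pos[i]) <= config$cisWindowBp]
    if (pi$restrict_maf[i])
      idx <- idx[si$maf[idx] > config$mafRestrictThreshold]
    if (!length(idx)) { n_nosnp <- n_nosnp + 1L; next }
    st <- .bulk_assoc(D[idx, , drop = FALSE], pheno[i, ])
    stats_full <- data.frame(p = rep(NA_real_, nrow(si)))
    stats_full$p[idx] <- st$p
    j <- .pick_best(stats_full, si, idx)
    if (is.na(j)) next
    stj <- st[match(j, idx), ]
    if (!is.na(stj$p) && stj$p < config$cisDiscoveryP)
      recs[[length(recs) + 1L]] <-
        .mqtl_record(pi[i, ], si, j, stj, "cis", cohort)
  }
  out <- if (length(recs)) do.call(rbind, recs) else .empty_records()
  counts <- list(n_probes = nrow(pi), n_no_snp_in_window = n_nosnp,
                 n_significant = nrow(out))
  .log_counts("cis-scan", counts)
  attr(out, "counts") <- counts
  out
}

#' Trans mQTL scan (two stages)
#'
#' Trans SNPs are all SNPs outside the cis window spanning `cisWindowBp` on
#' both sides of the CpG (including every SNP on other chromosomes). Stage
#' 1 scans directly genotyped SNPs for every probe-chromosome pair; pairs
#' reaching `transStage1P` are re-analysed in stage 2 with all SNPs
#' (genotyped and imputed) on that chromosome, and the best SNP per
#' probe-chromosome pair is kept when it beats `transDiscoveryP`.
#'
#' @inheritParams cisScan
#' @return data.frame of mQTL records (class `"trans"`).
#' @export
transScan <- function(geno, meth, config = scanConfig()) {
  si <- snpInfo(geno)
  pi <- probeInfo(meth)
  pheno <- .phenotypes(meth)
  D <- dosages(geno)
  cohort <- metadata(geno)$cohort %||% "discovery"
  recs <- list()
  by_chrom <- split(seq_len(nrow(si)), si$chrom)
  n_stage2 <- 0L
  for (i in seq_len(nrow(pi))) {
    for (ch in names(by_chrom)) {
      idx <- by_chrom[[ch]]
      if (ch == pi$chrom[i])
        idx <- idx[abs(si$pos[idx] - pi$cpg_pos[i]) > config$cisWindowBp]
      if (pi$restrict_maf[i])
        idx <- idx[si$maf[idx] > config$mafRestrictThreshold]
      g1 <- idx[si$genotyped[idx]]
      if (!length(g1)) next
      st1 <- .bulk_assoc(D[g1, , drop = FALSE], pheno[i, ])
      if (all(is.na(st1$p)) || min(st1$p, na.rm = TRUE) >= config$transStage1P)
        next
      n_stage2 <- n_stage2 + 1L
      st2 <- .bulk_assoc(D[idx, , drop = FALSE], pheno[i, ])
      stats_full <- data.frame(p = rep(NA_real_, nrow(si)))
      stats_full$p[idx] <- st2$p
      j <- .pick_best(stats_full, si, idx)
      if (is.na(j)) next
      stj <- st2[match(j, idx), ]
      if (!is.na(stj$p) && stj$p < config$transDiscoveryP)
        recs[[length(recs) + 1L]] <-
          .mqtl_record(pi[i, ], si, j, stj, "trans", cohort)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else .empty_records()
  counts <- list(n_probes = nrow(pi), n_stage2_pairs = n_stage2,
                 n_significant = nrow(out))
  .log_counts("trans-scan", counts)
  attr(out, "counts") <- counts
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replicate discovery mQTL in the other cohort
#'
#' Retests each discovery record's probe-SNP pair in the replication
#' cohort, after aligning alleles (a swapped ref/alt encoding flips the
#' sign of the replication effect; strand flips of unambiguous SNPs are
#' also recognised). Records are kept when the replication p-value beats
#' the class-specific threshold AND the effect direction agrees (when
#' `requireSameDirection`). SNPs or probes absent from the replication
#' cohort are dropped and counted separately from failed replication.
#'
#' @param records Discovery records from [cisScan()] / [transScan()].
#' @param otherGeno,otherMeth Replication cohort data.
#' @param config A [scanConfig()].
#' @return The replicated records with `rep_beta`, `rep_p`, `rep_r2`,
#'   `same_dir` filled; `attr(, "counts")` reports input / missing /
#'   failed / replicated counts.
#' @export
replicateMqtl <- function(records, otherGeno, otherMeth,
                          config = scanConfig()) {
  si <- snpInfo(otherGeno)
  D <- dosages(otherGeno)
  pheno <- .phenotypes(otherMeth)
  probe_idx <- match(records$probe_id, rownames(otherMeth))
  snp_idx <- match(records$snp_id, si$snp_id)
  keep <- logical(nrow(records)); n_missing <- 0L
  if (nrow(records)) {
    records$rep_beta <- records$rep_p <- records$rep_r2 <- NA_real_
    records$same_dir <- NA
  }
  for (k in seq_len(nrow(records))) {
    if (is.na(probe_idx[k]) || is.na(snp_idx[k])) { n_missing <- n_missing + 1L; next }
    flip <- .allele_flip(records$a1[k], records$a2[k],
                         si$ref[snp_idx[k]], si$alt[snp_idx[k]])
    if (is.na(flip)) { n_missing <- n_missing + 1L; next }
    st <- assocTest(D[snp_idx[k], ], pheno[probe_idx[k], ])
    if (is.na(st["p"])) { n_missing <- n_missing + 1L; next }
    rep_beta <- st["effect"] * flip
    thr <- if (records$class[k] == "cis") config$cisReplicationP
           else config$transReplicationP
    same_dir <- sign(records$beta[k]) == sign(rep_beta)
    records$rep_beta[k] <- rep_beta
    records$rep_p[k] <- st["p"]
    records$rep_r2[k] <- st["r2"]
    records$same_dir[k] <- same_dir
    keep[k] <- st["p"] < thr && (same_dir || !config$requireSameDirection)
  }
  out <- records[keep, , drop = FALSE]
  counts <- list(n_in = nrow(records), n_missing_in_replication = n_missing,
                 n_failed = nrow(records) - n_missing - nrow(out),
                 n_replicated = nrow(out))
  .log_counts("replicate", counts)
  attr(out, "counts") <- counts
  out
}

## +1 when the replication cohort encodes the same alt allele, -1 when
## ref/alt are swapped, NA when alleles are irreconcilable.
.allele_flip <- function(a1, a2, ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (identical(a1, ref) && identical(a2, alt)) return(1)
  if (identical(a1, alt) && identical(a2, ref)) return(-1)
  ## strand flip
  f1 <- unname(comp[a1]); f2 <- unname(comp[a2])
  if (identical(f1, ref) && identical(f2, alt)) return(1)
  if (identical(f1, alt) && identical(f2, ref)) return(-1)
  NA_real_
}

#' Select the SNP with the best combined evidence
#'
#' When one probe has a replicated association from both discovery
#' directions but at different SNPs, the SNP with the smaller
#' Fisher-combined p over its discovery and replication p-values
#' (chi-square `-2 (ln p1 + ln p2)` on 4 df) is retained; ties are broken
#' by chromosome, then position.
#'
#' @param recordA,recordB Single-row replicated record data.frames for the
#'   same probe (either may be NULL/empty).
#' @return The selected single-row record.
#' @export
selectBestCombined <- function(recordA, recordB) {
  if (is.null(recordB) || !nrow(recordB)) return(recordA)
  if (is.null(recordA) || !nrow(recordA)) return(recordB)
  fisher <- function(r) -2 * (log(r$p) + log(r$rep_p))
  fa <- fisher(recordA); fb <- fisher(recordB)
  if (fa > fb) return(recordA)
  if (fb > fa) return(recordB)
  o <- order(c(recordA$snp_chrom, recordB$snp_chrom),
             c(recordA$snp_pos, recordB$snp_pos))
  if (o[1] == 1) recordA else recordB
}

#' Merge replicated records from the two discovery directions
#'
#' Applies [selectBestCombined()] per probe (and per class) across the two
#' cohort-swapped analyses.
#'
#' @param recordsA,recordsB Replicated record data.frames.
#' @return Combined data.frame with one SNP per probe-class.
#' @export
combineCohorts <- function(recordsA, recordsB) {
  keys <- unique(rbind(recordsA[c("probe_id", "class")],
                       recordsB[c("probe_id", "class")]))
  out <- lapply(seq_len(nrow(keys)), function(i) {
    ra <- recordsA[recordsA$probe_id == keys$probe_id[i] &
                     recordsA$class == keys$class[i], , drop = FALSE]
    rb <- recordsB[recordsB$probe_id == keys$probe_id[i] &
                     recordsB$class == keys$class[i], , drop = FALSE]
    selectBestCombined(if (nrow(ra)) ra[1, ] else NULL,
                       if (nrow(rb)) rb[1, ] else NULL)
  })
  if (length(out)) do.call(rbind, out) else .empty_records()
}

#' Variance-explained summary of replicated mQTL
#'
#' Per-record variance explained is taken from the replication cohort
#' (`rep_r2`) when available, else the discovery `r2`. The headline mean is
#' computed over ALL probes, counting zero for probes without an mQTL. The
#' cross-cohort effect-size correlation is the Pearson correlation of
#' (discovery beta, replication beta) pairs.
#'
#' @param records Replicated mQTL records.
#' @param allProbeIds Character vector of every probe tested (the
#'   denominator of the mean).
#' @return List: `perRecordR2`, `meanR2AllProbes`, `effectCorrelation`,
#'   `nRecords`, `nProbes`.
#' @export
varianceExplainedSummary <- function(records, allProbeIds) {
  if (!nrow(records)) {
    warning("no records: correlation undefined")
    return(list(perRecordR2 = numeric(), meanR2AllProbes = 0,
                effectCorrelation = NA_real_, nRecords = 0L,
                nProbes = length(allProbeIds)))
  }
  r2 <- ifelse(!is.na(records$rep_r2), records$rep_r2, records$r2)
  per_probe <- tapply(r2, records$probe_id, sum)
  per_probe <- pmin(per_probe, 1)
  meanall <- sum(per_probe[names(per_probe) %in% allProbeIds]) /
    length(allProbeIds)
  corr <- if (sum(!is.na(records$rep_beta)) >= 3)
    stats::cor(records$beta, records$rep_beta, use = "complete.obs")
  else NA_real_
  list(perRecordR2 = r2, meanR2AllProbes = unname(meanall),
       effectCorrelation = corr, nRecords = nrow(records),
       nProbes = length(allProbeIds))
}
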