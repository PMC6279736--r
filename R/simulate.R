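#' Create a simulation configuration
#'
#' Defines the synthetic two-cohort study. Defaults follow the design of a
#' two-cohort whole-blood methylation study: a discovery/replication pair of
#' unrelated-sample cohorts of 614 and 1366 individuals, post-QC common SNPs
#' (MAF 0.05-0.5), local LD on a ~50 kb scale, logit-scale methylation noise
#' with chip/position/sex/age covariate structure, and ~10% of SNPs directly
#' genotyped (the remainder emulating imputed SNPs). The genome is a toy
#' three-autosome panel (160 Mbp) sized so that desk-scale simulations are
#' fast; all lengths are configurable.
#'
#' @param nIndividuals Named integer vector of per-cohort sample sizes.
#' @param nSnps,nProbes SNP and probe panel sizes.
#' @param chromLengths Named numeric vector of chromosome lengths (bp).
#' @param ldDecayBp LD decay scale in bp: the mosaic-haplotype recombination
#'   probability between adjacent SNPs spaced d bp apart is 1 - exp(-d /
#'   ldDecayBp). 0 gives an LD-free genome.
#' @param mafRange Range of simulated minor allele frequencies, in (0, 0.5].
#' @param cisEffects,transEffects data.frames (`probe`, `snp`, `varFrac`)
#'   of planted mQTL: panel indices and the fraction of logit-methylation
#'   variance the SNP explains. Cis probes are placed within 500 kb of their
#'   SNP; trans probes on another chromosome.
#' @param covariateEffects Named numeric effect SDs (logit scale) for the
#'   covariates chip, position, sex, age, age2, sex_age, sex_age2.
#' @param noiseVar Residual logit-scale variance.
#' @param genotypedFraction Fraction of SNPs flagged genotyped.
#' @param nGenes Genes in the toy gene model; default one per 150 kb.
#' @param seed Integer seed. The SNP/probe/gene panels are shared between
#'   cohorts (panel seed); samples are cohort-specific.
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nIndividuals = c(A = 100, B = 120), nSnps = 200,
#'                  nProbes = 10, chromLengths = c(`1` = 5e6), seed = 42)
#' @export
simConfig <- function(nIndividuals = c(discovery = 614L, replication = 1366L),
                      nSnps = 10000L,
                      nProbes = 400L,
                      chromLengths = c(`1` = 6e7, `2` = 6e7, `3` = 4e7),
                      ldDecayBp = 5e4,
                      mafRange = c(0.05, 0.5),
                      cisEffects = data.frame(probe = integer(),
                                              snp = integer(),
                                              varFrac = numeric()),
                      transEffects = data.frame(probe = integer(),
                                                snp = integer(),
                                                varFrac = numeric()),
                      covariateEffects = c(chip = 0.3, position = 0.1,
                                           sex = 0.2, age = 0.3, age2 = 0.1,
                                           sex_age = 0.1, sex_age2 = 0.05),
                      noiseVar = 1,
                      genotypedFraction = 0.1,
                      nGenes = NULL,
                      seed = 1L) {
  if (is.null(names(nIndividuals)))
    names(nIndividuals) <- paste0("cohort", seq_along(nIndividuals))
  if (is.null(nGenes)) nGenes <- max(1L, round(sum(chromLengths) / 1.5e5))
  new("SimConfig",
      nIndividuals = as.integer(nIndividuals) |>
        stats::setNames(names(nIndividuals)),
      nSnps = as.integer(nSnps), nProbes = as.integer(nProbes),
      chromLengths = chromLengths, ldDecayBp = as.numeric(ldDecayBp),
      mafRange = as.numeric(mafRange),
      cisEffects = cisEffects, transEffects = transEffects,
      covariateEffects = covariateEffects, noiseVar = as.numeric(noiseVar),
      genotypedFraction = as.numeric(genotypedFraction),
      nGenes = as.integer(nGenes), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %s samples; %d SNPs, %d probes on %d chromosome(s) (%.0f Mbp)\n",
              paste(sprintf("%s=%d", names(object@nIndividuals),
                            object@nIndividuals), collapse = ", "),
              object@nSnps, object@nProbes, length(object@chromLengths),
              sum(object@chromLengths) / 1e6))
  cat(sprintf("  LD decay %.0f bp; MAF %.2f-%.2f; planted cis/trans pairs: %d/%d; seed %d\n",
              object@ldDecayBp, object@mafRange[1], object@mafRange[2],
              nrow(object@cisEffects), nrow(object@transEffects), object@seed))
})

## ---- shared panels -------------------------------------------------------
## SNP panel (positions, founder haplotypes, genotyped flags) and probe panel
## are functions of the config seed only, so both cohorts share them.

.K_FOUNDERS <- 32L

.snpPanel <- function(config) {
  with_seed(config@seed, {
    cl <- config@chromLengths
    alloc <- .proportional_alloc(config@nSnps, cl)
    if (any(alloc > floor(cl)))
      stop("n_snps exceeds the positions available on chrom_lengths",
           call. = FALSE)
    chrom <- rep(names(cl), alloc)
    pos <- unlist(lapply(seq_along(cl), function(i) {
      sort(sample.int(as.integer(cl[i]), alloc[i]))
    }), use.names = FALSE)
    m <- length(pos)
    p <- stats::runif(m, config@mafRange[1], config@mafRange[2])
    nalt <- pmin(.K_FOUNDERS - 1L, pmax(1L, round(.K_FOUNDERS * p)))
    ## Founder haplotypes with local LD: carriers of the alt allele form a
    ## contiguous arc on a ring of founders; the arc offset jumps to a
    ## random position with the per-interval recombination probability
    ## 1 - exp(-d / ldDecayBp), so founder-level allele correlation decays
    ## on that scale while the founder allele count stays exactly nalt.
    founders <- matrix(0L, .K_FOUNDERS, m)
    o <- sample.int(.K_FOUNDERS, 1) - 1L
    for (j in seq_len(m)) {
      if (j > 1) {
        same_chrom <- chrom[j] == chrom[j - 1]
        u <- if (!same_chrom || config@ldDecayBp <= 0) 1
             else 1 - exp(-(pos[j] - pos[j - 1]) / config@ldDecayBp)
        if (stats::runif(1) < u) o <- sample.int(.K_FOUNDERS, 1) - 1L
      }
      carriers <- ((o + seq_len(nalt[j]) - 1L) %% .K_FOUNDERS) + 1L
      founders[carriers, j] <- 1L
    }
    genotyped <- stats::runif(m) < config@genotypedFraction
    refalt <- matrix(replicate(m, sample(c("A", "C", "G", "T"), 2)), nrow = 2)
    list(snp_id = sprintf("snp_%06d", seq_len(m)), chrom = chrom, pos = pos,
         ref = refalt[1, ], alt = refalt[2, ], founders = founders,
         genotyped = genotyped)
  })
}

.proportional_alloc <- function(total, weights) {
  raw <- total * weights / sum(weights)
  alloc <- floor(raw)
  rem <- total - sum(alloc)
  if (rem > 0) {
    o <- order(raw - alloc, decreasing = TRUE)
    alloc[o[seq_len(rem)]] <- alloc[o[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(alloc), names(weights))
}

.cohortIndex <- function(config, cohort) {
  if (is.character(cohort)) {
    i <- match(cohort, names(config@nIndividuals))
    .assert(!is.na(i), "unknown cohort '%s'", cohort)
    i
  } else as.integer(cohort)
}

#' Simulate a cohort's genotype panel
#'
#' Draws diploid genotypes under a mosaic-of-founder-haplotypes model: each
#' of the 2n sample haplotypes is a piecewise copy of 32 founder haplotypes,
#' switching founders between adjacent SNPs with probability
#' `1 - exp(-d / ldDecayBp)`. This produces blocky local LD whose pairwise
#' r-squared decays on the `ldDecayBp` scale, while per-SNP allele
#' frequencies are pinned to the founder frequencies drawn from `mafRange`.
#' The SNP panel (positions, founders, alleles, genotyped flags) depends on
#' the config seed only, so all cohorts share it; sample haplotypes are
#' cohort-specific and independent across cohorts.
#'
#' @param config A [SimConfig-class].
#' @param cohort Cohort name or index (into `nIndividuals`).
#' @return A [GenotypeMatrix-class]; `metadata()` records the cohort and
#'   seed.
#' @examples
#' g <- simulateGenotypes(simConfig(nIndividuals = c(A = 50, B = 50),
#'                                  nSnps = 100, nProbes = 0,
#'                                  chromLengths = c(`1` = 1e6), seed = 7), "A")
#' @export
simulateGenotypes <- function(config, cohort = 1L) {
  validObject(config)
  ci <- .cohortIndex(config, cohort)
  panel <- .snpPanel(config)
  n <- config@nIndividuals[ci]
  m <- length(panel$pos)
  dosage <- matrix(0L, m, n)
  with_seed(config@seed + 7919L * ci, {
    for (ch in unique(panel$chrom)) {
      idx <- which(panel$chrom == ch)
      d <- diff(panel$pos[idx])
      sw <- if (config@ldDecayBp > 0) 1 - exp(-d / config@ldDecayBp)
            else rep(1, length(d))
      mk <- length(idx)
      for (h in seq_len(2L * n)) {
        seg <- if (mk > 1) cumsum(c(0L, stats::runif(mk - 1) < sw)) else 0L
        draws <- sample.int(.K_FOUNDERS, max(seg) + 1L, replace = TRUE)
        hap <- panel$founders[cbind(draws[seg + 1L], idx)]
        smp <- (h + 1L) %/% 2L
        dosage[idx, smp] <- dosage[idx, smp] + hap
      }
    }
  })
  ids <- sprintf("%s_%04d", names(config@nIndividuals)[ci], seq_len(n))
  g <- GenotypeMatrix(dosage,
                      data.frame(snp_id = panel$snp_id, chrom = panel$chrom,
                                 pos = panel$pos, ref = panel$ref,
                                 alt = panel$alt,
                                 genotyped = panel$genotyped),
                      sampleIds = ids)
  metadata(g)$cohort <- names(config@nIndividuals)[ci]
  metadata(g)$cohort_index <- ci
  metadata(g)$seed <- config@seed
  g
}

## Probe panel: positions are shared across cohorts. Probes carrying a
## planted cis effect are placed within +/-500 kb of their SNP; trans-probe
## positions avoid the 2 Mbp cis window of their SNP (other chromosome when
## one exists).
.probePanel <- function(config, snp_chrom, snp_pos) {
  with_seed(config@seed + 1L, {
    np <- config@nProbes
    cl <- config@chromLengths
    chrom <- sample(names(cl), np, replace = TRUE, prob = cl / sum(cl))
    pos <- floor(stats::runif(np, 1, cl[chrom])) + 0
    for (k in seq_len(nrow(config@cisEffects))) {
      p <- config@cisEffects$probe[k]; s <- config@cisEffects$snp[k]
      chrom[p] <- snp_chrom[s]
      pos[p] <- max(1, min(cl[[snp_chrom[s]]],
                           snp_pos[s] + round(stats::runif(1, -5e5, 5e5))))
    }
    for (k in seq_len(nrow(config@transEffects))) {
      p <- config@transEffects$probe[k]; s <- config@transEffects$snp[k]
      others <- setdiff(names(cl), snp_chrom[s])
      if (length(others)) {
        chrom[p] <- sample(others, 1)
        pos[p] <- floor(stats::runif(1, 1, cl[[chrom[p]]]))
      } else {
        ## single-chromosome genome: place outside the cis window
        repeat {
          cand <- floor(stats::runif(1, 1, cl[[snp_chrom[s]]]))
          if (abs(cand - snp_pos[s]) > 2.5e6) break
        }
        pos[p] <- cand
      }
    }
    signs <- sample(c(-1, 1), nrow(config@cisEffects) +
                      nrow(config@transEffects), replace = TRUE)
    base <- stats::rnorm(np, 0, 1.2)
    list(probe_id = sprintf("probe_%04d", seq_len(np)),
         chrom = chrom, pos = as.integer(pos), signs = signs, base = base)
  })
}

#' Simulate a cohort's methylation matrix with planted mQTL
#'
#' Beta-values are generated as the inverse logit of probe baseline +
#' planted genetic effects + covariate structure + Gaussian noise, so every
#' beta lies strictly in (0, 1) and the logit-scale variance decomposition
#' is exact. A planted pair with variance fraction v contributes
#' `v / (1 - v_tot)` times the realized non-genetic variance of its probe,
#' so the dosage-vs-logit(beta) r-squared matches v up to the sampling
#' covariance between dosage and noise (O(1/sqrt(n))). Effect directions and probe positions are drawn from the panel
#' seed and therefore agree across cohorts (same-direction replication is
#' the truth). Covariates (chip, chip position, sex, age and interactions)
#' get probe-specific coefficients and are stored in `colData` for use in
#' normalization.
#'
#' @param geno A [GenotypeMatrix-class] from [simulateGenotypes()].
#' @param config The same [SimConfig-class] used to generate `geno`.
#' @return A list with elements `meth` (a [MethylationMatrix-class]) and
#'   `truth` (data.frame of planted pairs: probe_id, snp_id, class,
#'   var_frac, effect on the logit scale).
#' @export
simulateMethylation <- function(geno, config) {
  validObject(config)
  ci <- metadata(geno)$cohort_index
  .assert(!is.null(ci), "geno must come from simulateGenotypes()")
  si <- snpInfo(geno)
  eff <- rbind(
    if (nrow(config@cisEffects)) cbind(config@cisEffects, class = "cis"),
    if (nrow(config@transEffects)) cbind(config@transEffects, class = "trans"))
  if (is.null(eff))
    eff <- data.frame(probe = integer(), snp = integer(),
                      varFrac = numeric(), class = character())
  .assert(!nrow(eff) || max(eff$snp) <= nrow(si),
          "planted SNP index exceeds panel")
  .assert(!nrow(eff) || max(eff$probe) <= config@nProbes,
          "planted probe index exceeds panel")
  panel <- .probePanel(config, si$chrom, si$pos)
  n <- ncol(geno); np <- config@nProbes
  covE <- config@covariateEffects

  with_seed(config@seed + 7919L * ci + 13L, {
    ## covariate design (per sample)
    chip <- factor(rep(seq_len(ceiling(n / 12)), each = 12)[seq_len(n)])
    chip_z <- stats::rnorm(nlevels(chip))[chip]
    position <- rep(1:12, length.out = n)
    sex <- stats::rbinom(n, 1, 0.5)
    age <- stats::runif(n, 20, 80)
    X <- cbind(chip = chip_z, position = position, sex = sex,
               age = age, age2 = age^2,
               sex_age = sex * age, sex_age2 = sex * age^2)
    X <- scale(X)
    X[is.nan(X)] <- 0
    X <- X[, names(covE), drop = FALSE]
    coefs <- matrix(stats::rnorm(length(covE) * np), length(covE), np) * covE
    covTerm <- X %*% coefs                      # n x np
    noise <- matrix(stats::rnorm(n * np, 0, sqrt(config@noiseVar)), n, np)

    lgt <- sweep(covTerm + noise, 2, panel$base, `+`)
    ## realized non-genetic variance per probe: planted fractions refer to
    ## the variance actually simulated, not its expectation
    v0_real <- apply(covTerm + noise, 2, stats::var)
    truth <- NULL
    if (nrow(eff)) {
      vtot <- tapply(eff$varFrac, eff$probe, sum)[as.character(eff$probe)]
      g <- eff$varFrac / (1 - vtot) * v0_real[eff$probe]
      b <- numeric(nrow(eff))
      for (k in seq_len(nrow(eff))) {
        dos <- dosages(geno)[eff$snp[k], ]
        vd <- stats::var(dos)
        .assert(vd > 0, "planted SNP %d is monomorphic in this cohort",
                eff$snp[k])
        b[k] <- panel$signs[k] * sqrt(g[k] / vd)
        lgt[, eff$probe[k]] <- lgt[, eff$probe[k]] + b[k] * dos
      }
      truth <- data.frame(probe_id = panel$probe_id[eff$probe],
                          snp_id = si$snp_id[eff$snp],
                          class = eff$class, var_frac = eff$varFrac,
                          effect = b)
    } else {
      truth <- data.frame(probe_id = character(), snp_id = character(),
                          class = character(), var_frac = numeric(),
                          effect = numeric())
    }
    beta <- .invlogit(t(lgt))                   # probes x samples
    meth <- MethylationMatrix(
      beta,
      data.frame(probe_id = panel$probe_id, chrom = panel$chrom,
                 cpg_pos = panel$pos),
      sampleIds = sampleIds(geno))
    colData(meth)$chip <- chip
    colData(meth)$position <- position
    colData(meth)$sex <- sex
    colData(meth)$age <- age
    metadata(meth)$cohort <- metadata(geno)$cohort
    metadata(meth)$cohort_index <- ci
    list(meth = meth, truth = truth)
  })
}

#' Simulate GWAS summary statistics under the stratified LD score model
#'
#' Per-SNP chi-square statistics are drawn as scaled central 1-df
#' chi-squares with expectation `alpha + N * tauMqtl * L_mQTL +
#' N * tauG * L_G`, the expectation of association test statistics under a
#' polygenic architecture where each component contributes `tau` variance
#' per SNP. Effects and SEs are filled in consistently
#' (`chi2 = (effect / se)^2`, `se = 1 / sqrt(N)`).
#'
#' @param ldscores An [LDScoreTable-class] covering the SNPs.
#' @param tauMqtl,tauG Per-SNP variance coefficients (>= 0).
#' @param alpha Intercept (1 under no confounding).
#' @param nGwas GWAS sample size.
#' @param seed Integer seed.
#' @return data.frame of summary statistics: snp_id, a1, a2, freq, effect,
#'   se, p, chi2, n.
#' @export
simulateGwasSumstats <- function(ldscores, tauMqtl, tauG, alpha = 1,
                                 nGwas = 50000, seed = 1L) {
  .assert(tauMqtl >= 0 && tauG >= 0, "tau coefficients must be non-negative")
  tb <- ldTable(ldscores)
  lambda <- alpha + nGwas * tauMqtl * tb$L_mqtl + nGwas * tauG * tb$L_G
  .assert(all(lambda > 0), "expected chi-square must be positive")
  with_seed(seed, {
    chi2 <- lambda * stats::rchisq(nrow(tb), df = 1)
    se <- rep(1 / sqrt(nGwas), nrow(tb))
    effect <- sample(c(-1, 1), nrow(tb), replace = TRUE) * sqrt(chi2) * se
    data.frame(snp_id = tb$snp_id, a1 = "A", a2 = "G", freq = tb$maf,
               effect = effect, se = se,
               p = stats::pchisq(chi2, 1, lower.tail = FALSE),
               chi2 = chi2, n = nGwas)
  })
}

#' Simulate a toy gene model
#'
#' Places non-overlapping transcripts along the configured chromosomes:
#' each gene gets a strand, 1-8 exons with intervening introns, and (for
#' coding genes, 85%) a CDS leaving non-empty 5' and 3' UTRs, so that every
#' positional annotation category (exonic, UTRs, interior introns, ncRNA
#' exons/introns, upstream, downstream, intergenic) is realizable on the
#' toy genome.
#'
#' @param config A [SimConfig-class] (`chromLengths`, `nGenes`, `seed`).
#' @return A [GeneModel-class].
#' @export
simulateGeneModel <- function(config) {
  validObject(config)
  with_seed(config@seed + 2L, {
    cl <- config@chromLengths
    alloc <- .proportional_alloc(config@nGenes, cl)
    tx_chrom <- character(); tx_start <- tx_end <- integer()
    tx_strand <- character(); coding <- logical()
    cds_s <- cds_e <- integer(); exon_list <- list()
    gidx <- 0L
    for (ch in names(cl)) {
      ng <- alloc[[ch]]
      if (ng == 0) next
      binw <- floor(cl[[ch]] / ng)
      for (b in seq_len(ng)) {
        gidx <- gidx + 1L
        lo <- (b - 1L) * binw + 1L
        span <- max(200L, min(floor(binw * 0.6), 2e5))
        glen <- max(200L, floor(stats::runif(1, 0.3, 1) * span))
        gs <- lo + floor(stats::runif(1, 0, binw - glen - 1))
        ge <- gs + glen - 1L
        nex <- sample.int(min(8L, max(1L, glen %/% 400L)), 1)
        ## alternate exon/intron widths over 2*nex-1 blocks
        w <- stats::runif(2L * nex - 1L, 0.5, 1.5)
        w <- pmax(50L, floor(w / sum(w) * glen))
        bnd <- gs + cumsum(c(0L, w))
        bnd[length(bnd)] <- ge + 1L
        es <- bnd[seq(1, 2L * nex - 1L, by = 2)]
        ee <- bnd[seq(2, 2L * nex, by = 2)] - 1L
        ee[nex] <- ge
        if (any(ee < es)) { es <- gs; ee <- ge; nex <- 1L }  # degenerate: one exon
        is_coding <- stats::runif(1) < 0.85
        if (is_coding) {
          m5 <- max(10L, floor((ee[1] - es[1]) * 0.3))
          m3 <- max(10L, floor((ee[nex] - es[nex]) * 0.3))
          cs <- es[1] + m5; ce <- ee[nex] - m3
          if (cs > ce) { cs <- es[1]; ce <- ee[nex]; }
        } else cs <- ce <- NA_integer_
        tx_chrom <- c(tx_chrom, ch); tx_start <- c(tx_start, gs)
        tx_end <- c(tx_end, ge)
        tx_strand <- c(tx_strand, sample(c("+", "-"), 1))
        coding <- c(coding, is_coding)
        cds_s <- c(cds_s, cs); cds_e <- c(cds_e, ce)
        exon_list[[gidx]] <- IRanges(es, ee)
      }
    }
    tx_id <- sprintf("tx_%05d", seq_len(gidx))
    tx <- GRanges(tx_chrom, IRanges(tx_start, tx_end), strand = tx_strand,
                  tx_id = tx_id, gene_id = sub("tx", "gene", tx_id),
                  coding = coding, cds_start = cds_s, cds_end = cds_e)
    names(tx) <- tx_id
    ex <- GRangesList(lapply(seq_len(gidx), function(i)
      GRanges(tx_chrom[i], exon_list[[i]], strand = tx_strand[i])))
    names(ex) <- tx_id
    GeneModel(tx, ex)
  })
}
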