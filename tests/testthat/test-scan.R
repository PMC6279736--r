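## Independent normal-equations oracle for simple linear regression.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  bh <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% bh
  s2 <- sum(res^2) / (length(y) - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  tt <- bh[2] / se
  c(effect = bh[2], se = se, p = 2 * pt(-abs(tt), length(y) - 2),
    r2 = cor(x, y)^2)
}

test_that("assocTest agrees with the normal-equations oracle", {
  set.seed(33)
  for (rep in 1:200) {
    x <- rbinom(20, 2, runif(1, 0.1, 0.5))
    if (var(x) == 0) next
    y <- rnorm(20) + runif(1, -1, 1) * x
    got <- assocTest(x, y)
    want <- ols_oracle(x, y)
    expect_equal(got[["effect"]], want[["effect"]], tolerance = 1e-10)
    expect_equal(got[["se"]], want[["se"]], tolerance = 1e-10)
    expect_equal(got[["p"]], want[["p"]], tolerance = 1e-10)
    expect_equal(got[["r2"]], want[["r2"]], tolerance = 1e-10)
  }
})

test_that("assocTest handles exact fits and degenerate inputs", {
  d <- rep(0:2, each = 10)
  perfect <- assocTest(d, 2 * d)
  expect_equal(perfect[["r2"]], 1)
  expect_equal(perfect[["p"]], 0)
  expect_true(is.na(assocTest(rep(1, 30), rnorm(30))[["p"]]))   # no variance
  expect_true(is.na(assocTest(d[1:5], rnorm(5))[["p"]]))        # too few
})

test_that("null association p-values are uniform", {
  set.seed(44)
  p <- replicate(500, assocTest(rbinom(100, 2, 0.3), rnorm(100))[["p"]])
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("cis scan finds planted effects and keeps one best SNP per probe", {
  st <- small_study()
  rec <- cisScan(st$gA, st$mA)
  expect_true(all(rec$class == "cis"))
  ## both planted cis probes discovered at the stringent threshold
  expect_true(all(st$truthA$probe_id[st$truthA$class == "cis"] %in%
                    rec$probe_id))
  expect_true(all(rec$p < 1e-11))
  expect_equal(anyDuplicated(rec$probe_id), 0)
  ## every record satisfies the cis distance predicate
  expect_true(all(rec$probe_chrom == rec$snp_chrom &
                    abs(rec$snp_pos - rec$cpg_pos) <= 2e6))
})

test_that("tied p-values resolve to the lower genomic position", {
  set.seed(55)
  d <- rbinom(200, 2, 0.4)
  D <- rbind(d, rnorm(200) > 2, d)          # rows 1 and 3 identical
  y <- d * 1.5 + rnorm(200, 0, 0.5)
  g <- geno_from_dosage(D, pos = c(1e5, 2e5, 3e5))
  m <- meth_from_logit(matrix(y, 1), cpg_pos = 2e5)
  rec <- cisScan(g, m, scanConfig(cisDiscoveryP = 1e-4))
  expect_equal(rec$snp_id, "rs001")          # identical stats, lower position
})

test_that("trans scan honours the window, the two stages and the flags", {
  st <- small_study()
  rec <- transScan(st$gA, st$mA)
  tr <- st$truthA[st$truthA$class == "trans", ]
  expect_true(tr$probe_id %in% rec$probe_id)
  expect_true(all(rec$p < 1e-13))
  ## no trans record inside the cis window
  same <- rec$probe_chrom == rec$snp_chrom
  expect_true(all(!same | abs(rec$snp_pos - rec$cpg_pos) > 2e6))
})

test_that("a same-chromosome SNP beyond the cis window is trans, not cis", {
  set.seed(66)
  n <- 400
  d <- rbinom(n, 2, 0.4)
  D <- rbind(d, rbinom(n, 2, 0.3))
  ## SNP 3 Mbp from the CpG: outside the 2 Mbp-per-side cis window
  g <- geno_from_dosage(D, pos = c(4e6, 5e6))
  y <- 1.2 * d + rnorm(n, 0, 0.4)
  m <- meth_from_logit(matrix(y, 1), cpg_pos = 1e6)
  expect_equal(nrow(cisScan(g, m)), 0)
  rec <- transScan(g, m)
  expect_equal(rec$snp_id, "rs001")
  expect_equal(rec$class, "trans")
})

test_that("stage 1 of the trans scan only sees genotyped SNPs", {
  set.seed(67)
  n <- 400
  d <- rbinom(n, 2, 0.4)
  g <- geno_from_dosage(rbind(d, rbinom(n, 2, 0.3)), pos = c(4e6, 5e6),
                        genotyped = c(FALSE, FALSE))
  y <- 1.2 * d + rnorm(n, 0, 0.4)
  m <- meth_from_logit(matrix(y, 1), cpg_pos = 1e6)
  expect_equal(nrow(transScan(g, m)), 0)     # nothing to trigger stage 1
})

test_that("replication enforces threshold, direction and allele alignment", {
  set.seed(77)
  n <- 500
  dA <- rbinom(n, 2, 0.4); dB <- rbinom(n, 2, 0.4)
  gA <- geno_from_dosage(rbind(dA), pos = 1e5)
  mA <- meth_from_logit(rbind(1.5 * dA + rnorm(n, 0, 0.6)), cpg_pos = 1.2e5)
  disc <- cisScan(gA, mA, scanConfig(cisDiscoveryP = 1e-6))
  expect_equal(nrow(disc), 1)

  ## same-direction cohort B: replicates
  gB <- geno_from_dosage(rbind(dB), pos = 1e5)
  mB <- meth_from_logit(rbind(1.5 * dB + rnorm(n, 0, 0.6)), cpg_pos = 1.2e5)
  rep1 <- replicateMqtl(disc, gB, mB)
  expect_equal(nrow(rep1), 1)
  expect_true(rep1$same_dir)

  ## strong but opposite-direction effect: rejected
  mBopp <- meth_from_logit(rbind(-1.5 * dB + rnorm(n, 0, 0.6)), cpg_pos = 1.2e5)
  rep2 <- replicateMqtl(disc, gB, mBopp)
  expect_equal(nrow(rep2), 0)
  expect_equal(attr(rep2, "counts")$n_failed, 1)

  ## allele-swapped encoding in cohort B: dosage flipped, sign reconciled
  gBswap <- GenotypeMatrix(rbind(2 - dB),
                           data.frame(snp_id = "rs001", chrom = "1",
                                      pos = 1e5, ref = "G", alt = "A"),
                           sampleIds = sprintf("s%03d", 1:n))
  rep3 <- replicateMqtl(disc, gBswap, mB)
  expect_equal(nrow(rep3), 1)
  expect_true(rep3$same_dir)
  expect_equal(rep3$rep_beta, rep1$rep_beta, tolerance = 1e-12)

  ## SNP absent from the replication panel: dropped, counted separately
  gBmiss <- geno_from_dosage(rbind(dB), pos = 1e5)
  rownames(gBmiss) <- "rs999"
  rep4 <- replicateMqtl(disc, gBmiss, mB)
  expect_equal(nrow(rep4), 0)
  expect_equal(attr(rep4, "counts")$n_missing_in_replication, 1)
})

test_that("best-combined selection uses the Fisher statistic then position", {
  rec <- function(p, rep_p, pos) {
    r <- small_study()$gA  # just for scope; build a minimal record
    data.frame(probe_id = "p1", snp_id = paste0("rs", pos), p = p,
               rep_p = rep_p, snp_chrom = "1", snp_pos = pos)
  }
  a <- rec(1e-20, 1e-8, 500)   # Fisher chi2 = 128.9
  b <- rec(1e-12, 1e-12, 100)  # Fisher chi2 = 110.5
  expect_equal(selectBestCombined(a, b)$snp_pos, 500)
  expect_equal(-2 * (log(a$p) + log(a$rep_p)), 128.9, tolerance = 0.1)
  expect_equal(-2 * (log(b$p) + log(b$rep_p)), 110.5, tolerance = 0.1)
  ## identical evidence: lower position wins
  expect_equal(selectBestCombined(rec(1e-10, 1e-10, 900),
                                  rec(1e-10, 1e-10, 200))$snp_pos, 200)
  ## single record passes through
  expect_identical(selectBestCombined(a, NULL), a)
  expect_identical(selectBestCombined(NULL, b), b)
})

test_that("variance-explained summary averages over all probes", {
  recs <- data.frame(probe_id = c("p1", "p2"), r2 = c(0.5, 0.3),
                     rep_r2 = c(NA, NA), beta = c(1, 2),
                     rep_beta = c(1, 2), class = "cis")
  v <- varianceExplainedSummary(recs, paste0("p", 1:10))
  expect_equal(v$meanR2AllProbes, 0.08)
  ## identical effects across cohorts -> correlation 1 (needs >= 3 pairs)
  recs3 <- data.frame(probe_id = paste0("p", 1:3), r2 = c(0.5, 0.3, 0.2),
                      rep_r2 = NA_real_, beta = c(1, 2, 0.5),
                      rep_beta = c(1, 2, 0.5), class = "cis")
  expect_equal(varianceExplainedSummary(recs3, paste0("p", 1:10))$effectCorrelation, 1)
  ## empty input: mean 0, correlation signalled undefined
  expect_warning(v0 <- varianceExplainedSummary(recs[0, ], paste0("p", 1:10)))
  expect_equal(v0$meanR2AllProbes, 0)
  expect_true(is.na(v0$effectCorrelation))
})

test_that("the cis pipeline's type-I rate matches its threshold on null data", {
  ## LD-free genome so tests are independent; alpha scaled up for testability
  alpha <- 1e-4
  n_disc <- 0; n_tests <- 0
  for (s in 1:4) {
    cfg <- simConfig(nIndividuals = c(A = 200), nSnps = 250, nProbes = 40,
                     chromLengths = c(`1` = 4e6), ldDecayBp = 0, seed = 500 + s)
    g <- simulateGenotypes(cfg, "A")
    m <- normalizeMethylation(simulateMethylation(g, cfg)$meth)
    rec <- cisScan(g, m, scanConfig(cisDiscoveryP = alpha))
    ## every probe sees every SNP (window covers the whole chromosome)
    n_tests <- n_tests + 250 * 40
    n_disc <- n_disc + nrow(rec)
  }
  bounds <- qbinom(c(0.0005, 0.9995), n_tests, alpha)
  expect_gte(n_disc, bounds[1])
  expect_lte(n_disc, bounds[2])
})
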