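test_that("greedy LD pruning keeps the more significant of linked pairs", {
  set.seed(3)
  n <- 300
  d1 <- rbinom(n, 2, 0.4)
  d2 <- d1; flip <- sample(n, 12); d2[flip] <- rbinom(12, 2, 0.4)  # r2 ~ 0.9
  d3 <- rbinom(n, 2, 0.3)
  g <- geno_from_dosage(rbind(d1, d2, d3), pos = c(1e5, 2e5, 3e5))
  expect_gt(cor(d1, d2)^2, 0.8)
  kept <- ldPrune(c("rs001", "rs002", "rs003"), g,
                  order = c(1e-20, 1e-10, 1e-5))  # rs001 most significant
  expect_equal(kept, c("rs001", "rs003"))
  ## all pairs below the threshold: set unchanged, idempotent
  kept2 <- ldPrune(c("rs001", "rs003"), g)
  expect_equal(kept2, c("rs001", "rs003"))
})

test_that("pruned sets verify pair-exhaustively against a brute-force check", {
  cfg <- simConfig(nIndividuals = c(A = 250), nSnps = 100, nProbes = 0,
                   chromLengths = c(`1` = 2e6), ldDecayBp = 2e5, seed = 31)
  g <- simulateGenotypes(cfg, "A")
  si <- snpInfo(g)
  kept <- ldPrune(si$snp_id, g, r2Max = 0.8)
  D <- dosages(g)[kept, ]
  pos <- si$pos[match(kept, si$snp_id)]
  for (a in seq_along(kept))
    for (b in seq_len(a - 1)) {
      if (abs(pos[a] - pos[b]) > 1e6) next
      expect_lte(cor(D[a, ], D[b, ])^2, 0.8)
    }
  expect_gt(length(kept), 10)   # pruning should not collapse the set
})

test_that("matched null sets replicate the target's strata exactly", {
  set.seed(7)
  pool <- data.frame(snp_id = sprintf("v%04d", 1:600),
                     maf = runif(600, 0.01, 0.5),
                     category = sample(c("genic", "intergenic"), 600, TRUE))
  target <- pool$snp_id[sample(600, 40)]
  sets <- sampleMatchedSets(target, pool, B = 50, seed = 11)
  tbin <- table(mafBin(pool$maf[pool$snp_id %in% target]))
  for (s in sets[1:10]) {
    expect_length(s, 40)
    expect_false(any(s %in% target))
    expect_equal(table(mafBin(pool$maf[match(s, pool$snp_id)])), tbin)
  }
  ## with annotation matching, per-category counts also agree
  sets2 <- sampleMatchedSets(target, pool, matchAnnotation = TRUE, B = 20,
                             seed = 13)
  tcat <- table(pool$category[pool$snp_id %in% target])
  for (s in sets2)
    expect_equal(table(pool$category[match(s, pool$snp_id)]), tcat)
  ## deterministic under seed
  expect_identical(sets, sampleMatchedSets(target, pool, B = 50, seed = 11))
})

test_that("a single-bin target draws every null from that bin, or errors", {
  pool <- data.frame(snp_id = sprintf("v%03d", 1:120),
                     maf = c(runif(40, 0.25, 0.2999), runif(80, 0.05, 0.0999)))
  target <- pool$snp_id[1:10]                      # all in [0.25, 0.30)
  sets <- sampleMatchedSets(target, pool, B = 25, seed = 3)
  for (s in sets)
    expect_true(all(pool$maf[match(s, pool$snp_id)] >= 0.25 &
                      pool$maf[match(s, pool$snp_id)] < 0.30))
  ## forced outcome: pool bin contains exactly the needed SNPs
  pool2 <- data.frame(snp_id = c("a", "b", "c", "d"),
                      maf = c(0.26, 0.27, 0.26, 0.27))
  sets2 <- sampleMatchedSets(c("a", "b"), pool2, B = 5, seed = 1)
  for (s in sets2) expect_setequal(s, c("c", "d"))
  ## insufficient stratum: error naming it
  expect_error(sampleMatchedSets(pool$snp_id[1:35], pool, B = 2, seed = 1),
               "stratum")
})

test_that("enrichment tail arithmetic matches the normal approximation", {
  tail <- nullTailP(0.330, 0.083, 0.040)
  expect_equal(unname(tail["z"]), 6.175, tolerance = 1e-3)
  expect_equal(unname(tail["p"]), 3.3e-10, tolerance = 0.1)
  ## observed below the null mean: one-sided p > 0.5
  nulls <- list(rep(0.3, 30))
  res <- enrichmentTest("x", split(rnorm(30, 0.3, 0.02), 1:30),
                        statistic = function(ids)
                          if (identical(ids, "x")) 0.25 else mean(ids))
  expect_gt(res@pNormal, 0.5)
  expect_gt(res@pEmpirical, 0.5)
  ## B < 20 suppresses the normal approximation
  res2 <- enrichmentTest("x", split(rnorm(10, 0.3, 0.02), 1:10),
                         statistic = function(ids)
                           if (identical(ids, "x")) 0.5 else mean(ids))
  expect_true(is.na(res2@pNormal))
  expect_equal(res2@pEmpirical, 1 / 11)
})

test_that("the partition statistic detects planted mQTL-concentrated signal", {
  ## genome with LD; mQTL component carries twice the per-SNP variance
  cfg <- simConfig(nIndividuals = c(A = 300), nSnps = 800, nProbes = 0,
                   chromLengths = c(`1` = 1.6e7), ldDecayBp = 1e5, seed = 41)
  g <- simulateGenotypes(cfg, "A")
  si <- snpInfo(g)
  set.seed(42)
  target <- sort(sample(si$snp_id, 120))
  ld <- ldScores(g, mqtlIds = target)
  ## planted: tau twice as large in the mQTL component
  tb <- ldTable(ld)
  lam <- 1 + 5e4 * 4e-5 * tb$L_mqtl + 5e4 * 1e-5 * tb$L_G
  set.seed(43)
  ss <- data.frame(snp_id = tb$snp_id, chi2 = lam * rchisq(nrow(tb), 1),
                   n = 5e4)
  pool <- data.frame(snp_id = si$snp_id, maf = si$maf)
  nulls <- sampleMatchedSets(target, pool, B = 60, seed = 44)
  res <- enrichmentTest(target, nulls,
                        partitionStatistic(ss, ld, nGwas = 5e4))
  expect_gt(res@observed, res@nullMean)
  expect_lt(res@pEmpirical, 0.05)
  expect_lt(res@pNormal, 0.01)
})
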