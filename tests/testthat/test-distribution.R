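test_that("the subtelomeric genome fraction is exact arithmetic", {
  ## bundled GRCh37 autosomes with a 1 Mbp margin: 1.53% of the genome
  expect_equal(subtelomericFraction(), 0.0153, tolerance = 0.005)
  expect_equal(round(100 * subtelomericFraction(), 2), 1.53)
  ## one 10 Mbp chromosome: 2/10
  expect_equal(subtelomericFraction(1e6, c(`1` = 1e7)), 0.2)
  ## zero margin: zero
  expect_equal(subtelomericFraction(0, c(`1` = 1e7)), 0)
  ## margin too large
  expect_error(subtelomericFraction(6e6, c(`1` = 1e7)), "margin")
})

test_that("subtelomeric enrichment counts both chromosome ends", {
  cl <- c(`1` = 1e7, `2` = 2e7)
  res <- subtelomericEnrichment(c("1", "1", "2", "2"),
                                c(1, 5e6, 1.95e7, 1e7), marginBp = 1e6,
                                chromLengths = cl)
  expect_equal(res$observedFraction, 0.5)   # pos 1 and 1.95e7 are in margins
  ## every position at the chromosome start
  res1 <- subtelomericEnrichment(rep("1", 5), rep(1, 5), chromLengths = cl)
  expect_equal(res1$observedFraction, 1)
  expect_error(subtelomericEnrichment("9", 100, chromLengths = cl),
               "unknown")
})

test_that("the binomial test is calibrated under uniform placement", {
  set.seed(27)
  cl <- grch37AutosomeLengths()
  ps <- replicate(60, {
    chrom <- sample(names(cl), 400, TRUE, prob = cl / sum(cl))
    pos <- floor(runif(400, 1, cl[chrom]))
    subtelomericEnrichment(chrom, pos)$p
  })
  ## one-sided exact test: P(p <= alpha) <= alpha; check no gross anti-
  ## conservatism and that nulls are not all significant
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps > 0.2), 0.5)
})

test_that("strong subtelomeric placement is astronomically significant", {
  ## 362 of 2025 positions subtelomeric (17.9%) vs 1.53% expected
  set.seed(29)
  cl <- grch37AutosomeLengths()
  n <- 2025; n_sub <- 362
  chrom <- sample(names(cl), n, TRUE, prob = cl / sum(cl))
  pos <- floor(runif(n, 1.1e6, cl[chrom] - 1.1e6))       # interior
  sub_idx <- sample(n, n_sub)
  pos[sub_idx] <- sample(1e6, n_sub)                      # left margins
  res <- subtelomericEnrichment(chrom, pos)
  expect_equal(res$observedFraction, n_sub / n)
  expect_lt(res$p, 1e-10)
})

test_that("per-chromosome counts compare against gene-count expectations", {
  genes <- c(`1` = 100, `2` = 50, `3` = 50)
  ## counts exactly proportional to gene counts
  chrom <- rep(names(genes), genes / 10)
  res <- perChromosomeDistribution(chrom, genes)
  expect_equal(res$table$pearson_resid, rep(0, 3))
  expect_equal(res$correlation, 1)
  expect_equal(sum(res$table$expected), length(chrom))   # conservation
  ## one chromosome at 3x its expectation
  genes4 <- c(`1` = 100, `2` = 50, `3` = 50, `4` = 80)
  chrom2 <- rep(names(genes4), c(100, 150, 50, 80))
  res2 <- perChromosomeDistribution(chrom2, genes4, outliers = "2")
  expect_equal(res2$table$chrom[which.max(abs(res2$table$pearson_resid))],
               "2")
  ## excluding the inflated chromosome restores the gene-count relationship
  expect_equal(res2$correlationExclOutliers, 1, tolerance = 1e-12)
  expect_lt(res2$correlation, 1)
})

test_that("the goodness-of-fit chi-square matches a hand computation", {
  genes <- c(a = 20, b = 30, c = 10, d = 25, e = 15)
  obs <- c(a = 18, b = 35, c = 8, d = 22, e = 17)
  chrom <- rep(names(obs), obs)
  res <- perChromosomeDistribution(chrom, genes)
  expected <- sum(obs) * genes / sum(genes)
  chi2_hand <- sum((obs - expected)^2 / expected)
  expect_equal(res$chisq, unname(chi2_hand), tolerance = 1e-12)
  expect_equal(res$chisq_p, unname(pchisq(chi2_hand, 4, lower.tail = FALSE)),
               tolerance = 1e-12)
})
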