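test_that("probe filtering removes each violation for its own reason", {
  set.seed(4)
  b <- matrix(runif(10 * 20, 0.1, 0.9), 10, 20)
  b[2, 1:5] <- NA                                   # 25% missing
  pi <- data.frame(probe_id = sprintf("p%02d", 1:10),
                   chrom = c("X", rep("1", 9)),     # p01 on a sex chromosome
                   cpg_pos = seq(1e5, 1e6, length.out = 10))
  pi$is_cpg <- c(TRUE, TRUE, FALSE, rep(TRUE, 7))   # p03 non-CpG
  m <- MethylationMatrix(b, pi)
  out <- filterProbes(m, probeQcConfig(maxMissingFraction = 0.05))
  expect_equal(nrow(out), 7)
  cnt <- metadata(out)$probe_filter_counts
  expect_equal(cnt$sex_chrom, 1)
  expect_equal(cnt$missingness, 1)
  expect_equal(cnt$non_cpg, 1)
  ## idempotent
  out2 <- filterProbes(out, probeQcConfig(maxMissingFraction = 0.05))
  expect_identical(rownames(out), rownames(out2))
  ## blacklist path
  out3 <- filterProbes(m, probeQcConfig(maxMissingFraction = 0.05),
                       blacklist = c("p05", "p06"))
  expect_equal(nrow(out3), 5)
  ## clean autosomal CpG probe is always retained
  expect_true("p04" %in% rownames(out3))
})

test_that("intercept-only normalization centres the logits", {
  b <- c(0.2, 0.5, 0.8, 0.4, 0.6)
  r <- normalizeProbe(b, NULL)
  expect_equal(as.numeric(r), qlogis(b) - mean(qlogis(b)), tolerance = 1e-12)
  ## all betas equal -> all-zero residuals
  expect_equal(as.numeric(normalizeProbe(rep(0.3, 8), NULL)), rep(0, 8))
  ## boundary betas are clipped and counted
  r2 <- normalizeProbe(c(0, 0.5, 1, 0.5), NULL)
  expect_equal(attr(r2, "n_clipped"), 2)
  expect_true(all(is.finite(r2)))
})

test_that("residuals are orthogonal to every covariate column", {
  set.seed(11)
  n <- 120
  X <- cbind(age = runif(n, 20, 80), sex = rbinom(n, 1, 0.5),
             batch = rnorm(n))
  b <- plogis(0.5 + 0.02 * X[, "age"] - 0.4 * X[, "sex"] + rnorm(n, 0, 0.5))
  r <- normalizeProbe(b, X)
  for (j in colnames(X))
    expect_lt(abs(cor(as.numeric(r), X[, j])), 1e-8)
  ## matrix-level wrapper: every probe orthogonal, order preserved
  st <- small_study()
  norm <- SummarizedExperiment::assay(st$mA, "normalized")
  expect_identical(colnames(norm), sampleIds(st$gA))
  cd <- SummarizedExperiment::colData(st$mA)
  for (i in c(1, 5, 10))
    expect_lt(abs(cor(norm[i, ], cd$age)), 1e-8)
})

test_that("the 5-IQR outlier rule flags only genuinely extreme points", {
  ## bounded data: fences far outside the range
  r <- removeOutliers(1:100)
  expect_equal(sum(r$flags), 0)
  ## degenerate quartiles: IQR 0, any different value is flagged
  r2 <- removeOutliers(c(rep(0, 99), 1000))
  expect_equal(sum(r2$flags), 1)
  expect_true(r2$flags[100])
  expect_true(r2$degenerate)
  expect_true(is.na(r2$values[100]))
  ## k -> infinity: never flags
  r3 <- removeOutliers(c(rnorm(50), 1e6), iqrMultiplier = 1e12)
  expect_equal(sum(r3$flags), 0)
  ## restrict_maf mode leaves values but raises the probe flag
  r4 <- removeOutliers(c(rep(0, 99), 1000), mode = "restrict_maf")
  expect_equal(r4$values[100], 1000)
  expect_true(r4$restrict_maf)
  ## idempotent in remove mode
  r5 <- removeOutliers(r2$values)
  expect_equal(sum(r5$flags, na.rm = TRUE), 0)
  expect_error(removeOutliers(c(1, 2, NA, NA)), "at least 4")
})

test_that("matrix-level outlier handling honours the two cohort rules", {
  set.seed(21)
  lgt <- matrix(rnorm(3 * 60, 0, 0.3), 3, 60)
  lgt[2, 1] <- 25                                 # a wild measurement
  m <- meth_from_logit(lgt)
  rm_ <- handleOutliers(m, mode = "remove")
  expect_true(is.na(betas(rm_)[2, 1]))
  expect_false(any(is.na(betas(rm_)[1, ])))
  rs <- handleOutliers(m, mode = "restrict_maf")
  expect_false(any(is.na(betas(rs))))
  expect_true(SummarizedExperiment::rowData(rs)$restrict_maf[2])
  expect_false(SummarizedExperiment::rowData(rs)$restrict_maf[1])
})
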