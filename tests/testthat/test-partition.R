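test_that("noise-free chi-squares are recovered exactly", {
  ld <- synth_ld(500, 100)
  tb <- ldTable(ld)
  chi2 <- 1 + 0.002 * tb$L_mqtl + 0.001 * tb$L_G
  ss <- data.frame(snp_id = tb$snp_id, chi2 = chi2, n = 1e4)
  fit <- fitPartition(ss, ld, nGwas = 1e4)
  expect_equal(fit@alpha, 1, tolerance = 1e-10)
  expect_equal(unname(fit@beta[["mQTL"]]), 0.002, tolerance = 1e-10)
  expect_equal(unname(fit@beta[["G"]]), 0.001, tolerance = 1e-10)
  ## h2 conversion is exact: beta * M / N
  expect_equal(unname(fit@h2[["mQTL"]]), 0.002 * 100 / 1e4, tolerance = 1e-12)
})

test_that("the slope-to-heritability conversion is plain arithmetic", {
  expect_equal(h2FromSlope(0.002, 1000, 10000), 2e-4)
  f <- new("PartitionFit", alpha = 1, beta = c(mQTL = 1, G = 1),
           se = c(mQTL = 0, G = 0), M = c(mQTL = 1, G = 1), nGwas = 1,
           h2 = c(mQTL = 0.2, G = 0.2), proportion = 0.5, nSnpsUsed = 100L)
  expect_equal(proportionOfHeritability(f), 0.5)   # equal components
})

test_that("scaling all chi-squares scales slopes but not the proportion", {
  ld <- synth_ld(800, 200, seed = 3)
  ss <- simulateGwasSumstats(ld, 2e-5, 1e-5, nGwas = 5e4, seed = 4)
  f1 <- fitPartition(ss, ld, nGwas = 5e4)
  ss2 <- transform(ss, chi2 = chi2 * 7)
  f2 <- fitPartition(ss2, ld, nGwas = 5e4)
  expect_equal(f2@beta, f1@beta * 7, tolerance = 1e-9)
  expect_equal(f2@h2, f1@h2 * 7, tolerance = 1e-9)
  expect_equal(f2@proportion, f1@proportion, tolerance = 1e-9)
})

test_that("an empty mQTL component reduces to one-column LD score regression", {
  ld <- synth_ld(600, 150, seed = 5)
  tb <- ldTable(ld)
  tb$L_mqtl <- 0; tb$L_G <- tb$L_total
  ld1 <- LDScoreTable(tb, nRef = 500L, mqtlIds = character())
  ss <- simulateGwasSumstats(ld1, 0, 2e-5, nGwas = 5e4, seed = 6)
  expect_error(fitPartition(ss, ld1), "collinear")
  ## one-column fit as reference
  ols <- lm(ss$chi2 ~ tb$L_G)
  X <- cbind(1, tb$L_G)
  expect_equal(unname(coef(ols)[2]),
               unname(solve(crossprod(X), crossprod(X, ss$chi2))[2]),
               tolerance = 1e-10)
})

test_that("a null mQTL component estimates a near-zero proportion", {
  props <- vapply(1:20, function(s) {
    ld <- synth_ld(4000, 400, seed = 100 + s)
    ss <- simulateGwasSumstats(ld, 0, 2e-5, nGwas = 5e4, seed = 200 + s)
    suppressWarnings(fitPartition(ss, ld, nGwas = 5e4)@proportion)
  }, numeric(1))
  expect_lt(abs(mean(props)), 3 * sd(props) / sqrt(20))
})

test_that("planted mQTL proportions are recovered from stochastic stats", {
  ## proportion = (b_m M_m) / (b_m M_m + b_g M_g) planted at 1/3
  reps <- vapply(1:30, function(s) {
    ld <- synth_ld(6000, 600, seed = 300 + s)
    tau_g <- 1e-5
    ## M_m = 600, M_g = 5400: b_m = 2 b_g * 5400/600 / 2 -> solve for 0.33
    tau_m <- tau_g * (5400 / 600) / 2       # h2_m / h2_g = 1/2 -> prop 1/3
    ss <- simulateGwasSumstats(ld, tau_m, tau_g, nGwas = 5e4, seed = 400 + s)
    fitPartition(ss, ld, nGwas = 5e4)@proportion
  }, numeric(1))
  expect_lt(abs(median(reps) - 1 / 3), 0.05)
})

test_that("negative component estimates warn and propagate", {
  ld <- synth_ld(300, 60, seed = 9)
  tb <- ldTable(ld)
  chi2 <- 1 - 0.01 * tb$L_mqtl + 0.02 * tb$L_G
  ss <- data.frame(snp_id = tb$snp_id, chi2 = chi2, n = 1e4)
  expect_warning(fit <- fitPartition(ss, ld, nGwas = 1e4), "negative")
  expect_lt(fit@h2[["mQTL"]], 0)
})

test_that("the HLA-style region mask drops SNPs from the fit", {
  ld <- synth_ld(400, 80, seed = 11)
  ss <- simulateGwasSumstats(ld, 1e-5, 1e-5, nGwas = 1e4, seed = 12)
  f_all <- fitPartition(ss, ld, nGwas = 1e4)
  f_mask <- fitPartition(ss, ld, nGwas = 1e4,
                         excludeRegion = "1:1-50000")
  expect_equal(f_all@nSnpsUsed - f_mask@nSnpsUsed, 100)  # pos 500..50000
})
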