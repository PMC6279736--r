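test_that("positional annotation applies the precedence order", {
  gm <- two_tx_model()
  cfg <- annotationConfig(1000)
  ## inside txA's CDS -> Exonic
  expect_equal(as.character(annotatePositions("1", 2000, gm, cfg)), "Exonic")
  ## UTR5 of txA (1000..1499) overlaps the intron of txB (801..4999):
  ## UTR5 outranks Intronic
  expect_equal(as.character(annotatePositions("1", 1200, gm, cfg)), "UTR5")
  ## UTR3 of txA (2801..3000) also sits in txB's intron: UTR3 wins
  expect_equal(as.character(annotatePositions("1", 2900, gm, cfg)), "UTR3")
  ## intron of txB alone
  expect_equal(as.character(annotatePositions("1", 4000, gm, cfg)), "Intronic")
  ## 950 sits between the genes' starts but inside txB's intron
  expect_equal(as.character(annotatePositions("1", 950, gm,
                                              annotationConfig(100))),
               "Intronic")
  ## beyond both transcripts and their short downstream windows
  expect_equal(as.character(annotatePositions("1", 8000, gm,
                                              annotationConfig(100))),
               "Intergenic")
  expect_error(annotatePositions("99", 100, gm, cfg), "unknown chromosome")
})

test_that("positions far from every transcript are intergenic at 2 Mbp", {
  cfg <- simConfig(nIndividuals = c(A = 10), nSnps = 10, nProbes = 0,
                   chromLengths = c(`1` = 1e7), nGenes = 2, seed = 23)
  gm <- simulateGeneModel(cfg)
  tx <- transcripts(gm)
  far <- max(GenomicRanges::end(tx)) + 2e6 + 10
  expect_equal(as.character(annotatePositions("1", far, gm)), "Intergenic")
  ## within 2 Mbp downstream of a + strand transcript -> Downstream
  i <- which(as.character(GenomicRanges::strand(tx)) == "+")[1]
  near <- GenomicRanges::end(tx)[i] + 100
  cat <- as.character(annotatePositions("1", near, gm, annotationConfig(2e6)))
  expect_true(cat %in% c("Downstream", "Upstream", "Intronic", "Exonic",
                         "UTR5", "UTR3", "ncRNA-exonic", "ncRNA-intronic"))
  expect_false(cat == "Intergenic")
})

test_that("category proportions sum to one and recover planted composition", {
  gm <- two_tx_model()
  cfg <- annotationConfig(1000)
  tb <- categoryTable(rep("1", 10), rep(2000, 10), gm, cfg)
  expect_equal(unname(tb$proportions[["Exonic"]]), 1)
  ## planted 30/20/50 sample from known categories
  set.seed(31)
  n <- 1000
  draw <- sample(c("ex", "utr5", "intr"), n, TRUE, prob = c(0.3, 0.2, 0.5))
  pos <- ifelse(draw == "ex", sample(1500:2800, n, TRUE),
                ifelse(draw == "utr5", sample(1000:1499, n, TRUE),
                       sample(3100:4900, n, TRUE)))
  tb2 <- categoryTable(rep("1", n), pos, gm, cfg)
  props <- tb2$proportions
  ci <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(props[["Exonic"]] - 0.3), ci(0.3))
  expect_lt(abs(props[["UTR5"]] - 0.2), ci(0.2))
  expect_lt(abs(props[["Intronic"]] - 0.5), ci(0.5))
  expect_equal(sum(tb2$proportions), 1, tolerance = 1e-12)
})

test_that("category enrichment arithmetic and null behaviour are sound", {
  ## odds-ratio arithmetic on (30, 70, 10, 90)
  m <- matrix(c(30, 70, 10, 90), 2, byrow = TRUE)
  expect_equal((30 * 90) / (70 * 10), 3.857, tolerance = 1e-3)
  gm <- two_tx_model()
  cfg <- annotationConfig(1000)
  set.seed(41)
  bgpos <- sample(1000:6000, 600, TRUE)
  ## identical subset and background: no significant category
  en0 <- categoryEnrichment(rep("1", 300), bgpos[1:300], rep("1", 600), bgpos,
                            gm, cfg)
  expect_false(any(en0$significant))
  expect_true(all(abs(log(en0$odds_ratio)) < 1.5))
})

test_that("a planted upstream excess is flagged at Bonferroni 0.05", {
  cfg <- simConfig(nIndividuals = c(A = 10), nSnps = 10, nProbes = 0,
                   chromLengths = c(`1` = 2e7), nGenes = 20, seed = 47)
  gm <- simulateGeneModel(cfg)
  acfg <- annotationConfig(5e4)
  set.seed(49)
  bg_pos <- sample(2e7, 4000)
  bg_cat <- annotatePositions(rep("1", 4000), bg_pos, gm, acfg)
  ## subset: background plus a doubled share of Upstream positions
  up_pool <- bg_pos[bg_cat == "Upstream"]
  sub_pos <- c(sample(bg_pos, 1500), sample(up_pool, 500, TRUE))
  en <- categoryEnrichment(rep("1", length(sub_pos)), sub_pos,
                           rep("1", 4000), bg_pos, gm, acfg)
  up <- en[en$category == "Upstream", ]
  expect_gt(up$odds_ratio, 1.3)
  expect_true(up$significant)
})
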