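#' Annotation configuration
#'
#' Category set and precedence of the positional annotator. Precedence
#' (highest first): Exonic > UTR5 > UTR3 > ncRNA-exonic > Intronic >
#' ncRNA-intronic > Upstream > Downstream > Intergenic. The
#' upstream/downstream distance defaults to 2 Mbp, aligned with the cis
#' window definition; the conventional short-range value (e.g. 1 kb) can
#' be set for sensitivity checks.
#'
#' @param upstreamDownstreamBp Distance (bp) defining Upstream/Downstream
#'   regions from transcript bounds (strand-aware: Upstream is the 5'
#'   side).
#' @return A list of class `AnnotationConfig`.
#' @export
annotationConfig <- function(upstreamDownstreamBp = 2e6) {
  .assert(upstreamDownstreamBp >= 0, "distance must be non-negative")
  structure(list(upstreamDownstreamBp = upstreamDownstreamBp,
                 categories = .ANNOT_PRECEDENCE),
            class = "AnnotationConfig")
}

.ANNOT_PRECEDENCE <- c("Exonic", "UTR5", "UTR3", "ncRNA-exonic", "Intronic",
                       "ncRNA-intronic", "Upstream", "Downstream",
                       "Intergenic")

## Decompose a gene model into category-labelled features once; annotation
## is then an overlap query plus a precedence reduction.
.annotation_features <- function(model, config) {
  tx <- transcripts(model)
  exl <- exons(model)
  coding <- mcols(tx)$coding
  cs <- mcols(tx)$cds_start; ce <- mcols(tx)$cds_end
  plus <- as.character(strand(tx)) != "-"
  feats <- list()
  add <- function(gr, cat) {
    if (length(gr)) {
      mcols(gr) <- NULL
      gr$category <- cat
      feats[[length(feats) + 1L]] <<- gr
    }
  }
  for (i in seq_along(tx)) {
    e <- exl[[i]]
    intr <- GenomicRanges::setdiff(GRanges(seqnames(tx)[i],
                                           IRanges(start(tx)[i], end(tx)[i])),
                                   e, ignore.strand = TRUE)
    if (coding[i]) {
      cds_rng <- IRanges(cs[i], ce[i])
      ex_ir <- IRanges(start(e), end(e))
      cds_ex <- IRanges::intersect(ex_ir, cds_rng)
      add(GRanges(seqnames(tx)[i], cds_ex), "Exonic")
      left <- IRanges::intersect(ex_ir, IRanges(start(tx)[i], cs[i] - 1L))
      right <- IRanges::intersect(ex_ir, IRanges(ce[i] + 1L, end(tx)[i]))
      add(GRanges(seqnames(tx)[i], left), if (plus[i]) "UTR5" else "UTR3")
      add(GRanges(seqnames(tx)[i], right), if (plus[i]) "UTR3" else "UTR5")
      add(intr, "Intronic")
    } else {
      add(GRanges(seqnames(e), IRanges(start(e), end(e))), "ncRNA-exonic")
      add(intr, "ncRNA-intronic")
    }
  }
  d <- config$upstreamDownstreamBp
  if (d > 0) {
    up_start <- ifelse(plus, pmax(1, start(tx) - d), end(tx) + 1)
    up_end <- ifelse(plus, start(tx) - 1, end(tx) + d)
    dn_start <- ifelse(plus, end(tx) + 1, pmax(1, start(tx) - d))
    dn_end <- ifelse(plus, end(tx) + d, start(tx) - 1)
    okup <- up_end >= up_start; okdn <- dn_end >= dn_start
    add(GRanges(seqnames(tx)[okup], IRanges(up_start[okup], up_end[okup])),
        "Upstream")
    add(GRanges(seqnames(tx)[okdn], IRanges(dn_start[okdn], dn_end[okdn])),
        "Downstream")
  }
  out <- suppressWarnings(do.call(c, feats))
  mcols(out)$rank <- match(mcols(out)$category, .ANNOT_PRECEDENCE)
  out
}

#' Annotate genomic positions by category with precedence
#'
#' Assigns each position a single deterministic category. When transcripts
#' disagree (e.g. UTR5 of one gene, intron of another), the
#' highest-precedence category wins; positions farther than the
#' upstream/downstream distance from every transcript are Intergenic.
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param model A [GeneModel-class].
#' @param config An [annotationConfig()].
#' @return Factor of categories (levels in precedence order).
#' @export
annotatePositions <- function(chrom, pos, model, config = annotationConfig()) {
  known <- unique(as.character(seqnames(transcripts(model))))
  .assert(all(chrom %in% known | chrom %in%
                names(attr(model, "chromLengths") %||% character())),
          "unknown chromosome: %s",
          paste(setdiff(chrom, known), collapse = ","))
  feats <- .annotation_features(model, config)
  q <- GRanges(as.character(chrom), IRanges(pos, width = 1L))
  hits <- findOverlaps(q, feats, ignore.strand = TRUE)
  best <- tapply(mcols(feats)$rank[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits), min)
  cat <- rep("Intergenic", length(q))
  cat[as.integer(names(best))] <- .ANNOT_PRECEDENCE[best]
  factor(cat, levels = .ANNOT_PRECEDENCE)
}

#' Category proportion table
#'
#' Proportions of positions per annotation category (summing to 1 over
#' non-empty categories). Categories under `minReportFraction` are also
#' returned merged into an "other" entry in the `reported` element,
#' mirroring the convention of reporting only categories above 1%.
#'
#' @param chrom,pos Position vectors.
#' @param model A [GeneModel-class].
#' @param config An [annotationConfig()].
#' @param minReportFraction Reporting cutoff (default 0.01).
#' @return List: `counts`, `proportions` (named, all categories), and
#'   `reported` (categories above the cutoff).
#' @export
categoryTable <- function(chrom, pos, model, config = annotationConfig(),
                          minReportFraction = 0.01) {
  .assert(length(pos) > 0, "empty position list")
  cat <- annotatePositions(chrom, pos, model, config)
  counts <- table(cat)
  props <- as.numeric(counts) / sum(counts)
  names(props) <- names(counts)
  rep_mask <- props >= minReportFraction
  list(counts = counts, proportions = props,
       reported = props[rep_mask])
}

#' Category enrichment of a position subset versus background
#'
#' Per-category 2x2 test of subset versus background counts (Pearson
#' chi-square without continuity correction; Fisher's exact test when any
#' expected count is below 5, recorded in the `exact` column), with
#' Bonferroni correction across categories.
#'
#' @param subsetChrom,subsetPos Subset positions.
#' @param bgChrom,bgPos Background positions.
#' @param model A [GeneModel-class].
#' @param config An [annotationConfig()].
#' @return data.frame: category, n_subset, n_background, odds_ratio, p,
#'   p_bonferroni, exact, significant (at Bonferroni 0.05).
#' @export
categoryEnrichment <- function(subsetChrom, subsetPos, bgChrom, bgPos,
                               model, config = annotationConfig()) {
  cs <- annotatePositions(subsetChrom, subsetPos, model, config)
  cb <- annotatePositions(bgChrom, bgPos, model, config)
  ns <- length(cs); nb <- length(cb)
  cats <- .ANNOT_PRECEDENCE[.ANNOT_PRECEDENCE %in%
                              union(levels(droplevels(cs)), levels(droplevels(cb)))]
  cats <- names(which(table(cs)[cats] + table(cb)[cats] > 0))
  rows <- lapply(cats, function(cc) {
    a <- sum(cs == cc); b <- ns - a
    c_ <- sum(cb == cc); d <- nb - c_
    or <- (a * d) / (b * c_)
    m <- matrix(c(a, b, c_, d), 2)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    exact <- any(expected < 5)
    p <- if (exact) stats::fisher.test(m)$p.value
         else suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
    data.frame(category = cc, n_subset = a, n_background = c_,
               odds_ratio = or, p = p, exact = exact)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_bonferroni < 0.05
  out
}
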