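#' Pairwise LD r-squared from dosages
#'
#' Squared Pearson correlation of two SNPs' dosage vectors (composite LD,
#' no phasing required).
#'
#' @param geno A [GenotypeMatrix-class].
#' @param snpJ,snpK SNP ids or row indices.
#' @return r-squared in \[0, 1\].
#' @export
pairwiseR2 <- function(geno, snpJ, snpK) {
  D <- dosages(geno)
  ix <- function(s) if (is.character(s)) match(s, rownames(D)) else s
  x <- D[ix(snpJ), ]; y <- D[ix(snpK), ]
  .assert(stats::var(x, na.rm = TRUE) > 0 && stats::var(y, na.rm = TRUE) > 0,
          "monomorphic SNP: r-squared undefined")
  stats::cor(x, y, use = "complete.obs")^2
}

#' Construct an LDScoreTable directly
#'
#' Low-level constructor used when the per-SNP scores are already known
#' (e.g. simulated score tables); [ldScores()] builds one from genotypes.
#' Without the pairwise `r2`/`adj` structure the table cannot be
#' restratified.
#'
#' @param table data.frame with columns snp_id, chrom, pos, maf, L_total,
#'   L_mqtl, L_G, n_window.
#' @param r2,adj Optional sparse pairwise structure (see
#'   [LDScoreTable-class]).
#' @param nRef Reference-panel sample size.
#' @param windowBp Window width (bp).
#' @param mqtlIds SNP ids of the mQTL component.
#' @return An [LDScoreTable-class].
#' @export
LDScoreTable <- function(table, r2 = NULL, adj = NULL, nRef = NA_integer_,
                         windowBp = 1e6, mqtlIds = character()) {
  obj <- new("LDScoreTable", table = table, r2 = r2, adj = adj,
             nRef = as.integer(nRef), windowBp = windowBp,
             mqtlIds = as.character(mqtlIds))
  validObject(obj)
  obj
}

#' @rdname LDScoreTable
#' @param x An `LDScoreTable`.
#' @export
ldTable <- function(x) x@table

setMethod("show", "LDScoreTable", function(object) {
  tb <- object@table
  cat(sprintf("LDScoreTable: %d SNPs (%d in mQTL component), window %.0f kb, N_ref = %d\n",
              nrow(tb), length(object@mqtlIds), object@windowBp / 1e3,
              object@nRef))
  cat(sprintf("  mean L_total = %.3f (mQTL %.3f + G %.3f)\n",
              mean(tb$L_total), mean(tb$L_mqtl), mean(tb$L_G)))
})

setMethod("as.data.frame", "LDScoreTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)

#' Stratified LD scores from reference genotypes
#'
#' For each SNP j, the LD score over the window centred on it is
#' `L_j = 1 + sum(r2_jk) - n / N`, where the sum runs over the n other
#' SNPs within half the window width of j (the leading 1 is the self
#' term; a SNP exactly at the window edge is included) and N is the
#' reference sample size; the `- n / N` term removes the finite-sample
#' upward bias of squared sample correlations. Scores are stratified into
#' an mQTL component and a rest-of-genome component, each with its own
#' membership indicator and `- n_c / N` correction, so the two components
#' add exactly to the total. The pairwise structure is retained for cheap
#' restratification via [stratifyLdScores()].
#'
#' @param geno Reference [GenotypeMatrix-class] (all SNPs polymorphic).
#' @param windowBp Full window width in bp (default 1 Mbp, i.e. +/-500
#'   kb).
#' @param mqtlIds Character vector of SNP ids forming the mQTL component.
#' @return An [LDScoreTable-class].
#' @examples
#' g <- simulateGenotypes(simConfig(nIndividuals = c(A = 200), nSnps = 50,
#'                                  nProbes = 0, chromLengths = c(`1` = 2e6),
#'                                  seed = 3), "A")
#' ldScores(g, mqtlIds = rownames(g)[1:10])
#' @export
ldScores <- function(geno, windowBp = 1e6, mqtlIds = character()) {
  si <- snpInfo(geno)
  .assert(all(si$maf > 0), "monomorphic SNPs present: filter before ldScores")
  D <- dosages(geno)
  n_ref <- ncol(D)
  half <- windowBp / 2
  m <- nrow(si)
  Z <- D - rowMeans(D)
  sdv <- sqrt(rowSums(Z^2))
  Z <- Z / sdv                 # rows have unit norm; r = Z_j . Z_k
  trip_i <- vector("list", m); trip_j <- vector("list", m)
  trip_x <- vector("list", m)
  for (ch in unique(si$chrom)) {
    idx <- which(si$chrom == ch)
    pos <- si$pos[idx]
    hi <- findInterval(pos + half, pos)
    for (a in seq_along(idx)) {
      if (hi[a] <= a) next
      nb <- idx[(a + 1):hi[a]]
      r <- as.numeric(Z[nb, , drop = FALSE] %*% Z[idx[a], ])
      trip_i[[idx[a]]] <- rep(idx[a], length(nb))
      trip_j[[idx[a]]] <- nb
      trip_x[[idx[a]]] <- r^2
    }
  }
  ti <- unlist(trip_i); tj <- unlist(trip_j); tx <- unlist(trip_x)
  if (length(ti)) {
    r2 <- Matrix::sparseMatrix(i = c(ti, tj), j = c(tj, ti), x = c(tx, tx),
                               dims = c(m, m))
    adj <- Matrix::sparseMatrix(i = c(ti, tj), j = c(tj, ti),
                                x = rep(1, 2 * length(ti)), dims = c(m, m))
  } else {
    r2 <- adj <- Matrix::Matrix(0, m, m, sparse = TRUE)
  }
  obj <- new("LDScoreTable",
             table = data.frame(snp_id = si$snp_id, chrom = si$chrom,
                                pos = si$pos, maf = si$maf,
                                L_total = 0, L_mqtl = 0, L_G = 0,
                                n_window = 0L),
             r2 = r2, adj = adj, nRef = as.integer(n_ref),
             windowBp = windowBp, mqtlIds = character())
  stratifyLdScores(obj, mqtlIds)
}

#' Restratify an LD score table for a new mQTL SNP set
#'
#' Recomputes the mQTL / rest-of-genome components (and the totals) from
#' the stored pairwise structure; used heavily by the resampling null,
#' where every null SNP set needs its own stratification.
#'
#' @param x An [LDScoreTable-class] built by [ldScores()].
#' @param mqtlIds Character vector of SNP ids for the mQTL component.
#' @return A new [LDScoreTable-class].
#' @export
stratifyLdScores <- function(x, mqtlIds) {
  .assert(!is.null(x@r2), "this LDScoreTable has no pairwise structure")
  tb <- x@table
  m <- nrow(tb)
  ind <- as.numeric(tb$snp_id %in% mqtlIds)
  nw <- as.numeric(x@adj %*% rep(1, m))
  nw_m <- as.numeric(x@adj %*% ind)
  sum_r2 <- as.numeric(x@r2 %*% rep(1, m))
  sum_r2_m <- as.numeric(x@r2 %*% ind)
  L_total <- 1 + sum_r2 - nw / x@nRef
  L_m <- ind + sum_r2_m - nw_m / x@nRef
  tb$L_total <- L_total
  tb$L_mqtl <- L_m
  tb$L_G <- L_total - L_m
  tb$n_window <- as.integer(nw)
  new("LDScoreTable", table = tb, r2 = x@r2, adj = x@adj, nRef = x@nRef,
      windowBp = x@windowBp, mqtlIds = as.character(mqtlIds))
}

#' Write an LD score table as TSV
#'
#' @param x An [LDScoreTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLdScores <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x@table), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}
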