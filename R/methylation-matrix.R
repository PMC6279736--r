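#' Construct a MethylationMatrix
#'
#' @param beta Numeric matrix, probes x samples, beta-values in \[0, 1\]
#'   (NA for missing).
#' @param probeInfo data.frame with one row per probe: `probe_id`, `chrom`,
#'   `cpg_pos` (1-based position of the CpG cytosine), and optionally
#'   `probe_start`/`probe_end` (binding-region interval; defaults to the
#'   50 bp ending at the CpG, the typical single-end probe footprint),
#'   `is_cpg` (default TRUE), `multimapping` (default FALSE).
#' @param sampleIds Sample names; defaults to the beta column names.
#' @return A [MethylationMatrix-class].
#' @export
MethylationMatrix <- function(beta, probeInfo, sampleIds = colnames(beta)) {
  beta <- as.matrix(beta)
  .assert(nrow(beta) == nrow(probeInfo), "beta rows (%d) != probeInfo rows (%d)",
          nrow(beta), nrow(probeInfo))
  need <- c("probe_id", "chrom", "cpg_pos")
  .assert(all(need %in% names(probeInfo)), "probeInfo needs columns: %s",
          paste(need, collapse = ", "))
  if (is.null(sampleIds)) sampleIds <- paste0("sample_", seq_len(ncol(beta)))
  if (is.null(probeInfo$probe_start))
    probeInfo$probe_start <- pmax(1L, probeInfo$cpg_pos - 49L)
  if (is.null(probeInfo$probe_end)) probeInfo$probe_end <- probeInfo$cpg_pos
  if (is.null(probeInfo$is_cpg)) probeInfo$is_cpg <- TRUE
  if (is.null(probeInfo$multimapping)) probeInfo$multimapping <- FALSE
  gr <- GRanges(as.character(probeInfo$chrom),
                IRanges(probeInfo$probe_start, probeInfo$probe_end),
                cpg_pos = as.integer(probeInfo$cpg_pos),
                is_cpg = as.logical(probeInfo$is_cpg),
                multimapping = as.logical(probeInfo$multimapping),
                restrict_maf = FALSE)
  names(gr) <- as.character(probeInfo$probe_id)
  dimnames(beta) <- list(names(gr), sampleIds)
  new("MethylationMatrix", SummarizedExperiment(
    assays = SimpleList(beta = beta), rowRanges = gr))
}

#' @rdname MethylationMatrix-class
#' @export
setMethod("betas", "MethylationMatrix", function(x) assay(x, "beta"))

#' @rdname MethylationMatrix-class
#' @export
setMethod("probeInfo", "MethylationMatrix", function(x) {
  data.frame(probe_id = rownames(x),
             chrom = as.character(seqnames(x)),
             cpg_pos = rowData(x)$cpg_pos,
             probe_start = start(x),
             probe_end = end(x),
             is_cpg = rowData(x)$is_cpg,
             multimapping = rowData(x)$multimapping,
             restrict_maf = rowData(x)$restrict_maf,
             row.names = NULL)
})

#' @rdname MethylationMatrix-class
#' @export
setMethod("sampleIds", "MethylationMatrix", function(x) colnames(x))

setMethod("show", "MethylationMatrix", function(object) {
  cat(sprintf("MethylationMatrix: %d probes x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  chromosomes: %s\n", paste(seqlevels(object), collapse = ", ")))
  has_norm <- "normalized" %in% SummarizedExperiment::assayNames(object)
  cat(sprintf("  normalized assay: %s\n", if (has_norm) "yes" else "no"))
})

## Normalized phenotype used for association; falls back to raw logit(beta)
## when normalizeMethylation has not been run.
.phenotypes <- function(meth) {
  if ("normalized" %in% SummarizedExperiment::assayNames(meth))
    assay(meth, "normalized")
  else {
    b <- pmin(pmax(assay(meth, "beta"), 1e-6), 1 - 1e-6)
    .logit(b)
  }
}
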