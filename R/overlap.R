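#' Flag SNPs inside probe binding regions and CpG sites
#'
#' Pure interval geometry, independent of any mQTL result: a probe is
#' flagged `snp_in_probe` when any variant position falls within its
#' binding-region interval (1-based inclusive), and `snp_in_cpg` when any
#' variant falls within the 2-bp CpG dinucleotide (`cpg_pos`,
#' `cpg_pos + 1`). The variant set is typically a dense reference catalogue
#' (it may include rare variants absent from the analysis SNP panel).
#' Probes without interval metadata are flagged NA and excluded from
#' denominators downstream.
#'
#' @param meth A [MethylationMatrix-class] (its rowRanges are the probe
#'   intervals), or a GRanges of probe intervals with `cpg_pos` mcol.
#' @param variants data.frame with `chrom` and `pos` columns (or a GRanges).
#' @return data.frame: probe_id, snp_in_probe, snp_in_cpg.
#' @export
flagProbeSnps <- function(meth, variants) {
  probes <- if (is(meth, "MethylationMatrix")) rowRanges(meth) else meth
  vgr <- if (is(variants, "GRanges")) variants
         else GRanges(as.character(variants$chrom),
                      IRanges(variants$pos, width = 1L))
  in_probe <- IRanges::overlapsAny(probes, vgr)
  cpg <- GRanges(seqnames(probes),
                 IRanges(mcols(probes)$cpg_pos, width = 2L))
  in_cpg <- IRanges::overlapsAny(cpg, vgr)
  unknown <- is.na(start(probes)) | is.na(mcols(probes)$cpg_pos)
  in_probe[unknown] <- NA; in_cpg[unknown] <- NA
  data.frame(probe_id = names(probes), snp_in_probe = in_probe,
             snp_in_cpg = in_cpg, row.names = NULL)
}

#' Probe-SNP overlap accounting
#'
#' Compares the fraction of mQTL probes with a variant in their binding
#' region against the background fraction among probes with no mQTL, the
#' accounting used to bound how many cis mQTL could be measurement
#' artifacts: `attributable = max(0, cis% - background%)`. Flagged mQTL
#' are reported, not removed.
#'
#' @param flags Output of [flagProbeSnps()] covering all probes.
#' @param records Replicated mQTL records (columns `probe_id`, `class`).
#' @param allProbeIds All probes passing QC.
#' @return List of percentages and counts: `background_pct` (probes with
#'   no mQTL), `cis_pct`, `trans_pct`, `cis_cpg_pct` (cis mQTL with a
#'   variant in the CpG itself), `attributable_pct`, and the underlying
#'   counts.
#' @export
overlapSummary <- function(flags, records, allProbeIds) {
  flags <- flags[flags$probe_id %in% allProbeIds & !is.na(flags$snp_in_probe), ]
  cis_probes <- unique(records$probe_id[records$class == "cis"])
  trans_probes <- unique(records$probe_id[records$class == "trans"])
  mqtl_probes <- union(cis_probes, trans_probes)
  bg <- flags[!flags$probe_id %in% mqtl_probes, ]
  pct <- function(x) if (nrow(x) == 0) NA_real_ else 100 * mean(x$snp_in_probe)
  cis <- flags[flags$probe_id %in% cis_probes, ]
  trans <- flags[flags$probe_id %in% trans_probes, ]
  background_pct <- pct(bg); cis_pct <- pct(cis); trans_pct <- pct(trans)
  cis_cpg_pct <- if (nrow(cis)) 100 * mean(cis$snp_in_cpg) else NA_real_
  if (anyNA(c(background_pct)))
    warning("zero denominator: background proportion undefined")
  list(background_pct = background_pct, cis_pct = cis_pct,
       trans_pct = trans_pct, cis_cpg_pct = cis_cpg_pct,
       attributable_pct = if (is.na(cis_pct) || is.na(background_pct))
         NA_real_ else max(0, cis_pct - background_pct),
       n_background = nrow(bg), n_cis = nrow(cis), n_trans = nrow(trans))
}
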