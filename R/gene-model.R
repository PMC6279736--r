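#' Construct a GeneModel
#'
#' @param transcripts GRanges with mcols `tx_id`, `gene_id`, `coding`,
#'   `cds_start`, `cds_end`.
#' @param exons GRangesList named by `tx_id`, parallel to `transcripts`.
#' @return A validated [GeneModel-class].
#' @export
GeneModel <- function(transcripts, exons) {
  mcols(transcripts)$cds_start <- as.integer(mcols(transcripts)$cds_start)
  mcols(transcripts)$cds_end <- as.integer(mcols(transcripts)$cds_end)
  ## normalise exon order within transcript
  exons <- GRangesList(lapply(exons, function(g) g[order(start(g))]))
  names(exons) <- as.character(mcols(transcripts)$tx_id)
  obj <- new("GeneModel", transcripts = transcripts, exons = exons)
  validObject(obj)
  obj
}

#' @rdname GeneModel-class
#' @export
setMethod("transcripts", "GeneModel", function(x) x@transcripts)

#' @rdname GeneModel-class
#' @export
setMethod("exons", "GeneModel", function(x) x@exons)

setMethod("length", "GeneModel", function(x) length(x@transcripts))

setMethod("show", "GeneModel", function(object) {
  tx <- object@transcripts
  cat(sprintf("GeneModel: %d transcripts (%d coding) on %s\n",
              length(tx), sum(mcols(tx)$coding),
              paste(seqlevels(tx), collapse = ", ")))
})

#' Write a gene model as GFF3
#'
#' Emits gene/mRNA (or ncRNA)/exon/CDS features with ID/Parent links, one
#' mRNA per gene, via `rtracklayer`.
#'
#' @param model A [GeneModel-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGeneModelGff3 <- function(model, path) {
  tx <- model@transcripts
  feats <- list()
  mk <- function(gr, type, id, parent = NA_character_, phase = NA_integer_) {
    mcols(gr) <- NULL
    gr$source <- "mqtlkit"
    gr$type <- type
    gr$phase <- phase
    gr$ID <- id
    gr$Parent <- parent
    gr
  }
  txid <- as.character(mcols(tx)$tx_id)
  gid <- as.character(mcols(tx)$gene_id)
  feats$gene <- mk(tx, "gene", gid)
  feats$tx <- mk(tx, ifelse(mcols(tx)$coding, "mRNA", "ncRNA"), txid, gid)
  exs <- unlist(model@exons, use.names = FALSE)
  exparent <- rep(txid, lengths(model@exons))
  feats$exon <- mk(exs, "exon",
                   paste0(exparent, ".exon", unlist(lapply(lengths(model@exons), seq_len))),
                   exparent)
  has_cds <- mcols(tx)$coding & !is.na(mcols(tx)$cds_start)
  if (any(has_cds)) {
    cds <- GRanges(seqnames(tx)[has_cds],
                   IRanges(mcols(tx)$cds_start[has_cds],
                           mcols(tx)$cds_end[has_cds]),
                   strand = strand(tx)[has_cds])
    feats$cds <- mk(cds, "CDS", paste0(txid[has_cds], ".cds"), txid[has_cds],
                    phase = 0L)
  }
  all <- suppressWarnings(do.call(c, unname(feats)))
  rtracklayer::export(sort(all), path, format = "gff3")
  invisible(path)
}

#' Read a gene model from GFF3
#'
#' Expects gene/mRNA or ncRNA transcripts with exon children and optional
#' CDS features, as written by [writeGeneModelGff3()] or any conventional
#' GFF3 gene annotation with those feature types.
#'
#' @param path GFF3 file.
#' @return A [GeneModel-class].
#' @export
readGeneModelGff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  is_tx <- type %in% c("mRNA", "ncRNA", "transcript", "ncRNA_gene")
  txg <- g[is_tx]
  o <- order(match(as.character(seqnames(txg)), unique(as.character(seqnames(txg)))),
             start(txg))
  txg <- txg[o]
  type_tx <- type[is_tx][o]
  txid <- as.character(txg$ID)
  coding <- type_tx == "mRNA"
  parent_of <- function(x) vapply(x$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  exg <- g[type == "exon"]
  expar <- parent_of(exg)
  cdsg <- g[type == "CDS"]
  cdspar <- if (length(cdsg)) parent_of(cdsg) else character()
  cds_s <- cds_e <- rep(NA_integer_, length(txg))
  for (i in seq_along(txg)) {
    hit <- which(cdspar == txid[i])
    if (length(hit)) {
      cds_s[i] <- min(start(cdsg)[hit]); cds_e[i] <- max(end(cdsg)[hit])
    }
  }
  coding <- coding & !is.na(cds_s)
  tx <- GRanges(seqnames(txg), IRanges(start(txg), end(txg)),
                strand = strand(txg), tx_id = txid,
                gene_id = ifelse(is.na(parent_of(txg)), txid, parent_of(txg)),
                coding = coding, cds_start = cds_s, cds_end = cds_e)
  names(tx) <- txid
  ex <- lapply(txid, function(id) {
    e <- exg[which(expar == id)]
    mcols(e) <- NULL
    if (!length(e)) e <- GRanges(seqnames(tx)[match(id, txid)],
                                 IRanges(start(tx)[match(id, txid)],
                                         end(tx)[match(id, txid)]),
                                 strand = strand(tx)[match(id, txid)])
    e
  })
  ex <- GRangesList(ex)
  names(ex) <- txid
  GeneModel(tx, ex)
}

#' Read a gene model from BED12
#'
#' Block fields become exons and the thick interval becomes the CDS
#' (non-coding when the thick interval is empty). BED half-open 0-based
#' coordinates are converted to the 1-based inclusive convention used
#' throughout the package.
#'
#' @param path BED12 file.
#' @return A [GeneModel-class].
#' @export
readGeneModelBed <- function(path) {
  g <- rtracklayer::import(path, format = "bed")
  txid <- if (!is.null(g$name)) as.character(g$name)
          else sprintf("tx_%05d", seq_along(g))
  has_thick <- !is.null(g$thick) & if (!is.null(g$thick))
    width(g$thick) > 1 else FALSE
  cds_s <- rep(NA_integer_, length(g)); cds_e <- rep(NA_integer_, length(g))
  if (!is.null(g$thick)) {
    cds_s[has_thick] <- start(g$thick)[has_thick]
    cds_e[has_thick] <- end(g$thick)[has_thick]
  }
  tx <- GRanges(seqnames(g), IRanges(start(g), end(g)), strand = strand(g),
                tx_id = txid, gene_id = txid, coding = has_thick,
                cds_start = cds_s, cds_end = cds_e)
  names(tx) <- txid
  ex <- if (!is.null(g$blocks)) {
    GRangesList(lapply(seq_along(g), function(i) {
      bl <- g$blocks[[i]]
      GRanges(seqnames(g)[i], IRanges(start(g)[i] + start(bl) - 1L,
                                      start(g)[i] + end(bl) - 1L),
              strand = strand(g)[i])
    }))
  } else {
    GRangesList(lapply(seq_along(g), function(i) {
      e <- g[i]; mcols(e) <- NULL; e
    }))
  }
  names(ex) <- txid
  GeneModel(tx, ex)
}
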