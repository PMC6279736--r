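#' @rdname GenotypeMatrix-class
#' @param x A `GenotypeMatrix`.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname MethylationMatrix-class
#' @param x A `MethylationMatrix`.
#' @export
setGeneric("betas", function(x) standardGeneric("betas"))

#' @rdname MethylationMatrix-class
#' @export
setGeneric("probeInfo", function(x) standardGeneric("probeInfo"))

#' @rdname GeneModel-class
#' @param x A `GeneModel`.
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))

#' @rdname GeneModel-class
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
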