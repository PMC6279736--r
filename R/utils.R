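#' @importFrom stats plogis qlogis
NULL

## logit / inverse-logit on the beta-value scale; clipping is handled by
## callers that need it (normalizeProbe).
.logit <- function(p) qlogis(p)
.invlogit <- function(x) plogis(x)

## Package-internal RNG discipline: every stochastic entry point takes an
## explicit seed and restores the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

## Stage logging: counts in/out for filter audits. Messages are suppressed
## unless options(mqtlkit.verbose = TRUE); counts are always attached to the
## returned object so pipelines can be audited programmatically.
.log_counts <- function(stage, counts) {
  if (isTRUE(getOption("mqtlkit.verbose", FALSE))) {
    message(sprintf("[%s] %s", stage,
                    paste(names(counts), unlist(counts), sep = "=",
                          collapse = ", ")))
  }
  invisible(counts)
}

#' GRCh37 autosome lengths
#'
#' Chromosome lengths (bp) for the 22 human autosomes of the GRCh37/hg19
#' assembly, used as the default genome for subtelomeric-fraction
#' calculations. Sex chromosomes are excluded: the mQTL analyses operate on
#' autosomes only.
#'
#' @return Named numeric vector of 22 chromosome lengths in base pairs.
#' @examples
#' sum(grch37AutosomeLengths())  # ~2.88 Gbp
#' @export
grch37AutosomeLengths <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566)
}
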