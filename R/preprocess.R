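#' Probe QC configuration
#'
#' Bundles the probe-filtering rules: drop sex-chromosome probes, probes
#' annotated as binding multiple chromosomes (via a blacklist or the
#' `multimapping` flag), non-CpG probes, probes with excess missingness,
#' and probes failing detection (p < 0.001) in too many samples. The
#' missingness default (5%) is a configuration value; outlier handling uses
#' the 5-IQR rule (see [removeOutliers()]).
#'
#' @param dropSexChroms,dropMultimapping,dropNonCpg Logical flags.
#' @param maxMissingFraction Maximum fraction of missing beta values.
#' @param maxDetectionFailFraction Maximum fraction of samples with
#'   detection p >= 0.001.
#' @param iqrMultiplier Fence multiplier for the outlier rule.
#' @return A list of class `ProbeQcConfig`.
#' @export
probeQcConfig <- function(dropSexChroms = TRUE, dropMultimapping = TRUE,
                          dropNonCpg = TRUE, maxMissingFraction = 0.05,
                          maxDetectionFailFraction = 0.05,
                          iqrMultiplier = 5) {
  .assert(maxMissingFraction >= 0 && maxMissingFraction <= 1 &&
            maxDetectionFailFraction >= 0 && maxDetectionFailFraction <= 1,
          "fractions must lie in [0, 1]")
  .assert(iqrMultiplier > 0, "iqrMultiplier must be positive")
  structure(list(dropSexChroms = dropSexChroms,
                 dropMultimapping = dropMultimapping,
                 dropNonCpg = dropNonCpg,
                 maxMissingFraction = maxMissingFraction,
                 maxDetectionFailFraction = maxDetectionFailFraction,
                 iqrMultiplier = iqrMultiplier),
            class = "ProbeQcConfig")
}

.SEX_CHROMS <- c("X", "Y", "chrX", "chrY", "23", "24")

#' Filter methylation probes
#'
#' Removes probes on sex chromosomes, blacklisted or multi-mapping probes,
#' non-CpG probes, and probes exceeding the missingness or
#' detection-failure thresholds. Removal counts per reason are attached as
#' `metadata(x)$probe_filter_counts`. Idempotent; an empty result is a
#' warning, not an error.
#'
#' @param meth A [MethylationMatrix-class].
#' @param qc A [probeQcConfig()] list.
#' @param blacklist Character vector of probe ids annotated as binding
#'   multiple chromosomes.
#' @param detectionP Optional matrix of detection p-values (probes x
#'   samples) aligned with `meth`.
#' @return The filtered `MethylationMatrix`.
#' @export
filterProbes <- function(meth, qc = probeQcConfig(), blacklist = character(),
                         detectionP = NULL) {
  pi <- probeInfo(meth)
  reasons <- list(
    sex_chrom = qc$dropSexChroms & pi$chrom %in% .SEX_CHROMS,
    multimapping = qc$dropMultimapping &
      (pi$multimapping | pi$probe_id %in% blacklist),
    non_cpg = qc$dropNonCpg & !pi$is_cpg,
    missingness = rowMeans(is.na(betas(meth))) > qc$maxMissingFraction,
    detection = if (is.null(detectionP)) rep(FALSE, nrow(meth))
                else rowMeans(detectionP >= 0.001, na.rm = TRUE) >
                  qc$maxDetectionFailFraction
  )
  drop <- Reduce(`|`, reasons)
  out <- meth[!drop, ]
  counts <- c(list(n_in = nrow(meth)), lapply(reasons, sum),
              list(n_out = nrow(out)))
  .log_counts("probe-filter", counts)
  metadata(out)$probe_filter_counts <- counts
  if (nrow(out) == 0) warning("no probes remain after filtering")
  out
}

#' Normalize one probe against covariates
#'
#' Beta-values are mapped through the logistic link to the logit
#' (log-odds) scale and covariate effects are removed by linear
#' regression; the returned normalized phenotype is the vector of
#' logit-scale residuals, exactly orthogonal to every covariate column.
#' Values of exactly 0 or 1 are clipped to `[eps, 1 - eps]` first and the
#' clipped count attached as `attr(, "n_clipped")`. Missing values are
#' preserved in place.
#'
#' @param betaRow Numeric vector of beta-values in \[0, 1\].
#' @param covariates Design matrix (samples x covariates) or NULL for an
#'   intercept-only fit (residuals are then the centred logits).
#' @param eps Clipping bound for betas at 0/1 (default 1e-6).
#' @return Numeric vector of residuals, same length and order as
#'   `betaRow`.
#' @examples
#' b <- c(0.2, 0.5, 0.8, 0.4)
#' all.equal(normalizeProbe(b, NULL),
#'           qlogis(b) - mean(qlogis(b)), check.attributes = FALSE)
#' @export
normalizeProbe <- function(betaRow, covariates = NULL, eps = 1e-6) {
  n_clipped <- sum(betaRow <= 0 | betaRow >= 1, na.rm = TRUE)
  b <- pmin(pmax(betaRow, eps), 1 - eps)
  y <- .logit(b)
  ok <- !is.na(y)
  res <- rep(NA_real_, length(y))
  if (is.null(covariates)) {
    res[ok] <- y[ok] - mean(y[ok])
  } else {
    X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
    fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
    res[ok] <- fit$residuals
  }
  if (n_clipped) .log_counts("normalize", list(clipped = n_clipped))
  attr(res, "n_clipped") <- n_clipped
  res
}

#' Normalize a methylation matrix
#'
#' Applies [normalizeProbe()] to every probe using a covariate design built
#' from `colData(meth)`: chip (as factor dummies), chip position, sex, age,
#' age squared, and the sex-by-age interactions. When `group` names a
#' `colData` column, each group of samples is normalized separately and the
#' residuals recombined (the sub-cohort design). The result is stored as a
#' `normalized` assay; sample count and order are preserved.
#'
#' @param meth A [MethylationMatrix-class] whose `colData` carries the
#'   covariates (as produced by [simulateMethylation()]).
#' @param covariates Character vector of `colData` columns to correct for,
#'   or a ready-made design matrix. NULL uses every available column among
#'   chip, position, sex, age (expanding age2 and interactions).
#' @param group Optional `colData` column defining sub-cohorts normalized
#'   individually before combining.
#' @return `meth` with a `normalized` assay added.
#' @export
normalizeMethylation <- function(meth, covariates = NULL, group = NULL) {
  cd <- as.data.frame(colData(meth))
  X <- if (is.matrix(covariates)) covariates else .covariate_design(cd, covariates)
  grp <- if (is.null(group)) rep(1L, ncol(meth)) else cd[[group]]
  b <- betas(meth)
  norm <- matrix(NA_real_, nrow(b), ncol(b), dimnames = dimnames(b))
  for (gv in unique(grp)) {
    j <- which(grp == gv)
    Xg <- X[j, , drop = FALSE]
    if (!is.null(Xg)) Xg <- Xg[, apply(Xg, 2, function(v) stats::var(v) > 0),
                               drop = FALSE]
    for (i in seq_len(nrow(b)))
      norm[i, j] <- normalizeProbe(b[i, j], Xg)
  }
  assay(meth, "normalized", withDimnames = FALSE) <- norm
  meth
}

.covariate_design <- function(cd, covariates = NULL) {
  base <- intersect(c("chip", "position", "sex", "age"), names(cd))
  if (!is.null(covariates)) base <- intersect(covariates, names(cd))
  if (!length(base)) return(NULL)
  parts <- list()
  if ("chip" %in% base && length(unique(cd$chip)) > 1)
    parts$chip <- stats::model.matrix(~ factor(chip), cd)[, -1, drop = FALSE]
  if ("position" %in% base) parts$position <- cbind(position = cd$position)
  if ("sex" %in% base) parts$sex <- cbind(sex = as.numeric(cd$sex))
  if ("age" %in% base) {
    parts$age <- cbind(age = cd$age, age2 = cd$age^2)
    if ("sex" %in% base)
      parts$sex_age <- cbind(sex_age = as.numeric(cd$sex) * cd$age,
                             sex_age2 = as.numeric(cd$sex) * cd$age^2)
  }
  do.call(cbind, parts)
}

#' Flag or remove outlying measurements
#'
#' A value is an outlier iff it lies more than `iqrMultiplier` interquartile
#' ranges beyond its nearest quartile (type-7 quartiles). Two handling
#' modes mirror the two cohorts' rules: `"remove"` sets outliers to NA;
#' `"restrict_maf"` leaves the values untouched but marks the probe for
#' association testing against common SNPs only (MAF > 0.05).
#'
#' @param values Numeric vector (>= 4 non-missing values).
#' @param iqrMultiplier Fence multiplier k: fences are Q1 - k IQR and
#'   Q3 + k IQR (default 5).
#' @param mode `"remove"` or `"restrict_maf"`.
#' @return List with `values` (possibly with outliers set NA), `flags`
#'   (logical outlier indicators), `restrict_maf` (TRUE when mode is
#'   restrict_maf and an outlier was seen), and `degenerate` (TRUE when
#'   IQR = 0 yet values differ).
#' @examples
#' removeOutliers(c(rep(0, 99), 1000))$flags |> sum()  # 1
#' @export
removeOutliers <- function(values, iqrMultiplier = 5,
                           mode = c("remove", "restrict_maf")) {
  mode <- match.arg(mode)
  ok <- !is.na(values)
  .assert(sum(ok) >= 4, "need at least 4 non-missing values")
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - iqrMultiplier * iqr
  hi <- q[2] + iqrMultiplier * iqr
  flags <- !is.na(values) & (values < lo | values > hi)
  degenerate <- iqr == 0 && length(unique(values[ok])) > 1
  out <- values
  if (mode == "remove") out[flags] <- NA_real_
  list(values = out, flags = flags,
       restrict_maf = mode == "restrict_maf" && any(flags),
       degenerate = degenerate)
}

#' Apply outlier handling to a methylation matrix
#'
#' Runs [removeOutliers()] on the normalized (or raw logit) values of every
#' probe. In `"remove"` mode outliers become NA in both the beta and
#' normalized assays; in `"restrict_maf"` mode affected probes get
#' `rowData(meth)$restrict_maf = TRUE`, which the scan honours by testing
#' those probes against MAF > 0.05 SNPs only.
#'
#' @inheritParams removeOutliers
#' @param meth A [MethylationMatrix-class].
#' @return The updated `MethylationMatrix`; outlier counts in
#'   `metadata()$outlier_counts`.
#' @export
handleOutliers <- function(meth, iqrMultiplier = 5,
                           mode = c("remove", "restrict_maf")) {
  mode <- match.arg(mode)
  vals <- .phenotypes(meth)
  nflag <- 0L
  for (i in seq_len(nrow(meth))) {
    r <- removeOutliers(vals[i, ], iqrMultiplier, mode)
    if (any(r$flags)) {
      nflag <- nflag + sum(r$flags)
      if (mode == "remove") {
        assay(meth, "beta")[i, r$flags] <- NA_real_
        if ("normalized" %in% SummarizedExperiment::assayNames(meth))
          assay(meth, "normalized")[i, r$flags] <- NA_real_
      } else {
        rowData(meth)$restrict_maf[i] <- TRUE
      }
    }
  }
  counts <- list(n_outliers = nflag,
                 n_restricted = sum(rowData(meth)$restrict_maf))
  .log_counts("outliers", counts)
  metadata(meth)$outlier_counts <- counts
  meth
}
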