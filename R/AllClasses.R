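#' @import methods
NULL

GWAS_COLUMNS <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Container for GWAS summary statistics
#'
#' One row per SNP: identifier, chromosome, 1-based position, effect and
#' other allele (single bases A/C/G/T), effect-allele frequency (may be
#' missing), per-allele effect estimate, its standard error, p-value and
#' sample size. Effects are in SD units for quantitative traits
#' (`effectScale = "sd"`) or log odds ratios for binary traits
#' (`effectScale = "logor"`).
#'
#' @slot data data.frame with the canonical columns `snp`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @slot trait character(1) trait label.
#' @slot effectScale `"sd"` or `"logor"`.
#' @export
setClass("GwasSummaryStats",
  representation(data = "data.frame", trait = "character",
                 effectScale = "character"),
  prototype(trait = "trait", effectScale = "sd"))

validateGwasRows <- function(d) {
  problems <- character(0)
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      problems <<- c(problems,
        sprintf("%s at row(s) %s", what, paste(utils::head(idx, 10), collapse = ", ")))
  }
  bad(!(d$effect_allele %in% VALID_ALLELES), "invalid effect_allele (must be A/C/G/T)")
  bad(!(d$other_allele %in% VALID_ALLELES), "invalid other_allele (must be A/C/G/T)")
  bad(d$effect_allele == d$other_allele, "effect_allele equals other_allele")
  bad(!is.finite(d$se) | d$se <= 0, "se must be > 0")
  bad(!is.finite(d$beta), "beta must be finite")
  bad(!is.finite(d$pval) | d$pval <= 0 | d$pval > 1, "pval must be in (0, 1]")
  bad(!is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1), "eaf must be in [0, 1]")
  bad(!is.finite(d$pos) | d$pos < 1, "pos must be >= 1")
  bad(!is.finite(d$n) | d$n < 1, "n must be a positive integer")
  bad(duplicated(d$snp), "duplicated snp identifier")
  problems
}

setValidity("GwasSummaryStats", function(object) {
  d <- object@data
  missing_cols <- setdiff(GWAS_COLUMNS, names(d))
  if (length(missing_cols))
    return(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (length(object@trait) != 1L) return("trait must be a single string")
  if (!object@effectScale %in% c("sd", "logor"))
    return("effectScale must be 'sd' or 'logor'")
  problems <- validateGwasRows(d)
  if (length(problems)) return(paste(problems, collapse = "; "))
  TRUE
})

#' Harmonized exposure/outcome instrument set
#'
#' The exposure and outcome associations of the intersecting SNPs placed on
#' a shared effect allele. Every intersecting SNP appears exactly once with
#' its harmonization action (`kept`, `flipped` or `dropped`); dropped rows
#' never enter the estimators.
#'
#' @slot data data.frame with columns `snp`, `effect_allele`, `other_allele`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_exposure`, `eaf_outcome`, `palindromic`, `action`, `reason`.
#' @slot exposure,outcome trait labels.
#' @slot outcomeScale effect scale of the outcome trait (`"sd"` or `"logor"`).
#' @export
setClass("HarmonizedInstruments",
  representation(data = "data.frame", exposure = "character",
                 outcome = "character", outcomeScale = "character"),
  prototype(exposure = "exposure", outcome = "outcome", outcomeScale = "sd"))

setValidity("HarmonizedInstruments", function(object) {
  d <- object@data
  need <- c("snp", "beta_exposure", "se_exposure", "beta_outcome",
            "se_outcome", "palindromic", "action")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    return(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (!all(d$action %in% c("kept", "flipped", "dropped")))
    return("action must be kept/flipped/dropped")
  live <- d$action != "dropped"
  if (any(live & (!is.finite(d$se_exposure) | d$se_exposure <= 0)))
    return("se_exposure must be > 0 for retained instruments")
  if (any(live & (!is.finite(d$se_outcome) | d$se_outcome <= 0)))
    return("se_outcome must be > 0 for retained instruments")
  TRUE
})

#' A single causal-effect estimate
#'
#' @slot method one of `"IVW-fixed"`, `"IVW-random"`, `"Egger"`,
#'   `"WeightedMedian"`, `"WaldRatio"`.
#' @slot beta,se point estimate and standard error.
#' @slot ciLow,ciHigh 95\% Wald interval (multiplier 1.959964).
#' @slot pval two-sided p-value.
#' @slot nSnps number of instruments used.
#' @slot scale effect-scale note (`"per 1 SD exposure"` or `"log-OR"`).
#' @slot extra list of method-specific quantities (e.g. the Cochran Q used
#'   by the fixed/random switch).
#' @export
setClass("MrEstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
                 nSnps = "integer", scale = "character", extra = "list"),
  prototype(method = "IVW-fixed", beta = NA_real_, se = NA_real_,
            ciLow = NA_real_, ciHigh = NA_real_, pval = NA_real_,
            nSnps = 0L, scale = "per 1 SD exposure", extra = list()))

setValidity("MrEstimate", function(object) {
  if (!is.na(object@beta) &&
      (object@ciLow > object@beta || object@beta > object@ciHigh))
    return("ciLow <= beta <= ciHigh violated")
  if (!is.na(object@pval) && (object@pval <= 0 || object@pval > 1))
    return("pval must be in (0, 1]")
  TRUE
})

#' MR-Egger intercept test
#' @slot estimate,se intercept and its standard error.
#' @slot pval two-sided p-value from the t distribution with J-2 df.
#' @export
setClass("EggerIntercept",
  representation(estimate = "numeric", se = "numeric", pval = "numeric"))

#' MR-Egger fit: slope estimate plus intercept test
#' @slot slope [MrEstimate] for the causal slope.
#' @slot intercept [EggerIntercept].
#' @slot q [QResult] residual heterogeneity about the Egger fit.
#' @export
setClass("EggerFit",
  representation(slope = "MrEstimate", intercept = "EggerIntercept",
                 q = "ANY"))

#' Cochran heterogeneity statistic
#' @slot Q weighted heterogeneity statistic, >= 0.
#' @slot df J-1 (IVW) or J-2 (Egger).
#' @slot pval upper-tail chi-square p-value.
#' @slot model `"ivw"` or `"egger"`.
#' @export
setClass("QResult",
  representation(Q = "numeric", df = "integer", pval = "numeric",
                 model = "character"))

setValidity("QResult", function(object) {
  if (object@Q < -1e-12) return("Q must be >= 0")
  if (object@pval <= 0 || object@pval > 1) return("pval must be in (0, 1]")
  TRUE
})

setClassUnion("MrEstimateOrNULL", c("MrEstimate", "NULL"))

#' MR-PRESSO residual-sum and outlier test result
#'
#' @slot rssObs observed global weighted residual sum of squares.
#' @slot globalPval empirical global p-value, in [1/(nSim+1), 1].
#' @slot outlierPvals named per-SNP Bonferroni-adjusted empirical p-values.
#' @slot outliers SNP ids flagged at the outlier alpha.
#' @slot corrected IVW re-fit on the non-outlier subset, or NULL when no
#'   outlier was flagged.
#' @slot nSim,seed simulation size and seed (reproducibility contract).
#' @slot distortion the distortion test is not computed; always the string
#'   `"not computed"`.
#' @export
setClass("PressoResult",
  representation(rssObs = "numeric", globalPval = "numeric",
                 outlierPvals = "numeric", outliers = "character",
                 corrected = "MrEstimateOrNULL", nSim = "integer",
                 seed = "integer", distortion = "character"),
  prototype(distortion = "not computed"))

setValidity("PressoResult", function(object) {
  lo <- 1 / (object@nSim + 1)
  if (object@globalPval < lo - 1e-12 || object@globalPval > 1)
    return("globalPval outside [1/(nSim+1), 1]")
  if (!all(object@outliers %in% names(object@outlierPvals)))
    return("outliers must be a subset of the instrument set")
  TRUE
})

setClassUnion("PressoOrNULL", c("PressoResult", "NULL"))
setClassUnion("EggerFitOrNULL", c("EggerFit", "NULL"))
setClassUnion("QResultOrNULL", c("QResult", "NULL"))

#' Sensitivity diagnostics for one exposure-outcome pair
#'
#' @slot qIvw Cochran Q about the IVW fit.
#' @slot qEgger residual Q about the Egger fit (NULL when J < 3).
#' @slot egger the Egger fit used for the intercept test (NULL when J < 3).
#' @slot presso [PressoResult] (NULL when J < 4 or disabled).
#' @slot leaveOneOut data.frame of leave-one-out IVW estimates (empty when
#'   J < 3); column `influential` flags drops moving the estimate by more
#'   than one full-sample SE.
#' @export
setClass("SensitivityReport",
  representation(qIvw = "QResultOrNULL", qEgger = "QResultOrNULL",
                 egger = "EggerFitOrNULL", presso = "PressoOrNULL",
                 leaveOneOut = "data.frame"))

#' One exposure-outcome pair of the bidirectional screen
#'
#' @slot direction `"forward"` (panel trait -> disease) or `"reverse"`.
#' @slot exposure,outcome trait labels.
#' @slot instruments the [HarmonizedInstruments] the estimates used.
#' @slot estimates named list of [MrEstimate] / [EggerFit] objects.
#' @slot sensitivity [SensitivityReport] or NULL.
#' @slot pvalIvw primary IVW (mode auto) p-value entering the FDR family.
#' @slot pvalFdr Benjamini-Hochberg adjusted p-value over the family.
#' @export
setClass("ScreenResult",
  representation(direction = "character", exposure = "character",
                 outcome = "character", instruments = "ANY",
                 estimates = "list", sensitivity = "ANY",
                 pvalIvw = "numeric", pvalFdr = "numeric"))

#' Assembled screen across a trait panel
#'
#' @slot results list of [ScreenResult], one per panel trait.
#' @slot summary tidy data.frame (one row per trait and method).
#' @slot direction screen direction.
#' @slot config resolved configuration list.
#' @export
setClass("MrScreen",
  representation(results = "list", summary = "data.frame",
                 direction = "character", config = "list"))
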