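scaleNote <- function(x) {
  if (is(x, "HarmonizedInstruments") && x@outcomeScale == "logor")
    "log-OR" else "per 1 SD exposure"
}

#' Per-instrument Wald ratio estimates
#'
#' The causal effect of each instrument is the ratio of the outcome to the
#' exposure association, `ratio = beta_outcome / beta_exposure`, with the
#' first-order delta standard error `se_outcome / |beta_exposure|` and
#' inverse-variance weight `se^-2`.
#'
#' @param instruments [HarmonizedInstruments-class]; every retained
#'   exposure beta must be non-zero.
#' @param secondOrder when TRUE, use the second-order delta SE that also
#'   propagates the exposure SE:
#'   `sqrt(se_out^2/g^2 + beta_out^2 * se_exp^2 / g^4)`.
#' @return data.frame with columns `snp`, `ratio`, `se`, `weight`.
#' @export
waldRatios <- function(instruments, secondOrder = FALSE) {
  d <- instrumentData(instruments)
  zero <- d$snp[d$beta_exposure == 0]
  if (length(zero))
    validationError("exposure beta is zero for SNP(s): %s (Wald ratio undefined)",
                    paste(zero, collapse = ", "))
  ratio <- d$beta_outcome / d$beta_exposure
  se <- if (secondOrder) {
    sqrt(d$se_outcome^2 / d$beta_exposure^2 +
           d$beta_outcome^2 * d$se_exposure^2 / d$beta_exposure^4)
  } else {
    d$se_outcome / abs(d$beta_exposure)
  }
  data.frame(snp = d$snp, ratio = ratio, se = se, weight = se^-2,
             stringsAsFactors = FALSE)
}

ivwCore <- function(ratio, weight) {
  beta <- sum(weight * ratio) / sum(weight)
  se <- sqrt(1 / sum(weight))
  Q <- sum(weight * (ratio - beta)^2)
  list(beta = beta, se = se, Q = Q)
}

#' Inverse-variance-weighted causal estimate
#'
#' The fixed-effect estimate is the inverse-variance-weighted mean of the
#' Wald ratios, `beta = sum(w_j b_j) / sum(w_j)` with `w_j` the ratio
#' weights and `se = sum(w_j)^-1/2`. The random-effects variant applies
#' multiplicative overdispersion, scaling the SE by
#' `max(1, sqrt(Q / (J - 1)))`, and never deflates below the fixed-effect
#' SE. Mode `"auto"` applies the heterogeneity switch: random effects when
#' the Cochran Q p-value is below `qAlpha`, fixed effects otherwise.
#' P-values are two-sided normal.
#'
#' A single instrument degenerates to its Wald ratio (with a warning);
#' zero instruments yield a structured empty estimate with a warning.
#'
#' @param instruments [HarmonizedInstruments-class].
#' @param mode `"auto"` (default), `"fixed"` or `"random"`.
#' @param qAlpha heterogeneity switch level for mode `"auto"` (default 0.05).
#' @return [MrEstimate-class]; `extra` carries the Q statistic, its df and
#'   p-value, and the overdispersion factor applied.
#' @export
mrIvw <- function(instruments, mode = c("auto", "fixed", "random"),
                  qAlpha = 0.05) {
  mode <- match.arg(mode)
  scale <- scaleNote(instruments)
  J <- nInstruments(instruments)
  if (J == 0) {
    warning("no instruments: returning an empty IVW estimate", call. = FALSE)
    return(new("MrEstimate", method = "IVW-fixed", nSnps = 0L,
               scale = scale))
  }
  r <- waldRatios(instruments)
  if (J == 1) {
    warning("single instrument: IVW degenerates to its Wald ratio",
            call. = FALSE)
    return(newMrEstimate("IVW-fixed", r$ratio, r$se, 1L, scale,
                         extra = list(Q = 0, Q_df = 0L, Q_pval = NA_real_,
                                      dispersion = 1)))
  }
  fit <- ivwCore(r$ratio, r$weight)
  q_df <- J - 1L
  q_pval <- stats::pchisq(fit$Q, df = q_df, lower.tail = FALSE)
  use_random <- switch(mode,
    fixed = FALSE,
    random = TRUE,
    auto = q_pval < qAlpha)
  dispersion <- if (use_random) max(1, sqrt(fit$Q / q_df)) else 1
  method <- if (use_random) "IVW-random" else "IVW-fixed"
  newMrEstimate(method, fit$beta, fit$se * dispersion, J, scale,
                extra = list(Q = fit$Q, Q_df = q_df, Q_pval = q_pval,
                             dispersion = dispersion))
}

eggerDesign <- function(instruments) {
  d <- instrumentData(instruments)
  flip <- d$beta_exposure < 0
  g <- ifelse(flip, -d$beta_exposure, d$beta_exposure)
  y <- ifelse(flip, -d$beta_outcome, d$beta_outcome)
  list(g = g, y = y, w = d$se_outcome^-2, snp = d$snp)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome associations on the exposure
#' associations with a free intercept, weights `se_outcome^-2`, after
#' orienting every instrument to a non-negative exposure beta (both betas
#' negated when the exposure beta is negative, so the fit is invariant to
#' allele orientation). The intercept estimates the average directional
#' pleiotropic effect; the slope is the causal estimate. Standard errors
#' are inflated by `max(1, sqrt(Q / (J - 2)))` and p-values use the t
#' distribution with `J - 2` degrees of freedom.
#'
#' @param instruments [HarmonizedInstruments-class] with at least 3
#'   retained instruments.
#' @return [EggerFit-class] holding the slope [MrEstimate-class], the
#'   [EggerIntercept-class] test and the residual [QResult-class].
#' @export
mrEgger <- function(instruments) {
  J <- nInstruments(instruments)
  if (J < 3)
    validationError("MR-Egger requires at least 3 instruments, got %d", J)
  dd <- eggerDesign(instruments)
  X <- cbind(intercept = 1, slope = dd$g)
  XtW <- t(X * dd$w)
  covU <- solve(XtW %*% X)
  coefs <- drop(covU %*% (XtW %*% dd$y))
  fitted <- drop(X %*% coefs)
  Q <- sum(dd$w * (dd$y - fitted)^2)
  df <- J - 2L
  inflation <- max(1, sqrt(Q / df))
  ses <- sqrt(diag(covU)) * inflation
  q <- new("QResult", Q = Q, df = df,
           pval = max(stats::pchisq(Q, df = df, lower.tail = FALSE),
                      .Machine$double.xmin),
           model = "egger")
  slope <- newMrEstimate("Egger", coefs[["slope"]], ses[["slope"]], J,
                         scaleNote(instruments), df = df,
                         extra = list(Q = Q, Q_df = df, Q_pval = q@pval))
  tcpt <- coefs[["intercept"]] / ses[["intercept"]]
  intercept <- new("EggerIntercept", estimate = coefs[["intercept"]],
                   se = ses[["intercept"]],
                   pval = pmax(2 * stats::pt(-abs(tcpt), df = df),
                               .Machine$double.xmin))
  new("EggerFit", slope = slope, intercept = intercept, q = q)
}

weightedMedianCore <- function(ratio, weight) {
  ord <- order(ratio)
  b <- ratio[ord]
  w <- weight[ord] / sum(weight)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(b[1])
  if (cum[length(cum)] < 0.5) return(b[length(b)])
  below <- max(which(cum < 0.5))
  b[below] + (b[below + 1] - b[below]) *
    (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

#' Weighted median causal estimate
#'
#' The estimate at the 50% point of the Wald ratios ordered by value and
#' weighted by inverse variance: cumulative standardized weights are
#' interpolated linearly at the 0.5 crossing. Consistent when less than
#' half the total weight comes from invalid instruments. The standard
#' error is a parametric bootstrap: each ratio is redrawn from a normal
#' centred on its estimate with its delta SE, the weighted median is
#' recomputed, and the SD over replicates is the SE. The p-value is
#' two-sided normal.
#'
#' @param instruments [HarmonizedInstruments-class] with at least 3
#'   retained instruments.
#' @param nBoot bootstrap replicates (default 1000; below 100 triggers a
#'   warning).
#' @param seed integer seed for the bootstrap; omitting it in pipeline use
#'   breaks reproducibility, so `NULL` triggers a warning.
#' @return [MrEstimate-class] with method `"WeightedMedian"`.
#' @export
mrWeightedMedian <- function(instruments, nBoot = 1000, seed = NULL) {
  J <- nInstruments(instruments)
  if (J < 3)
    validationError("weighted median requires at least 3 instruments, got %d", J)
  if (nBoot < 100)
    warning("nBoot below 100 gives an unstable bootstrap SE", call. = FALSE)
  if (is.null(seed))
    warning("no seed supplied: weighted-median bootstrap is not reproducible",
            call. = FALSE)
  r <- waldRatios(instruments)
  est <- weightedMedianCore(r$ratio, r$weight)
  boots <- withSeedIfGiven(seed, {
    vapply(seq_len(nBoot), function(i) {
      weightedMedianCore(stats::rnorm(J, r$ratio, r$se), r$weight)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  newMrEstimate("WeightedMedian", est, se, J, scaleNote(instruments),
                extra = list(nBoot = nBoot, seed = seed))
}

#' Render a log-OR estimate on the odds-ratio scale
#'
#' `OR = exp(beta)` with 95\% CI `exp(beta +/- 1.959964 * se)`, and a label
#' rendered at 3 decimals in the form `"1.115 (1.024–1.215)"`.
#'
#' @param est [MrEstimate-class] on the log-OR scale.
#' @return list with `or`, `ciLow`, `ciHigh`, `label`.
#' @export
toOddsRatio <- function(est) {
  stopifnot(is(est, "MrEstimate"))
  or <- exp(est@beta)
  lo <- exp(est@beta - Z95 * est@se)
  hi <- exp(est@beta + Z95 * est@se)
  list(or = or, ciLow = lo, ciHigh = hi,
       label = fmtEstimateCi(or, lo, hi))
}
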