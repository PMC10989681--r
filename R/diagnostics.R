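#' Cochran heterogeneity statistic about a fitted causal model
#'
#' For the IVW model, `Q = sum(w_j * (ratio_j - slope)^2)` with the Wald
#' ratio weights and `J - 1` degrees of freedom. For the Egger model the
#' statistic is computed on the outcome scale,
#' `Q = sum(w_j * (beta_out_j - (intercept + slope * beta_exp_j))^2)` with
#' weights `se_outcome^-2` on orientation-corrected betas and `J - 2`
#' degrees of freedom. The p-value is the upper chi-square tail.
#'
#' @param instruments [HarmonizedInstruments-class].
#' @param slope fitted causal slope.
#' @param model `"ivw"` (default) or `"egger"`.
#' @param intercept Egger intercept (ignored for `"ivw"`).
#' @return [QResult-class].
#' @export
cochranQ <- function(instruments, slope, model = c("ivw", "egger"),
                     intercept = 0) {
  model <- match.arg(model)
  J <- nInstruments(instruments)
  df <- J - switch(model, ivw = 1L, egger = 2L)
  if (df <= 0)
    validationError("Cochran Q undefined: %d instruments leave %d df", J, df)
  if (model == "ivw") {
    r <- waldRatios(instruments)
    Q <- sum(r$weight * (r$ratio - slope)^2)
  } else {
    dd <- eggerDesign(instruments)
    Q <- sum(dd$w * (dd$y - (intercept + slope * dd$g))^2)
  }
  new("QResult", Q = Q, df = df,
      pval = max(stats::pchisq(Q, df = df, lower.tail = FALSE),
                 .Machine$double.xmin),
      model = model)
}

# Leave-one-out IVW slopes for every instrument, vectorized.
looSlopes <- function(ratio, weight) {
  (sum(weight * ratio) - weight * ratio) / (sum(weight) - weight)
}

#' Leave-one-out sensitivity series
#'
#' Drops each instrument in turn and re-estimates the causal effect by IVW
#' (mode auto) on the remainder; an entry whose estimate moves by more than
#' one full-sample SE from the all-instrument fit is flagged influential.
#'
#' @param instruments [HarmonizedInstruments-class] with at least 3
#'   retained instruments (so every remainder has at least 2).
#' @return data.frame with one row per dropped SNP: `snp_dropped`, `method`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pval`, `influential`.
#' @export
leaveOneOut <- function(instruments) {
  J <- nInstruments(instruments)
  if (J < 3)
    validationError("leave-one-out requires at least 3 instruments, got %d", J)
  d <- instrumentData(instruments)
  full <- suppressWarnings(mrIvw(instruments, mode = "auto"))
  rows <- lapply(seq_len(J), function(j) {
    sub <- HarmonizedInstruments(d[-j, , drop = FALSE],
                                 exposure = instruments@exposure,
                                 outcome = instruments@outcome,
                                 outcomeScale = instruments@outcomeScale)
    est <- suppressWarnings(mrIvw(sub, mode = "auto"))
    data.frame(snp_dropped = d$snp[j], method = est@method,
               beta = est@beta, se = est@se, ci_low = est@ciLow,
               ci_high = est@ciHigh, pval = est@pval,
               influential = abs(est@beta - full@beta) > full@se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MR-PRESSO global residual-sum and per-variant outlier test
#'
#' The observed global statistic is the outcome-weighted residual sum of
#' squares about the leave-one-out IVW prediction,
#' `RSS = sum_j w_j * (beta_out_j - slope_(-j) * beta_exp_j)^2` with
#' `w_j = se_outcome^-2` and `slope_(-j)` the IVW slope excluding SNP j.
#' Its null distribution is built by parametric simulation: exposure betas
#' are redrawn around their estimates and outcome betas around the
#' leave-one-out predictions, each with the observed SEs; the same
#' statistic is recomputed on every replicate. The global p-value is the
#' empirical upper tail with the +1 correction `(r + 1) / (nSim + 1)`.
#' Each SNP's weighted residual is compared against its own simulated tail
#' and Bonferroni-adjusted by J; SNPs below `outlierAlpha` are removed and
#' the corrected estimate is the IVW (mode auto) re-fit on the remainder.
#' The distortion test is not computed.
#'
#' @param instruments [HarmonizedInstruments-class] with at least 4
#'   retained instruments.
#' @param nSim simulation replicates for the empirical null (default 1000).
#' @param seed integer seed; required for reproducible p-values.
#' @param outlierAlpha per-SNP outlier level after Bonferroni (default 0.05).
#' @return [PressoResult-class].
#' @export
mrPresso <- function(instruments, nSim = 1000, seed = NULL,
                     outlierAlpha = 0.05) {
  J <- nInstruments(instruments)
  if (J < 4)
    validationError("insufficient instruments for MR-PRESSO (need >= 4, got %d)", J)
  d <- instrumentData(instruments)
  r <- waldRatios(instruments)
  w_out <- d$se_outcome^-2
  slope_loo <- looSlopes(r$ratio, r$weight)
  res_obs <- w_out * (d$beta_outcome - slope_loo * d$beta_exposure)^2
  rss_obs <- sum(res_obs)

  sim <- withSeedIfGiven(seed, {
    # nSim x J matrices; each row one simulated dataset under the no-outlier null
    g_star <- matrix(stats::rnorm(nSim * J, mean = rep(d$beta_exposure, each = nSim),
                                  sd = rep(d$se_exposure, each = nSim)),
                     nrow = nSim)
    y_star <- matrix(stats::rnorm(nSim * J, mean = rep(slope_loo * d$beta_exposure, each = nSim),
                                  sd = rep(d$se_outcome, each = nSim)),
                     nrow = nSim)
    ratio_star <- y_star / g_star
    w_star <- sweep(g_star^2, 2, d$se_outcome^2, "/")
    sw <- rowSums(w_star)
    swb <- rowSums(w_star * ratio_star)
    slope_star <- (swb - w_star * ratio_star) / (sw - w_star)  # leave-one-out
    res_star <- sweep((y_star - slope_star * g_star)^2, 2, d$se_outcome^2, "/")
    list(rss = rowSums(res_star), res = res_star)
  })

  global_pval <- (sum(sim$rss >= rss_obs) + 1) / (nSim + 1)
  per_snp <- (colSums(sim$res >= rep(res_obs, each = nSim)) + 1) / (nSim + 1)
  outlier_pvals <- pmin(per_snp * J, 1)
  names(outlier_pvals) <- d$snp
  outliers <- d$snp[outlier_pvals < outlierAlpha]

  corrected <- NULL
  if (length(outliers) && length(outliers) < J - 1) {
    sub <- HarmonizedInstruments(d[!d$snp %in% outliers, , drop = FALSE],
                                 exposure = instruments@exposure,
                                 outcome = instruments@outcome,
                                 outcomeScale = instruments@outcomeScale)
    corrected <- suppressWarnings(mrIvw(sub, mode = "auto"))
  }
  new("PressoResult", rssObs = rss_obs, globalPval = global_pval,
      outlierPvals = outlier_pvals, outliers = outliers,
      corrected = corrected, nSim = as.integer(nSim),
      seed = as.integer(seed %||% NA_integer_), distortion = "not computed")
}

#' Assemble the full sensitivity report for one instrument set
#'
#' Bundles the IVW Cochran Q, the Egger residual Q and intercept test
#' (when J >= 3), MR-PRESSO (when J >= 4 and enabled) and the leave-one-out
#' series (when J >= 3).
#'
#' @param instruments [HarmonizedInstruments-class].
#' @param nSim,seed,outlierAlpha passed to [mrPresso()].
#' @param presso set FALSE to skip the PRESSO simulation.
#' @return [SensitivityReport-class].
#' @export
sensitivityReport <- function(instruments, nSim = 1000, seed = NULL,
                              outlierAlpha = 0.05, presso = TRUE) {
  J <- nInstruments(instruments)
  ivw <- suppressWarnings(mrIvw(instruments, mode = "fixed"))
  qIvw <- if (J >= 2) cochranQ(instruments, ivw@beta, "ivw") else NULL
  egger <- NULL; qEgger <- NULL
  if (J >= 3) {
    egger <- mrEgger(instruments)
    qEgger <- egger@q
  }
  pres <- if (presso && J >= 4)
    mrPresso(instruments, nSim = nSim, seed = seed,
             outlierAlpha = outlierAlpha) else NULL
  loo <- if (J >= 3) leaveOneOut(instruments) else
    data.frame(snp_dropped = character(0))
  new("SensitivityReport", qIvw = qIvw, qEgger = qEgger, egger = egger,
      presso = pres, leaveOneOut = loo)
}
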