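# Builders for small in-code fixtures used across the suite.

# A GwasSummaryStats from minimal inputs, defaulting the bookkeeping columns.
makeGwas <- function(snp, beta, se, pval = NULL, eaf = 0.3,
                     effect_allele = "A", other_allele = "G",
                     chrom = "1", pos = NULL, n = 5000,
                     trait = "trait", effectScale = "sd") {
  k <- length(snp)
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  if (is.null(pos)) pos <- seq_len(k) * 2e7
  GwasSummaryStats(data.frame(
    snp = snp, chrom = rep_len(chrom, k), pos = pos,
    effect_allele = rep_len(effect_allele, k),
    other_allele = rep_len(other_allele, k),
    eaf = rep_len(eaf, k), beta = beta, se = se, pval = pval,
    n = rep_len(n, k), stringsAsFactors = FALSE),
    trait = trait, effectScale = effectScale)
}

# Harmonized instruments directly from the four association vectors.
toyInstruments <- function(beta_exposure, se_exposure, beta_outcome,
                           se_outcome, outcomeScale = "sd") {
  J <- length(beta_exposure)
  HarmonizedInstruments(data.frame(
    snp = sprintf("rs%03d", seq_len(J)),
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    stringsAsFactors = FALSE), outcomeScale = outcomeScale)
}

# Instruments whose Wald ratios and ratio SEs are exactly as requested
# (unit exposure betas, negligible exposure SE).
ratioInstruments <- function(ratios, ses, outcomeScale = "sd") {
  toyInstruments(rep(1, length(ratios)), rep(1e-6, length(ratios)),
                 ratios, ses, outcomeScale = outcomeScale)
}

writeGwasTsv <- function(df, path = withr::local_tempfile(fileext = ".tsv",
                                                          .local_envir = parent.frame())) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent weighted-median oracle: build the piecewise-linear weighted
# CDF W(m) and root-find W(m) = 0.5, instead of interpolating the quantile
# directly at the crossing.
bruteWeightedMedian <- function(ratios, weights) {
  ord <- order(ratios)
  b <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(b[1])
  if (cum[length(b)] < 0.5) return(b[length(b)])
  W <- stats::approxfun(b, cum, rule = 2, ties = "ordered")
  stats::uniroot(function(m) W(m) - 0.5,
                 range(b), tol = 1e-14)$root
}
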