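#' Benjamini-Hochberg step-up adjusted p-values over a declared family
#'
#' Computes BH adjusted p-values when only the smallest members of a
#' larger test family are supplied: the `length(pvals)` values are declared
#' the smallest of a family of `m` tests (ranks 1..count), the raw adjusted
#' value at rank i is `p_i * m / i`, and monotone step-up enforcement runs
#' from the largest supplied rank downward, capped at 1. With
#' `m = length(pvals)` this reduces to the ordinary BH adjustment.
#'
#' @param pvals p-values in (0, 1]; unsorted input is sorted internally and
#'   results are returned in the original order.
#' @param m family size, at least `length(pvals)`.
#' @return adjusted p-values aligned with `pvals`.
#' @export
bhAdjust <- function(pvals, m = length(pvals)) {
  k <- length(pvals)
  if (!k) return(numeric(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    validationError("p-values must lie in (0, 1]")
  if (m < k)
    configError("family size m (%d) smaller than the number of p-values (%d)",
                m, k)
  ord <- order(pvals)
  raw <- pmin(pvals[ord] * m / seq_len(k), 1)
  adj <- rev(cummin(rev(raw)))
  out <- numeric(k)
  out[ord] <- adj
  out
}

#' Screen configuration with the pipeline's default thresholds
#'
#' Defaults: instrument p-value threshold 1e-5, clumping r-squared 0.001
#' over a 10,000 kb window, minimum F-statistic 10, heterogeneity switch
#' and outlier level 0.05, 1000 bootstrap and 1000 PRESSO replicates,
#' palindromic ambiguity band 0.08.
#'
#' @param pThreshold,clumpR2,clumpKb,fMin,qAlpha,outlierAlpha,nBoot,nSim
#'   pipeline thresholds (see the estimator and diagnostic functions).
#' @param ambiguityBand palindromic eaf ambiguity half-width.
#' @param seed master seed; all stochastic stages derive their seeds from it.
#' @param familySize BH family size; `NULL` means the panel size.
#' @param sensitivity run the sensitivity battery (Q, Egger intercept,
#'   PRESSO, leave-one-out) per pair.
#' @param ld optional LD matrix for clumping.
#' @return named list of resolved settings.
#' @export
screenConfig <- function(pThreshold = 1e-5, clumpR2 = 0.001, clumpKb = 10000,
                         fMin = 10, qAlpha = 0.05, outlierAlpha = 0.05,
                         nBoot = 1000, nSim = 1000, ambiguityBand = 0.08,
                         seed = 1L, familySize = NULL, sensitivity = TRUE,
                         ld = NULL) {
  list(pThreshold = pThreshold, clumpR2 = clumpR2, clumpKb = clumpKb,
       fMin = fMin, qAlpha = qAlpha, outlierAlpha = outlierAlpha,
       nBoot = nBoot, nSim = nSim, ambiguityBand = ambiguityBand,
       seed = as.integer(seed), familySize = familySize,
       sensitivity = isTRUE(sensitivity), ld = ld)
}

# Seed for a trait derived from the master seed and the trait's name only,
# so screen output is invariant to panel ordering.
traitSeed <- function(masterSeed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) %% 7919)
  as.integer((as.numeric(masterSeed) * 10007 + h) %% 2000000000)
}

screenOnePair <- function(exposure, outcome, config, direction) {
  pairSeed <- traitSeed(config$seed,
                        paste(trait(exposure), trait(outcome), sep = "|"))
  selected <- selectByPvalue(exposure, config$pThreshold)
  if (nrow(snpData(selected)) > 0)
    selected <- clumpInstruments(selected, ld = config$ld,
                                 r2Threshold = config$clumpR2,
                                 windowKb = config$clumpKb)
  # strength filter: drop weak instruments when eaf/n allow F to be computed
  d <- snpData(selected)
  if (nrow(d) && !anyNA(d$eaf) && !anyNA(d$n)) {
    strength <- instrumentStrength(selected, "per-snp")
    selected <- initialize(selected,
                           data = d[strength$f_stat > config$fMin, , drop = FALSE])
  }
  harm <- suppressWarnings(
    harmonize(selected, outcome, ambiguityBand = config$ambiguityBand))
  J <- nInstruments(harm)
  estimates <- list()
  sens <- NULL
  pval_ivw <- 1
  if (J >= 1) {
    ivw <- suppressWarnings(mrIvw(harm, mode = "auto", qAlpha = config$qAlpha))
    estimates$ivw <- ivw
    pval_ivw <- ivw@pval
    if (J >= 3) {
      estimates$egger <- mrEgger(harm)
      estimates$weighted_median <- suppressWarnings(
        mrWeightedMedian(harm, nBoot = config$nBoot, seed = pairSeed))
    }
    if (config$sensitivity)
      sens <- sensitivityReport(harm, nSim = config$nSim, seed = pairSeed + 1L,
                                outlierAlpha = config$outlierAlpha,
                                presso = TRUE)
  }
  new("ScreenResult", direction = direction, exposure = trait(exposure),
      outcome = trait(outcome), instruments = harm, estimates = estimates,
      sensitivity = sens, pvalIvw = pval_ivw, pvalFdr = NA_real_)
}

#' Run the one-direction MR screen over a trait panel
#'
#' For every panel trait: p-value selection, LD clumping, weak-instrument
#' filtering, harmonization against the disease GWAS, all estimators and
#' (optionally) the sensitivity battery. The primary IVW (mode auto)
#' p-values are BH-adjusted over the full declared family; traits that
#' yield no usable instrument contribute p = 1 rather than shrinking the
#' family. In the `"forward"` direction the panel traits are the exposures
#' and the disease the outcome; `"reverse"` swaps the roles (the disease's
#' instruments against each panel trait).
#'
#' @param panel named list of [GwasSummaryStats-class] (the trait panel).
#' @param disease [GwasSummaryStats-class] for the disease.
#' @param direction `"forward"` (default) or `"reverse"`.
#' @param config [screenConfig()] list.
#' @return [MrScreen-class]. Output is invariant to panel ordering.
#' @export
runScreen <- function(panel, disease, direction = c("forward", "reverse"),
                      config = screenConfig()) {
  direction <- match.arg(direction)
  if (!length(panel)) configError("panel must be non-empty")
  if (is.null(names(panel)))
    names(panel) <- vapply(panel, trait, character(1))
  panel <- panel[order(names(panel))]
  results <- lapply(panel, function(tr) {
    if (direction == "forward") screenOnePair(tr, disease, config, direction)
    else screenOnePair(disease, tr, config, direction)
  })
  m <- config$familySize %||% length(panel)
  pvals <- vapply(results, function(r) r@pvalIvw, numeric(1))
  fdr <- bhAdjust(pvals, m = max(m, length(pvals)))
  results <- Map(function(r, q) { r@pvalFdr <- q; r }, results, fdr)
  smry <- do.call(rbind, lapply(results, summarizeResult))
  rownames(smry) <- NULL
  new("MrScreen", results = results, summary = smry, direction = direction,
      config = utils::modifyList(config, list(familySize = max(m, length(pvals))),
                                 keep.null = TRUE))
}

summarizeResult <- function(r) {
  J <- nInstruments(r@instruments)
  flat <- list()
  for (nm in names(r@estimates)) {
    e <- r@estimates[[nm]]
    if (is(e, "EggerFit")) e <- e@slope
    flat[[length(flat) + 1L]] <- data.frame(
      exposure = r@exposure, outcome = r@outcome, direction = r@direction,
      nsnp = e@nSnps, method = e@method, beta = e@beta, se = e@se,
      ci_low = e@ciLow, ci_high = e@ciHigh, pval = e@pval,
      pval_fdr = if (e@method %in% c("IVW-fixed", "IVW-random"))
        r@pvalFdr else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(flat))
    flat[[1L]] <- data.frame(
      exposure = r@exposure, outcome = r@outcome, direction = r@direction,
      nsnp = J, method = "none", beta = NA_real_, se = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, pval = r@pvalIvw,
      pval_fdr = r@pvalFdr, stringsAsFactors = FALSE)
  do.call(rbind, flat)
}

#' Run both screen directions for one or more diseases
#'
#' @param panel named list of [GwasSummaryStats-class].
#' @param diseases list of [GwasSummaryStats-class] disease GWASs.
#' @param config [screenConfig()] list.
#' @return named list of [MrScreen-class], keys
#'   `"<disease>_forward"` / `"<disease>_reverse"`.
#' @export
runBidirectional <- function(panel, diseases, config = screenConfig()) {
  if (is(diseases, "GwasSummaryStats")) diseases <- list(diseases)
  out <- list()
  for (dz in diseases) {
    out[[paste0(trait(dz), "_forward")]] <-
      runScreen(panel, dz, "forward", config)
    out[[paste0(trait(dz), "_reverse")]] <-
      runScreen(panel, dz, "reverse", config)
  }
  out
}

estimateLabel <- function(e, outcomeScale) {
  if (is.na(e@beta)) return("NA")
  if (outcomeScale == "logor") toOddsRatio(e)$label
  else fmtEstimateCi(e@beta, e@ciLow, e@ciHigh)
}

#' Export screen results as report tables
#'
#' Writes an estimate table (one row per trait and method; odds ratios with
#' 95\% CI for binary outcomes, betas with CI otherwise), a sensitivity
#' table (Q statistics, Egger intercept test, PRESSO global p) and the
#' concatenated leave-one-out series. Numbers are rendered at 3 decimals;
#' p-values below 0.001 use scientific notation (`2.35E-4`).
#'
#' @param screen [MrScreen-class] (or list of them, written side by side).
#' @param dir output directory (created if needed).
#' @param format `"tsv"` (default) or `"markdown"` for the estimate table.
#' @return character vector of files written, invisibly.
#' @export
renderReport <- function(screen, dir, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  if (is(screen, "MrScreen")) screen <- list(screen = screen)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  est_rows <- list(); sens_rows <- list(); loo_rows <- list()
  for (key in names(screen)) {
    sc <- screen[[key]]
    for (r in sc@results) {
      scale_out <- if (is(r@instruments, "HarmonizedInstruments"))
        r@instruments@outcomeScale else "sd"
      for (nm in names(r@estimates)) {
        e <- r@estimates[[nm]]
        if (is(e, "EggerFit")) e <- e@slope
        est_rows[[length(est_rows) + 1L]] <- data.frame(
          exposure = r@exposure, outcome = r@outcome,
          direction = r@direction, nsnp = e@nSnps, method = e@method,
          estimate = estimateLabel(e, scale_out),
          pval = fmtPval(e@pval),
          pval_fdr = if (e@method %in% c("IVW-fixed", "IVW-random"))
            fmtPval(r@pvalFdr) else "",
          stringsAsFactors = FALSE)
      }
      s <- r@sensitivity
      if (!is.null(s)) {
        sens_rows[[length(sens_rows) + 1L]] <- data.frame(
          exposure = r@exposure, outcome = r@outcome,
          direction = r@direction,
          q_ivw = if (!is.null(s@qIvw)) fmt3(s@qIvw@Q) else "",
          q_ivw_pval = if (!is.null(s@qIvw)) fmtPval(s@qIvw@pval) else "",
          q_egger = if (!is.null(s@qEgger)) fmt3(s@qEgger@Q) else "",
          q_egger_pval = if (!is.null(s@qEgger)) fmtPval(s@qEgger@pval) else "",
          egger_intercept = if (!is.null(s@egger))
            fmt3(s@egger@intercept@estimate) else "",
          egger_intercept_pval = if (!is.null(s@egger))
            fmtPval(s@egger@intercept@pval) else "",
          presso_global_pval = if (!is.null(s@presso))
            fmtPval(s@presso@globalPval) else "",
          presso_outliers = if (!is.null(s@presso))
            paste(s@presso@outliers, collapse = ",") else "",
          stringsAsFactors = FALSE)
        if (nrow(s@leaveOneOut)) {
          loo <- s@leaveOneOut
          loo$exposure <- r@exposure; loo$outcome <- r@outcome
          loo$direction <- r@direction
          loo_rows[[length(loo_rows) + 1L]] <- loo
        }
      }
    }
  }
  files <- character(0)
  est <- do.call(rbind, est_rows)
  if (format == "tsv") {
    f <- file.path(dir, "estimates.tsv")
    data.table::fwrite(est, f, sep = "\t", quote = FALSE)
  } else {
    f <- file.path(dir, "estimates.md")
    lines <- c(paste0("| ", paste(names(est), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(est)), collapse = "|"), "|"),
               apply(est, 1, function(row)
                 paste0("| ", paste(row, collapse = " | "), " |")))
    writeLines(lines, f)
  }
  files <- c(files, f)
  if (length(sens_rows)) {
    f <- file.path(dir, "sensitivity.tsv")
    data.table::fwrite(do.call(rbind, sens_rows), f, sep = "\t", quote = FALSE)
    files <- c(files, f)
  }
  if (length(loo_rows)) {
    f <- file.path(dir, "leave_one_out.tsv")
    loo_all <- do.call(rbind, loo_rows)
    num <- vapply(loo_all, is.numeric, logical(1))
    loo_all[num] <- lapply(loo_all[num], function(x) round(x, 6))
    data.table::fwrite(loo_all, f, sep = "\t", quote = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
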