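#' @describeIn GwasSummaryStats-class the per-SNP association table.
#' @export
setMethod("snpData", "GwasSummaryStats", function(x) x@data)

#' @describeIn GwasSummaryStats-class trait label.
#' @export
setMethod("trait", "GwasSummaryStats", function(x) x@trait)

#' @describeIn HarmonizedInstruments-class retained (non-dropped)
#'   instruments; the table every estimator consumes.
#' @export
setMethod("instrumentData", "HarmonizedInstruments", function(x) {
  d <- x@data[x@data$action != "dropped", , drop = FALSE]
  rownames(d) <- NULL
  d
})

#' @describeIn HarmonizedInstruments-class per-SNP action log
#'   (snp, action, reason), one row per intersecting SNP.
#' @export
setMethod("harmonizationLog", "HarmonizedInstruments", function(x) {
  d <- x@data[, c("snp", "action", "reason"), drop = FALSE]
  rownames(d) <- NULL
  d
})

#' @describeIn HarmonizedInstruments-class number of retained instruments.
#' @export
setMethod("nInstruments", "HarmonizedInstruments",
          function(x) sum(x@data$action != "dropped"))

#' @describeIn MrScreen-class tidy summary table, one row per trait/method.
#' @export
setMethod("screenSummary", "MrScreen", function(x) x@summary)

#' @describeIn MrScreen-class list of per-pair [ScreenResult] objects.
#' @export
setMethod("screenResults", "MrScreen", function(x) x@results)

setMethod("show", "GwasSummaryStats", function(object) {
  cat(sprintf("GwasSummaryStats '%s' (%s scale): %d SNPs\n",
              object@trait, object@effectScale, nrow(object@data)))
  if (nrow(object@data))
    print(utils::head(object@data, 5L))
  invisible(object)
})

setMethod("show", "HarmonizedInstruments", function(object) {
  tab <- table(factor(object@data$action,
                      levels = c("kept", "flipped", "dropped")))
  cat(sprintf("HarmonizedInstruments %s -> %s: %d retained (%d kept as-is, %d flipped, %d dropped)\n",
              object@exposure, object@outcome,
              sum(object@data$action != "dropped"),
              tab[["kept"]], tab[["flipped"]], tab[["dropped"]]))
  invisible(object)
})

setMethod("show", "MrEstimate", function(object) {
  cat(sprintf("%s estimate (%d SNPs, %s): beta %.4f, se %.4f, 95%% CI [%.4f, %.4f], p %.3g\n",
              object@method, object@nSnps, object@scale, object@beta,
              object@se, object@ciLow, object@ciHigh, object@pval))
  invisible(object)
})

setMethod("show", "EggerFit", function(object) {
  show(object@slope)
  cat(sprintf("  Egger intercept %.4f (se %.4f), p %.3g\n",
              object@intercept@estimate, object@intercept@se,
              object@intercept@pval))
  invisible(object)
})

setMethod("show", "QResult", function(object) {
  cat(sprintf("Cochran Q (%s): Q %.3f on %d df, p %.3g\n",
              object@model, object@Q, object@df, object@pval))
  invisible(object)
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO: global RSS %.3f, global p %.4g (%d simulations)\n",
              object@rssObs, object@globalPval, object@nSim))
  if (length(object@outliers))
    cat("  outliers:", paste(object@outliers, collapse = ", "), "\n")
  else cat("  no outliers detected\n")
  invisible(object)
})

setMethod("show", "MrScreen", function(object) {
  cat(sprintf("MrScreen (%s): %d panel traits, FDR family size %d\n",
              object@direction, length(object@results),
              object@config$familySize))
  ivw <- object@summary[object@summary$method %in% c("IVW-fixed", "IVW-random"), ]
  if (nrow(ivw))
    print(utils::head(ivw[order(ivw$pval_fdr), ], 5L))
  invisible(object)
})
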