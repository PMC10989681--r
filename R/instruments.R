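#' Select candidate instruments by association p-value
#'
#' Keeps rows with `pval` strictly below the threshold (the conventional
#' genome-wide-suggestive cutoff 1e-5 by default), preserving input order.
#'
#' @param stats [GwasSummaryStats-class].
#' @param threshold p-value cutoff in (0, 1); strict `<` comparison, so a
#'   row at exactly the threshold is excluded.
#' @return [GwasSummaryStats-class] (possibly with zero rows).
#' @export
selectByPvalue <- function(stats, threshold = 1e-5) {
  stopifnot(is(stats, "GwasSummaryStats"))
  if (threshold <= 0 || threshold >= 1)
    configError("p-value threshold must be in (0, 1), got %g", threshold)
  d <- snpData(stats)
  keep <- d[d$pval < threshold, , drop = FALSE]
  rownames(keep) <- NULL
  initialize(stats, data = keep)
}

#' Read a square LD matrix from TSV
#'
#' Expects a header row of SNP ids and an id column; values are pairwise
#' r-squared. Validated for symmetry and a unit diagonal.
#'
#' @param path TSV path.
#' @return numeric matrix with SNP-id dimnames.
#' @export
readLdMatrix <- function(path) {
  if (!file.exists(path)) configError("LD matrix file not found: %s", path)
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- ids
  validateLdMatrix(m)
  m
}

validateLdMatrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    configError("LD matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    configError("LD matrix must carry identical SNP-id row and column names")
  if (max(abs(m - t(m))) > 1e-8)
    configError("LD matrix must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8)
    configError("LD matrix diagonal must be exactly 1")
  if (any(m < -1e-8) || any(m > 1 + 1e-8))
    configError("LD r-squared values must lie in [0, 1]")
  invisible(m)
}

#' Greedy LD clumping of candidate instruments
#'
#' Repeatedly keeps the smallest-p remaining SNP (ties broken by
#' lexicographic SNP id) and discards the remaining SNPs on the same
#' chromosome within `windowKb` that are also in LD with it at
#' `r2 >= r2Threshold`. When no LD matrix is supplied only the distance
#' criterion applies (any same-chromosome SNP within the window is
#' discarded). Distance is `|pos difference| <= windowKb * 1000`, so two
#' SNPs exactly one base beyond the window both survive.
#'
#' @param stats [GwasSummaryStats-class]; must be non-empty.
#' @param ld optional square r-squared matrix covering all SNPs (see
#'   [readLdMatrix()]).
#' @param r2Threshold LD pruning threshold (default 0.001).
#' @param windowKb clumping window in kilobases (default 10000).
#' @return [GwasSummaryStats-class] with the retained index SNPs, sorted
#'   by chromosome then position. Deterministic under input permutation.
#' @export
clumpInstruments <- function(stats, ld = NULL, r2Threshold = 0.001,
                             windowKb = 10000) {
  stopifnot(is(stats, "GwasSummaryStats"))
  d <- snpData(stats)
  if (!nrow(d)) configError("clumping requires a non-empty SNP set")
  if (!is.null(ld)) {
    validateLdMatrix(ld)
    missing_ids <- setdiff(d$snp, rownames(ld))
    if (length(missing_ids))
      configError("LD matrix lacks SNP(s): %s",
                  paste(missing_ids, collapse = ", "))
  }
  window_bp <- windowKb * 1000
  remaining <- d[order(d$pval, d$snp), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining)) {
    index <- remaining[1, ]
    kept <- c(kept, index$snp)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining)) {
      near <- remaining$chrom == index$chrom &
        abs(remaining$pos - index$pos) <= window_bp
      if (!is.null(ld))
        near <- near & ld[index$snp, remaining$snp] >= r2Threshold
      remaining <- remaining[!near, , drop = FALSE]
    }
  }
  out <- d[d$snp %in% kept, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  initialize(stats, data = out)
}

#' Instrument strength: variance explained and F-statistic
#'
#' Per-SNP variance explained is `r2 = 2 * MAF * (1 - MAF) * beta^2` with
#' `MAF = min(eaf, 1 - eaf)`; strength is `F = r2 * (n - k - 1) / (k * (1 - r2))`.
#' In per-SNP mode `k = 1` and each SNP uses its own `r2` and `n`; in pooled
#' mode `R2 = sum(r2_j)`, `k` is the number of SNPs and `n` the smallest
#' per-SNP sample size. Instruments with `F <= 10` are flagged weak.
#'
#' @param stats [GwasSummaryStats-class]; `eaf` and `n` must be present for
#'   every SNP.
#' @param aggregate `"per-snp"` (default) or `"pooled"`.
#' @return data.frame with columns `snp`, `maf`, `r2`, `f_stat`, `weak`
#'   (per-SNP mode) or a single row with `r2`, `f_stat`, `k`, `n`, `weak`
#'   (pooled mode).
#' @export
instrumentStrength <- function(stats, aggregate = c("per-snp", "pooled")) {
  stopifnot(is(stats, "GwasSummaryStats"))
  aggregate <- match.arg(aggregate)
  d <- snpData(stats)
  no_eaf <- d$snp[is.na(d$eaf)]
  if (length(no_eaf))
    validationError("eaf missing for SNP(s): %s",
                    paste(no_eaf, collapse = ", "))
  no_n <- d$snp[is.na(d$n)]
  if (length(no_n))
    validationError("sample size missing for SNP(s): %s",
                    paste(no_n, collapse = ", "))
  maf <- pmin(d$eaf, 1 - d$eaf)
  r2 <- 2 * maf * (1 - maf) * d$beta^2
  if (aggregate == "per-snp") {
    f <- r2 * (d$n - 2) / (1 - r2)
    data.frame(snp = d$snp, maf = maf, r2 = r2, f_stat = f,
               weak = f <= 10, stringsAsFactors = FALSE)
  } else {
    k <- nrow(d)
    R2 <- sum(r2)
    n <- min(d$n)
    f <- R2 * (n - k - 1) / (k * (1 - R2))
    data.frame(r2 = R2, f_stat = f, k = k, n = n, weak = f <= 10)
  }
}
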