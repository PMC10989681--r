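#' Construct a GwasSummaryStats object from a data frame
#'
#' @param data data.frame holding the canonical columns (`snp`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `n`); `eaf` may be absent and is then set to `NA`.
#' @param trait trait label.
#' @param effectScale `"sd"` (quantitative trait, default) or `"logor"`.
#' @return a validated [GwasSummaryStats-class] object; row order preserved.
#' @export
GwasSummaryStats <- function(data, trait = "trait", effectScale = "sd") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"eaf" %in% names(data)) data$eaf <- NA_real_
  missing_cols <- setdiff(GWAS_COLUMNS, names(data))
  if (length(missing_cols))
    configError("missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  data <- data[, GWAS_COLUMNS, drop = FALSE]
  data$snp <- as.character(data$snp)
  data$chrom <- as.character(data$chrom)
  data$pos <- as.numeric(data$pos)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    data[[col]] <- as.numeric(data[[col]])
  rownames(data) <- NULL
  problems <- validateGwasRows(data)
  if (length(problems))
    validationError("invalid summary statistics for trait '%s': %s",
                    trait, paste(problems, collapse = "; "))
  new("GwasSummaryStats", data = data, trait = trait,
      effectScale = effectScale)
}

#' Default column mapping for summary-statistics files
#'
#' Maps canonical field names to file column names. Any entry can be
#' overridden, e.g. `columnMap(snp = "rsid", pval = "p")`.
#'
#' @param ... canonical-name = file-column-name overrides.
#' @return named character vector keyed by canonical name.
#' @export
columnMap <- function(...) {
  map <- stats::setNames(GWAS_COLUMNS, GWAS_COLUMNS)
  override <- c(...)
  if (length(override)) {
    unknown <- setdiff(names(override), GWAS_COLUMNS)
    if (length(unknown))
      configError("unknown canonical column(s) in column map: %s",
                  paste(unknown, collapse = ", "))
    map[names(override)] <- override
  }
  map
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file with a header, renames columns via
#' the supplied mapping and validates every row against the
#' `GwasSummaryStats` invariants. A missing `eaf` column is tolerated (with
#' a warning); missing `beta`, `se` or `pval` columns are configuration
#' errors. Row-level violations (indel allele codes, non-positive SEs, ...)
#' raise a validation error citing the offending file line numbers.
#'
#' @param path file path.
#' @param map column mapping from [columnMap()].
#' @param trait trait label (defaults to the file stem).
#' @param effectScale `"sd"` or `"logor"`.
#' @return [GwasSummaryStats-class], file row order preserved.
#' @export
readSummaryStats <- function(path, map = columnMap(), trait = NULL,
                             effectScale = "sd") {
  if (!file.exists(path))
    configError("summary-statistics file not found: %s", path)
  trait <- trait %||% sub("\\.[^.]*$", "", basename(path))
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           colClasses = list(character = unname(map[c("snp", "chrom")])))
  required <- setdiff(GWAS_COLUMNS, "eaf")
  for (canon in required) {
    if (!map[[canon]] %in% names(raw))
      configError("file '%s' lacks required column '%s' (mapped from '%s')",
                  path, map[[canon]], canon)
  }
  if (!map[["eaf"]] %in% names(raw)) {
    warning(sprintf("file '%s' has no '%s' column; eaf set to missing",
                    path, map[["eaf"]]), call. = FALSE)
    raw[[map[["eaf"]]]] <- NA_real_
  }
  d <- raw[, unname(map), drop = FALSE]
  names(d) <- names(map)
  d$effect_allele <- toupper(as.character(d$effect_allele))
  d$other_allele <- toupper(as.character(d$other_allele))
  problems <- validateGwasRows(d)
  if (length(problems)) {
    # report file line numbers (+1 for the header)
    problems <- vapply(problems, function(p) {
      gsub("row\\(s\\) ([0-9, ]+)", "row(s) \\1", p)
    }, character(1))
    bad_rows <- unique(unlist(regmatches(problems,
                                         gregexpr("[0-9]+", problems))))
    validationError("file '%s': %s (file line(s) %s, counting the header as line 1)",
                    path, paste(problems, collapse = "; "),
                    paste(as.integer(bad_rows) + 1L, collapse = ", "))
  }
  GwasSummaryStats(d, trait = trait, effectScale = effectScale)
}

#' Write summary statistics as tab-delimited text
#'
#' @param x [GwasSummaryStats-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(x, path) {
  stopifnot(is(x, "GwasSummaryStats"))
  data.table::fwrite(snpData(x), path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

isPalindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Construct a HarmonizedInstruments object directly
#'
#' Convenience constructor for already-aligned instrument sets (simulation
#' truths, toy examples). All rows get `action = "kept"` unless an `action`
#' column is supplied.
#'
#' @param data data.frame with at least `snp`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`.
#' @param exposure,outcome trait labels.
#' @param outcomeScale `"sd"` or `"logor"`.
#' @return [HarmonizedInstruments-class].
#' @export
HarmonizedInstruments <- function(data, exposure = "exposure",
                                  outcome = "outcome", outcomeScale = "sd") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  defaults <- list(effect_allele = "A", other_allele = "G",
                   eaf_exposure = NA_real_, eaf_outcome = NA_real_,
                   palindromic = FALSE, action = "kept", reason = "")
  for (col in names(defaults))
    if (!col %in% names(data)) data[[col]] <- defaults[[col]]
  new("HarmonizedInstruments", data = data, exposure = exposure,
      outcome = outcome, outcomeScale = outcomeScale)
}

#' Harmonize exposure and outcome associations onto a shared effect allele
#'
#' Intersects the two SNP sets by identifier and aligns the outcome
#' association to the exposure's effect allele. Outcome rows whose alleles
#' match in swapped order have their beta negated and eaf replaced by
#' 1 - eaf; strand-complement pairs of non-palindromic SNPs are resolved
#' the same way. Palindromic SNPs (A/T or C/G) are aligned by allele
#' frequency when both frequencies lie outside `0.5 +/- ambiguityBand`,
#' and dropped otherwise; allele pairs that match in no orientation are
#' dropped. Every intersecting SNP appears exactly once in the result with
#' its action (`kept`, `flipped`, `dropped`) and reason recorded.
#'
#' @param exposure,outcome [GwasSummaryStats-class] objects.
#' @param ambiguityBand half-width of the eaf ambiguity band around 0.5
#'   inside which a palindromic SNP is dropped (default 0.08).
#' @return [HarmonizedInstruments-class]. An empty SNP intersection yields
#'   an empty result with a warning, not an error.
#' @export
harmonize <- function(exposure, outcome, ambiguityBand = 0.08) {
  stopifnot(is(exposure, "GwasSummaryStats"), is(outcome, "GwasSummaryStats"))
  ex <- snpData(exposure)
  ou <- snpData(outcome)
  common <- ex$snp[ex$snp %in% ou$snp]
  out_cols <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
                "beta_exposure", "se_exposure", "eaf_exposure",
                "beta_outcome", "se_outcome", "eaf_outcome",
                "pval_exposure", "pval_outcome", "palindromic",
                "action", "reason")
  if (!length(common)) {
    warning("no SNPs shared between exposure and outcome", call. = FALSE)
    empty <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(out_cols))), out_cols)
    return(new("HarmonizedInstruments", data = empty,
               exposure = trait(exposure), outcome = trait(outcome),
               outcomeScale = outcome@effectScale))
  }
  ex <- ex[match(common, ex$snp), ]
  ou <- ou[match(common, ou$snp), ]

  rows <- lapply(seq_along(common), function(i) {
    e <- ex[i, ]; o <- ou[i, ]
    palin <- isPalindromic(e$effect_allele, e$other_allele)
    action <- "dropped"; reason <- "allele_mismatch"
    beta_o <- o$beta; eaf_o <- o$eaf
    if (palin) {
      same_pair <- setequal(c(o$effect_allele, o$other_allele),
                            c(e$effect_allele, e$other_allele))
      if (!same_pair) {
        # stays dropped: allele_mismatch
      } else if (is.na(e$eaf) || is.na(o$eaf) ||
                 abs(e$eaf - 0.5) <= ambiguityBand ||
                 abs(o$eaf - 0.5) <= ambiguityBand) {
        reason <- "palindromic_ambiguous"
      } else if ((e$eaf < 0.5) == (o$eaf < 0.5)) {
        action <- "kept"; reason <- "palindromic_eaf_aligned"
      } else {
        action <- "flipped"; reason <- "palindromic_eaf_flipped"
        beta_o <- -beta_o; eaf_o <- 1 - eaf_o
      }
    } else if (o$effect_allele == e$effect_allele &&
               o$other_allele == e$other_allele) {
      action <- "kept"; reason <- "same_alleles"
    } else if (o$effect_allele == e$other_allele &&
               o$other_allele == e$effect_allele) {
      action <- "flipped"; reason <- "swapped_alleles"
      beta_o <- -beta_o; eaf_o <- 1 - eaf_o
    } else if (COMPLEMENT[o$effect_allele] == e$effect_allele &&
               COMPLEMENT[o$other_allele] == e$other_allele) {
      action <- "kept"; reason <- "strand_complement"
    } else if (COMPLEMENT[o$effect_allele] == e$other_allele &&
               COMPLEMENT[o$other_allele] == e$effect_allele) {
      action <- "flipped"; reason <- "strand_complement"
      beta_o <- -beta_o; eaf_o <- 1 - eaf_o
    }
    data.frame(snp = e$snp, chrom = e$chrom, pos = e$pos,
               effect_allele = e$effect_allele,
               other_allele = e$other_allele,
               beta_exposure = e$beta, se_exposure = e$se,
               eaf_exposure = e$eaf,
               beta_outcome = beta_o, se_outcome = o$se, eaf_outcome = eaf_o,
               pval_exposure = e$pval, pval_outcome = o$pval,
               palindromic = palin, action = action, reason = reason,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  new("HarmonizedInstruments", data = d, exposure = trait(exposure),
      outcome = trait(outcome), outcomeScale = outcome@effectScale)
}

#' Write the harmonization action log as TSV
#'
#' @param x [HarmonizedInstruments-class].
#' @param path output path; columns `snp`, `action`, `reason`.
#' @return `path`, invisibly.
#' @export
writeHarmonizationLog <- function(x, path) {
  data.table::fwrite(harmonizationLog(x), path, sep = "\t", quote = FALSE)
  invisible(path)
}
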