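#' The circulating-cytokine panel emulated by the generator
#'
#' Returns the 41-trait inflammatory-cytokine panel (trait abbreviation and
#' GWAS sample size, 839 to 8,293) whose structure the synthetic generator
#' reproduces.
#'
#' @return data.frame with columns `trait`, `n`.
#' @export
cytokinePanel <- function() {
  path <- system.file("extdata", "cytokine_panel.tsv", package = "mrscreen")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Configuration of a synthetic two-sample GWAS pair
#'
#' Defaults emulate the cytokine-to-thyroid-disease study design: 8-30
#' independent instruments per trait; exposure sample sizes drawn from the
#' cytokine panel's 839-8,293 range; a binary disease outcome with
#' 458,620 samples (log-OR scale); minor-allele frequencies uniform on
#' [0.05, 0.5]; per-SNP F-statistic targets uniform on [11.2, 789], the
#' instrument-strength range observed across the real panel; 15% of SNPs
#' palindromic. Exposure effects are in SD units of the cytokine.
#'
#' @param nSnps instrument count; `NULL` draws uniformly from 8 to 30.
#' @param nExposure exposure GWAS sample size; `NULL` draws from the
#'   cytokine panel's sizes.
#' @param nOutcome outcome GWAS sample size (default 458620).
#' @param theta true causal effect of exposure on outcome.
#' @param regime pleiotropy regime: `"none"`, `"balanced"`,
#'   `"directional"` or `"inside_violating"`.
#' @param muAlpha,sigmaAlpha mean and SD of the per-SNP direct
#'   (pleiotropic) effects alpha_j; `"balanced"` forces mean 0.
#' @param rho correlation between alpha_j and the instrument effect
#'   gamma_j under `"inside_violating"` (|rho| <= 1).
#' @param mafRange minor-allele-frequency range (non-degenerate).
#' @param fRange per-SNP F-statistic target range for valid instruments.
#' @param weakFraction fraction of SNPs generated at weak strength
#'   (F targets uniform on [2, 8]).
#' @param palindromicFraction fraction of SNPs given A/T or C/G alleles.
#' @param outcomeType `"binary"` (log-OR outcome scale) or `"continuous"`.
#' @return SimConfig list.
#' @export
simConfig <- function(nSnps = NULL, nExposure = NULL, nOutcome = 458620,
                      theta = 0, regime = c("none", "balanced",
                                            "directional", "inside_violating"),
                      muAlpha = 0, sigmaAlpha = 0, rho = 0,
                      mafRange = c(0.05, 0.5), fRange = c(11.2, 789),
                      weakFraction = 0, palindromicFraction = 0.15,
                      outcomeType = c("binary", "continuous")) {
  regime <- match.arg(regime)
  if (mafRange[1] >= mafRange[2] || mafRange[1] <= 0 || mafRange[2] > 0.5)
    configError("degenerate MAF range [%g, %g]", mafRange[1], mafRange[2])
  if (abs(rho) > 1) configError("|rho| must be <= 1")
  if (sigmaAlpha < 0) configError("sigmaAlpha must be >= 0")
  list(nSnps = nSnps, nExposure = nExposure, nOutcome = nOutcome,
       theta = theta, regime = regime, muAlpha = muAlpha,
       sigmaAlpha = sigmaAlpha, rho = rho, mafRange = mafRange,
       fRange = fRange, weakFraction = weakFraction,
       palindromicFraction = palindromicFraction,
       outcomeType = match.arg(outcomeType))
}

drawAlleles <- function(J, palindromicFraction) {
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  npal_pairs <- list(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                     c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
  is_pal <- stats::runif(J) < palindromicFraction
  t(vapply(seq_len(J), function(j) {
    if (is_pal[j]) pal_pairs[[sample.int(4, 1)]]
    else npal_pairs[[sample.int(8, 1)]]
  }, character(2)))
}

#' Simulate a two-sample exposure/outcome GWAS pair with known truth
#'
#' Per SNP j: MAF uniform on the configured range; the true instrument
#' effect gamma_j is drawn from a normal centred on the scale implied by an
#' F-statistic target (sd a quarter of the centre) and truncated positive
#' (the effect allele is oriented exposure-increasing); the exposure SE is
#' the standard per-allele GWAS value `(2 maf (1-maf) n_exp)^-1/2` for a
#' unit-variance phenotype, and the estimate is
#' `gamma_hat ~ N(gamma, se^2)`. The outcome association is
#' `Gamma_j = theta * gamma_j + alpha_j` with alpha_j set by the pleiotropy
#' regime, observed with SE `(2 maf (1-maf) n_out)^-1/2`. The two samples
#' share no noise (non-overlapping two-sample design). P-values are
#' two-sided normal. SNPs sit on alternating chromosomes more than the
#' clumping window apart, so the generated instruments are independent.
#'
#' @param config [simConfig()] list.
#' @param seed integer seed; the same config and seed reproduce the pair
#'   exactly.
#' @param idOffset integer offset for SNP identifiers (used by
#'   [simulatePanel()] to keep panels disjoint).
#' @return list with `exposure` and `outcome`
#'   ([GwasSummaryStats-class]) and `truth` (theta, per-SNP gamma, alpha,
#'   validity flags, regime, seed).
#' @export
simulatePair <- function(config = simConfig(), seed, idOffset = 0L) {
  withr::with_seed(as.integer(seed), {
    J <- config$nSnps %||% sample(8:30, 1)
    n_exp <- config$nExposure %||% sample(cytokinePanel()$n, 1)
    n_out <- config$nOutcome
    maf <- stats::runif(J, config$mafRange[1], config$mafRange[2])
    n_weak <- round(config$weakFraction * J)
    weak <- seq_len(J) <= n_weak
    f_target <- ifelse(weak, stats::runif(J, 2, 8),
                       stats::runif(J, config$fRange[1], config$fRange[2]))
    # invert F = r2 (n-2) / (1 - r2) at k = 1 for the target variance explained
    r2_target <- f_target / (n_exp - 2 + f_target)
    centre <- sqrt(r2_target / (2 * maf * (1 - maf)))
    gamma <- abs(stats::rnorm(J, centre, centre / 4))
    se_exp <- 1 / sqrt(2 * maf * (1 - maf) * n_exp)
    gamma_hat <- stats::rnorm(J, gamma, se_exp)
    alpha <- switch(config$regime,
      none = rep(0, J),
      balanced = stats::rnorm(J, 0, config$sigmaAlpha),
      directional = stats::rnorm(J, config$muAlpha, config$sigmaAlpha),
      inside_violating = {
        sg <- stats::sd(gamma)
        if (!is.finite(sg) || sg == 0) sg <- 1
        config$muAlpha +
          config$rho * config$sigmaAlpha * (gamma - mean(gamma)) / sg +
          sqrt(1 - config$rho^2) * stats::rnorm(J, 0, config$sigmaAlpha)
      })
    Gamma <- config$theta * gamma + alpha
    se_out <- 1 / sqrt(2 * maf * (1 - maf) * n_out)
    Gamma_hat <- stats::rnorm(J, Gamma, se_out)
    alleles <- drawAlleles(J, config$palindromicFraction)
    eaf <- ifelse(stats::runif(J) < 0.5, maf, 1 - maf)
    chrom <- as.character(((seq_len(J) - 1) %% 22) + 1)
    pos <- 1e6 + ((seq_len(J) - 1) %/% 22) * 2.1e7
    snp <- sprintf("rs%08d", idOffset + seq_len(J))
    base <- data.frame(snp = snp, chrom = chrom, pos = pos,
                       effect_allele = alleles[, 1],
                       other_allele = alleles[, 2], eaf = eaf,
                       stringsAsFactors = FALSE)
    exposure <- base
    exposure$beta <- gamma_hat
    exposure$se <- se_exp
    exposure$pval <- pvalNormal2(gamma_hat / se_exp)
    exposure$n <- n_exp
    outcome <- base
    outcome$beta <- Gamma_hat
    outcome$se <- se_out
    outcome$pval <- pvalNormal2(Gamma_hat / se_out)
    outcome$n <- n_out
    truth <- list(theta = config$theta, snp = snp, gamma = gamma,
                  alpha = alpha, valid = alpha == 0,
                  regime = config$regime, seed = as.integer(seed))
    list(exposure = GwasSummaryStats(exposure, trait = "exposure",
                                     effectScale = "sd"),
         outcome = GwasSummaryStats(
           outcome, trait = "outcome",
           effectScale = if (config$outcomeType == "binary") "logor" else "sd"),
         truth = truth)
  })
}

#' Simulate a whole trait panel against one disease outcome
#'
#' Generates one exposure GWAS per panel trait (names and sample sizes
#' taken from the cytokine panel) plus a single outcome GWAS covering all
#' their instruments; `nCausal` traits receive the non-zero causal effect
#' `theta`, the rest are null. SNP identifiers are disjoint across traits.
#' Optionally writes the exposure/outcome TSVs, a manifest and a JSON-lines
#' truth file to `dir`.
#'
#' @param config base [simConfig()]; per-trait sample sizes override its
#'   `nExposure`.
#' @param nTraits number of panel traits (default 41).
#' @param nCausal number of causal traits (default 2; must be <= nTraits).
#' @param theta causal effect assigned to the causal traits (default 0.1).
#' @param seed master seed; per-trait seeds derive from it and the trait
#'   name.
#' @param dir optional output directory for TSV/manifest/truth files.
#' @return list with `exposures` (named list of [GwasSummaryStats-class]),
#'   `outcome` ([GwasSummaryStats-class] over all instruments), `truths`
#'   (named list), `manifest` (data.frame) and `files` (paths, when `dir`
#'   was given).
#' @export
simulatePanel <- function(config = simConfig(), nTraits = 41, nCausal = 2,
                          theta = 0.1, seed, dir = NULL) {
  if (nCausal > nTraits)
    configError("nCausal (%d) exceeds nTraits (%d)", nCausal, nTraits)
  panel <- cytokinePanel()
  traits <- if (nTraits <= nrow(panel)) panel[seq_len(nTraits), ] else
    data.frame(trait = sprintf("trait%02d", seq_len(nTraits)),
               n = rep_len(panel$n, nTraits))
  causal <- withr::with_seed(as.integer(seed),
                             sample(traits$trait, nCausal))
  exposures <- list(); truths <- list(); outcome_rows <- list()
  manifest <- list()
  for (i in seq_len(nrow(traits))) {
    nm <- traits$trait[i]
    cfg <- config
    cfg$nExposure <- traits$n[i]
    cfg$theta <- if (nm %in% causal) theta else 0
    pair <- simulatePair(cfg, seed = traitSeed(seed, nm),
                         idOffset = (i - 1L) * 1000L)
    pair$exposure@trait <- nm
    exposures[[nm]] <- pair$exposure
    truths[[nm]] <- pair$truth
    outcome_rows[[nm]] <- snpData(pair$outcome)
    manifest[[nm]] <- data.frame(trait = nm, n = traits$n[i],
                                 theta = cfg$theta, causal = nm %in% causal,
                                 n_snps = nrow(snpData(pair$exposure)),
                                 stringsAsFactors = FALSE)
  }
  outcome <- GwasSummaryStats(do.call(rbind, outcome_rows),
                              trait = "disease",
                              effectScale = if (config$outcomeType == "binary")
                                "logor" else "sd")
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (nm in names(exposures)) {
      f <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", nm), ".tsv"))
      writeSummaryStats(exposures[[nm]], f)
      files <- c(files, f)
    }
    f_out <- file.path(dir, "outcome.tsv")
    writeSummaryStats(outcome, f_out)
    manifest$file <- basename(files)
    f_man <- file.path(dir, "manifest.tsv")
    data.table::fwrite(manifest, f_man, sep = "\t", quote = FALSE)
    f_truth <- file.path(dir, "truth.jsonl")
    con <- file(f_truth, "w")
    for (nm in names(truths))
      writeLines(jsonlite::toJSON(c(list(trait = nm), truths[[nm]]),
                                  auto_unbox = TRUE, digits = NA), con)
    close(con)
    files <- c(files, f_out, f_man, f_truth)
  }
  list(exposures = exposures, outcome = outcome, truths = truths,
       manifest = manifest, files = files)
}
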