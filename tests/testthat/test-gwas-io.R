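test_that("a well-formed TSV reads back in file order", {
  df <- data.frame(snp = c("rs3", "rs1", "rs2"), chr = "2",
                   pos = c(100, 200, 300), effect_allele = "A",
                   other_allele = "G", eaf = c(0.1, 0.2, 0.3),
                   beta = c(0.1, -0.2, 0.05), se = 0.04,
                   pval = c(1e-6, 2e-7, 0.5), n = 3682)
  path <- writeGwasTsv(df)
  gw <- readSummaryStats(path, columnMap(chrom = "chr"))
  expect_s4_class(gw, "GwasSummaryStats")
  expect_identical(snpData(gw)$snp, c("rs3", "rs1", "rs2"))
  expect_equal(snpData(gw)$beta, df$beta)
})

test_that("indel allele codes are rejected with the offending rows", {
  df <- data.frame(snp = c("rs1", "rs2"), chr = "1", pos = c(1, 2),
                   effect_allele = c("I", "A"), other_allele = c("D", "G"),
                   eaf = 0.2, beta = 0.1, se = 0.02, pval = 0.01, n = 1000)
  path <- writeGwasTsv(df)
  expect_error(readSummaryStats(path, columnMap(chrom = "chr")),
               "invalid effect_allele.*row")
})

test_that("a missing eaf column is tolerated with a warning", {
  df <- data.frame(snp = "rs1", chr = "1", pos = 5, effect_allele = "A",
                   other_allele = "C", beta = 0.1, se = 0.02,
                   pval = 0.01, n = 1000)
  path <- writeGwasTsv(df)
  expect_warning(gw <- readSummaryStats(path, columnMap(chrom = "chr")),
                 "eaf")
  expect_true(is.na(snpData(gw)$eaf))
})

test_that("a missing required column names the column", {
  df <- data.frame(snp = "rs1", chr = "1", pos = 5, effect_allele = "A",
                   other_allele = "C", eaf = 0.3, beta = 0.1,
                   pval = 0.01, n = 1000)
  path <- writeGwasTsv(df)
  expect_error(readSummaryStats(path, columnMap(chrom = "chr")), "'se'",
               class = "mrscreenConfigError")
  expect_error(readSummaryStats(tempfile("nope")), "not found",
               class = "mrscreenConfigError")
})

test_that("summary statistics survive a write/read round trip", {
  pair <- simulatePair(simConfig(nSnps = 12), seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSummaryStats(pair$exposure, path)
  back <- readSummaryStats(path, trait = "exposure")
  expect_equal(snpData(back)$beta, snpData(pair$exposure)$beta,
               tolerance = 1e-10)
  expect_equal(snpData(back)$se, snpData(pair$exposure)$se,
               tolerance = 1e-10)
  expect_identical(snpData(back)$snp, snpData(pair$exposure)$snp)
})

harmPair <- function(exp_alleles, out_alleles, out_beta = 0.05,
                     exp_eaf = 0.3, out_eaf = 0.3) {
  ex <- makeGwas("rs1", 0.1, 0.02, eaf = exp_eaf,
                 effect_allele = exp_alleles[1],
                 other_allele = exp_alleles[2])
  ou <- makeGwas("rs1", out_beta, 0.03, eaf = out_eaf,
                 effect_allele = out_alleles[1],
                 other_allele = out_alleles[2])
  harmonize(ex, ou)
}

test_that("matching alleles are kept and swapped alleles flip the outcome", {
  kept <- instrumentData(harmPair(c("A", "G"), c("A", "G")))
  expect_identical(kept$action, "kept")
  expect_equal(kept$beta_outcome, 0.05)

  flip <- instrumentData(harmPair(c("A", "G"), c("G", "A"), out_eaf = 0.3))
  expect_identical(flip$action, "flipped")
  expect_equal(flip$beta_outcome, -0.05)
  expect_equal(flip$eaf_outcome, 0.7)
})

test_that("palindromic SNPs follow the frequency-alignment policy", {
  # eaf at exactly 0.5: inside the ambiguity band, dropped
  h <- harmPair(c("A", "T"), c("A", "T"), exp_eaf = 0.5, out_eaf = 0.2)
  expect_identical(harmonizationLog(h)$action, "dropped")
  expect_identical(nInstruments(h), 0L)
  # frequencies informative and concordant: kept
  h <- harmPair(c("A", "T"), c("A", "T"), exp_eaf = 0.2, out_eaf = 0.25)
  expect_identical(harmonizationLog(h)$action, "kept")
  # informative but discordant: flipped with beta negated
  h <- harmPair(c("C", "G"), c("C", "G"), exp_eaf = 0.2, out_eaf = 0.8)
  d <- instrumentData(h)
  expect_identical(d$action, "flipped")
  expect_equal(d$beta_outcome, -0.05)
  # frequency just inside the band on either side: dropped
  h <- harmPair(c("A", "T"), c("T", "A"), exp_eaf = 0.44, out_eaf = 0.2)
  expect_identical(harmonizationLog(h)$action, "dropped")
})

test_that("unmatchable allele pairs drop and the intersection partitions", {
  h <- harmPair(c("A", "G"), c("A", "C"))
  expect_identical(harmonizationLog(h)$action, "dropped")
  expect_identical(harmonizationLog(h)$reason, "allele_mismatch")

  pair <- simulatePair(simConfig(nSnps = 25), seed = 99)
  h <- harmonize(pair$exposure, pair$outcome)
  log <- harmonizationLog(h)
  n_common <- length(intersect(snpData(pair$exposure)$snp,
                               snpData(pair$outcome)$snp))
  expect_identical(nrow(log), n_common)
  expect_identical(sum(log$action %in% c("kept", "flipped", "dropped")),
                   n_common)
})

test_that("an empty intersection warns and returns a structured empty set", {
  ex <- makeGwas("rs1", 0.1, 0.02)
  ou <- makeGwas("rs2", 0.1, 0.02)
  expect_warning(h <- harmonize(ex, ou), "no SNPs shared")
  expect_identical(nInstruments(h), 0L)
  expect_identical(nrow(harmonizationLog(h)), 0L)
})

harmToGwas <- function(h) {
  d <- h@data[h@data$action != "dropped", ]
  list(
    exposure = GwasSummaryStats(data.frame(
      snp = d$snp, chrom = d$chrom, pos = d$pos,
      effect_allele = d$effect_allele, other_allele = d$other_allele,
      eaf = d$eaf_exposure, beta = d$beta_exposure, se = d$se_exposure,
      pval = d$pval_exposure, n = 5000)),
    outcome = GwasSummaryStats(data.frame(
      snp = d$snp, chrom = d$chrom, pos = d$pos,
      effect_allele = d$effect_allele, other_allele = d$other_allele,
      eaf = d$eaf_outcome, beta = d$beta_outcome, se = d$se_outcome,
      pval = d$pval_outcome, n = 5000)))
}

test_that("harmonization is idempotent", {
  for (seed in c(3, 17, 29)) {
    pair <- simulatePair(simConfig(nSnps = 20), seed = seed)
    h1 <- harmonize(pair$exposure, pair$outcome)
    back <- harmToGwas(h1)
    h2 <- harmonize(back$exposure, back$outcome)
    d1 <- instrumentData(h1); d2 <- instrumentData(h2)
    expect_identical(d2$action, rep("kept", nrow(d2)))
    expect_equal(d2$beta_outcome, d1$beta_outcome, tolerance = 1e-12)
    expect_equal(d2$beta_exposure, d1$beta_exposure, tolerance = 1e-12)
  }
})

test_that("relabelling the outcome alleles leaves the instruments unchanged", {
  pair <- simulatePair(simConfig(nSnps = 20, palindromicFraction = 0),
                       seed = 7)
  od <- snpData(pair$outcome)
  relabelled <- GwasSummaryStats(transform(
    od, effect_allele = other_allele, other_allele = effect_allele,
    beta = -beta, eaf = 1 - eaf))
  h1 <- instrumentData(harmonize(pair$exposure, pair$outcome))
  h2 <- instrumentData(harmonize(pair$exposure, relabelled))
  expect_identical(h2$snp, h1$snp)
  expect_equal(h2$beta_outcome, h1$beta_outcome, tolerance = 1e-12)
  expect_equal(h2$eaf_outcome, h1$eaf_outcome, tolerance = 1e-12)
})
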