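# 95% Wald interval multiplier used throughout
Z95 <- 1.959964

configError <- function(msg, ...) {
  stop(structure(class = c("mrscreenConfigError", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

validationError <- function(msg, ...) {
  stop(structure(class = c("mrscreenValidationError", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

withSeedIfGiven <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Two-sided normal p-value, never exactly 0 (kept inside (0, 1])
pvalNormal2 <- function(z) pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)

newMrEstimate <- function(method, beta, se, nSnps, scale, df = NULL,
                          extra = list()) {
  if (is.na(beta) || is.na(se) || se <= 0) {
    p <- NA_real_; lo <- NA_real_; hi <- NA_real_
    se <- if (is.na(se) || se <= 0) NA_real_ else se
  } else if (!is.null(df)) {
    p <- pmax(2 * stats::pt(-abs(beta / se), df = df), .Machine$double.xmin)
    lo <- beta - Z95 * se; hi <- beta + Z95 * se
  } else {
    p <- pvalNormal2(beta / se)
    lo <- beta - Z95 * se; hi <- beta + Z95 * se
  }
  new("MrEstimate", method = method, beta = beta, se = se, ciLow = lo,
      ciHigh = hi, pval = p, nSnps = as.integer(nSnps), scale = scale,
      extra = extra)
}

# Fixed-point rendering at 3 decimals
fmt3 <- function(x) formatC(x, format = "f", digits = 3)

# p-value rendering: 3 decimals, scientific "2.35E-4" style below 0.001
fmtPval <- function(p) {
  out <- character(length(p))
  small <- !is.na(p) & p < 1e-3
  out[small] <- sub("E([+-])0+(\\d)", "E\\1\\2",
                    formatC(p[small], format = "E", digits = 2))
  out[!small & !is.na(p)] <- fmt3(p[!small & !is.na(p)])
  out[is.na(p)] <- "NA"
  out
}

# "1.115 (1.024–1.215)" with an en dash
fmtEstimateCi <- function(mid, lo, hi)
  sprintf("%s (%s–%s)", fmt3(mid), fmt3(lo), fmt3(hi))

logMsg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}
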