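test_that("Wald ratios follow the first-order delta formula", {
  h <- toyInstruments(c(1, 0.2, -0.2), c(0.01, 0.01, 0.01),
                      c(0.05, 0.05, 0.05), c(0.02, 0.02, 0.02))
  r <- waldRatios(h)
  expect_equal(r$ratio, c(0.05, 0.25, -0.25))
  expect_equal(r$se, c(0.02, 0.10, 0.10))
  expect_equal(r$weight, r$se^-2)

  h0 <- toyInstruments(c(0.2, 0), c(0.01, 0.01), c(0.05, 0.05),
                       c(0.02, 0.02))
  expect_error(waldRatios(h0), "rs002", class = "mrscreenValidationError")
})

test_that("the second-order ratio SE adds the exposure term", {
  h <- toyInstruments(0.2, 0.05, 0.05, 0.02)
  r2 <- waldRatios(h, secondOrder = TRUE)
  expect_equal(r2$se, sqrt(0.02^2 / 0.2^2 + 0.05^2 * 0.05^2 / 0.2^4))
  expect_gt(r2$se, waldRatios(h)$se)
})

test_that("IVW equals the precision-weighted mean of the ratios", {
  h <- ratioInstruments(c(0.10, 0.20, 0.30), c(0.1, 0.1, 0.1))
  est <- mrIvw(h, mode = "fixed")
  expect_equal(est@beta, 0.20, tolerance = 1e-10)
  expect_equal(est@se, 0.1 / sqrt(3), tolerance = 1e-10)
  expect_identical(est@method, "IVW-fixed")
  expect_identical(est@nSnps, 3L)

  # homogeneous ratios: Q = 0 and mode auto stays fixed
  hom <- ratioInstruments(rep(0.2, 4), c(0.1, 0.2, 0.1, 0.3))
  auto <- mrIvw(hom, mode = "auto")
  expect_equal(auto@extra$Q, 0, tolerance = 1e-20)
  expect_identical(auto@method, "IVW-fixed")
})

test_that("IVW degenerates gracefully at zero or one instrument", {
  one <- ratioInstruments(0.25, 0.1)
  expect_warning(est <- mrIvw(one), "single instrument")
  expect_equal(est@beta, 0.25)
  expect_equal(est@se, 0.1)

  empty <- HarmonizedInstruments(data.frame(
    snp = "rs1", beta_exposure = 1, se_exposure = 0.01,
    beta_outcome = 0.1, se_outcome = 0.02, action = "dropped"))
  expect_warning(e0 <- mrIvw(empty), "no instruments")
  expect_true(is.na(e0@beta))
  expect_identical(e0@nSnps, 0L)
})

test_that("random-effects IVW inflates but never deflates the SE", {
  set.seed(21)
  for (i in 1:10) {
    J <- sample(3:12, 1)
    h <- ratioInstruments(rnorm(J, 0.2, 0.3), runif(J, 0.05, 0.3))
    fx <- mrIvw(h, "fixed"); rnd <- mrIvw(h, "random")
    expect_equal(rnd@beta, fx@beta)
    expect_gte(rnd@se, fx@se)
    expect_equal(rnd@se,
                 fx@se * max(1, sqrt(fx@extra$Q / (J - 1))),
                 tolerance = 1e-12)
  }
})

test_that("IVW-fixed equals the intercept-free weighted regression slope", {
  set.seed(8)
  for (i in 1:10) {
    J <- sample(4:15, 1)
    g <- runif(J, 0.05, 0.5) * sample(c(-1, 1), J, TRUE)
    h <- toyInstruments(g, rep(1e-8, J), 0.3 * g + rnorm(J, 0, 0.02),
                        runif(J, 0.01, 0.05))
    d <- instrumentData(h)
    lmfit <- lm(beta_outcome ~ 0 + beta_exposure, data = d,
                weights = d$se_outcome^-2)
    expect_equal(mrIvw(h, "fixed")@beta, unname(coef(lmfit)),
                 tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact linear law and its intercept", {
  g <- c(0.1, 0.2, 0.3, 0.4)
  h <- toyInstruments(g, rep(1e-8, 4), 0.5 * g + 0.03, rep(0.05, 4))
  fit <- mrEgger(h)
  expect_equal(fit@slope@beta, 0.5, tolerance = 1e-10)
  expect_equal(fit@intercept@estimate, 0.03, tolerance = 1e-10)
  expect_equal(fit@q@Q, 0, tolerance = 1e-16)

  expect_error(mrEgger(toyInstruments(c(0.1, 0.2), c(0.01, 0.01),
                                      c(0.05, 0.1), c(0.02, 0.02))),
               "at least 3", class = "mrscreenValidationError")
})

test_that("Egger is invariant to flipping the instrument orientation", {
  set.seed(5)
  g <- runif(6, 0.1, 0.5)
  y <- 0.4 * g + rnorm(6, 0.02, 0.01)
  h1 <- toyInstruments(g, rep(0.01, 6), y, rep(0.05, 6))
  h2 <- toyInstruments(-g, rep(0.01, 6), -y, rep(0.05, 6))
  f1 <- mrEgger(h1); f2 <- mrEgger(h2)
  expect_equal(f2@slope@beta, f1@slope@beta, tolerance = 1e-12)
  expect_equal(f2@intercept@estimate, f1@intercept@estimate,
               tolerance = 1e-12)
  expect_equal(f2@slope@se, f1@slope@se, tolerance = 1e-12)
})

test_that("Egger matches the weighted lm oracle including inflated SEs", {
  set.seed(13)
  for (i in 1:8) {
    J <- sample(5:15, 1)
    g <- runif(J, 0.05, 0.6)
    y <- 0.25 * g + rnorm(J, 0.01, 0.04)
    w <- runif(J, 100, 2000)
    h <- toyInstruments(g, rep(0.01, J), y, 1 / sqrt(w))
    fit <- mrEgger(h)
    lmfit <- lm(y ~ g, weights = w)
    sm <- summary(lmfit)
    expect_equal(fit@slope@beta, unname(coef(lmfit)[2]), tolerance = 1e-10)
    expect_equal(fit@intercept@estimate, unname(coef(lmfit)[1]),
                 tolerance = 1e-10)
    # lm scales SEs by sigma-hat; the Egger convention never deflates
    adj <- max(1, sm$sigma) / sm$sigma
    expect_equal(fit@slope@se, unname(sm$coefficients[2, 2]) * adj,
                 tolerance = 1e-8)
  }
})

test_that("the weighted median interpolates the 0.5 weight crossing", {
  same <- ratioInstruments(rep(0.2, 5), c(0.1, 0.5, 0.2, 0.1, 0.3))
  expect_equal(suppressWarnings(mrWeightedMedian(same, seed = 1))@beta, 0.2)

  h <- ratioInstruments(c(0.1, 0.2, 0.9), rep(0.1, 3))
  est <- mrWeightedMedian(h, nBoot = 200, seed = 1)
  expect_equal(est@beta, 0.2, tolerance = 1e-12)

  expect_error(mrWeightedMedian(ratioInstruments(c(0.1, 0.2), c(0.1, 0.1)),
                                seed = 1),
               "at least 3", class = "mrscreenValidationError")
  expect_warning(mrWeightedMedian(h, nBoot = 50, seed = 1), "nBoot")
  expect_warning(mrWeightedMedian(h, nBoot = 200), "seed")
})

test_that("the weighted median bootstrap is seed-reproducible", {
  h <- ratioInstruments(c(0.05, 0.1, 0.15, 0.4), c(0.05, 0.06, 0.05, 0.2))
  e1 <- mrWeightedMedian(h, nBoot = 300, seed = 42)
  e2 <- mrWeightedMedian(h, nBoot = 300, seed = 42)
  e3 <- mrWeightedMedian(h, nBoot = 300, seed = 43)
  expect_identical(e1@se, e2@se)
  expect_false(identical(e1@se, e3@se))
})

test_that("estimators agree at a single dominant instrument", {
  # two instruments carry vanishing weight; all methods approach the
  # dominant Wald ratio
  h <- ratioInstruments(c(0.30, 0.9, -0.5), c(0.01, 50, 50))
  wald <- waldRatios(h)$ratio[1]
  expect_equal(mrIvw(h, "fixed")@beta, wald, tolerance = 1e-5)
  expect_equal(mrWeightedMedian(h, nBoot = 200, seed = 1)@beta, wald,
               tolerance = 1e-5)
})

test_that("odds-ratio rendering matches the printed-table convention", {
  # back-calculated from a published CI: log(1.115)=0.10922, se from the
  # CI width / (2 * 1.959964)
  est <- mrscreen:::newMrEstimate("IVW-fixed", 0.10922, 0.043627, 8L,
                                  "log-OR")
  o <- toOddsRatio(est)
  expect_identical(o$label, "1.115 (1.024–1.215)")

  zero <- mrscreen:::newMrEstimate("IVW-fixed", 0, 0.05, 8L, "log-OR")
  oz <- toOddsRatio(zero)
  expect_equal(oz$or, 1)
  expect_equal(oz$ciLow, exp(-mrscreen:::Z95 * 0.05))

  neg <- mrscreen:::newMrEstimate("IVW-fixed", -0.10922, 0.043627, 8L,
                                  "log-OR")
  on <- toOddsRatio(neg)
  expect_equal(on$or, 1 / o$or, tolerance = 1e-12)
  expect_equal(on$ciLow, 1 / o$ciHigh, tolerance = 1e-12)
  expect_equal(on$ciHigh, 1 / o$ciLow, tolerance = 1e-12)
})
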