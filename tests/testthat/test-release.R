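test_that("cumulative release applies the sampling-replacement correction", {
  expect_equal(cumulative_release(0.001, Ve = 1, Vo = 200, m = 1), 20)
  expect_equal(cumulative_release(c(0.001, 0.002), 1, 200, 1), c(20, 40.1))
  # Ve = 0 removes the correction entirely
  conc <- c(0.01, 0.02, 0.03)
  expect_equal(cumulative_release(conc, 0, 200, 10), 200 * conc / 10 * 100)
  expect_error(cumulative_release(conc, 1, 0, 1), "positive")
  expect_error(cumulative_release(conc, 1, 200, 0), "positive")
  expect_error(cumulative_release(c(-1, 1), 1, 200, 1), "non-negative")
  # non-decreasing whenever concentrations are non-decreasing
  for (s in 1:10) {
    set.seed(s)
    cc <- sort(runif(8, 0, 0.05))
    expect_true(all(diff(cumulative_release(cc, 1, 200, 20)) >= 0))
  }
})

test_that("noise-free curves return their generating parameters", {
  t <- release_times()
  kp <- fit_kinetic("korsmeyer_peppas", t, 21.174 * t^0.410)
  expect_equal(coef(kp)[["KKP"]], 21.174, tolerance = 1e-6)
  expect_equal(coef(kp)[["n"]], 0.410, tolerance = 1e-6)
  fo <- fit_kinetic("first_order", t, 100 * (1 - exp(-0.314 * t)))
  expect_equal(coef(fo)[["K1"]], 0.314, tolerance = 1e-6)
  hg <- fit_kinetic("higuchi", t, 19.5 * sqrt(t))
  expect_equal(coef(hg)[["KH"]], 19.5, tolerance = 1e-6)
  zo <- fit_kinetic("zero_order", t, 3.2 * t)
  expect_equal(coef(zo)[["K0"]], 3.2, tolerance = 1e-6)
  hc <- fit_kinetic("hixson_crowell", t, 100 - (100^(1 / 3) - 0.12 * t)^3)
  expect_equal(coef(hc)[["KHC"]], 0.12, tolerance = 1e-6)
})

test_that("fitting is invariant to the ordering of the input points", {
  t <- release_times()
  cr <- 21.174 * t^0.410 + c(0.3, -0.2, 0.1, 0, -0.4, 0.2, -0.1)
  f1 <- fit_kinetic("korsmeyer_peppas", t, cr)
  ord <- c(4, 1, 7, 2, 6, 3, 5)
  f2 <- fit_kinetic("korsmeyer_peppas", t[ord], cr[ord])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$MSC, f2$MSC, tolerance = 1e-10)
})

test_that("input validation for kinetic fits", {
  t <- release_times()
  expect_error(fit_kinetic("weibull", t, t), "unknown kinetic model")
  expect_error(fit_kinetic("zero_order", c(0, 1, 2), c(0, 1, 2)),
               "strictly positive")
  expect_error(fit_kinetic("korsmeyer_peppas", c(1, 2), c(10, 20)),
               "n_params")
})

test_that("information criteria follow the unweighted DDsolver forms", {
  ic <- information_criteria(63.2, 63.2 / (1 - 0.9943), 8, 2)
  expect_equal(ic$AIC, 8 * log(63.2) + 4, tolerance = 1e-12)
  expect_equal(ic$AIC, 37.17, tolerance = 0.01)
  # SSR = SST degenerates to R2 = 0, MSC = -2p/n
  ic0 <- information_criteria(10, 10, 8, 2)
  expect_equal(ic0$r_squared, 0)
  expect_equal(ic0$MSC, -0.5)
  # halving SSR at fixed n, p drops AIC by n ln 2
  expect_equal(information_criteria(5, 10, 8, 2)$AIC,
               ic0$AIC - 8 * log(2), tolerance = 1e-12)
  # perfect fit sentinels
  icp <- information_criteria(0, 10, 8, 2)
  expect_identical(icp$AIC, -Inf)
  expect_identical(icp$MSC, Inf)
  expect_error(information_criteria(1, 10, 2, 2), "exceed")
})

test_that("MSC and R-squared satisfy their identity on every stored fit", {
  t <- release_times()
  curves <- list(
    kp = gen_release_curve("korsmeyer_peppas", c(KKP = 21.174, n = 0.410),
                           t, sd = 1, seed = 11)$cr,
    fo = gen_release_curve("first_order", c(K1 = 0.314), t, sd = 1,
                           seed = 12)$cr)
  for (cr in curves)
    for (fit in fit_all_kinetics(t, cr)) {
      expect_equal(fit$MSC,
                   -log(1 - fit$r_squared) - 2 * fit$n_params / fit$n_points,
                   tolerance = 1e-10)
      expect_lte(fit$r_squared, 1)
    }
})

test_that("the diffusional exponent maps to its transport mechanism", {
  expect_equal(classify_exponent(0.395), "quasi-Fickian diffusion")
  expect_equal(classify_exponent(0.410), "quasi-Fickian diffusion")
  expect_equal(classify_exponent(0.45), "Fickian diffusion")
  expect_equal(classify_exponent(0.60), "non-Fickian (anomalous) transport")
  expect_equal(classify_exponent(0.89), "case-II (zero-order) transport")
  expect_equal(classify_exponent(1.2), "super case-II transport")
  # equality tolerance at the thresholds
  expect_equal(classify_exponent(0.45 + 1e-12), "Fickian diffusion")
  expect_error(classify_exponent(NaN), "finite")
})

test_that("model selection ranks by MSC with a parsimony tie-break", {
  t <- release_times()
  # data generated from the two-parameter model: it wins outright
  cr_kp <- 21.174 * t^0.410
  sel <- select_model(fit_all_kinetics(t, cr_kp))
  expect_equal(sel$model, "korsmeyer_peppas")
  # first-order data with mild noise: one-parameter first-order wins
  fo <- gen_release_curve("first_order", c(K1 = 0.314), t, sd = 0.5,
                          seed = 0)
  fits <- fit_all_kinetics(fo$t, fo$cr)
  expect_equal(select_model(fits)$model, "first_order")
  # exhaustive oracle: the winner has the max MSC among converged fits
  msc <- vapply(fits, `[[`, numeric(1), "MSC")
  expect_equal(select_model(fits)$MSC, max(msc))
  # two identical candidates: fewer parameters preferred
  a <- fits$first_order
  b <- fits$korsmeyer_peppas
  b$MSC <- a$MSC
  expect_equal(select_model(list(b, a))$model, "first_order")
  expect_error(select_model(list()), "selection failed")
})

test_that("constant release data is reported as degenerate", {
  t <- release_times()
  fit <- fit_kinetic("zero_order", t, rep(50, length(t)))
  expect_true(fit$degenerate)
  expect_true(is.nan(fit$r_squared))
})

test_that("exponent recovery from noisy Korsmeyer-Peppas curves", {
  t <- release_times()
  err <- vapply(1:200, function(s) {
    g <- gen_release_curve("korsmeyer_peppas", c(KKP = 21.174, n = 0.410),
                           t, sd = 1, seed = 5000 + s)
    abs(coef(fit_kinetic("korsmeyer_peppas", g$t, g$cr))[["n"]] - 0.410)
  }, numeric(1))
  expect_lt(median(err), 0.02)
})
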