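test_that("OLS coefficients match the normal-equations oracle", {
  des <- table2_design()
  Z <- coded_settings(des)
  term_sets <- list(
    c("1", "A", "B", "C"),
    c("1", "A", "B", "C", "AC", "BC", "A2"),
    c("1", "A", "B", "C", "AB", "BC", "A2", "B2", "C2"),
    quadratic_terms(des))
  for (resp in c("Y1", "Y2", "Y3", "Y4"))
    for (terms in term_sets) {
      fit <- fit_rsm(des, resp, terms)
      oracle <- ols_oracle(oracle_model_matrix(Z, terms), des[[resp]])
      expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-10)
    }
})

test_that("published design refits reproduce the reported coefficients", {
  des <- cbd_sln_design()
  dl <- fit_rsm(des, "Y4", names(eq_dl))
  expect_equal(coef(dl)[["AC"]], -0.1250, tolerance = 1e-10)
  expect_equal(coef(dl)[["BC"]], -0.0175, tolerance = 1e-10)
  expect_equal(coef(dl)[["C"]], 0.5163, tolerance = 0.01)
  expect_equal(coef(dl)[["A"]], -0.3425, tolerance = 0.01)
  expect_equal(round(coef(dl)[["1"]], 2), 1.36)
  size <- fit_rsm(des, "Y1", names(eq_size))
  expect_equal(coef(size)[["B"]], -35.20, tolerance = 0.01)
  expect_equal(coef(size)[["C"]], -33.95, tolerance = 0.01)
  pdi <- fit_rsm(des, "Y2", names(eq_pdi))
  expect_equal(coef(pdi)[["AB"]], -0.0913, tolerance = 0.01)
})

test_that("pure error comes from the replicate groups", {
  des <- table2_design()
  pe <- pure_error(des, "Y1")
  expect_equal(pe$SS, 14 / 3, tolerance = 1e-12)  # centers 139, 138, 136
  expect_equal(pe$df, 2L)
  # identical replicates give zero pure error
  des2 <- set_responses(des, Yc = c(seq_len(12), 5, 5, 5))
  expect_equal(pure_error(des2, "Yc")$SS, 0)
  # no replicates at all: SS = 0, df = 0, with a warning
  des1 <- bbd_design(table1_factors(), n_center = 1)
  des1 <- set_responses(des1, Y = rnorm(13))
  expect_warning(pe1 <- pure_error(des1, "Y"), "no replicated runs")
  expect_equal(pe1$df, 0L)
})

test_that("ANOVA decomposition identities hold", {
  des <- table2_design()
  for (resp in c("Y1", "Y4")) {
    fit <- fit_rsm(des, resp, quadratic_terms(des))
    expect_equal(fit$SS$model + fit$SS$residual, fit$SS$total,
                 tolerance = 1e-8 * fit$SS$total)
    expect_equal(fit$lack_of_fit$SS + fit$pure_error$SS, fit$SS$residual,
                 tolerance = 1e-8)
    expect_equal(fit$lack_of_fit$df + fit$pure_error$df, fit$df_residual)
    expect_gte(fit$r_squared, 0); expect_lte(fit$r_squared, 1)
    expect_lte(fit$adj_r_squared, fit$r_squared)
  }
})

test_that("coefficients are invariant to dropping other linear/interaction terms", {
  # BBD orthogonality: removing any other first-order or interaction term
  # leaves the remaining estimates unchanged
  des <- table2_design()
  full <- c("1", "A", "B", "C", "AB", "AC", "BC")
  fit_full <- fit_rsm(des, "Y1", full)
  for (drop in c("A", "B", "C", "AB", "AC", "BC")) {
    kept <- setdiff(full, drop)
    fit_red <- fit_rsm(des, "Y1", kept)
    expect_equal(coef(fit_red)[setdiff(kept, "1")],
                 coef(fit_full)[setdiff(kept, "1")], tolerance = 1e-10)
  }
})

test_that("adding a term never decreases R-squared", {
  des <- table2_design()
  terms <- c("1", "A")
  prev <- fit_rsm(des, "Y2", terms)$r_squared
  for (tm in c("B", "C", "AB", "AC", "BC", "A2", "B2", "C2")) {
    terms <- c(terms, tm)
    cur <- fit_rsm(des, "Y2", terms)$r_squared
    expect_gte(cur + 1e-12, prev)
    prev <- cur
  }
})

test_that("noise-free synthetic surfaces are interpolated exactly", {
  des <- bbd_design(table1_factors(), 3)
  synth <- gen_rsm_dataset(des, eq_dl, sd = 0)
  fit <- fit_rsm(synth, "Y", names(eq_dl))
  expect_equal(coef(fit), eq_dl, tolerance = 1e-10)
})

test_that("predicted R-squared matches a leave-one-out refit oracle", {
  des <- table2_design()
  for (resp in c("Y1", "Y3")) {
    terms <- c("1", "A", "B", "C", "AB", "A2")
    fit <- fit_rsm(des, resp, terms)
    X <- oracle_model_matrix(coded_settings(des), terms)
    y <- des[[resp]]
    press <- sum(vapply(seq_along(y), function(i) {
      b <- ols_oracle(X[-i, , drop = FALSE], y[-i])
      (y[i] - sum(X[i, ] * b))^2
    }, numeric(1)))
    expect_equal(predicted_r2(fit), 1 - press / sum((y - mean(y))^2),
                 tolerance = 1e-8)
  }
})

test_that("intercept-only predicted R-squared is non-positive on symmetric data", {
  des <- bbd_design(table1_factors(), 3)
  y <- c(rep(c(-1, 1), 6), 0, 0, 0)
  fit <- fit_rsm(set_responses(des, Y = y), "Y", "1")
  # closed form: LOO residual of the mean model is e_i * n/(n-1)
  n <- length(y)
  press <- sum((y - mean(y))^2 * (n / (n - 1))^2)
  expect_equal(predicted_r2(fit), 1 - press / sum((y - mean(y))^2),
               tolerance = 1e-10)
  expect_lte(predicted_r2(fit), 0)
})

test_that("saturated and rank-deficient model matrices are caught", {
  des <- table2_design()
  # edge runs only: A^2 + B^2 + C^2 = 2 is collinear with the intercept
  edge <- des[!des$center, , drop = FALSE]
  attr(edge, "factors") <- attr(des, "factors")
  class(edge) <- class(des)
  expect_error(fit_rsm(edge, "Y1", c("1", "A2", "B2", "C2")),
               "singular fit")
  # more terms than runs
  three <- des[13:15, , drop = FALSE]
  attr(three, "factors") <- attr(des, "factors")
  class(three) <- class(des)
  expect_error(fit_rsm(three, "Y1", c("1", "A", "B", "C")),
               "more model terms")
})

test_that("missing or unknown responses are data errors", {
  des <- bbd_design(table1_factors(), 3)
  expect_error(fit_rsm(des, "Y9", c("1", "A")), "not found")
  desNA <- set_responses(des, Y = c(NA, rnorm(14)))
  expect_error(fit_rsm(desNA, "Y", c("1", "A")), "missing values")
})

test_that("backward elimination reproduces the published reduced models", {
  des <- cbd_sln_design()
  ee <- reduce_model(des, "Y3", alpha = 0.05)
  expect_setequal(ee$terms, c("1", "A", "B", "C"))
  dl <- reduce_model(des, "Y4", alpha = 0.05)
  expect_setequal(dl$terms, c("1", "A", "B", "C", "AC", "BC", "A2"))
  expect_true(all(c("AB", "B2", "C2") %in% dl$elimination$dropped))
  # every surviving non-protected term is significant
  expect_true(all(dl$anova$p <= 0.05))
})

test_that("elimination recovers a linear-only truth from light noise", {
  # each spurious term survives with roughly the type-I rate (5%), so exact
  # recovery happens in about 0.95^6 of datasets; the true linear terms must
  # always survive
  des <- bbd_design(table1_factors(), 3)
  truth <- c("1" = 10, A = 2, B = -1.5, C = 1)
  spurious <- vapply(1:40, function(s) {
    synth <- gen_rsm_dataset(des, truth, sd = 0.05, seed = s)
    terms <- reduce_model(synth, "Y", alpha = 0.05)$terms
    expect_true(all(c("1", "A", "B", "C") %in% terms))
    length(setdiff(terms, c("1", "A", "B", "C")))
  }, numeric(1))
  expect_gte(mean(spurious == 0), 0.5)
  expect_lte(mean(spurious), 1)
})

test_that("constant responses degrade gracefully", {
  des <- bbd_design(table1_factors(), 3)
  flat <- set_responses(des, Y = rep(7, 15))
  expect_warning(fit <- fit_rsm(flat, "Y", c("1", "A", "B")),
                 "constant response")
  expect_equal(unname(coef(fit)), c(7, 0, 0), tolerance = 1e-12)
  expect_true(is.nan(fit$r_squared))
})

test_that("coefficient estimates are unbiased on noisy synthetic surfaces", {
  des <- bbd_design(table1_factors(), 3)
  truth <- eq_dl
  sims <- vapply(1:500, function(s) {
    synth <- gen_rsm_dataset(des, truth, sd = 0.02, seed = 1000 + s)
    coef(fit_rsm(synth, "Y", names(truth)))
  }, numeric(length(truth)))
  est_mean <- rowMeans(sims)
  est_se <- apply(sims, 1, sd) / sqrt(ncol(sims))
  expect_true(all(abs(est_mean - truth) < 3 * est_se))
})
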