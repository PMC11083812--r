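# Study fixtures built in code, plus independent oracles used across tests.

table1_factors <- function() {
  list(bbd_factor("A", 1.5, 2.5, "g"),
       bbd_factor("B", 0.6, 1.0, "g"),
       bbd_factor("C", 10, 20, "mg"))
}

# the published 15-run design with its four measured responses
table2_design <- function() {
  des <- bbd_design(table1_factors(), n_center = 3)
  set_responses(des,
    Y1 = c(223, 300, 234, 140, 196, 183, 130, 119, 257, 127, 122, 120,
           139, 138, 136),
    Y2 = c(0.2544, 0.4440, 0.4328, 0.2574, 0.2999, 0.3165, 0.2548, 0.2602,
           0.2862, 0.2770, 0.2516, 0.2043, 0.2914, 0.2905, 0.2844),
    Y3 = c(92.7, 96.5, 87.9, 90.8, 87.0, 89.4, 92.4, 94.9, 86.6, 84.6,
           96.1, 91.8, 90.2, 91.9, 91.3),
    Y4 = c(1.82, 1.15, 1.75, 1.08, 1.15, 0.71, 2.45, 1.51, 0.86, 0.84,
           1.91, 1.82, 1.34, 1.37, 1.36))
}

# brute-force OLS through the normal equations (oracle for fit_rsm)
ols_oracle <- function(X, y) drop(solve(t(X) %*% X, t(X) %*% y))

# model-matrix builder independent of the package internals
oracle_model_matrix <- function(Z, terms) {
  cols <- lapply(terms, function(tm) {
    if (tm == "1") rep(1, nrow(Z))
    else if (tm %in% colnames(Z)) Z[, tm]
    else if (grepl("2$", tm)) Z[, sub("2$", "", tm)]^2
    else Z[, substr(tm, 1, 1)] * Z[, substr(tm, 2, 2)]
  })
  do.call(cbind, stats::setNames(cols, terms))
}

# published reduced-model coefficient vectors (coded units)
eq_size <- c("1" = 137.91, A = -5.26, B = -35.20, C = -33.95, AB = -42.65,
             BC = 32.12, A2 = 43.62, B2 = 43.15, C2 = -24.08)
eq_pdi <- c("1" = 0.2888, A = 0.0045, B = -0.0081, C = -0.0261,
            AB = -0.0913, A2 = 0.0432, B2 = 0.0152, C2 = -0.0491)
eq_ee <- c("1" = 91.12, A = 1.44, B = -2.47, C = 3.10)
eq_dl <- c("1" = 1.36, A = -0.3425, B = -0.0338, C = 0.5163, AC = -0.1250,
           BC = -0.0175, A2 = 0.0979)

# evaluate a published equation at coded settings through the public API
eval_equation <- function(coefs, point) {
  des <- bbd_design(table1_factors(), n_center = 3)
  fit <- fit_rsm(gen_rsm_dataset(des, coefs, sd = 0), "Y", names(coefs))
  predict(fit, point)
}

release_times <- function() c(0.5, 1, 2, 4, 8, 12, 24)

# one fresh normal draw under a local seed (for coverage experiments)
with_seed_draw <- function(seed, mean, sd) {
  set.seed(seed)
  rnorm(1, mean, sd)
}

withr_tempfile <- function(ext = ".csv") {
  f <- tempfile(fileext = ext)
  withr::defer(unlink(f), envir = parent.frame())
  f
}

withr_tempdir <- function() {
  d <- tempfile()
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = parent.frame())
  d
}
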