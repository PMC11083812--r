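#' Cumulative percent released with sampling-replacement correction
#'
#' In a dialysis release experiment an aliquot of volume `Ve` is withdrawn at
#' each timepoint and replaced with fresh medium, so drug removed in earlier
#' aliquots must be added back.  For measured concentrations `C_1..C_N`
#' (mg/mL) the cumulative percent released at point n is
#' `CR_n = (Ve * sum(C_1..C_{n-1}) + Vo * C_n) / m * 100`, where `Vo` is the
#' vessel volume (mL) and `m` the total drug in the dialysis bag (mg).
#'
#' @param conc Measured concentrations at successive timepoints (mg/mL).
#' @param Ve Aliquot (collection) volume, mL; 0 disables the correction.
#' @param Vo Medium volume, mL (> 0).
#' @param m Total drug in the bag, mg (> 0).
#' @return Cumulative percent released at each timepoint.
#' @examples
#' cumulative_release(c(0.001, 0.002), Ve = 1, Vo = 200, m = 1)  # 20, 40.1
#' @export
cumulative_release <- function(conc, Ve, Vo, m) {
  if (!is.numeric(conc) || any(conc < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (Ve < 0) stop("'Ve' must be non-negative", call. = FALSE)
  if (Vo <= 0 || m <= 0)
    stop("'Vo' and 'm' must be positive", call. = FALSE)
  n <- length(conc)
  prior <- c(0, cumsum(conc)[-n])       # sum of earlier aliquot concentrations
  (Ve * prior + Vo * conc) / m * 100
}

# invert cumulative_release: concentrations that reproduce a CR profile
concentrations_from_cr <- function(cr, Ve, Vo, m) {
  conc <- numeric(length(cr))
  prior <- 0
  for (i in seq_along(cr)) {
    conc[i] <- (m * cr[i] / 100 - Ve * prior) / Vo
    prior <- prior + conc[i]
  }
  conc
}

# ---- kinetic model registry ------------------------------------------------

# Each model: release fraction F(t) in percent, parameter names, an
# admissibility check, and a linearized start-value estimator.
kinetic_models <- function() {
  list(
    zero_order = list(
      params = "K0",
      fn = function(t, p) p[["K0"]] * t,
      start = function(t, cr)
        c(K0 = unname(stats::coef(stats::lm(cr ~ t - 1)))),
      check = function(p) p[["K0"]] >= 0),
    first_order = list(
      params = "K1",
      fn = function(t, p) 100 * (1 - exp(-p[["K1"]] * t)),
      start = function(t, cr) {
        z <- log(pmax(1 - cr / 100, 1e-6))
        c(K1 = max(1e-6, -unname(stats::coef(stats::lm(z ~ t - 1)))))
      },
      check = function(p) p[["K1"]] > 0),
    higuchi = list(
      params = "KH",
      fn = function(t, p) p[["KH"]] * sqrt(t),
      start = function(t, cr)
        c(KH = unname(stats::coef(stats::lm(cr ~ I(sqrt(t)) - 1)))),
      check = function(p) p[["KH"]] >= 0),
    korsmeyer_peppas = list(
      params = c("KKP", "n"),
      fn = function(t, p) p[["KKP"]] * t^p[["n"]],
      start = function(t, cr) {
        ok <- cr > 0
        co <- stats::coef(stats::lm(log(cr[ok]) ~ log(t[ok])))
        c(KKP = unname(exp(co[1])), n = unname(co[2]))
      },
      check = function(p) p[["KKP"]] > 0 && p[["n"]] > 0),
    hixson_crowell = list(
      params = "KHC",
      fn = function(t, p) 100 - (100^(1 / 3) - p[["KHC"]] * t)^3,
      start = function(t, cr) {
        z <- 100^(1 / 3) - pmax(100 - cr, 0)^(1 / 3)
        c(KHC = max(1e-6, unname(stats::coef(stats::lm(z ~ t - 1)))))
      },
      check = function(p) p[["KHC"]] >= 0)
  )
}

#' Names of the supported release kinetic models
#' @return Character vector of model ids.
#' @export
kinetic_model_ids <- function() names(kinetic_models())

#' Goodness-of-fit criteria for a release-model fit
#'
#' `R2 = 1 - SSR/SST`, the DDsolver-style unweighted
#' `AIC = n * ln(SSR) + 2p`, and the model selection criterion
#' `MSC = ln(SST/SSR) - 2p/n` (higher is better).
#'
#' @param SSR Residual sum of squares (model).
#' @param SST Total sum of squares about the mean of the data.
#' @param n Number of fitted points (> p).
#' @param p Number of model parameters.
#' @return List with `r_squared`, `AIC`, `MSC`.  A perfect fit (SSR = 0)
#'   yields `-Inf`/`+Inf` sentinels.
#' @examples
#' information_criteria(63.2, 63.2 / (1 - 0.994), 8, 2)
#' @export
information_criteria <- function(SSR, SST, n, p) {
  if (n <= p) stop("'n' must exceed the parameter count", call. = FALSE)
  if (SST <= 0) stop("'SST' must be positive", call. = FALSE)
  if (SSR < 0) stop("'SSR' must be non-negative", call. = FALSE)
  if (SSR == 0)
    return(list(r_squared = 1, AIC = -Inf, MSC = Inf))
  list(r_squared = 1 - SSR / SST,
       AIC = n * log(SSR) + 2 * p,
       MSC = log(SST / SSR) - 2 * p / n)
}

#' Classify the Korsmeyer-Peppas diffusional exponent
#'
#' Maps the release exponent n to the transport mechanism for thin films:
#' n < 0.45 quasi-Fickian diffusion, n = 0.45 Fickian, 0.45 < n < 0.89
#' non-Fickian (anomalous), n = 0.89 case-II (zero-order), n > 0.89
#' super case-II.  Equality is judged with tolerance 1e-9.
#'
#' @param n Diffusional exponent (finite scalar or vector).
#' @return Character vector of mechanism labels.
#' @examples
#' classify_exponent(0.395)  # "quasi-Fickian diffusion"
#' @export
classify_exponent <- function(n) {
  if (any(!is.finite(n))) stop("'n' must be finite", call. = FALSE)
  tol <- 1e-9
  vapply(n, function(ni) {
    if (abs(ni - 0.45) <= tol) "Fickian diffusion"
    else if (abs(ni - 0.89) <= tol) "case-II (zero-order) transport"
    else if (ni < 0.45) "quasi-Fickian diffusion"
    else if (ni < 0.89) "non-Fickian (anomalous) transport"
    else "super case-II transport"
  }, character(1))
}

#' Fit one kinetic model to a cumulative-release profile
#'
#' Nonlinear least squares on the untransformed cumulative-release percents
#' (Levenberg-Marquardt, via \pkg{minpack.lm}), with starting values from the
#' model's linearized regression (log-log for Korsmeyer-Peppas).  The
#' first-order and Hixson-Crowell models are anchored at complete release
#' (F-infinity = 100%), leaving a single rate parameter.
#'
#' @param model Model id (see [kinetic_model_ids()]).
#' @param t Timepoints in hours (strictly positive; t = 0 rows are not
#'   accepted -- release at time zero is zero by definition).
#' @param cr Cumulative percent released at `t`.
#' @return A `"kinetic_fit"` with the estimated parameters, `r_squared`,
#'   `AIC`, `MSC`, `SSR`, `n_points`, `n_params`, `converged`, and -- for
#'   Korsmeyer-Peppas -- the `mechanism` classification of the exponent.
#' @examples
#' t <- c(0.5, 1, 2, 4, 8, 12, 24)
#' fit <- fit_kinetic("korsmeyer_peppas", t, 21.174 * t^0.410)
#' coef(fit)
#' @export
fit_kinetic <- function(model, t, cr) {
  models <- kinetic_models()
  if (!model %in% names(models))
    stop(sprintf("unknown kinetic model '%s'", model), call. = FALSE)
  spec <- models[[model]]
  if (any(t <= 0))
    stop("timepoints must be strictly positive for fitting", call. = FALSE)
  if (length(t) != length(cr))
    stop("'t' and 'cr' lengths differ", call. = FALSE)
  p <- length(spec$params)
  if (length(t) < p + 1)
    stop("need at least n_params + 1 points", call. = FALSE)
  ord <- order(t)
  t <- t[ord]; cr <- cr[ord]

  SST <- sum((cr - mean(cr))^2)
  start <- spec$start(t, cr)
  degenerate <- SST <= .Machine$double.eps * max(1, sum(cr^2))

  est <- start; converged <- FALSE
  pnames <- spec$params
  model_fn <- spec$fn
  fwrap <- function(...) model_fn(t, stats::setNames(list(...), pnames))
  form <- stats::as.formula(
    paste0("cr ~ fwrap(", paste(pnames, collapse = ", "), ")"))
  environment(form) <- environment()
  if (!degenerate) {
    nlfit <- tryCatch(
      minpack.lm::nlsLM(form, start = as.list(start),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(nlfit)) {
      est <- stats::setNames(stats::coef(nlfit)[pnames], pnames)
      converged <- TRUE
    }
  }
  resid <- cr - spec$fn(t, as.list(est))
  SSR <- sum(resid^2)

  ic <- if (degenerate)
    list(r_squared = NaN, AIC = NaN, MSC = NaN)
  else information_criteria(SSR, SST, length(t), p)

  structure(list(
    model = model,
    parameters = est,
    converged = converged,
    degenerate = degenerate,
    fitted = spec$fn(t, as.list(est)),
    residuals = resid,
    t = t, cr = cr,
    SSR = SSR, SST = SST,
    n_points = length(t), n_params = p,
    r_squared = ic$r_squared, AIC = ic$AIC, MSC = ic$MSC,
    mechanism = if (model == "korsmeyer_peppas" && is.finite(est[["n"]]))
      classify_exponent(est[["n"]]) else NA_character_
  ), class = "kinetic_fit")
}

# helper: vector -> named parameter list for nlsLM
par_vec <- function(v, nms) stats::setNames(as.numeric(v), nms)

#' @export
coef.kinetic_fit <- function(object, ...) object$parameters

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): %s\n", x$model,
              if (x$converged) "converged" else "linearized estimate only",
              paste(sprintf("%s = %.4g", names(x$parameters), x$parameters),
                    collapse = ", ")))
  cat(sprintf("  R2 = %.4f, AIC = %.2f, MSC = %.4f (n = %d, p = %d)\n",
              x$r_squared, x$AIC, x$MSC, x$n_points, x$n_params))
  if (!is.na(x$mechanism)) cat("  mechanism:", x$mechanism, "\n")
  invisible(x)
}

#' Fit all kinetic models to one release profile
#'
#' @param t,cr Timepoints (h) and cumulative percent released.
#' @param models Model ids to fit (default: all five).
#' @return Named list of [fit_kinetic()] results.
#' @export
fit_all_kinetics <- function(t, cr, models = kinetic_model_ids()) {
  stats::setNames(lapply(models, fit_kinetic, t = t, cr = cr), models)
}

#' Select the best kinetic model
#'
#' Ranks converged fits by MSC, descending (at fixed n this is identical to
#' ascending AIC); MSC ties within 1e-9 are broken in favour of the model
#' with fewer parameters.
#'
#' @param results List of [fit_kinetic()] results on identical data.
#' @return The winning `"kinetic_fit"`.
#' @export
select_model <- function(results) {
  ok <- Filter(function(r) isTRUE(r$converged) && is.finite(r$MSC) ||
                 (isTRUE(r$converged) && is.infinite(r$MSC) && r$MSC > 0),
               results)
  if (!length(ok))
    stop("model selection failed: no converged fits", call. = FALSE)
  msc <- vapply(ok, `[[`, numeric(1), "MSC")
  npar <- vapply(ok, `[[`, numeric(1), "n_params")
  best_msc <- max(msc)
  tied <- which(msc >= best_msc - 1e-9)
  ok[[tied[which.min(npar[tied])]]]
}

#' Table-style summary of a set of kinetic fits
#'
#' @param results List of [fit_kinetic()] results.
#' @return Data frame with model, parameter string, R2, AIC, MSC, mechanism.
#' @export
kinetics_report <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    model = r$model,
    parameters = paste(sprintf("%s = %.4g", names(r$parameters),
                               r$parameters), collapse = ", "),
    r_squared = r$r_squared, AIC = r$AIC, MSC = r$MSC,
    mechanism = r$mechanism, converged = r$converged,
    stringsAsFactors = FALSE)))
}
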