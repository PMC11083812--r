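#' @title Seeded synthetic-data generators
#' @description Every generator is a pure function of its parameters and an
#'   explicit integer seed: the global RNG stream is saved and restored, so
#'   identical calls give identical output and generators never interfere
#'   with surrounding code.  Zero-noise settings round-trip exactly through
#'   the corresponding analysis stage.
#' @name synthdata
NULL

with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("a single integer seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate responses on a design from a known response surface
#'
#' Evaluates a quadratic truth (coefficients in coded units) at every run of
#' the design and adds independent Gaussian noise.  `sd = 0` returns the
#' exact model values, so an OLS refit recovers the coefficients to machine
#' precision.
#'
#' @param design A [bbd_design()].
#' @param coefficients Named numeric vector over model terms, e.g.
#'   `c("1" = 1.36, A = -0.34, AC = -0.125, A2 = 0.098)`.
#' @param sd Noise standard deviation in response units (>= 0).
#' @param seed Integer seed.
#' @param response Name of the response column to create (default `"Y"`).
#' @return The design with the simulated response attached; the truth is
#'   recorded in attribute `"truth"`.
#' @export
gen_rsm_dataset <- function(design, coefficients, sd = 0, seed = 1,
                            response = "Y") {
  if (sd < 0) stop("'sd' must be non-negative", call. = FALSE)
  terms <- names(coefficients)
  if (is.null(terms) || !all(terms %in% quadratic_terms(design)))
    stop("coefficient names must be quadratic terms of the design",
         call. = FALSE)
  X <- rsm_model_matrix(coded_settings(design), terms)
  mu <- drop(X %*% coefficients)
  y <- if (sd == 0) mu else with_seed(seed, mu + stats::rnorm(length(mu), 0, sd))
  out <- design
  out[[response]] <- y
  attr(out, "truth") <- list(coefficients = coefficients, sd = sd, seed = seed)
  out
}

#' Simulate a drug-release curve from a kinetic model
#'
#' Generates the true cumulative-release profile `CR(t)` for one of the five
#' kinetic models, optionally back-converts it to the aliquot concentrations
#' a sampling-with-replacement dialysis experiment would measure (so
#' [cumulative_release()] applied to the result reproduces `CR` exactly at
#' `sd = 0`), and adds Gaussian noise on the CR scale.  Profiles are clipped
#' at 100% (complete release) with a warning.
#'
#' @param model Kinetic model id (see [kinetic_model_ids()]).
#' @param params Named parameters for the model (e.g.
#'   `c(KKP = 21.174, n = 0.410)`).
#' @param t Timepoints, hours (> 0).
#' @param sd Noise SD on the cumulative-release percent scale (>= 0).
#' @param seed Integer seed.
#' @param sampling Optional list `list(Ve = , Vo = , m = )`; when given, the
#'   returned object carries the concentrations implied by the sampling
#'   scheme.
#' @return List of class `"release_curve"`: `t`, `cr` (noisy), `cr_true`,
#'   and when `sampling` is given `conc`, `Ve`, `Vo`, `m`.
#' @export
gen_release_curve <- function(model, params, t, sd = 0, seed = 1,
                              sampling = NULL) {
  models <- kinetic_models()
  if (!model %in% names(models))
    stop(sprintf("unknown kinetic model '%s'", model), call. = FALSE)
  spec <- models[[model]]
  params <- params[spec$params]
  if (anyNA(params) || !spec$check(params))
    stop("parameters out of the model's admissible range", call. = FALSE)
  if (any(t <= 0)) stop("timepoints must be positive", call. = FALSE)
  if (sd < 0) stop("'sd' must be non-negative", call. = FALSE)
  t <- sort(t)
  cr_true <- spec$fn(t, as.list(params))
  if (any(cr_true > 100)) {
    warning("release profile reaches 100%: clipping at complete release",
            call. = FALSE)
    cr_true <- pmin(cr_true, 100)
  }
  cr <- if (sd == 0) cr_true else
    with_seed(seed, cr_true + stats::rnorm(length(t), 0, sd))
  out <- list(model = model, params = params, t = t, cr = cr,
              cr_true = cr_true, sd = sd, seed = seed)
  if (!is.null(sampling)) {
    stopifnot(all(c("Ve", "Vo", "m") %in% names(sampling)))
    out$Ve <- sampling$Ve; out$Vo <- sampling$Vo; out$m <- sampling$m
    out$conc <- concentrations_from_cr(cr, sampling$Ve, sampling$Vo,
                                       sampling$m)
  }
  structure(out, class = "release_curve")
}

#' @export
print.release_curve <- function(x, ...) {
  cat(sprintf("Simulated %s release curve: %d timepoints, sd = %g\n",
              x$model, length(x$t), x$sd))
  print(data.frame(t_h = x$t, cr_pct = x$cr), row.names = FALSE)
  invisible(x)
}

#' Simulate a plate assay with known residual levels
#'
#' Draws replicate well signals for each condition around its true
#' percent-of-control level, with lognormal multiplicative noise of the
#' given coefficient of variation, scaled so the stimulated control sits at
#' a mean signal of 100 units.  The stimulated control condition
#' (`"stimulated"`) is added automatically at level 100.
#'
#' @param true_levels Named numeric vector mapping condition to true
#'   percent-of-control level.
#' @param cv Coefficient of variation of the replicate noise (>= 0).
#' @param n Replicates per condition (>= 1).
#' @param seed Integer seed.
#' @param scale Mean signal of the stimulated control (arbitrary units).
#' @return Long-format data frame with `condition`, `replicate`, `signal`.
#' @export
gen_assay_plate <- function(true_levels, cv = 0.1, n = 3, seed = 1,
                            scale = 100) {
  if (cv < 0) stop("'cv' must be non-negative", call. = FALSE)
  if (n < 1 || n != round(n)) stop("'n' must be a positive integer",
                                   call. = FALSE)
  if (is.null(names(true_levels)) || any(!nzchar(names(true_levels))))
    stop("'true_levels' must be named by condition", call. = FALSE)
  levels <- c(stimulated = 100, true_levels)
  levels <- levels[!duplicated(names(levels))]
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    rows <- lapply(names(levels), function(cond) {
      mu <- levels[[cond]] / 100 * scale
      noise <- if (cv == 0) rep(1, n) else
        stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      data.frame(condition = cond, replicate = seq_len(n),
                 signal = mu * noise, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
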