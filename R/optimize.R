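#' Declare a desirability goal for one response
#'
#' Derringer-Suich individual desirability: each predicted response is mapped
#' to \[0, 1\] by a linear ramp between the `low` and `high` anchors, raised
#' to the `weight` power.  `minimize` gives d = 1 at/below `low` and 0
#' at/above `high`; `maximize` is the mirror image; `target` ramps up to
#' `target` and back down; `in_range` is 1 inside the anchors and 0 outside.
#' An optional hard constraint (`hard_max`/`hard_min`) forces d = 0 whenever
#' violated, e.g. a particle-size cap of 200 nm.
#'
#' @param response Response name the goal applies to.
#' @param goal One of `"minimize"`, `"maximize"`, `"target"`, `"in_range"`.
#' @param low,high Anchor values in response units (`low < high`).  A common
#'   default is the observed response range.
#' @param target Target value (required for `goal = "target"`).
#' @param weight Ramp exponent (> 0); 1 is linear.
#' @param importance Relative importance in the overall desirability
#'   geometric mean.
#' @param hard_max,hard_min Optional hard bounds; outside them d = 0.
#' @return A `"desirability_goal"` object.
#' @export
desirability_goal <- function(response,
                              goal = c("minimize", "maximize", "target",
                                       "in_range"),
                              low, high, target = NULL, weight = 1,
                              importance = 1,
                              hard_max = NULL, hard_min = NULL) {
  goal <- match.arg(goal)
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("anchors must be finite with low < high", call. = FALSE)
  if (goal == "target" &&
      (is.null(target) || target <= low || target >= high))
    stop("'target' must lie strictly between the anchors", call. = FALSE)
  if (weight <= 0 || importance <= 0)
    stop("'weight' and 'importance' must be positive", call. = FALSE)
  structure(list(response = response, goal = goal, low = low, high = high,
                 target = target, weight = weight, importance = importance,
                 hard_max = hard_max, hard_min = hard_min),
            class = "desirability_goal")
}

#' Individual desirability of a response value
#'
#' @param value Numeric vector of (predicted) response values.
#' @param goal A [desirability_goal()].
#' @return Desirabilities in \[0, 1\], vectorized over `value`.
#' @examples
#' g <- desirability_goal("Y1", "minimize", low = 119, high = 200,
#'                        hard_max = 200)
#' desirability(c(119, 159.5, 200), g)  # 1, 0.5, 0
#' @export
desirability <- function(value, goal) {
  stopifnot(inherits(goal, "desirability_goal"))
  lo <- goal$low; hi <- goal$high; w <- goal$weight
  ramp <- function(x) pmin(1, pmax(0, x))^w
  d <- switch(goal$goal,
    minimize = ramp((hi - value) / (hi - lo)),
    maximize = ramp((value - lo) / (hi - lo)),
    target = {
      up <- ramp((value - lo) / (goal$target - lo))
      down <- ramp((hi - value) / (hi - goal$target))
      ifelse(value <= goal$target, up, down)
    },
    in_range = as.numeric(value >= lo & value <= hi))
  if (!is.null(goal$hard_max)) d[value > goal$hard_max] <- 0
  if (!is.null(goal$hard_min)) d[value < goal$hard_min] <- 0
  d
}

#' Overall desirability
#'
#' Weighted geometric mean `D = (prod d_i^importance_i)^(1/sum importance)`;
#' zero whenever any individual desirability is zero.
#'
#' @param d Numeric vector of individual desirabilities.
#' @param importance Positive importances, recycled to `length(d)`.
#' @return Scalar overall desirability in \[0, 1\].
#' @export
overall_desirability <- function(d, importance = 1) {
  importance <- rep_len(importance, length(d))
  if (any(d == 0)) return(0)
  exp(sum(importance * log(d)) / sum(importance))
}

#' Goals defaulting to the observed response ranges
#'
#' Builds the study's standard goal set from a design with measured
#' responses: anchor each goal at the observed minimum and maximum of its
#' response (the Design-Expert default when no anchors are supplied).
#'
#' @param design A [bbd_design()] with responses.
#' @param goals Named character vector mapping response name to goal kind.
#' @param hard_max Named numeric vector of hard upper bounds (optional).
#' @return List of [desirability_goal()] objects.
#' @export
range_goals <- function(design, goals, hard_max = NULL) {
  lapply(names(goals), function(nm) {
    y <- check_response(design, nm)
    desirability_goal(nm, goals[[nm]], low = min(y), high = max(y),
                      hard_max = if (!is.null(hard_max) && nm %in% names(hard_max))
                        hard_max[[nm]] else NULL)
  })
}

#' Multi-response desirability optimization over the coded cube
#'
#' Maximizes overall desirability over the coded design cube \[-1, 1\]^k by
#' deterministic multistart search: all points of an `n_grid`^k lattice are
#' scored, the best `n_starts` seed Nelder-Mead polishes (coordinates
#' projected back onto the cube), and the best polished point wins.  Ties in
#' D (within 1e-9) are broken by the smaller predicted value of the first
#' minimize-type goal (for the nanoparticle study: smaller predicted size).
#'
#' @param fits List of [fit_rsm()] results sharing one factor space.
#' @param goals List of [desirability_goal()], one per fit, matched by
#'   response name.
#' @param n_grid Lattice points per dimension (default 21).
#' @param n_starts Number of local polishes (default 8).
#' @param seed Accepted for interface symmetry; the search is deterministic.
#' @return An `"sln_optimum"` list: `coded`, `actual`, `actual_rounded`,
#'   `predicted`, `desirability` (per response), `D`, and the grid/polish
#'   trace.
#' @export
optimize_desirability <- function(fits, goals, n_grid = 21, n_starts = 8,
                                  seed = NULL) {
  stopifnot(length(fits) == length(goals))
  resp <- vapply(fits, `[[`, character(1), "response")
  gresp <- vapply(goals, `[[`, character(1), "response")
  goals <- goals[match(resp, gresp)]
  if (anyNA(match(resp, gresp)))
    stop("every fit needs a goal for its response", call. = FALSE)
  facs <- fits[[1]]$factors
  fnames <- names(facs)
  k <- length(fnames)
  imp <- vapply(goals, `[[`, numeric(1), "importance")

  score <- function(Z) {
    # Z: matrix of coded points; returns overall desirability per row
    pred <- vapply(fits, function(f) predict(f, Z), numeric(nrow(Z)))
    pred <- matrix(pred, nrow = nrow(Z))
    dmat <- vapply(seq_along(goals), function(j)
      desirability(pred[, j], goals[[j]]), numeric(nrow(Z)))
    dmat <- matrix(dmat, nrow = nrow(Z))
    apply(dmat, 1, overall_desirability, importance = imp)
  }

  grid1 <- seq(-1, 1, length.out = n_grid)
  G <- as.matrix(expand.grid(rep(list(grid1), k)))
  colnames(G) <- fnames
  Dgrid <- score(G)
  if (all(Dgrid == 0))
    stop("no feasible point: desirability is zero everywhere on the grid",
         call. = FALSE)
  starts <- G[order(-Dgrid)[seq_len(min(n_starts, nrow(G)))], , drop = FALSE]

  clamp <- function(z) pmin(1, pmax(-1, z))
  polish <- function(z0) {
    obj <- function(z) -score(matrix(clamp(z), nrow = 1,
                                     dimnames = list(NULL, fnames)))
    res <- stats::optim(z0, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    list(coded = clamp(res$par), D = -res$value)
  }
  cands <- lapply(seq_len(nrow(starts)), function(i) polish(starts[i, ]))
  Dvals <- vapply(cands, `[[`, numeric(1), "D")

  # tie-break: larger D, then smaller predicted value of first minimize goal
  best_D <- max(Dvals)
  tied <- which(Dvals >= best_D - 1e-9)
  min_goal <- which(vapply(goals, `[[`, character(1), "goal") == "minimize")[1]
  if (length(tied) > 1 && !is.na(min_goal)) {
    sz <- vapply(tied, function(i)
      predict(fits[[min_goal]], cands[[i]]$coded), numeric(1))
    best <- tied[which.min(sz)]
  } else best <- tied[which.max(Dvals[tied])]

  coded <- cands[[best]]$coded
  names(coded) <- fnames
  pred <- vapply(fits, function(f) predict(f, coded), numeric(1))
  names(pred) <- resp
  dind <- vapply(seq_along(goals), function(j)
    desirability(pred[j], goals[[j]]), numeric(1))
  names(dind) <- resp
  actual <- vapply(fnames, function(nm) to_actual(facs[[nm]], coded[[nm]]),
                   numeric(1))
  structure(list(
    coded = coded,
    actual = actual,
    actual_rounded = round_settings(actual, facs),
    predicted = pred,
    desirability = dind,
    D = cands[[best]]$D,
    trace = list(grid_best = max(Dgrid), starts = starts, polished_D = Dvals)
  ), class = "sln_optimum")
}

# report actual settings at a practical precision: 2 decimals, except
# integer-rounded when the factor spans tens of units (e.g. a mg-scale dose)
round_settings <- function(actual, facs) {
  vapply(names(facs), function(nm) {
    digits <- if (facs[[nm]]$half_range >= 2.5) 0 else 2
    round(actual[[nm]], digits)
  }, numeric(1))
}

#' @export
print.sln_optimum <- function(x, ...) {
  cat("Desirability optimum (overall D =", sprintf("%.4f", x$D), ")\n")
  cat("  coded:  ", paste(sprintf("%s = %+.4f", names(x$coded), x$coded),
                          collapse = ", "), "\n")
  cat("  actual: ", paste(sprintf("%s = %g", names(x$actual_rounded),
                                  x$actual_rounded), collapse = ", "), "\n")
  for (nm in names(x$predicted))
    cat(sprintf("  %s: predicted %.4g (d = %.3f)\n", nm, x$predicted[[nm]],
                x$desirability[[nm]]))
  invisible(x)
}

#' Prediction interval for a single future observation
#'
#' `yhat +/- t * s * sqrt(1 + leverage)` with `s^2` the residual mean square
#' of the fit and leverage `x0' (X'X)^-1 x0` at the prediction point.
#'
#' @param fit An [fit_rsm()] result.
#' @param point Coded factor settings (named vector or one-row matrix).
#' @param level Coverage level in (0, 1); default 0.95.
#' @return List with `fit` (point prediction), `lwr`, `upr`, `leverage`,
#'   `se`, `df`.
#' @export
predict_interval <- function(fit, point, level = 0.95) {
  stopifnot(inherits(fit, "rsm_fit"))
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("'level' must lie in (0, 1)", call. = FALSE)
  if (fit$df_residual == 0)
    stop("prediction interval undefined: zero residual degrees of freedom",
         call. = FALSE)
  Z <- as_coded_matrix(point, names(fit$factors))
  x0 <- drop(rsm_model_matrix(Z, fit$terms))
  XtXinv <- chol2inv(chol(crossprod(fit$model_matrix)))
  lev <- drop(t(x0) %*% XtXinv %*% x0)
  yhat <- sum(x0 * fit$coefficients)
  se <- sqrt(fit$MSE * (1 + lev))
  tq <- stats::qt((1 + level) / 2, fit$df_residual)
  list(fit = yhat, lwr = yhat - tq * se, upr = yhat + tq * se,
       leverage = lev, se = se, df = fit$df_residual)
}

#' Signed percent error of an observation against a prediction
#'
#' `(observed - predicted) / predicted * 100`; rounding is left to
#' presentation.
#'
#' @param observed,predicted Numeric vectors (recycled).
#' @return Signed percent error.
#' @examples
#' percent_error(123.40, 119.36)  # 3.38 at 2 dp
#' @export
percent_error <- function(observed, predicted) {
  if (any(predicted == 0))
    stop("percent error undefined for predicted value 0", call. = FALSE)
  (observed - predicted) / predicted * 100
}

#' Table of predicted vs observed responses with prediction intervals
#'
#' Builds a validation report in the style of a formulation-study
#' confirmation table: predicted value, 95% prediction interval, observed
#' value and percent error for each fitted response at one coded point.
#'
#' @param fits List of [fit_rsm()] results.
#' @param point Coded settings of the confirmation run.
#' @param observed Named numeric vector of observed response values.
#' @param level Prediction-interval coverage (default 0.95).
#' @return Data frame with one row per response.
#' @export
validate_optimum <- function(fits, point, observed, level = 0.95) {
  rows <- lapply(fits, function(f) {
    pi <- predict_interval(f, point, level)
    obs <- observed[[f$response]]
    data.frame(response = f$response, predicted = pi$fit,
               pi_low = pi$lwr, pi_high = pi$upr,
               observed = if (is.null(obs)) NA_real_ else obs,
               pct_error = if (is.null(obs)) NA_real_ else
                 percent_error(obs, pi$fit),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
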