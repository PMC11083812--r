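#' @title Quadratic response-surface models on coded designs
#' @description Model terms are named after the coded factors: `"1"` is the
#'   intercept, `"A"` a linear term, `"AB"` the A-by-B interaction and `"A2"`
#'   the quadratic term in A.  All fitting happens in coded units, so
#'   coefficient magnitudes are directly comparable across factors.
#' @name rsm-terms
NULL

#' Full quadratic term set for a design
#'
#' @param design A [bbd_design()], or a character vector of factor names.
#' @return Character vector: intercept, linear, two-way interaction and
#'   quadratic terms, e.g. `c("1","A","B","C","AB","AC","BC","A2","B2","C2")`.
#' @export
quadratic_terms <- function(design) {
  nms <- if (is.character(design)) design else factor_names(design)
  k <- length(nms)
  inter <- if (k >= 2)
    unlist(lapply(seq_len(k - 1), function(i)
      paste0(nms[i], nms[(i + 1):k])))
  else character(0)
  c("1", nms, inter, paste0(nms, "2"))
}

# factor names a term depends on ("AB" -> A,B; "A2" -> A; "1" -> none)
term_parents <- function(term, factor_names) {
  if (term == "1") return(character(0))
  if (term %in% factor_names) return(term)
  sq <- paste0(factor_names, "2")
  if (term %in% sq) return(factor_names[match(term, sq)])
  hit <- factor_names[vapply(factor_names, grepl, logical(1), x = term,
                             fixed = TRUE)]
  if (nchar(paste0(sort(hit), collapse = "")) != nchar(term) ||
      length(hit) != 2L)
    stop(sprintf("unknown model term '%s'", term), call. = FALSE)
  hit
}

# one model-matrix column per term, from the coded settings matrix
term_column <- function(term, Z) {
  nms <- colnames(Z)
  if (term == "1") return(rep(1, nrow(Z)))
  if (term %in% nms) return(Z[, term])
  if (term %in% paste0(nms, "2")) {
    f <- nms[match(term, paste0(nms, "2"))]
    return(Z[, f]^2)
  }
  par <- term_parents(term, nms)
  Z[, par[1]] * Z[, par[2]]
}

# coded model matrix for a term set (columns named by term)
rsm_model_matrix <- function(Z, terms) {
  X <- vapply(terms, term_column, numeric(nrow(Z)), Z = Z)
  matrix(X, nrow = nrow(Z), dimnames = list(NULL, terms))
}

normalize_terms <- function(terms) {
  terms <- unique(as.character(terms))
  union("1", terms)  # intercept always present, listed first
}

#' Pure-error sum of squares from replicated runs
#'
#' Replicate groups are runs with identical coded settings.  The pure-error
#' sum of squares is the within-group sum of squared deviations from the
#' group mean; its degrees of freedom are the group sizes minus one, summed.
#'
#' @param design A [bbd_design()] with the response attached.
#' @param response Response column name.
#' @return List with `SS`, `df`, and `has_replicates` (FALSE, with a warning,
#'   when every run is unique).
#' @examples
#' # three center replicates 139, 138, 136 nm give SS = 14/3, df = 2
#' @export
pure_error <- function(design, response) {
  y <- check_response(design, response)
  key <- apply(coded_settings(design), 1, paste, collapse = "/")
  groups <- split(y, key)
  SS <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- sum(vapply(groups, length, integer(1)) - 1L)
  if (df == 0L) {
    warning("no replicated runs: pure error is zero with 0 df",
            call. = FALSE)
    return(list(SS = 0, df = 0L, has_replicates = FALSE))
  }
  list(SS = SS, df = df, has_replicates = TRUE)
}

#' Fit a response-surface model by ordinary least squares
#'
#' Fits the requested terms to one response of a coded design by OLS and
#' assembles the ANOVA bookkeeping used throughout the package: per-term
#' partial (type-III) sums of squares, the lack-of-fit / pure-error partition
#' enabled by replicated runs, R-squared, adjusted and PRESS-based predicted
#' R-squared, and adequate precision (signal-to-noise ratio
#' `(max fitted - min fitted) / sqrt(p * MSE / n)`).
#'
#' @param design A [bbd_design()] with the response attached.
#' @param response Response column name.
#' @param terms Character vector of model terms (see [quadratic_terms()]);
#'   the intercept `"1"` is always included.
#' @return An object of class `"rsm_fit"`.
#' @examples
#' des <- cbd_sln_design()
#' fit <- fit_rsm(des, "Y4", c("1","A","B","C","AC","BC","A2"))
#' coef(fit)[["AC"]]   # -0.125
#' @export
fit_rsm <- function(design, response, terms = quadratic_terms(design)) {
  y <- check_response(design, response)
  terms <- normalize_terms(terms)
  Z <- coded_settings(design)
  X <- rsm_model_matrix(Z, terms)
  n <- nrow(X); p <- ncol(X)
  if (n <= p)
    stop("more model terms than runs", call. = FALSE)

  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- terms[qrX$pivot[(qrX$rank + 1):p]]
    stop(sprintf("singular fit: collinear terms {%s}",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  lmfit <- stats::lm.fit(X, y)
  beta <- lmfit$coefficients
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  SS_res <- sum(resid^2)
  SS_tot <- sum((y - mean(y))^2)
  SS_mod <- SS_tot - SS_res
  df_res <- n - p
  MSE <- SS_res / df_res

  # partial SS: extra residual SS when the term is removed from the full set
  drop_ss <- vapply(setdiff(terms, "1"), function(tm) {
    Xr <- X[, setdiff(terms, tm), drop = FALSE]
    sum(stats::lm.fit(Xr, y)$residuals^2) - SS_res
  }, numeric(1))
  Fval <- drop_ss / MSE
  pval <- stats::pf(Fval, 1, df_res, lower.tail = FALSE)
  anova_tab <- data.frame(term = character(0), SS = numeric(0),
                          df = integer(0), MS = numeric(0), F = numeric(0),
                          p = numeric(0), stringsAsFactors = FALSE)
  if (length(drop_ss))
    anova_tab <- data.frame(term = names(drop_ss), SS = unname(drop_ss),
                            df = 1L, MS = unname(drop_ss),
                            F = unname(Fval), p = unname(pval),
                            stringsAsFactors = FALSE)

  pe <- suppressWarnings(pure_error(design, response))
  lof <- NULL
  if (pe$has_replicates && df_res > pe$df) {
    SS_lof <- SS_res - pe$SS
    df_lof <- df_res - pe$df
    F_lof <- (SS_lof / df_lof) / (pe$SS / pe$df)
    lof <- list(SS = SS_lof, df = df_lof, F = F_lof,
                p = stats::pf(F_lof, df_lof, pe$df, lower.tail = FALSE))
  }

  hat <- stats::hat(X, intercept = FALSE)
  degenerate <- SS_tot <= .Machine$double.eps * max(1, sum(y^2))
  if (degenerate)
    warning("constant response: R-squared and F statistics are undefined",
            call. = FALSE)
  R2 <- if (degenerate) NaN else 1 - SS_res / SS_tot
  adjR2 <- if (degenerate) NaN else
    1 - (SS_res / df_res) / (SS_tot / (n - 1))
  F_mod <- if (degenerate) NaN else (SS_mod / (p - 1)) / MSE

  fit <- structure(list(
    response = response,
    terms = terms,
    coefficients = beta,
    model_matrix = X,
    coded = Z,
    y = y,
    fitted = fitted,
    residuals = resid,
    hat = hat,
    n = n, p = p, df_residual = df_res,
    SS = list(total = SS_tot, model = SS_mod, residual = SS_res),
    MSE = MSE,
    F_model = F_mod,
    anova = anova_tab,
    pure_error = pe,
    lack_of_fit = lof,
    r_squared = R2,
    adj_r_squared = adjR2,
    factors = design_factors(design)
  ), class = "rsm_fit")
  fit$pred_r_squared <- tryCatch(predicted_r2(fit), error = function(e) NA_real_)
  fit$adeq_precision <- if (degenerate) NaN else
    (max(fitted) - min(fitted)) / sqrt(p * MSE / n)
  fit
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
residuals.rsm_fit <- function(object, ...) object$residuals

#' @export
fitted.rsm_fit <- function(object, ...) object$fitted

#' Predict a response-surface model at coded settings
#'
#' @param object An [fit_rsm()] result.
#' @param newdata Matrix or data frame of coded factor settings (columns
#'   named after the factors), or a single named/ordered numeric vector.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rsm_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  Z <- as_coded_matrix(newdata, names(object$factors))
  drop(rsm_model_matrix(Z, object$terms) %*% object$coefficients)
}

as_coded_matrix <- function(x, factor_names) {
  if (is.numeric(x) && is.null(dim(x)))
    x <- matrix(x, nrow = 1, dimnames = list(NULL, if (is.null(names(x)))
      factor_names else names(x)))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- factor_names
  x[, factor_names, drop = FALSE]
}

#' PRESS-based predicted R-squared
#'
#' `1 - PRESS / SS_total` where `PRESS = sum((e_i / (1 - h_ii))^2)` is the
#' leave-one-out prediction error sum of squares.  Can be negative when the
#' model predicts new points worse than the response mean.
#'
#' @param fit An [fit_rsm()] result.
#' @return Predicted R-squared (scalar).
#' @export
predicted_r2 <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  h <- fit$hat
  if (any(h >= 1 - 1e-10))
    stop("leave-one-out prediction undefined: a run has leverage 1",
         call. = FALSE)
  PRESS <- sum((fit$residuals / (1 - h))^2)
  1 - PRESS / fit$SS$total
}

#' Backward elimination of non-significant model terms
#'
#' Starting from the full quadratic model, repeatedly drops the term with the
#' largest partial-F p-value above `alpha` and refits, until every remaining
#' term is significant or protected.  The intercept is never dropped.  With
#' `hierarchy = TRUE` (default) a main effect stays while any retained
#' interaction or quadratic term depends on it.
#'
#' @param design A [bbd_design()] with the response attached.
#' @param response Response column name.
#' @param alpha Significance level for retention (0 < alpha < 1).
#' @param hierarchy Enforce model hierarchy? Default `TRUE`.
#' @param terms Starting term set; defaults to the full quadratic.
#' @return An `"rsm_fit"` whose `$elimination` element records each dropped
#'   term and its p-value at the time of removal.
#' @examples
#' des <- cbd_sln_design()
#' fit <- reduce_model(des, "Y3", alpha = 0.05)
#' fit$terms  # linear-only model for encapsulation efficiency
#' @export
reduce_model <- function(design, response, alpha = 0.05, hierarchy = TRUE,
                         terms = quadratic_terms(design)) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)
  terms <- normalize_terms(terms)
  fnames <- factor_names(design)
  trace <- data.frame(dropped = character(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  repeat {
    fit <- fit_rsm(design, response, terms)
    tab <- fit$anova
    cand <- tab[tab$p > alpha & !is.na(tab$p), , drop = FALSE]
    if (hierarchy && nrow(cand)) {
      protected <- unique(unlist(lapply(setdiff(terms, "1"), term_parents,
                                        factor_names = fnames)))
      cand <- cand[!(cand$term %in% protected), , drop = FALSE]
    }
    if (!nrow(cand)) break
    worst <- cand$term[which.max(cand$p)]
    trace <- rbind(trace, data.frame(dropped = worst,
                                     p = max(cand$p),
                                     stringsAsFactors = FALSE))
    terms <- setdiff(terms, worst)
  }
  fit$elimination <- trace
  fit
}

#' Format a fitted model as a regression equation
#'
#' @param fit An [fit_rsm()] result.
#' @param digits Coefficient digits.
#' @return Single string, e.g. `"Y4 = +1.36 - 0.34A + ..."`.
#' @export
rsm_equation <- function(fit, digits = 4) {
  b <- fit$coefficients
  piece <- function(val, term) {
    sprintf("%s %s%s", if (val < 0) "-" else "+",
            trimws(formatC(abs(val), digits = digits, format = "fg")),
            if (term == "1") "" else term)
  }
  paste0(fit$response, " = ",
         paste(mapply(piece, b, names(b)), collapse = " "))
}

format_p <- function(p) ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p))

#' @export
print.rsm_fit <- function(x, ...) {
  cat("Response-surface fit (coded units)\n")
  cat(" ", rsm_equation(x), "\n", sep = "")
  cat(sprintf("  n = %d, terms = %d, residual df = %d\n",
              x$n, x$p, x$df_residual))
  cat(sprintf("  R2 = %.4f, adj R2 = %.4f, pred R2 = %.4f, adeq precision = %.2f\n",
              x$r_squared, x$adj_r_squared, x$pred_r_squared,
              x$adeq_precision))
  invisible(x)
}

#' @export
summary.rsm_fit <- function(object, ...) {
  x <- object
  print(x)
  tab <- x$anova
  tab$p <- format_p(tab$p)
  cat("\nPer-term ANOVA (partial SS):\n")
  print(tab, row.names = FALSE, digits = 5)
  if (!is.null(x$lack_of_fit))
    cat(sprintf("\nLack of fit: SS = %.5g (df %d), F = %.3f, p = %s\n",
                x$lack_of_fit$SS, x$lack_of_fit$df, x$lack_of_fit$F,
                format_p(x$lack_of_fit$p)))
  if (x$pure_error$has_replicates)
    cat(sprintf("Pure error:  SS = %.5g (df %d)\n",
                x$pure_error$SS, x$pure_error$df))
  invisible(x)
}

# serializable summary used by the pipeline report
rsm_fit_report <- function(fit) {
  list(response = fit$response,
       equation = rsm_equation(fit),
       terms = fit$terms,
       coefficients = as.list(fit$coefficients),
       anova = fit$anova,
       lack_of_fit = fit$lack_of_fit,
       pure_error = fit$pure_error[c("SS", "df")],
       r_squared = fit$r_squared,
       adj_r_squared = fit$adj_r_squared,
       pred_r_squared = fit$pred_r_squared,
       adeq_precision = fit$adeq_precision,
       elimination = fit$elimination)
}
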