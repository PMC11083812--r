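#' Define an experimental factor
#'
#' A factor is described by its actual values at the coded low (-1) and high
#' (+1) levels.  The coded transform is the usual midpoint/half-range scaling:
#' `coded = (actual - center) / half_range` with `center = (low + high)/2`.
#'
#' @param name Short label used in design tables and model terms
#'   (single letters such as `"A"`, `"B"`, `"C"` keep term names like `"AB"`
#'   readable).
#' @param low,high Actual factor values at coded -1 and +1. `low < high`.
#' @param units Free-text units (e.g. `"g"`, `"mg"`).
#' @return An object of class `"bbd_factor"` with fields `name`, `low`,
#'   `high`, `units`, `center` and `half_range`.
#' @examples
#' gms <- bbd_factor("A", 1.5, 2.5, "g")
#' to_coded(gms, 1.6)   # -0.8
#' @export
bbd_factor <- function(name, low, high, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(low) || !is.finite(high))
    stop("factor levels must be finite", call. = FALSE)
  if (low >= high)
    stop("degenerate factor: 'low' must be strictly less than 'high'",
         call. = FALSE)
  structure(
    list(name = name, low = low, high = high, units = units,
         center = (low + high) / 2, half_range = (high - low) / 2),
    class = "bbd_factor")
}

#' @export
print.bbd_factor <- function(x, ...) {
  cat(sprintf("Factor %s: %g to %g %s (center %g, half-range %g)\n",
              x$name, x$low, x$high, x$units, x$center, x$half_range))
  invisible(x)
}

#' Convert between actual and coded factor units
#'
#' @param factor A [bbd_factor()].
#' @param actual,coded Numeric vectors of settings to convert.
#' @return Numeric vector of the same length. Extrapolation beyond the
#'   \[-1, +1\] cube is allowed; `to_coded()` warns when it occurs.
#' @examples
#' f <- bbd_factor("C", 10, 20, "mg")
#' to_coded(f, 20)         # +1
#' to_actual(f, to_coded(f, 12.5))  # round trip
#' @export
to_coded <- function(factor, actual) {
  stopifnot(inherits(factor, "bbd_factor"))
  if (factor$half_range <= 0)
    stop("degenerate factor: zero half-range", call. = FALSE)
  z <- (actual - factor$center) / factor$half_range
  if (any(is.finite(z) & abs(z) > 1 + 1e-9))
    warning(sprintf("setting outside the design range for factor %s",
                    factor$name), call. = FALSE)
  z
}

#' @rdname to_coded
#' @export
to_actual <- function(factor, coded) {
  stopifnot(inherits(factor, "bbd_factor"))
  factor$center + coded * factor$half_range
}

# Coded 12-run edge portion of the 3-factor Box-Behnken design, in block
# order AB, AC, BC (the pair varied over (-,-),(+,-),(-,+),(+,+) while the
# third factor sits at its center).
bbd3_edge_matrix <- function() {
  pm <- cbind(c(-1, 1, -1, 1), c(-1, -1, 1, 1))
  rbind(cbind(pm, 0),
        cbind(pm[, 1], 0, pm[, 2]),
        cbind(0, pm))
}

#' Generate a three-factor Box-Behnken design
#'
#' Produces the 12 edge-midpoint runs of the three-factor Box-Behnken design
#' (block order AB, AC, BC) followed by `n_center` replicated center runs.
#' Run order is deterministic; set `randomize = TRUE` to shuffle (requires a
#' seed so designs remain reproducible).
#'
#' @param factors List of exactly three [bbd_factor()] objects.
#' @param n_center Number of replicated center points (>= 1).
#' @param randomize Shuffle run order? Default `FALSE` (the canonical order).
#' @param seed Integer seed, required when `randomize = TRUE`.
#' @return A `"bbd_design"` object: a data frame with columns `run`,
#'   one coded column per factor name, `center` (logical replicate marker)
#'   and, via [set_responses()] or [read_design_csv()], response columns.
#'   The factor definitions are attached as attribute `"factors"`.
#' @examples
#' facs <- list(bbd_factor("A", 1.5, 2.5, "g"),
#'              bbd_factor("B", 0.6, 1.0, "g"),
#'              bbd_factor("C", 10, 20, "mg"))
#' des <- bbd_design(facs, n_center = 3)
#' nrow(des)  # 15
#' @export
bbd_design <- function(factors, n_center = 3, randomize = FALSE, seed = NULL) {
  if (!is.list(factors) || length(factors) != 3L ||
      !all(vapply(factors, inherits, logical(1), "bbd_factor")))
    stop("unsupported design: exactly 3 'bbd_factor' objects are required",
         call. = FALSE)
  if (!is.numeric(n_center) || length(n_center) != 1L || n_center < 1 ||
      n_center != round(n_center))
    stop("'n_center' must be a positive integer", call. = FALSE)
  nms <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("factor names must be unique", call. = FALSE)

  coded <- rbind(bbd3_edge_matrix(),
                 matrix(0, nrow = n_center, ncol = 3))
  colnames(coded) <- nms
  n <- nrow(coded)
  runs <- data.frame(run = paste0("F", seq_len(n)), coded,
                     center = c(rep(FALSE, 12), rep(TRUE, n_center)),
                     stringsAsFactors = FALSE)
  if (randomize) {
    if (is.null(seed)) stop("randomized run order requires a seed",
                            call. = FALSE)
    ord <- withr_seed_sample(seed, n)
    runs <- runs[ord, , drop = FALSE]
    rownames(runs) <- NULL
  }
  names(factors) <- nms
  structure(runs, factors = factors, class = c("bbd_design", "data.frame"))
}

# sample() under a local seed without touching the global RNG stream
withr_seed_sample <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(n)
}

#' @export
print.bbd_design <- function(x, ...) {
  facs <- design_factors(x)
  cat(sprintf("Box-Behnken design: %d runs (%d center replicates), factors %s\n",
              nrow(x), sum(x$center),
              paste(names(facs), collapse = ", ")))
  print(as.data.frame(x), ...)
  invisible(x)
}

design_factors <- function(design) {
  facs <- attr(design, "factors")
  if (is.null(facs)) stop("design carries no factor definitions", call. = FALSE)
  facs
}

factor_names <- function(design) names(design_factors(design))

#' Coded and actual settings of a design
#'
#' @param design A [bbd_design()].
#' @return `coded_settings()`: numeric matrix of coded settings (runs x
#'   factors). `actual_settings()`: the same matrix converted to actual units.
#' @export
coded_settings <- function(design) {
  as.matrix(as.data.frame(design)[, factor_names(design), drop = FALSE])
}

#' @rdname coded_settings
#' @export
actual_settings <- function(design) {
  facs <- design_factors(design)
  z <- coded_settings(design)
  for (nm in names(facs)) z[, nm] <- to_actual(facs[[nm]], z[, nm])
  z
}

#' Attach measured responses to a design
#'
#' @param design A [bbd_design()].
#' @param ... Named numeric vectors, one value per run, e.g.
#'   `Y1 = c(...)`.
#' @return The design with the response columns added.
#' @export
set_responses <- function(design, ...) {
  resp <- list(...)
  if (is.null(names(resp)) || any(!nzchar(names(resp))))
    stop("responses must be named", call. = FALSE)
  for (nm in names(resp)) {
    v <- resp[[nm]]
    if (length(v) != nrow(design))
      stop(sprintf("response '%s' has %d values for %d runs",
                   nm, length(v), nrow(design)), call. = FALSE)
    design[[nm]] <- as.numeric(v)
  }
  design
}

response_names <- function(design) {
  setdiff(names(design), c("run", "center", factor_names(design)))
}

# stop unless the named response exists and is complete
check_response <- function(design, response) {
  if (!response %in% names(design))
    stop(sprintf("response '%s' not found in design", response), call. = FALSE)
  y <- design[[response]]
  if (anyNA(y))
    stop(sprintf("response '%s' has missing values", response), call. = FALSE)
  as.numeric(y)
}
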