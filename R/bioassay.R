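#' Normalize a plate-reader signal to the stimulated control
#'
#' @param signal Raw signal (absorbance/fluorescence, arbitrary units).
#' @param control_mean Mean signal of the stimulated, untreated control
#'   wells (> 0).
#' @return Percent of control.
#' @export
percent_of_control <- function(signal, control_mean) {
  if (any(control_mean <= 0))
    stop("normalization error: control mean must be positive", call. = FALSE)
  signal / control_mean * 100
}

#' Percent inhibition from a percent-of-control level
#'
#' A treatment that leaves a mediator at `level_percent` of the stimulated
#' control has inhibited `100 - level_percent` of it.
#'
#' @param level_percent Residual level, percent of control.
#' @return Percent inhibition.
#' @examples
#' percent_inhibition(27)  # 73
#' @export
percent_inhibition <- function(level_percent) 100 - level_percent

#' Fold potency of a test treatment relative to a reference
#'
#' Defined as the ratio of residual mediator levels,
#' `level_reference / level_test`: a treatment leaving less mediator behind
#' is proportionally more potent (e.g. residual NO of 77% vs 62% gives a
#' 1.2-fold potency advantage).
#'
#' @param level_reference Residual level under the reference treatment (%).
#' @param level_test Residual level under the test treatment (> 0, %).
#' @return Fold potency (full precision; report to one decimal).
#' @examples
#' round(fold_potency(77, 62), 1)  # 1.2
#' @export
fold_potency <- function(level_reference, level_test) {
  if (any(level_test <= 0))
    stop("fold potency undefined for a zero or negative test level",
         call. = FALSE)
  level_reference / level_test
}

#' Summarize a plate assay against its stimulated control
#'
#' Aggregates replicate signals per condition (mean, SD, n), normalizes the
#' condition means to the stimulated-control mean, and reports percent
#' inhibition.  A Welch two-sample t-test against the stimulated control is
#' included as a convenience when both sides have at least two replicates.
#'
#' @param plate Long-format data frame with columns `condition`,
#'   `replicate`, `signal`.
#' @param stimulated Name of the stimulated (untreated, induced) control
#'   condition.
#' @return Data frame with per-condition `mean_signal`, `sd_signal`, `n`,
#'   `level_pct` (percent of control), `inhibition_pct` and `p_welch`.
#' @export
summarize_plate <- function(plate, stimulated = "stimulated") {
  need <- c("condition", "replicate", "signal")
  if (!all(need %in% names(plate)))
    stop("plate table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!stimulated %in% plate$condition)
    stop(sprintf("stimulated control '%s' not present", stimulated),
         call. = FALSE)
  groups <- split(plate$signal, plate$condition)
  ctrl <- groups[[stimulated]]
  ctrl_mean <- mean(ctrl)
  rows <- lapply(names(groups), function(cond) {
    g <- groups[[cond]]
    lvl <- percent_of_control(mean(g), ctrl_mean)
    p <- if (cond != stimulated && length(g) >= 2 && length(ctrl) >= 2 &&
             (stats::sd(g) > 0 || stats::sd(ctrl) > 0))
      stats::t.test(g, ctrl)$p.value else NA_real_
    data.frame(condition = cond,
               mean_signal = mean(g),
               sd_signal = if (length(g) >= 2) stats::sd(g) else NA_real_,
               n = length(g),
               level_pct = lvl,
               inhibition_pct = percent_inhibition(lvl),
               p_welch = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(match(out$condition, unique(plate$condition))), , drop = FALSE]
}
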