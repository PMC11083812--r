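#' Encapsulation efficiency
#'
#' `EE (%) = (Wt - Ws) / Wt * 100`: the fraction of the dosed drug retained
#' in the particles, from the initial drug mass `Wt` and the free drug
#' recovered in the supernatant `Ws`.  Any mass unit works as long as both
#' arguments share it.
#'
#' @param Wt Initial drug mass added to the formulation (> 0).
#' @param Ws Free drug in the supernatant (0 <= Ws <= Wt).
#' @return Encapsulation efficiency, percent.
#' @examples
#' encapsulation_efficiency(20, 0.968)  # 95.16
#' @export
encapsulation_efficiency <- function(Wt, Ws) {
  if (any(Wt <= 0)) stop("'Wt' must be positive", call. = FALSE)
  if (any(Ws < 0) || any(Ws > Wt))
    stop("invalid measurement: 'Ws' must lie in [0, Wt]", call. = FALSE)
  (Wt - Ws) / Wt * 100
}

#' Drug loading
#'
#' `DL (%) = (Wt - Ws) / Wnp * 100`: encapsulated drug mass per mass of
#' recovered (lyophilized) nanoparticles `Wnp`.  Satisfies the identity
#' `EE * Wt = DL * Wnp` exactly.
#'
#' @param Wt Initial drug mass added.
#' @param Ws Free drug in the supernatant.
#' @param Wnp Lyophilized nanoparticle mass (> 0), same unit as `Wt`.
#' @return Drug loading, percent.
#' @examples
#' drug_loading(20, 0.968, 806.4)  # ~2.36
#' @export
drug_loading <- function(Wt, Ws, Wnp) {
  if (any(Wnp <= 0)) stop("'Wnp' must be positive", call. = FALSE)
  if (any(Ws < 0) || any(Ws > Wt))
    stop("invalid measurement: 'Ws' must lie in [0, Wt]", call. = FALSE)
  (Wt - Ws) / Wnp * 100
}

#' Colloidal quality checks for a nanoparticle dispersion
#'
#' Applies the standard acceptance rules for lipid-based colloidal carriers:
#' a polydispersity index (PDI) of at most `pdi_max` (0.3) is acceptable for
#' drug delivery; a PDI above `pdi_aggregation` (0.7) indicates a
#' distribution prone to aggregation (ISO guidance); and an absolute zeta
#' potential of at least `zeta_min` (30 mV) indicates electrostatic
#' stabilization.  All comparisons are inclusive at the stated bound.
#'
#' @param pdi Polydispersity index.
#' @param zeta Zeta potential, mV (sign retained; magnitude is checked).
#' @param pdi_max Acceptance threshold for PDI (default 0.3).
#' @param pdi_aggregation Aggregation-warning threshold (default 0.7).
#' @param zeta_min Minimum absolute zeta potential, mV (default 30).
#' @return List with logical flags `pdi_ok`, `zeta_ok`,
#'   `aggregation_warning`, overall `pass`, and the thresholds used.
#' @examples
#' colloidal_checks(pdi = 0.2099, zeta = -31.25)$pass  # TRUE
#' @export
colloidal_checks <- function(pdi, zeta, pdi_max = 0.3,
                             pdi_aggregation = 0.7, zeta_min = 30) {
  pdi_ok <- pdi <= pdi_max
  zeta_ok <- abs(zeta) >= zeta_min
  agg <- pdi > pdi_aggregation
  list(pdi = pdi, zeta = zeta,
       pdi_ok = pdi_ok, zeta_ok = zeta_ok, aggregation_warning = agg,
       pass = pdi_ok && zeta_ok && !agg,
       thresholds = list(pdi_max = pdi_max,
                         pdi_aggregation = pdi_aggregation,
                         zeta_min = zeta_min))
}

#' Batch formulation metrics from a measurement table
#'
#' @param batch Data frame with columns `batch_id`, `Wt_mg`, `Ws_mg`,
#'   `Wnp_mg` and optionally `size_nm`, `pdi`, `zeta_mV`.
#' @param ... Threshold overrides passed to [colloidal_checks()].
#' @return The input with `EE_pct`, `DL_pct` and, when PDI/zeta are present,
#'   `pdi_ok`, `zeta_ok`, `aggregation_warning`, `pass` columns appended.
#' @export
formulation_report <- function(batch, ...) {
  need <- c("batch_id", "Wt_mg", "Ws_mg", "Wnp_mg")
  if (!all(need %in% names(batch)))
    stop("batch table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  batch$EE_pct <- encapsulation_efficiency(batch$Wt_mg, batch$Ws_mg)
  batch$DL_pct <- drug_loading(batch$Wt_mg, batch$Ws_mg, batch$Wnp_mg)
  if (all(c("pdi", "zeta_mV") %in% names(batch))) {
    chk <- lapply(seq_len(nrow(batch)), function(i)
      colloidal_checks(batch$pdi[i], batch$zeta_mV[i], ...))
    for (f in c("pdi_ok", "zeta_ok", "aggregation_warning", "pass"))
      batch[[f]] <- vapply(chk, `[[`, logical(1), f)
  }
  batch
}
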