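## End-to-end orchestration: raw assay table -> rates -> QC -> MM fits ->
## kinetic traits -> thermal models, with one exclusion ledger threaded
## through every stage.

#' Run the full kinetics pipeline on an assay campaign
#'
#' @param assay assay table (see [read_assay_table()] /
#'   [simulate_campaign()]).
#' @param soil soil context table.
#' @param p_gate significance gate on Vmax/Km (fits with either p above
#'   the gate are excluded from trait tables).
#' @param T0 MMRT reference temperature (K).
#' @param ... passed to [fit_mm_all()] (e.g. `lambda_grid`).
#' @return list with `rates`, `qc` (kept rates), `fits` (all timepoints),
#'   `selection` (incubation time per temperature), `gated`, `traits`,
#'   `thermal`, `ledger`, `exclusions` (ledger summary).
#' @export
run_pipeline <- function(assay, soil, p_gate = 0.05, T0 = 315, ...) {
  rates <- reduce_rates(assay, soil)
  qc <- qc_rates(rates)
  mm <- fit_mm_all(qc$rates, ledger = qc$ledger, p_gate = p_gate, ...)
  traits <- derive_traits_all(mm$gated, soil)
  th <- thermal_all(traits, ledger = mm$ledger, T0 = T0)
  thermal <- th$thermal
  ## downstream thermal trait tables contain only valid MMRT fits
  thermal_valid <- thermal[is.na(thermal$mmrt_valid) | thermal$mmrt_valid, ]
  list(rates = rates, qc = qc$rates, fits = mm$fits,
       selection = mm$selection, gated = mm$gated, traits = traits,
       thermal = thermal, thermal_valid = thermal_valid,
       ledger = th$ledger, exclusions = exclusion_summary(th$ledger))
}
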