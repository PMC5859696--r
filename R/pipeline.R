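#' Run the full LV flow-component analysis
#'
#' Orchestrates the analysis on in-memory objects: optional preprocessing
#' (temporal unwrap and background-offset correction when a static mask is
#' available), pathline emission and tracing, four-component classification,
#' mid-diastasis detection and E/A splitting, inflow-outflow QC, and
#' per-component kinetic-energy curves.
#'
#' @param field a [velocity_field()].
#' @param seg an [lv_segmentation()].
#' @param timing a [cardiac_timing()].
#' @param static_mask optional static-tissue mask; enables background
#'   correction.
#' @param unwrap apply temporal phase unwrapping first (default TRUE).
#' @param rho density of blood (kg/m^3).
#' @param step_fraction RK4 step as a fraction of the frame interval.
#' @param qc_max_discrepancy_pct inflow-outflow QC threshold (percent).
#' @param speed_source `"field"` or `"trajectory"`, see [component_curves()].
#' @return A list: `paths`, `labels`, `timing` (with mid-diastasis), `qc`,
#'   `results` (a `component_result`), `preprocessing` (wrap count and
#'   background residuals, when run).
#' @export
run_flow_analysis <- function(field, seg, timing, static_mask = NULL,
                              unwrap = TRUE, rho = VF_BLOOD_DENSITY,
                              step_fraction = 0.25,
                              qc_max_discrepancy_pct = 15,
                              speed_source = "field") {
  prep <- list()
  if (unwrap) {
    uw <- unwrap_temporal(field)
    field <- uw$field
    prep$wrap_count <- uw$wrap_count
    prep$unreliable_voxels <- sum(uw$unreliable)
  }
  if (!is.null(static_mask)) {
    model <- fit_background(field, static_mask)
    field <- subtract_background(field, model)
    prep$background_residual_rms_ms <- model$residual_rms
  }
  paths <- emit_all(field, seg, timing, step_fraction = step_fraction)
  labels <- classify_pathlines(paths, seg)
  timing <- find_mid_diastasis(paths, seg, timing, labels)
  labels <- split_e_a(paths, labels, seg, timing)
  qc <- qc_inflow_outflow(labels, paths$voxel_volume_ml,
                          max_discrepancy_pct = qc_max_discrepancy_pct)
  results <- component_curves(paths, labels, field, timing, rho = rho,
                              speed_source = speed_source)
  list(paths = paths, labels = labels, timing = timing, qc = qc,
       results = results, preprocessing = prep, field = field)
}
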