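#' Simulate a per-complex measurement table directly (tabular mode)
#'
#' Bypasses rendering and tracing: draws folded binding positions, bend
#' angles, volumes, max heights and QD flags straight from the configured
#' distributions, in exactly the schema produced by the imaging pipeline
#' ([measure_scene()]), so the statistics layer is agnostic to the data route.
#' Max heights are the nominal blob peak heights perturbed by
#' Normal(0, `noise_sd_nm`).
#'
#' @param config An [afm_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param condition Condition label stored in the table.
#' @param replicate Replicate label stored in the table.
#' @return A tibble with columns `molecule_id`, `position_pct_folded`,
#'   `bend_angle_deg`, `volume_nm3`, `max_height_nm`, `is_qd`, `condition`,
#'   `replicate`, and attribute `n_dna` (number of molecules simulated,
#'   including those without complexes).
#' @examples
#' simulate_measurements(afm_config(n_molecules = 50, seed = 2))
#' @export
simulate_measurements <- function(config, seed = config$seed,
                                  condition = "synthetic", replicate = "r1") {
  set.seed(seed)
  cx <- place_complexes(config$n_molecules, config)
  out <- tibble::tibble(
    molecule_id = cx$molecule_id,
    position_pct_folded = fold_position_pct(100 * cx$position_fraction),
    bend_angle_deg = cx$bend_angle_true,
    volume_nm3 = cx$volume_true,
    max_height_nm = cx$height_true +
      if (nrow(cx) > 0) rnorm(nrow(cx), 0, config$noise_sd_nm) else numeric(0),
    is_qd = cx$is_qd,
    condition = if (nrow(cx) > 0) condition else character(0),
    replicate = if (nrow(cx) > 0) replicate else character(0)
  )
  attr(out, "n_dna") <- config$n_molecules
  out
}

measurement_schema <- c("molecule_id", "position_pct_folded", "bend_angle_deg",
                        "volume_nm3", "max_height_nm", "is_qd", "condition",
                        "replicate")

#' Validate the shared per-complex measurement schema
#'
#' Checks that a table has the columns every pipeline stage exchanges
#' (`molecule_id`, `position_pct_folded`, `bend_angle_deg`, `volume_nm3`,
#' `max_height_nm`, `is_qd`, `condition`, `replicate`) and that folded
#' positions lie in `[0, 50]`.
#'
#' @param measurements A data frame.
#' @return The input, invisibly; aborts on schema violation.
#' @export
validate_measurements <- function(measurements) {
  missing <- setdiff(measurement_schema, names(measurements))
  if (length(missing) > 0) {
    abort(paste0("measurement table is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "afmdna_schema_error")
  }
  p <- measurements$position_pct_folded
  if (any(!is.na(p) & (p < 0 | p > 50))) {
    abort("position_pct_folded must lie in [0, 50]",
          class = "afmdna_schema_error")
  }
  invisible(measurements)
}
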