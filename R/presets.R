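#' Scenario presets for the dwell simulator
#'
#' Two ready-made configurations spanning the contrast a stratified transport
#' table is built around:
#'
#' * `low_transporter` — the defaults of [sim_config()]: small-solute MTACs at
#'   the low-transport means (urea 8.3, creatinine 3.3, phosphate 2.3,
#'   potassium 18.6 mL/min), positive net ultrafiltration (~295 mL over 4 h),
#'   clean effluent.
#' * `peritonitis` — doubled urea/creatinine/phosphate/glucose MTAC (the
#'   inflamed membrane transports small solutes about twice as fast),
#'   potassium MTAC unchanged, and lymphatic absorption raised to 2.3 mL/min
#'   so expected net ultrafiltration is negative (~ -137 mL); effluent is
#'   culture-positive and cloudy with leukocytes around 1.0 x 10^9/L.
#'
#' @param name `"low_transporter"` or `"peritonitis"`.
#' @param ... Passed on to [sim_config()] to override any field (e.g.
#'   `seed`, `noise_cv`).
#' @return A `"spa_sim_config"`.
#' @examples
#' scenario_preset("peritonitis", seed = 3)
#' @export
scenario_preset <- function(name = c("low_transporter", "peritonitis"), ...) {
  name <- match.arg(name)
  switch(name,
    low_transporter = sim_config(...),
    peritonitis = sim_config(
      true_mtac = c(urea = 2 * 8.3, creatinine = 2 * 3.3,
                    phosphate = 2 * 2.3, glucose = 2 * 3.9),
      lymphatic_rate = 2.3,
      culture_positive = TRUE,
      cloudy_effluent = TRUE,
      leukocyte_mean = 1.0,
      ...
    )
  )
}
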