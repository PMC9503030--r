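#' Assemble the measurements of one SPA dwell
#'
#' Bundles everything measured during a single standard peritoneal
#' permeability assessment: the timed dialysate series, the sparse plasma
#' series, the volume ledger, the albumin marker concentrations used for
#' residual-volume estimation, and the effluent diagnostics.
#'
#' Internal units are fixed: minutes, mL, mM for small solutes, g/L for
#' albumin and total protein. Unit conversion belongs to the I/O layer
#' ([read_dwell_tables()]).
#'
#' @param dialysate Tibble with columns `solute`, `time_min`, `conc`: the
#'   dialysate concentration series. Each solute's times must start at 0 and
#'   be strictly increasing; concentrations must be non-negative.
#' @param plasma Tibble with columns `solute`, `time_min`, `conc`: plasma
#'   samples, normally at 0/120/240 min. `NA` concentrations mark missing
#'   samples.
#' @param instilled_volume Volume of the fresh bag, mL.
#' @param drain_volume_end Volume of the complete drain at the end, mL.
#' @param sample_volume_total Total volume retained through sampling, mL.
#' @param duration Dwell duration in minutes (default 240).
#' @param albumin_overnight_effluent Albumin in the drained overnight
#'   effluent, g/L (marker for the pre-dwell residual volume).
#' @param albumin_flush Albumin in the effluent of the post-dwell flush, g/L.
#' @param flush_volume Volume of the post-dwell flush, mL.
#' @param body_weight Body weight in kg, used for BSA normalization
#'   (`NA` to skip normalization).
#' @param diagnostics Optional list with elements `culture_positive`,
#'   `cloudy_effluent` (logical or `NA`) and `leukocyte_count`
#'   (10^9 cells/L or `NA`), for peritonitis classification.
#' @param dwell_id,animal_id Identifiers carried through to results.
#'
#' @return An object of class `"spa_dwell"`.
#' @seealso [analyze_spa()], [simulate_dwell()]
#' @export
spa_dwell <- function(dialysate,
                      plasma = NULL,
                      instilled_volume,
                      drain_volume_end = NA_real_,
                      sample_volume_total = 0,
                      duration = 240,
                      albumin_overnight_effluent = NA_real_,
                      albumin_flush = NA_real_,
                      flush_volume = NA_real_,
                      body_weight = NA_real_,
                      diagnostics = NULL,
                      dwell_id = NA_character_,
                      animal_id = NA_character_) {
  dialysate <- as_tibble(dialysate)
  need <- c("solute", "time_min", "conc")
  if (!all(need %in% names(dialysate))) {
    stop_spakit("`dialysate` needs columns solute, time_min, conc.",
                "spakit_error_input")
  }
  if (instilled_volume <= 0) {
    stop_spakit("`instilled_volume` must be positive.", "spakit_error_input")
  }
  if (sample_volume_total < 0 || sample_volume_total >= instilled_volume) {
    stop_spakit("`sample_volume_total` must be in [0, instilled_volume).",
                "spakit_error_input")
  }
  if (duration <= 0) stop_spakit("`duration` must be positive.", "spakit_error_input")
  check_series <- function(d) {
    for (s in unique(d$solute)) {
      tt <- d$time_min[d$solute == s]
      cc <- d$conc[d$solute == s]
      if (length(tt) > 0 && (is.na(tt[1]) || tt[1] != 0)) {
        stop_spakit(sprintf("Dialysate series for %s must start at t = 0.", s),
                    "spakit_error_input")
      }
      if (any(diff(tt) <= 0)) {
        stop_spakit(sprintf("Times for %s must be strictly increasing.", s),
                    "spakit_error_input")
      }
      if (any(cc < 0, na.rm = TRUE)) {
        stop_spakit(sprintf("Negative concentration in series for %s.", s),
                    "spakit_error_input")
      }
    }
  }
  check_series(dialysate)
  # canonical ordering, so construction is independent of input row order
  dialysate <- dplyr::arrange(dialysate, .data$solute, .data$time_min)
  if (!is.null(plasma)) {
    plasma <- as_tibble(plasma)
    if (!all(need %in% names(plasma))) {
      stop_spakit("`plasma` needs columns solute, time_min, conc.",
                  "spakit_error_input")
    }
    if (any(plasma$conc < 0, na.rm = TRUE)) {
      stop_spakit("Negative plasma concentration.", "spakit_error_input")
    }
    plasma <- dplyr::arrange(plasma, .data$solute, .data$time_min)
  } else {
    plasma <- tibble(solute = character(), time_min = numeric(), conc = numeric())
  }
  if (!is.null(diagnostics)) {
    diagnostics <- list(
      culture_positive = diagnostics$culture_positive %||% NA,
      cloudy_effluent = diagnostics$cloudy_effluent %||% NA,
      leukocyte_count = diagnostics$leukocyte_count %||% NA_real_
    )
    if (!is.na(diagnostics$leukocyte_count) && diagnostics$leukocyte_count < 0) {
      stop_spakit("Negative leukocyte count.", "spakit_error_input")
    }
  }
  structure(
    list(
      dwell_id = dwell_id,
      animal_id = animal_id,
      dialysate = dialysate,
      plasma = plasma,
      instilled_volume = instilled_volume,
      drain_volume_end = drain_volume_end,
      sample_volume_total = sample_volume_total,
      duration = duration,
      albumin_overnight_effluent = albumin_overnight_effluent,
      albumin_flush = albumin_flush,
      flush_volume = flush_volume,
      body_weight = body_weight,
      diagnostics = diagnostics
    ),
    class = "spa_dwell"
  )
}

# dialysate concentration of one solute at one time, NA if not sampled
dialysate_at <- function(dwell, solute, time) {
  d <- dwell$dialysate
  hit <- d$solute == solute & d$time_min == time
  if (!any(hit)) return(NA_real_)
  d$conc[which(hit)[1]]
}

plasma_series <- function(dwell, solute, times = c(0, 120, 240)) {
  p <- dwell$plasma[dwell$plasma$solute == solute, , drop = FALSE]
  vapply(times, function(t) {
    hit <- p$time_min == t
    if (!any(hit)) NA_real_ else p$conc[which(hit)[1]]
  }, numeric(1))
}

#' @export
print.spa_dwell <- function(x, ...) {
  cat("<spa_dwell>", if (!is.na(x$dwell_id)) x$dwell_id else "", "\n")
  cat("  instilled:", x$instilled_volume, "mL; drained:",
      x$drain_volume_end, "mL; duration:", x$duration, "min\n")
  cat("  dialysate solutes:", paste(unique(x$dialysate$solute), collapse = ", "), "\n")
  cat("  plasma solutes:   ", paste(unique(x$plasma$solute), collapse = ", "), "\n")
  if (!is.null(x$diagnostics)) {
    cat("  effluent diagnostics: culture=", format(x$diagnostics$culture_positive),
        ", cloudy=", format(x$diagnostics$cloudy_effluent),
        ", leukocytes=", format(x$diagnostics$leukocyte_count), " x10^9/L\n",
        sep = "")
  }
  invisible(x)
}
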