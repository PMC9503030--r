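#' Residual volume by indicator dilution
#'
#' Estimates the fluid volume left in the peritoneal cavity after a drain from
#' the dilution of an endogenous marker (albumin in practice) between the
#' drained effluent and the freshly mixed dialysate:
#' \deqn{RV = \frac{V_{in} \, C_{t0}}{C_{drain} - C_{t0}}}
#' The same relation serves before a dwell (overnight effluent vs. the t = 0
#' sample of the fresh bag) and after it (final drain vs. flush effluent).
#'
#' @param v_in Instilled volume of fresh dialysate (or flush fluid), mL.
#' @param c_t0 Marker concentration in the freshly mixed fluid (g/L).
#' @param c_drain Marker concentration in the drained effluent that carried the
#'   marker (g/L). Must exceed `c_t0`: the marker has to be more concentrated
#'   in the residual fluid than after mixing.
#'
#' @return Residual volume in mL, always `>= 0`.
#'
#' @details `c_drain <= c_t0` is an indicator-dilution failure (the inversion
#'   would give a negative or infinite volume) and raises an error of class
#'   `"spakit_error_indicator_dilution"` rather than clamping. [analyze_spa()]
#'   catches this and flags the dwell.
#'
#' @examples
#' residual_volume(2000, 0.3, 2.3) # 300 mL
#' residual_volume(2000, 0, 2.5)   # no marker in mixed fluid: 0 mL
#' @export
residual_volume <- function(v_in, c_t0, c_drain) {
  if (any(v_in <= 0)) stop_spakit("`v_in` must be positive.", "spakit_error_input")
  if (any(c_t0 < 0)) stop_spakit("`c_t0` must be non-negative.", "spakit_error_input")
  if (any(c_drain <= c_t0)) {
    stop_spakit(
      paste0(
        "Indicator-dilution failure: marker concentration in the drained ",
        "effluent (", format(c_drain[which(c_drain <= c_t0)[1]]),
        ") does not exceed the mixed-fluid concentration (",
        format(c_t0[which(c_drain <= c_t0)[1]]), ")."
      ),
      "spakit_error_indicator_dilution"
    )
  }
  (v_in * c_t0) / (c_drain - c_t0)
}

#' Net effective ultrafiltration volume of a dwell
#'
#' Volume balance of a single dwell: everything that came out (final drain,
#' post-dwell residual volume, sampling losses) minus everything that was in
#' the cavity at the start.
#'
#' @param v_t240 Volume of the complete drain at the end of the dwell, mL.
#' @param rv_t240 Residual volume left after that drain, mL.
#' @param v_sample Total dialysate volume retained through sampling, mL.
#' @param v_t0 Total intraperitoneal volume at the start (instilled volume plus
#'   the pre-dwell residual volume), mL.
#'
#' @return Net ultrafiltration in mL. Negative values mean net fluid
#'   absorption, as typically seen during peritonitis.
#' @examples
#' net_ultrafiltration(2200, 150, 40, 2300) # 90 mL
#' @export
net_ultrafiltration <- function(v_t240, rv_t240, v_sample, v_t0) {
  if (any(c(v_t240, rv_t240, v_sample, v_t0) < 0)) {
    stop_spakit("All volumes must be non-negative.", "spakit_error_input")
  }
  v_t240 + rv_t240 + v_sample - v_t0
}

#' Mass transfer area coefficient (Garred log-ratio formula)
#'
#' The mass transfer area coefficient (MTAC) is the theoretical maximal
#' diffusive clearance of a solute across the peritoneal membrane, attained
#' when the dialysate concentration is still zero. The simplified Garred
#' estimator recovers it from a single dwell:
#' \deqn{MTAC = \frac{V_t}{t}\,
#'   \ln\!\frac{V_0\,(P - D_0)}{V_t\,(P - D_t)}}
#'
#' For a glucose-containing dwell against lower plasma glucose both gradients
#' \eqn{P - D} are negative and the log argument is still positive; the
#' formula applies unchanged.
#'
#' @param v_0 Dialysate volume at the start of the dwell, mL.
#' @param v_t Dialysate volume at the end of the dwell, mL.
#' @param t Dwell duration, minutes.
#' @param d_0,d_t Dialysate solute concentration at the start and end.
#' @param p Plasma solute concentration (conventionally the mean of the
#'   plasma values over the dwell; see [mean_plasma()]).
#'
#' @return MTAC in mL/min. Exactly zero when `d_t == d_0` and `v_t == v_0`.
#'
#' @details If `p - d_0` and `p - d_t` differ in sign the transmembrane
#'   gradient crossed zero during the dwell; the single-exponential model
#'   behind the estimator is then violated and an error of class
#'   `"spakit_error_gradient_crossover"` is raised instead of extrapolating.
#' @examples
#' # constant-volume closed form D(t) = P (1 - exp(-MTAC t / V)), MTAC = 5:
#' mtac_garred(2000, 2000, 240, 0, 10 * (1 - exp(-0.6)), 10)
#' @export
mtac_garred <- function(v_0, v_t, t, d_0, d_t, p) {
  if (any(v_0 <= 0) || any(v_t <= 0) || any(t <= 0)) {
    stop_spakit("`v_0`, `v_t` and `t` must be positive.", "spakit_error_input")
  }
  g0 <- p - d_0
  gt <- p - d_t
  if (any(g0 * gt <= 0)) {
    stop_spakit(
      paste0(
        "Transmembrane gradient crossed or reached zero during the dwell ",
        "(P - D_0 = ", format(g0[which(g0 * gt <= 0)[1]]), ", P - D_t = ",
        format(gt[which(g0 * gt <= 0)[1]]),
        "); MTAC is not identifiable from this dwell."
      ),
      "spakit_error_gradient_crossover"
    )
  }
  (v_t / t) * log((v_0 * g0) / (v_t * gt))
}

#' Total solute removal over a dwell
#'
#' Mass of solute removed with the dialysate: end content minus start content.
#'
#' @param c_t,c_0 Dialysate concentration at the end / start (mM, or g/L for
#'   proteins).
#' @param v_t,v_0 Total intraperitoneal dialysate volume at the end / start, mL.
#'
#' @return Amount removed, in mmol for concentrations in mM (g for g/L).
#'   Negative for absorbed solutes such as glucose.
#' @examples
#' total_solute_removal(4.0, 2100, 0, 2000) # 8.4 mmol
#' @export
total_solute_removal <- function(c_t, v_t, c_0, v_0) {
  if (any(v_t <= 0) || any(v_0 <= 0)) {
    stop_spakit("Volumes must be positive.", "spakit_error_input")
  }
  if (any(c_t < 0) || any(c_0 < 0)) {
    stop_spakit("Concentrations must be non-negative.", "spakit_error_input")
  }
  (c_t * v_t - c_0 * v_0) / 1000
}

#' Dialysate clearance rate
#'
#' Clearance as total solute removal per unit time, referenced to the mean
#' plasma concentration: `TSR / (C_av * t)`.
#'
#' @param tsr Total solute removal over the dwell (mmol, or g for proteins);
#'   see [total_solute_removal()].
#' @param c_av Mean plasma concentration over the dwell (mM, or g/L).
#' @param t Dwell duration, minutes.
#'
#' @return Clearance in mL/min.
#' @examples
#' clearance(8.4, 6, 240) # 5.833... mL/min
#' @export
clearance <- function(tsr, c_av, t) {
  if (any(t <= 0)) stop_spakit("`t` must be positive.", "spakit_error_input")
  if (any(c_av <= 0)) {
    stop_spakit(
      "Clearance is undefined for a non-positive mean plasma concentration.",
      "spakit_error_no_plasma"
    )
  }
  1000 * tsr / (c_av * t)
}

#' Mean plasma concentration over a dwell
#'
#' Arithmetic mean of the plasma values sampled at 0, 120 and 240 minutes. A
#' single missing interior value is filled by linear interpolation between its
#' neighbours; a missing endpoint is carried from the nearest available value
#' (and the result is annotated, so downstream reports can flag the
#' imputation).
#'
#' @param conc Plasma concentrations aligned with `times`; `NA` marks a
#'   missing sample.
#' @param times Sampling times in minutes; defaults to `c(0, 120, 240)`.
#'
#' @return The mean concentration, with an attribute `"imputed"` naming any
#'   imputed time points (character(0) when none).
#' @examples
#' mean_plasma(c(4, NA, 8)) # interior gap interpolated to 6; mean 6
#' @export
mean_plasma <- function(conc, times = c(0, 120, 240)) {
  if (length(conc) != length(times)) {
    stop_spakit("`conc` and `times` must have the same length.", "spakit_error_input")
  }
  if (all(is.na(conc))) {
    stop_spakit("No plasma data: all values are missing.", "spakit_error_no_plasma")
  }
  if (any(conc < 0, na.rm = TRUE)) {
    stop_spakit("Plasma concentrations must be non-negative.", "spakit_error_input")
  }
  ord <- order(times)
  times <- times[ord]
  conc <- conc[ord]
  imputed <- character(0)
  filled <- conc
  for (i in seq_along(filled)) {
    if (!is.na(filled[i])) next
    obs <- which(!is.na(conc))
    if (any(obs < i) && any(obs > i)) {
      filled[i] <- approx(times[obs], conc[obs], xout = times[i])$y
      imputed <- c(imputed, sprintf("t%g_interpolated", times[i]))
    } else {
      nearest <- obs[which.min(abs(times[obs] - times[i]))]
      filled[i] <- conc[nearest]
      imputed <- c(imputed, sprintf("t%g_carried_from_t%g", times[i], times[nearest]))
    }
  }
  structure(mean(filled), imputed = imputed)
}

#' Dialysate-to-plasma concentration ratio
#'
#' D/P ratio of a solute at a stated dwell time; higher values indicate a
#' faster-transporting peritoneal membrane.
#'
#' @param dialysate Dialysate concentration.
#' @param plasma Plasma concentration (must be positive).
#' @return The ratio `dialysate / plasma`.
#' @examples
#' dp_ratio(2.05, 5) # 0.41
#' @export
dp_ratio <- function(dialysate, plasma) {
  if (any(plasma <= 0)) {
    stop_spakit("D/P ratio is undefined for non-positive plasma concentration.",
                "spakit_error_no_plasma")
  }
  if (any(dialysate < 0)) {
    stop_spakit("Dialysate concentration must be non-negative.", "spakit_error_input")
  }
  dialysate / plasma
}

#' Glucose D/D0 ratio
#'
#' Dialysate glucose at the end of the dwell divided by its initial value.
#' Lower values indicate faster glucose absorption (higher transport).
#'
#' @param glucose_t Dialysate glucose at the stated time.
#' @param glucose_0 Initial dialysate glucose (must be positive).
#' @return The ratio `glucose_t / glucose_0`.
#' @examples
#' dd0_ratio(48.75, 75) # 0.65
#' @export
dd0_ratio <- function(glucose_t, glucose_0) {
  if (any(glucose_0 <= 0)) {
    stop_spakit("D/D0 is undefined for non-positive initial glucose.",
                "spakit_error_input")
  }
  if (any(glucose_t < 0)) {
    stop_spakit("Glucose concentration must be non-negative.", "spakit_error_input")
  }
  glucose_t / glucose_0
}

#' Body surface area from body weight
#'
#' Allometric power law `k * weight^a`. The default coefficients are the
#' porcine Kelley formula (k = 0.0734, a = 0.656, weight in kg, BSA in m2),
#' the convention used for normalizing transport parameters in swine studies;
#' both coefficients are configurable.
#'
#' @param weight Body weight in kg (positive).
#' @param k,a Allometric coefficients.
#' @return Body surface area in m2, strictly increasing in `weight`.
#' @examples
#' body_surface_area(60)
#' @export
body_surface_area <- function(weight, k = 0.0734, a = 0.656) {
  if (any(weight <= 0)) {
    stop_spakit("`weight` must be positive.", "spakit_error_input")
  }
  k * weight^a
}
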