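#' Longitudinal plasma trajectory of an induced uremic episode
#'
#' Emulates the plasma solute course of a nephrotoxin-induced
#' acute-on-chronic kidney injury superimposed on stable CKD: a smooth rise
#' from the CKD baseline to a peak around day 12, followed by exponential
#' relaxation back toward baseline that keeps the value noticeably above
#' baseline beyond day 28. The rise is a half-sine-squared ramp (zero slope
#' at both ends), the recovery `baseline + (peak - baseline) exp(-(d -
#' peak_day)/recovery_timescale)`.
#'
#' Default baselines and peaks are available for urea (3.6 -> 16.7 mM) and
#' creatinine (0.212 -> 0.932 mM); other solutes need explicit parameters.
#'
#' @param solute Solute name.
#' @param baseline,peak Plasma concentration at stable CKD and at the peak of
#'   the episode (mM); `peak > baseline > 0`.
#' @param peak_day Day of the peak (default 12).
#' @param recovery_timescale E-folding time of the recovery, days (default 5,
#'   which leaves the day-28 value about 14% above baseline for the default
#'   creatinine episode).
#' @param horizon Last day of the trajectory (default 42); `peak_day` must
#'   lie within it.
#' @param noise_cv Day-to-day multiplicative noise (default 0: the smooth
#'   trajectory itself).
#' @param seed Seed used when `noise_cv > 0`.
#'
#' @return A tibble of class `"spa_uremia_course"` with columns `day` and
#'   `value`, plus the parameters as attributes.
#' @examples
#' simulate_uremia_course("urea")
#' @export
simulate_uremia_course <- function(solute = "urea",
                                   baseline = NULL, peak = NULL,
                                   peak_day = 12, recovery_timescale = 5,
                                   horizon = 42, noise_cv = 0, seed = NULL) {
  defaults <- list(
    urea = c(baseline = 3.6, peak = 16.7),
    creatinine = c(baseline = 0.212, peak = 0.932)
  )
  if (is.null(baseline) || is.null(peak)) {
    if (!solute %in% names(defaults)) {
      stop_spakit(sprintf("No default episode parameters for '%s'; give `baseline` and `peak`.",
                          solute), "spakit_error_input")
    }
    baseline <- baseline %||% defaults[[solute]][["baseline"]]
    peak <- peak %||% defaults[[solute]][["peak"]]
  }
  if (!(peak > baseline && baseline > 0)) {
    stop_spakit("Need `peak` > `baseline` > 0.", "spakit_error_input")
  }
  if (peak_day <= 0 || peak_day > horizon) {
    stop_spakit("`peak_day` must lie within (0, horizon].", "spakit_error_input")
  }
  if (recovery_timescale <= 0) {
    stop_spakit("`recovery_timescale` must be positive.", "spakit_error_input")
  }
  day <- seq(0, horizon)
  shape <- ifelse(
    day <= peak_day,
    sin(pi / 2 * day / peak_day)^2,
    exp(-(day - peak_day) / recovery_timescale)
  )
  value <- baseline + (peak - baseline) * shape
  if (noise_cv > 0) {
    draw <- function() pmax(0, value * (1 + noise_cv * rnorm(length(value))))
    value <- if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
  }
  structure(
    tibble(day = day, value = value),
    solute = solute, baseline = baseline, peak = peak,
    peak_day = peak_day, recovery_timescale = recovery_timescale,
    class = c("spa_uremia_course", class(tibble()))
  )
}

#' Plasma level at a given day of a uremic episode
#'
#' Convenience accessor linking a [simulate_uremia_course()] trajectory to
#' the dwell simulator: pick the plasma level of the episode day on which a
#' dwell is performed and pass it to [sim_config()] as
#' `plasma_level = c(<solute> = ...)`.
#'
#' @param course A `"spa_uremia_course"`.
#' @param day Episode day (must be on the trajectory grid).
#' @return The plasma concentration on that day.
#' @export
plasma_from_course <- function(course, day) {
  stopifnot(inherits(course, "spa_uremia_course"))
  hit <- which(course$day == day)
  if (!length(hit)) {
    stop_spakit("`day` is outside the simulated horizon.", "spakit_error_input")
  }
  course$value[hit]
}
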