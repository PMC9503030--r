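#' Per-solute parameter table for the dwell simulator
#'
#' Defaults emulate a 2 L, 4 h, 1.36% glucose dwell in a large uremic animal
#' at the peak of acute-on-chronic kidney injury: plasma urea 16.7 mM and
#' creatinine 0.932 mM (the uremic peak), phosphate 2.6 mM, potassium 4.4 mM;
#' dialysate starts at 75 mM glucose and 132 mM sodium, everything else zero.
#' True MTACs sit at the low-transporter values typical of a porcine
#' peritoneum (urea 8.3, creatinine 3.3, phosphate 2.3, potassium 18.6
#' mL/min); the glucose MTAC of 3.9 mL/min is the constant-volume closed-form
#' inversion of a 4 h D/D0 of 0.65. Sieving is 0.75 for small solutes (a low
#' glucose dwell drives most ultrafiltration through the small pores) and
#' near zero for proteins. Residual-fluid concentrations (`residual_conc`)
#' reflect a near-equilibrated overnight dwell: 90% of plasma for small
#' solutes, plasma level for glucose.
#'
#' @return A tibble with columns `solute`, `true_mtac` (mL/min),
#'   `plasma_level` (mM; g/L for proteins), `sieving` (0-1),
#'   `initial_dialysate`, `residual_conc`.
#' @export
sim_solutes <- function() {
  tibble(
    solute = c("urea", "creatinine", "phosphate", "potassium",
               "sodium", "glucose", "albumin", "total_protein"),
    true_mtac = c(8.3, 3.3, 2.3, 18.6, 15, 3.9, 0.05, 0.08),
    plasma_level = c(16.7, 0.932, 2.6, 4.4, 140, 5.0, 35, 60),
    sieving = c(0.75, 0.75, 0.75, 0.75, 0.6, 0.75, 0.05, 0.05),
    initial_dialysate = c(0, 0, 0, 0, 132, 75, 0, 0),
    residual_conc = c(0.9 * 16.7, 0.9 * 0.932, 0.9 * 2.6, 0.9 * 4.4,
                      138, 5.0, 2.3, 3.0)
  )
}

#' Configuration of one simulated SPA dwell
#'
#' Ground truth and noise model for [simulate_dwell()]. Scalar defaults
#' follow the standard protocol: a 2 L instillation sampled at
#' 0/10/30/60/120/180/240 min with 5 mL retained per sample, a 300 mL
#' residual volume from the overnight dwell carrying 2.3 g/L albumin, an
#' ultrafiltration inflow of 4 mL/min decaying with a 120 min time constant
#' as the glucose gradient dissipates, and a constant 0.5 mL/min lymphatic
#' (bulk) absorption, for an integrated net ultrafiltration of about 295 mL
#' over 4 h.
#'
#' @param solutes Per-solute parameter tibble; see [sim_solutes()].
#' @param true_mtac,plasma_level,sieving,initial_dialysate,residual_conc
#'   Named numeric vectors overriding single cells of `solutes`, e.g.
#'   `true_mtac = c(creatinine = 6.6)`.
#' @param instilled_volume Fresh-bag volume, mL.
#' @param residual_volume_true Residual volume from the overnight dwell, mL.
#' @param residual_volume_post_true Residual volume left by the final drain,
#'   mL (defaults to `residual_volume_true`).
#' @param residual_albumin Albumin concentration of the residual fluid, g/L.
#' @param flush_volume Post-dwell flush volume, mL.
#' @param uf_rate_initial Transcapillary ultrafiltration rate at t = 0,
#'   mL/min.
#' @param uf_decay_time Exponential decay time of the ultrafiltration rate,
#'   minutes.
#' @param lymphatic_rate Constant lymphatic absorption, mL/min (removes fluid
#'   at dialysate concentration).
#' @param sample_times Sampling schedule in minutes, strictly increasing and
#'   starting at 0.
#' @param sample_retained_volume Aliquot retained per sample, mL (protocols
#'   retain 2-7 mL).
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   measurement noise applied to measured concentrations (never to the truth
#'   ledger); measured values are truncated at zero.
#' @param body_weight Body weight in kg, carried to the observed dwell.
#' @param culture_positive,cloudy_effluent,leukocyte_mean Effluent
#'   diagnostics of the simulated dwell; the measured leukocyte count gets
#'   the same multiplicative noise as concentrations.
#' @param ode_rtol,ode_atol Integration tolerances passed to
#'   [deSolve::lsoda()].
#' @param seed Integer seed making the dwell reproducible; `NULL` draws from
#'   the current RNG state.
#' @param dwell_id,animal_id Identifiers stamped on the observed dwell.
#'
#' @return A list of class `"spa_sim_config"`.
#' @export
sim_config <- function(solutes = sim_solutes(),
                       true_mtac = NULL, plasma_level = NULL, sieving = NULL,
                       initial_dialysate = NULL, residual_conc = NULL,
                       instilled_volume = 2000,
                       residual_volume_true = 300,
                       residual_volume_post_true = residual_volume_true,
                       residual_albumin = 2.3,
                       flush_volume = 2000,
                       uf_rate_initial = 4,
                       uf_decay_time = 120,
                       lymphatic_rate = 0.5,
                       sample_times = c(0, 10, 30, 60, 120, 180, 240),
                       sample_retained_volume = 5,
                       noise_cv = 0.05,
                       body_weight = 60,
                       culture_positive = FALSE,
                       cloudy_effluent = FALSE,
                       leukocyte_mean = 0.02,
                       ode_rtol = 1e-12,
                       ode_atol = 1e-12,
                       seed = NULL,
                       dwell_id = "sim-1",
                       animal_id = "sim-animal") {
  solutes <- as_tibble(solutes)
  patch <- function(tab, col, vals) {
    if (is.null(vals)) return(tab)
    bad <- setdiff(names(vals), tab$solute)
    if (length(bad)) {
      stop_spakit(paste0("Unknown solute(s) in `", col, "`: ",
                         paste(bad, collapse = ", ")), "spakit_error_input")
    }
    tab[[col]][match(names(vals), tab$solute)] <- unname(vals)
    tab
  }
  solutes <- patch(solutes, "true_mtac", true_mtac)
  solutes <- patch(solutes, "plasma_level", plasma_level)
  solutes <- patch(solutes, "sieving", sieving)
  solutes <- patch(solutes, "initial_dialysate", initial_dialysate)
  solutes <- patch(solutes, "residual_conc", residual_conc)
  # albumin residual fluid tracks the configured marker concentration
  solutes$residual_conc[solutes$solute == "albumin"] <- residual_albumin

  if (any(solutes$true_mtac < 0) || any(solutes$plasma_level < 0)) {
    stop_spakit("MTACs and plasma levels must be non-negative.", "spakit_error_input")
  }
  if (any(solutes$sieving < 0 | solutes$sieving > 1)) {
    stop_spakit("Sieving coefficients must lie in [0, 1].", "spakit_error_input")
  }
  if (uf_rate_initial < 0 || lymphatic_rate < 0 || uf_decay_time <= 0) {
    stop_spakit("Rates must be non-negative and `uf_decay_time` positive.",
                "spakit_error_input")
  }
  if (length(sample_times) < 2 || sample_times[1] != 0 || any(diff(sample_times) <= 0)) {
    stop_spakit("`sample_times` must start at 0 and be strictly increasing.",
                "spakit_error_input")
  }
  if (sample_retained_volume < 0) {
    stop_spakit("`sample_retained_volume` must be non-negative.", "spakit_error_input")
  }
  if (noise_cv < 0) stop_spakit("`noise_cv` must be non-negative.", "spakit_error_input")
  if (instilled_volume <= 0 || residual_volume_true < 0 ||
      residual_volume_post_true < 0 || flush_volume <= 0) {
    stop_spakit("Volumes must be positive (residual volumes non-negative).",
                "spakit_error_input")
  }
  structure(
    list(
      solutes = solutes,
      instilled_volume = instilled_volume,
      residual_volume_true = residual_volume_true,
      residual_volume_post_true = residual_volume_post_true,
      residual_albumin = residual_albumin,
      flush_volume = flush_volume,
      uf_rate_initial = uf_rate_initial,
      uf_decay_time = uf_decay_time,
      lymphatic_rate = lymphatic_rate,
      sample_times = sample_times,
      sample_retained_volume = sample_retained_volume,
      noise_cv = noise_cv,
      body_weight = body_weight,
      culture_positive = culture_positive,
      cloudy_effluent = cloudy_effluent,
      leukocyte_mean = leukocyte_mean,
      ode_rtol = ode_rtol,
      ode_atol = ode_atol,
      seed = seed,
      dwell_id = dwell_id,
      animal_id = animal_id
    ),
    class = "spa_sim_config"
  )
}

# multiplicative Gaussian noise, truncated at zero; draws in a fixed order
measure <- function(true, cv) {
  if (cv == 0) return(true)
  pmax(0, true * (1 + cv * rnorm(length(true))))
}

#' Simulate the overnight dwell preceding a SPA
#'
#' The overnight dwell only matters for the assessment through what it leaves
#' behind: a residual volume of near-equilibrated fluid whose albumin
#' concentration, measured in the drained overnight effluent, is the
#' indicator for the pre-dwell residual-volume estimate. Because fresh
#' dialysate contains no albumin, the t = 0 concentration after mixing is
#' always strictly below the effluent concentration, so the indicator
#' dilution is well posed on synthetic data.
#'
#' @param config A [sim_config()].
#' @return A list with `residual_volume` (true, mL) and `effluent_albumin`
#'   (the measured overnight effluent albumin, g/L, carrying measurement
#'   noise when `config$noise_cv > 0`).
#' @export
simulate_overnight <- function(config) {
  stopifnot(inherits(config, "spa_sim_config"))
  run <- function() {
    list(
      residual_volume = config$residual_volume_true,
      effluent_albumin = measure(config$residual_albumin, config$noise_cv)
    )
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

# right-hand side of the two-pool model:
#   d(V D_s)/dt = MTAC_s (P_s - D_s) + S_s Qu(t) P_s - L D_s
#   dV/dt       = Qu(t) - L,   Qu(t) = uf0 exp(-t / tau)
# auxiliary states accumulate the three flux integrals per solute
dwell_rhs <- function(t, y, parms) {
  ns <- parms$ns
  V <- y[1]
  M <- y[2:(1 + ns)]
  D <- M / V
  qu <- parms$uf0 * exp(-t / parms$tau)
  diffusive <- parms$mtac * (parms$plasma - D)
  convective <- parms$sieving * qu * parms$plasma
  lymphatic <- parms$lymph * D
  list(c(qu - parms$lymph, diffusive + convective - lymphatic,
         diffusive, convective, lymphatic))
}

#' Simulate one SPA dwell with ground truth
#'
#' Integrates the two-pool kinetic model of a dwell: per solute,
#' `d(V D)/dt = MTAC (P - D) + S Qu(t) P - L D` with volume kinetics
#' `dV/dt = Qu(t) - L` and an exponentially decaying ultrafiltration inflow
#' `Qu(t) = uf_rate_initial exp(-t / uf_decay_time)`. At each scheduled
#' sample time the retained aliquot is removed instantaneously at the current
#' concentration. Plasma concentrations are held constant within the dwell.
#'
#' Measurement noise (multiplicative Gaussian, truncated at zero) is applied
#' to measured concentrations only; the truth ledger is never perturbed.
#' Identical configurations with identical seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `"spa_sim_dwell"` with elements
#'   \describe{
#'     \item{`observed`}{the measured dwell as a [spa_dwell()], ready for
#'       [analyze_spa()];}
#'     \item{`truth`}{the ground-truth ledger: true MTACs, the volume
#'       trajectory at sample times, analytic integrated ultrafiltration and
#'       lymphatic volumes, sampled volume and per-solute sampled mass, the
#'       per-solute flux integrals (diffusive, convective, lymphatic), true
#'       dialysate concentrations, initial/final solute mass, and the true
#'       residual and drain volumes;}
#'     \item{`config`}{the configuration echo.}
#'   }
#' @examples
#' sim <- simulate_dwell(sim_config(seed = 7))
#' sim$truth$integrated_uf - sim$truth$integrated_lymphatic # true net UF
#' @export
simulate_dwell <- function(config) {
  stopifnot(inherits(config, "spa_sim_config"))
  run <- function() simulate_dwell_impl(config)
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

simulate_dwell_impl <- function(config) {
  sol <- config$solutes
  ns <- nrow(sol)
  times <- config$sample_times
  t_end <- times[length(times)]
  vs <- config$sample_retained_volume
  rv <- config$residual_volume_true

  # overnight dwell: residual fluid + measured effluent albumin (1 RNG draw)
  effluent_albumin <- measure(config$residual_albumin, config$noise_cv)

  V <- config$instilled_volume + rv
  M <- config$instilled_volume * sol$initial_dialysate + rv * sol$residual_conc
  aux <- rep(0, 3 * ns) # cumulative diffusive / convective / lymphatic flux
  parms <- list(ns = ns, mtac = sol$true_mtac, plasma = sol$plasma_level,
                sieving = sol$sieving, uf0 = config$uf_rate_initial,
                tau = config$uf_decay_time, lymph = config$lymphatic_rate)

  d_true <- matrix(NA_real_, length(times), ns,
                   dimnames = list(NULL, sol$solute))
  v_pre_sample <- v_post_sample <- numeric(length(times))
  sampled_mass <- setNames(rep(0, ns), sol$solute)

  # the volume ODE is autonomous and concave (Qu decays, L is constant), so
  # within an interval the minimum volume sits at the interval end; check the
  # closed-form volume there before integrating to fail fast on pathological
  # configurations instead of letting the solver run into V <= 0
  v_analytic_drop <- function(t0, t1) {
    config$uf_rate_initial * config$uf_decay_time *
      (exp(-t0 / config$uf_decay_time) - exp(-t1 / config$uf_decay_time)) -
      config$lymphatic_rate * (t1 - t0)
  }

  for (i in seq_along(times)) {
    if (i > 1) {
      if (V + v_analytic_drop(times[i - 1], times[i]) <= max(vs, 1)) {
        stop_spakit(
          sprintf("Intraperitoneal volume driven to zero before t = %g min; the configuration is pathological.",
                  times[i]),
          "spakit_error_volume"
        )
      }
      out <- deSolve::lsoda(
        y = c(V, M, aux), times = c(times[i - 1], times[i]), func = dwell_rhs,
        parms = parms, rtol = config$ode_rtol, atol = config$ode_atol
      )
      y <- unname(out[nrow(out), -1])
      V <- y[1]
      M <- y[2:(1 + ns)]
      aux <- y[-(1:(1 + ns))]
    }
    if (V <= vs) {
      stop_spakit(
        sprintf("Intraperitoneal volume driven to %.1f mL at t = %g min; the configuration is pathological.",
                V, times[i]),
        "spakit_error_volume"
      )
    }
    v_pre_sample[i] <- V
    d_true[i, ] <- M / V
    sampled_mass <- sampled_mass + d_true[i, ] * vs
    M <- M - d_true[i, ] * vs
    V <- V - vs
    v_post_sample[i] <- V
  }

  rv_post <- config$residual_volume_post_true
  drain <- V - rv_post
  if (drain <= 0) {
    stop_spakit("Final drain volume would be non-positive; the configuration is pathological.",
                "spakit_error_volume")
  }

  # measured series; fixed draw order: dialysate by time then solute,
  # plasma by time then solute, flush albumin, leukocytes
  d_obs <- matrix(measure(as.vector(t(d_true)), config$noise_cv),
                  nrow = length(times), ncol = ns, byrow = TRUE)
  plasma_times <- c(0, 120, 240)
  p_true <- matrix(rep(sol$plasma_level, each = length(plasma_times)),
                   nrow = length(plasma_times))
  p_obs <- matrix(measure(as.vector(t(p_true)), config$noise_cv),
                  nrow = length(plasma_times), ncol = ns, byrow = TRUE)
  alb_idx <- which(sol$solute == "albumin")
  flush_alb_true <- rv_post * unname(d_true[length(times), alb_idx]) /
    (rv_post + config$flush_volume)
  flush_alb <- measure(flush_alb_true, config$noise_cv)
  leukocytes <- measure(config$leukocyte_mean, config$noise_cv)

  dialysate <- tibble(
    solute = rep(sol$solute, each = length(times)),
    time_min = rep(times, ns),
    conc = as.vector(d_obs)
  )
  plasma <- tibble(
    solute = rep(sol$solute, each = length(plasma_times)),
    time_min = rep(plasma_times, ns),
    conc = as.vector(p_obs)
  )

  observed <- spa_dwell(
    dialysate = dialysate,
    plasma = plasma,
    instilled_volume = config$instilled_volume,
    drain_volume_end = drain,
    sample_volume_total = vs * length(times),
    duration = t_end,
    albumin_overnight_effluent = effluent_albumin,
    albumin_flush = flush_alb,
    flush_volume = config$flush_volume,
    body_weight = config$body_weight,
    diagnostics = list(
      culture_positive = config$culture_positive,
      cloudy_effluent = config$cloudy_effluent,
      leukocyte_count = leukocytes
    ),
    dwell_id = config$dwell_id,
    animal_id = config$animal_id
  )

  aux <- matrix(aux, nrow = ns, ncol = 3,
                dimnames = list(sol$solute, c("diffusive", "convective", "lymphatic")))
  truth <- list(
    mtac = setNames(sol$true_mtac, sol$solute),
    plasma = setNames(sol$plasma_level, sol$solute),
    volume = tibble(time_min = times, v_pre_sample = v_pre_sample,
                    v_post_sample = v_post_sample),
    integrated_uf = config$uf_rate_initial * config$uf_decay_time *
      (1 - exp(-t_end / config$uf_decay_time)),
    integrated_lymphatic = config$lymphatic_rate * t_end,
    sampled_volume = vs * length(times),
    sampled_mass = sampled_mass,
    fluxes = as_tibble(aux, rownames = "solute"),
    dialysate_true = as_tibble(d_true) |>
      dplyr::mutate(time_min = times, .before = 1),
    initial_mass = setNames(config$instilled_volume * sol$initial_dialysate +
                              rv * sol$residual_conc, sol$solute),
    final_mass = setNames(M, sol$solute),
    rv_pre = rv,
    rv_post = rv_post,
    drain_volume = drain,
    final_volume_pre_drain = V
  )
  structure(list(observed = observed, truth = truth, config = config),
            class = "spa_sim_dwell")
}

#' Simulate a seeded batch of dwells
#'
#' Runs [simulate_dwell()] `n` times with per-dwell seeds derived
#' deterministically from `seed` (`seed + 1, ..., seed + n`), stamping
#' sequential dwell identifiers.
#'
#' @param config A [sim_config()], e.g. from [scenario_preset()].
#' @param n Number of dwells.
#' @param seed Integer base seed.
#' @param id_prefix Prefix for the generated dwell identifiers.
#' @return A list of `n` `"spa_sim_dwell"` objects.
#' @export
simulate_batch <- function(config, n, seed, id_prefix = "dwell") {
  stopifnot(inherits(config, "spa_sim_config"), n >= 1)
  purrr::map(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- seed + i
    cfg$dwell_id <- sprintf("%s-%03d", id_prefix, i)
    simulate_dwell(cfg)
  })
}

#' @export
print.spa_sim_dwell <- function(x, ...) {
  cat("<spa_sim_dwell>", x$config$dwell_id, "\n")
  cat(sprintf("  true MTACs (mL/min): %s\n",
              paste(sprintf("%s=%.3g", names(x$truth$mtac), x$truth$mtac),
                    collapse = ", ")))
  cat(sprintf("  true net UF: %.1f mL; drain: %.1f mL; RV pre/post: %g/%g mL\n",
              x$truth$integrated_uf - x$truth$integrated_lymphatic,
              x$truth$drain_volume, x$truth$rv_pre, x$truth$rv_post))
  invisible(x)
}
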