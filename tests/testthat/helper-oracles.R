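# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# constant-volume, constant-plasma solution of the two-pool model:
# D(t) = P + (D0 - P) exp(-MTAC t / V)
closed_form_dialysate <- function(t, mtac, v, p, d0 = 0) {
  p + (d0 - p) * exp(-mtac * t / v)
}

# analytic intraperitoneal volume between sampling events:
# V(t) = V0 + uf0 tau (1 - e^(-t/tau)) - L t
analytic_volume <- function(t, v0, uf0, tau, lymph) {
  v0 + uf0 * tau * (1 - exp(-t / tau)) - lymph * t
}

# brute-force peritonitis oracle: enumerate every completion of the unknown
# criteria; definitive only when all completions agree on the 2-of-3 rule
oracle_peritonitis <- function(culture, cloudy, leukocytes, dwell_min) {
  leuk <- if (is.na(leukocytes) || dwell_min < 120) NA else leukocytes > 0.1
  crit <- list(culture, cloudy, leuk)
  unknown <- which(vapply(crit, is.na, logical(1)))
  completions <- if (length(unknown) == 0) {
    list(unlist(crit))
  } else {
    grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(unknown)))
    lapply(seq_len(nrow(grid)), function(i) {
      filled <- crit
      filled[unknown] <- as.list(as.logical(grid[i, ]))
      unlist(filled)
    })
  }
  verdicts <- vapply(completions, function(x) sum(x) >= 2, logical(1))
  if (all(verdicts)) "peritonitis" else if (all(!verdicts)) "no_peritonitis" else "indeterminate"
}

# hand-rolled type-7 quantile so summary statistics are cross-checked against
# an implementation that shares no code with stats::quantile
naive_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

naive_summary <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- sum(x) / n
  list(
    n = n,
    mean = m,
    sd = if (n >= 2) sqrt(sum((x - m)^2) / (n - 1)) else NA_real_,
    median = naive_quantile7(x, 0.5),
    iqr = naive_quantile7(x, 0.75) - naive_quantile7(x, 0.25)
  )
}

# a minimal hand-built dwell with exact closed-form concentrations, for tests
# that must not depend on the simulator
manual_dwell <- function(mtac = c(urea = 5), p = c(urea = 10), v = 2000,
                         duration = 240, rv = 0, body_weight = NA_real_) {
  times <- c(0, duration)
  dial <- purrr::map_dfr(names(mtac), function(s) {
    tibble::tibble(
      solute = s, time_min = times,
      conc = closed_form_dialysate(times, mtac[[s]], v, p[[s]])
    )
  })
  alb_t0 <- rv * 2.3 / (v + rv)
  dial <- dplyr::bind_rows(
    dial,
    tibble::tibble(solute = "albumin", time_min = times, conc = c(alb_t0, 0.4))
  )
  plasma <- purrr::map_dfr(names(mtac), function(s) {
    tibble::tibble(solute = s, time_min = c(0, 120, 240), conc = p[[s]])
  })
  spa_dwell(
    dialysate = dial, plasma = plasma,
    instilled_volume = v, drain_volume_end = v, sample_volume_total = 0,
    duration = duration, albumin_overnight_effluent = 2.3,
    albumin_flush = rv * 0.4 / (rv + 2000), flush_volume = 2000,
    body_weight = body_weight
  )
}
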