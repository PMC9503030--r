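#' Analysis options for a SPA dwell
#'
#' Collects the conventions that are fixed for a run: the BSA normalization
#' constant, the allometric BSA coefficients, which plasma value the D/P
#' denominator uses, which volumes enter the Garred formula, and which solutes
#' get an MTAC and clearance.
#'
#' @param normalization_bsa Reference body surface area for normalization,
#'   m2 (default 1.73).
#' @param bsa_k,bsa_a Allometric coefficients for [body_surface_area()];
#'   defaults are the porcine Kelley formula.
#' @param dp_denominator `"end"` uses the plasma value at the end of the dwell
#'   as the D/P denominator; `"mean"` uses the mean of the 0/120/240 values.
#'   Published assessments differ on this point.
#' @param mtac_volumes `"drained"` feeds the instilled and drained dialysate
#'   volumes into the Garred prefactor and log ratio (the literal reading of
#'   the formula); `"intraperitoneal"` adds the residual volumes so total
#'   intraperitoneal volumes are used (a defensible alternative, which makes
#'   MTAC depend on a successful residual-volume measurement).
#' @param mtac_solutes Solutes for which MTAC, total solute removal and
#'   clearance are computed. By default urea, creatinine, phosphate and
#'   potassium; sodium and total protein are carried as measured series only.
#' @param quantile_type Quantile algorithm for IQRs in stratified summaries
#'   (type 7 = linear interpolation, the R default).
#'
#' @return A list of class `"spa_options"`.
#' @export
spa_options <- function(normalization_bsa = 1.73,
                        bsa_k = 0.0734,
                        bsa_a = 0.656,
                        dp_denominator = c("end", "mean"),
                        mtac_volumes = c("drained", "intraperitoneal"),
                        mtac_solutes = c("urea", "creatinine", "phosphate", "potassium"),
                        quantile_type = 7) {
  structure(
    list(
      normalization_bsa = normalization_bsa,
      bsa_k = bsa_k,
      bsa_a = bsa_a,
      dp_denominator = match.arg(dp_denominator),
      mtac_volumes = match.arg(mtac_volumes),
      mtac_solutes = mtac_solutes,
      quantile_type = quantile_type
    ),
    class = "spa_options"
  )
}

#' Full transport-parameter report for one dwell
#'
#' Orchestrates the whole per-dwell computation: residual volumes before and
#' after the dwell by indicator dilution, net ultrafiltration, per-solute
#' MTAC (Garred), total solute removal and clearance against the mean plasma
#' concentration, D/P ratios for urea and creatinine, the glucose D/D0 ratio,
#' and BSA normalization (x 1.73 / BSA) of MTAC and clearance.
#'
#' Any per-solute failure (gradient crossover, missing plasma) or marker
#' failure (indicator dilution) is converted into a flag on the result; the
#' affected quantities are `NA`, nothing is dropped silently, and the
#' remaining quantities are still reported.
#'
#' @param dwell A [spa_dwell()], or a list of them (a batch; results are
#'   returned in the same order).
#' @param options An [spa_options()] list.
#'
#' @return An object of class `"spa_result"` (or a list of them for a batch)
#'   with elements `rv_pre`, `rv_post`, `ufv_net`, `bsa`, `dp_urea_4h`,
#'   `dp_creatinine_4h`, `dd0_glucose_4h`, a per-solute tibble `solutes`
#'   (`mtac`, `mtac_normalized`, `tsr`, `clearance`, `clearance_normalized`,
#'   `flag`) and a character vector `flags`. Supports [tidy()] (long tibble)
#'   and [glance()] (one-row tibble).
#' @examples
#' sim <- simulate_dwell(sim_config(seed = 1, noise_cv = 0))
#' res <- analyze_spa(sim$observed)
#' glance(res)
#' @export
analyze_spa <- function(dwell, options = spa_options()) {
  if (is.list(dwell) && !inherits(dwell, "spa_dwell")) {
    return(purrr::map(dwell, analyze_spa, options = options))
  }
  stopifnot(inherits(dwell, "spa_dwell"))
  flags <- character(0)
  note <- function(tag, cnd) {
    flags <<- c(flags, paste0(tag, ": ", conditionMessage(cnd)))
  }
  grab <- function(tag, expr) {
    tryCatch(expr, spakit_error = function(e) {
      note(tag, e)
      NA_real_
    })
  }

  t_end <- dwell$duration

  # residual volume before the dwell: overnight effluent vs t0 albumin
  alb_t0 <- dialysate_at(dwell, "albumin", 0)
  rv_pre <- grab("rv_pre", {
    if (is.na(alb_t0) || is.na(dwell$albumin_overnight_effluent)) {
      stop_spakit("albumin marker concentrations missing", "spakit_error_missing")
    }
    residual_volume(dwell$instilled_volume, alb_t0, dwell$albumin_overnight_effluent)
  })

  # residual volume after the dwell: final-drain albumin vs flush effluent
  alb_end <- dialysate_at(dwell, "albumin", t_end)
  rv_post <- grab("rv_post", {
    if (is.na(alb_end) || is.na(dwell$albumin_flush) || is.na(dwell$flush_volume)) {
      stop_spakit("flush albumin or flush volume missing", "spakit_error_missing")
    }
    residual_volume(dwell$flush_volume, dwell$albumin_flush, alb_end)
  })

  ufv <- grab("ufv_net", {
    if (is.na(rv_pre) || is.na(rv_post) || is.na(dwell$drain_volume_end)) {
      stop_spakit("requires both residual volumes and the final drain volume",
                  "spakit_error_missing")
    }
    net_ultrafiltration(dwell$drain_volume_end, rv_post,
                        dwell$sample_volume_total,
                        dwell$instilled_volume + rv_pre)
  })

  bsa <- if (is.na(dwell$body_weight)) {
    flags <- c(flags, "bsa: no body weight; normalized values not computed")
    NA_real_
  } else {
    body_surface_area(dwell$body_weight, options$bsa_k, options$bsa_a)
  }
  norm_factor <- if (is.na(bsa)) NA_real_ else options$normalization_bsa / bsa

  # volumes entering the Garred formula and the solute mass balance
  v0_mtac <- switch(options$mtac_volumes,
    drained = dwell$instilled_volume,
    intraperitoneal = dwell$instilled_volume + rv_pre
  )
  vt_mtac <- switch(options$mtac_volumes,
    drained = dwell$drain_volume_end,
    intraperitoneal = dwell$drain_volume_end + rv_post
  )
  v0_tsr <- dwell$instilled_volume + rv_pre
  vt_tsr <- dwell$drain_volume_end + rv_post

  solutes <- sort(unique(dwell$dialysate$solute))
  per_solute <- purrr::map_dfr(solutes, function(s) {
    row <- tibble(
      solute = s, mtac = NA_real_, mtac_normalized = NA_real_,
      tsr = NA_real_, clearance = NA_real_, clearance_normalized = NA_real_,
      flag = NA_character_
    )
    if (!s %in% options$mtac_solutes) return(row)
    sflags <- character(0)
    d0 <- dialysate_at(dwell, s, 0)
    dt <- dialysate_at(dwell, s, t_end)
    p <- plasma_series(dwell, s)
    p_mean <- tryCatch({
      m <- mean_plasma(p)
      imp <- attr(m, "imputed")
      if (length(imp)) sflags <- c(sflags, paste0("plasma_", imp))
      as.numeric(m)
    }, spakit_error = function(e) {
      sflags <<- c(sflags, paste0("no_plasma: ", conditionMessage(e)))
      NA_real_
    })
    if (!is.na(p_mean) && !is.na(d0) && !is.na(dt)) {
      row$mtac <- tryCatch(
        {
          if (is.na(v0_mtac) || is.na(vt_mtac)) {
            stop_spakit("volumes for the Garred formula unavailable",
                        "spakit_error_missing")
          }
          mtac_garred(v0_mtac, vt_mtac, t_end, d0, dt, p_mean)
        },
        spakit_error = function(e) {
          sflags <<- c(sflags, paste0("mtac: ", conditionMessage(e)))
          NA_real_
        }
      )
      row$tsr <- tryCatch(
        {
          if (is.na(v0_tsr) || is.na(vt_tsr)) {
            stop_spakit("requires residual volumes", "spakit_error_missing")
          }
          total_solute_removal(dt, vt_tsr, d0, v0_tsr)
        },
        spakit_error = function(e) {
          sflags <<- c(sflags, paste0("tsr: ", conditionMessage(e)))
          NA_real_
        }
      )
      row$clearance <- if (is.na(row$tsr)) NA_real_ else {
        tryCatch(clearance(row$tsr, p_mean, t_end), spakit_error = function(e) {
          sflags <<- c(sflags, paste0("clearance: ", conditionMessage(e)))
          NA_real_
        })
      }
    } else if (is.na(d0) || is.na(dt)) {
      sflags <- c(sflags, "dialysate series incomplete at 0 or end of dwell")
    }
    row$mtac_normalized <- row$mtac * norm_factor
    row$clearance_normalized <- row$clearance * norm_factor
    if (length(sflags)) row$flag <- paste(sflags, collapse = "; ")
    row
  })
  for (i in which(!is.na(per_solute$flag))) {
    flags <- c(flags, paste0(per_solute$solute[i], ": ", per_solute$flag[i]))
  }

  dp_den <- function(s) {
    p <- plasma_series(dwell, s)
    switch(options$dp_denominator,
      end = if (!is.na(p[3])) {
        p[3]
      } else if (all(is.na(p))) {
        NA_real_
      } else {
        flags <<- c(flags, sprintf("dp_%s: end plasma missing, used nearest", s))
        p[max(which(!is.na(p)))]
      },
      mean = as.numeric(tryCatch(mean_plasma(p), spakit_error = function(e) NA_real_))
    )
  }
  dp_urea <- grab("dp_urea_4h", {
    den <- dp_den("urea")
    num <- dialysate_at(dwell, "urea", t_end)
    if (is.na(num) || is.na(den)) stop_spakit("missing urea data", "spakit_error_missing")
    dp_ratio(num, den)
  })
  dp_crea <- grab("dp_creatinine_4h", {
    den <- dp_den("creatinine")
    num <- dialysate_at(dwell, "creatinine", t_end)
    if (is.na(num) || is.na(den)) stop_spakit("missing creatinine data", "spakit_error_missing")
    dp_ratio(num, den)
  })
  dd0_glu <- grab("dd0_glucose_4h", {
    g0 <- dialysate_at(dwell, "glucose", 0)
    gt <- dialysate_at(dwell, "glucose", t_end)
    if (is.na(g0) || is.na(gt)) stop_spakit("missing glucose data", "spakit_error_missing")
    dd0_ratio(gt, g0)
  })

  structure(
    list(
      dwell_id = dwell$dwell_id,
      animal_id = dwell$animal_id,
      rv_pre = rv_pre,
      rv_post = rv_post,
      ufv_net = ufv,
      bsa = bsa,
      dp_urea_4h = dp_urea,
      dp_creatinine_4h = dp_crea,
      dd0_glucose_4h = dd0_glu,
      solutes = per_solute,
      flags = flags,
      options = options
    ),
    class = "spa_result"
  )
}

#' @export
print.spa_result <- function(x, ...) {
  cat("<spa_result>", if (!is.na(x$dwell_id)) x$dwell_id else "", "\n")
  cat(sprintf("  RV pre/post: %s / %s mL; net UF: %s mL; BSA: %s m2\n",
              format(x$rv_pre, digits = 4), format(x$rv_post, digits = 4),
              format(x$ufv_net, digits = 4), format(x$bsa, digits = 3)))
  cat(sprintf("  D/P urea %s, D/P creatinine %s, D/D0 glucose %s\n",
              format(x$dp_urea_4h, digits = 3),
              format(x$dp_creatinine_4h, digits = 3),
              format(x$dd0_glucose_4h, digits = 3)))
  print(x$solutes)
  if (length(x$flags)) {
    cat("  flags:\n")
    for (f in x$flags) cat("   -", f, "\n")
  }
  invisible(x)
}

#' @describeIn analyze_spa Long tibble of every derived parameter of a result
#'   (`parameter`, `solute`, `value`).
#' @param x An `spa_result`.
#' @param ... Unused.
#' @export
tidy.spa_result <- function(x, ...) {
  dwell <- list(
    rv_pre = x$rv_pre, rv_post = x$rv_post, ufv_net = x$ufv_net, bsa = x$bsa,
    dp_urea_4h = x$dp_urea_4h, dp_creatinine_4h = x$dp_creatinine_4h,
    dd0_glucose_4h = x$dd0_glucose_4h
  )
  dlevel <- tibble(
    dwell_id = x$dwell_id,
    parameter = names(dwell),
    solute = NA_character_,
    value = unlist(dwell, use.names = FALSE)
  )
  slevel <- x$solutes |>
    tidyr::pivot_longer(
      cols = c("mtac", "mtac_normalized", "tsr", "clearance", "clearance_normalized"),
      names_to = "parameter", values_to = "value"
    ) |>
    dplyr::transmute(
      dwell_id = x$dwell_id,
      parameter = .data$parameter,
      solute = .data$solute,
      value = .data$value
    )
  dplyr::bind_rows(dlevel, slevel)
}

#' @describeIn analyze_spa One-row tibble of the dwell-level quantities.
#' @export
glance.spa_result <- function(x, ...) {
  tibble(
    dwell_id = x$dwell_id, animal_id = x$animal_id,
    rv_pre = x$rv_pre, rv_post = x$rv_post, ufv_net = x$ufv_net, bsa = x$bsa,
    dp_urea_4h = x$dp_urea_4h, dp_creatinine_4h = x$dp_creatinine_4h,
    dd0_glucose_4h = x$dd0_glucose_4h,
    n_solutes = nrow(x$solutes), n_flags = length(x$flags)
  )
}

#' Wide table of a batch of SPA results
#'
#' One row per dwell with every dwell-level quantity plus per-solute MTAC and
#' clearance columns (`mtac_<solute>`, `clearance_<solute>`, and their
#' `_normalized` versions), the layout consumed by [stratify_results()].
#'
#' @param results A list of [analyze_spa()] results (a single `spa_result` is
#'   accepted too).
#' @param classification Optional per-dwell classification from
#'   [classify_peritonitis()], added as a column.
#' @return A tibble with one row per dwell, in input order.
#' @export
spa_results_table <- function(results, classification = NULL) {
  if (inherits(results, "spa_result")) results <- list(results)
  wide <- purrr::map_dfr(results, function(r) {
    g <- glance(r)[, c("dwell_id", "animal_id", "rv_pre", "rv_post", "ufv_net",
                       "bsa", "dp_urea_4h", "dp_creatinine_4h", "dd0_glucose_4h")]
    s <- r$solutes[!is.na(r$solutes$mtac) | !is.na(r$solutes$clearance), ]
    if (nrow(s)) {
      vals <- c(
        setNames(s$mtac, paste0("mtac_", s$solute)),
        setNames(s$mtac_normalized, paste0("mtac_normalized_", s$solute)),
        setNames(s$clearance, paste0("clearance_", s$solute)),
        setNames(s$clearance_normalized, paste0("clearance_normalized_", s$solute))
      )
      g <- dplyr::bind_cols(g, as_tibble(as.list(vals)))
    }
    g
  })
  if (!is.null(classification)) {
    wide <- dplyr::mutate(wide,
                          classification = as.character(classification),
                          .after = "animal_id")
  }
  wide
}
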