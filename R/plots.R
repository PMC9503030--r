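#' Plot a simulated dwell
#'
#' Dialysate concentration time courses, one panel per solute: the noiseless
#' truth as a line, the measured samples as points. A quick visual check that
#' small solutes rise toward plasma, glucose falls, and noise looks like the
#' configured CV.
#'
#' @param object A `"spa_sim_dwell"` from [simulate_dwell()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spa_sim_dwell <- function(object, ...) {
  truth_long <- tidyr::pivot_longer(object$truth$dialysate_true, -"time_min",
                                    names_to = "solute", values_to = "conc")
  ggplot2::ggplot(object$observed$dialysate,
                  ggplot2::aes(x = .data$time_min, y = .data$conc)) +
    ggplot2::geom_line(data = truth_long, colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~solute, scales = "free_y") +
    ggplot2::labs(
      x = "dwell time (min)",
      y = "dialysate concentration (mM; g/L for proteins)",
      title = object$config$dwell_id
    )
}

#' Plot a transport-parameter report
#'
#' Per-solute MTAC and clearance of one analyzed dwell as a dot plot; for
#' diffusive transport the clearance sits below the MTAC, which this view
#' makes immediately visible.
#'
#' @param object An `"spa_result"` from [analyze_spa()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spa_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$solutes, c("mtac", "clearance"),
                              names_to = "parameter", values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$solute, y = .data$value,
                                     colour = .data$parameter)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = NULL, y = "mL/min", colour = NULL,
                  title = object$dwell_id)
}

#' Plot a uremic episode trajectory
#'
#' @param object A `"spa_uremia_course"` from [simulate_uremia_course()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spa_uremia_course <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "baseline"), linetype = 2) +
    ggplot2::labs(
      x = "day since nephrotoxin administration",
      y = sprintf("plasma %s (mM)", attr(object, "solute"))
    )
}

#' Stratified summary dot-range plot
#'
#' Mean +/- SD of each parameter by peritonitis group, the graphical
#' counterpart of the stratified summary table.
#'
#' @param summaries Output of [stratify_results()].
#' @param parameters Optional subset of parameter names to show.
#' @return A ggplot.
#' @export
plot_stratified <- function(summaries, parameters = NULL) {
  d <- summaries[summaries$group != "all" & summaries$n > 0, ]
  if (!is.null(parameters)) d <- d[d$parameter %in% parameters, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - dplyr::coalesce(.data$sd, 0),
      ymax = .data$mean + dplyr::coalesce(.data$sd, 0)
    )) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± SD")
}
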