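#' Classify peritonitis from effluent diagnostics
#'
#' Applies the two-of-three case definition used for PD effluent: (1) a
#' positive microbial culture, (2) cloudy effluent, (3) an elevated effluent
#' leukocyte count (> 0.1 x 10^9/L), the latter only interpretable after a
#' dwell of at least 2 h.
#'
#' Unknown criteria are handled with three-valued logic rather than being
#' defaulted to negative: a dwell is `peritonitis` when at least two criteria
#' are definitely met, `no_peritonitis` when at most one criterion could
#' possibly be met, and `indeterminate` when unknowns leave the two-of-three
#' threshold undecidable in both directions. A leukocyte count measured after
#' a dwell shorter than 120 minutes is treated as unobserved.
#'
#' @param culture_positive Logical (or `NA` for unknown): positive effluent
#'   culture. May also be a data frame holding all four arguments as columns,
#'   in which case a tibble with an added `classification` column is returned.
#' @param cloudy_effluent Logical or `NA`: cloudy effluent.
#' @param leukocyte_count Effluent leukocytes in 10^9 cells/L, or `NA`.
#' @param dwell_duration Dwell duration in minutes (default 240).
#'
#' @return A factor with levels `peritonitis`, `no_peritonitis`,
#'   `indeterminate` (vectorized over the inputs), or the augmented tibble for
#'   data-frame input.
#' @examples
#' classify_peritonitis(TRUE, TRUE, 0.05, 240)   # 2 of 3: peritonitis
#' classify_peritonitis(FALSE, FALSE, 0.5, 240)  # only 1 of 3: no_peritonitis
#' classify_peritonitis(TRUE, NA, 0.5, 90)       # leukocytes void: indeterminate
#' @export
classify_peritonitis <- function(culture_positive, cloudy_effluent = NA,
                                 leukocyte_count = NA_real_, dwell_duration = 240) {
  if (is.data.frame(culture_positive)) {
    d <- culture_positive
    cls <- classify_peritonitis(
      d$culture_positive, d$cloudy_effluent, d$leukocyte_count,
      d$dwell_duration %||% 240
    )
    return(dplyr::mutate(as_tibble(d), classification = cls))
  }
  if (any(leukocyte_count < 0, na.rm = TRUE)) {
    stop_spakit("Negative leukocyte count.", "spakit_error_input")
  }
  n <- max(length(culture_positive), length(cloudy_effluent),
           length(leukocyte_count), length(dwell_duration))
  culture_positive <- rep_len(as.logical(culture_positive), n)
  cloudy_effluent <- rep_len(as.logical(cloudy_effluent), n)
  leukocyte_count <- rep_len(as.numeric(leukocyte_count), n)
  dwell_duration <- rep_len(as.numeric(dwell_duration), n)

  leuk_criterion <- ifelse(
    is.na(leukocyte_count) | dwell_duration < 120,
    NA, leukocyte_count > 0.1
  )
  crit <- cbind(culture_positive, cloudy_effluent, leuk_criterion)
  n_met <- rowSums(crit, na.rm = TRUE)
  n_unknown <- rowSums(is.na(crit))
  out <- ifelse(n_met >= 2, "peritonitis",
                ifelse(n_met + n_unknown < 2, "no_peritonitis", "indeterminate"))
  factor(out, levels = c("peritonitis", "no_peritonitis", "indeterminate"))
}

#' Classify a batch of dwells from their attached diagnostics
#'
#' @param dwells A list of [spa_dwell()] objects carrying `diagnostics`.
#' @return A factor of classifications, one per dwell; dwells without
#'   diagnostics are `indeterminate`.
#' @export
classify_dwells <- function(dwells) {
  if (inherits(dwells, "spa_dwell")) dwells <- list(dwells)
  cls <- purrr::map_chr(dwells, function(d) {
    if (is.null(d$diagnostics)) return("indeterminate")
    as.character(classify_peritonitis(
      d$diagnostics$culture_positive, d$diagnostics$cloudy_effluent,
      d$diagnostics$leukocyte_count, d$duration
    ))
  })
  factor(cls, levels = c("peritonitis", "no_peritonitis", "indeterminate"))
}
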