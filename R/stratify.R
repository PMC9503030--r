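#' Stratified descriptive summary of SPA results
#'
#' Summarizes every transport parameter of a batch of dwells for the whole
#' cohort and separately for dwells without and with peritonitis, in the
#' dual-display convention of transport tables: both mean +/- SD and
#' median (IQR) are always emitted, with the per-group n counting the
#' non-missing values. Which display a report prints is a presentation
#' choice, not computed here.
#'
#' @param results A list of [analyze_spa()] results, or a wide data frame as
#'   produced by [spa_results_table()] (one row per dwell, numeric parameter
#'   columns).
#' @param classification Per-dwell classification, typically from
#'   [classify_peritonitis()] / [classify_dwells()]. May be omitted when
#'   `results` is a data frame that already has a `classification` column.
#'   `indeterminate` dwells contribute to the `all` group only.
#' @param quantile_type Quantile algorithm for the IQR (default type 7,
#'   linear interpolation).
#'
#' @return A tibble with columns `parameter`, `group`
#'   (`all` / `no_peritonitis` / `peritonitis`), `n`, `mean`, `sd`, `median`,
#'   `iqr`, and `flag` (`"sd_undefined"` when a group holds a single value).
#' @examples
#' sims <- simulate_batch(scenario_preset("low_transporter"), n = 3, seed = 42)
#' res <- analyze_spa(purrr::map(sims, "observed"))
#' stratify_results(res, classify_dwells(purrr::map(sims, "observed")))
#' @export
stratify_results <- function(results, classification = NULL, quantile_type = 7) {
  if (is.data.frame(results)) {
    wide <- as_tibble(results)
    if (is.null(classification) && "classification" %in% names(wide)) {
      classification <- wide$classification
    }
  } else {
    if (inherits(results, "spa_result")) results <- list(results)
    if (length(results) == 0) {
      stop_spakit("No results to summarize.", "spakit_error_input")
    }
    wide <- spa_results_table(results)
  }
  if (nrow(wide) == 0) stop_spakit("No results to summarize.", "spakit_error_input")
  if (is.null(classification)) classification <- rep(NA_character_, nrow(wide))
  classification <- as.character(classification)
  if (length(classification) != nrow(wide)) {
    stop_spakit("`classification` must have one entry per dwell.", "spakit_error_input")
  }

  drop_cols <- c("dwell_id", "animal_id", "classification", "bsa",
                 "rv_pre", "rv_post")
  params <- names(wide)[vapply(wide, is.numeric, logical(1))]
  params <- setdiff(params, drop_cols)

  summarize_group <- function(rows, group) {
    purrr::map_dfr(params, function(p) {
      v <- wide[[p]][rows]
      v <- v[!is.na(v)]
      n <- length(v)
      tibble(
        parameter = p,
        group = group,
        n = n,
        mean = if (n) mean(v) else NA_real_,
        sd = if (n >= 2) sd(v) else NA_real_,
        median = if (n) median(v) else NA_real_,
        iqr = if (n) IQR(v, type = quantile_type) else NA_real_,
        flag = if (n == 1) "sd_undefined" else NA_character_
      )
    })
  }

  dplyr::bind_rows(
    summarize_group(rep(TRUE, nrow(wide)), "all"),
    summarize_group(!is.na(classification) & classification == "no_peritonitis",
                    "no_peritonitis"),
    summarize_group(!is.na(classification) & classification == "peritonitis",
                    "peritonitis")
  )
}
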