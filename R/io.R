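# Long (tidy) sample-table schema shared by the reader, the writer and the
# simulator: one measurement per row.
#   dwell_id, animal_id, compartment, variable, time_min, value, unit
# Compartments: dialysate | plasma | effluent_diagnostics | dwell (scalars).
# Units are declared per row and converted at ingest; internal units are
# fixed (min, mL, mM, g/L, 10^9 cells/L, kg).

sample_table_columns <- c("dwell_id", "animal_id", "compartment", "variable",
                          "time_min", "value", "unit")

protein_solutes <- c("albumin", "total_protein")
dwell_volume_vars <- c("instilled_volume", "drain_volume_end",
                       "sample_volume_total", "flush_volume")
dwell_protein_vars <- c("albumin_overnight_effluent", "albumin_flush")

# conversion factor to the internal unit for one (variable, unit) pair
unit_factor <- function(variable, compartment, unit) {
  tab <- if (compartment %in% c("dialysate", "plasma")) {
    if (variable %in% protein_solutes) {
      c("g/L" = 1, "g/dL" = 10, "mg/mL" = 1)
    } else {
      c("mM" = 1, "mmol/L" = 1, "umol/L" = 1e-3, "uM" = 1e-3)
    }
  } else if (variable %in% dwell_volume_vars) {
    c("mL" = 1, "L" = 1000)
  } else if (variable %in% dwell_protein_vars) {
    c("g/L" = 1, "g/dL" = 10)
  } else if (variable == "duration") {
    c("min" = 1, "h" = 60)
  } else if (variable == "body_weight") {
    c("kg" = 1)
  } else if (variable == "leukocyte_count") {
    c("1e9/L" = 1, "10^9/L" = 1)
  } else if (variable %in% c("culture_positive", "cloudy_effluent")) {
    return(if (unit %in% c("bool", "")) 1 else NA_real_)
  } else {
    return(NA_real_)
  }
  unname(tab[unit])
}

#' Read dwell sample tables from delimited text
#'
#' Parses a long-format sample table (comma- or tab-separated, header row)
#' with columns `dwell_id`, `animal_id`, `compartment`
#' (`dialysate` / `plasma` / `effluent_diagnostics` / `dwell`), `variable`
#' (solute name, diagnostic field or dwell-level scalar), `time_min`,
#' `value`, `unit`, converts every value to the internal units (min, mL, mM,
#' g/L) and assembles one [spa_dwell()] per `dwell_id`, in order of first
#' appearance. Partial dwells load fine; whatever is missing surfaces as
#' flags when the dwell is analyzed.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @return A named list of [spa_dwell()] objects.
#' @details Malformed input is rejected with the offending line numbers:
#'   missing mandatory columns, duplicate `(dwell_id, compartment, variable,
#'   time_min)` keys, unparseable numeric values, unknown variables or units.
#' @export
read_dwell_tables <- function(path) {
  if (!file.exists(path)) {
    stop_spakit(sprintf("File not found: %s", path), "spakit_error_io")
  }
  delim <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  raw <- suppressWarnings(readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      dwell_id = readr::col_character(),
      animal_id = readr::col_character(),
      compartment = readr::col_character(),
      variable = readr::col_character(),
      time_min = readr::col_double(),
      value = readr::col_double(),
      unit = readr::col_character()
    )
  ))
  missing_cols <- setdiff(sample_table_columns, names(raw))
  if (length(missing_cols)) {
    stop_spakit(paste0("Missing mandatory column(s): ",
                       paste(missing_cols, collapse = ", ")), "spakit_error_io")
  }
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    stop_spakit(
      paste0("Unparseable values at line(s) ",
             paste(unique(probs$row + 1), collapse = ", "), " of ", path),
      "spakit_error_io"
    )
  }
  raw$unit[is.na(raw$unit)] <- ""
  key <- paste(raw$dwell_id, raw$compartment, raw$variable,
               ifelse(is.na(raw$time_min), "", raw$time_min))
  dup <- duplicated(key)
  if (any(dup)) {
    stop_spakit(
      paste0("Duplicate (dwell, compartment, variable, time) key at line(s) ",
             paste(which(dup) + 1, collapse = ", "), " of ", path),
      "spakit_error_io"
    )
  }
  factors <- unname(mapply(unit_factor, raw$variable, raw$compartment, raw$unit))
  if (any(is.na(factors))) {
    bad <- which(is.na(factors))
    stop_spakit(
      paste0("Unknown variable/unit combination at line(s) ",
             paste(bad + 1, collapse = ", "), " of ", path, " (e.g. variable '",
             raw$variable[bad[1]], "', unit '", raw$unit[bad[1]], "')"),
      "spakit_error_io"
    )
  }
  raw$value <- raw$value * factors

  ids <- unique(raw$dwell_id)
  dwells <- lapply(ids, function(id) {
    rows <- raw[raw$dwell_id == id, ]
    meta <- rows[rows$compartment == "dwell", ]
    getm <- function(v) {
      hit <- meta$variable == v
      if (!any(hit)) NA_real_ else meta$value[which(hit)[1]]
    }
    diag_rows <- rows[rows$compartment == "effluent_diagnostics", ]
    getd <- function(v) {
      hit <- diag_rows$variable == v
      if (!any(hit)) NA_real_ else diag_rows$value[which(hit)[1]]
    }
    diagnostics <- if (nrow(diag_rows)) {
      list(
        culture_positive = if (is.na(getd("culture_positive"))) NA else getd("culture_positive") > 0,
        cloudy_effluent = if (is.na(getd("cloudy_effluent"))) NA else getd("cloudy_effluent") > 0,
        leukocyte_count = getd("leukocyte_count")
      )
    } else {
      NULL
    }
    dialysate <- rows[rows$compartment == "dialysate",
                      c("variable", "time_min", "value")]
    names(dialysate) <- c("solute", "time_min", "conc")
    dialysate <- dplyr::arrange(dialysate, .data$solute, .data$time_min)
    plasma <- rows[rows$compartment == "plasma",
                   c("variable", "time_min", "value")]
    names(plasma) <- c("solute", "time_min", "conc")
    spa_dwell(
      dialysate = dialysate,
      plasma = plasma,
      instilled_volume = getm("instilled_volume"),
      drain_volume_end = getm("drain_volume_end"),
      sample_volume_total = if (is.na(getm("sample_volume_total"))) 0 else getm("sample_volume_total"),
      duration = if (is.na(getm("duration"))) 240 else getm("duration"),
      albumin_overnight_effluent = getm("albumin_overnight_effluent"),
      albumin_flush = getm("albumin_flush"),
      flush_volume = getm("flush_volume"),
      body_weight = getm("body_weight"),
      diagnostics = diagnostics,
      dwell_id = id,
      animal_id = rows$animal_id[1]
    )
  })
  names(dwells) <- ids
  dwells
}

#' Write dwells to the long sample-table format
#'
#' Inverse of [read_dwell_tables()]: serializes a list of [spa_dwell()]
#' objects to one delimited file in the long schema, in internal units.
#'
#' @param dwells A list of [spa_dwell()] objects (or a single one).
#' @param path Output `.csv` (or `.tsv`) path.
#' @return `path`, invisibly.
#' @export
write_dwell_tables <- function(dwells, path) {
  if (inherits(dwells, "spa_dwell")) dwells <- list(dwells)
  rows <- purrr::map_dfr(dwells, function(d) {
    conc_unit <- function(s) ifelse(s %in% protein_solutes, "g/L", "mM")
    meta_vals <- c(
      instilled_volume = d$instilled_volume,
      drain_volume_end = d$drain_volume_end,
      sample_volume_total = d$sample_volume_total,
      duration = d$duration,
      albumin_overnight_effluent = d$albumin_overnight_effluent,
      albumin_flush = d$albumin_flush,
      flush_volume = d$flush_volume,
      body_weight = d$body_weight
    )
    meta_units <- c("mL", "mL", "mL", "min", "g/L", "g/L", "mL", "kg")
    out <- dplyr::bind_rows(
      tibble(compartment = "dialysate", variable = d$dialysate$solute,
             time_min = d$dialysate$time_min, value = d$dialysate$conc,
             unit = conc_unit(d$dialysate$solute)),
      tibble(compartment = "plasma", variable = d$plasma$solute,
             time_min = d$plasma$time_min, value = d$plasma$conc,
             unit = conc_unit(d$plasma$solute)),
      tibble(compartment = "dwell", variable = names(meta_vals),
             time_min = NA_real_, value = unname(meta_vals), unit = meta_units)
    )
    if (!is.null(d$diagnostics)) {
      out <- dplyr::bind_rows(out, tibble(
        compartment = "effluent_diagnostics",
        variable = c("culture_positive", "cloudy_effluent", "leukocyte_count"),
        time_min = NA_real_,
        value = c(as.numeric(d$diagnostics$culture_positive),
                  as.numeric(d$diagnostics$cloudy_effluent),
                  d$diagnostics$leukocyte_count),
        unit = c("bool", "bool", "1e9/L")
      ))
    }
    dplyr::mutate(out,
                  dwell_id = d$dwell_id, animal_id = d$animal_id,
                  .before = 1)
  })
  rows <- rows[!is.na(rows$value), ]
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

serialize_result <- function(r, classification = NA_character_) {
  list(
    dwell_id = r$dwell_id, animal_id = r$animal_id,
    classification = classification,
    rv_pre = r$rv_pre, rv_post = r$rv_post, ufv_net = r$ufv_net, bsa = r$bsa,
    dp_urea_4h = r$dp_urea_4h, dp_creatinine_4h = r$dp_creatinine_4h,
    dd0_glucose_4h = r$dd0_glucose_4h,
    solutes = r$solutes,
    flags = as.list(r$flags)
  )
}

#' Write a run's results and summaries to disk
#'
#' Writes a machine-readable `results.json` (every result with its flags and
#' classification, the analysis options echo, the package version and the
#' seed — enough to re-run the computation exactly) and, when `summaries` is
#' given, a `summary.csv` in the stratified parameter-by-group layout.
#' Normalized parameter rows appear in the summary only when a body weight
#' made normalization possible.
#'
#' @param results A list of [analyze_spa()] results (may be empty).
#' @param summaries Optional tibble from [stratify_results()].
#' @param path Output directory (created if needed).
#' @param classification Optional per-dwell classification stored with each
#'   result.
#' @param seed Seed recorded in the file, if the run was seeded.
#' @return The paths written, invisibly.
#' @export
write_results <- function(results, summaries = NULL, path,
                          classification = NULL, seed = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (inherits(results, "spa_result")) results <- list(results)
  if (is.null(classification)) classification <- rep(NA_character_, length(results))
  classification <- as.character(classification)
  payload <- list(
    package = "spakit",
    version = as.character(packageVersion("spakit")),
    seed = seed,
    options = if (length(results)) unclass(results[[1]]$options) else unclass(spa_options()),
    n_results = length(results),
    results = purrr::map2(results, classification, serialize_result)
  )
  written <- character(0)
  results_path <- file.path(path, "results.json")
  jsonlite::write_json(payload, results_path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  written <- results_path
  if (!is.null(summaries)) {
    keep <- summaries$parameter[summaries$group == "all" & summaries$n > 0]
    summary_path <- file.path(path, "summary.csv")
    readr::write_csv(summaries[summaries$parameter %in% keep, ], summary_path,
                     progress = FALSE)
    written <- c(written, summary_path)
  }
  invisible(written)
}

#' Read back a results file
#'
#' @param path The `results.json` written by [write_results()], or the
#'   directory containing it.
#' @return A list with `results` (a list of `spa_result` objects),
#'   `classification` (factor) and `meta` (package version, seed, options).
#' @export
read_results <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "results.json")
  if (!file.exists(path)) {
    stop_spakit(sprintf("Results file not found: %s", path), "spakit_error_io")
  }
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  opts <- payload$options
  opts$mtac_solutes <- unlist(opts$mtac_solutes)
  class(opts) <- "spa_options"
  n <- payload$n_results %||% 0
  results <- list()
  classification <- character(0)
  if (n > 0) {
    results <- purrr::map(seq_len(n), function(i) {
      r <- if (is.data.frame(payload$results)) {
        as.list(payload$results[i, ])
      } else {
        payload$results[[i]]
      }
      num <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x)
      sol <- r$solutes
      if (is.list(sol) && !is.data.frame(sol)) sol <- sol[[1]]
      structure(
        list(
          dwell_id = r$dwell_id %||% NA_character_,
          animal_id = r$animal_id %||% NA_character_,
          rv_pre = num(r$rv_pre), rv_post = num(r$rv_post),
          ufv_net = num(r$ufv_net), bsa = num(r$bsa),
          dp_urea_4h = num(r$dp_urea_4h),
          dp_creatinine_4h = num(r$dp_creatinine_4h),
          dd0_glucose_4h = num(r$dd0_glucose_4h),
          solutes = as_tibble(sol),
          flags = as.character(unlist(r$flags)),
          options = opts
        ),
        class = "spa_result"
      )
    })
    classification <- purrr::map_chr(seq_len(n), function(i) {
      r <- if (is.data.frame(payload$results)) payload$results[i, ] else payload$results[[i]]
      cls <- r$classification
      if (is.null(cls) || length(cls) == 0 || is.na(cls)) NA_character_ else as.character(cls)
    })
  }
  list(
    results = results,
    classification = factor(classification,
                            levels = c("peritonitis", "no_peritonitis", "indeterminate")),
    meta = list(package = payload$package, version = payload$version,
                seed = payload$seed, options = opts)
  )
}
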