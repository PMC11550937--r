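#' Read plate-reader OD600 exports
#'
#' Reads wide (one `time_h` column, one column per well) or long (`well`,
#' `time_h`, `od600`) plate-reader CSVs and attaches well metadata from a
#' well map. Time columns named `time_h`, `time_min` or `time_s` are
#' converted to hours; comma decimal separators (common in European
#' instrument exports) are normalized on read.
#'
#' @param path CSV file path.
#' @param layout `"auto"` (detect from header), `"wide"` or `"long"`.
#' @param well_map A data frame or CSV path with columns `well`,
#'   `isolate_id`, `phage_id` (empty/`none` = control), `moi`, `replicate`.
#' @return A long tibble of growth curves (`well_id`, `isolate_id`,
#'   `phage_id`, `moi`, `replicate`, `time_h`, `od600`) ready for
#'   [analyze_killing_assay()].
#' @export
read_plate_reader <- function(path, layout = c("auto", "wide", "long"),
                              well_map) {
  layout <- match.arg(layout)
  raw <- read_csv_normalized(path)
  nm <- names(raw)
  time_col <- intersect(c("time_h", "time_min", "time_s"), nm)
  if (length(time_col) != 1) abort("expected exactly one time_h/time_min/time_s column")
  if (layout == "auto") {
    layout <- if (all(c("well", "od600") %in% nm)) "long" else "wide"
  }

  long <- if (layout == "wide") {
    tidyr::pivot_longer(raw, -dplyr::all_of(time_col),
                        names_to = "well", values_to = "od600")
  } else {
    if (!all(c("well", "od600") %in% nm)) {
      abort("long layout needs columns well, od600")
    }
    raw
  }
  long$time_h <- switch(time_col,
                        time_h = long[[time_col]],
                        time_min = long[[time_col]] / 60,
                        time_s = long[[time_col]] / 3600)
  if (time_col != "time_h") long[[time_col]] <- NULL

  if (is.character(well_map)) well_map <- read_csv_normalized(well_map)
  need <- c("well", "isolate_id", "phage_id", "moi", "replicate")
  miss <- setdiff(need, names(well_map))
  if (length(miss)) abort(paste("well map missing column(s):",
                                paste(miss, collapse = ", ")))
  orphan <- setdiff(unique(long$well), well_map$well)
  if (length(orphan)) {
    abort(paste("well(s) absent from well map:", paste(orphan, collapse = ", ")))
  }
  well_map$phage_id[well_map$phage_id %in% c("", "none", "NA")] <- NA_character_

  out <- long |>
    dplyr::inner_join(well_map, by = "well") |>
    dplyr::rename(well_id = "well") |>
    dplyr::mutate(moi = suppressWarnings(as.numeric(.data$moi)),
                  replicate = as.integer(.data$replicate)) |>
    dplyr::select("well_id", "isolate_id", "phage_id", "moi", "replicate",
                  "time_h", "od600") |>
    dplyr::arrange(.data$well_id, .data$time_h)
  bad_time <- out |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$time_h, strictly = TRUE),
                     .groups = "drop")
  if (!all(bad_time$ok)) abort("non-monotone time column")
  if (anyNA(out$od600)) warn("rows with missing OD flagged (NA od600)")
  out
}

# read_csv with comma-decimal fallback: columns that came in as character but
# look like decimal-comma numbers are converted.
read_csv_normalized <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  dplyr::mutate(raw, dplyr::across(
    dplyr::where(is.character),
    function(x) {
      y <- sub(",", ".", x, fixed = TRUE)
      num <- suppressWarnings(as.numeric(y))
      if (all(!is.na(num) | is.na(x) | x == "")) num else x
    }
  ))
}

#' Read a dilution-series count sheet
#' @param path CSV with columns `sample_id`, `analyte`, `dilution_exponent`,
#'   `plated_volume_ml`, `count`.
#' @return A validated tibble.
#' @export
read_count_sheet <- function(path) {
  sheet <- read_csv_normalized(path)
  check_count_sheet(sheet)
  dplyr::mutate(sheet,
                dilution_exponent = as.integer(.data$dilution_exponent),
                count = as.integer(.data$count))
}

#' Read spot/plaque host-range records
#' @param path CSV with columns `phage_id`, `isolate_id`, `replicate`,
#'   `outcome`, `plaque_count`, `dilution_exponent`, `plated_volume_ml`.
#' @return A tibble of spot records.
#' @export
read_spot_sheet <- function(path) {
  spots <- read_csv_normalized(path)
  need <- c("phage_id", "isolate_id", "replicate", "outcome")
  miss <- setdiff(need, names(spots))
  if (length(miss)) abort(paste("spot sheet missing column(s):",
                                paste(miss, collapse = ", ")))
  spots
}

#' Read explant endpoint records
#' @param path CSV with columns `uterus_id`, `group`, `phage_id`,
#'   `cfu_per_ml`, `pfu_per_ml`, `ldh_6h`, `ldh_24h`.
#' @return A tibble of endpoint records.
#' @export
read_endpoint_sheet <- function(path) {
  ep <- read_csv_normalized(path)
  if (!"group" %in% names(ep)) abort("endpoint sheet missing 'group' column")
  ep
}

#' Write a set of result tables with run metadata
#'
#' Writes each named table as `<name>.csv` under `output_dir` plus a
#' `run_metadata.json` capturing the config, seed and package version.
#' Re-running with identical inputs and seed reproduces byte-identical CSVs.
#'
#' @param results Named list of data frames.
#' @param output_dir Directory (created if needed).
#' @param config Optional named list recorded in the metadata JSON.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, output_dir, config = list()) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) abort(paste("cannot create", output_dir))
  stopifnot(is.list(results), !is.null(names(results)))
  paths <- purrr::imap_chr(results, function(tab, name) {
    p <- file.path(output_dir, paste0(name, ".csv"))
    tab <- dplyr::mutate(tibble::as_tibble(tab),
                         dplyr::across(dplyr::where(is.list),
                                       ~ purrr::map_chr(.x, paste, collapse = ";")))
    readr::write_csv(tab, p, progress = FALSE)
    p
  })
  meta <- file.path(output_dir, "run_metadata.json")
  jsonlite::write_json(
    list(package = "phagekit",
         version = as.character(utils::packageVersion("phagekit")),
         config = config,
         files = basename(unname(paths))),
    meta, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(c(paths, metadata = meta))
}
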