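#' Efficiency of plating
#'
#' EOP is the ratio of a phage's titer on a test bacterial isolate to its
#' titer on the original host; 1 means equal plating efficiency. An EOP of 0
#' (no plaques) is graded as no sensitivity downstream.
#'
#' @param test_titer Titer on the test isolate (PFU/mL), `>= 0`.
#' @param reference_titer Titer on the original host (PFU/mL), `> 0`.
#' @return `test_titer / reference_titer`, vectorized.
#' @examples
#' compute_eop(5e6, 1e8)  # 0.05
#' @export
compute_eop <- function(test_titer, reference_titer) {
  if (any(reference_titer <= 0)) abort("reference_titer must be > 0")
  if (any(test_titer < 0)) abort("test_titer must be >= 0")
  test_titer / reference_titer
}

#' The six host-range sensitivity grades, in increasing order
#' @return Character vector of grade levels.
#' @export
eop_grades <- function() {
  c("no_sensitivity", "moderately_low", "low", "moderate", "high", "ultimate")
}

#' Grade efficiency of plating into sensitivity categories
#'
#' Applies the six-level sensitivity partition: no sensitivity (no plaque
#' formation, EOP 0 or outcome `"none"`), moderately low (opaque plaque
#' only), low (EOP < 0.1), moderate (0.1 <= EOP <= 1), high (1 < EOP <= 10),
#' ultimate (EOP > 10). Bounds are applied exactly as written: EOP 0.1 and 1
#' are moderate, EOP 10 is high.
#'
#' @param eop Numeric EOP values (`NA` allowed where `outcome` decides).
#' @param outcome Optional character vector; `"none"` and `"opaque"` override
#'   `eop` with no_sensitivity / moderately_low. `"count"` (or `NA`) defers
#'   to `eop`.
#' @return Factor with levels [eop_grades()].
#' @examples
#' grade_eop(c(0, 0.05, 0.1, 1, 1.01, 10, 10.1))
#' grade_eop(NA, outcome = "opaque")
#' @export
grade_eop <- function(eop, outcome = NULL) {
  n <- max(length(eop), length(outcome))
  eop <- rep_len(eop, n)
  if (!is.null(outcome)) outcome <- rep_len(as.character(outcome), n)
  if (any(!is.na(eop) & eop < 0)) abort("EOP must be >= 0")

  g <- rep(NA_character_, n)
  num <- !is.na(eop)
  g[num & eop == 0] <- "no_sensitivity"
  g[num & eop > 0 & eop < 0.1] <- "low"
  g[num & eop >= 0.1 & eop <= 1] <- "moderate"
  g[num & eop > 1 & eop <= 10] <- "high"
  g[num & eop > 10] <- "ultimate"
  if (!is.null(outcome)) {
    g[outcome %in% "none"] <- "no_sensitivity"
    g[outcome %in% "opaque"] <- "moderately_low"
  }
  if (anyNA(g)) abort("ungradable record: need a numeric EOP or a none/opaque outcome")
  factor(g, levels = eop_grades())
}

#' Aggregate replicate spot records into one EOP record per cell
#'
#' For each (phage, isolate) cell: replicates with plaque counts are turned
#' into per-replicate titers, averaged at the titer level, and divided by the
#' phage's reference titer to give one EOP (ratio of mean titers, not mean of
#' ratios). Replicates with outcome `"none"` count as zero in that mean.
#' Cells whose replicates are all `"none"` grade as no_sensitivity; cells
#' with opaque outcomes and no countable plaques grade as moderately_low
#' (opaque replicates alongside counts are excluded from the titer mean).
#'
#' @param spots Spot-record tibble: `phage_id`, `isolate_id`, `replicate`,
#'   `outcome`, `plaque_count`, `dilution_exponent`, `plated_volume_ml`.
#' @param reference_titers Named numeric vector (names = phage ids) or a data
#'   frame with columns `phage_id`, `reference_titer`.
#' @return A tibble with one row per cell: `phage_id`, `isolate_id`, `eop`,
#'   `grade`, `n_replicates`.
#' @examples
#' spots <- tibble::tibble(
#'   phage_id = "p1", isolate_id = "i1", replicate = 1:3,
#'   outcome = "count", plaque_count = c(100L, 90L, 110L),
#'   dilution_exponent = -6L, plated_volume_ml = 0.1
#' )
#' eop_from_spots(spots, c(p1 = 1e9))  # EOP 1 -> moderate
#' @export
eop_from_spots <- function(spots, reference_titers) {
  need <- c("phage_id", "isolate_id", "replicate", "outcome", "plaque_count",
            "dilution_exponent", "plated_volume_ml")
  miss <- setdiff(need, names(spots))
  if (length(miss)) abort(paste("spot records missing column(s):",
                                paste(miss, collapse = ", ")))
  if (nrow(spots) == 0) abort("empty spot records")
  ref <- as_reference_lookup(reference_titers)
  unknown <- setdiff(unique(spots$phage_id), names(ref))
  if (length(unknown)) {
    abort(paste("no reference titer for phage(s):",
                paste(unknown, collapse = ", ")))
  }

  spots |>
    dplyr::group_by(.data$phage_id, .data$isolate_id) |>
    dplyr::group_modify(function(d, key) {
      ref_t <- ref[[key$phage_id]]
      out <- d$outcome
      if (all(out == "none")) {
        return(tibble::tibble(eop = NA_real_,
                              grade = factor("no_sensitivity", eop_grades()),
                              n_replicates = nrow(d)))
      }
      if (!any(out == "count")) {
        return(tibble::tibble(eop = NA_real_,
                              grade = factor("moderately_low", eop_grades()),
                              n_replicates = nrow(d)))
      }
      use <- out != "opaque"
      titers <- ifelse(
        d$outcome[use] == "count",
        d$plaque_count[use] /
          (10^d$dilution_exponent[use] * d$plated_volume_ml[use]),
        0
      )
      eop <- mean(titers) / ref_t
      tibble::tibble(eop = eop, grade = grade_eop(eop),
                     n_replicates = nrow(d))
    }) |>
    dplyr::ungroup()
}

as_reference_lookup <- function(reference_titers) {
  if (is.data.frame(reference_titers)) {
    stopifnot(all(c("phage_id", "reference_titer") %in% names(reference_titers)))
    ref <- setNames(as.list(reference_titers$reference_titer),
                    reference_titers$phage_id)
  } else {
    ref <- as.list(reference_titers)
  }
  if (any(unlist(ref) <= 0)) abort("reference titers must be > 0")
  ref
}

#' Summarize a host-range matrix per phage
#'
#' Counts susceptible isolates per phage. Every grade except no_sensitivity
#' counts as susceptible, including moderately_low (opaque) cells — an opaque
#' plaque is evidence of lytic activity.
#'
#' @param records EOP-record tibble from [eop_from_spots()] (columns
#'   `phage_id`, `isolate_id`, `grade`).
#' @return A tibble per phage: `n_susceptible`, `n_total`, `pct_susceptible`
#'   (percentage, 1 decimal).
#' @examples
#' recs <- tibble::tibble(
#'   phage_id = "p1", isolate_id = paste0("i", 1:37),
#'   grade = factor(rep(c("moderate", "no_sensitivity"), c(30, 7)),
#'                  eop_grades())
#' )
#' summarize_host_range(recs)  # 30/37 = 81.1%
#' @export
summarize_host_range <- function(records) {
  stopifnot(all(c("phage_id", "isolate_id", "grade") %in% names(records)))
  records |>
    dplyr::group_by(.data$phage_id) |>
    dplyr::summarise(
      n_susceptible = sum(.data$grade != "no_sensitivity"),
      n_total = dplyr::n(),
      pct_susceptible = round(100 * .data$n_susceptible / .data$n_total, 1),
      .groups = "drop"
    )
}

#' Pivot EOP records to a phage x isolate matrix
#'
#' @param records EOP-record tibble.
#' @param value `"eop"` (numeric, NA where no plaques) or `"grade"`.
#' @return A tibble with one row per phage and one column per isolate.
#' @export
eop_matrix <- function(records, value = c("eop", "grade")) {
  value <- match.arg(value)
  records |>
    dplyr::mutate(grade = as.character(.data$grade)) |>
    dplyr::select("phage_id", "isolate_id", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "isolate_id",
                       values_from = dplyr::all_of(value))
}
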