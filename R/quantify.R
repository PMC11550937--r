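#' Flag countable plates in a dilution-series count sheet
#'
#' Marks each plate as countable when its count lies inside the countable
#' range (inclusive on both ends). The default 10-300 colonies/plaques is
#' standard plate-count practice and is configurable.
#'
#' @param counts A count-sheet data frame with columns `sample_id`,
#'   `analyte`, `dilution_exponent`, `plated_volume_ml`, `count`.
#' @param countable_range Length-2 numeric `c(min, max)`, `min < max`.
#' @return The input as a tibble with a logical `countable` column.
#' @examples
#' sheet <- simulate_dilution_series(1e6, -2:-6, seed = 1)
#' flag_countable(sheet)
#' @export
flag_countable <- function(counts, countable_range = c(10, 300)) {
  check_count_sheet(counts)
  if (length(countable_range) != 2 || countable_range[1] >= countable_range[2]) {
    abort("countable_range must be c(min, max) with min < max")
  }
  dplyr::mutate(
    tibble::as_tibble(counts),
    countable = .data$count >= countable_range[1] &
      .data$count <= countable_range[2]
  )
}

check_count_sheet <- function(counts) {
  need <- c("sample_id", "analyte", "dilution_exponent", "plated_volume_ml",
            "count")
  miss <- setdiff(need, names(counts))
  if (length(miss)) abort(paste("count sheet missing column(s):",
                                paste(miss, collapse = ", ")))
  if (nrow(counts) == 0) abort("empty count sheet")
  if (any(counts$count < 0)) abort("counts must be >= 0")
  if (any(counts$plated_volume_ml <= 0)) abort("plated_volume_ml must be > 0")
  if (any(counts$dilution_exponent > 0)) {
    abort("dilution exponents must be <= 0 (10^exponent applied to the stock)")
  }
  invisible(counts)
}

#' Estimate titers from dilution-series plate counts
#'
#' Weighted two-dilution plate-count estimator. For each sample, countable
#' plates at (up to) two adjacent decimal dilution levels enter the ratio
#' \deqn{\frac{\sum \text{counts, all countable plates}}
#'            {n_{lowest} \cdot 1 + n_{2nd\,lowest} \cdot 0.1}}
#' where "lowest dilution" is the least dilute countable level; the ratio is
#' the count per plated aliquot of that level and is rescaled to per-mL of
#' undiluted sample by dividing by `10^e_low * plated_volume`. With a single
#' countable level the formula degenerates to that level's mean count. When
#' more than two consecutive levels are countable, extras are dropped from
#' the less-dilute end (noted). A series whose plates are all zero is
#' reported censored at the limit of detection
#' `1 / (10^e_min * plated_volume)` for its least dilute level `e_min`.
#'
#' @param counts A count sheet (see [flag_countable()]); multiple samples and
#'   analytes are grouped automatically.
#' @param countable_range Passed to [flag_countable()]; ignored if the sheet
#'   already carries a `countable` column.
#' @return A tibble with one row per (`sample_id`, `analyte`):
#'   `concentration` (per mL), `log10_concentration`, `limit_of_detection`,
#'   `censored`, `n_countable_dilutions`, `n_plates_used`, `note`.
#' @examples
#' sheet <- tibble::tibble(
#'   sample_id = "s1", analyte = "CFU",
#'   dilution_exponent = c(-3, -3, -4, -4),
#'   plated_volume_ml = 0.1, count = c(98L, 102L, 11L, 9L)
#' )
#' estimate_titer(sheet)  # 220 / 2.2 = 100 -> 1e6 per mL
#' @export
estimate_titer <- function(counts, countable_range = c(10, 300)) {
  if (!"countable" %in% names(counts)) {
    counts <- flag_countable(counts, countable_range)
  } else {
    check_count_sheet(counts)
  }
  counts |>
    dplyr::group_by(.data$sample_id, .data$analyte) |>
    dplyr::group_modify(function(d, key) {
      est <- titer_core(d$count, d$dilution_exponent, d$plated_volume_ml,
                        d$countable)
      tibble::as_tibble(est)
    }) |>
    dplyr::ungroup()
}

# Core single-series estimator; lean base R so exhaustive enumerations of
# small series stay cheap.
titer_core <- function(count, exponent, volume, countable) {
  if (length(unique(volume)) != 1) {
    stop("mixed plated volumes within one series", call. = FALSE)
  }
  vol <- volume[1]
  note <- NA_character_

  if (!any(countable)) {
    if (all(count == 0)) {
      e_min <- max(exponent)   # least dilute plated level
      lod <- 1 / (10^e_min * vol)
      return(list(concentration = NA_real_, log10_concentration = NA_real_,
                  limit_of_detection = lod, censored = TRUE,
                  n_countable_dilutions = 0L, n_plates_used = 0L,
                  note = sprintf("no growth; < %.3g per mL", lod)))
    }
    # No countable plate but counts present: fall back to the level whose
    # mean count is closest (log scale) to the countable-range midpoint.
    means <- vapply(split(count, exponent), mean, numeric(1))
    means[means == 0] <- NA
    pick <- names(means)[which.min(abs(log10(means) - log10(sqrt(10 * 300))))]
    keep <- exponent == as.integer(pick)
    count <- count[keep]; exponent <- exponent[keep]
    countable <- rep(TRUE, length(count))
    note <- "no countable plates; nearest level used"
  }

  cc <- count[countable]
  ce <- exponent[countable]
  levels_c <- sort(unique(ce), decreasing = TRUE)  # least dilute first
  if (length(levels_c) > 1 && any(diff(levels_c) != -1)) {
    stop("countable plates at non-adjacent dilution levels", call. = FALSE)
  }
  if (length(levels_c) > 2) {
    drop_lv <- levels_c[seq_len(length(levels_c) - 2)]
    keep <- !(ce %in% drop_lv)
    cc <- cc[keep]; ce <- ce[keep]
    levels_c <- levels_c[-seq_len(length(levels_c) - 2)]
    note <- paste(c(note[!is.na(note)],
                    sprintf("dropped less-dilute countable level(s) %s",
                            paste(drop_lv, collapse = ","))), collapse = "; ")
  }
  e_low <- levels_c[1]
  n1 <- sum(ce == e_low)
  n2 <- sum(ce == e_low - 1L)
  per_plating <- sum(cc) / (n1 * 1 + n2 * 0.1)
  conc <- per_plating / (10^e_low * vol)
  e_min <- max(exponent)
  list(concentration = conc,
       log10_concentration = if (conc > 0) log10(conc) else NA_real_,
       limit_of_detection = 1 / (10^e_min * vol),
       censored = FALSE,
       n_countable_dilutions = length(levels_c),
       n_plates_used = length(cc),
       note = note)
}

#' Multiplicity of infection from dosed phage and present bacteria
#'
#' Input MOI: phage particles added per bacterial cell present at
#' inoculation. No adsorption correction is applied (this is not the
#' effective MOI).
#'
#' @param pfu_added Phage dose (PFU), `>= 0`.
#' @param cfu_present Bacteria present (CFU), `> 0`.
#' @return `pfu_added / cfu_present`, vectorized.
#' @examples
#' compute_moi(1e7, 1e7)  # 1
#' compute_moi(1e8, 1e7)  # 10
#' @export
compute_moi <- function(pfu_added, cfu_present) {
  if (any(cfu_present <= 0)) abort("cfu_present must be > 0")
  if (any(pfu_added < 0)) abort("pfu_added must be >= 0")
  pfu_added / cfu_present
}

#' Approximate cell density of a McFarland turbidity standard
#'
#' Table lookup of the conventional approximate bacterial densities of
#' McFarland standards; the table is configurable.
#'
#' @param standard McFarland value(s), e.g. `0.5` or `3`.
#' @param table Named numeric vector mapping standard to cells/mL.
#' @return Approximate density in cells/mL.
#' @examples
#' mcfarland_to_density(0.5)  # 1.5e8
#' mcfarland_to_density(3)    # 9e8
#' @export
mcfarland_to_density <- function(standard,
                                 table = c(`0.5` = 1.5e8, `1` = 3e8,
                                           `2` = 6e8, `3` = 9e8,
                                           `4` = 1.2e9, `5` = 1.5e9)) {
  key <- format(as.numeric(standard), trim = TRUE, drop0trailing = TRUE)
  missing <- !key %in% names(table)
  if (any(missing)) {
    abort(sprintf("McFarland standard %s not in table",
                  paste(key[missing], collapse = ", ")))
  }
  unname(table[key])
}
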