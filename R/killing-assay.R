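#' Area under an OD600 growth curve
#'
#' Trapezoidal integral of OD600 over the recorded window, optionally after
#' baseline correction. Negative post-baseline values are clipped at 0 before
#' integration.
#'
#' @param time_h Observation times (hours), strictly increasing, length >= 2.
#' @param od600 OD600 readings, same length; `NA` signals a read failure and
#'   errors.
#' @param baseline `"raw"` (integrate as reported, the default),
#'   `"subtract_t0"` (subtract the first reading), or `"subtract_blank"`
#'   (subtract `blank`).
#' @param blank Blank OD for `baseline = "subtract_blank"`.
#' @param window Optional `c(t_start, t_end)` in hours restricting
#'   integration to grid points inside the window.
#' @return AUC in OD·h.
#' @examples
#' compute_auc(0:24, rep(0.3, 25))      # 7.2
#' compute_auc(c(0, 24), c(0, 1))       # 12
#' @export
compute_auc <- function(time_h, od600,
                        baseline = c("raw", "subtract_t0", "subtract_blank"),
                        blank = 0, window = NULL) {
  baseline <- match.arg(baseline)
  if (length(time_h) != length(od600)) abort("time and OD lengths differ")
  if (anyNA(od600)) abort("NA OD values (read failure)")
  if (!is.null(window)) {
    keep <- time_h >= window[1] & time_h <= window[2]
    time_h <- time_h[keep]; od600 <- od600[keep]
  }
  if (length(time_h) < 2) abort("need at least 2 time points")
  if (any(diff(time_h) <= 0)) abort("time must be strictly increasing")
  y <- switch(baseline,
              raw = od600,
              subtract_t0 = od600 - od600[1],
              subtract_blank = od600 - blank)
  y <- pmax(y, 0)
  sum(diff(time_h) * (head(y, -1) + y[-1]) / 2)
}

#' Virulence index from treatment and control AUCs
#'
#' The normalized AUC reduction `V = 100 * (1 - auc_treatment/auc_control)`:
#' 0 means no effect, 100 complete growth suppression. Values are not
#' clamped; a treatment that grew more than its control gives V < 0 and is
#' worth inspecting.
#'
#' @param auc_treatment,auc_control AUCs in OD·h; `auc_control > 0`.
#' @return Virulence index on the 0-100 scale, vectorized.
#' @examples
#' virulence_index(0.478, 1)  # 52.2
#' @export
virulence_index <- function(auc_treatment, auc_control) {
  if (any(auc_control <= 0)) abort("auc_control must be > 0")
  if (any(auc_treatment < 0)) abort("auc_treatment must be >= 0")
  100 * (1 - auc_treatment / auc_control)
}

#' Analyze a planktonic killing assay
#'
#' Turns a long table of OD600 growth curves into per-condition killing
#' metrics: replicate AUCs, mean treatment and control AUCs, a virulence
#' index per (phage, MOI) computed from the mean AUCs, and a
#' treatment-versus-control comparison. Controls are wells with
#' `phage_id = NA`, matched to treatments on `isolate_id`. Each comparison
#' runs a Shapiro-Wilk normality check on both AUC sets at `alpha`; when both
#' pass, Welch's unpaired t-test is used, otherwise the Wilcoxon rank-sum
#' test.
#'
#' @param curves Long tibble of growth curves: `well_id`, `isolate_id`,
#'   `phage_id` (`NA` = control), `moi`, `replicate`, `time_h`, `od600`.
#' @param baseline,blank,window Passed to [compute_auc()].
#' @param alpha Significance level for the normality gate and the comparison.
#' @return An object of class `killing_assay`; see [tidy.killing_assay()]
#'   for the per-condition table and [glance.killing_assay()] for a
#'   one-row summary.
#' @examples
#' assay <- simulate_killing_assay(n_replicates = 3, seed = 1)
#' fit <- analyze_killing_assay(assay$curves)
#' tidy(fit)
#' @export
analyze_killing_assay <- function(curves, baseline = "raw", blank = 0,
                                  window = NULL, alpha = 0.05) {
  need <- c("well_id", "isolate_id", "phage_id", "moi", "replicate",
            "time_h", "od600")
  miss <- setdiff(need, names(curves))
  if (length(miss)) abort(paste("curves missing column(s):",
                                paste(miss, collapse = ", ")))

  aucs <- curves |>
    dplyr::group_by(.data$well_id, .data$isolate_id, .data$phage_id,
                    .data$moi, .data$replicate) |>
    dplyr::summarise(
      auc = compute_auc(.data$time_h, .data$od600, baseline = baseline,
                        blank = blank, window = window),
      grid = paste(.data$time_h, collapse = ","),
      .groups = "drop"
    )

  treatments <- dplyr::filter(aucs, !is.na(.data$phage_id))
  controls <- dplyr::filter(aucs, is.na(.data$phage_id))
  if (nrow(treatments) == 0) abort("no treatment wells (non-NA phage_id)")

  results <- treatments |>
    dplyr::group_by(.data$isolate_id, .data$phage_id, .data$moi) |>
    dplyr::group_modify(function(d, key) {
      ctrl <- dplyr::filter(controls, .data$isolate_id == key$isolate_id)
      if (nrow(ctrl) == 0) {
        abort(sprintf("no control wells for isolate %s", key$isolate_id))
      }
      if (length(unique(c(d$grid, ctrl$grid))) != 1) {
        abort("unequal time grids within a comparison (plate misalignment?)")
      }
      auc_t <- mean(d$auc)
      auc_c <- mean(ctrl$auc)
      v <- virulence_index(auc_t, auc_c)
      cmp <- compare_auc_sets(d$auc, ctrl$auc, alpha)
      tibble::tibble(
        n_replicates = nrow(d),
        auc_treatment = auc_t,
        auc_control = auc_c,
        virulence_index = v,
        v_flagged = v < 0 | v > 100,
        test_name = cmp$test_name,
        statistic = cmp$statistic,
        p_value = cmp$p_value,
        significant = cmp$significant,
        replicate_aucs = list(d$auc),
        replicate_v = list(virulence_index(d$auc, auc_c))
      )
    }) |>
    dplyr::ungroup()

  structure(
    list(results = results, aucs = dplyr::select(aucs, -"grid"),
         curves = tibble::as_tibble(curves),
         config = list(baseline = baseline, blank = blank, window = window,
                       alpha = alpha)),
    class = "killing_assay"
  )
}

# Normality-gated two-sample comparison of replicate AUC sets.
compare_auc_sets <- function(x, y, alpha) {
  if (length(x) < 2 || length(y) < 2) {
    return(list(test_name = "none (need >= 2 replicates)",
                statistic = NA_real_, p_value = NA_real_,
                significant = NA))
  }
  # identical constant sets: no variation, nothing to test
  if (stats::sd(c(x, y)) == 0) {
    return(list(test_name = "degenerate (no variation)", statistic = 0,
                p_value = 1, significant = FALSE))
  }
  normal <- function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(FALSE)
    shapiro.test(v)$p.value > alpha
  }
  if (normal(x) && normal(y)) {
    tt <- t.test(x, y)  # Welch
    list(test_name = "welch_t", statistic = unname(tt$statistic),
         p_value = tt$p.value, significant = tt$p.value < alpha)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    list(test_name = "wilcoxon_rank_sum", statistic = unname(wt$statistic),
         p_value = wt$p.value, significant = wt$p.value < alpha)
  }
}

#' @describeIn analyze_killing_assay Per-condition results, one row per
#'   (isolate, phage, MOI): AUCs, virulence index, comparison test and
#'   p-value.
#' @param x A `killing_assay` object.
#' @param ... Unused.
#' @method tidy killing_assay
#' @export
tidy.killing_assay <- function(x, ...) {
  dplyr::select(x$results, -"replicate_aucs", -"replicate_v")
}

#' @describeIn analyze_killing_assay One-row overview: numbers of conditions
#'   and wells, virulence-index range, how many comparisons were significant.
#' @method glance killing_assay
#' @export
glance.killing_assay <- function(x, ...) {
  tibble::tibble(
    n_conditions = nrow(x$results),
    n_wells = dplyr::n_distinct(x$curves$well_id),
    v_min = min(x$results$virulence_index),
    v_max = max(x$results$virulence_index),
    n_significant = sum(x$results$significant, na.rm = TRUE),
    alpha = x$config$alpha
  )
}

#' @export
print.killing_assay <- function(x, ...) {
  cat("<killing_assay>\n")
  print(tidy(x))
  invisible(x)
}
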