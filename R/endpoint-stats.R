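#' Log10-transform concentrations with censoring policy
#'
#' Transforms concentrations to log10 for downstream comparisons. Zero (or
#' below-detection) values cannot be logged directly; the policy decides:
#' `"half_lod"` substitutes half the limit of detection (default, preserves
#' sample size), `"lod"` substitutes the limit itself, `"drop"` excludes the
#' value (returned as `NA`).
#'
#' @param concentration Non-negative concentrations (per mL).
#' @param lod Limit of detection (per mL); scalar or per-value. Required for
#'   the `half_lod` and `lod` policies whenever zeros are present.
#' @param policy Censoring policy.
#' @return Numeric vector of log10 values, `NA` where dropped. The logical
#'   attribute `"censored"` marks substituted/dropped positions.
#' @examples
#' log10_transform(c(1e7, 0), lod = 100)          # 7, log10(50)
#' log10_transform(0, lod = 100, policy = "drop") # NA
#' @export
log10_transform <- function(concentration, lod = NULL,
                            policy = c("half_lod", "lod", "drop")) {
  policy <- match.arg(policy)
  if (any(concentration < 0, na.rm = TRUE)) abort("concentrations must be >= 0")
  cens <- is.na(concentration) | concentration == 0
  if (any(cens) && policy != "drop") {
    if (is.null(lod)) abort("lod required for half_lod/lod policies")
    lod <- rep_len(lod, length(concentration))
  }
  out <- ifelse(cens, NA_real_, log10(pmax(concentration, .Machine$double.xmin)))
  if (any(cens)) {
    out[cens] <- switch(policy,
                        half_lod = log10(lod[cens] / 2),
                        lod = log10(lod[cens]),
                        drop = NA_real_)
  }
  attr(out, "censored") <- cens
  out
}

#' Normality-gated two-sample location test
#'
#' Runs a Shapiro-Wilk normality check on each sample at `alpha`; when both
#' pass, an unpaired Welch t-test compares locations, otherwise the Wilcoxon
#' rank-sum test does. The path taken is reported.
#'
#' @param x,y Numeric samples, each `n >= 3` (normality is not assessable
#'   below that).
#' @param alpha Significance level.
#' @return One-row tibble: `test_name`, `statistic`, `p_value`, `alpha`,
#'   `significant`, `shapiro_p_x`, `shapiro_p_y`.
#' @examples
#' two_sample_test(rnorm(10), rnorm(10, 3))
#' @export
two_sample_test <- function(x, y, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3) abort("each sample needs n >= 3")
  sw <- function(v) {
    if (stats::sd(v) == 0) return(0)   # constant sample: clearly non-normal
    shapiro.test(v)$p.value
  }
  px <- sw(x); py <- sw(y)
  if (identical(sort(x), sort(y))) {
    res <- list(test_name = "welch_t", statistic = 0, p_value = 1)
  } else if (px > alpha && py > alpha) {
    tt <- t.test(x, y)
    res <- list(test_name = "welch_t", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    res <- list(test_name = "wilcoxon_rank_sum",
                statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  tibble::tibble(
    test_name = res$test_name, statistic = res$statistic,
    p_value = res$p_value, alpha = alpha,
    significant = res$p_value < alpha,
    shapiro_p_x = px, shapiro_p_y = py
  )
}

#' Dunn's rank-based multiple comparisons
#'
#' Pairwise post-hoc z-tests on the pooled mid-ranks of k groups, with the
#' standard tie correction
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
#'          \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' where \eqn{\bar R} are mean pooled ranks and the tie sum runs over tied
#' groups of size t. Two-sided p-values are adjusted over the tested pairs
#' (Bonferroni by default).
#'
#' @param data Data frame in long format.
#' @param value,group Column names (strings) of the response and the
#'   grouping variable.
#' @param p_adjust Adjustment method for [stats::p.adjust()] (`"bonferroni"`,
#'   `"holm"`, `"none"`, ...).
#' @param alpha Significance level applied to adjusted p-values.
#' @return A tibble with one row per pair: `group1`, `group2`,
#'   `mean_rank_1`, `mean_rank_2`, `statistic` (z), `p_value`, `adjusted_p`,
#'   `significant`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b", "c"), each = 5),
#'                 y = c(rnorm(10), rnorm(5, 5)))
#' dunn_test(d, "y", "g")
#' @export
dunn_test <- function(data, value, group, p_adjust = "bonferroni",
                      alpha = 0.05) {
  y <- data[[value]]
  g <- factor(data[[group]])
  if (anyNA(y)) {
    keep <- !is.na(y); y <- y[keep]; g <- droplevels(g[keep])
  }
  n_i <- table(g)
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(n_i == 0)) abort("empty group")

  N <- length(y)
  rk <- rank(y)  # mid-ranks
  mean_ranks <- tapply(rk, g, mean)
  ties <- table(rk)
  tie_sum <- sum(ties^3 - ties)
  var_term <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))

  pairs <- utils::combn(levels(g), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(var_term * (1 / n_i[[a]] + 1 / n_i[[b]]))
    z <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    tibble::tibble(
      group1 = a, group2 = b,
      mean_rank_1 = mean_ranks[[a]], mean_rank_2 = mean_ranks[[b]],
      statistic = z, p_value = 2 * pnorm(-abs(z))
    )
  })
  res$adjusted_p <- pmin(p.adjust(res$p_value, method = p_adjust), 1)
  res$significant <- res$adjusted_p < alpha
  res
}

#' Bin LDH activity into damage categories
#'
#' Lactate-dehydrogenase release is an explant-damage proxy; values are
#' grouped into < 50 U/L, 50-100 U/L and > 100 U/L. Both boundary values (50
#' and 100) fall in the middle bin.
#'
#' @param value LDH activity in U/L, `>= 0`.
#' @return Factor with levels `lt50`, `b50_100`, `gt100`.
#' @examples
#' ldh_bin(c(42, 50, 100, 150))
#' @export
ldh_bin <- function(value) {
  if (any(value < 0, na.rm = TRUE)) abort("LDH values must be >= 0")
  cut(value, breaks = c(-Inf, 50, 100, Inf),
      labels = c("lt50", "b50_100", "gt100"),
      right = TRUE, include.lowest = TRUE) |>
    (\(f) {
      # cut() with right=TRUE puts 50 into lt50; move boundary 50 to middle
      f[!is.na(value) & value == 50] <- "b50_100"
      f
    })()
}

#' Pearson chi-square test on a contingency table
#'
#' Chi-square test of independence on a bins x groups count table, without
#' continuity correction. All-zero rows or columns are removed before testing
#' (flagged), and a warning flag is set when any expected count falls below
#' 5.
#'
#' @param table Matrix (or table) of non-negative integer counts, at least
#'   2 x 2 after removing all-zero margins.
#' @param alpha Significance level.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `alpha`,
#'   `significant`, `min_expected`, `low_expected_warning`,
#'   `df_reduced`.
#' @examples
#' chi_square_contingency(matrix(c(10, 0, 0, 10), 2))  # statistic 20
#' @export
chi_square_contingency <- function(table, alpha = 0.05) {
  m <- as.matrix(table)
  if (any(m < 0)) abort("counts must be >= 0")
  if (sum(m) == 0) abort("all-zero table")
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  reduced <- !all(keep_r) || !all(keep_c)
  m <- m[keep_r, keep_c, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("need at least 2 non-empty rows and 2 non-empty columns")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble::tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    alpha = alpha,
    significant = ct$p.value < alpha,
    min_expected = min(ct$expected),
    low_expected_warning = any(ct$expected < 5),
    df_reduced = reduced
  )
}

#' Summarize explant endpoints per group
#'
#' Per-group mean and SD of a concentration endpoint on the linear and log10
#' scales (censoring handled by [log10_transform()]).
#'
#' @param endpoints Data frame with a `group` column.
#' @param var Name of the concentration column (e.g. `"cfu_per_ml"`).
#' @param lod,policy Passed to [log10_transform()].
#' @return A tibble per group: n, linear mean/sd, log10 mean/sd, number
#'   censored.
#' @export
summarize_endpoints <- function(endpoints, var = "cfu_per_ml", lod = 100,
                                policy = "half_lod") {
  stopifnot("group" %in% names(endpoints), var %in% names(endpoints))
  endpoints |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      x <- d[[var]]
      lx <- log10_transform(x, lod = lod, policy = policy)
      tibble::tibble(
        n = length(x),
        mean = mean(x, na.rm = TRUE),
        sd = stats::sd(x, na.rm = TRUE),
        mean_log10 = mean(lx, na.rm = TRUE),
        sd_log10 = stats::sd(lx, na.rm = TRUE),
        n_censored = sum(attr(lx, "censored"))
      )
    }) |>
    dplyr::ungroup()
}
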