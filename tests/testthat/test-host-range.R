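# EOP computation, grading, replicate aggregation, host-range summaries

test_that("EOP is the titer ratio and is scale invariant", {
  expect_equal(compute_eop(1e8, 1e8), 1)
  expect_equal(compute_eop(5e6, 1e8), 0.05)
  expect_equal(compute_eop(0, 1e8), 0)
  expect_error(compute_eop(1e6, 0), "> 0")
  for (k in c(0.5, 10, 1e3)) {
    expect_equal(compute_eop(k * 5e6, k * 1e8), 0.05)
  }
})

test_that("grading applies the printed partition with exact boundaries", {
  eops <- c(0, 0.05, 0.1, 1.0, 1.01, 10, 10.1)
  want <- c("no_sensitivity", "low", "moderate", "moderate", "high", "high",
            "ultimate")
  expect_equal(as.character(grade_eop(eops)), want)
  expect_equal(as.character(grade_eop(NA, outcome = "opaque")),
               "moderately_low")
  expect_equal(as.character(grade_eop(NA, outcome = "none")),
               "no_sensitivity")
  expect_error(grade_eop(-0.1), ">= 0")
})

test_that("grading is a total deterministic partition of its domain", {
  withr::with_seed(42, {
    eops <- c(10^runif(300, -4, 3), 0, 0.1, 1, 10)
    g <- grade_eop(eops)
    expect_false(anyNA(g))
    expect_identical(g, grade_eop(eops))
    # each value falls in exactly one grade, consistent with its magnitude
    expect_true(all(g[eops > 10] == "ultimate"))
    expect_true(all(g[eops <= 1 & eops >= 0.1] == "moderate"))
  })
})

make_spots <- function(counts = NULL, outcomes = NULL, exponent = -6L) {
  n <- max(length(counts), length(outcomes))
  tibble::tibble(
    phage_id = "p1", isolate_id = "i1", replicate = seq_len(n),
    outcome = if (is.null(outcomes)) rep("count", n) else outcomes,
    plaque_count = if (is.null(counts)) NA_integer_ else as.integer(counts),
    dilution_exponent = exponent, plated_volume_ml = 0.1
  )
}

test_that("replicates are averaged at the titer level before one EOP", {
  # [100, 90, 110] at 10^-6, 0.1 mL -> mean titer 1e9; reference 1e9 -> EOP 1
  rec <- eop_from_spots(make_spots(c(100, 90, 110)), c(p1 = 1e9))
  expect_equal(rec$eop, 1)
  expect_equal(as.character(rec$grade), "moderate")
  expect_equal(rec$n_replicates, 3L)
})

test_that("all-none and all-opaque cells grade categorically", {
  none <- eop_from_spots(make_spots(outcomes = rep("none", 3)), c(p1 = 1e9))
  expect_equal(as.character(none$grade), "no_sensitivity")
  expect_true(is.na(none$eop))
  op <- eop_from_spots(make_spots(outcomes = rep("opaque", 3)), c(p1 = 1e9))
  expect_equal(as.character(op$grade), "moderately_low")
})

test_that("discordant none/count replicates treat none as zero count", {
  spots <- make_spots(c(100, 90, NA))
  spots$outcome <- c("count", "count", "none")
  rec <- eop_from_spots(spots, c(p1 = 1e9))
  # titers 1e9, 0.9e9, 0 -> mean 0.6333e9 -> EOP 0.6333
  expect_equal(rec$eop, mean(c(1e9, 0.9e9, 0)) / 1e9)
})

test_that("host-range summary reports the printed percentages", {
  grades <- function(n_pos, n_tot) {
    factor(rep(c("moderate", "no_sensitivity"), c(n_pos, n_tot - n_pos)),
           eop_grades())
  }
  recs <- dplyr::bind_rows(
    tibble::tibble(phage_id = "broad", isolate_id = paste0("i", 1:37),
                   grade = grades(30, 37)),
    tibble::tibble(phage_id = "second", isolate_id = paste0("i", 1:37),
                   grade = grades(29, 37)),
    tibble::tibble(phage_id = "dud", isolate_id = paste0("i", 1:37),
                   grade = grades(0, 37))
  )
  s <- summarize_host_range(recs)
  expect_equal(s$pct_susceptible[s$phage_id == "broad"], 81.1)
  expect_equal(s$pct_susceptible[s$phage_id == "second"], 78.4)
  expect_equal(s$pct_susceptible[s$phage_id == "dud"], 0)
  expect_true(all(s$n_total == 37))
})

test_that("opaque-only cells count as susceptible in the summary", {
  recs <- tibble::tibble(
    phage_id = "p", isolate_id = c("a", "b"),
    grade = factor(c("moderately_low", "no_sensitivity"), eop_grades())
  )
  expect_equal(summarize_host_range(recs)$n_susceptible, 1)
})

test_that("simulated host range round-trips truth through the pipeline", {
  truth <- default_host_range_truth(seed = 3)
  spots <- simulate_host_range(truth, ref_titer = 1e9, n_replicates = 3,
                               seed = 3)
  recs <- eop_from_spots(spots, setNames(rep(1e9, nrow(truth)),
                                         rownames(truth)))
  expect_equal(nrow(recs), 13 * 37)
  truth_long <- tibble::as_tibble(as.table(truth), .name_repair = ~
                                    c("phage_id", "isolate_id", "true_eop"))
  joined <- dplyr::inner_join(recs, truth_long,
                              by = c("phage_id", "isolate_id"))
  # NA / opaque pattern is recovered exactly
  expect_true(all(is.na(joined$true_eop) ==
                    (joined$grade == "no_sensitivity")))
  expect_true(all((joined$true_eop %in% -1) ==
                    (joined$grade == "moderately_low"), na.rm = TRUE))
  # numeric cells land in the truth's grading bin >= 95% of the time
  num <- joined[!is.na(joined$true_eop) & joined$true_eop != -1, ]
  agree <- as.character(num$grade) == as.character(grade_eop(num$true_eop))
  expect_gte(mean(agree), 0.95)
  # count preservation: per-phage susceptible counts match the truth
  s <- summarize_host_range(recs)
  expect_equal(s$n_susceptible[match(rownames(truth), s$phage_id)],
               unname(rowSums(!is.na(truth))))
})

test_that("heatmap is a complete grid with the six-grade legend", {
  truth <- default_host_range_truth(seed = 1)
  spots <- simulate_host_range(truth, ref_titer = 1e9, seed = 1)
  recs <- eop_from_spots(spots, setNames(rep(1e9, 13), rownames(truth)))
  p <- plot_host_range(recs)
  built <- ggplot2::ggplot_build(p)
  expect_equal(nrow(built$data[[1]]), 13 * 37)
  expect_s3_class(p, "ggplot")
  expect_error(plot_host_range(recs[0, ]), "empty")
  path <- withr::local_tempfile(fileext = ".pdf")
  render_heatmap(recs, path)
  expect_true(file.exists(path) && file.size(path) > 0)
})

test_that("wide EOP matrix has one row per phage, one column per isolate", {
  truth <- default_host_range_truth(seed = 1)
  spots <- simulate_host_range(truth, ref_titer = 1e9, seed = 1)
  recs <- eop_from_spots(spots, setNames(rep(1e9, 13), rownames(truth)))
  m <- eop_matrix(recs, "grade")
  expect_equal(dim(m), c(13, 38))  # phage_id + 37 isolates
})
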