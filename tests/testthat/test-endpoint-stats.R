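# Explant endpoint statistics: transforms, test battery, LDH binning

test_that("log10 transform applies the censoring policy", {
  expect_equal(log10_transform(1e7), 7, ignore_attr = TRUE)
  expect_equal(as.numeric(log10_transform(0, lod = 100)), log10(50))
  expect_equal(as.numeric(log10_transform(0, lod = 100, policy = "lod")), 2)
  dropped <- log10_transform(c(10, 0), policy = "drop")
  expect_true(is.na(dropped[2]))
  expect_equal(attr(dropped, "censored"), c(FALSE, TRUE))
  expect_error(log10_transform(-1), ">= 0")
  expect_error(log10_transform(0), "lod required")
})

test_that("two-sample test separates distant groups and not identical ones", {
  same <- two_sample_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_false(same$significant)
  expect_gte(same$p_value, 0.99)
  withr::with_seed(1, {
    far <- two_sample_test(rnorm(30), rnorm(30, 3))
    expect_true(far$significant)
    expect_equal(far$test_name, "welch_t")
  })
  expect_error(two_sample_test(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("non-normal samples are routed to the rank-sum path", {
  withr::with_seed(2, {
    x <- exp(rnorm(50, 0, 2))   # heavily skewed
    y <- exp(rnorm(50, 0, 2))
    res <- two_sample_test(x, y)
    expect_equal(res$test_name, "wilcoxon_rank_sum")
  })
})

test_that("two-sample battery holds its type-I error near alpha", {
  withr::with_seed(11, {
    rej <- vapply(1:1000, function(i) {
      two_sample_test(rnorm(10), rnorm(10))$significant
    }, logical(1))
    expect_gte(mean(rej), 0.03)
    expect_lte(mean(rej), 0.07)
  })
})

test_that("Dunn test finds only the separated group", {
  withr::with_seed(7, {
    d <- data.frame(
      g = rep(c("a", "b", "c"), each = 15),
      y = c(rnorm(15, 0), rnorm(15, 0), rnorm(15, 5))
    )
    res <- dunn_test(d, "y", "g")
    expect_equal(nrow(res), 3)
    hit_c <- res$group1 == "c" | res$group2 == "c"
    expect_true(all(res$significant[hit_c]))
    expect_false(any(res$significant[!hit_c]))
  })
})

test_that("Dunn on identical groups rejects nothing", {
  d <- data.frame(g = rep(c("a", "b", "c"), each = 6), y = rep(1:6, 3))
  res <- dunn_test(d, "y", "g")
  expect_false(any(res$significant))
  expect_true(all(abs(res$statistic) < 1e-10))
})

test_that("Dunn z agrees with the longhand rank computation for k = 2", {
  withr::with_seed(5, {
    for (i in 1:10) {
      x <- rnorm(8)
      y <- rnorm(10, 0.5)
      # inject ties to exercise the tie correction
      y[1:2] <- x[1:2]
      d <- data.frame(g = rep(c("x", "y"), c(8, 10)), y = c(x, y))
      res <- dunn_test(d, "y", "g")
      expect_equal(res$statistic, oracle_dunn_z(x, y))
      expect_true(sign(res$statistic) ==
                    sign(res$mean_rank_1 - res$mean_rank_2) ||
                    res$statistic == 0)
    }
  })
})

test_that("Dunn variance term matches kruskal.test's tie correction", {
  withr::with_seed(8, {
    y <- sample(rep(1:6, 4))
    g <- rep(c("a", "b", "c"), each = 8)
    res <- dunn_test(data.frame(g = g, y = y), "y", "g")
    # reconstruct H from pairwise machinery: compare against kruskal.test
    kt <- kruskal.test(y, factor(g))
    N <- length(y)
    rk <- rank(y)
    mr <- tapply(rk, g, mean)
    ties <- table(rk)
    denom <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
    h <- sum(table(g) * (mr - (N + 1) / 2)^2) / (N * (N + 1) / 12) /
      (1 - sum(ties^3 - ties) / (N^3 - N))
    expect_equal(unname(kt$statistic), h)
    # and the package's z uses the same tie-corrected variance
    z_ab <- (mr[["a"]] - mr[["b"]]) / sqrt(denom * (1 / 8 + 1 / 8))
    expect_equal(res$statistic[res$group1 == "a" & res$group2 == "b"], z_ab)
  })
})

test_that("adjusted Dunn p-values are monotone above raw p-values", {
  withr::with_seed(13, {
    d <- data.frame(g = rep(letters[1:4], each = 8), y = rnorm(32))
    res <- dunn_test(d, "y", "g", p_adjust = "bonferroni")
    expect_true(all(res$adjusted_p >= res$p_value - 1e-12))
    expect_true(all(res$adjusted_p <= 1))
  })
})

test_that("Dunn per-comparison type-I error is calibrated under the null", {
  withr::with_seed(21, {
    rej <- unlist(lapply(1:1000, function(i) {
      d <- data.frame(g = rep(c("a", "b", "c"), each = 10), y = rnorm(30))
      dunn_test(d, "y", "g", p_adjust = "none")$p_value < 0.05
    }))
    expect_gte(mean(rej), 0.03)
    expect_lte(mean(rej), 0.07)
  })
})

test_that("LDH binning is a partition with boundaries in the middle bin", {
  expect_equal(as.character(ldh_bin(c(0, 42, 49.9))), rep("lt50", 3))
  expect_equal(as.character(ldh_bin(c(50, 75, 100))), rep("b50_100", 3))
  expect_equal(as.character(ldh_bin(c(100.1, 150, 1e4))), rep("gt100", 3))
  expect_error(ldh_bin(-1), ">= 0")
  withr::with_seed(3, {
    v <- runif(500, 0, 200)
    expect_false(anyNA(ldh_bin(v)))  # every value lands in exactly one bin
  })
})

test_that("chi-square matches hand computation and flags degeneracies", {
  res <- chi_square_contingency(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  same <- chi_square_contingency(matrix(c(5, 5, 5, 5), 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(chi_square_contingency(matrix(0, 2, 2)), "all-zero")
  zcol <- chi_square_contingency(matrix(c(4, 6, 0, 0, 5, 5), 2))
  expect_true(zcol$df_reduced)
  expect_true(res$low_expected_warning == (res$min_expected < 5))
})

test_that("chi-square is invariant to row and column permutation", {
  m <- matrix(c(12, 3, 7, 8, 2, 9), 2)
  base <- chi_square_contingency(m)$statistic
  expect_equal(chi_square_contingency(m[2:1, ])$statistic, base)
  expect_equal(chi_square_contingency(m[, c(3, 1, 2)])$statistic, base)
})

test_that("endpoint summaries report both scales and censoring", {
  ep <- tibble::tibble(
    group = rep(c("positive_control", "moi1"), each = 4),
    cfu_per_ml = c(1e7, 2e7, 1.5e7, 0, 5e6, 8e6, 1e7, 2e6)
  )
  s <- summarize_endpoints(ep, "cfu_per_ml", lod = 100)
  expect_equal(nrow(s), 2)
  expect_equal(s$n_censored[s$group == "positive_control"], 1)
  expect_equal(s$mean[s$group == "moi1"], mean(c(5e6, 8e6, 1e7, 2e6)))
})
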