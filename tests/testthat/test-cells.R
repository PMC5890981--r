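test_that("analysis config validates the exclusion rule", {
  cfg <- analysis_config()
  expect_equal(cfg$n_cells, 100L)
  expect_equal(retained_cells_range <- range(cagdrift:::retained_cells(cfg)),
               c(6L, 95L))
  expect_length(cagdrift:::retained_cells(cfg), 90L)
  expect_error(analysis_config(n_cells = 10, n_exclude_each_end = 5), "n_cells")
})

test_that("uniform combined distribution gives one support value per cell", {
  u <- tibble::tibble(dcag = 1:100, weight = rep(0.01, 100))
  cfg <- analysis_config(n_cells = 100, n_exclude_each_end = 0)
  edges <- combined_quantile_edges(u, u, cfg)
  expect_equal(edges, as.numeric(1:99))
  cells <- findInterval(u$dcag, edges, left.open = TRUE) + 1
  expect_equal(as.vector(table(cells)), rep(1L, 100))
  # with 5 excluded per end the retained cells are 6..95 (90 cells)
  cfg5 <- analysis_config(100, 5)
  expect_equal(cagdrift:::retained_cells(cfg5), 6:95)
})

test_that("quantile edges match brute-force weighted-CDF inversion", {
  withr::with_seed(51, {
    for (i in 1:200) {
      a <- random_distribution()
      b <- random_distribution()
      n_cells <- sample(c(4, 10, 50, 100), 1)
      cfg <- analysis_config(n_cells, 0)
      edges <- combined_quantile_edges(a, b, cfg)
      comb <- rbind(cbind(a$dcag, a$weight / 2), cbind(b$dcag, b$weight / 2))
      for (j in seq_along(edges)) {
        expect_equal(edges[j],
                     oracle_weighted_quantile(comb[, 1], comb[, 2], j / n_cells),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("degenerate single-support combined distributions are refused", {
  pt <- tibble::tibble(dcag = 3, weight = 1)
  expect_error(combined_quantile_edges(pt, pt), "single support")
})

test_that("edge-based cell means match brute-force masking", {
  # point mass lands in exactly one cell
  edges <- c(1, 2, 3)
  pm <- tibble::tibble(dcag = 0, weight = 1)
  m <- cell_means_from_edges(pm, edges)
  expect_equal(m, c(0, NA, NA, NA))
  # two equal-weight points in one cell average; others stay missing
  two <- tibble::tibble(dcag = c(2.2, 4), weight = c(0.5, 0.5))
  m2 <- cell_means_from_edges(two, c(0, 2, 5, 7))
  expect_equal(m2, c(NA, NA, 3.1, NA, NA))
  m3 <- cell_means_from_edges(tibble::tibble(dcag = c(2, 4), weight = c(0.5, 0.5)),
                              c(0, 1, 5, 7))
  expect_equal(m3, c(NA, NA, 3.0, NA, NA))
  withr::with_seed(52, {
    for (i in 1:200) {
      d <- random_distribution()
      edges <- sort(runif(sample(3:30, 1), -25, 45))
      expect_equal(cell_means_from_edges(d, edges),
                   oracle_cell_means_edges(d$dcag, d$weight, edges),
                   tolerance = 1e-9)
    }
  })
})

test_that("equal-mass slice means match the interval-overlap oracle", {
  withr::with_seed(53, {
    for (i in 1:200) {
      d <- random_distribution()
      n_cells <- sample(c(2, 7, 50, 100), 1)
      got <- quantile_cell_means(d, n_cells)
      expect_equal(got, oracle_slice_means(d$dcag, d$weight, n_cells),
                   tolerance = 1e-9)
    }
  })
})

test_that("slice means conserve the distribution mean and shift additively", {
  withr::with_seed(54, {
    for (i in 1:50) {
      d <- random_distribution()
      m <- quantile_cell_means(d, 100)
      expect_equal(mean(m), sum(d$dcag * d$weight) / sum(d$weight),
                   tolerance = 1e-9)
      shifted <- dplyr::mutate(d, dcag = dcag + 3.7)
      expect_equal(quantile_cell_means(shifted, 100), m + 3.7, tolerance = 1e-9)
      # slice means are non-decreasing (quantile ordering)
      expect_true(all(diff(m) > -1e-9))
    }
  })
})

test_that("variance gate decisions agree with an independent F-test", {
  expect_equal(variance_gate(c(1, 2, 3), c(4, 5, 6))$test, "Student")
  withr::with_seed(55, {
    x <- rnorm(10, 0, 10)
    y <- rnorm(10, 0, 1)
    expect_equal(variance_gate(x, y)$test, "Welch")
    for (i in 1:1000) {
      n1 <- sample(3:12, 1)
      n2 <- sample(3:12, 1)
      a <- rnorm(n1, 0, sample(c(1, 5), 1))
      b <- rnorm(n2, 0, 1)
      got <- variance_gate(a, b)
      orc <- oracle_f_test(a, b)
      expect_equal(got$f_statistic, orc$f, tolerance = 1e-9)
      expect_equal(got$p_value, orc$p, tolerance = 1e-9)
      expect_equal(got$test, if (orc$p < 0.05) "Welch" else "Student")
    }
  })
  expect_error(variance_gate(1, c(1, 2)), "at least 2")
  expect_error(variance_gate(c(1, 1), c(1, 1)), "zero combined variance")
})

test_that("a hand-worked cell comparison reproduces the Student t-test", {
  cfg <- analysis_config(n_cells = 2, n_exclude_each_end = 0)
  u <- matrix(c(1, 2, 3), nrow = 3, ncol = 2)
  t_ <- matrix(c(2, 3, 4), nrow = 3, ncol = 2)
  res <- tidy(compare_cells(u, t_, cfg))[1, ]
  expect_equal(res$diff, -1)
  expect_equal(res$test, "Student")
  expect_equal(res$se_diff, sqrt(2 / 3), tolerance = 1e-4)  # 0.8165
  expect_equal(res$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.2879, tolerance = 1e-3)
  expect_false(res$significant)
})

test_that("identical groups give zero difference and p = 1", {
  cfg <- analysis_config(n_cells = 2, n_exclude_each_end = 0)
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3)
  res <- tidy(compare_cells(m, m, cfg))
  expect_equal(res$diff, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
  # constant identical groups hit the degenerate convention
  k <- matrix(2, nrow = 3, ncol = 2)
  resk <- tidy(compare_cells(k, k, cfg))
  expect_equal(resk$p_value, c(1, 1))
  expect_equal(resk$diff, c(0, 0))
})

test_that("t statistics match brute-force Student/Welch formulas", {
  withr::with_seed(56, {
    for (i in 1:200) {
      n1 <- sample(3:8, 1)
      n2 <- sample(3:8, 1)
      x <- rnorm(n1, 1, sample(c(1, 6), 1))
      y <- rnorm(n2)
      cfg <- analysis_config(n_cells = 2, n_exclude_each_end = 0)
      res <- tidy(compare_cells(cbind(x, x), cbind(y, y), cfg))[1, ]
      orc <- if (res$test == "Welch") oracle_welch_t(x, y) else oracle_student_t(x, y)
      expect_equal(res$statistic, orc$t, tolerance = 1e-9)
      expect_equal(res$df, orc$df, tolerance = 1e-9)
      expect_equal(res$se_diff, orc$se, tolerance = 1e-9)
      expect_equal(res$p_value, orc$p, tolerance = 1e-9)
      gate <- oracle_f_test(x, y)
      expect_equal(res$test, if (gate$p < 0.05) "Welch" else "Student")
    }
  })
})

test_that("cells with fewer than two animals per group are flagged untested", {
  cfg <- analysis_config(n_cells = 2, n_exclude_each_end = 0)
  u <- matrix(c(1, NA, NA, 1, 2, 3), nrow = 3)
  t_ <- matrix(c(4, 5, 6, 4, 5, 6), nrow = 3)
  res <- tidy(compare_cells(u, t_, cfg))
  expect_false(res$tested[1])
  expect_true(res$tested[2])
  expect_true(is.na(res$p_value[1]))
  expect_false(res$significant[1])
})

test_that("one-way ANOVA matches brute-force sums of squares", {
  expect_equal(anova_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$p_value, 1)
  expect_equal(anova_groups(rep(5, 6), rep(c("a", "b"), each = 3))$p_value, 1)
  tiny <- anova_groups(c(0, 0.01, -0.01, 10, 10.01, 9.99),
                       rep(c("a", "b"), each = 3))
  expect_lt(tiny$p_value, 1e-6)
  withr::with_seed(57, {
    for (i in 1:200) {
      k <- sample(2:4, 1)
      n <- sample(3:6, 1)
      vals <- rnorm(k * n, rep(rnorm(k, 0, 2), each = n))
      grp <- rep(letters[1:k], each = n)
      got <- anova_groups(vals, grp)
      orc <- oracle_anova(vals, grp)
      expect_equal(got$f_statistic, orc$f, tolerance = 1e-9)
      expect_equal(got$p_value, orc$p, tolerance = 1e-9)
    }
  })
})

test_that("adding a uniform shift to untreated moves every cell diff by it", {
  withr::with_seed(58, {
    deltas <- dplyr::bind_rows(lapply(1:6, function(a) {
      d <- random_distribution(n_points = 25)
      d$animal <- paste0("an", a)
      d$group <- if (a <= 3) "U" else "T"
      d
    }))
    cfg <- analysis_config(20, 2)
    base <- tidy(compare_groups(deltas, "U", "T", cfg))
    shifted <- deltas |>
      dplyr::mutate(dcag = dcag + ifelse(group == "U", 2.5, 0))
    res <- tidy(compare_groups(shifted, "U", "T", cfg))
    expect_equal(res$diff, base$diff + 2.5, tolerance = 1e-9)
  })
})

test_that("Benjamini-Hochberg correction is applied only when requested", {
  withr::with_seed(59, {
    u <- matrix(rnorm(30), nrow = 3)
    t_ <- matrix(rnorm(30, 2), nrow = 3)
    cfg <- analysis_config(10, 0)
    raw <- tidy(compare_cells(u, t_, cfg))
    adj <- tidy(compare_cells(u, t_, analysis_config(10, 0, p_adjust = "BH")))
    expect_equal(adj$p_value, p.adjust(raw$p_value, "BH"))
  })
})
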