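test_that("signed-rank: a uniform positive shift gives W = 0 and p = 2/2^n", {
  x0 <- c(5, 7, 9, 11, 13, 15, 17, 19)
  res <- wilcoxon_signed_rank(x0, x0 + 3)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 2 / 2^8)
  expect_equal(res$p_method, "exact")
})

test_that("signed-rank: perfectly antisymmetric differences give p = 1", {
  res <- wilcoxon_signed_rank(rep(c(-1, 1), 4))
  expect_equal(res$w_plus, res$n * (res$n + 1) / 4)
  expect_equal(res$p_value, 1)
})

test_that("signed-rank exact p matches brute-force sign enumeration", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, -4))$p_value,
               naive_signed_rank_p(c(1, 2, 3, -4)))
  withr::with_seed(17, {
    for (n in 3:10) {
      for (rep in 1:5) {
        d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # ties likely
        expect_equal(wilcoxon_signed_rank(d)$p_value, naive_signed_rank_p(d),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("signed-rank agrees with the reference implementation on tie-free data", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      n <- sample(6:12, 1)
      x <- rnorm(n); y <- x + rnorm(n, 0.3)
      ours <- wilcoxon_signed_rank(x, y)
      ref <- suppressWarnings(stats::wilcox.test(y, x, paired = TRUE, exact = TRUE))
      expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
    }
    # large-sample normal approximation tracks the reference
    x <- rnorm(40); y <- x + rnorm(40, 0.2)
    ours <- wilcoxon_signed_rank(x, y)
    expect_equal(ours$p_method, "normal_approx")
    ref <- stats::wilcox.test(y, x, paired = TRUE, exact = FALSE, correct = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-6)
  })
})

test_that("signed-rank degenerate and zero-handling conventions", {
  res <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_equal(res$p_value, 1)
  expect_match(res$note, "zero")
  # zeros are discarded before ranking under the default convention
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, 2, -3))$n, 3)
  # Pratt keeps zeros in the ranking, changing the rank sums
  w <- wilcoxon_signed_rank(c(0, 1, -2), zero_method = "wilcoxon")
  p <- wilcoxon_signed_rank(c(0, 1, -2), zero_method = "pratt")
  expect_equal(w$w_plus, 1)
  expect_equal(p$w_plus, 2)
})

test_that("spearman: monotone relations give rho of exactly +/- 1", {
  x <- c(2, 5, 1, 9, 4, 7)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  expect_equal(spearman_cor(x, exp(x))$p_value, 0)
})

test_that("spearman matches the classical closed form on tie-free data", {
  # by hand: rank differences (1,1,1,1,0), so rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_cor(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
  expect_equal(spearman_closed_form(1:5, c(2, 1, 4, 3, 5)), 0.8)
  expect_equal(unname(stats::cor(1:5, c(2, 1, 4, 3, 5), method = "spearman")), 0.8)
  withr::with_seed(29, {
    for (rep in 1:25) {
      n <- sample(5:12, 1)
      x <- rnorm(n); y <- rnorm(n)
      r <- spearman_cor(x, y)
      expect_equal(r$rho, spearman_closed_form(x, y), tolerance = 1e-12)
      # symmetry and invariance under strictly monotone transforms
      expect_equal(spearman_cor(y, x)$rho, r$rho, tolerance = 1e-12)
      expect_equal(spearman_cor(exp(x), atan(y))$rho, r$rho, tolerance = 1e-12)
      # reference implementation cross-check
      expect_equal(r$rho, unname(stats::cor(x, y, method = "spearman")),
                   tolerance = 1e-12)
    }
  })
})

test_that("spearman permutation p is seeded, reproducible, and close to the t approximation", {
  withr::with_seed(37, {
    x <- rnorm(11); y <- 0.4 * x + rnorm(11)
  })
  p1 <- spearman_cor(x, y, p_method = "permutation", n_perm = 99999, seed = 5)
  p2 <- spearman_cor(x, y, p_method = "permutation", n_perm = 99999, seed = 5)
  expect_identical(p1$p_value, p2$p_value)
  pt_ <- spearman_cor(x, y, p_method = "t_approx")
  expect_lt(abs(p1$p_value - pt_$p_value), 0.02)
})

test_that("spearman flags degenerate rank variance", {
  res <- spearman_cor(rep(1, 5), c(2, 1, 4, 3, 5))
  expect_true(is.na(res$rho))
  expect_equal(res$p_method, "degenerate")
})

test_that("results tables: 12 correlation cells, degenerate cohorts, permutation invariance", {
  mk_row <- function(pid, ss, msda, fim, age) {
    tibble::tibble(patient_id = pid, session = ss, n_days = 2, age = age,
                   sex = "female", fim_motor = fim,
                   minutes_lying = 900 + msda, minutes_sitting_standing = 500,
                   minutes_walking = 5 + msda / 10, minutes_gap = 30,
                   msda_total = msda, msda_training = 0.4 * msda,
                   msda_nontraining = 0.6 * msda,
                   hrr_mean_total = 10 + msda / 5, hrr_mean_training = 22,
                   hrr_mean_nontraining = 9, hr_rest = 62)
  }
  withr::with_seed(41, {
    n <- 8
    fim <- sample(20:80, n); age <- sample(40:85, n)
    rows <- list()
    for (i in seq_len(n)) {
      rows[[2 * i - 1]] <- mk_row(sprintf("P%02d", i), "0W", 10 + fim[i] / 10 + rnorm(1), fim[i], age[i])
      rows[[2 * i]] <- mk_row(sprintf("P%02d", i), "4W", 12 + fim[i] / 8 + rnorm(1), fim[i] + 5, age[i])
    }
    cohort <- do.call(rbind, rows)
  })
  b <- build_results_tables(cohort)
  expect_equal(nrow(b$correlations), 12)
  expect_setequal(unique(b$correlations$metric), c("total", "training", "nontraining"))
  expect_equal(nrow(b$comparisons), 9)
  expect_true(all(b$comparisons$n_pairs == 8))

  # shuffling patient row order changes nothing
  b2 <- build_results_tables(cohort[rev(seq_len(nrow(cohort))), ])
  expect_equal(b$correlations$rho, b2$correlations$rho)
  expect_equal(b$comparisons$p_value, b2$comparisons$p_value)

  # a cohort of identical patients: all paired p = 1, all rho flagged
  clones <- do.call(rbind, lapply(1:6, function(i) {
    r <- rbind(mk_row(sprintf("P%02d", i), "0W", 10, 50, 65),
               mk_row(sprintf("P%02d", i), "4W", 10, 50, 65))
    r
  }))
  bc <- build_results_tables(clones)
  expect_true(all(bc$comparisons$p_value == 1))
  expect_true(all(is.na(bc$correlations$rho)))

  # report renders a line per correlation row and comparison row
  rpt <- format_results_report(b)
  expect_true(any(grepl("nontraining", rpt)))
  expect_true(any(grepl("Wilcoxon", rpt)))
})
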