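#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on within-pair differences, implemented from
#' first principles with an exact small-sample p value. Differences of zero
#' are discarded (classic Wilcoxon convention; `zero_method = "pratt"` keeps
#' them in the ranking). Absolute differences are ranked with mid-ranks for
#' ties. The statistic is `W = min(W+, W-)`. For `n <= exact_n_max` the p
#' value is computed by full enumeration of all `2^n` sign assignments
#' (subset-sum doubling, valid under ties); otherwise a normal approximation
#' with continuity and tie correction is used.
#'
#' @param x Admission values, or a vector of paired differences if `y` is
#'   `NULL`.
#' @param y Follow-up values; differences are `y - x`.
#' @param zero_method `"wilcoxon"` (drop zero differences) or `"pratt"`.
#' @param exact_n_max Largest n for which the exact enumeration is used.
#' @param alpha Significance level recorded in the result.
#' @return A `stat_result` list: `method`, `n`, `statistic` (W), `w_plus`,
#'   `p_value`, `p_method`, `alpha`, `note`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 zero_method = c("wilcoxon", "pratt"),
                                 exact_n_max = 15, alpha = 0.05) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(y) - as.numeric(x)
  d <- d[!is.na(d)]
  if (zero_method == "wilcoxon") {
    d_nz <- d[d != 0]
  } else {
    d_nz <- d  # zeros ranked, then removed from both sums (Pratt)
  }
  if (length(d_nz) == 0 || all(d_nz == 0)) {
    return(stat_result("wilcoxon_signed_rank", n = 0, statistic = 0,
                       w_plus = 0, p_value = 1, p_method = "degenerate",
                       alpha = alpha, note = "all differences zero"))
  }
  r <- rank(abs(d_nz))
  if (zero_method == "pratt") {
    keep <- d_nz != 0
    r <- r[keep]; d_nz <- d_nz[keep]
  }
  n <- length(d_nz)
  w_plus <- sum(r[d_nz > 0])
  w_minus <- sum(r[d_nz < 0])
  w <- min(w_plus, w_minus)
  if (n <= exact_n_max) {
    dist <- signed_rank_sums(r)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(dist <= w_plus + eps), mean(dist >= w_plus - eps)))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sig2 <- sum(r^2) / 4  # equals n(n+1)(2n+1)/24 minus the tie correction
    z <- (w_plus - mu - 0.5 * sign(w_plus - mu)) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  stat_result("wilcoxon_signed_rank", n = n, statistic = w, w_plus = w_plus,
              p_value = p, p_method = method, alpha = alpha)
}

# All 2^n values of W+ over sign assignments, by subset-sum doubling.
signed_rank_sums <- function(r) {
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)
  sums
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of mid-rank-transformed data. The
#' two-sided p value uses the t approximation with `n - 2` degrees of
#' freedom by default; a seeded Monte-Carlo permutation p value is available
#' for small samples.
#'
#' @param x,y Numeric vectors of equal length, no missing values.
#' @param p_method `"t_approx"` or `"permutation"`.
#' @param n_perm Number of Monte-Carlo permutations (>= 99999 recommended
#'   for small n).
#' @param seed Integer seed for the permutation draw.
#' @param alpha Significance level recorded in the result.
#' @return A `stat_result` list with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y, p_method = c("t_approx", "permutation"),
                         n_perm = 99999, seed = 1L, alpha = 0.05) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y)) abort("x and y must not contain missing values",
                                  class = "wearrehab_error_input")
  n <- length(x)
  if (n < 4) abort("need at least 4 observations", class = "wearrehab_error_input")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(stat_result("spearman", n = n, statistic = NA_real_, rho = NA_real_,
                       p_value = NA_real_, p_method = "degenerate",
                       alpha = alpha, note = "zero variance in ranks"))
  }
  rho <- stats::cor(rx, ry)
  if (p_method == "t_approx") {
    if (abs(rho) >= 1 - 1e-12) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  } else {
    p <- withr::with_seed(as.integer(seed), {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        rp <- stats::cor(rx, sample(ry))
        if (abs(rp) >= abs(rho) - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (1 + n_perm)
    })
  }
  stat_result("spearman", n = n, statistic = rho, rho = rho, p_value = p,
              p_method = p_method, alpha = alpha)
}

stat_result <- function(method, n, statistic, p_value, p_method,
                        alpha = 0.05, rho = NULL, w_plus = NULL, note = NULL) {
  structure(list(method = method, n = n, statistic = statistic, rho = rho,
                 w_plus = w_plus, p_value = p_value, p_method = p_method,
                 alpha = alpha, note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s (n = %d, p_method = %s)\n",
              x$method, x$n, x$p_method))
  if (!is.null(x$rho)) cat(sprintf("  rho = %.4f", x$rho))
  else cat(sprintf("  W = %g", x$statistic))
  cat(sprintf(", p = %.4g\n", x$p_value))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Correlation grid and paired comparisons for a cohort
#'
#' Builds (a) the Spearman correlation grid of MSDA (total, training,
#' nontraining) versus FIM motor score and age at each session, and (b)
#' paired Wilcoxon signed-rank comparisons (admission vs 4 weeks) for
#' posture minutes, mean %HRR and MSDA. Patients missing a session are
#' dropped from the paired tests but kept in the cross-sectional
#' correlations; counts are reported per cell.
#'
#' @param cohort A `CohortTable` from [cohort_summaries()].
#' @param p_method,n_perm,seed Passed to [spearman_cor()].
#' @param holm Apply a Holm correction across each family of p values?
#'   Off by default.
#' @param alpha Significance level.
#' @return A list of class `results_bundle` with tibbles `correlations` and
#'   `comparisons`.
#' @export
build_results_tables <- function(cohort, p_method = "t_approx",
                                 n_perm = 99999, seed = 1L,
                                 holm = FALSE, alpha = 0.05) {
  msda_metrics <- c(total = "msda_total", training = "msda_training",
                    nontraining = "msda_nontraining")
  covars <- c(fim_motor = "fim_motor", age = "age")
  grid <- expand.grid(metric = names(msda_metrics), covariate = names(covars),
                      session = SESSION_LEVELS, stringsAsFactors = FALSE)
  cor_rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sub <- cohort[cohort$session == g$session, ]
    xx <- sub[[covars[[g$covariate]]]]
    yy <- sub[[msda_metrics[[g$metric]]]]
    ok <- is.finite(xx) & is.finite(yy)
    res <- if (sum(ok) >= 4) {
      spearman_cor(xx[ok], yy[ok], p_method = p_method, n_perm = n_perm,
                   seed = derive_seed(seed, i), alpha = alpha)
    } else {
      stat_result("spearman", n = sum(ok), statistic = NA_real_, rho = NA_real_,
                  p_value = NA_real_, p_method = "insufficient_n", alpha = alpha)
    }
    tibble(metric = g$metric, covariate = g$covariate, session = g$session,
           n = res$n, rho = res$rho %||% NA_real_, p_value = res$p_value,
           p_method = res$p_method)
  })
  correlations <- do.call(rbind, cor_rows)

  paired_metrics <- c("minutes_lying", "minutes_sitting_standing",
                      "minutes_walking", "hrr_mean_total", "hrr_mean_training",
                      "hrr_mean_nontraining", "msda_total", "msda_training",
                      "msda_nontraining")
  w0 <- cohort[cohort$session == "0W", ]
  w4 <- cohort[cohort$session == "4W", ]
  ids <- intersect(w0$patient_id, w4$patient_id)
  cmp_rows <- lapply(paired_metrics, function(m) {
    x0 <- w0[[m]][match(ids, w0$patient_id)]
    x4 <- w4[[m]][match(ids, w4$patient_id)]
    ok <- is.finite(x0) & is.finite(x4)
    if (sum(ok) >= 3) {
      res <- wilcoxon_signed_rank(x0[ok], x4[ok], alpha = alpha)
      tibble(metric = m, n_pairs = sum(ok), statistic = res$statistic,
             p_value = res$p_value, p_method = res$p_method,
             mean_0w = mean(x0[ok]), mean_4w = mean(x4[ok]))
    } else {
      tibble(metric = m, n_pairs = sum(ok), statistic = NA_real_,
             p_value = NA_real_, p_method = "insufficient_pairs",
             mean_0w = NA_real_, mean_4w = NA_real_)
    }
  })
  comparisons <- do.call(rbind, cmp_rows)

  if (holm) {
    correlations$p_adjusted <- stats::p.adjust(correlations$p_value, "holm")
    comparisons$p_adjusted <- stats::p.adjust(comparisons$p_value, "holm")
  }
  structure(list(correlations = correlations, comparisons = comparisons,
                 alpha = alpha, p_method = p_method),
            class = "results_bundle")
}

#' Render a results bundle as a Markdown report
#'
#' Mirrors the study-style layout: a grid of Spearman coefficients of MSDA
#' versus FIM motor score and age by period and session, followed by the
#' paired admission-vs-4-week comparisons.
#'
#' @param bundle A `results_bundle` from [build_results_tables()].
#' @return A character vector of Markdown lines.
#' @export
format_results_report <- function(bundle) {
  co <- bundle$correlations
  fmt_cell <- function(metric, covariate, session) {
    r <- co[co$metric == metric & co$covariate == covariate &
              co$session == session, ]
    if (!is.finite(r$rho)) return("-- | --")
    sprintf("%.2f | %s", r$rho, format_p(r$p_value))
  }
  lines <- c(
    "# Cohort activity monitoring results",
    "",
    "## Spearman rank correlations: MSDA versus FIM motor score and age",
    "",
    "| MSDA | vs FIM 0W (rho \\| P) | vs FIM 4W (rho \\| P) | vs age 0W (rho \\| P) | vs age 4W (rho \\| P) |",
    "|---|---|---|---|---|"
  )
  for (m in c("total", "training", "nontraining")) {
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s |", m,
                              fmt_cell(m, "fim_motor", "0W"),
                              fmt_cell(m, "fim_motor", "4W"),
                              fmt_cell(m, "age", "0W"),
                              fmt_cell(m, "age", "4W")))
  }
  cm <- bundle$comparisons
  lines <- c(lines, "",
             "## Paired comparisons, admission vs 4 weeks (Wilcoxon signed-rank)",
             "",
             "| metric | n pairs | mean 0W | mean 4W | W | P |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(cm))) {
    lines <- c(lines, sprintf("| %s | %d | %s | %s | %s | %s |",
                              cm$metric[i], cm$n_pairs[i],
                              format_num(cm$mean_0w[i]), format_num(cm$mean_4w[i]),
                              format_num(cm$statistic[i]), format_p(cm$p_value[i])))
  }
  c(lines, "", sprintf("Significance level alpha = %.2f; p method: %s.",
                       bundle$alpha, bundle$p_method))
}

format_p <- function(p) {
  if (!length(p) || !is.finite(p)) return("--")
  if (p < 0.001) "<.001" else sub("^0", "", sprintf("%.3f", p))
}

format_num <- function(x) {
  if (!length(x) || !is.finite(x)) return("--")
  sprintf("%.2f", x)
}
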