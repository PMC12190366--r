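test_that("the unweighted workload total is the plain six-dimension sum", {
  expect_equal(tlx_total(c(0, 0, 0, 0, 0, 0)), 0)
  expect_equal(tlx_total(rep(20, 6)), 120)
  expect_equal(tlx_total(c(11.64, 3.08, 9.11, 6.31, 12.81, 7.72)), 50.67)
  expect_error(tlx_total(c(21, 0, 0, 0, 0, 0)), "\\[0, 20\\]")
  expect_error(tlx_total(c(1, 2, 3)), "six")
})

test_that("block metrics count check-feedback trials over scored trials", {
  fb <- feedback_symbols()
  log <- make_tiny_log(c(rep(fb["correct"], 9), fb["incorrect"]))
  m <- block_metrics(log)
  expect_equal(m$correct_count, 9)
  expect_equal(m$accuracy, 0.9)

  # all no-response: zero correct under the default error-counting switch
  silent <- make_tiny_log(rep(fb["no_response"], 10))
  expect_equal(block_metrics(silent)$accuracy, 0)
  # excluding no-responses leaves an empty denominator -> NaN accuracy
  expect_true(is.nan(block_metrics(silent,
                                   count_no_response_as_error = FALSE)$accuracy))

  # recount oracle: an independent pass over the raw feedback symbols
  set.seed(1)
  symbols <- sample(unname(feedback_symbols()), 50, replace = TRUE)
  mixed <- make_tiny_log(symbols)
  m2 <- block_metrics(mixed)
  expect_equal(m2$correct_count, sum(symbols == fb["correct"]))
  expect_equal(m2$accuracy, sum(symbols == fb["correct"]) / 50)
})

test_that("percent decline matches the printed first/last block arithmetic", {
  expect_equal(percent_decline(150.47, 141.07), 6.25)
  expect_equal(percent_decline(94.68, 91.77), 3.07)
  expect_equal(percent_decline(5, 5), 0)
  expect_error(percent_decline(0, 1), "positive")
})

test_that("PVT metrics average valid responses and count lapses", {
  pvt <- data.frame(rt_ms = c(250, 99, 600),
                    valid = c(TRUE, FALSE, TRUE),
                    lapse = c(FALSE, FALSE, TRUE))
  m <- pvt_metrics(pvt)
  expect_equal(m$mean_rt_ms, 425)   # mean of {250, 600}
  expect_equal(m$lapse_count, 1)
  expect_equal(m$n_valid, 2)

  all300 <- data.frame(rt_ms = rep(300, 5), valid = TRUE, lapse = FALSE)
  expect_equal(pvt_metrics(all300)$mean_rt_ms, 300)
  expect_equal(pvt_metrics(all300)$lapse_count, 0)

  none <- data.frame(rt_ms = 50, valid = FALSE, lapse = FALSE)
  expect_warning(m0 <- pvt_metrics(none), "undefined")
  expect_true(is.na(m0$mean_rt_ms))
})

test_that("paired comparisons route on normality of the differences", {
  expect_identical(paired_compare(1:10, 1:10)$method, "degenerate")
  expect_equal(paired_compare(1:10, 1:10)$effect_size$cohens_d, 0)

  # known standardized shift: Cohen's d should sit near 1
  set.seed(2)
  y <- rnorm(100)
  x <- y + rnorm(100, mean = 1, sd = 1)
  res <- paired_compare(x, y)
  expect_identical(res$method, "paired_t")
  expect_lt(abs(res$effect_size$cohens_d - 1), 3 / sqrt(100))

  # heavily skewed differences select the rank route almost always
  routes <- vapply(1:40, function(s) {
    set.seed(s)
    y <- rnorm(60)
    x <- y + rexp(60, rate = 0.2)^2
    paired_compare(x, y)$method
  }, "")
  expect_gte(mean(routes == "wilcoxon"), 0.95)

  # rank-biserial correlation stays in [-1, 1] and is signed correctly
  set.seed(3)
  y <- rnorm(50)
  x <- y + rexp(50)^2
  r <- paired_compare(x, y)
  expect_true(r$effect_size$rank_biserial >= -1 &&
                r$effect_size$rank_biserial <= 1)
  expect_gt(r$effect_size$rank_biserial, 0)
})

test_that("RM-ANOVA matches a from-scratch sums-of-squares decomposition", {
  hand <- matrix(c(3, 5, 4,
                   6, 7, 8,
                   2, 4, 3,
                   7, 9, 8), nrow = 4, byrow = TRUE)
  res <- rm_anova_gg(hand)
  o <- oracle_rm_anova(hand)
  expect_equal(res$details$df_uncorrected, c(o$df1, o$df2))
  expect_equal(res$statistic, o$F, tolerance = 1e-10)
  expect_equal(res$effect_size$partial_eta_sq, o$partial_eta_sq,
               tolerance = 1e-10)
  expect_equal(res$details$p_uncorrected, o$p, tolerance = 1e-10)
  # epsilon agrees with the covariance-based formula and stays in bounds
  expect_equal(res$details$epsilon_gg, oracle_gg_epsilon(hand),
               tolerance = 1e-10)
  k <- ncol(hand)
  expect_gte(res$details$epsilon_gg, 1 / (k - 1) - 1e-12)
  expect_lte(res$details$epsilon_gg, 1 + 1e-12)
})

test_that("two conditions make sphericity trivial; degenerate input errors", {
  set.seed(4)
  two <- matrix(rnorm(30), ncol = 2)
  res <- rm_anova_gg(two)
  expect_equal(res$details$epsilon_gg, 1)
  expect_equal(res$df, res$details$df_uncorrected)

  # compound-symmetric data: epsilon near 1, corrected and uncorrected agree
  set.seed(5)
  subj <- rnorm(40, sd = 2)
  cs <- sapply(1:4, function(j) subj + rnorm(40))
  rcs <- rm_anova_gg(cs)
  expect_gt(rcs$details$epsilon_gg, 0.85)
  expect_equal(rcs$p_value, rcs$details$p_uncorrected, tolerance = 0.02)

  flat <- matrix(rep(1:5, 3), ncol = 3)
  expect_error(rm_anova_gg(flat), "rank-deficient")
  expect_error(rm_anova_gg(matrix(rnorm(4), 2, 2)), "participants")
})

test_that("Friedman/Kendall agree with the textbook rank-sum formula", {
  set.seed(6)
  m <- matrix(rnorm(20), 5, 4)
  res <- friedman_kendall(m)
  expect_equal(res$statistic, oracle_friedman_chisq(m), tolerance = 1e-10)
  expect_equal(res$effect_size$kendalls_w, oracle_kendalls_w_ranks(m),
               tolerance = 1e-10)

  # identical orderings across participants: perfect concordance
  ordered <- t(replicate(8, sort(rnorm(5))))
  expect_equal(friedman_kendall(ordered)$effect_size$kendalls_w, 1)

  expect_identical(friedman_kendall(matrix(1, 4, 3))$method, "degenerate")

  ph <- friedman_kendall(m, posthoc = TRUE)$details$posthoc
  expect_equal(nrow(ph), choose(4, 2))
  expect_equal(ph$p_bonferroni, pmin(1, ph$p_raw * 6))
})

test_that("Spearman matrices are symmetric with tie-aware ranks and flagged NAs", {
  set.seed(7)
  x <- rnorm(30)
  tab <- data.frame(a = x, b = exp(x), c = rnorm(30))
  sm <- spearman_matrix(tab)
  expect_equal(sm$rho["a", "b"], 1)          # monotone pair
  expect_equal(sm$rho, t(sm$rho))
  expect_equal(unname(diag(sm$rho)), rep(1, 3))
  expect_equal(sm$rho["a", "c"], oracle_spearman(tab$a, tab$c),
               tolerance = 1e-12)

  big <- as.data.frame(matrix(rnorm(500 * 4), 500, 4))
  smb <- spearman_matrix(big)
  off <- smb$rho[upper.tri(smb$rho)]
  expect_true(all(abs(off) < 0.15))          # independent columns

  cst <- data.frame(a = rnorm(10), b = rep(2, 10))
  expect_warning(smc <- spearman_matrix(cst), "constant")
  expect_true(is.na(smc$rho["a", "b"]))
})

test_that("normality routing picks the parametric path only for normal columns", {
  set.seed(8)
  norm_mat <- sapply(1:4, function(j) rnorm(40, mean = j))
  expect_identical(route_repeated(norm_mat)$method, "rm_anova_gg")
  skew_mat <- sapply(1:4, function(j) rexp(40)^2 + j)
  expect_identical(route_repeated(skew_mat)$method, "friedman")
})
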