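#' Unweighted NASA-TLX total
#'
#' Sum of the six 0-20 workload dimensions (mental demand, physical demand,
#' temporal demand, performance, effort, frustration), giving a 0-120 total.
#'
#' @param scores Numeric vector of six dimension scores, each in `[0, 20]`.
#' @return The unweighted total.
#' @export
#' @examples
#' tlx_total(c(11.64, 3.08, 9.11, 6.31, 12.81, 7.72))  # 50.67
tlx_total <- function(scores) {
  assert_that(length(scores) == 6, "exactly six dimension scores are required")
  assert_that(all(scores >= 0 & scores <= 20), "each score must be in [0, 20]")
  sum(scores)
}

#' Per-block behavioural metrics
#'
#' Counts correct-feedback trials per block and divides by the number of
#' scored trials. By default a no-response trial counts as an error (it is
#' in the denominator); set `count_no_response_as_error = FALSE` to score
#' accuracy over answered trials only.
#'
#' @param log A `bs_session_log`.
#' @param count_no_response_as_error Include no-response trials in the
#'   accuracy denominator (default `TRUE`).
#' @return Data frame `block_index` (1-based), `n_scored`, `correct_count`,
#'   `accuracy`, `mean_rt_ms`.
#' @export
block_metrics <- function(log, count_no_response_as_error = TRUE) {
  assert_that(inherits(log, "bs_session_log"), "need a bs_session_log")
  assert_that(length(log$blocks) >= 1, "log contains no blocks")
  rows <- lapply(seq_along(log$blocks), function(b) {
    blk <- log$blocks[[b]]
    r <- blk$responses
    assert_that(nrow(r) > 0, "empty block")
    n <- nrow(r)
    correct_count <- sum(r$correct, na.rm = TRUE)
    denom <- if (count_no_response_as_error) n else sum(!is.na(r$correct))
    data.frame(block_index = b, n_scored = n, correct_count = correct_count,
               accuracy = correct_count / denom,
               mean_rt_ms = mean(r$rt_ms, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Percent decline between first and last block
#'
#' `100 * (first - last) / first`, reported to 2 decimals.
#'
#' @param first,last Positive scalar (first-block and last-block values).
#' @return Percentage decline, rounded to 2 decimals.
#' @export
#' @examples
#' percent_decline(150.47, 141.07)  # 6.25
#' percent_decline(94.68, 91.77)    # 3.07
percent_decline <- function(first, last) {
  assert_that(is_scalar_number(first) && first > 0, "first must be positive")
  assert_that(is_scalar_number(last), "last must be a number")
  round(100 * (first - last) / first, 2)
}

#' PVT summary metrics
#'
#' Mean reaction time over valid responses (>= 100 ms) and the number of
#' attention lapses (>= 500 ms).
#'
#' @param pvt_trials Data frame from [run_pvt()] (columns `rt_ms`, `valid`,
#'   `lapse`).
#' @return List `mean_rt_ms`, `lapse_count`, `n_valid`. With zero valid
#'   trials the mean is `NA` and a warning flags it.
#' @export
pvt_metrics <- function(pvt_trials) {
  assert_that(all(c("rt_ms", "valid", "lapse") %in% names(pvt_trials)),
              "need rt_ms, valid, lapse columns")
  n_valid <- sum(pvt_trials$valid)
  if (n_valid == 0L) {
    warning("no valid PVT responses; mean RT undefined", call. = FALSE)
    mean_rt <- NA_real_
  } else {
    mean_rt <- mean(pvt_trials$rt_ms[pvt_trials$valid])
  }
  list(mean_rt_ms = mean_rt, lapse_count = sum(pvt_trials$lapse),
       n_valid = n_valid)
}

#' Normality test used for routing
#'
#' Shapiro-Wilk, or the Lilliefors-corrected Kolmogorov-Smirnov test (the
#' appropriate KS variant when mean and SD are estimated from the sample).
#'
#' @param x Numeric vector.
#' @param method `"shapiro"` or `"lilliefors"`.
#' @return An `htest` object.
#' @export
normality_test <- function(x, method = c("shapiro", "lilliefors")) {
  method <- match.arg(method)
  switch(method,
         shapiro = shapiro.test(x),
         lilliefors = nortest::lillie.test(x))
}

new_test_result <- function(method, statistic, df, p_value, effect_size,
                            normality_route = NULL, details = list()) {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 effect_size = effect_size,
                 normality_route = normality_route, details = details),
            class = "bs_test_result")
}

#' @export
print.bs_test_result <- function(x, ...) {
  cat("<bs_test_result>", x$method, "\n")
  df_txt <- if (length(x$df)) paste0("(",
    paste(formatC(x$df, format = "fg", digits = 6), collapse = ", "), ")") else ""
  cat("  statistic", df_txt, " = ", formatC(x$statistic, digits = 4,
                                            format = "fg"),
      ", p = ", format_p(x$p_value), "\n", sep = "")
  if (length(x$effect_size)) {
    cat("  effect size:", paste(names(x$effect_size), "=",
                                round(unlist(x$effect_size), 3),
                                collapse = ", "), "\n")
  }
  if (!is.null(x$normality_route)) {
    cat("  route:", x$normality_route, "\n")
  }
  invisible(x)
}

#' Format a p-value the way results tables print them
#'
#' @param p Numeric p-value(s).
#' @return Character: three decimals, or `"<0.001"`.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", formatC(p, digits = 3, format = "f"))
}

#' Normality-routed paired comparison
#'
#' Tests pairwise differences for normality (Shapiro-Wilk by default); if
#' normality holds at `alpha_normality` a matched t-test is run with Cohen's
#' d (mean difference / SD of differences), otherwise a Wilcoxon signed-rank
#' test with the matched-pairs rank-biserial correlation
#' `r = (W+ - W-) / (W+ + W-)`.
#'
#' @param x,y Paired numeric samples of equal length (n >= 3).
#' @param alpha_normality Normality-routing threshold (default 0.05).
#' @param normality `"shapiro"` or `"lilliefors"`.
#' @return A `bs_test_result`; all-zero differences yield the degenerate
#'   flag with effect size 0.
#' @export
paired_compare <- function(x, y, alpha_normality = 0.05,
                           normality = c("shapiro", "lilliefors")) {
  normality <- match.arg(normality)
  assert_that(length(x) == length(y) && length(x) >= 3,
              "x and y must be paired with length >= 3")
  d <- x - y
  if (all(d == 0)) {
    return(new_test_result("degenerate", NA_real_, NA_real_, NA_real_,
                           list(cohens_d = 0),
                           normality_route = "degenerate: all differences zero"))
  }
  sw <- normality_test(d, normality)
  if (sw$p.value >= alpha_normality) {
    tt <- t.test(x, y, paired = TRUE)
    new_test_result("paired_t", tt$statistic, tt$parameter, tt$p.value,
                    list(cohens_d = mean(d) / sd(d)),
                    normality_route = sprintf("%s p = %.3f >= %.2f: t route",
                                              normality, sw$p.value,
                                              alpha_normality))
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                       correct = TRUE))
    dz <- d[d != 0]
    rk <- rank(abs(dz))
    w_pos <- sum(rk[dz > 0])
    w_neg <- sum(rk[dz < 0])
    new_test_result("wilcoxon", wt$statistic, NA_real_, wt$p.value,
                    list(rank_biserial = (w_pos - w_neg) / (w_pos + w_neg)),
                    normality_route = sprintf("%s p = %.3f < %.2f: Wilcoxon route",
                                              normality, sw$p.value,
                                              alpha_normality))
  }
}

#' One-way repeated-measures ANOVA with sphericity correction
#'
#' Fits the within-subject ANOVA on a participants x conditions matrix,
#' tests sphericity (Mauchly), and when sphericity is rejected at
#' `alpha_sphericity` multiplies both degrees of freedom by the
#' Greenhouse-Geisser epsilon. Reports F, (possibly corrected) dfs, p and
#' partial eta squared.
#'
#' @param data Numeric matrix, rows = participants, columns = conditions
#'   (k >= 2; at least k + 1 participants for the sphericity test).
#' @param alpha_sphericity Mauchly-test threshold for applying the
#'   correction (default 0.05).
#' @return A `bs_test_result` with details `epsilon_gg`, `mauchly_w`,
#'   `mauchly_p`, `df_uncorrected`, `p_uncorrected`.
#' @export
rm_anova_gg <- function(data, alpha_sphericity = 0.05) {
  data <- as.matrix(data)
  assert_that(is.numeric(data) && all(is.finite(data)),
              "data must be a finite numeric matrix")
  n <- nrow(data); k <- ncol(data)
  assert_that(k >= 2, "need at least 2 conditions")
  assert_that(n >= k + 1, "need at least conditions + 1 participants")
  if (qr(var(data))$rank < k - 1) {
    stop("rank-deficient covariance matrix: cannot fit the within-subject model",
         call. = FALSE)
  }
  idata <- data.frame(condition = factor(seq_len(k)))
  fit <- stats::lm(data ~ 1)
  av <- car::Anova(fit, idata = idata, idesign = ~condition, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))  # "HF eps > 1" note
  ut <- s$univariate.tests
  ss_effect <- ut["condition", "Sum Sq"]
  ss_error <- ut["condition", "Error SS"]
  f_stat <- ut["condition", "F value"]
  df1 <- ut["condition", "num Df"]
  df2 <- ut["condition", "den Df"]
  p_unc <- ut["condition", "Pr(>F)"]
  if (k == 2L) {
    # sphericity trivially holds with a single within-subject contrast
    eps <- 1
    mauchly_w <- 1
    mauchly_p <- NA_real_
  } else {
    mt <- stats::mauchly.test(fit, X = ~1)
    mauchly_w <- unname(mt$statistic)
    mauchly_p <- mt$p.value
    # Greenhouse-Geisser epsilon from the eigenvalues of the covariance
    # projected onto an orthonormal contrast basis
    M <- diag(k) - 1 / k
    C <- eigen(M, symmetric = TRUE)$vectors[, seq_len(k - 1), drop = FALSE]
    lam <- eigen(t(C) %*% stats::cov(data) %*% C, symmetric = TRUE,
                 only.values = TRUE)$values
    eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  }
  corrected <- k > 2L && !is.na(mauchly_p) && mauchly_p < alpha_sphericity
  use_eps <- if (corrected) eps else 1
  df_c <- c(df1, df2) * use_eps
  p <- pf(f_stat, df_c[1], df_c[2], lower.tail = FALSE)
  new_test_result(
    "rm_anova_gg", f_stat, df_c, p,
    list(partial_eta_sq = ss_effect / (ss_effect + ss_error)),
    normality_route = if (corrected)
      sprintf("Mauchly p = %.3f: GG correction applied (eps = %.3f)", mauchly_p, eps)
    else "sphericity not rejected: uncorrected dfs",
    details = list(epsilon_gg = eps, mauchly_w = mauchly_w,
                   mauchly_p = mauchly_p, df_uncorrected = c(df1, df2),
                   p_uncorrected = p_unc, n = n, k = k)
  )
}

#' Friedman test with Kendall's W
#'
#' Friedman rank test on a participants x timepoints matrix (average ranks
#' for ties), with Kendall's coefficient of concordance derived from the
#' chi-square statistic via the identity `W = chi^2 / (n * (k - 1))`.
#' Optionally runs Bonferroni-corrected pairwise Wilcoxon signed-rank post
#' hocs.
#'
#' @param data Numeric matrix, rows = participants (n >= 2), columns =
#'   timepoints (k >= 3).
#' @param posthoc Run pairwise signed-rank post hocs (default `FALSE`).
#' @return A `bs_test_result` with effect size `kendalls_w`; `details$posthoc`
#'   holds the pairwise table when requested. An all-constant matrix yields
#'   the degenerate flag.
#' @export
friedman_kendall <- function(data, posthoc = FALSE) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  assert_that(n >= 2, "need at least 2 participants")
  assert_that(k >= 3, "need at least 3 timepoints")
  if (all(apply(data, 1, function(r) length(unique(r)) == 1L))) {
    return(new_test_result("degenerate", NA_real_, k - 1, NA_real_,
                           list(kendalls_w = NA_real_),
                           normality_route = "degenerate: all rows constant"))
  }
  ft <- friedman.test(data)
  w <- kendalls_w(ft$statistic, n, k)
  details <- list(n = n, k = k)
  if (posthoc) {
    pairs <- utils::combn(k, 2)
    ph <- apply(pairs, 2, function(ij) {
      wt <- suppressWarnings(wilcox.test(data[, ij[1]], data[, ij[2]],
                                         paired = TRUE, exact = FALSE))
      wt$p.value
    })
    details$posthoc <- data.frame(t1 = pairs[1, ], t2 = pairs[2, ],
                                  p_raw = ph,
                                  p_bonferroni = pmin(1, ph * ncol(pairs)))
  }
  new_test_result("friedman", ft$statistic, ft$parameter, ft$p.value,
                  list(kendalls_w = w), details = details)
}

#' Kendall's W from a Friedman chi-square
#'
#' The concordance effect size for the Friedman test:
#' `W = chi^2 / (n * (k - 1))`, in `[0, 1]`.
#'
#' @param chisq Friedman chi-square statistic.
#' @param n Number of participants.
#' @param k Number of timepoints.
#' @return Kendall's W.
#' @export
#' @examples
#' kendalls_w(310.89, n = 72, k = 7)  # 0.720 (to 3 decimals)
kendalls_w <- function(chisq, n, k) {
  assert_that(n >= 1 && k >= 2, "need n >= 1 and k >= 2")
  unname(chisq / (n * (k - 1)))
}

#' Spearman correlation matrix with p-values
#'
#' Pairwise Spearman rank correlations (tie-corrected via average ranks)
#' between the given columns, with asymptotic p-values. Constant columns
#' produce `NA` correlations and a warning rather than a silent zero.
#'
#' @param block_table Data frame or matrix of numeric columns (n >= 4 rows),
#'   e.g. per-participant subjective items and behavioural metrics within
#'   one block.
#' @return List with `rho` (symmetric, unit diagonal) and `p` matrices.
#' @export
spearman_matrix <- function(block_table) {
  m <- as.matrix(block_table)
  assert_that(is.numeric(m), "columns must be numeric")
  assert_that(nrow(m) >= 4, "need at least 4 rows")
  v <- ncol(m)
  constant <- apply(m, 2, function(col) length(unique(col)) == 1L)
  if (any(constant)) {
    warning("constant column(s): ", paste(colnames(m)[constant], collapse = ", "),
            "; correlations undefined (NA)", call. = FALSE)
  }
  rho <- matrix(NA_real_, v, v, dimnames = list(colnames(m), colnames(m)))
  p <- rho
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(v - 1)) {
    for (j in (i + 1):v) {
      if (constant[i] || constant[j]) next
      ct <- suppressWarnings(cor.test(m[, i], m[, j], method = "spearman",
                                      exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = p)
}

#' Participants x blocks matrix of a behavioural metric
#'
#' @param logs List of `bs_session_log` objects (a cohort).
#' @param metric `"accuracy"`, `"correct_count"` or `"mean_rt_ms"`.
#' @param count_no_response_as_error Passed to [block_metrics()].
#' @return Numeric matrix, one row per participant.
#' @export
cohort_block_matrix <- function(logs, metric = c("accuracy", "correct_count",
                                                 "mean_rt_ms"),
                                count_no_response_as_error = TRUE) {
  metric <- match.arg(metric)
  rows <- lapply(logs, function(log) {
    block_metrics(log, count_no_response_as_error)[[metric]]
  })
  do.call(rbind, rows)
}

#' Participants x blocks matrix of a VAS item
#'
#' @param logs List of `bs_session_log` objects from the time-on-task
#'   protocol.
#' @param item VAS item name.
#' @param include_baseline Include the block-0 baseline column (default
#'   `FALSE`; the fatigue item is typically analysed including baseline,
#'   the others without).
#' @return Numeric matrix, one row per participant.
#' @export
cohort_vas_matrix <- function(logs, item, include_baseline = FALSE) {
  rows <- lapply(logs, function(log) {
    v <- log$vas[log$vas$item == item, ]
    v <- v[order(v$block), ]
    if (!include_baseline) v <- v[v$block > 0, ]
    v$score
  })
  do.call(rbind, rows)
}

#' Per-participant PVT summaries for a cohort
#'
#' @param logs List of `bs_session_log` objects with pre/post PVT runs.
#' @return Data frame `participant_id`, `phase`, `mean_rt_ms`, `lapse_count`.
#' @export
cohort_pvt_table <- function(logs) {
  do.call(rbind, lapply(logs, function(log) {
    pre <- pvt_metrics(log$pvt$pre)
    post <- pvt_metrics(log$pvt$post)
    data.frame(participant_id = rep(log$participant_id %||% "P001", 2),
               phase = c("pre", "post"),
               mean_rt_ms = c(pre$mean_rt_ms, post$mean_rt_ms),
               lapse_count = c(pre$lapse_count, post$lapse_count),
               stringsAsFactors = FALSE)
  }))
}
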