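#' Route a repeated-measures comparison by normality
#'
#' Applies a normality test to every column; if all columns pass at `alpha`
#' the one-way repeated-measures ANOVA (with sphericity correction) is used,
#' otherwise the Friedman test with Kendall's W. Mirrors the convention of
#' screening each timepoint's distribution before choosing the parametric
#' or rank-based test.
#'
#' @param data Participants x timepoints numeric matrix.
#' @param normality `"lilliefors"` (default; appropriate when moments are
#'   estimated) or `"shapiro"`.
#' @param alpha Normality threshold (default 0.05).
#' @return A `bs_test_result` from [rm_anova_gg()] or [friedman_kendall()],
#'   with the route recorded.
#' @export
route_repeated <- function(data, normality = c("lilliefors", "shapiro"),
                           alpha = 0.05) {
  normality <- match.arg(normality)
  data <- as.matrix(data)
  ps <- apply(data, 2, function(col) {
    if (length(unique(col)) == 1L) return(0)  # constant: clearly non-normal
    normality_test(col, normality)$p.value
  })
  if (all(ps >= alpha)) {
    res <- rm_anova_gg(data)
    res$normality_route <- paste0("all columns normal (", normality,
                                  "): RM-ANOVA; ", res$normality_route)
  } else {
    res <- friedman_kendall(data)
    res$normality_route <- paste0("non-normal column(s) (", normality,
                                  "): Friedman")
  }
  res
}

#' Full time-on-task cohort report
#'
#' Runs the complete fatigue-analysis pipeline on a cohort of time-on-task
#' session logs: block-wise descriptives for the four subjective items and
#' the two behavioural metrics, normality-routed repeated-measures tests
#' (the fatigue item includes its baseline timepoint; the others start at
#' block 1), first-to-last-block percent declines, pre/post PVT paired
#' comparisons, and per-block Spearman matrices between subjective and
#' behavioural indicators.
#'
#' @param logs List of `bs_session_log` objects from [run_tot_protocol()] /
#'   [generate_cohort()].
#' @param normality Normality test for routing (default `"lilliefors"`).
#' @return List of class `bs_tot_report`: `descriptives` (long data frame),
#'   `tests` (named list of `bs_test_result`), `declines`, `pvt`,
#'   `spearman_by_block`.
#' @export
tot_report <- function(logs, normality = "lilliefors") {
  assert_that(length(logs) >= 2, "need a cohort of at least 2 logs")
  items <- vas_item_names()
  mats <- c(
    stats::setNames(lapply(items, function(it) {
      cohort_vas_matrix(logs, it, include_baseline = it == "mental_fatigue")
    }), items),
    list(correct_count = cohort_block_matrix(logs, "correct_count"),
         accuracy = cohort_block_matrix(logs, "accuracy"))
  )
  desc <- do.call(rbind, lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    has_base <- ncol(m) > length(logs[[1]]$blocks)
    data.frame(indicator = nm,
               block = if (has_base) seq_len(ncol(m)) - 1L else seq_len(ncol(m)),
               mean = colMeans(m), sd = apply(m, 2, sd),
               stringsAsFactors = FALSE)
  }))
  tests <- lapply(mats, route_repeated, normality = normality)
  declines <- vapply(c("correct_count", "accuracy"), function(nm) {
    m <- mats[[nm]]
    percent_decline(mean(m[, 1]), mean(m[, ncol(m)]))
  }, 1.0)
  pvt_tab <- cohort_pvt_table(logs)
  pre <- pvt_tab[pvt_tab$phase == "pre", ]
  post <- pvt_tab[pvt_tab$phase == "post", ]
  pvt_tests <- list(
    mean_rt_ms = paired_compare(post$mean_rt_ms, pre$mean_rt_ms),
    lapse_count = paired_compare(post$lapse_count, pre$lapse_count)
  )
  n_blocks <- length(logs[[1]]$blocks)
  spearman_by_block <- lapply(seq_len(n_blocks), function(b) {
    tab <- data.frame(
      mental_fatigue = mats$mental_fatigue[, b + 1L],  # col 1 is baseline
      mental_effort = mats$mental_effort[, b],
      mental_stress = mats$mental_stress[, b],
      boredom = mats$boredom[, b],
      correct_count = mats$correct_count[, b],
      accuracy = mats$accuracy[, b]
    )
    suppressWarnings(spearman_matrix(tab))
  })
  structure(list(descriptives = desc, tests = tests, declines = declines,
                 pvt = list(table = pvt_tab, tests = pvt_tests),
                 spearman_by_block = spearman_by_block,
                 n_participants = length(logs)),
            class = "bs_tot_report")
}

#' @export
print.bs_tot_report <- function(x, ...) {
  cat("Time-on-task cohort report (n =", x$n_participants, ")\n\n")
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    es <- round(unlist(t$effect_size), 3)
    cat(sprintf("  %-15s %-12s stat = %8.2f  p = %7s  %s = %s\n",
                nm, t$method, t$statistic, format_p(t$p_value),
                names(es)[1], es[1]))
  }
  cat("\n  declines block 1 -> last: correct trials ",
      x$declines["correct_count"], "%, accuracy ",
      x$declines["accuracy"], "%\n", sep = "")
  for (nm in names(x$pvt$tests)) {
    t <- x$pvt$tests[[nm]]
    cat(sprintf("  PVT %-12s %-10s p = %s\n", nm, t$method, format_p(t$p_value)))
  }
  invisible(x)
}

#' Workload comparison between the dual task and the 2-back task
#'
#' Paired, normality-routed comparisons of the six workload dimensions, the
#' unweighted total, and the behavioural metrics between matched sessions
#' of the deadline-pressured dual task and the 2-back comparison task.
#'
#' @param bs_logs,back2_logs Equal-length lists of session logs (one pair
#'   per participant).
#' @return List: `descriptives`, `tests` (named `bs_test_result`s).
#' @export
hmw_report <- function(bs_logs, back2_logs) {
  assert_that(length(bs_logs) == length(back2_logs) && length(bs_logs) >= 3,
              "need >= 3 paired sessions")
  tlx_bs <- do.call(rbind, lapply(bs_logs, function(l) l$tlx))
  tlx_2b <- do.call(rbind, lapply(back2_logs, function(l) l$tlx))
  tot_bs <- apply(tlx_bs, 1, tlx_total)
  tot_2b <- apply(tlx_2b, 1, tlx_total)
  perf <- function(logs, metric) {
    vapply(logs, function(l) {
      df <- do.call(rbind, lapply(l$blocks, function(b) b$responses))
      if (metric == "rt") mean(df$rt_ms, na.rm = TRUE)
      else sum(df$correct, na.rm = TRUE) / nrow(df)
    }, 1.0)
  }
  tests <- list(tlx_total = paired_compare(tot_bs, tot_2b))
  for (j in seq_len(ncol(tlx_bs))) {
    tests[[colnames(tlx_bs)[j]]] <- paired_compare(tlx_bs[, j], tlx_2b[, j])
  }
  tests$reaction_time <- paired_compare(perf(bs_logs, "rt"), perf(back2_logs, "rt"))
  tests$accuracy <- paired_compare(perf(bs_logs, "acc"), perf(back2_logs, "acc"))
  desc <- data.frame(
    indicator = c("tlx_total", colnames(tlx_bs), "reaction_time", "accuracy"),
    bs_mean = c(mean(tot_bs), colMeans(tlx_bs), mean(perf(bs_logs, "rt")),
                mean(perf(bs_logs, "acc"))),
    back2_mean = c(mean(tot_2b), colMeans(tlx_2b), mean(perf(back2_logs, "rt")),
                   mean(perf(back2_logs, "acc")))
  )
  list(descriptives = desc, tests = tests)
}
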