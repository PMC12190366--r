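#' Keep only correct trials
#'
#' First preprocessing stage of the time-pressure calibration: incorrect
#' trials are removed for each participant before any outlier screening.
#'
#' @param observations Data frame with at least columns `participant_id`,
#'   `condition`, `rt_ms`, `correct`.
#' @return The subset with `correct == TRUE`, order preserved.
#' @export
filter_correct <- function(observations) {
  check_rt_observations(observations)
  out <- observations[!is.na(observations$correct) & observations$correct, ,
                      drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove trial-level reaction-time outliers
#'
#' Within each (participant, condition) group, removes trials whose RT lies
#' outside mean +/- `k` * SD of that group, where mean and SD are computed
#' once from the group's pre-removal values (a single pass; no iteration).
#' The SD is the sample SD (n - 1 denominator). Groups of size 1 are retained
#' unchanged (their SD is undefined) with a warning.
#'
#' @param observations Data frame as in [filter_correct()].
#' @param k Rejection width in standard deviations (default 3).
#' @return The retained observations, order preserved, with attribute
#'   `n_removed` giving the number of rejected trials.
#' @export
remove_trial_outliers <- function(observations, k = 3) {
  check_rt_observations(observations)
  if (nrow(observations) == 0L) {
    attr(observations, "n_removed") <- 0L
    return(observations)
  }
  grp <- interaction(observations$participant_id, observations$condition,
                     drop = TRUE)
  mu <- ave(observations$rt_ms, grp, FUN = mean)
  n_grp <- ave(observations$rt_ms, grp, FUN = length)
  sdev <- ave(observations$rt_ms, grp, FUN = function(x) {
    if (length(x) < 2L) 0 else sd(x)
  })
  if (any(n_grp == 1L)) {
    warning("singleton (participant, condition) group(s): retained unchanged, ",
            "SD undefined", call. = FALSE)
  }
  keep <- observations$rt_ms >= mu - k * sdev & observations$rt_ms <= mu + k * sdev
  keep[n_grp == 1L] <- TRUE
  out <- observations[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove group-level outlier participants
#'
#' A participant is excluded when any of their per-condition mean RTs falls
#' outside the group's mean +/- `k` * SD for that condition (means and SDs
#' computed once, over all participants, before any exclusion). Exclusion is
#' participant-wise: one extreme condition mean drops the whole participant.
#'
#' @param condition_means Data frame with columns `participant_id`,
#'   `condition`, `mean_rt_ms` (one row per participant x condition).
#' @param k Rejection width in standard deviations (default 3).
#' @return List with `retained` (the surviving rows), `excluded_participants`
#'   (character vector) and `report` (per-condition group mean/SD and the
#'   flagged cells).
#' @export
remove_group_outliers <- function(condition_means, k = 3) {
  assert_that(all(c("participant_id", "condition", "mean_rt_ms") %in%
                    names(condition_means)),
              "condition_means needs participant_id, condition, mean_rt_ms")
  n_part <- length(unique(condition_means$participant_id))
  assert_that(n_part >= 2, "group-level screening needs at least 2 participants")
  grp <- factor(condition_means$condition)
  gmu <- ave(condition_means$mean_rt_ms, grp, FUN = mean)
  gsd <- ave(condition_means$mean_rt_ms, grp, FUN = sd)
  flagged <- condition_means$mean_rt_ms < gmu - k * gsd |
             condition_means$mean_rt_ms > gmu + k * gsd
  excluded <- unique(as.character(condition_means$participant_id[flagged]))
  keep <- !(as.character(condition_means$participant_id) %in% excluded)
  retained <- condition_means[keep, , drop = FALSE]
  rownames(retained) <- NULL
  report <- data.frame(
    condition = condition_means$condition,
    participant_id = condition_means$participant_id,
    mean_rt_ms = condition_means$mean_rt_ms,
    group_mean = gmu, group_sd = gsd, flagged = flagged,
    stringsAsFactors = FALSE
  )
  list(retained = retained, excluded_participants = excluded, report = report)
}

#' Available time from a mean required time
#'
#' Core calibration rule: the response deadline (available time, AT) is set
#' to `pressure_factor` times the mean reaction time measured without any
#' response deadline (required time, RT), so that RT / AT = 1 /
#' `pressure_factor` = 0.8 at the default factor 1.25 - the ratio at which
#' responders experience time pressure. The product is rounded half-up to the
#' nearest multiple of `rounding_quantum_ms`.
#'
#' @param mean_rt_ms Positive mean reaction time(s) in ms (vectorised).
#' @param pressure_factor AT/RT ratio (default 1.25).
#' @param rounding_quantum_ms Rounding quantum in ms (default 100; use 1 for
#'   no rounding).
#' @return Available time(s) in ms.
#' @export
#' @examples
#' compute_available_time(1815.63)  # 2300
#' compute_available_time(2110.47)  # 2600
compute_available_time <- function(mean_rt_ms, pressure_factor = 1.25,
                                   rounding_quantum_ms = 100) {
  assert_that(is.numeric(mean_rt_ms) && all(mean_rt_ms > 0),
              "mean_rt_ms must be positive")
  assert_that(is_scalar_number(pressure_factor) && pressure_factor > 0,
              "pressure_factor must be positive")
  assert_that(is_scalar_number(rounding_quantum_ms) && rounding_quantum_ms > 0,
              "rounding_quantum_ms must be positive")
  round_half_up(pressure_factor * mean_rt_ms, rounding_quantum_ms)
}

#' Full time-pressure calibration pipeline
#'
#' Composes the preprocessing and deadline computation applied to
#' unconstrained-response-time data: (1) drop incorrect trials per
#' participant, (2) drop trial-level 3SD outliers within each (participant,
#' condition) group, (3) per-participant condition means, (4) drop
#' participants with any group-level 3SD-outlying condition mean, (5) group
#' condition means, (6) available time per condition.
#'
#' @param observations Data frame with columns `participant_id`, `condition`
#'   (1..4), `rt_ms`, `correct`, collected with no response deadline.
#' @inheritParams compute_available_time
#' @param k Outlier rejection width in SDs at both levels (default 3).
#' @return An object of class `bs_calibration`: per-condition `mean_rt_ms`
#'   and `available_time_ms`, retention counts per stage, and the exclusion
#'   report.
#' @export
calibrate <- function(observations, pressure_factor = 1.25,
                      rounding_quantum_ms = 100, k = 3) {
  check_rt_observations(observations)
  n0 <- nrow(observations)
  correct <- filter_correct(observations)
  trimmed <- remove_trial_outliers(correct, k = k)

  means <- aggregate(rt_ms ~ participant_id + condition, data = trimmed,
                     FUN = mean)
  names(means)[names(means) == "rt_ms"] <- "mean_rt_ms"
  screened <- remove_group_outliers(means, k = k)

  group_means <- tapply(screened$retained$mean_rt_ms,
                        factor(screened$retained$condition, levels = 1:4),
                        mean)
  at <- compute_available_time(as.numeric(group_means),
                               pressure_factor = pressure_factor,
                               rounding_quantum_ms = rounding_quantum_ms)
  names(at) <- names(group_means) <- as.character(1:4)

  structure(
    list(
      mean_rt_ms = group_means,
      available_time_ms = at,
      pressure_factor = pressure_factor,
      rounding_quantum_ms = rounding_quantum_ms,
      n_trials_input = n0,
      n_trials_incorrect_removed = n0 - nrow(correct),
      n_trials_outliers_removed = attr(trimmed, "n_removed"),
      n_participants_input = length(unique(observations$participant_id)),
      n_participants_retained = length(unique(screened$retained$participant_id)),
      excluded_participants = screened$excluded_participants,
      exclusion_report = screened$report
    ),
    class = "bs_calibration"
  )
}

#' @export
print.bs_calibration <- function(x, ...) {
  cat("Time-pressure calibration (AT =", x$pressure_factor, "x mean RT,",
      "quantum", x$rounding_quantum_ms, "ms)\n")
  tab <- data.frame(condition = 1:4,
                    mean_rt_ms = round(as.numeric(x$mean_rt_ms), 2),
                    available_time_ms = as.numeric(x$available_time_ms))
  print(tab, row.names = FALSE)
  cat("trials: ", x$n_trials_input, " in; ",
      x$n_trials_incorrect_removed, " incorrect and ",
      x$n_trials_outliers_removed, " outliers removed\n", sep = "")
  cat("participants: ", x$n_participants_retained, "/",
      x$n_participants_input, " retained",
      if (length(x$excluded_participants))
        paste0(" (excluded: ",
               paste(x$excluded_participants, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

check_rt_observations <- function(observations) {
  assert_that(is.data.frame(observations), "observations must be a data frame")
  needed <- c("participant_id", "condition", "rt_ms", "correct")
  assert_that(all(needed %in% names(observations)),
              paste("observations need columns:", paste(needed, collapse = ", ")))
  if (nrow(observations) > 0) {
    assert_that(all(observations$rt_ms > 0, na.rm = TRUE), "rt_ms must be positive")
  }
  invisible(TRUE)
}
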