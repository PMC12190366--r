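#' Feedback symbols
#'
#' Every scored trial receives exactly one of three feedback glyphs during
#' the 500 ms inter-stimulus interval: check (correct key within the
#' deadline), cross (wrong key within the deadline), dash (no key before the
#' deadline elapsed).
#'
#' @return Named character vector `correct`, `incorrect`, `no_response`.
#' @export
feedback_symbols <- function() {
  c(correct = "√", incorrect = "×", no_response = "–")
}

#' Default per-condition response deadlines
#'
#' The calibrated available times of the final paradigm: 2300, 3000, 2600
#' and 2800 ms for conditions 1-4.
#'
#' @return Named numeric vector (names `"1"`..`"4"`), ms.
#' @export
default_available_times <- function() {
  c(`1` = 2300, `2` = 3000, `3` = 2600, `4` = 2800)
}

#' Configuration for the 30-minute time-on-task protocol
#'
#' Six 5-minute blocks of the deadline-pressured task, each filled with
#' pseudo-random balanced batches of the four conditions (1:1:1:1) until the
#' block clock expires; a baseline VAS before the first block and a VAS after
#' every block; a 3-minute PVT before the first and after the last block.
#'
#' @param n_blocks Number of blocks (default 6).
#' @param block_duration_ms Block length (default 300000 = 5 min).
#' @param isi_feedback_ms Feedback/ISI duration (default 500).
#' @param available_times Per-condition deadlines ([default_available_times()]).
#' @param mapping Key mapping.
#' @param vas_items VAS item names.
#' @param pvt_duration_ms PVT length (default 180000 = 3 min).
#' @param pvt_interval_bounds PVT inter-stimulus interval bounds, ms.
#' @return List of class `bs_session_config`.
#' @export
tot_config <- function(n_blocks = 6, block_duration_ms = 300000,
                       isi_feedback_ms = 500,
                       available_times = default_available_times(),
                       mapping = key_mapping("A"),
                       vas_items = vas_item_names(),
                       pvt_duration_ms = 180000,
                       pvt_interval_bounds = c(2000, 10000)) {
  assert_that(n_blocks >= 1, "block_count must be >= 1")
  structure(list(protocol = "tot_induction", n_blocks = n_blocks,
                 block_duration_ms = block_duration_ms,
                 isi_feedback_ms = isi_feedback_ms,
                 available_times = available_times, mapping = mapping,
                 vas_items = vas_items, pvt_duration_ms = pvt_duration_ms,
                 pvt_interval_bounds = pvt_interval_bounds),
            class = "bs_session_config")
}

#' Configuration for the blocked workload-comparison protocol
#'
#' Eight blocks of 8 scored trials (each condition twice, pseudo-random),
#' 20 s rest between blocks, workload scale after the task.
#'
#' @param n_blocks Number of blocks (default 8).
#' @param per_condition_per_block Scored trials per condition per block
#'   (default 2, i.e. 8 scored trials per block).
#' @param rest_duration_ms Inter-block rest (default 20000).
#' @inheritParams tot_config
#' @param practice_accuracy_gate Accuracy required to pass practice
#'   (default 0.90).
#' @return List of class `bs_session_config`.
#' @export
hmw_config <- function(n_blocks = 8, per_condition_per_block = 2,
                       rest_duration_ms = 20000, isi_feedback_ms = 500,
                       available_times = default_available_times(),
                       mapping = key_mapping("A"),
                       practice_accuracy_gate = 0.90) {
  assert_that(n_blocks >= 1, "block_count must be >= 1")
  assert_that(practice_accuracy_gate >= 0 && practice_accuracy_gate <= 1,
              "practice gate must be in [0, 1]")
  structure(list(protocol = "hmw_blocks", n_blocks = n_blocks,
                 per_condition_per_block = per_condition_per_block,
                 rest_duration_ms = rest_duration_ms,
                 isi_feedback_ms = isi_feedback_ms,
                 available_times = available_times, mapping = mapping,
                 practice_accuracy_gate = practice_accuracy_gate),
            class = "bs_session_config")
}

# Clock charge for an unscored lead-in trial: displayed for the rounded mean
# deadline when deadlines are configured, free in unlimited mode.
lead_in_charge <- function(available_times) {
  if (is.null(available_times)) 0 else round_half_up(mean(available_times))
}

#' Run one task block against a responder
#'
#' Queries the responder for every scored trial (vectorised). A response
#' slower than the trial's deadline is recorded as a no-response (dash
#' feedback, `key`/`rt_ms`/`correct` all `NA`); otherwise the key is scored
#' against the expected key (check/cross feedback). The virtual clock
#' advances by `min(rt, available_time)` plus the ISI per scored trial, and
#' by the mean deadline for the unscored lead-in. In unlimited mode (deadline
#' `NA`) the engine waits for the key.
#'
#' @param responder A `bs_responder`.
#' @param trials A `bs_trials` data frame.
#' @param block_index 0-based block position passed to the responder.
#' @param isi_ms Feedback/ISI duration, ms.
#' @return List with `responses` (trial_index, key, rt_ms, correct,
#'   feedback) and `elapsed_ms`.
#' @export
run_bs_block <- function(responder, trials, block_index = 0, isi_ms = 500) {
  assert_that(inherits(responder, "bs_responder"), "need a bs_responder")
  scored <- trials[trials$scored, , drop = FALSE]
  resp <- responder$respond_bs(scored, block_index)
  assert_that(all(resp$rt_ms >= 0), "protocol error: responder returned negative RT")
  rec <- score_responses(scored, resp)
  n_lead <- sum(!trials$scored)
  at_charge <- if (all(is.na(trials$available_time_ms))) NULL
               else trials$available_time_ms[trials$scored]
  elapsed <- sum(rec$effective_ms) + nrow(scored) * isi_ms +
    n_lead * lead_in_charge(at_charge)
  rec$effective_ms <- NULL
  list(responses = rec, elapsed_ms = elapsed)
}

# Shared scoring of raw responder output against trial definitions.
score_responses <- function(scored, resp) {
  fb <- feedback_symbols()
  at <- scored$available_time_ms
  rt <- resp$rt_ms
  key <- as.character(resp$key)
  no_resp <- !is.na(at) & rt > at
  correct <- key == scored$expected_key
  feedback <- rep(unname(fb["incorrect"]), length(rt))
  feedback[correct] <- fb["correct"]
  feedback[no_resp] <- fb["no_response"]
  key[no_resp] <- NA_character_
  rt[no_resp] <- NA_real_
  correct[no_resp] <- NA
  effective <- pmin(resp$rt_ms, at)
  effective[is.na(at)] <- resp$rt_ms[is.na(at)]
  quick_df(list(
    trial_index = scored$index,
    key = key,
    rt_ms = rt,
    correct = correct,
    feedback = feedback,
    effective_ms = effective
  ))
}

#' Run the practice phase with an accuracy gate
#'
#' Repeats 16-trial practice blocks (each condition four times) until the
#' block accuracy reaches `gate` or the attempt cap is exhausted.
#' No-response trials count as errors.
#'
#' @param responder A `bs_responder`.
#' @param mapping Key mapping.
#' @param gate Accuracy threshold in `[0, 1]` (default 0.90).
#' @param n_trials Scored trials per practice block (default 16).
#' @param available_times Optional deadlines (practice defaults to
#'   unlimited).
#' @param max_attempts Attempt cap; exhaustion is flagged, not an error.
#' @param seed Optional integer seed.
#' @return List `passed`, `accuracy` (last attempt), `attempts`.
#' @export
run_practice <- function(responder, mapping = key_mapping("A"), gate = 0.90,
                         n_trials = 16, available_times = NULL,
                         max_attempts = 10, seed = NULL) {
  assert_that(gate >= 0 && gate <= 1, "gate must be in [0, 1]")
  assert_that(n_trials %% 4 == 0, "n_trials must be a multiple of 4")
  with_seed_if(seed, {
    acc <- NA_real_
    for (attempt in seq_len(max_attempts)) {
      cond <- generate_condition_sequence(rep(n_trials / 4, 4))
      trials <- realize_trials(cond, mapping = mapping,
                               available_times = available_times)
      block <- run_bs_block(responder, trials, block_index = 0)
      acc <- sum(block$responses$correct, na.rm = TRUE) / n_trials
      if (acc >= gate) {
        return(list(passed = TRUE, accuracy = acc, attempts = attempt))
      }
    }
    list(passed = FALSE, accuracy = acc, attempts = max_attempts)
  })
}

#' Run a psychomotor vigilance test
#'
#' Schedules target stimuli at uniformly random inter-stimulus intervals
#' (the drawn interval includes the 1 s feedback display that follows each
#' key press); each trial consumes its interval plus the reaction time, and
#' trials are delivered while the elapsed clock is below `duration_ms`.
#' Responses of at least 100 ms are valid; responses of at least 500 ms are
#' attention lapses.
#'
#' @param responder A `bs_responder`.
#' @param duration_ms Test length (default 180000 = 3 min).
#' @param interval_bounds Inter-stimulus interval bounds, ms (default
#'   2000-10000).
#' @param phase `"pre"` or `"post"` (forwarded to the responder).
#' @param seed Optional integer seed.
#' @return Data frame of class `bs_pvt_trials`: `foreperiod_ms`, `rt_ms`,
#'   `valid`, `lapse`.
#' @export
run_pvt <- function(responder, duration_ms = 180000,
                    interval_bounds = c(2000, 10000),
                    phase = c("pre", "post"), seed = NULL) {
  phase <- match.arg(phase)
  assert_that(duration_ms > 0, "duration must be positive")
  assert_that(length(interval_bounds) == 2 && interval_bounds[1] > 0 &&
                interval_bounds[1] <= interval_bounds[2],
              "interval bounds must be ordered and positive")
  with_seed_if(seed, {
    cap <- ceiling(duration_ms / interval_bounds[1]) + 2L
    fp <- runif(cap, interval_bounds[1], interval_bounds[2])
    rt <- responder$respond_pvt(cap, phase)
    assert_that(all(rt >= 0), "protocol error: responder returned negative RT")
    total <- fp + rt
    starts <- cumsum(total) - total
    keep <- starts < duration_ms
    out <- data.frame(foreperiod_ms = fp[keep], rt_ms = rt[keep],
                      valid = rt[keep] >= 100, lapse = rt[keep] >= 500)
    class(out) <- c("bs_pvt_trials", "data.frame")
    attr(out, "elapsed_ms") <- sum(total[keep])
    attr(out, "phase") <- phase
    out
  })
}

# Fill one timed block with balanced condition batches until the block clock
# expires, chunk-wise so the responder can be queried in vectorised calls.
fill_timed_block <- function(responder, config, block_index) {
  D <- config$block_duration_ms
  isi <- config$isi_feedback_ms
  at <- config$available_times
  trials_acc <- NULL
  resp_acc <- NULL
  elapsed <- lead_in_charge(at)
  last_cell <- NULL
  repeat {
    remaining <- D - elapsed
    nb <- max(2L, ceiling(remaining / (4 * (isi + 1000))) + 1L)
    conds <- balanced_condition_batches(nb)
    first <- is.null(trials_acc)
    trials <- realize_trials(conds, mapping = config$mapping,
                             available_times = at, lead_in = first,
                             previous = if (!first) list(grid_cell = last_cell))
    scored <- trials[trials$scored, , drop = FALSE]
    resp <- responder$respond_bs(scored, block_index)
    assert_that(all(resp$rt_ms >= 0),
                "protocol error: responder returned negative RT")
    rec <- score_responses(scored, resp)
    batch_ms <- colSums(matrix(rec$effective_ms + isi, nrow = 4L))
    batch_start <- elapsed + cumsum(batch_ms) - batch_ms
    keep_b <- batch_start < D
    n_keep <- sum(keep_b)
    keep_rows <- seq_len(4L * n_keep)
    keep_trials <- if (first) c(1L, 1L + keep_rows) else keep_rows
    trials_acc <- rbind(trials_acc, trials[keep_trials, , drop = FALSE])
    resp_acc <- rbind(resp_acc, rec[keep_rows, , drop = FALSE])
    elapsed <- elapsed + sum(batch_ms[keep_b])
    if (n_keep < nb || elapsed >= D) break
    last_cell <- trials$grid_cell[nrow(trials)]
  }
  # re-index contiguously within the block
  trials_acc$index <- seq_len(nrow(trials_acc)) - 1L
  resp_acc$trial_index <- trials_acc$index[trials_acc$scored]
  resp_acc$effective_ms <- NULL
  rownames(trials_acc) <- rownames(resp_acc) <- NULL
  class(trials_acc) <- c("bs_trials", "data.frame")
  list(block_index = block_index, trials = trials_acc, responses = resp_acc,
       elapsed_ms = elapsed)
}

#' Run the 30-minute time-on-task fatigue-induction protocol
#'
#' Baseline VAS, pre-task PVT, six timed blocks (VAS after each), post-task
#' PVT, all on a virtual clock (a 30-minute session executes in
#' milliseconds). A responder error mid-session yields a partial log with
#' `truncated = TRUE`.
#'
#' @param responder A `bs_responder`.
#' @param config A [tot_config()].
#' @param seed Optional integer seed.
#' @return An object of class `bs_session_log`: `blocks` (list of
#'   `block_index`/`trials`/`responses`/`elapsed_ms`), `vas` (data frame
#'   `block`, `item`, `score`; block 0 = baseline), `pvt` (`pre`, `post`),
#'   `config`, `truncated`.
#' @export
run_tot_protocol <- function(responder, config = tot_config(), seed = NULL) {
  assert_that(inherits(responder, "bs_responder"), "need a bs_responder")
  assert_that(identical(config$protocol, "tot_induction"),
              "config must be a tot_config()")
  with_seed_if(seed, {
    log <- list(protocol = "tot_induction", config = config,
                blocks = list(), vas = NULL,
                pvt = list(pre = NULL, post = NULL),
                truncated = FALSE, seed = seed)
    log$vas <- vas_record(0L, responder$report_vas(0L, config$vas_items))
    log$pvt$pre <- run_pvt(responder, config$pvt_duration_ms,
                           config$pvt_interval_bounds, phase = "pre")
    ok <- tryCatch({
      for (b in seq_len(config$n_blocks)) {
        blk <- fill_timed_block(responder, config, block_index = b - 1L)
        log$blocks[[b]] <- blk
        log$vas <- rbind(log$vas,
                         vas_record(b, responder$report_vas(b, config$vas_items)))
      }
      TRUE
    }, error = function(e) {
      warning("responder failed mid-session; returning truncated log: ",
              conditionMessage(e), call. = FALSE)
      FALSE
    })
    log$truncated <- !ok
    if (ok) {
      log$pvt$post <- run_pvt(responder, config$pvt_duration_ms,
                              config$pvt_interval_bounds, phase = "post")
    }
    structure(log, class = "bs_session_log")
  })
}

vas_record <- function(block, scores) {
  assert_that(all(scores >= 0 & scores <= 100), "VAS scores must be in 0..100")
  data.frame(block = block, item = names(scores),
             score = as.integer(scores), stringsAsFactors = FALSE)
}

#' Run the blocked workload-comparison protocol (deadline-pressured task)
#'
#' Eight blocks of eight scored trials (each condition twice,
#' pseudo-random), one unscored lead-in per block, 20 s rests between
#' blocks; a six-dimension workload report after the task.
#'
#' @param responder A `bs_responder`.
#' @param config A [hmw_config()].
#' @param seed Optional integer seed.
#' @return A `bs_session_log` with elements `blocks`, `tlx`, `config`.
#' @export
run_hmw_protocol <- function(responder, config = hmw_config(), seed = NULL) {
  assert_that(inherits(responder, "bs_responder"), "need a bs_responder")
  assert_that(identical(config$protocol, "hmw_blocks"),
              "config must be an hmw_config()")
  with_seed_if(seed, {
    blocks <- vector("list", config$n_blocks)
    for (b in seq_len(config$n_blocks)) {
      cond <- generate_condition_sequence(rep(config$per_condition_per_block, 4))
      trials <- realize_trials(cond, mapping = config$mapping,
                               available_times = config$available_times)
      blk <- run_bs_block(responder, trials, block_index = b - 1L,
                          isi_ms = config$isi_feedback_ms)
      blocks[[b]] <- list(block_index = b - 1L, trials = trials,
                          responses = blk$responses,
                          elapsed_ms = blk$elapsed_ms +
                            if (b < config$n_blocks) config$rest_duration_ms else 0)
    }
    structure(list(protocol = "hmw_blocks", config = config, blocks = blocks,
                   tlx = responder$report_tlx("bs"), truncated = FALSE,
                   seed = seed),
              class = "bs_session_log")
  })
}

#' Run a 2-back comparison session
#'
#' Eight blocks of 10 letters each (8 scorable trials per block, 50% 2-back
#' match rate), fixed pacing of 0.5 s letter + 2 s blank and no feedback;
#' responses are accepted any time within the 2.5 s window. A workload
#' report follows the task.
#'
#' @param responder A `bs_responder`.
#' @param n_blocks Number of blocks (default 8).
#' @param n_scorable_per_block Scorable trials per block (default 8; two
#'   lead-in letters are added).
#' @param match_rate 2-back match rate (default 0.5).
#' @param rest_duration_ms Inter-block rest (default 20000).
#' @param seed Optional integer seed.
#' @return A `bs_session_log` with 2-back blocks and `tlx`.
#' @export
run_2back_session <- function(responder, n_blocks = 8, n_scorable_per_block = 8,
                              match_rate = 0.5, rest_duration_ms = 20000,
                              seed = NULL) {
  with_seed_if(seed, {
    window <- 2500
    blocks <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      seq2 <- generate_2back_sequence(n_scorable_per_block + 2L, match_rate)
      resp <- responder$respond_2back(seq2, b - 1L)
      assert_that(all(resp$rt_ms >= 0),
                  "protocol error: responder returned negative RT")
      scorable <- !is.na(seq2$is_match)
      answered <- !is.na(resp$key) & resp$rt_ms <= window
      truth <- ifelse(isTRUE_na(seq2$is_match), "match", "nonmatch")
      correct <- ifelse(!scorable | !answered, NA, resp$key == truth)
      responses <- data.frame(trial_index = seq2$index,
                              key = ifelse(answered, resp$key, NA_character_),
                              rt_ms = ifelse(answered, resp$rt_ms, NA_real_),
                              correct = correct, stringsAsFactors = FALSE)
      blocks[[b]] <- list(block_index = b - 1L, trials = seq2,
                          responses = responses,
                          elapsed_ms = nrow(seq2) * window +
                            if (b < n_blocks) rest_duration_ms else 0)
    }
    structure(list(protocol = "2back", blocks = blocks,
                   tlx = responder$report_tlx("2back"), truncated = FALSE,
                   seed = seed),
              class = "bs_session_log")
  })
}

#' Run the unlimited-deadline full task (calibration data collection)
#'
#' One 121-trial session (one lead-in plus 30 scored trials per condition)
#' with no response deadline, as used to measure per-condition required
#' times.
#'
#' @param responder A `bs_responder`.
#' @param mapping Key mapping.
#' @param seed Optional integer seed.
#' @return A `bs_session_log` with a single block.
#' @export
run_calibration_session <- function(responder, mapping = key_mapping("A"),
                                    seed = NULL) {
  with_seed_if(seed, {
    trials <- bs_task_trials(mapping = mapping, available_times = NULL)
    blk <- run_bs_block(responder, trials, block_index = 0)
    structure(list(protocol = "calibration",
                   blocks = list(list(block_index = 0L, trials = trials,
                                      responses = blk$responses,
                                      elapsed_ms = blk$elapsed_ms)),
                   truncated = FALSE, seed = seed),
              class = "bs_session_log")
  })
}

#' Extract trial-level RT observations from calibration sessions
#'
#' Flattens a list of unlimited-deadline session logs into the observation
#' table [calibrate()] consumes.
#'
#' @param logs List of `bs_session_log` objects.
#' @return Data frame `participant_id`, `condition`, `rt_ms`, `correct`.
#' @export
session_rt_observations <- function(logs) {
  do.call(rbind, lapply(logs, function(log) {
    rows <- lapply(log$blocks, function(blk) {
      sc <- blk$trials[blk$trials$scored, , drop = FALSE]
      data.frame(participant_id = log$participant_id %||% "P001",
                 condition = sc$condition,
                 rt_ms = blk$responses$rt_ms,
                 correct = !is.na(blk$responses$correct) & blk$responses$correct,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
}

#' @export
print.bs_session_log <- function(x, ...) {
  cat("<bs_session_log>", x$protocol,
      if (!is.null(x$participant_id)) paste0("(", x$participant_id, ")"), "\n")
  n_sc <- vapply(x$blocks, function(b) sum(b$trials$scored %||% NA), 1)
  cat("  blocks:", length(x$blocks),
      "| scored trials:", sum(n_sc, na.rm = TRUE), "\n")
  if (!is.null(x$vas)) cat("  VAS records:", nrow(x$vas), "\n")
  if (!is.null(x$pvt$pre)) {
    cat("  PVT trials: pre", nrow(x$pvt$pre), "/ post",
        if (is.null(x$pvt$post)) 0 else nrow(x$pvt$post), "\n")
  }
  if (isTRUE(x$truncated)) cat("  [truncated]\n")
  invisible(x)
}
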