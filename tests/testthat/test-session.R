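test_that("block execution yields the feedback trichotomy with correct semantics", {
  fb <- feedback_symbols()
  at <- default_available_times()
  trials <- realize_trials(c(1L, 2L, 3L, 4L), available_times = at, seed = 1)

  fast <- run_bs_block(perfect_responder(rt_ms = 1), trials)
  expect_true(all(fast$responses$feedback == fb["correct"]))

  slow <- run_bs_block(scripted_responder(bs_rts = 5000), trials)
  expect_true(all(slow$responses$feedback == fb["no_response"]))
  expect_true(all(is.na(slow$responses$key)))
  expect_true(all(is.na(slow$responses$correct)))

  wrong <- run_bs_block(scripted_responder(bs_rts = 100,
                                           bs_keys = c("F", "F", "F", "F")),
                        trials)
  sc <- trials[trials$scored, ]
  expect_equal(wrong$responses$feedback,
               unname(ifelse(sc$expected_key == "F", fb["correct"],
                             fb["incorrect"])))
  # every scored trial got exactly one of the three symbols
  expect_true(all(rbind(fast$responses, slow$responses,
                        wrong$responses)$feedback %in% fb))

  neg <- new_responder(list(respond_bs = function(trials, block_index) {
    data.frame(key = trials$expected_key, rt_ms = -1)
  }))
  expect_error(run_bs_block(neg, trials), "negative RT")
})

test_that("the block clock is conserved: sum of capped RTs, ISIs and lead-in", {
  at <- c(`1` = 2300, `2` = 3000, `3` = 2600, `4` = 2800)
  trials <- realize_trials(c(1L, 2L, 3L), available_times = at, seed = 2)
  blk <- run_bs_block(scripted_responder(bs_rts = c(1000, 9999, 2000)), trials,
                      isi_ms = 500)
  # hand-summed: lead-in shows for the rounded mean of the block's deadlines
  # (mean(2300, 3000, 2600) = 2633.33 -> 2633), then 1000 + min(9999, 3000)
  # + 2000, plus 3 ISIs of 500
  expect_equal(blk$elapsed_ms, 2633 + 1000 + 3000 + 2000 + 3 * 500)

  # unlimited mode: no deadline capping, lead-in free
  unlim <- realize_trials(c(1L, 2L, 3L), seed = 2)
  blk2 <- run_bs_block(scripted_responder(bs_rts = c(1000, 9999, 2000)), unlim,
                       isi_ms = 500)
  expect_equal(blk2$elapsed_ms, 1000 + 9999 + 2000 + 3 * 500)
})

test_that("practice gate passes perfect responders and blocks chance responders", {
  perfect <- run_practice(perfect_responder(), seed = 1)
  expect_true(perfect$passed)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$attempts, 1)

  always <- run_practice(noisy_key_responder(accuracy = 0), gate = 0,
                         max_attempts = 1, seed = 2)
  expect_true(always$passed)   # gate 0 always passes

  # a coin-flipping responder must reach 15/16 to clear the 0.9 gate;
  # per attempt that has probability pbinom(14, 16, .5, lower = FALSE)
  p_attempt <- pbinom(14, 16, 0.5, lower.tail = FALSE)
  expect_lt(p_attempt, 3e-4)
  fails <- vapply(1:10, function(s) {
    !run_practice(noisy_key_responder(accuracy = 0.5), max_attempts = 3,
                  seed = s)$passed
  }, TRUE)
  expect_true(all(fails))
})

test_that("PVT flags validity at 100 ms and lapses at 500 ms", {
  scripted <- scripted_responder(pvt_rts = c(250, 99, 600))
  pvt <- run_pvt(scripted, duration_ms = 20000, seed = 3)
  expect_gte(nrow(pvt), 3)
  expect_equal(pvt$valid[1:3], c(TRUE, FALSE, TRUE))
  expect_equal(pvt$lapse[1:3], c(FALSE, FALSE, TRUE))
  expect_true(all(pvt$lapse <= pvt$valid))  # lapse implies valid

  clean <- run_pvt(scripted_responder(pvt_rts = 250), seed = 4)
  expect_true(all(clean$valid))
  expect_equal(sum(clean$lapse), 0)
})

test_that("PVT trial count follows the event clock", {
  pvt <- run_pvt(scripted_responder(pvt_rts = 250), duration_ms = 180000,
                 interval_bounds = c(2000, 10000), seed = 5)
  expect_true(all(pvt$foreperiod_ms >= 2000 & pvt$foreperiod_ms <= 10000))
  # clock conservation: recorded elapsed equals the sum of trial components
  expect_equal(attr(pvt, "elapsed_ms"), sum(pvt$foreperiod_ms + pvt$rt_ms))
  # every delivered trial started before the deadline, and the mean-rate
  # prediction duration / (mean interval + RT) holds within +/- 2 trials
  starts <- cumsum(pvt$foreperiod_ms + pvt$rt_ms) - (pvt$foreperiod_ms + pvt$rt_ms)
  expect_true(all(starts < 180000))
  predicted <- 180000 / (mean(pvt$foreperiod_ms) + 250)
  expect_lte(abs(nrow(pvt) - predicted), 2)
})

test_that("the time-on-task protocol has the published session structure", {
  log <- run_tot_protocol(sim_responder(), seed = 11)
  expect_s3_class(log, "bs_session_log")
  expect_length(log$blocks, 6)
  # 7 scale administrations (baseline + one per block) x 4 items
  expect_equal(nrow(log$vas), 28)
  expect_equal(sort(unique(log$vas$block)), 0:6)
  expect_false(is.null(log$pvt$pre))
  expect_false(is.null(log$pvt$post))

  for (blk in log$blocks) {
    sc <- blk$trials[blk$trials$scored, ]
    # balanced batches: within a block every condition appears equally often
    expect_equal(length(unique(table(sc$condition))), 1)
    # the block never starts a batch after its clock expired
    expect_lte(blk$elapsed_ms, tot_config()$block_duration_ms + 4 * 3500 + 2700)
    # one response per scored trial
    expect_equal(nrow(blk$responses), nrow(sc))
    # conditions are faithful after chaining and truncation
    expect_identical(rescore_conditions(blk$trials), sc$condition)
  }
  # block sizes differ only by whole batches
  sizes <- vapply(log$blocks, function(b) sum(b$trials$scored), 1)
  expect_true(all(sizes %% 4 == 0))
  expect_lte(max(sizes) - min(sizes), 12)
})

test_that("sessions replay bit-identically from the same seed", {
  a <- run_tot_protocol(sim_responder(), seed = 21)
  b <- run_tot_protocol(sim_responder(), seed = 21)
  expect_identical(a$vas, b$vas)
  expect_identical(a$blocks, b$blocks)
  expect_identical(a$pvt, b$pvt)
})

test_that("a responder failure mid-session yields a truncated partial log", {
  expect_warning(
    log <- run_tot_protocol(failing_responder(fail_at_block_index = 2), seed = 8),
    "truncated")
  expect_true(log$truncated)
  expect_length(log$blocks, 2)
  expect_null(log$pvt$post)
})

test_that("the blocked comparison protocol runs 8 blocks of 8 scored trials", {
  log <- run_hmw_protocol(sim_responder(), seed = 13)
  expect_length(log$blocks, 8)
  for (blk in log$blocks) {
    sc <- blk$trials[blk$trials$scored, ]
    expect_equal(nrow(sc), 8)
    expect_equal(as.vector(table(sc$condition)), rep(2L, 4))
  }
  # inter-block rest is on the clock for all but the last block
  expect_gte(log$blocks[[1]]$elapsed_ms, 20000)
  expect_lt(log$blocks[[8]]$elapsed_ms, 20000 + 8 * 3500 + 2700)
  expect_length(log$tlx, 6)
  expect_true(all(log$tlx >= 0 & log$tlx <= 20))
})

test_that("the 2-back session paces trials and scores against the 2-back rule", {
  log <- run_2back_session(sim_responder(), seed = 17)
  expect_length(log$blocks, 8)
  for (blk in log$blocks) {
    expect_equal(nrow(blk$trials), 10)
    scorable <- !is.na(blk$trials$is_match)
    expect_equal(sum(scorable), 8)
    expect_true(all(is.na(blk$responses$correct[!scorable])))
    # independent re-score from the letter stream
    truth <- blk$trials$letter[3:10] == blk$trials$letter[1:8]
    answered <- !is.na(blk$responses$key[scorable])
    got <- blk$responses$key[scorable] == ifelse(truth, "match", "nonmatch")
    expect_equal(blk$responses$correct[scorable][answered], got[answered])
  }
})
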