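make_obs <- function(participant, condition, rt, correct = TRUE) {
  data.frame(participant_id = participant, condition = condition, rt_ms = rt,
             correct = correct, stringsAsFactors = FALSE)
}

test_that("incorrect trials are removed first, order preserved", {
  obs <- make_obs("P1", 1, c(900, 1000, 1100, 1200), c(TRUE, FALSE, TRUE, FALSE))
  kept <- filter_correct(obs)
  expect_equal(kept$rt_ms, c(900, 1100))
  expect_identical(filter_correct(kept), kept)           # all-correct: identity
  expect_equal(nrow(filter_correct(obs[0, ])), 0)        # empty in, empty out
})

test_that("trial-level 3SD screening removes exactly the extreme trials", {
  # identical RTs: SD = 0, bounds collapse onto the mean, nothing removed
  same <- make_obs("P1", 1, rep(2000, 20))
  expect_equal(nrow(remove_trial_outliers(same)), 20)

  rts <- c(rep(1000, 19), 10000)
  grp <- make_obs("P1", 1, rts)
  # independent check that 10000 actually exceeds mean + 3SD of the group
  expect_gt(10000, mean(rts) + 3 * sd(rts))
  out <- remove_trial_outliers(grp)
  expect_equal(out$rt_ms, rep(1000, 19))
  expect_equal(attr(out, "n_removed"), 1L)

  # all values within 1 SD: identity
  mild <- make_obs("P1", 1, seq(900, 1100, length.out = 10))
  expect_equal(nrow(remove_trial_outliers(mild)), 10)

  # screening is per (participant, condition): the same RT can be an outlier
  # in a tight group but not in a wide one
  two <- rbind(make_obs("P1", 1, c(rep(1000, 19), 2000)),
               make_obs("P2", 1, c(seq(500, 3000, length.out = 20))))
  out2 <- remove_trial_outliers(two)
  expect_false(2000 %in% out2$rt_ms[out2$participant_id == "P1"])
  expect_true(any(abs(out2$rt_ms[out2$participant_id == "P2"] - 2000) < 70))

  expect_warning(remove_trial_outliers(make_obs("P1", 1, 1000)), "singleton")
})

test_that("group-level screening drops whole participants with extreme means", {
  means <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:20), each = 4),
    condition = rep(1:4, 20),
    mean_rt_ms = rep(c(1800, 2400, 2100, 2250), 20) + rnorm(80, 0, 30)
  )
  all_kept <- remove_group_outliers(means)
  expect_length(all_kept$excluded_participants, 0)
  expect_equal(nrow(all_kept$retained), 80)

  means$mean_rt_ms[means$participant_id == "P07" & means$condition == 2] <- 20000
  grp2 <- means$mean_rt_ms[means$condition == 2]
  expect_gt(20000, mean(grp2) + 3 * sd(grp2))   # independently an outlier
  one_out <- remove_group_outliers(means)
  expect_identical(one_out$excluded_participants, "P07")
  expect_equal(nrow(one_out$retained), 76)      # the whole participant dropped

  expect_error(remove_group_outliers(means[means$participant_id == "P01", ]),
               "2 participants")
})

test_that("a 100-participant cohort with 6 planted outliers loses exactly 6", {
  set.seed(404)
  means <- expand.grid(participant_id = sprintf("P%03d", 1:100), condition = 1:4)
  means$mean_rt_ms <- c(1800, 2400, 2100, 2250)[means$condition] + rnorm(400, 0, 120)
  planted <- sprintf("P%03d", c(4, 19, 33, 52, 76, 98))
  for (i in seq_along(planted)) {
    hit <- means$participant_id == planted[i] & means$condition == ((i %% 4) + 1)
    means$mean_rt_ms[hit] <- 15000
  }
  res <- remove_group_outliers(means)
  expect_setequal(res$excluded_participants, planted)
  expect_equal(length(unique(res$retained$participant_id)), 94)
})

test_that("available time is 1.25 x mean RT rounded half-up to the quantum", {
  expect_equal(compute_available_time(1815.63), 2300)
  expect_equal(compute_available_time(2394.17), 3000)
  expect_equal(compute_available_time(2110.47), 2600)  # rounds down
  expect_equal(compute_available_time(2251.46), 2800)
  expect_equal(compute_available_time(1000, rounding_quantum_ms = 1), 1250)
  # half-up at an exact .5 boundary: 1.25 * 1000 = 1250 -> 1300, not 1200
  expect_equal(compute_available_time(1000, rounding_quantum_ms = 100), 1300)
  # unrounded ratio identity RT / AT = 0.8
  for (m in c(812.3, 1500, 2987.1)) {
    expect_equal(m / compute_available_time(m, rounding_quantum_ms = 1e-9), 0.8,
                 tolerance = 1e-9)
  }
  expect_error(compute_available_time(-5), "positive")
  expect_error(compute_available_time(1000, pressure_factor = 0), "positive")
})

test_that("the full calibration pipeline matches independently computed means", {
  set.seed(77)
  true_mean <- c(1800, 2400, 2100, 2250)
  obs <- do.call(rbind, lapply(1:24, function(p) {
    do.call(rbind, lapply(1:4, function(cond) {
      data.frame(participant_id = sprintf("P%02d", p), condition = cond,
                 rt_ms = rlnorm(30, log(true_mean[cond]) - 0.02, 0.2),
                 correct = runif(30) > 0.08, stringsAsFactors = FALSE)
    }))
  }))
  cal <- calibrate(obs)
  # oracle: recompute the pipeline means by explicit grouping
  kept <- obs[obs$correct, ]
  grp <- split(kept, list(kept$participant_id, kept$condition))
  kept <- do.call(rbind, lapply(grp, function(g) {
    g[abs(g$rt_ms - mean(g$rt_ms)) <= 3 * sd(g$rt_ms), ]
  }))
  pm <- aggregate(rt_ms ~ participant_id + condition, kept, mean)
  oracle_means <- tapply(pm$rt_ms, pm$condition, mean)
  expect_equal(as.numeric(cal$mean_rt_ms), as.numeric(oracle_means),
               tolerance = 1e-12)
  expect_equal(as.numeric(cal$available_time_ms),
               as.numeric(round(1.25 * oracle_means / 100) * 100))
  expect_equal(cal$n_participants_retained, 24)

  # planted trial- and participant-level outliers barely move the result
  dirty <- rbind(obs,
                 data.frame(participant_id = "P01", condition = 1,
                            rt_ms = 60000, correct = TRUE),
                 do.call(rbind, lapply(1:4, function(cond) {
                   data.frame(participant_id = "P99", condition = cond,
                              rt_ms = rlnorm(30, log(30000), 0.05),
                              correct = TRUE)
                 })))
  cal2 <- calibrate(dirty)
  expect_true("P99" %in% cal2$excluded_participants)
  expect_equal(as.numeric(cal2$mean_rt_ms), as.numeric(cal$mean_rt_ms),
               tolerance = 0.02)
  expect_equal(as.numeric(cal2$available_time_ms),
               as.numeric(cal$available_time_ms), tolerance = 0.05)
})

test_that("pipeline stages only ever shrink the observation set", {
  set.seed(5)
  obs <- make_obs(rep(c("P1", "P2", "P3"), each = 40),
                  rep(rep(1:4, each = 10), 3),
                  rlnorm(120, log(2000), 0.3),
                  runif(120) > 0.1)
  s1 <- filter_correct(obs)
  s2 <- remove_trial_outliers(s1)
  expect_lte(nrow(s1), nrow(obs))
  expect_lte(nrow(s2), nrow(s1))
  # retained rows are a subset of the previous stage
  key <- function(d) paste(d$participant_id, d$condition, d$rt_ms)
  expect_true(all(key(s2) %in% key(s1)))
  expect_true(all(key(s1) %in% key(obs)))
})
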