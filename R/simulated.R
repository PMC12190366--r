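#' Parameters of the stochastic simulated participant
#'
#' The simulated participant is a generative stand-in that makes every
#' protocol exercisable at desk scale. Task reaction times follow a
#' lognormal kernel per condition (moment-matched to a target mean/SD);
#' time-on-task fatigue is a linear-in-block drift that inflates RT by a
#' fraction `d_rt` and lowers accuracy by `d_acc` per block; PVT responses
#' are a lapse mixture; subjective fatigue follows a saturating-exponential
#' trajectory (largest increment in the first block, then diminishing).
#'
#' The default preset emulates the scale of the paradigm's published
#' behaviour (deadline-pressured RTs around 1.2-1.6 s, block accuracy in the
#' low 90s declining by a few points over 30 minutes, PVT means near 275 ms
#' with rare lapses that multiply after the task). It is an emulation for
#' engine exercise, not a reproduction of any human data set.
#'
#' @param bs_mean_rt_ms,bs_sd_rt_ms Length-4 numeric: per-condition RT
#'   moments (ms) under time pressure.
#' @param bs_unlimited_mean_rt_ms,bs_unlimited_sd_rt_ms Per-condition RT
#'   moments without a response deadline (calibration mode).
#' @param base_accuracy Length-4 numeric in `[0, 1]`: first-block accuracy
#'   per condition.
#' @param d_rt Fractional RT increase per block index (block 1 has index 0).
#' @param d_acc Absolute accuracy decrease per block index.
#' @param pvt_mean_rt_ms,pvt_sd_rt_ms PVT base kernel moments (ms).
#' @param pvt_lapse_prob Per-trial lapse probability in the pre-task phase.
#' @param pvt_post_lapse_multiplier Multiplier on the lapse probability after
#'   the fatigue-induction task.
#' @param vas Named list (one entry per VAS item) of lists with `baseline`,
#'   `asymptote`, `rate`, `noise_sd`: the reported mean at block b is
#'   `baseline + asymptote * (1 - exp(-rate * b))` plus Gaussian noise,
#'   clamped to 0-100 and rounded to the scale's unit.
#' @param back2_mean_rt_ms,back2_sd_rt_ms,back2_accuracy 2-back comparison
#'   task kernel.
#' @param tlx_mean_bs,tlx_mean_2back,tlx_sd Workload-scale report means (per
#'   dimension, 0-20) and common SD.
#' @return An object of class `bs_responder_params`.
#' @export
responder_params <- function(bs_mean_rt_ms = c(1200, 1550, 1350, 1450),
                             bs_sd_rt_ms = c(320, 400, 360, 380),
                             bs_unlimited_mean_rt_ms = c(1815, 2395, 2110, 2250),
                             bs_unlimited_sd_rt_ms = c(460, 560, 520, 540),
                             base_accuracy = c(0.96, 0.93, 0.95, 0.95),
                             d_rt = 0.01,
                             d_acc = 0.006,
                             pvt_mean_rt_ms = 272,
                             pvt_sd_rt_ms = 40,
                             pvt_lapse_prob = 0.005,
                             pvt_post_lapse_multiplier = 3.5,
                             vas = list(
                               mental_fatigue = list(baseline = 5, asymptote = 57,
                                                     rate = 0.45, noise_sd = 6),
                               mental_effort = list(baseline = 25, asymptote = 38,
                                                    rate = 0.55, noise_sd = 8),
                               mental_stress = list(baseline = 8, asymptote = 18,
                                                    rate = 0.35, noise_sd = 6),
                               boredom = list(baseline = 3, asymptote = 17,
                                              rate = 0.30, noise_sd = 4)
                             ),
                             back2_mean_rt_ms = 900,
                             back2_sd_rt_ms = 230,
                             back2_accuracy = 0.955,
                             tlx_mean_bs = c(11.6, 3.1, 9.1, 6.3, 12.8, 7.7),
                             tlx_mean_2back = c(9.9, 3.2, 7.0, 4.9, 11.4, 6.1),
                             tlx_sd = 3) {
  p <- list(
    bs_mean_rt_ms = bs_mean_rt_ms, bs_sd_rt_ms = bs_sd_rt_ms,
    bs_unlimited_mean_rt_ms = bs_unlimited_mean_rt_ms,
    bs_unlimited_sd_rt_ms = bs_unlimited_sd_rt_ms,
    base_accuracy = base_accuracy, d_rt = d_rt, d_acc = d_acc,
    pvt_mean_rt_ms = pvt_mean_rt_ms, pvt_sd_rt_ms = pvt_sd_rt_ms,
    pvt_lapse_prob = pvt_lapse_prob,
    pvt_post_lapse_multiplier = pvt_post_lapse_multiplier,
    vas = vas,
    back2_mean_rt_ms = back2_mean_rt_ms, back2_sd_rt_ms = back2_sd_rt_ms,
    back2_accuracy = back2_accuracy,
    tlx_mean_bs = tlx_mean_bs, tlx_mean_2back = tlx_mean_2back, tlx_sd = tlx_sd
  )
  assert_that(all(p$base_accuracy >= 0 & p$base_accuracy <= 1),
              "accuracies must be in [0, 1]")
  assert_that(p$pvt_lapse_prob >= 0 && p$pvt_lapse_prob <= 1,
              "lapse probability must be in [0, 1]")
  assert_that(all(c(bs_sd_rt_ms, pvt_sd_rt_ms) > 0), "scales must be positive")
  assert_that(all(vapply(p$vas, function(v) v$asymptote >= 0 &&
                           v$asymptote <= 100, TRUE)),
              "VAS asymptotes must be in [0, 100]")
  structure(p, class = "bs_responder_params")
}

# Lognormal meanlog/sdlog matched to a target mean m and SD s.
lnorm_pars <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# Lognormal draws with target arithmetic mean/SD (vectorised over kernels).
rlnorm_ms <- function(n, m, s) {
  lp <- lnorm_pars(m, s)
  rlnorm(n, lp$meanlog, lp$sdlog)
}

#' Draw simulated task responses for a set of trials
#'
#' RTs come from the condition's lognormal kernel, scaled by
#' `1 + d_rt * block_index`; the expected key is pressed with probability
#' `base_accuracy[condition] - d_acc * block_index`, the other key otherwise.
#' Trials with no deadline (`available_time_ms` is `NA`) use the unlimited
#' kernel without drift (calibration mode).
#'
#' @param trials Scored `bs_trials` rows.
#' @param block_index 0-based block position (block 1 = 0).
#' @param params A [responder_params()] object.
#' @return Data frame with columns `key`, `rt_ms`.
#' @export
respond_bs <- function(trials, block_index, params = responder_params()) {
  n <- nrow(trials)
  cond <- trials$condition
  unlimited <- is.na(trials$available_time_ms)
  m <- ifelse(unlimited, params$bs_unlimited_mean_rt_ms[cond],
              params$bs_mean_rt_ms[cond] * (1 + params$d_rt * block_index))
  s <- ifelse(unlimited, params$bs_unlimited_sd_rt_ms[cond],
              params$bs_sd_rt_ms[cond] * (1 + params$d_rt * block_index))
  rt <- rlnorm_ms(n, m, s)
  drop <- rep(params$d_acc * block_index, n)
  drop[unlimited] <- 0
  acc <- clamp(params$base_accuracy[cond] - drop, 0, 1)
  ok <- runif(n) < acc
  key <- trials$expected_key
  key[!ok] <- c(F = "J", J = "F")[key[!ok]]
  quick_df(list(key = key, rt_ms = rt))
}

#' Draw simulated PVT reaction times
#'
#' Mixture model: with the phase's lapse probability (base probability times
#' the post-task multiplier in phase `"post"`) the RT is a lapse draw of at
#' least 500 ms (500 + exponential, mean 100); otherwise it comes from the
#' base lognormal kernel truncated at 100 ms.
#'
#' @param n Number of trials.
#' @param phase `"pre"` or `"post"`.
#' @param params A [responder_params()] object.
#' @return Numeric vector of RTs (ms).
#' @export
respond_pvt <- function(n, phase = c("pre", "post"), params = responder_params()) {
  phase <- match.arg(phase)
  p_lapse <- params$pvt_lapse_prob *
    if (phase == "post") params$pvt_post_lapse_multiplier else 1
  p_lapse <- min(p_lapse, 1)
  lapse <- runif(n) < p_lapse
  rt <- rlnorm_ms(n, params$pvt_mean_rt_ms, params$pvt_sd_rt_ms)
  for (i in which(rt < 100)) {           # truncate the base kernel at 100 ms
    while (rt[i] < 100) rt[i] <- rlnorm_ms(1, params$pvt_mean_rt_ms,
                                           params$pvt_sd_rt_ms)
  }
  rt[lapse] <- 500 + rexp(sum(lapse), rate = 1 / 100)
  rt
}

#' Draw a simulated subjective-scale report
#'
#' Mean trajectory `baseline + asymptote * (1 - exp(-rate * block))`: the
#' increment between consecutive blocks is strictly decreasing, emulating
#' the diminishing growth of reported fatigue over time on task. Gaussian
#' noise is added, then the value is clamped to 0-100 and rounded to the
#' scale's 1-unit resolution.
#'
#' @param block_index 0 for baseline, 1.. for post-block reports.
#' @param item VAS item name (must be a name of `params$vas`).
#' @param params A [responder_params()] object.
#' @return Integer in 0..100.
#' @export
report_vas <- function(block_index, item, params = responder_params()) {
  assert_that(block_index >= 0, "block_index must be >= 0")
  v <- params$vas[[item]]
  assert_that(!is.null(v), paste("unknown VAS item:", item))
  m <- v$baseline + v$asymptote * (1 - exp(-v$rate * block_index))
  as.integer(round_half_up(clamp(m + rnorm(1, 0, v$noise_sd), 0, 100)))
}

#' Wrap the simulated participant model as a responder
#'
#' @param params A [responder_params()] object.
#' @return A `bs_responder` whose callbacks draw from the model; randomness
#'   comes from the session RNG stream (seed the session, not the responder).
#' @export
sim_responder <- function(params = responder_params()) {
  new_responder(list(
    respond_bs = function(trials, block_index) respond_bs(trials, block_index, params),
    respond_pvt = function(n, phase) respond_pvt(n, phase, params),
    respond_2back = function(trials, block_index) {
      n <- nrow(trials)
      ok <- runif(n) < params$back2_accuracy
      truth <- ifelse(isTRUE_na(trials$is_match), "match", "nonmatch")
      key <- ifelse(ok, truth, ifelse(truth == "match", "nonmatch", "match"))
      data.frame(key = key,
                 rt_ms = pmin(rlnorm_ms(n, params$back2_mean_rt_ms,
                                        params$back2_sd_rt_ms), 2500),
                 stringsAsFactors = FALSE)
    },
    report_vas = function(block_index, items) {
      stats::setNames(vapply(items, function(it)
        report_vas(block_index, it, params), 1L), items)
    },
    report_tlx = function(task) {
      m <- if (task == "bs") params$tlx_mean_bs else params$tlx_mean_2back
      stats::setNames(clamp(round_half_up(rnorm(6, m, params$tlx_sd)), 0, 20),
                      tlx_dimensions())
    }
  ))
}

#' Simulate a cohort of session logs
#'
#' Draws per-participant parameters around a preset (between-participant
#' heterogeneity), runs the requested protocol once per participant, and
#' returns the session logs the analysis pipeline consumes. Fully
#' reproducible from `seed`; each participant gets a derived seed, so cohort
#' members are independent but replayable.
#'
#' @param n_participants Cohort size (>= 1).
#' @param protocol `"tot"` (30-min fatigue induction), `"hmw"` (blocked
#'   workload comparison) or `"calibration"` (unlimited-deadline full task).
#' @param params Preset [responder_params()].
#' @param jitter Named list of between-participant spreads: `rt_cv`
#'   (lognormal coefficient of variation on RT means), `acc_sd` (Gaussian SD
#'   on accuracies), `vas_asym_sd`, `vas_rate_cv`, `pvt_rt_sd`.
#'   Use zeros for a homogeneous cohort.
#' @param config Optional protocol config ([tot_config()] / [hmw_config()]).
#' @param seed Integer seed.
#' @return List of `bs_session_log` objects (length `n_participants`).
#' @export
generate_cohort <- function(n_participants, protocol = c("tot", "hmw", "calibration"),
                            params = responder_params(),
                            jitter = list(rt_cv = 0.18, acc_sd = 0.025,
                                          vas_asym_sd = 18, vas_rate_cv = 0.3,
                                          pvt_rt_sd = 25),
                            config = NULL, seed = NULL) {
  protocol <- match.arg(protocol)
  assert_that(is_scalar_number(n_participants) && n_participants >= 1,
              "n_participants must be >= 1")
  base_seed <- if (is.null(seed)) sample.int(2^31 - 1, 1) else seed
  lapply(seq_len(n_participants), function(i) {
    pseed <- derive_seed(base_seed, i)
    withr::with_seed(pseed, {
      pp <- jitter_params(params, jitter)
      resp <- sim_responder(pp)
      log <- switch(protocol,
        tot = run_tot_protocol(resp, config = config %||% tot_config()),
        hmw = run_hmw_protocol(resp, config = config %||% hmw_config()),
        calibration = run_calibration_session(resp)
      )
      log$participant_id <- sprintf("P%03d", i)
      log$seed <- pseed
      log
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

jitter_params <- function(params, jitter) {
  j <- utils::modifyList(list(rt_cv = 0, acc_sd = 0, vas_asym_sd = 0,
                              vas_rate_cv = 0, pvt_rt_sd = 0), jitter)
  p <- params
  if (j$rt_cv > 0) {
    f <- rlnorm_ms(1, 1, j$rt_cv)
    p$bs_mean_rt_ms <- p$bs_mean_rt_ms * f
    p$bs_unlimited_mean_rt_ms <- p$bs_unlimited_mean_rt_ms * f
  }
  if (j$acc_sd > 0) {
    p$base_accuracy <- clamp(p$base_accuracy + rnorm(4, 0, j$acc_sd), 0.5, 0.995)
  }
  if (j$vas_asym_sd > 0 || j$vas_rate_cv > 0) {
    p$vas <- lapply(p$vas, function(v) {
      v$asymptote <- clamp(v$asymptote + rnorm(1, 0, j$vas_asym_sd), 0, 100)
      if (j$vas_rate_cv > 0) v$rate <- v$rate * rlnorm_ms(1, 1, j$vas_rate_cv)
      v
    })
  }
  if (j$pvt_rt_sd > 0) {
    p$pvt_mean_rt_ms <- max(120, p$pvt_mean_rt_ms + rnorm(1, 0, j$pvt_rt_sd))
  }
  p
}
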