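# Independent textbook-formula oracles and fixture builders. These stay
# deliberately naive (explicit sums, no shared code with the package) so
# they can serve as from-scratch cross-checks.

# Friedman chi-square from the rank-sum formula (assumes no within-row ties).
oracle_friedman_chisq <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  R <- colSums(t(apply(mat, 1, rank)))
  12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
}

# Kendall's W straight from rank sums (no-tie formulation).
oracle_kendalls_w_ranks <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  R <- colSums(t(apply(mat, 1, rank)))
  (12 * sum(R^2) - 3 * n^2 * k * (k + 1)^2) / (n^2 * k * (k^2 - 1))
}

# One-way within-subject ANOVA by explicit sums-of-squares decomposition.
oracle_rm_anova <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  gm <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - gm)^2)
  ss_subj <- k * sum((rowMeans(mat) - gm)^2)
  ss_tot <- sum((mat - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  list(F = f, df1 = df1, df2 = df2,
       partial_eta_sq = ss_cond / (ss_cond + ss_err),
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Greenhouse-Geisser epsilon from the sample covariance matrix.
oracle_gg_epsilon <- function(mat) {
  S <- stats::cov(mat)
  k <- ncol(S)
  sbar <- mean(S)
  sdiag <- mean(diag(S))
  srow <- rowMeans(S)
  num <- k^2 * (sdiag - sbar)^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(srow^2) + k^2 * sbar^2)
  num / den
}

# Spearman rho as Pearson correlation of average ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Minimal hand-built session log (one block) for metric tests.
make_tiny_log <- function(feedback, rt_ms = rep(1000, length(feedback))) {
  fb <- feedback_symbols()
  stopifnot(all(feedback %in% fb))
  n <- length(feedback)
  trials <- data.frame(
    index = seq_len(n), grid_cell = 0L, ink_color = "red", word = "red",
    back_consistent = TRUE, stroop_congruent = TRUE, condition = 1L,
    expected_key = "F", available_time_ms = 2300, scored = TRUE,
    stringsAsFactors = FALSE
  )
  responses <- data.frame(
    trial_index = seq_len(n),
    key = ifelse(feedback == fb["no_response"], NA, "F"),
    rt_ms = ifelse(feedback == fb["no_response"], NA, rt_ms),
    correct = ifelse(feedback == fb["no_response"], NA,
                     feedback == fb["correct"]),
    feedback = feedback, stringsAsFactors = FALSE
  )
  structure(list(protocol = "tot_induction",
                 blocks = list(list(block_index = 0L, trials = trials,
                                    responses = responses,
                                    elapsed_ms = sum(rt_ms))),
                 truncated = FALSE),
            class = "bs_session_log")
}

# A responder whose respond_bs fails on a chosen block (for truncation tests).
failing_responder <- function(fail_at_block_index) {
  base <- sim_responder()
  new_responder(list(
    respond_bs = function(trials, block_index) {
      if (block_index >= fail_at_block_index) stop("responder gave up")
      base$respond_bs(trials, block_index)
    },
    respond_pvt = base$respond_pvt,
    report_vas = base$report_vas
  ))
}
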