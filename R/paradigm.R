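#' Colour palette and word set for the 1-back Stroop task
#'
#' The task uses four ink colours, each of which is also a possible word
#' meaning. Words are stored as colour identities; a display front-end renders
#' them as the corresponding Chinese characters (see [color_characters()]).
#'
#' @return Character vector of the four colour names.
#' @export
bs_palette <- function() c("red", "yellow", "blue", "green")

#' Chinese character rendering table for the colour words
#'
#' Maps each colour identity to the character a front-end would display.
#' The engine itself never consumes these glyphs.
#'
#' @return Named character vector (names are the colour identities).
#' @export
color_characters <- function() {
  c(red = "红", yellow = "黄", blue = "蓝", green = "绿")
}

#' Classify a trial into one of the four task conditions
#'
#' A trial's condition is determined by two binary judgements: whether the
#' stimulus occupies the same grid cell as the previous trial (1-back
#' consistency) and whether the word's meaning matches its ink colour (Stroop
#' congruency). Condition 1: both consistent; condition 2: both inconsistent;
#' condition 3: 1-back consistent, Stroop incongruent; condition 4: 1-back
#' inconsistent, Stroop congruent.
#'
#' @param back_consistent Logical vector; 1-back position match.
#' @param stroop_congruent Logical vector; word/ink match.
#' @return Integer vector of conditions in 1..4.
#' @export
#' @examples
#' classify_condition(TRUE, TRUE)    # 1
#' classify_condition(FALSE, FALSE)  # 2
classify_condition <- function(back_consistent, stroop_congruent) {
  assert_that(is.logical(back_consistent) && is.logical(stroop_congruent),
              "flags must be logical")
  assert_that(length(back_consistent) == length(stroop_congruent),
              "flag vectors must have equal length")
  assert_that(!anyNA(back_consistent) && !anyNA(stroop_congruent),
              "flags must not contain NA")
  out <- integer(length(back_consistent))
  out[back_consistent & stroop_congruent] <- 1L
  out[!back_consistent & !stroop_congruent] <- 2L
  out[back_consistent & !stroop_congruent] <- 3L
  out[!back_consistent & stroop_congruent] <- 4L
  out
}

#' Invert a condition code back to its two judgement flags
#'
#' @param condition Integer vector in 1..4.
#' @return Data frame with logical columns `back_consistent`,
#'   `stroop_congruent`.
#' @export
condition_flags <- function(condition) {
  assert_that(all(condition %in% 1:4), "condition must be in 1..4")
  data.frame(
    back_consistent  = condition %in% c(1L, 3L),
    stroop_congruent = condition %in% c(1L, 4L)
  )
}

#' Construct a response key mapping
#'
#' Key assignment is counterbalanced across participants: variant A presses
#' "F" for conditions 1-2 (the two "both same" XNOR-true cases) and "J" for
#' conditions 3-4; variant B is the reverse.
#'
#' @param variant `"A"` or `"B"`.
#' @return An object of class `bs_key_mapping`.
#' @export
key_mapping <- function(variant = c("A", "B")) {
  variant <- match.arg(variant)
  keys <- if (variant == "A") c(same = "F", diff = "J") else c(same = "J", diff = "F")
  structure(
    list(variant = variant, same_key = unname(keys["same"]),
         diff_key = unname(keys["diff"])),
    class = "bs_key_mapping"
  )
}

#' Expected response key for a condition
#'
#' The correct key is a function of the XNOR of the two judgement flags:
#' conditions 1 and 2 (flags agree) share one key, conditions 3 and 4 (flags
#' disagree) share the other.
#'
#' @param condition Integer vector in 1..4.
#' @param mapping A [key_mapping()] object.
#' @return Character vector of key labels.
#' @export
expected_key <- function(condition, mapping = key_mapping("A")) {
  assert_that(inherits(mapping, "bs_key_mapping"), "mapping must be a bs_key_mapping")
  assert_that(all(condition %in% 1:4), "condition must be in 1..4")
  ifelse(condition %in% c(1L, 2L), mapping$same_key, mapping$diff_key)
}

#' Generate a constrained pseudo-random condition sequence
#'
#' Draws a random permutation of the requested per-condition counts and
#' rejects sequences containing a run of identical conditions longer than
#' `max_run_length`. The bounded-run constraint is the conventional reading
#' of "pseudo-random" balance in task design; it is configurable.
#'
#' @param counts Integer vector of length 4 (or a named map condition ->
#'   count): number of scored trials per condition. Default 30 each, i.e. the
#'   full 120-scored-trial task.
#' @param max_run_length Maximum allowed run of identical consecutive
#'   conditions (default 4).
#' @param seed Optional integer seed; identical `(counts, seed)` give
#'   identical sequences.
#' @param max_tries Rejection-sampling retry cap; exhaustion raises an
#'   infeasibility error.
#' @return Integer vector of conditions whose multiset equals `counts`.
#' @export
generate_condition_sequence <- function(counts = rep(30L, 4), max_run_length = 4,
                                        seed = NULL, max_tries = 10000) {
  assert_that(length(counts) == 4 && all(counts >= 0) && all(counts == floor(counts)),
              "counts must be 4 nonnegative integers")
  assert_that(max_run_length >= 1, "max_run_length must be >= 1")
  pool <- rep(1:4, times = counts)
  if (length(pool) == 0L) return(integer(0))
  with_seed_if(seed, {
    for (i in seq_len(max_tries)) {
      cand <- pool[sample.int(length(pool))]
      if (max(rle(cand)$lengths) <= max_run_length) return(cand)
    }
    stop("infeasible sequence constraints: no ordering with max run length ",
         max_run_length, " found in ", max_tries, " tries", call. = FALSE)
  })
}

# Vectorised within-batch shuffles: `n_batches` consecutive random
# permutations of 1:4, used by the time-on-task block filler.
balanced_condition_batches <- function(n_batches) {
  v <- rep(1:4, times = n_batches)
  v[order(rep(seq_len(n_batches), each = 4), runif(4L * n_batches))]
}

#' Realize a condition sequence into concrete trials
#'
#' Expands an ordered list of conditions into stimuli on the 3x3 grid
#' (cells indexed 0..8, row-major) with ink colours and colour words drawn
#' from the four-colour palette, such that recomputing both judgement flags
#' from the stimuli reproduces the requested condition of every scored trial.
#' Back-inconsistent trials draw their cell uniformly from the 8 cells
#' different from the previous trial's; Stroop-incongruent trials draw their
#' word uniformly from the 3 colours different from the ink.
#'
#' A single unscored lead-in trial (uniform random cell/colour/word,
#' congruency unconstrained, `condition = NA`) is prepended by default so the
#' first scored trial has a 1-back referent; the full default task is
#' therefore 121 trials of which 120 are scored.
#'
#' @param conditions Integer vector of requested conditions (1..4).
#' @param mapping [key_mapping()] used to annotate each scored trial with its
#'   expected key.
#' @param available_times Named numeric vector of per-condition response
#'   deadlines in ms (names `"1"`..`"4"`), or `NULL` for unlimited response
#'   time (calibration mode).
#' @param lead_in Prepend one unscored lead-in trial (default `TRUE`).
#' @param previous Optional list with element `grid_cell`: when `lead_in` is
#'   `FALSE`, the 1-back referent for the first trial (used to chain blocks).
#' @param seed Optional integer seed.
#' @return Data frame of class `bs_trials` with columns `index`, `grid_cell`,
#'   `ink_color`, `word`, `back_consistent`, `stroop_congruent`, `condition`,
#'   `expected_key`, `available_time_ms`, `scored`.
#' @export
realize_trials <- function(conditions, mapping = key_mapping("A"),
                           available_times = NULL, lead_in = TRUE,
                           previous = NULL, seed = NULL) {
  assert_that(length(conditions) >= 1, "conditions must be non-empty")
  assert_that(all(conditions %in% 1:4), "unknown condition label")
  if (!lead_in && is.null(previous)) {
    stop("without a lead-in trial, `previous` must supply the 1-back referent",
         call. = FALSE)
  }
  if (!is.null(available_times)) {
    assert_that(all(as.character(1:4) %in% names(available_times)),
                "available_times must be named '1'..'4'")
    assert_that(all(available_times > 0), "available times must be positive")
  }
  with_seed_if(seed, {
    n <- length(conditions)
    conditions <- as.integer(conditions)
    palette <- bs_palette()
    bc <- conditions == 1L | conditions == 3L
    sc <- conditions == 1L | conditions == 4L

    # Grid-cell chain: consistent trials copy the previous cell; inconsistent
    # trials add a uniform offset in 1..8 (mod 9), which is exactly a uniform
    # draw over the 8 other cells. cumsum makes the recurrence vectorisable.
    start_cell <- if (lead_in) sample.int(9L, 1L) - 1L else as.integer(previous$grid_cell)
    offsets <- integer(n)
    offsets[!bc] <- sample.int(8L, sum(!bc), replace = TRUE)
    cells <- (start_cell + cumsum(offsets)) %% 9L

    ink <- sample.int(4L, n, replace = TRUE)
    word <- ink
    word[!sc] <- ((ink[!sc] - 1L + sample.int(3L, sum(!sc), replace = TRUE)) %% 4L) + 1L

    at <- if (is.null(available_times)) rep(NA_real_, n)
          else unname(available_times[as.character(conditions)])
    ekey <- rep(mapping$diff_key, n)
    ekey[conditions <= 2L] <- mapping$same_key

    if (lead_in) {
      lead_ink <- sample.int(4L, 1L)
      lead_word <- sample.int(4L, 1L)   # congruency unconstrained
      cells <- c(start_cell, cells)
      ink <- c(lead_ink, ink)
      word <- c(lead_word, word)
      bc <- c(NA, bc)
      # the lead-in's Stroop flag is observable even though unscored
      sc <- c(lead_word == lead_ink, sc)
      conditions <- c(NA_integer_, conditions)
      ekey <- c(NA_character_, ekey)
      at <- c(NA_real_, at)
    }
    N <- length(cells)
    out <- quick_df(list(
      index = seq_len(N) - 1L,
      grid_cell = cells,
      ink_color = palette[ink],
      word = palette[word],
      back_consistent = bc,
      stroop_congruent = sc,
      condition = conditions,
      expected_key = ekey,
      available_time_ms = at,
      scored = if (lead_in) c(FALSE, rep(TRUE, n)) else rep(TRUE, n)
    ))
    class(out) <- c("bs_trials", "data.frame")
    attr(out, "mapping") <- mapping
    out
  })
}

#' Recompute judgement flags and conditions directly from stimuli
#'
#' Independent re-scoring of a realized trial list: 1-back consistency is
#' recomputed from consecutive grid cells and Stroop congruency from
#' word/ink equality, then mapped to a condition. Used to verify that trial
#' realization is faithful to the requested condition sequence.
#'
#' @param trials A `bs_trials` data frame (or anything with `grid_cell`,
#'   `ink_color`, `word`, `scored` columns).
#' @return Integer vector of recomputed conditions for the scored trials.
#' @export
rescore_conditions <- function(trials) {
  cells <- trials$grid_cell
  bc <- c(NA, cells[-1L] == cells[-length(cells)])
  sc <- trials$word == trials$ink_color
  keep <- trials$scored
  classify_condition(bc[keep], sc[keep])
}

#' Generate the full default 1-back Stroop task
#'
#' Convenience wrapper: 30 scored trials per condition (120 scored), one
#' unscored lead-in (121 trials total), bounded-run pseudo-random ordering.
#'
#' @inheritParams generate_condition_sequence
#' @inheritParams realize_trials
#' @param n_per_condition Scored trials per condition (default 30).
#' @return A `bs_trials` data frame.
#' @export
bs_task_trials <- function(n_per_condition = 30L, mapping = key_mapping("A"),
                           available_times = NULL, max_run_length = 4,
                           seed = NULL) {
  with_seed_if(seed, {
    cond <- generate_condition_sequence(rep(n_per_condition, 4),
                                        max_run_length = max_run_length)
    realize_trials(cond, mapping = mapping, available_times = available_times)
  })
}

#' Generate a 2-back letter sequence
#'
#' Comparison task: a pseudo-random stream of upper-case letters in which,
#' among trials with at least two predecessors, a fixed proportion repeat the
#' letter shown two trials earlier (default 50% match rate). Non-match trials
#' draw uniformly from the 25 letters different from the 2-back referent.
#'
#' @param n_trials Total number of letters (>= 3).
#' @param match_rate Proportion of scorable (index >= 2, 0-based) trials that
#'   are 2-back matches; the realized count is `round(match_rate * (n - 2))`.
#' @param seed Optional integer seed.
#' @return Data frame with columns `index` (0-based), `letter`, `is_match`
#'   (NA for the first two trials).
#' @export
generate_2back_sequence <- function(n_trials, match_rate = 0.5, seed = NULL) {
  assert_that(is_scalar_number(n_trials) && n_trials >= 3, "n_trials must be >= 3")
  assert_that(is_scalar_number(match_rate) && match_rate >= 0 && match_rate <= 1,
              "match_rate must be in [0, 1]")
  with_seed_if(seed, {
    n <- as.integer(n_trials)
    n_scorable <- n - 2L
    n_match <- as.integer(round(match_rate * n_scorable))
    is_match <- rep(FALSE, n)
    is_match[2L + sample.int(n_scorable, n_match)] <- TRUE
    letters_idx <- integer(n)
    letters_idx[1:2] <- sample.int(26L, 2L, replace = TRUE)
    for (i in 3:n) {
      ref <- letters_idx[i - 2L]
      letters_idx[i] <- if (is_match[i]) ref
        else ((ref - 1L + sample.int(25L, 1L)) %% 26L) + 1L
    }
    data.frame(
      index = seq_len(n) - 1L,
      letter = LETTERS[letters_idx],
      is_match = ifelse(seq_len(n) <= 2L, NA, is_match),
      stringsAsFactors = FALSE
    )
  })
}
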