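#' Write a session log to JSON
#'
#' JSON is the lossless canonical form for session logs: trials, responses,
#' scale records and PVT runs are stored row-wise with full numeric
#' precision, so `read_session_log(write_session_log(log))` reproduces the
#' data model.
#'
#' @param log A `bs_session_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  assert_that(inherits(log, "bs_session_log"), "need a bs_session_log")
  x <- list(
    format = "bstask-session-log", version = 1L,
    protocol = log$protocol,
    participant_id = log$participant_id,
    seed = log$seed,
    truncated = isTRUE(log$truncated),
    config = serialize_config(log$config),
    vas = log$vas,
    tlx = if (!is.null(log$tlx)) as.list(log$tlx),
    pvt = list(pre = strip_class(log$pvt$pre), post = strip_class(log$pvt$post)),
    blocks = lapply(log$blocks, function(b) {
      list(block_index = b$block_index, elapsed_ms = b$elapsed_ms,
           trials = strip_class(b$trials), responses = b$responses)
    })
  )
  jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                       na = "null", null = "null", digits = NA, pretty = FALSE)
  invisible(path)
}

strip_class <- function(df) {
  if (is.null(df)) return(NULL)
  class(df) <- "data.frame"
  df
}

serialize_config <- function(config) {
  if (is.null(config)) return(NULL)
  cfg <- unclass(config)
  if (!is.null(cfg$mapping)) cfg$mapping <- unclass(cfg$mapping)
  cfg
}

#' Read a session log from JSON
#'
#' Rebuilds the `bs_session_log` data model and validates it
#' ([validate_session_log()]); schema violations raise errors naming the
#' offending field and row.
#'
#' @param path JSON file written by [write_session_log()].
#' @return A `bs_session_log`.
#' @export
read_session_log <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  assert_that(identical(x$format, "bstask-session-log"),
              "not a bstask session-log file")
  log <- list(protocol = x$protocol, participant_id = x$participant_id,
              seed = x$seed, truncated = isTRUE(x$truncated),
              config = deserialize_config(x$config),
              vas = fix_df(x$vas, c(block = "integer", item = "character",
                                    score = "integer")),
              tlx = if (!is.null(x$tlx)) unlist(x$tlx),
              pvt = list(pre = fix_pvt(x$pvt$pre), post = fix_pvt(x$pvt$post)),
              blocks = NULL)
  blocks <- x$blocks
  if (is.data.frame(blocks)) {   # jsonlite simplifies a list of records
    log$blocks <- lapply(seq_len(nrow(blocks)), function(i) {
      list(block_index = as.integer(blocks$block_index[i]),
           elapsed_ms = blocks$elapsed_ms[i],
           trials = fix_trials(blocks$trials[[i]]),
           responses = fix_responses(blocks$responses[[i]]))
    })
  } else {
    log$blocks <- lapply(blocks, function(b) {
      list(block_index = as.integer(b$block_index), elapsed_ms = b$elapsed_ms,
           trials = fix_trials(b$trials), responses = fix_responses(b$responses))
    })
  }
  log <- structure(log, class = "bs_session_log")
  validate_session_log(log)
  log
}

deserialize_config <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  if (!is.null(cfg$mapping)) {
    cfg$mapping <- structure(cfg$mapping, class = "bs_key_mapping")
  }
  if (!is.null(cfg$available_times)) {
    cfg$available_times <- unlist(cfg$available_times)
  }
  if (!is.null(cfg$pvt_interval_bounds)) {
    cfg$pvt_interval_bounds <- as.numeric(unlist(cfg$pvt_interval_bounds))
  }
  structure(cfg, class = "bs_session_config")
}

fix_df <- function(df, types) {
  if (is.null(df) || (is.list(df) && length(df) == 0)) return(NULL)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (nm in names(types)) {
    if (nm %in% names(df)) {
      df[[nm]] <- switch(types[[nm]],
                         integer = as.integer(df[[nm]]),
                         numeric = as.numeric(df[[nm]]),
                         character = as.character(df[[nm]]),
                         logical = as.logical(df[[nm]]))
    }
  }
  df
}

fix_trials <- function(df) {
  df <- fix_df(df, c(index = "integer", grid_cell = "integer",
                     ink_color = "character", word = "character",
                     back_consistent = "logical", stroop_congruent = "logical",
                     condition = "integer", expected_key = "character",
                     available_time_ms = "numeric", scored = "logical",
                     letter = "character", is_match = "logical"))
  if (!is.null(df) && "grid_cell" %in% names(df)) {
    class(df) <- c("bs_trials", "data.frame")
  }
  df
}

fix_responses <- function(df) {
  fix_df(df, c(trial_index = "integer", key = "character", rt_ms = "numeric",
               correct = "logical", feedback = "character"))
}

fix_pvt <- function(df) {
  df <- fix_df(df, c(foreperiod_ms = "numeric", rt_ms = "numeric",
                     valid = "logical", lapse = "logical"))
  if (!is.null(df)) class(df) <- c("bs_pvt_trials", "data.frame")
  df
}

#' Validate a session log against the schema
#'
#' Checks value ranges and structural invariants (VAS scores 0-100,
#' workload dimensions 0-20, grid cells 0-8, conditions 1-4, feedback
#' trichotomy, one response per scored trial). Violations raise errors that
#' name the field and row.
#'
#' @param log A `bs_session_log`.
#' @return `TRUE` invisibly.
#' @export
validate_session_log <- function(log) {
  if (!is.null(log$vas)) {
    bad <- which(log$vas$score < 0 | log$vas$score > 100)
    if (length(bad)) {
      stop("vas$score out of range [0, 100] at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(log$tlx)) {
    bad <- which(log$tlx < 0 | log$tlx > 20)
    if (length(bad)) {
      stop("tlx score out of range [0, 20]: ",
           paste(names(log$tlx)[bad], collapse = ", "), call. = FALSE)
    }
  }
  fb <- unname(feedback_symbols())
  for (i in seq_along(log$blocks)) {
    b <- log$blocks[[i]]
    tr <- b$trials
    if (!is.null(tr$grid_cell)) {
      bad <- which(tr$grid_cell < 0 | tr$grid_cell > 8)
      if (length(bad)) {
        stop("blocks[[", i, "]]$trials$grid_cell out of range [0, 8] at row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      bad <- which(!is.na(tr$condition) & !(tr$condition %in% 1:4))
      if (length(bad)) {
        stop("blocks[[", i, "]]$trials$condition invalid at row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      if (!is.null(b$responses$feedback)) {
        bad <- which(!(b$responses$feedback %in% fb))
        if (length(bad)) {
          stop("blocks[[", i, "]]$responses$feedback invalid at row(s) ",
               paste(bad, collapse = ", "), call. = FALSE)
        }
        if (nrow(b$responses) != sum(tr$scored)) {
          stop("blocks[[", i, "]]: ", sum(tr$scored), " scored trials but ",
               nrow(b$responses), " responses", call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}

#' Flatten a session log to a trial-level table
#'
#' One row per trial with stimulus, latent flags, condition, deadline and
#' the response record; the flat form exported to CSV. Numeric columns
#' carry explicit units in their names.
#'
#' @param log A `bs_session_log` from a task protocol.
#' @return Data frame.
#' @export
session_log_to_df <- function(log) {
  do.call(rbind, lapply(log$blocks, function(b) {
    tr <- strip_class(b$trials)
    tr$block <- b$block_index + 1L
    resp <- b$responses
    m <- match(tr$index, resp$trial_index)
    tr$key <- resp$key[m]
    tr$rt_ms <- resp$rt_ms[m]
    tr$correct <- resp$correct[m]
    tr$feedback <- resp$feedback[m]
    tr$participant_id <- log$participant_id %||% "P001"
    tr[, c("participant_id", "block", "index", "grid_cell", "ink_color",
           "word", "back_consistent", "stroop_congruent", "condition",
           "available_time_ms", "scored", "key", "rt_ms", "correct",
           "feedback")]
  }))
}

#' Write / read a flat trial-level CSV
#'
#' UTF-8, comma-separated, mandatory header. Reading validates ranges
#' (grid cell 0-8, condition 1-4, RT positive) with row-addressed errors.
#'
#' @param x Data frame from [session_log_to_df()] or a `bs_trials` object.
#' @param path CSV path.
#' @return `write_trials_csv`: `path` invisibly; `read_trials_csv`: the
#'   validated data frame.
#' @export
write_trials_csv <- function(x, path) {
  write.csv(strip_class(as.data.frame(x)), path, row.names = FALSE,
            fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                 na.strings = "")
  if ("grid_cell" %in% names(df)) {
    bad <- which(df$grid_cell < 0 | df$grid_cell > 8)
    if (length(bad)) stop("grid_cell out of range [0, 8] at row(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("condition" %in% names(df)) {
    bad <- which(!is.na(df$condition) & !(df$condition %in% 1:4))
    if (length(bad)) stop("condition invalid at row(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("rt_ms" %in% names(df)) {
    bad <- which(!is.na(df$rt_ms) & df$rt_ms <= 0)
    if (length(bad)) stop("rt_ms must be positive at row(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a block-metrics CSV with schema validation
#'
#' Expects columns `block_index`, `correct_count`, `accuracy` (proportion in
#' `[0, 1]`); violations raise errors naming the row.
#'
#' @param path CSV path.
#' @return The validated data frame.
#' @export
read_block_metrics_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("block_index", "correct_count", "accuracy")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("missing column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  bad <- which(df$accuracy < 0 | df$accuracy > 1)
  if (length(bad)) stop("accuracy out of range [0, 1] at row(s) ",
                        paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' Compute block metrics from a flat trial-level table
#'
#' Same computation as [block_metrics()] but starting from the flat CSV/data
#' frame form, so JSON and CSV exports of a log analyse identically.
#'
#' @param df Data frame from [session_log_to_df()]/[read_trials_csv()].
#' @param count_no_response_as_error As in [block_metrics()].
#' @return Data frame `block_index`, `n_scored`, `correct_count`,
#'   `accuracy`, `mean_rt_ms`.
#' @export
block_metrics_df <- function(df, count_no_response_as_error = TRUE) {
  sc <- df[df$scored, , drop = FALSE]
  rows <- lapply(sort(unique(sc$block)), function(b) {
    r <- sc[sc$block == b, ]
    n <- nrow(r)
    cc <- sum(r$correct, na.rm = TRUE)
    denom <- if (count_no_response_as_error) n else sum(!is.na(r$correct))
    data.frame(block_index = b, n_scored = n, correct_count = cc,
               accuracy = cc / denom, mean_rt_ms = mean(r$rt_ms, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Read a task configuration from YAML
#'
#' Presets shipped with the package (see
#' `system.file("extdata", package = "bstask")`) encode the published
#' protocol parameters; user YAML files use the same keys.
#'
#' @param path YAML file with a `protocol` key (`tot_induction`,
#'   `hmw_blocks`).
#' @return A `bs_session_config`.
#' @export
read_task_config <- function(path) {
  y <- yaml::read_yaml(path)
  assert_that(!is.null(y$protocol), "config must name a protocol")
  at <- if (!is.null(y$available_times)) {
    stats::setNames(as.numeric(unlist(y$available_times)), as.character(1:4))
  }
  mapping <- key_mapping(y$key_variant %||% "A")
  switch(y$protocol,
    tot_induction = tot_config(
      n_blocks = y$n_blocks %||% 6,
      block_duration_ms = y$block_duration_ms %||% 300000,
      isi_feedback_ms = y$isi_feedback_ms %||% 500,
      available_times = at %||% default_available_times(),
      mapping = mapping,
      pvt_duration_ms = y$pvt_duration_ms %||% 180000,
      pvt_interval_bounds = as.numeric(unlist(y$pvt_interval_bounds %||%
                                                c(2000, 10000)))),
    hmw_blocks = hmw_config(
      n_blocks = y$n_blocks %||% 8,
      per_condition_per_block = y$per_condition_per_block %||% 2,
      rest_duration_ms = y$rest_duration_ms %||% 20000,
      isi_feedback_ms = y$isi_feedback_ms %||% 500,
      available_times = at %||% default_available_times(),
      mapping = mapping,
      practice_accuracy_gate = y$practice_accuracy_gate %||% 0.90),
    calibration = structure(list(protocol = "calibration", mapping = mapping,
                                 pressure_factor = y$pressure_factor %||% 1.25,
                                 rounding_quantum_ms = y$rounding_quantum_ms %||% 100),
                            class = "bs_session_config"),
    stop("unknown protocol: ", y$protocol, call. = FALSE)
  )
}
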