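#' Responder interface
#'
#' A responder is the engine's abstraction of a participant: any object of
#' class `bs_responder` providing vectorised callbacks. The engine is
#' headless; a display front-end would wrap a human in the same interface,
#' and [sim_responder()] wraps the stochastic participant model.
#'
#' Required elements:
#' \describe{
#'   \item{`respond_bs(trials, block_index)`}{scored trials (a `bs_trials`
#'     subset), 0-based block index; returns a data frame with columns `key`
#'     and `rt_ms` (one row per trial).}
#'   \item{`respond_pvt(n, phase)`}{`n` reaction times (ms) for phase
#'     `"pre"` or `"post"`.}
#'   \item{`respond_2back(trials, block_index)`}{data frame `key`
#'     (`"match"`/`"nonmatch"`), `rt_ms` for a 2-back letter block.}
#'   \item{`report_vas(block_index, items)`}{named integer vector of 0-100
#'     scale scores (block 0 = baseline).}
#'   \item{`report_tlx(task)`}{named numeric vector of the six 0-20 workload
#'     dimensions for task `"bs"` or `"2back"`.}
#' }
#'
#' @param callbacks Named list providing the elements above; missing scale
#'   callbacks default to all-zero reporters.
#' @return An object of class `bs_responder`.
#' @export
new_responder <- function(callbacks) {
  defaults <- list(
    respond_pvt = function(n, phase) rep(250, n),
    respond_2back = function(trials, block_index) {
      data.frame(key = ifelse(isTRUE_na(trials$is_match), "match", "nonmatch"),
                 rt_ms = rep(900, nrow(trials)), stringsAsFactors = FALSE)
    },
    report_vas = function(block_index, items) {
      stats::setNames(rep(0L, length(items)), items)
    },
    report_tlx = function(task) {
      stats::setNames(rep(0, 6), tlx_dimensions())
    }
  )
  obj <- utils::modifyList(defaults, callbacks)
  assert_that(is.function(obj$respond_bs), "respond_bs callback is required")
  structure(obj, class = "bs_responder")
}

isTRUE_na <- function(x) !is.na(x) & x

#' Deterministic always-correct responder
#'
#' Presses the expected key after a fixed latency; used for engine contract
#' tests and as a degenerate baseline.
#'
#' @param rt_ms Fixed response latency in ms.
#' @param pvt_rt_ms Fixed PVT latency in ms.
#' @return A `bs_responder`.
#' @export
perfect_responder <- function(rt_ms = 1, pvt_rt_ms = 250) {
  new_responder(list(
    respond_bs = function(trials, block_index) {
      data.frame(key = trials$expected_key, rt_ms = rep(rt_ms, nrow(trials)),
                 stringsAsFactors = FALSE)
    },
    respond_pvt = function(n, phase) rep(pvt_rt_ms, n)
  ))
}

#' Scripted responder
#'
#' Replays pre-specified keys/latencies in order, recycling if the script is
#' shorter than the session. `bs_keys = NULL` means "always the expected
#' key". Useful for hand-computable clock and feedback oracles.
#'
#' @param bs_rts Numeric vector of task latencies (ms), recycled.
#' @param bs_keys Optional character vector of keys, recycled.
#' @param pvt_rts Numeric vector of PVT latencies (ms), recycled.
#' @return A `bs_responder`.
#' @export
scripted_responder <- function(bs_rts = 1000, bs_keys = NULL, pvt_rts = 250) {
  bs_pos <- 0L
  pvt_pos <- 0L
  take <- function(script, pos, n) script[((pos + seq_len(n) - 1L) %% length(script)) + 1L]
  new_responder(list(
    respond_bs = function(trials, block_index) {
      n <- nrow(trials)
      rts <- take(bs_rts, bs_pos, n)
      keys <- if (is.null(bs_keys)) trials$expected_key else take(bs_keys, bs_pos, n)
      bs_pos <<- bs_pos + n
      data.frame(key = keys, rt_ms = rts, stringsAsFactors = FALSE)
    },
    respond_pvt = function(n, phase) {
      rts <- take(pvt_rts, pvt_pos, n)
      pvt_pos <<- pvt_pos + n
      rts
    }
  ))
}

#' Fixed-accuracy responder
#'
#' Presses the expected key with probability `accuracy` (the wrong key
#' otherwise) at a fixed latency; accuracy is exact in expectation only.
#'
#' @param accuracy Probability of a correct key press.
#' @param rt_ms Fixed latency (ms).
#' @return A `bs_responder`.
#' @export
noisy_key_responder <- function(accuracy = 0.5, rt_ms = 1000) {
  new_responder(list(
    respond_bs = function(trials, block_index) {
      n <- nrow(trials)
      ok <- runif(n) < accuracy
      key <- ifelse(ok, trials$expected_key,
                    ifelse(trials$expected_key == "F", "J", "F"))
      data.frame(key = key, rt_ms = rep(rt_ms, n), stringsAsFactors = FALSE)
    }
  ))
}

tlx_dimensions <- function() {
  c("mental_demand", "physical_demand", "temporal_demand",
    "performance", "effort", "frustration")
}

vas_item_names <- function() {
  c("mental_fatigue", "mental_effort", "mental_stress", "boredom")
}
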