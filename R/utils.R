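#' @importFrom stats rnorm runif rlnorm rexp sd var cor cor.test t.test
#'   wilcox.test shapiro.test friedman.test pf pchisq aggregate ave setNames lm
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Run `code` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means "consume the global stream" (no scoping).
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Derive a child seed from a parent seed, staying within 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 8191) %% 2147483647L)
}

# Half-up rounding to a multiple of `quantum` (base round() is half-even,
# which would send 2269.5/100 the wrong way half the time).
round_half_up <- function(x, quantum = 1) {
  floor(x / quantum + 0.5) * quantum
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# data.frame() without the coercion/name checking overhead; columns must be
# equal-length atomic vectors (hot engine paths only).
quick_df <- function(lst) {
  structure(lst, class = "data.frame",
            row.names = c(NA_integer_, -length(lst[[1L]])))
}
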