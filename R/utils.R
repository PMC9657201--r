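#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers (and tests) can distinguish contract
# violations from genuine failures.
stop_silfat <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "silfat_error", "error", "condition")))
}

assert_that <- function(ok, msg, class = "silfat_invalid_argument") {
  if (!isTRUE(ok)) stop_silfat(msg, class)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to a deterministic state, evaluates `code`, and restores the
#' caller's RNG state, so that seeded operations are pure functions of
#' `(inputs, seed)` and do not disturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Running mean with odd window k, ends handled by shrinking the window.
run_mean <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n < 3L) return(x)
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
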