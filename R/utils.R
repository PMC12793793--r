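# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so simulation functions are reproducible without
#' clobbering the global stream. A `NULL` seed leaves the RNG untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a string, used to derive independent
# per-subject substreams from one base seed: adding subjects to a study
# never perturbs the streams of existing ones.
hash_string31 <- function(x) {
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 31 + v) %% 2147483647L
  as.integer(h)
}

#' @noRd
derive_seed <- function(base_seed, key) {
  if (is.character(key)) key <- hash_string31(key)
  as.integer((as.double(base_seed) * 48271 + as.double(key) * 16807 + 1) %%
               2147483647)
}

# Hamming window (periodic-symmetric form as used for spectral analysis)
hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Trapezoid integral over an ordered grid
trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_thetamod <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "thetamod_error")))
}
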