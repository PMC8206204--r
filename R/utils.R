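# Internal helpers shared across modules: seeded RNG scoping, deterministic
# seed derivation, and half-open window indexing on a uniform time axis.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the previous RNG state so
#' seeded library functions do not perturb the caller's random stream.
#' A `NULL` seed evaluates `code` under the ambient stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed and an index path
#'
#' Splittable counter scheme: a master seed plus a path of integer indices
#' (subject, trial, stage, ...) maps to a stable seed below 2^31, so adding
#' downstream stages never perturbs earlier random streams.
#'
#' @param seed master seed (integer).
#' @param ... integer indices identifying the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, ...) {
  ix <- c(seed, ...)
  stopifnot(length(ix) >= 1L, all(is.finite(ix)))
  m <- 2147483647  # 2^31 - 1 (prime)
  h <- 0
  for (k in ix) {
    h <- (h * 48271 + (abs(k) %% m) + 1) %% m
  }
  as.integer(h)
}

# Indices of samples whose time lies in the half-open interval [start, end).
# The onset sample (t == 0) belongs to the post-stimulus window.
window_index <- function(time, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  which(time >= window[1] - 1e-9 & time < window[2] - 1e-9)
}

# Validate that `time` is a strictly increasing uniform axis; returns the step.
check_time_axis <- function(time) {
  if (length(time) < 2L) stop("time axis needs at least 2 samples", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time axis must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6 * mean(dt)) {
    stop("time axis must be uniformly sampled", call. = FALSE)
  }
  mean(dt)
}

# Stop with a classed condition so callers/tests can match on error type.
stop_classed <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
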