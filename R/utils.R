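# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never disturbs the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Derive independent sub-seeds from a master seed
#'
#' Deterministic: the same master seed always yields the same sub-seeds.
#' Values stay below 2^31 so they are valid R integer seeds.
#' @noRd
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# stopifnot-style check with a named, formatted message
check_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) stop(sprintf(msg, ...), call. = FALSE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# ms interval -> integer sample offsets relative to an event at sample 0
window_offsets <- function(window_ms, srate) {
  check_that(length(window_ms) == 2L && window_ms[1] < window_ms[2],
             "window must be an increasing (start, end) ms pair")
  seq(round(window_ms[1] * srate / 1000), round(window_ms[2] * srate / 1000))
}

# indices of epoch time axis (ms) inside a ms window, inclusive
time_index <- function(times_ms, window_ms) {
  which(times_ms >= window_ms[1] & times_ms <= window_ms[2])
}

#' Maximal runs of TRUE in a logical vector
#' @return data.frame(start, end) of 1-based indices; zero rows when none.
#' @noRd
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
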