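# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that simulation functions are
#' deterministic for a given seed without clobbering the global stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a master seed and a path of labels
#'
#' Deterministic, order-sensitive polynomial hash of the label path combined
#' with the master seed; the result is always in `[0, 2^31 - 2]` so it is a
#' valid R integer seed.  Adding a new subject/center/scan to a study never
#' changes the seeds of existing ones.
#'
#' @param master_seed Integer master seed.
#' @param ... Character or numeric labels identifying the stream, e.g.
#'   `derive_seed(7, "subject", 3, "center", "C1", "ir")`.
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "subject", 1) != derive_seed(1, "subject", 2)
#' @export
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, is.finite(master_seed))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master_seed) %% m
  labels <- unlist(lapply(list(...), as.character), use.names = FALSE)
  for (lab in labels) {
    for (b in utf8ToInt(lab)) h <- (h * 31 + b) %% m
    h <- (h * 31 + 7) %% m  # label separator so c("ab","c") != c("a","bc")
  }
  as.integer(h)
}

#' @noRd
stop_relaxo <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

#' Smooth low-frequency random scalar field on a grid
#'
#' Sum of a small number of random-phase separable cosine modes with at most
#' `max_cycles` cycles across each dimension; used for multiplicative bias
#' fields and displacement fields.  Returned as an array of `dim = shape`
#' with zero mean removed and unit RMS (or all zeros if degenerate).
#' @noRd
smooth_random_field <- function(shape, n_modes = 6L, max_cycles = 2) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  co <- lapply(shape, function(n) (seq_len(n) - 0.5) / n)  # in (0,1)
  f <- array(0, dim = shape)
  for (k in seq_len(n_modes)) {
    freq <- stats::runif(3, 0, max_cycles)
    phase <- stats::runif(3, 0, 2 * pi)
    amp <- stats::rnorm(1)
    gx <- cos(2 * pi * freq[1] * co[[1]] + phase[1])
    gy <- cos(2 * pi * freq[2] * co[[2]] + phase[2])
    gz <- cos(2 * pi * freq[3] * co[[3]] + phase[3])
    f <- f + amp * (gx %o% gy %o% gz)
  }
  r <- sqrt(mean(f^2))
  if (r > 0) f / r else f
}
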