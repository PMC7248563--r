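# Acquisition protocols: the sampling-time axis of a relaxometry series.

#' Acquisition protocol for a relaxometry series
#'
#' Describes how the fourth (time) dimension of an [image_series()] samples
#' the relaxation curve: inversion times TI for an inversion-recovery T1
#' series, or echo times TE for a multi-echo T2 series, plus the repetition
#' time TR.  All times are in milliseconds.
#'
#' @param modality `"IR_T1"` or `"MULTIECHO_T2"`.
#' @param times_ms Strictly increasing positive sampling times (TI or TE),
#'   at least 3 of them (three-parameter fits need three points).
#' @param tr_ms Positive repetition time.  Note that a multi-echo spin-echo
#'   train can legitimately have `tr_ms < max(times_ms)` (one excitation,
#'   many echoes), so only `tr_ms > 0` is required.
#' @return An object of class `acquisition_protocol`.
#' @seealso [default_ir_protocol()], [default_multiecho_protocol()]
#' @examples
#' acquisition_protocol("IR_T1", c(247, 408, 674, 1112, 1838, 3030, 5000), 6500)
#' @export
acquisition_protocol <- function(modality, times_ms, tr_ms) {
  modality <- match.arg(modality, c("IR_T1", "MULTIECHO_T2"))
  times_ms <- as.numeric(times_ms)
  if (length(times_ms) < 3L)
    stop_relaxo("protocol needs >= 3 sampling times, got %d", length(times_ms))
  if (any(!is.finite(times_ms)) || any(times_ms <= 0))
    stop_relaxo("sampling times must be finite and > 0")
  if (any(diff(times_ms) <= 0))
    stop_relaxo("sampling times must be strictly increasing")
  if (!is.numeric(tr_ms) || length(tr_ms) != 1L || !is.finite(tr_ms) || tr_ms <= 0)
    stop_relaxo("tr_ms must be a single positive number")
  structure(list(modality = modality, times_ms = times_ms, tr_ms = as.numeric(tr_ms)),
            class = "acquisition_protocol")
}

#' Standard 7-point inversion-recovery protocol
#'
#' TI = 247, 408, 674, 1112, 1838, 3030, 5000 ms with TR = 6500 ms: an
#' approximately log-spaced sampling of the T1 recovery curve suitable for
#' rat brain at 7 T.
#' @return An `acquisition_protocol` with modality `"IR_T1"`.
#' @export
default_ir_protocol <- function() {
  acquisition_protocol("IR_T1", c(247, 408, 674, 1112, 1838, 3030, 5000), 6500)
}

#' Standard 28-echo multi-echo protocol
#'
#' TE = 8, 16, ..., 224 ms (28 equally spaced echoes) with TR = 600 ms.
#' @return An `acquisition_protocol` with modality `"MULTIECHO_T2"`.
#' @export
default_multiecho_protocol <- function() {
  acquisition_protocol("MULTIECHO_T2", seq(8, 224, by = 8), 600)
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("<acquisition_protocol> %s, %d time points (%g..%g ms), TR %g ms\n",
              x$modality, length(x$times_ms), min(x$times_ms), max(x$times_ms),
              x$tr_ms))
  invisible(x)
}
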