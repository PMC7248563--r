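# Signal models for magnitude relaxometry.

#' Magnitude inversion-recovery signal model
#'
#' `|a * (1 - b * exp(-ti / t1))|`: the three-parameter magnitude model for
#' inversion-prepared acquisitions without phase information.  `a` is the
#' fully relaxed amplitude (proportional to proton density), `b` the
#' inversion factor (2 for a perfect inversion; a free `b` also absorbs
#' incomplete recovery over TR), `t1` the longitudinal relaxation time.
#' The signal nulls at `ti = t1 * log(2)` when `b = 2`.
#'
#' @param ti_ms Inversion time(s), ms; vectorized.
#' @param a,b,t1_ms Model parameters; `t1_ms` must be > 0.
#' @return Signal magnitude, same length as `ti_ms`.
#' @examples
#' ir_model(1000 * log(2), a = 1000, b = 2, t1_ms = 1000)  # ~0
#' @export
ir_model <- function(ti_ms, a, b, t1_ms) {
  if (any(t1_ms <= 0)) stop_relaxo("t1_ms must be > 0")
  abs(a * (1 - b * exp(-ti_ms / t1_ms)))
}

#' Mono-exponential transverse decay model
#'
#' `a * exp(-te / t2)`: the two-parameter model shared by all multi-echo T2
#' estimation procedures.  Its logarithm is linear in TE with slope `-1/t2`.
#'
#' @param te_ms Echo time(s), ms; vectorized.
#' @param a,t2_ms Amplitude and transverse relaxation time; `t2_ms` > 0.
#' @return Signal, same length as `te_ms`.
#' @examples
#' t2_model(50, a = 100, t2_ms = 50)  # 100 / e
#' @export
t2_model <- function(te_ms, a, t2_ms) {
  if (any(t2_ms <= 0)) stop_relaxo("t2_ms must be > 0")
  a * exp(-te_ms / t2_ms)
}
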