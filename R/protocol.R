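#' Blue-light stimulation protocol
#'
#' A protocol is an ordered set of non-overlapping constant-amplitude light
#' pulses driving bPAC, each given as an on time, an off time (minutes) and a
#' dimensionless amplitude in \[0, 1\]. The input is piecewise constant with a
#' right-open convention: the light is on for `t_on <= t < t_off`.
#'
#' @param pulses a data.frame (or matrix) with columns `t_on`, `t_off`,
#'   `amplitude`, one row per pulse. May have zero rows (no stimulus).
#' @param t_end end of the simulated experiment in minutes; must be at or
#'   after the last `t_off`.
#' @return an object of class `light_protocol`.
#' @examples
#' two_pulse_protocol()
#' @export
light_protocol <- function(pulses, t_end = NULL) {
  pulses <- as.data.frame(pulses)
  if (nrow(pulses) > 0) {
    stopifnot(all(c("t_on", "t_off", "amplitude") %in% names(pulses)))
    pulses <- pulses[order(pulses$t_on), c("t_on", "t_off", "amplitude")]
    if (any(pulses$t_off <= pulses$t_on))
      stop("each pulse must have t_off > t_on")
    if (any(pulses$amplitude < 0 | pulses$amplitude > 1))
      stop("pulse amplitudes must lie in [0, 1]")
    if (nrow(pulses) > 1 &&
        any(pulses$t_on[-1] < pulses$t_off[-nrow(pulses)]))
      stop("pulses must not overlap")
  } else {
    pulses <- data.frame(t_on = numeric(0), t_off = numeric(0),
                         amplitude = numeric(0))
  }
  if (is.null(t_end)) t_end <- if (nrow(pulses)) max(pulses$t_off) else 0
  if (nrow(pulses) && t_end < max(pulses$t_off))
    stop("t_end must be >= the last t_off")
  structure(list(pulses = pulses, t_end = t_end), class = "light_protocol")
}

#' Standard two-pulse protocol
#'
#' The default experimental drive: a dark lead-in followed by two 40-min ON /
#' 40-min OFF pulses (the duration at which most cells reach steady state in
#' their ERK-KTR N/C signal).
#'
#' @param amplitudes amplitudes of the two pulses.
#' @param on,off pulse width and inter-pulse gap in minutes.
#' @param lead dark period before the first pulse, minutes.
#' @param tail dark period after the last pulse, minutes.
#' @export
two_pulse_protocol <- function(amplitudes = c(1, 1), on = 40, off = 40,
                               lead = 40, tail = off) {
  n <- length(amplitudes)
  t_on <- lead + (seq_len(n) - 1) * (on + off)
  light_protocol(
    data.frame(t_on = t_on, t_off = t_on + on, amplitude = amplitudes),
    t_end = t_on[n] + on + tail
  )
}

#' Single-pulse protocol
#' @inheritParams two_pulse_protocol
#' @param amplitude pulse amplitude in \[0, 1\].
#' @export
one_pulse_protocol <- function(amplitude = 1, on = 40, lead = 40, tail = 60) {
  light_protocol(
    data.frame(t_on = lead, t_off = lead + on, amplitude = amplitude),
    t_end = lead + on + tail
  )
}

#' Light amplitude at a time point
#'
#' Evaluates the piecewise-constant bPAC drive. Times inside
#' `[t_on, t_off)` of a pulse return that pulse's amplitude, all other times
#' (including `t_off` itself and times beyond the protocol) return 0.
#'
#' @param protocol a [light_protocol()].
#' @param t time(s) in minutes, each >= 0. Vectorised.
#' @return numeric vector of amplitudes.
#' @export
light_input <- function(protocol, t) {
  stopifnot(inherits(protocol, "light_protocol"), all(t >= 0))
  p <- protocol$pulses
  out <- numeric(length(t))
  for (k in seq_len(nrow(p))) {
    inside <- t >= p$t_on[k] & t < p$t_off[k]
    out[inside] <- p$amplitude[k]
  }
  out
}

#' Pulse windows of a protocol
#'
#' @param protocol a [light_protocol()].
#' @return data.frame with `pulse_index`, `t_on`, `t_off`, `off_end` (end of
#'   the post-pulse OFF period: the next pulse's onset, or `t_end`).
#' @export
pulse_windows <- function(protocol) {
  p <- protocol$pulses
  n <- nrow(p)
  if (n == 0) return(data.frame(pulse_index = integer(0), t_on = numeric(0),
                                t_off = numeric(0), off_end = numeric(0)))
  data.frame(
    pulse_index = seq_len(n),
    t_on = p$t_on, t_off = p$t_off,
    off_end = c(if (n > 1) p$t_on[-1] else NULL, protocol$t_end)
  )
}

#' @export
print.light_protocol <- function(x, ...) {
  cat("<light_protocol> ", nrow(x$pulses), " pulse(s), t_end = ",
      x$t_end, " min\n", sep = "")
  if (nrow(x$pulses)) print(x$pulses, row.names = FALSE)
  invisible(x)
}

# Segment boundaries where the right-hand side changes discontinuously
# (pulse edges); integration restarts at each.
protocol_breaks <- function(protocol, extra = numeric(0)) {
  p <- protocol$pulses
  sort(unique(pmin(pmax(c(0, p$t_on, p$t_off, protocol$t_end, extra), 0),
                   protocol$t_end)))
}
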