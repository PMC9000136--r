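#' Pulse-response metrics for one signal
#'
#' Per-pulse statistics of a sampled signal over a stimulus pulse window
#' `[t_on, t_off]` and the following OFF period:
#' \itemize{
#'   \item `s_start`: signal at pulse onset; `s_max`: maximum over the
#'     window; `s_end`: signal at pulse end;
#'   \item `time_to_max`: minutes from onset to the first sample attaining
#'     the maximum;
#'   \item `time_to_ss`: minutes from onset to the first sample at or after
#'     the maximum whose value is within `ss_fraction` of `s_end` relative
#'     to `s_max`, i.e. `|S(t) - s_end| <= ss_fraction * (s_max - s_end)`
#'     (two-sided band; always `>= time_to_max`);
#'   \item `overshoot_ratio`: `(s_max - s_start) / (s_end - s_start)`;
#'   \item `undershoot_depth`: `max(0, s_start - min(S))` over the post-pulse
#'     OFF period.
#' }
#' Metrics are computed on the sampled grid without interpolation. When the
#' pulse produces no net response (`|s_end - s_start| < eps`) the ratio is
#' undefined and the row is flagged `valid = FALSE`.
#'
#' @param time,signal numeric vectors, the sampled trace.
#' @param t_on,t_off pulse window (min), inside the trace span.
#' @param off_end end of the post-pulse OFF period (min); defaults to the
#'   end of the trace.
#' @param ss_fraction steady-state band half-width as a fraction of
#'   `s_max - s_end` (0.3: "within 30 percent").
#' @param eps degenerate-denominator threshold; default 1% of the trace's
#'   global dynamic range.
#' @return one-row data.frame with the metric fields and `valid`.
#' @export
compute_pulse_metrics <- function(time, signal, t_on, t_off,
                                  off_end = max(time), ss_fraction = 0.3,
                                  eps = NULL) {
  stopifnot(length(time) == length(signal), t_off > t_on,
            t_on >= min(time), t_off <= max(time))
  if (is.null(eps)) eps <- 0.01 * diff(range(signal))
  in_win <- which(time >= t_on & time <= t_off)
  if (length(in_win) < 3) stop("need >= 3 samples inside the pulse window")
  tw <- time[in_win]; sw <- signal[in_win]
  s_start <- sw[1]
  s_end <- sw[length(sw)]
  i_max <- which.max(sw)            # earliest index attaining the max
  s_max <- sw[i_max]
  time_to_max <- tw[i_max] - t_on
  band <- ss_fraction * (s_max - s_end)
  after <- seq(i_max, length(sw))
  i_ss <- after[abs(sw[after] - s_end) <= band][1]
  time_to_ss <- if (is.na(i_ss)) tw[length(tw)] - t_on else tw[i_ss] - t_on
  denom <- s_end - s_start
  valid <- abs(denom) >= eps
  overshoot_ratio <- if (valid) (s_max - s_start) / denom else NA_real_
  in_off <- which(time > t_off & time <= off_end)
  undershoot_depth <- if (length(in_off))
    max(0, s_start - min(signal[in_off])) else NA_real_
  data.frame(s_start = s_start, s_max = s_max, s_end = s_end,
             time_to_max = time_to_max, time_to_ss = time_to_ss,
             overshoot_ratio = overshoot_ratio,
             undershoot_depth = undershoot_depth, valid = valid)
}

#' Per-cell, per-pulse metrics table for a cohort
#'
#' Applies [compute_pulse_metrics()] to every cell of a simulation (or any
#' long trace table) for every pulse of the protocol.
#'
#' @param x a `trace_set` from [simulate_tissue()], or a long data.frame
#'   with columns `cell_id`, `role`, `time_min`, and the signal column.
#' @param protocol the driving [light_protocol()]; taken from the trace set
#'   metadata when omitted.
#' @param signal which signal to analyse (column name; `ktr_nc` by default,
#'   `camp` also useful for `trace_set` input).
#' @param ss_fraction,eps passed to [compute_pulse_metrics()].
#' @return data.frame with `cell_id`, `role`, `pulse_index` and the metric
#'   columns.
#' @export
pulse_metrics_table <- function(x, protocol = NULL, signal = "ktr_nc",
                                ss_fraction = 0.3, eps = NULL) {
  if (inherits(x, "trace_set")) {
    protocol <- protocol %||% x$meta$protocol
    df <- as.data.frame(x)
    if (!signal %in% names(df))
      df[[signal]] <- as.vector(x[[signal]])
  } else df <- x
  stopifnot(!is.null(protocol), signal %in% names(df))
  win <- pulse_windows(protocol)
  out <- list()
  for (id in unique(df$cell_id)) {
    sub <- df[df$cell_id == id, ]
    sub <- sub[order(sub$time_min), ]
    for (k in seq_len(nrow(win))) {
      m <- compute_pulse_metrics(sub$time_min, sub[[signal]],
                                 win$t_on[k], win$t_off[k], win$off_end[k],
                                 ss_fraction = ss_fraction, eps = eps)
      out[[length(out) + 1]] <- cbind(
        data.frame(cell_id = id, role = sub$role[1],
                   pulse_index = win$pulse_index[k]), m)
    }
  }
  do.call(rbind, out)
}

#' Shift traces to zero at a pulse onset
#'
#' Subtracts from each trace its own value at the beginning of the chosen
#' pulse, so the population standard deviation at the onset is exactly zero
#' (removal of baseline variability).
#'
#' @param traces matrix of signals, one column per cell, rows on a shared
#'   time grid.
#' @param time the shared time grid (min).
#' @param protocol the [light_protocol()].
#' @param pulse_index which pulse's onset to use.
#' @return matrix of shifted traces.
#' @export
shift_traces <- function(traces, time, protocol, pulse_index = 1) {
  traces <- as.matrix(traces)
  win <- pulse_windows(protocol)
  stopifnot(pulse_index %in% win$pulse_index)
  t_on <- win$t_on[pulse_index]
  i_on <- which(time >= t_on)[1]
  if (is.na(i_on)) stop("pulse onset lies outside the time grid")
  sweep(traces, 2, traces[i_on, ], "-")
}

#' Peak-normalize shifted traces by a chosen pulse
#'
#' Divides each onset-shifted trace by its own peak response during the
#' chosen pulse (peak minus onset value), removing per-cell peak-amplitude
#' variability in that pulse; each cell's normalized peak in the chosen
#' pulse is exactly 1. Cells whose in-pulse response is below `eps` are
#' dropped with a warning.
#'
#' @inheritParams shift_traces
#' @param eps minimal peak - onset difference; default 1% of the cohort's
#'   dynamic range.
#' @return matrix of normalized traces (possibly fewer columns); the number
#'   of excluded cells is attached as attribute `n_excluded`.
#' @export
peak_normalize <- function(traces, time, protocol, pulse_index = 1,
                           eps = NULL) {
  traces <- as.matrix(traces)
  if (is.null(eps)) eps <- 0.01 * diff(range(traces))
  shifted <- shift_traces(traces, time, protocol, pulse_index)
  win <- pulse_windows(protocol)
  in_win <- time >= win$t_on[pulse_index] & time <= win$t_off[pulse_index]
  peak <- apply(shifted[in_win, , drop = FALSE], 2, max)
  keep <- peak > eps
  if (!all(keep))
    warning(sum(!keep), " flat trace(s) excluded from peak normalization")
  out <- sweep(shifted[, keep, drop = FALSE], 2, peak[keep], "/")
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Segment-wise population mean and standard deviation
#'
#' Pointwise mean and sample standard deviation across traces, computed
#' segment by segment where segments are delimited by pulse onsets (each
#' pulse's statistics run up to just before the next pulse begins).
#'
#' @inheritParams shift_traces
#' @param shift if `TRUE` (default), each trace is re-shifted to zero at the
#'   onset of each segment's pulse, enforcing zero standard deviation at the
#'   beginning of every pulse.
#' @return data.frame with `time`, `segment`, `mean`, `sd`.
#' @export
population_mean_sd <- function(traces, time, protocol, shift = TRUE) {
  traces <- as.matrix(traces)
  if (ncol(traces) < 2) stop("need >= 2 traces for a standard deviation")
  win <- pulse_windows(protocol)
  bounds <- c(if (nrow(win)) win$t_on else 0, Inf)
  if (!nrow(win) || win$t_on[1] > min(time)) bounds <- c(min(time), bounds)
  out <- list()
  for (s in seq_len(length(bounds) - 1)) {
    sel <- time >= bounds[s] & time < bounds[s + 1]
    if (!any(sel)) next
    seg <- traces[sel, , drop = FALSE]
    if (shift) seg <- sweep(seg, 2, seg[1, ], "-")
    out[[s]] <- data.frame(time = time[sel], segment = s,
                           mean = rowMeans(seg), sd = apply(seg, 1, stats::sd))
  }
  do.call(rbind, out)
}
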