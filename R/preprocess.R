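# Trace preprocessing: zero-phase low-pass filtering, kinematic
# differentiation, baseline subtraction, direction pooling, and windowed
# response-gain extraction. Traces are numeric vectors (one trial) or
# matrices (trials x samples) on a uniform 1 ms grid; the companion time
# vector `t` is in ms relative to the (display-corrected) cursor jump.

apply_rows <- function(x, f) {
  if (is.matrix(x)) t(apply(x, 1, f)) else f(x)
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' with odd-reflection padding at both ends to suppress edge transients; DC
#' is preserved and the effective attenuation is the squared single-pass
#' magnitude response.
#'
#' @param x Numeric vector or trials-x-samples matrix.
#' @param cutoff Cutoff frequency in Hz (default 50); must be below Nyquist.
#' @param fs Sampling rate in Hz (default 1000).
#' @param order Butterworth order of each pass (default 4).
#' @return Filtered series, same shape as `x`.
#' @export
lowpass <- function(x, cutoff = 50, fs = 1000, order = 4) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- if (is.matrix(x)) ncol(x) else length(x)
  pad <- min(n - 1, 150)
  apply_rows(x, function(v) {
    # odd reflection about the endpoints (preserves level and slope)
    left <- 2 * v[1] - v[(pad + 1):2]
    right <- 2 * v[n] - v[(n - 1):(n - pad)]
    y <- signal::filtfilt(bf, c(left, v, right))
    y[(pad + 1):(pad + n)]
  })
}

#' Differentiate a velocity trace to acceleration
#'
#' Central differences on the 1 ms grid, with the endpoint derivative
#' replicated from the adjacent interior value; a velocity in cm/s sampled
#' at `fs` Hz yields acceleration in cm/s^2.
#'
#' @param v Numeric vector or matrix of velocities (cm/s).
#' @param fs Sampling rate in Hz (default 1000).
#' @return Acceleration series, same shape as `v`.
#' @export
differentiate <- function(v, fs = 1000) {
  apply_rows(v, function(x) {
    n <- length(x)
    if (n < 3) stop("need at least 3 samples to differentiate")
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
    d[1] <- d[2]; d[n] <- d[n - 1]
    d
  })
}

#' Subtract an unperturbed baseline trace
#'
#' Pointwise difference on identical time grids. The baseline is the
#' per-subject mean trace of unperturbed trials of the matching trial type
#' (channel baselines for channel trials, standard baselines for standard
#' trials).
#'
#' @param trace Numeric vector or matrix.
#' @param baseline Numeric vector of the same sample count.
#' @return `trace - baseline` (baseline recycled across matrix rows).
#' @export
subtract_baseline <- function(trace, baseline) {
  n <- if (is.matrix(trace)) ncol(trace) else length(trace)
  if (length(baseline) != n) stop("trace and baseline grids do not match")
  if (is.matrix(trace)) sweep(trace, 2, baseline) else trace - baseline
}

#' Pool traces across jump directions
#'
#' Negates rightward-jump traces and merges them with leftward ones, so a
#' positive value always means a correction toward the center target.
#' Applying the pooling twice restores the original right-jump traces
#' (sign flip is an involution).
#'
#' @param traces Trials-x-samples matrix (a vector is treated as one row).
#' @param direction Character vector, one of "left"/"right" per trial.
#' @return Matrix with right-jump rows negated.
#' @export
pool_directions <- function(traces, direction) {
  if (!is.matrix(traces)) traces <- matrix(traces, nrow = 1)
  if (length(direction) != nrow(traces))
    stop("one direction per trial required")
  if (!all(direction %in% c("left", "right")))
    stop("pooling requires jump_direction left or right (no 'none' trials)")
  traces[direction == "right", ] <- -traces[direction == "right", , drop = FALSE]
  traces
}

#' Windowed response gain
#'
#' Arithmetic mean of a baseline-subtracted, direction-pooled trace over
#' the analysis window (default 170-220 ms inclusive: 51 samples).
#'
#' @param trace Numeric vector or matrix.
#' @param t Time vector (ms) matching the sample count.
#' @param window Length-2 window bounds in ms, inclusive.
#' @return Mean over the window (one value per trial row).
#' @export
response_gain <- function(trace, t, window = c(170, 220)) {
  n <- if (is.matrix(trace)) ncol(trace) else length(trace)
  if (length(t) != n) stop("time vector does not match trace")
  if (window[1] < min(t) || window[2] > max(t))
    stop("analysis window exceeds trace support")
  sel <- t >= window[1] & t <= window[2]
  if (is.matrix(trace)) rowMeans(trace[, sel, drop = FALSE])
  else mean(trace[sel])
}

#' Correct the time axis for display latency
#'
#' Raw timestamps are aligned to the commanded cursor jump; the jump is
#' displayed `display_latency` ms later, so event times relative to the
#' displayed jump are `t - display_latency`.
#'
#' @param t Time vector (ms) aligned to the commanded jump.
#' @param display_latency Display latency in ms (default 24).
#' @return Shifted time vector with t = 0 at the displayed jump.
#' @export
latency_correct <- function(t, display_latency = 24) {
  t - display_latency
}

#' Extract response gains from simulated (or same-schema) trace data
#'
#' Per subject: low-pass filters all traces, forms the mean unperturbed
#' baseline per trial type, subtracts it from cursor-jump traces of the
#' same type, pools directions, and averages the gain window — one gain
#' observation per subject x condition x direction.
#'
#' @param traces Long data frame: `trial_id`, `t_ms`, `value`.
#' @param trials Trial table with `trial_id`, `subject_id`, `condition`,
#'   `r_ratio`, `p_ratio`, `trial_type`, `jump_direction`, `phase`.
#' @param trial_type Which trial type to analyze (default "channel").
#' @param window Analysis window (ms).
#' @param cutoff Low-pass cutoff (Hz); NULL skips filtering.
#' @return Gain-observation data frame in the [simulate_gain_table()] schema.
#' @export
extract_gains <- function(traces, trials, trial_type = "channel",
                          window = c(170, 220), cutoff = 50) {
  t_grid <- sort(unique(traces$t_ms))
  wide <- function(ids) {
    m <- t(vapply(ids, function(id) {
      tr <- traces[traces$trial_id == id, ]
      tr$value[order(tr$t_ms)]
    }, numeric(length(t_grid))))
    if (!is.null(cutoff)) m <- lowpass(m, cutoff = cutoff) else m
  }
  out <- list()
  for (sid in unique(trials$subject_id)) {
    tt <- trials[trials$subject_id == sid & trials$phase == "main" &
                   trials$trial_type == trial_type, ]
    base_ids <- tt$trial_id[tt$jump_direction == "none"]
    if (length(base_ids) == 0) stop("no unperturbed baseline trials for ", sid)
    baseline <- colMeans(wide(base_ids))
    jt <- tt[tt$jump_direction != "none", ]
    for (cond in unique(jt$condition)) {
      for (dir in c("left", "right")) {
        ids <- jt$trial_id[jt$condition == cond & jt$jump_direction == dir]
        if (length(ids) == 0) next
        m <- subtract_baseline(wide(ids), baseline)
        m <- pool_directions(m, rep(dir, nrow(m)))
        g <- mean(response_gain(m, t_grid, window))
        out[[length(out) + 1]] <- data.frame(
          subject_id = sid, condition = cond,
          r_ratio = jt$r_ratio[jt$condition == cond][1],
          p_ratio = jt$p_ratio[jt$condition == cond][1],
          jump_direction = dir, gain = g, n_trials = length(ids),
          window_lo = window[1], window_hi = window[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
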