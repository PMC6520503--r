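# Signal-detection onset analysis: at every 1 ms sample the area under the
# ROC curve (aROC) measures how separable two trace ensembles are; the
# series is truncated once it exceeds criterion, a dog-leg (flat at 0.5 then
# linear) is fitted, and the onset is the later of the dog-leg breakpoint
# and the last local minimum of the aROC curve.

#' Area under the ROC curve at a single sample
#'
#' Probability that a random draw from `values_b` exceeds one from
#' `values_a`, with ties credited 0.5 (the Mann-Whitney convention):
#' `(#\{b > a\} + 0.5 #\{b = a\}) / (n_a n_b)`. Computed from midranks, which
#' is identical to the brute-force all-pairs count.
#'
#' @param values_a,values_b Non-empty numeric vectors (group A = reference,
#'   group B = ensemble expected to diverge upward).
#' @return aROC in \[0, 1\]; 0.5 means indistinguishable.
#' @export
aroc_at_sample <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty")
  r <- rank(c(values_a, values_b))
  u <- sum(r[(na + 1):(na + nb)]) - nb * (nb + 1) / 2
  u / (na * nb)
}

#' aROC time series for two trace ensembles
#'
#' Applies [aroc_at_sample()] independently at every sample of a common
#' time grid.
#'
#' @param group_a,group_b Trials-x-samples matrices on the same grid.
#' @param t Time vector (ms) matching the column count.
#' @return An `aroc_series` object: list with `t`, `aroc`, and
#'   `truncation_time` (NULL until truncated).
#' @export
aroc_series <- function(group_a, group_b, t) {
  if (!is.matrix(group_a)) group_a <- matrix(group_a, nrow = 1)
  if (!is.matrix(group_b)) group_b <- matrix(group_b, nrow = 1)
  if (ncol(group_a) != ncol(group_b)) stop("time grids do not match")
  if (length(t) != ncol(group_a)) stop("time vector does not match traces")
  a <- vapply(seq_along(t), function(j)
    aroc_at_sample(group_a[, j], group_b[, j]), numeric(1))
  structure(list(t = t, aroc = a, truncation_time = NULL),
            class = "aroc_series")
}

#' Truncate an aROC series at sustained supra-criterion separation
#'
#' Finds the first run of at least `run` consecutive samples strictly above
#' `criterion` and discards that run and everything after it (samples up to
#' and including the last pre-run sample are kept). The time of the run's
#' first sample is recorded as `truncation_time`; a series with no such run
#' is returned untouched.
#'
#' @param series An `aroc_series`.
#' @param criterion aROC criterion (default 0.62; 0.75 recovers the stricter
#'   historical variant).
#' @param run Required consecutive supra-criterion samples (default 3).
#' @return The truncated `aroc_series`.
#' @export
truncate_aroc <- function(series, criterion = 0.62, run = 3) {
  above <- series$aroc > criterion
  n <- length(above)
  if (n >= run) {
    runsum <- stats::filter(as.numeric(above), rep(1, run), sides = 1)
    hit <- which(runsum == run)
    if (length(hit) > 0) {
      start <- hit[1] - run + 1
      series$truncation_time <- series$t[start]
      keep <- seq_len(start - 1)
      series$t <- series$t[keep]
      series$aroc <- series$aroc[keep]
    }
  }
  series
}

#' Fit a dog-leg to an aROC series
#'
#' Least-squares fit of a flat line fixed at 0.5 up to a breakpoint,
#' followed by a linear component continuous at 0.5: `f(t) = 0.5` for
#' `t <= t_b`, `0.5 + s (t - t_b)` after. The breakpoint is chosen by
#' exhaustive scan over the sample times (ties broken toward the earliest
#' breakpoint); the slope is the conditional least-squares solution. A
#' series with zero variance is flagged degenerate (slope 0, breakpoint at
#' the last sample).
#'
#' @param series An `aroc_series`, normally truncated first; at least 3
#'   samples required.
#' @return List with `flat_end` (ms), `slope` (per ms), `sse`, `degenerate`.
#' @export
fit_dogleg <- function(series) {
  t <- series$t; y <- series$aroc
  n <- length(t)
  if (n < 3) stop("need at least 3 samples to fit a dog-leg")
  if (max(y) - min(y) < .Machine$double.eps^0.5)
    return(list(flat_end = t[n], slope = 0, sse = sum((y - 0.5)^2),
                degenerate = TRUE))
  dev <- y - 0.5
  best <- NULL
  for (k in seq_len(n - 1)) {       # breakpoint at t[k]; >= 1 sample after
    dt <- t[(k + 1):n] - t[k]
    dy <- dev[(k + 1):n]
    s <- sum(dt * dy) / sum(dt * dt)
    sse <- sum(dev[1:k]^2) + sum((dy - s * dt)^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(flat_end = t[k], slope = s, sse = sse, degenerate = FALSE)
  }
  best
}

#' Last local minimum of an aROC series
#'
#' Time of the last sample strictly lower than both neighbors. A plateau of
#' equal values flanked by higher values on both sides counts as a minimum,
#' located at the plateau's last sample. A series with no interior minimum
#' (e.g. monotone) returns the series start.
#'
#' @param series An `aroc_series` with at least 3 samples.
#' @return Time (ms) of the last local minimum, or the first sample time.
#' @export
last_local_minimum <- function(series) {
  y <- series$aroc
  if (length(y) < 3) stop("need at least 3 samples")
  r <- rle(y)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  cand <- which(seq_len(k) > 1 & seq_len(k) < k &
                  r$values < c(Inf, r$values[-k]) &
                  r$values < c(r$values[-1], Inf))
  if (length(cand) == 0) return(series$t[1])
  series$t[ends[max(cand)]]
}

#' Detect the divergence onset of two trace ensembles
#'
#' Pipeline: aROC series -> truncation at sustained supra-criterion
#' separation -> dog-leg fit and last-local-minimum search on the truncated
#' series; the onset is the later of the dog-leg breakpoint and the last
#' local minimum (a conservative estimate). The dog-leg assumes an upward
#' departure from 0.5; if the series instead runs below 0.5 (group labels
#' reversed relative to the divergence direction), `reflect = "auto"`
#' substitutes `1 - aROC` before fitting.
#'
#' @param group_a,group_b Trials-x-samples matrices on a common grid
#'   (group B is expected to diverge upward from group A).
#' @param t Time vector (ms).
#' @param criterion,run Truncation parameters (see [truncate_aroc()]).
#' @param reflect One of "auto", "never", "always".
#' @return An `onset_estimate` list: `onset`, `flat_end`, `last_local_min`,
#'   `dogleg_slope`, `truncation_time`, `reflected`, `degenerate`.
#' @export
detect_onset <- function(group_a, group_b, t, criterion = 0.62, run = 3,
                         reflect = c("auto", "never", "always")) {
  reflect <- match.arg(reflect)
  series <- aroc_series(group_a, group_b, t)
  flip <- switch(reflect,
                 always = TRUE, never = FALSE,
                 auto = mean(series$aroc - 0.5) < 0)
  if (flip) series$aroc <- 1 - series$aroc
  series <- truncate_aroc(series, criterion = criterion, run = run)
  dl <- fit_dogleg(series)
  lmin <- last_local_minimum(series)
  structure(list(onset = max(dl$flat_end, lmin),
                 flat_end = dl$flat_end, last_local_min = lmin,
                 dogleg_slope = dl$slope,
                 truncation_time = series$truncation_time,
                 reflected = flip, degenerate = dl$degenerate),
            class = "onset_estimate")
}
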