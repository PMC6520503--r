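# Shared helpers: independent oracles and small ensemble builders.

# Brute-force all-pairs aROC with ties credited 0.5 (independent of the
# rank-based implementation).
brute_aroc <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) tot <- tot + (y > x) + 0.5 * (y == x)
  tot / (length(a) * length(b))
}

# Mean of a Gaussian truncated to [lo, hi], by numerical quadrature.
truncnorm_mean_quadrature <- function(mean, sd, lo = 0, hi = 1) {
  z <- pnorm(hi, mean, sd) - pnorm(lo, mean, sd)
  integrate(function(x) x * dnorm(x, mean, sd) / z, lo, hi,
            rel.tol = 1e-10)$value
}

# Ensemble of synthetic traces as a trials-x-samples matrix.
trace_ensemble <- function(n, gain, onset = 150, rise_time = 60,
                           duration = 300, noise_sd = 0) {
  t(vapply(seq_len(n), function(i)
    synthesize_trace(gain, onset = onset, rise_time = rise_time,
                     duration = duration, noise_sd = noise_sd)$value,
    numeric(duration + 101)))
}

aroc_from_values <- function(t, y) {
  structure(list(t = t, aroc = y, truncation_time = NULL),
            class = "aroc_series")
}

# Homogeneous-subject gain table with exact (noise-free) gains.
exact_gain_table <- function(alpha, beta, model = "value_neutral", w = 0.5,
                             n_subjects = 4) {
  conds <- exp3_conditions()
  subj <- data.frame(subject_id = sprintf("s%02d", seq_len(n_subjects)),
                     intercept = alpha, slope = beta, risk_weight = w,
                     noise_sd = 1)
  g <- simulate_gain_table(conds, subj, trials_per_cell = 18, seed = 1,
                           model = model)
  x <- model_predictor(g, model, w = if (model == "value_risk") w else NULL)
  g$gain <- alpha + beta * x
  g
}
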