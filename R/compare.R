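# Model comparison: WAIC on the deviance scale, pairwise Bayes factors
# K = exp(dWAIC / 2), Kass-Raftery evidence labels, and the hit-rate-ratio
# versus gain regression.

#' Watanabe-Akaike information criterion (deviance scale)
#'
#' `WAIC = -2 (lppd - p_WAIC)`, with the log pointwise predictive density
#' computed by a stabilized log-mean-exp over posterior draws and the
#' effective-parameter penalty `p_WAIC` the summed posterior variance of
#' the pointwise log-likelihood. Lower is better.
#'
#' @param loglik Draws-x-observations matrix of pointwise log-likelihood
#'   (e.g. the `loglik` element of an `hgfit`), or an `hgfit` itself.
#' @return List of class `waic`: `waic`, `lppd`, `p_waic`.
#' @export
compute_waic <- function(loglik) {
  if (inherits(loglik, "hgfit")) loglik <- loglik$loglik
  if (nrow(loglik) < 100)
    warning("fewer than 100 draws: WAIC penalty estimate may be unstable")
  m <- apply(loglik, 2, max)
  lppd <- sum(m + log(colMeans(exp(sweep(loglik, 2, m)))))
  p_waic <- sum(apply(loglik, 2, var))
  structure(list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic),
            class = "waic")
}

#' @export
print.waic <- function(x, ...) {
  cat(sprintf("WAIC (deviance scale) = %.1f  [lppd %.1f, p_waic %.1f]\n",
              x$waic, x$lppd, x$p_waic))
  invisible(x)
}

as_waic_value <- function(x) {
  if (inherits(x, "waic")) x$waic else as.numeric(x)
}

#' Pairwise Bayes factor from WAIC scores
#'
#' `K = exp((WAIC_other - WAIC_ref) / 2)` on the deviance scale: `K > 1`
#' favors the reference model. Satisfies `K(a, b) * K(b, a) = 1` and is
#' invariant to adding a constant to both scores.
#'
#' @param waic_other,waic_ref WAIC values (numbers or `waic` objects).
#' @return The Bayes factor K (> 0).
#' @export
waic_bayes_factor <- function(waic_other, waic_ref) {
  exp((as_waic_value(waic_other) - as_waic_value(waic_ref)) / 2)
}

#' Kass-Raftery evidence label for a Bayes factor
#'
#' Bands: K < 1 "negative" (evidence against the reference model);
#' 1-3 "barely worth mentioning"; 3-20 "positive"; 20-150 "strong";
#' > 150 "very strong".
#'
#' @param K Bayes factor(s), positive.
#' @return Character vector of labels.
#' @export
evidence_label <- function(K) {
  if (any(K <= 0)) stop("Bayes factors must be positive")
  vapply(K, function(k) {
    if (k < 1) "negative"
    else if (k < 3) "barely worth mentioning"
    else if (k < 20) "positive"
    else if (k <= 150) "strong"
    else "very strong"
  }, character(1))
}

#' Regression of hit-rate ratio on response gain
#'
#' Ordinary least squares of the per-condition outer/center hit-rate ratio
#' on the per-condition mean response gain, with the two-sided t test of
#' the slope. Under the default generator (hits more likely the larger the
#' corrective gain toward the cued target) the slope is negative: stronger
#' correction toward the center trades outer-target hits for center hits.
#'
#' @param gain_means Per-condition mean response gains (toward center).
#' @param hit_ratios Per-condition hit-rate ratios (outer / center).
#' @return List: `slope`, `intercept`, `p_value`, `r_squared`.
#' @export
hit_rate_gain_regression <- function(gain_means, hit_ratios) {
  if (length(gain_means) < 3) stop("need at least 3 conditions")
  if (length(hit_ratios) != length(gain_means)) stop("length mismatch")
  if (var(gain_means) < .Machine$double.eps) stop("constant predictor")
  fit <- lm(hit_ratios ~ gain_means)
  cf <- summary(fit)$coefficients
  list(slope = cf[2, 1], intercept = cf[1, 1], p_value = cf[2, 4],
       r_squared = summary(fit)$r.squared)
}

#' Fit and compare all four gain models
#'
#' Fits the probability, reward, risk-neutral value and risk-sensitive
#' value models to the same gain table, computes WAIC for each, and
#' reports the pairwise Bayes factor of every model against the best
#' (lowest-WAIC) model with its Kass-Raftery label.
#'
#' @param gains Gain-observation data frame.
#' @param config A [sampler_config()].
#' @param models Models to fit (default all four).
#' @return List of class `model_comparison`: `table` (model, waic, p_waic,
#'   k_vs_best, label, r_squared) sorted by WAIC, and `fits` (named list of
#'   `hgfit` objects).
#' @export
compare_gain_models <- function(gains, config = sampler_config(),
                                models = gain_models) {
  fits <- lapply(models, function(m) fit_hierarchical(gains, m, config))
  names(fits) <- models
  waics <- vapply(fits, function(f) compute_waic(f)$waic, numeric(1))
  p_waics <- vapply(fits, function(f) compute_waic(f)$p_waic, numeric(1))
  r2 <- vapply(fits, function(f) variance_explained(f), numeric(1))
  best <- which.min(waics)
  K <- exp((waics - waics[best]) / 2)
  tab <- data.frame(model = models, waic = waics, p_waic = p_waics,
                    k_vs_best = K,
                    label = ifelse(seq_along(K) == best, "(best)",
                                   evidence_label(pmax(K, 1))),
                    r_squared = r2, row.names = NULL,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$waic), ]
  structure(list(table = tab, fits = fits), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Gain model comparison (WAIC, deviance scale; K vs best model)\n")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Run the full Experiment-3 analysis pipeline on synthetic data
#'
#' Chains: simulate an Experiment-3 cohort -> fit all four gain models ->
#' WAIC comparison -> hit-rate-ratio regression.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param seed Integer seed.
#' @param config A [sampler_config()].
#' @param ... Passed to [simulate_exp3_cohort()].
#' @return List: `cohort`, `comparison` (a `model_comparison`),
#'   `hit_regression`.
#' @export
run_value_pipeline <- function(n_subjects = 10, seed = 1,
                               config = sampler_config(reduced = TRUE,
                                                       seed = seed), ...) {
  cohort <- simulate_exp3_cohort(n_subjects = n_subjects, seed = seed, ...)
  comparison <- compare_gain_models(cohort$gains, config)
  key <- paste(cohort$gains$r_ratio, cohort$gains$p_ratio)
  gmean <- tapply(cohort$gains$gain, key, mean)
  hkey <- paste(cohort$hits$r_ratio, cohort$hits$p_ratio)
  hr <- hit_rate_gain_regression(gmean[hkey], cohort$hits$hit_ratio)
  list(cohort = cohort, comparison = comparison, hit_regression = hr)
}
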