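# Four linear models of the windowed response gain G as a function of the
# block condition, and their hierarchical Bayesian fit:
#
#   G_{s,c} ~ Normal(alpha_s + beta_s * x_c, sigma)
#
# with subject-level alpha_s, beta_s Gaussian around group means, a
# risk-weight w_s (risk-sensitive model only) Gaussian truncated to [0,1],
# weak Normal(0, 10000 SD) priors on group means and half-Cauchy(scale 5)
# priors on group SDs and the error scale. Sampled with JAGS.

gain_models <- c("probability", "reward", "value_neutral", "value_risk")

#' Condition predictor of each gain model
#'
#' \describe{
#'   \item{probability}{`ln(P_O / P_C)`}
#'   \item{reward}{`ln(R_O / R_C)`}
#'   \item{value_neutral}{`ln(R_O P_O / (R_C P_C))` — log relative value}
#'   \item{value_risk}{`2 [(1 - w) ln(R_O / R_C) + w ln(P_O / P_C)]`}
#' }
#' The factor 2 in the risk-sensitive predictor makes `w = 0.5` reproduce
#' the risk-neutral log relative value exactly (rather than up to a slope
#' rescaling); `w < 0.5` weights the reward ratio more (risk seeking),
#' `w > 0.5` the probability ratio (risk aversion). Swapping the outer and
#' center labels negates every predictor.
#'
#' @param condition One or more `condition_design` rows (needs columns
#'   `r_ratio` and `p_ratio`, or the reward/probability fields).
#' @param model One of `"probability"`, `"reward"`, `"value_neutral"`,
#'   `"value_risk"`.
#' @param w Risk weight in \[0, 1\]; required iff `model = "value_risk"`.
#' @return Numeric predictor value(s).
#' @export
model_predictor <- function(condition, model, w = NULL) {
  model <- match.arg(model, gain_models)
  r <- if (!is.null(condition$r_ratio)) condition$r_ratio
       else condition$reward_outer / condition$reward_center
  p <- if (!is.null(condition$p_ratio)) condition$p_ratio
       else condition$p_outer / condition$p_center
  if (any(r <= 0) || any(p <= 0)) stop("ratios must be positive")
  if (model == "value_risk") {
    if (is.null(w)) stop("value_risk requires a risk weight w")
    if (any(w < 0 | w > 1)) stop("w must lie in [0, 1]")
  } else if (!is.null(w)) {
    stop("w is only meaningful for the value_risk model")
  }
  switch(model,
         probability = log(p),
         reward = log(r),
         value_neutral = log(r * p),
         value_risk = 2 * ((1 - w) * log(r) + w * log(p)))
}

#' Sampler configuration
#'
#' The full schedule mirrors the reference analysis (tune 1000, 30000
#' draws, first 5000 discarded); `reduced = TRUE` gives a fast profile
#' (tune 500, 2000 draws, 500 discarded) for tests and quick checks.
#'
#' @param tune_draws Adaptation iterations.
#' @param draws Sampling iterations per chain.
#' @param burn_discard Leading draws dropped from each chain (< `draws`).
#' @param chains Number of chains (>= 2 for split-R-hat).
#' @param seed Integer seed (drives per-chain RNG seeds).
#' @param reduced Use the reduced profile defaults.
#' @return List of class `sampler_config`.
#' @export
sampler_config <- function(tune_draws = 1000, draws = 30000,
                           burn_discard = 5000, chains = 4, seed = 1,
                           reduced = FALSE) {
  if (reduced) { tune_draws <- 500; draws <- 2000; burn_discard <- 500 }
  if (burn_discard >= draws) stop("burn_discard must be < draws")
  structure(list(tune_draws = tune_draws, draws = draws,
                 burn_discard = burn_discard, chains = chains, seed = seed),
            class = "sampler_config")
}

jags_model_string <- function(model) {
  x_term <- if (model == "value_risk")
    "2 * ((1 - w[sub[i]]) * lr[i] + w[sub[i]] * lp[i])" else "x[i]"
  w_block <- if (model == "value_risk") "
    w[s] ~ dnorm(mu.w, pow(sd.w, -2)) T(0, 1)" else ""
  w_priors <- if (model == "value_risk") "
  mu.w ~ dnorm(0, 1e-8) T(0, 1)
  sd.w ~ dt(0, 0.04, 1) T(0,)" else ""
  sprintf("
model {
  for (i in 1:N) {
    mu[i] <- alpha[sub[i]] + beta[sub[i]] * %s
    y[i] ~ dnorm(mu[i], pow(sigma, -2))
  }
  for (s in 1:S) {
    alpha[s] ~ dnorm(mu.alpha, pow(sd.alpha, -2))
    beta[s] ~ dnorm(mu.beta, pow(sd.beta, -2))%s
  }
  mu.alpha ~ dnorm(0, 1e-8)
  mu.beta ~ dnorm(0, 1e-8)
  sd.alpha ~ dt(0, 0.04, 1) T(0,)
  sd.beta ~ dt(0, 0.04, 1) T(0,)%s
  sigma ~ dt(0, 0.04, 1) T(0,)
}", x_term, w_block, w_priors)
}

# Pool gain observations across jump directions (mean per subject x
# condition); gains are already in the toward-center sign convention.
pool_gain_table <- function(gains) {
  agg <- aggregate(gain ~ subject_id + condition + r_ratio + p_ratio,
                   data = gains, FUN = mean)
  agg[order(agg$subject_id, agg$condition), ]
}

#' Fit a hierarchical Bayesian gain model
#'
#' Fits `G ~ Normal(alpha_s + beta_s x, sigma)` with partial pooling of
#' subject intercepts/slopes (and risk weights for the risk-sensitive
#' model) via MCMC in JAGS. Group-mean priors are Normal with SD 10000
#' (the group risk-weight mean additionally truncated to \[0, 1\]); group
#' SDs and the error scale have half-Cauchy(5) priors.
#'
#' @param gains Gain-observation data frame (schema of
#'   [simulate_gain_table()]): needs `subject_id`, `r_ratio`, `p_ratio`,
#'   `gain`, and `jump_direction` when `pool = TRUE`.
#' @param model One of the four gain models (see [model_predictor()]).
#' @param config A [sampler_config()].
#' @param pool Average the two jump directions per subject x condition
#'   before fitting (default TRUE).
#' @param rhat_threshold Convergence threshold; a warning is issued when
#'   any split-R-hat exceeds it.
#' @return An object of class `hgfit`: list with `model`, `draws` (pooled
#'   post-burn-in draw matrix), `chains` (per-chain matrices), `summary`
#'   (posterior mean/SD/95% quantile CI per parameter), `rhat`, `map`
#'   (parameter values of the highest-joint-log-posterior draw), `loglik`
#'   (draws x observations pointwise log-likelihood), `data`, `config`.
#' @export
fit_hierarchical <- function(gains, model = "value_risk",
                             config = sampler_config(), pool = TRUE,
                             rhat_threshold = 1.01) {
  model <- match.arg(model, gain_models)
  dat <- if (pool) pool_gain_table(gains) else gains
  subjects <- sort(unique(dat$subject_id))
  if (length(subjects) < 2) stop("need at least 2 subjects")
  if (length(unique(paste(dat$r_ratio, dat$p_ratio))) < 2)
    stop("need at least 2 distinct conditions")
  sub <- match(dat$subject_id, subjects)
  jdata <- list(N = nrow(dat), S = length(subjects), sub = sub, y = dat$gain)
  if (model == "value_risk") {
    jdata$lr <- log(dat$r_ratio); jdata$lp <- log(dat$p_ratio)
  } else {
    jdata$x <- model_predictor(dat, model)
  }

  monitors <- c("mu.alpha", "mu.beta", "sd.alpha", "sd.beta", "sigma",
                "alpha", "beta")
  if (model == "value_risk") monitors <- c(monitors, "mu.w", "sd.w", "w")
  inits <- lapply(seq_len(config$chains), function(k) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = config$seed * 1000L + k)
    if (model == "value_risk") ini$w <- rep(0.5, length(subjects))
    ini
  })
  jm <- rjags::jags.model(textConnection(jags_model_string(model)),
                          data = jdata, inits = inits,
                          n.chains = config$chains,
                          n.adapt = config$tune_draws, quiet = TRUE)
  sm <- rjags::coda.samples(jm, monitors, n.iter = config$draws)
  kept <- lapply(sm, function(ch)
    as.matrix(ch)[(config$burn_discard + 1):config$draws, , drop = FALSE])
  draws <- do.call(rbind, kept)

  rhat <- compute_rhat(kept)
  if (any(rhat > rhat_threshold, na.rm = TRUE))
    warning("split-R-hat above ", rhat_threshold, " for: ",
            paste(names(rhat)[rhat > rhat_threshold], collapse = ", "))

  ll <- pointwise_loglik(draws, dat, sub, model)
  lpost <- rowSums(ll) + log_prior(draws, length(subjects), model)
  map_idx <- which.max(lpost)

  qs <- t(apply(draws, 2, quantile, probs = c(0.025, 0.975)))
  summary_df <- data.frame(parameter = colnames(draws),
                           mean = colMeans(draws),
                           sd = apply(draws, 2, sd),
                           ci_2.5 = qs[, 1], ci_97.5 = qs[, 2],
                           rhat = rhat[colnames(draws)],
                           row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model = model, draws = draws, chains = kept,
                 summary = summary_df, rhat = rhat,
                 map = draws[map_idx, ], loglik = ll,
                 data = dat, subjects = subjects, config = config),
            class = "hgfit")
}

# Per-draw, per-observation log-likelihood.
pointwise_loglik <- function(draws, dat, sub, model) {
  S <- length(unique(sub))
  alpha <- draws[, paste0("alpha[", sub, "]"), drop = FALSE]
  beta <- draws[, paste0("beta[", sub, "]"), drop = FALSE]
  sigma <- draws[, "sigma"]
  x <- if (model == "value_risk") {
    w <- draws[, paste0("w[", sub, "]"), drop = FALSE]
    2 * ((1 - w) * rep(log(dat$r_ratio), each = nrow(draws)) +
           w * rep(log(dat$p_ratio), each = nrow(draws)))
  } else {
    rep(model_predictor(dat, model), each = nrow(draws))
  }
  mu <- alpha + beta * x
  ll <- dnorm(rep(dat$gain, each = nrow(draws)), mu, sigma, log = TRUE)
  matrix(ll, nrow = nrow(draws),
         dimnames = list(NULL, paste0("obs", seq_len(nrow(dat)))))
}

# Joint log-prior density of each draw (for the MAP-draw selection).
log_prior <- function(draws, S, model) {
  half_cauchy <- function(v) dcauchy(v, 0, 5, log = TRUE) + log(2)
  lp <- dnorm(draws[, "mu.alpha"], 0, 10000, log = TRUE) +
    dnorm(draws[, "mu.beta"], 0, 10000, log = TRUE) +
    half_cauchy(draws[, "sd.alpha"]) + half_cauchy(draws[, "sd.beta"]) +
    half_cauchy(draws[, "sigma"])
  for (s in seq_len(S)) {
    lp <- lp + dnorm(draws[, paste0("alpha[", s, "]")],
                     draws[, "mu.alpha"], draws[, "sd.alpha"], log = TRUE) +
      dnorm(draws[, paste0("beta[", s, "]")],
            draws[, "mu.beta"], draws[, "sd.beta"], log = TRUE)
  }
  if (model == "value_risk") {
    muw <- draws[, "mu.w"]; sdw <- draws[, "sd.w"]
    z <- pnorm(1, muw, sdw) - pnorm(0, muw, sdw)
    for (s in seq_len(S)) {
      ws <- draws[, paste0("w[", s, "]")]
      lp <- lp + dnorm(ws, muw, sdw, log = TRUE) - log(z)
    }
    lp <- lp + half_cauchy(sdw)
  }
  lp
}

#' Split-chain Gelman-Rubin R-hat
#'
#' Each chain is split in half; R-hat is computed per parameter from the
#' between- and within-half variances of the resulting 2m half-chains. A
#' parameter with zero total variance returns 1 (converged by degeneracy).
#'
#' @param chains List of draw matrices (iterations x parameters), one per
#'   chain, or a `coda::mcmc.list`.
#' @return Named vector of R-hat values.
#' @export
compute_rhat <- function(chains) {
  if (inherits(chains, "mcmc.list")) chains <- lapply(chains, as.matrix)
  if (is.matrix(chains)) chains <- list(chains)
  if (length(chains) < 2 && nrow(chains[[1]]) < 4)
    stop("need at least 2 chains or a chain long enough to split")
  halves <- list()
  for (ch in chains) {
    n <- nrow(ch); h <- floor(n / 2)
    halves <- c(halves, list(ch[1:h, , drop = FALSE],
                             ch[(n - h + 1):n, , drop = FALSE]))
  }
  m <- length(halves); n <- nrow(halves[[1]])
  vapply(colnames(chains[[1]]), function(p) {
    x <- vapply(halves, function(hh) hh[, p], numeric(n))
    means <- colMeans(x); vars <- apply(x, 2, var)
    w <- mean(vars); b <- n * var(means)
    if (w < .Machine$double.eps) return(1)
    sqrt(((n - 1) / n * w + b / n) / w)
  }, numeric(1))
}

#' Posterior predictive summary over conditions
#'
#' For each condition, draws of the group-level regression line
#' `mu.alpha + mu.beta * x` are formed (for the risk-sensitive model the
#' predictor is re-evaluated per draw at that draw's group risk weight),
#' and 50% and 95% central credible bands are returned. `type =
#' "predictive"` adds Normal(0, sigma) observation noise per draw.
#'
#' @param fit An `hgfit`.
#' @param conditions `condition_design` rows (default: the fitted
#'   conditions).
#' @param type `"mean"` (estimation uncertainty of the group line) or
#'   `"predictive"` (adds observation noise).
#' @return Data frame: condition label, predictor (at the posterior-mean
#'   risk weight for value_risk), `mean`, `lo50`, `hi50`, `lo95`, `hi95`.
#' @export
posterior_predict <- function(fit, conditions = NULL,
                              type = c("mean", "predictive")) {
  type <- match.arg(type)
  if (is.null(conditions)) {
    conditions <- unique(fit$data[, c("condition", "r_ratio", "p_ratio")])
    names(conditions)[1] <- "label"
  }
  d <- fit$draws
  out <- lapply(seq_len(nrow(conditions)), function(i) {
    cond <- conditions[i, ]
    x <- if (fit$model == "value_risk")
      2 * ((1 - d[, "mu.w"]) * log(cond$r_ratio) +
             d[, "mu.w"] * log(cond$p_ratio))
    else model_predictor(cond, fit$model)
    pred <- d[, "mu.alpha"] + d[, "mu.beta"] * x
    if (type == "predictive")
      pred <- pred + rnorm(length(pred), 0, d[, "sigma"])
    q <- quantile(pred, c(0.025, 0.25, 0.75, 0.975))
    x_point <- if (fit$model == "value_risk")
      model_predictor(cond, "value_risk", w = mean(d[, "mu.w"]))
    else model_predictor(cond, fit$model)
    data.frame(condition = cond$label, predictor = x_point,
               mean = mean(pred), lo95 = q[[1]], lo50 = q[[2]],
               hi50 = q[[3]], hi95 = q[[4]], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Proportion of condition-mean gain variance explained
#'
#' `1 - SS_resid / SS_total` of the observed condition-mean gains against
#' the posterior-mean model predictions (subject-level posterior-mean
#' parameters, predictions averaged per condition).
#'
#' @param fit An `hgfit`.
#' @param gains Gain table (default: the data the model was fitted to).
#' @return R-squared (can be negative for a badly misspecified model).
#' @export
variance_explained <- function(fit, gains = NULL) {
  dat <- if (is.null(gains)) fit$data else pool_gain_table(gains)
  sub <- match(dat$subject_id, fit$subjects)
  pm <- colMeans(fit$draws)
  alpha <- pm[paste0("alpha[", sub, "]")]
  beta <- pm[paste0("beta[", sub, "]")]
  x <- if (fit$model == "value_risk") {
    w <- pm[paste0("w[", sub, "]")]
    2 * ((1 - w) * log(dat$r_ratio) + w * log(dat$p_ratio))
  } else model_predictor(dat, fit$model)
  pred <- alpha + beta * x
  key <- paste(dat$r_ratio, dat$p_ratio)
  obs_m <- tapply(dat$gain, key, mean)
  pred_m <- tapply(pred, key, mean)[names(obs_m)]
  sst <- sum((obs_m - mean(obs_m))^2)
  if (sst < .Machine$double.eps) stop("zero-variance condition means")
  1 - sum((obs_m - pred_m)^2) / sst
}

#' @export
print.hgfit <- function(x, ...) {
  cat("Hierarchical gain model fit:", x$model, "\n")
  cat(sprintf("  %d subjects, %d observations, %d chains x %d kept draws\n",
              length(x$subjects), nrow(x$data), length(x$chains),
              nrow(x$chains[[1]])))
  grp <- x$summary[grepl("^(mu|sd)\\.|^sigma$", x$summary$parameter), ]
  print(grp, digits = 3, row.names = FALSE)
  invisible(x)
}
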