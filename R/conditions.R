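#' Construct a block condition design
#'
#' A condition describes the reward/probability structure of one experimental
#' block: the rewards attached to the outer and center targets, the
#' probability that the outer vs center target is cued after a cursor jump,
#' and the cue probabilities of the three targets on unperturbed trials.
#'
#' @param experiment Integer 1, 2 or 3.
#' @param reward_outer,reward_center Rewards (currency units) of the outer and
#'   center targets; must be positive.
#' @param p_outer_given_jump,p_center_given_jump Probability that the
#'   jump-side outer / center target is cued on a cursor-jump trial. Only the
#'   center and the jump-side outer target can be cued after a jump, so the
#'   two must sum to 1.
#' @param unperturbed_probs Length-3 probability vector (left, center, right)
#'   for target cueing on unperturbed trials; must sum to 1.
#' @param label Optional condition label.
#' @return A one-row data frame of class `condition_design` with columns
#'   `experiment`, `label`, `reward_outer`, `reward_center`, `p_outer`,
#'   `p_center`, `up_left`, `up_center`, `up_right`, `r_ratio`, `p_ratio`,
#'   `rel_value` (the relative value, `r_ratio * p_ratio`).
#' @export
condition_design <- function(experiment, reward_outer, reward_center,
                             p_outer_given_jump, p_center_given_jump,
                             unperturbed_probs, label = NULL) {
  experiment <- as.integer(experiment)
  if (!experiment %in% 1:3) stop("unknown experiment id: ", experiment)
  if (reward_outer <= 0 || reward_center <= 0) stop("rewards must be positive")
  probs <- c(p_outer_given_jump, p_center_given_jump)
  if (any(probs < 0 | probs > 1)) stop("jump-cue probabilities must be in [0, 1]")
  if (abs(sum(probs) - 1) > 1e-8)
    stop("p_outer_given_jump + p_center_given_jump must equal 1")
  if (length(unperturbed_probs) != 3 || any(unperturbed_probs < 0))
    stop("unperturbed_probs must be 3 non-negative probabilities")
  if (abs(sum(unperturbed_probs) - 1) > 1e-8)
    stop("unperturbed_probs must sum to 1")
  r_ratio <- reward_outer / reward_center
  p_ratio <- p_outer_given_jump / p_center_given_jump
  if (is.null(label)) label <- sprintf("e%d_r%g_p%g", experiment, r_ratio, p_ratio)
  out <- data.frame(
    experiment = experiment, label = label,
    reward_outer = reward_outer, reward_center = reward_center,
    p_outer = p_outer_given_jump, p_center = p_center_given_jump,
    up_left = unperturbed_probs[1], up_center = unperturbed_probs[2],
    up_right = unperturbed_probs[3],
    r_ratio = r_ratio, p_ratio = p_ratio, rel_value = r_ratio * p_ratio,
    stringsAsFactors = FALSE
  )
  class(out) <- c("condition_design", class(out))
  out
}

#' Condition grids of the three experiments
#'
#' `exp1_conditions()` returns the two reward-manipulation blocks (20-fold
#' reward asymmetry, equiprobable jump-cue targets).
#' `exp2_conditions()` returns the two probability-manipulation blocks
#' (2-fold cue-probability asymmetry, equal rewards).
#' `exp3_conditions()` returns the 8 value-manipulation blocks: all
#' combinations of reward ratio and jump-cue probability ratio in
#' \{0.5, 1, 2\} except the ratio-1/ratio-1 cell, giving 5 distinct relative
#' values \{0.25, 0.5, 1, 2, 4\}. On Experiment-3 unperturbed trials only the
#' center target is cued.
#'
#' @return A data frame with one `condition_design` row per block.
#' @export
exp1_conditions <- function() {
  rbind(
    condition_design(1, reward_outer = 10, reward_center = 0.5,
                     p_outer_given_jump = 0.5, p_center_given_jump = 0.5,
                     unperturbed_probs = rep(1 / 3, 3), label = "outer_rewarded"),
    condition_design(1, reward_outer = 0.5, reward_center = 10,
                     p_outer_given_jump = 0.5, p_center_given_jump = 0.5,
                     unperturbed_probs = rep(1 / 3, 3), label = "center_rewarded")
  )
}

#' @rdname exp1_conditions
#' @export
exp2_conditions <- function() {
  rbind(
    condition_design(2, reward_outer = 1, reward_center = 1,
                     p_outer_given_jump = 2 / 3, p_center_given_jump = 1 / 3,
                     unperturbed_probs = c(0.4, 0.2, 0.4), label = "outer_probable"),
    condition_design(2, reward_outer = 1, reward_center = 1,
                     p_outer_given_jump = 1 / 3, p_center_given_jump = 2 / 3,
                     unperturbed_probs = c(0.25, 0.5, 0.25), label = "center_probable")
  )
}

#' @rdname exp1_conditions
#' @export
exp3_conditions <- function() {
  grid <- expand.grid(r = c(0.5, 1, 2), p = c(0.5, 1, 2))
  grid <- grid[!(grid$r == 1 & grid$p == 1), ]
  rewards <- list(`0.5` = c(5, 10), `1` = c(10, 10), `2` = c(10, 5))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$r[i]; p <- grid$p[i]
    rw <- rewards[[as.character(r)]]
    condition_design(3, reward_outer = rw[1], reward_center = rw[2],
                     p_outer_given_jump = p / (1 + p),
                     p_center_given_jump = 1 / (1 + p),
                     unperturbed_probs = c(0, 1, 0))
  })
  do.call(rbind, rows)
}
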