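# Level-wise Bayes-factor analyses built on population-level posterior
# predictions. The H1 priors incorporate the expectation that harder
# conditions produce smaller effects: the H1 sd at level i is half the
# predicted effect at the next-easier level i+1, with a fixed wide sd at the
# easiest level.

as_prediction_list <- function(predictions) {
  # Accepts a data frame (level_index implicit by row order, hardest first)
  # or a list of lists with mean/sd.
  if (is.data.frame(predictions)) {
    lapply(seq_len(nrow(predictions)), function(i)
      list(mean = predictions$mean[i], sd = predictions$sd[i]))
  } else predictions
}

#' Bayes factors for above-chance performance per level
#'
#' At each level the observed effect is the population posterior predictive
#' (mean, sd) of performance. H0 is `Normal(0.5, 0.005)`; H1 is a
#' half-Normal (upper tail) centered at 0.5 whose sd is half the excess over
#' chance of the predicted performance at the next-easier level; the easiest
#' level uses sd 0.25. If the neighboring prediction falls below chance the
#' H1 sd is floored at `sd_floor` and the level is flagged.
#'
#' @param predictions Per-level predictive summaries ordered hardest first:
#'   a data frame with `mean`, `sd` columns or a list of `list(mean, sd)`.
#' @param easiest_sd H1 sd at the easiest level.
#' @param sd_floor Floor for degenerate H1 sds.
#' @return Data frame with `level_index`, `obs_mean`, `obs_sd`, `h1_sd`,
#'   `bf10`, `floored`.
#' @export
bf_above_chance <- function(predictions, easiest_sd = 0.25,
                            sd_floor = 0.005) {
  preds <- as_prediction_list(predictions)
  L <- length(preds)
  out <- lapply(seq_len(L), function(i) {
    if (i < L) {
      h1_sd <- (preds[[i + 1]]$mean - 0.5) / 2
    } else {
      h1_sd <- easiest_sd
    }
    floored <- h1_sd < sd_floor
    if (floored) h1_sd <- sd_floor
    bf <- bayes_factor(preds[[i]]$mean, preds[[i]]$sd,
      h0 = prior_spec("normal", center = 0.5, sd = 0.005),
      h1 = prior_spec("half_normal_upper", center = 0.5, sd = h1_sd))
    data.frame(level_index = i, obs_mean = preds[[i]]$mean,
               obs_sd = preds[[i]]$sd, h1_sd = h1_sd, bf10 = bf$bf10,
               floored = floored)
  })
  do.call(rbind, out)
}

#' Bayes factors for per-level differences between two analyses
#'
#' The observed effect at each level is the posterior predictive (mean, sd)
#' of the A - B difference. Prior families:
#' \describe{
#'   \item{`type2_HRFAR`, `conditional`}{H0 point at 0; H1 half-Normal
#'     (upper tail) centered at 0 with sd half the predicted difference at
#'     the next-easier level, and sd 0.5 at the easiest level.}
#'   \item{`interval_order`}{H0 point at 0; H1 two-tailed Normal(0, 0.1) at
#'     every level.}
#' }
#'
#' @param predictions_a,predictions_b Per-level predictive summaries
#'   (hardest first), as in [bf_above_chance()]. Differences are formed as
#'   mean A - mean B with sds combined in quadrature, unless
#'   `predictions_diff` is supplied with the difference summaries directly.
#' @param family Analysis family (see Details).
#' @param predictions_diff Optional per-level summaries of the difference
#'   itself (e.g. from [posterior_predict_diff()]); overrides A/B.
#' @param easiest_sd H1 sd at the easiest level for the half-normal
#'   families.
#' @param sd_floor Floor for degenerate H1 sds.
#' @return Data frame with `level_index`, `obs_mean`, `obs_sd`, `h1_sd`,
#'   `bf10`, `floored`.
#' @export
bf_difference <- function(predictions_a = NULL, predictions_b = NULL,
                          family = c("type2_HRFAR", "conditional",
                                     "interval_order"),
                          predictions_diff = NULL,
                          easiest_sd = 0.5, sd_floor = 0.005) {
  family <- match.arg(family)
  if (is.null(predictions_diff)) {
    pa <- as_prediction_list(predictions_a)
    pb <- as_prediction_list(predictions_b)
    if (length(pa) != length(pb)) {
      stop("A and B predictions must cover the same levels", call. = FALSE)
    }
    preds <- lapply(seq_along(pa), function(i)
      list(mean = pa[[i]]$mean - pb[[i]]$mean,
           sd = sqrt(pa[[i]]$sd^2 + pb[[i]]$sd^2)))
  } else {
    preds <- as_prediction_list(predictions_diff)
  }
  L <- length(preds)
  out <- lapply(seq_len(L), function(i) {
    floored <- FALSE
    if (family == "interval_order") {
      h1 <- prior_spec("normal", center = 0, sd = 0.1)
      h1_sd <- 0.1
    } else {
      h1_sd <- if (i < L) preds[[i + 1]]$mean / 2 else easiest_sd
      floored <- h1_sd < sd_floor
      if (floored) h1_sd <- sd_floor
      h1 <- prior_spec("half_normal_upper", center = 0, sd = h1_sd)
    }
    bf <- bayes_factor(preds[[i]]$mean, preds[[i]]$sd,
                       h0 = prior_spec("point", center = 0), h1 = h1)
    data.frame(level_index = i, obs_mean = preds[[i]]$mean,
               obs_sd = preds[[i]]$sd, h1_sd = h1_sd, bf10 = bf$bf10,
               floored = floored)
  })
  do.call(rbind, out)
}

#' Fit the above-chance analysis for one correctness variable
#'
#' Convenience wrapper: aggregates a correctness flag per participant x
#' level, fits the hierarchical logistic model, extracts posterior
#' predictions at each scaled level and computes the per-level above-chance
#' Bayes factors.
#'
#' @param trials A `trial_records` data frame of one task.
#' @param which `"orientation"` or `"interval"` correctness.
#' @param chains,iter,seed Sampler settings.
#' @return List with `fit`, `predictions` (data frame) and `bf` (data
#'   frame from [bf_above_chance()]).
#' @export
analyze_above_chance <- function(trials,
                                 which = c("orientation", "interval"),
                                 chains = 2, iter = 2000, seed = 1) {
  which <- match.arg(which)
  tk <- single_task(trials)
  lev <- condition_levels(tk)
  xs <- scale_levels(lev$physical_value)
  flag <- if (which == "orientation") trials$ori_correct else
    trials$int_correct
  dat <- data.frame(participant = trials$participant_id,
                    level = xs[trials$level_index],
                    correct = flag)
  fit <- fit_hier_logistic(dat, chains = chains, iter = iter, seed = seed)
  preds <- posterior_predict(fit, xs)
  bf <- bf_above_chance(preds)
  list(fit = fit, predictions = preds, bf = bf)
}
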