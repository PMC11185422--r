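# Hierarchical Bayesian logistic regression with participants as random
# effects. Correctness is Bernoulli with logit p = a_participant +
# b_participant * level (level scaled to (0,1]); participant intercepts and
# slopes are drawn from population-level Normals whose means carry
# Normal(0, 0.25) and Normal(0, 1) priors and whose standard deviations
# carry Exponential(1) priors. Trial-level Bernoulli data are aggregated to
# binomial counts per participant x level (identical likelihood). Sampling
# is delegated to JAGS; split-Rhat and effective sample sizes are checked
# after the run.

JAGS_SLOPE_MODEL <- "
model {
  for (i in 1:N) {
    y[i] ~ dbin(p[i], n[i])
    logit(p[i]) <- a[pid[i]] + b[pid[i]] * x[i]
  }
  for (j in 1:J) {
    a[j] ~ dnorm(abar, tau_a)
    b[j] ~ dnorm(bbar, tau_b)
  }
  abar ~ dnorm(0, prec_abar)
  bbar ~ dnorm(0, prec_bbar)
  sigma_a ~ dexp(1)
  sigma_b ~ dexp(1)
  tau_a <- 1 / (sigma_a * sigma_a)
  tau_b <- 1 / (sigma_b * sigma_b)
}
"

JAGS_INTERCEPT_MODEL <- "
model {
  for (i in 1:N) {
    y[i] ~ dbin(p[i], n[i])
    logit(p[i]) <- a[pid[i]]
  }
  for (j in 1:J) {
    a[j] ~ dnorm(abar, tau_a)
  }
  abar ~ dnorm(0, prec_abar)
  sigma_a ~ dexp(1)
  tau_a <- 1 / (sigma_a * sigma_a)
}
"

#' Specification of the hierarchical logistic model
#'
#' @param include_slope Include per-participant slopes on scaled level.
#' @param prior_a_bar_sd Standard deviation of the Normal prior on the
#'   population intercept (0.25 for performance models, 1 for the
#'   intercept-only response-bias model).
#' @param prior_b_bar_sd Standard deviation of the Normal prior on the
#'   population slope.
#' @return A `logistic_model_spec` list.
#' @export
logistic_model_spec <- function(include_slope = TRUE,
                                prior_a_bar_sd = 0.25,
                                prior_b_bar_sd = 1) {
  structure(list(include_slope = include_slope,
                 prior_a_bar_sd = prior_a_bar_sd,
                 prior_b_bar_sd = prior_b_bar_sd),
            class = "logistic_model_spec")
}

aggregate_bernoulli <- function(data) {
  if (all(c("k", "n") %in% names(data))) return(data)
  stopifnot(all(c("participant", "level", "correct") %in% names(data)))
  key <- interaction(data$participant, data$level, drop = TRUE)
  out <- do.call(rbind, lapply(split(data, key), function(sub) {
    data.frame(participant = sub$participant[1], level = sub$level[1],
               k = sum(sub$correct), n = nrow(sub))
  }))
  rownames(out) <- NULL
  out
}

#' Fit the hierarchical logistic model by MCMC
#'
#' @param data Either trial-level data (`participant`, `level`, `correct`)
#'   or aggregated counts (`participant`, `level`, `k`, `n`). `level` must
#'   already be scaled to (0, 1] (0 allowed for intercept-only models).
#' @param spec A [logistic_model_spec()].
#' @param chains,iter,warmup Sampler settings. `iter` counts post-warmup
#'   draws per chain; adaptation/warmup defaults to `iter / 2`.
#' @param seed Integer seed; chain seeds are derived deterministically.
#' @param rhat_limit Diagnostic threshold; exceeding it raises a warning and
#'   sets `diagnostics$ok = FALSE`.
#' @return A `hier_logistic_fit` with `draws` (matrix of population-level
#'   and per-participant parameters), `participants`, `spec`, `diagnostics`
#'   (`rhat`, `n_eff`, `ok`).
#' @export
fit_hier_logistic <- function(data, spec = logistic_model_spec(),
                              chains = 4, iter = 2000,
                              warmup = max(500, iter %/% 2),
                              seed = 1, rhat_limit = 1.01) {
  agg <- aggregate_bernoulli(data)
  participants <- sort(unique(as.character(agg$participant)))
  if (length(participants) < 2L) {
    stop("hierarchical model needs >= 2 participants", call. = FALSE)
  }
  if (spec$include_slope && length(unique(agg$level)) < 2L) {
    stop("slope model needs >= 2 levels", call. = FALSE)
  }
  jd <- list(y = as.integer(agg$k), n = as.integer(agg$n),
             pid = match(as.character(agg$participant), participants),
             N = nrow(agg), J = length(participants),
             prec_abar = 1 / spec$prior_a_bar_sd^2)
  monitor <- c("abar", "sigma_a", "a")
  model_str <- JAGS_INTERCEPT_MODEL
  if (spec$include_slope) {
    jd$x <- agg$level
    jd$prec_bbar <- 1 / spec$prior_b_bar_sd^2
    monitor <- c("abar", "bbar", "sigma_a", "sigma_b", "a", "b")
    model_str <- JAGS_SLOPE_MODEL
  }
  inits <- lapply(seq_len(chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, i))
  })
  jm <- rjags::jags.model(textConnection(model_str), data = jd,
                          inits = inits, n.chains = chains,
                          n.adapt = warmup, quiet = TRUE)
  samp <- rjags::coda.samples(jm, monitor, n.iter = iter)
  rhat <- tryCatch(
    coda::gelman.diag(samp, multivariate = FALSE,
                      autoburnin = FALSE)$psrf[, 1],
    error = function(e) NULL)
  n_eff <- coda::effectiveSize(samp)
  ok <- !is.null(rhat) && all(is.finite(rhat)) && all(rhat < rhat_limit)
  if (!ok) {
    warning("MCMC diagnostics: split-Rhat >= ", rhat_limit,
            " on some parameters; treat estimates with caution",
            call. = FALSE)
  }
  draws <- do.call(rbind, lapply(samp, as.matrix))
  structure(list(draws = draws, participants = participants, spec = spec,
                 diagnostics = list(rhat = rhat, n_eff = n_eff, ok = ok),
                 chains = chains, iter = iter, seed = seed),
            class = "hier_logistic_fit")
}

#' Population-level posterior prediction on the probability scale
#'
#' Summarizes `inverse-logit(abar + bbar * level)` over posterior draws. For
#' intercept-only fits the slope term is absent. For difference analyses use
#' [posterior_predict_diff()].
#'
#' @param fit A `hier_logistic_fit`.
#' @param level Scaled level value (vectorized).
#' @param draws Return the raw predictive draws as well.
#' @return For scalar `level`, a list `mean`, `sd` (and `draws`); for vector
#'   `level`, a data frame with one row per level.
#' @export
posterior_predict <- function(fit, level, draws = FALSE) {
  stopifnot(inherits(fit, "hier_logistic_fit"))
  if (any(level < 0 | level > 1)) {
    warning("level outside (0,1]: extrapolating beyond the scaled design",
            call. = FALSE)
  }
  one <- function(lv) {
    eta <- fit$draws[, "abar"]
    if (fit$spec$include_slope) eta <- eta + fit$draws[, "bbar"] * lv
    stats::plogis(eta)
  }
  if (length(level) == 1L) {
    p <- one(level)
    out <- list(mean = mean(p), sd = stats::sd(p))
    if (draws) out$draws <- p
    return(out)
  }
  do.call(rbind, lapply(level, function(lv) {
    p <- one(lv)
    data.frame(level = lv, mean = mean(p), sd = stats::sd(p))
  }))
}

#' Posterior prediction of a difference between two fitted models
#'
#' Pairs the two fits' predictive draws at a level and summarizes the A - B
#' difference. The fits are independent, so the pairing is arbitrary; the
#' draws are aligned by index (truncated to the shorter chain).
#'
#' @param fit_a,fit_b `hier_logistic_fit` objects.
#' @param level Scaled level value.
#' @return List `mean`, `sd` of the difference on the probability scale.
#' @export
posterior_predict_diff <- function(fit_a, fit_b, level) {
  pa <- posterior_predict(fit_a, level, draws = TRUE)$draws
  pb <- posterior_predict(fit_b, level, draws = TRUE)$draws
  m <- min(length(pa), length(pb))
  d <- pa[seq_len(m)] - pb[seq_len(m)]
  list(mean = mean(d), sd = stats::sd(d))
}
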