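# Bayes-factor calculator in the style of Dienes: the effect of interest is
# summarized by a Normal likelihood (obs_mean, obs_sd) and integrated against
# an H0 and an H1 prior. Priors may be a point mass, a Normal, or a
# half-Normal truncated to the upper or lower tail.

#' Specify a prior for Bayes-factor computation
#'
#' @param kind One of `"point"`, `"normal"`, `"half_normal_upper"`,
#'   `"half_normal_lower"`.
#' @param center Prior center (the point for `"point"`; the truncation point
#'   and mode for half-normals).
#' @param sd Prior standard deviation parameter (ignored for `"point"`).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(kind = c("point", "normal", "half_normal_upper",
                                "half_normal_lower"),
                       center, sd = NULL) {
  kind <- match.arg(kind)
  assert_scalar_number(center, "center")
  if (kind != "point") {
    assert_scalar_number(sd, "sd")
    if (sd <= 0) stop("prior sd must be positive", call. = FALSE)
  }
  structure(list(kind = kind, center = center, sd = sd), class = "prior_spec")
}

prior_density <- function(prior, theta) {
  switch(prior$kind,
    normal = stats::dnorm(theta, prior$center, prior$sd),
    half_normal_upper = ifelse(theta >= prior$center,
      2 * stats::dnorm(theta, prior$center, prior$sd), 0),
    half_normal_lower = ifelse(theta <= prior$center,
      2 * stats::dnorm(theta, prior$center, prior$sd), 0),
    stop("no density for point priors", call. = FALSE)
  )
}

#' Marginal likelihood of a summarized effect under a prior
#'
#' Computes the integral of `Normal(obs_mean; theta, obs_sd)` times the prior
#' density over theta, by adaptive quadrature (relative tolerance 1e-8,
#' bounds at 12 standard deviations beyond the prior/likelihood support).
#' For a point prior this is the Normal density at the point; for a Normal
#' prior it equals the closed form
#' `Normal(obs_mean; center, sqrt(obs_sd^2 + sd^2))`.
#'
#' @param obs_mean,obs_sd Effect summary (posterior or sampling mean and sd).
#' @param prior A [prior_spec()].
#' @return Positive scalar.
#' @export
marginal_likelihood <- function(obs_mean, obs_sd, prior) {
  assert_scalar_number(obs_mean, "obs_mean")
  assert_scalar_number(obs_sd, "obs_sd")
  if (obs_sd <= 0) stop("obs_sd must be positive", call. = FALSE)
  stopifnot(inherits(prior, "prior_spec"))
  if (prior$kind == "point") {
    return(stats::dnorm(obs_mean, prior$center, obs_sd))
  }
  # The integrand is the product of two bell curves; essentially all of its
  # mass lies in the intersection of their 12-sd windows. Integrating only
  # there keeps adaptive quadrature from missing a narrow likelihood spike
  # inside a wide prior.
  lo_pr <- prior$center - 12 * prior$sd
  hi_pr <- prior$center + 12 * prior$sd
  if (prior$kind == "half_normal_upper") lo_pr <- prior$center
  if (prior$kind == "half_normal_lower") hi_pr <- prior$center
  lo <- max(lo_pr, obs_mean - 12 * obs_sd)
  hi <- min(hi_pr, obs_mean + 12 * obs_sd)
  if (lo >= hi) return(0)  # windows disjoint: marginal underflows to zero
  f <- function(theta) stats::dnorm(obs_mean, theta, obs_sd) *
    prior_density(prior, theta)
  stats::integrate(f, lo, hi, rel.tol = 1e-8, abs.tol = 0,
                   subdivisions = 400L)$value
}

#' Bayes factor between two hypotheses about a summarized effect
#'
#' `bf10` is the ratio of the marginal likelihood of the observed effect
#' under the H1 prior to that under the H0 prior; swapping the hypotheses
#' inverts the ratio exactly.
#'
#' @param obs_mean,obs_sd Effect summary treated as a Normal likelihood.
#' @param h0,h1 [prior_spec()] objects.
#' @return A `bf_result` list with `bf10`, `obs_mean`, `obs_sd`, `h0`, `h1`.
#' @export
bayes_factor <- function(obs_mean, obs_sd, h0, h1) {
  m0 <- marginal_likelihood(obs_mean, obs_sd, h0)
  m1 <- marginal_likelihood(obs_mean, obs_sd, h1)
  structure(list(bf10 = m1 / m0, obs_mean = obs_mean, obs_sd = obs_sd,
                 h0 = h0, h1 = h1), class = "bf_result")
}

#' Central prior interval of a logistic-normal threshold prior
#'
#' With the regression intercept given a `Normal(0, sd)` prior, the implied
#' group-level threshold `inverse-logit(intercept)` has a central `mass`
#' interval computed in closed form from Normal quantiles. With `sd = 0.25`
#' and `mass = 0.95` this gives (0.38, 0.62) to two decimals: the prior
#' expects near-chance thresholds.
#'
#' @param sd Positive standard deviation of the intercept prior.
#' @param mass Interval probability mass in (0, 1).
#' @return Numeric vector `c(lo, hi)` on the probability scale.
#' @export
prior_threshold_interval <- function(sd, mass = 0.95) {
  assert_scalar_number(sd, "sd")
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("mass must be in (0,1)", call. = FALSE)
  alpha <- (1 - mass) / 2
  stats::plogis(stats::qnorm(c(alpha, 1 - alpha), mean = 0, sd = sd))
}

#' One-sample t test from raw values or summary statistics
#'
#' Used for group-level response-bias tests against 50%. Either pass the raw
#' per-participant values `x`, or the summary triple (`mean`, `sd`, `n`).
#'
#' @param x Optional numeric vector of per-participant values.
#' @param mu Null value.
#' @param mean,sd,n Summary statistics, used when `x` is `NULL`.
#' @return List with `t`, `df`, `p`, `mean`, `sd`, `n`.
#' @export
one_sample_t <- function(x = NULL, mu = 0, mean = NULL, sd = NULL, n = NULL) {
  if (!is.null(x)) {
    if (length(x) < 2L) stop("t undefined: need at least 2 values",
                             call. = FALSE)
    mean <- base::mean(x); sd <- stats::sd(x); n <- length(x)
  } else {
    assert_scalar_number(mean, "mean"); assert_scalar_number(sd, "sd")
    assert_scalar_number(n, "n")
    if (n < 2) stop("t undefined: need n >= 2", call. = FALSE)
  }
  tval <- if (sd == 0) {
    if (mean == mu) 0 else sign(mean - mu) * Inf
  } else {
    (mean - mu) / (sd / sqrt(n))
  }
  df <- n - 1
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       mean = mean, sd = sd, n = n)
}

#' Bayes factor for a positive performance slope
#'
#' Fits a (maximum-likelihood) logistic regression of per-level correct
#' counts on scaled level for one participant, summarizes the slope as
#' (estimate, standard error), and contrasts H1 "positive slope"
#' (half-Gaussian prior, mean 0, sd 2.30, upper tail) against H0 "null
#' slope" (point prior at 0). Complete separation is handled by add-0.5
#' count smoothing per level; the result is flagged `penalized`.
#'
#' @param k Integer vector of correct counts per level.
#' @param n Integer vector of trial counts per level.
#' @param x Scaled level values in (0, 1], same length.
#' @param h1_sd Standard deviation of the half-Gaussian H1 prior.
#' @return A `bf_result` with extra fields `slope`, `se`, `penalized`.
#' @export
slope_bf <- function(k, n, x, h1_sd = 2.30) {
  if (length(x) < 2L) stop("slope undefined: need >= 2 levels", call. = FALSE)
  stopifnot(length(k) == length(n), length(n) == length(x))
  fit_once <- function(k, n) {
    stats::glm(cbind(k, n - k) ~ x, family = stats::binomial())
  }
  penalized <- FALSE
  fit <- withCallingHandlers(
    fit_once(k, n),
    warning = function(w) {
      penalized <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  co <- summary(fit)$coefficients
  if (penalized || !is.finite(co["x", "Std. Error"]) ||
      abs(co["x", "Estimate"]) > 15) {
    penalized <- TRUE
    fit <- suppressWarnings(fit_once(k + 0.5, n + 1))
    co <- summary(fit)$coefficients
  }
  res <- bayes_factor(co["x", "Estimate"], co["x", "Std. Error"],
                      h0 = prior_spec("point", center = 0),
                      h1 = prior_spec("half_normal_upper", center = 0,
                                      sd = h1_sd))
  res$slope <- unname(co["x", "Estimate"])
  res$se <- unname(co["x", "Std. Error"])
  res$penalized <- penalized
  res
}
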