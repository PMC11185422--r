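# Seven Bayesian observers based on two-dimensional signal detection theory.
# Evidence for the two offset orientations spans a Cartesian plane; a
# stimulus of evidence strength c is a bivariate Gaussian source with
# identity covariance at [c, 0] (left) or [0, c] (right). The neutral
# (offset-absent) Vernier is either at the origin or, in models that reserve
# the origin for "no stimulus at all", on the main diagonal at [c/2, c/2].
# Orientation is judged from the posterior over the two orientations, either
# marginalizing over a grid of candidate strengths or conditioning on the
# most likely strength (hierarchical). The interval judgment compares either
# the confidence in the orientation choice (models 1-4) or the posterior
# visibility of an offset (models 5-7) between the two intervals via a log
# decision variable D; OP is chosen when D (plus access noise of sd sigma_D)
# exceeds 0.

MODEL_ATTRS <- data.frame(
  model_id = 1:7,
  placement = c("origin", "origin", "diagonal", "diagonal",
                "origin", "diagonal", "diagonal"),
  strategy = c("marginalize", "hierarchical", "marginalize", "hierarchical",
               "marginalize", "marginalize", "hierarchical"),
  judgment = c("confidence", "confidence", "confidence", "confidence",
               "visibility", "visibility", "visibility"),
  stringsAsFactors = FALSE
)

LOG_FLOOR <- -745  # below exp() underflow; guards log(0) in visibility ratios

#' Observer model specification
#'
#' The seven models combine three attributes: neutral-source placement
#' (origin vs diagonal), strength handling (marginalizing vs hierarchical),
#' and interval-judgment type (confidence vs visibility). Model 5 has only
#' one possible offset-absent source, so its hierarchical and marginalizing
#' variants are equivalent; one canonical computation is used regardless of
#' the `strategy` argument.
#'
#' @param model_id Integer 1..7.
#' @param sigma_d Nonnegative sd of Gaussian noise added to the interval
#'   decision variable D (0 = ideal observer).
#' @param c_grid Candidate evidence strengths (default 0 to 5 in steps of
#'   0.1, 51 values).
#' @param strategy Optional; only meaningful for model 5, where either value
#'   yields the same observer.
#' @return An `observer_spec` list.
#' @export
observer_spec <- function(model_id, sigma_d = 0, c_grid = seq(0, 5, by = 0.1),
                          strategy = NULL) {
  if (!model_id %in% 1:7) stop("model_id must be 1..7", call. = FALSE)
  if (sigma_d < 0) stop("sigma_d must be nonnegative", call. = FALSE)
  if (length(c_grid) == 0L) stop("empty c_grid", call. = FALSE)
  at <- MODEL_ATTRS[MODEL_ATTRS$model_id == model_id, ]
  structure(list(model_id = model_id, placement = at$placement,
                 strategy = at$strategy, judgment = at$judgment,
                 sigma_d = sigma_d, c_grid = sort(c_grid)),
            class = "observer_spec")
}

#' Mean of an evidence source
#'
#' Left and right sources sit at `[c, 0]` and `[0, c]`. The neutral source
#' is at the origin for origin placement and at `[c/2, c/2]` for diagonal
#' placement; "absent" is always the origin. Covariance is the identity
#' throughout and is not exposed.
#'
#' @param placement `"origin"` or `"diagonal"`.
#' @param source_kind `"left"`, `"right"`, `"neutral"`, or `"absent"`.
#' @param c Evidence strength (>= 0).
#' @return Numeric 2-vector.
#' @export
source_mean <- function(placement = c("origin", "diagonal"),
                        source_kind = c("left", "right", "neutral", "absent"),
                        c) {
  placement <- match.arg(placement)
  source_kind <- match.arg(source_kind)
  if (c < 0) stop("evidence strength c must be nonnegative", call. = FALSE)
  switch(source_kind,
         left = c(c, 0),
         right = c(0, c),
         neutral = if (placement == "origin") c(0, 0) else c(c / 2, c / 2),
         absent = c(0, 0))
}

#' Draw one trial's evidence samples
#'
#' The OP-interval sample comes from the oriented source at strength `c`;
#' the OA-interval sample from the neutral source (placement-dependent) at
#' the same strength. Uses the current R random-number stream; seed with
#' `set.seed()` or `withr::with_seed()`.
#'
#' @param spec An [observer_spec()].
#' @param c Evidence strength.
#' @param true_orientation `"left"` or `"right"`.
#' @return List with `d_op` and `d_oa`, each a numeric 2-vector.
#' @export
sample_evidence <- function(spec, c, true_orientation = c("left", "right")) {
  true_orientation <- match.arg(true_orientation)
  mu_op <- source_mean(spec$placement, true_orientation, c)
  mu_oa <- source_mean(spec$placement, "neutral", c)
  list(d_op = mu_op + stats::rnorm(2), d_oa = mu_oa + stats::rnorm(2))
}

# Log bivariate-normal kernels (constant dropped; it cancels in every
# posterior ratio used here). X is n x 2; mx/my are length-G source means.
ll_sources <- function(X, mx, my) {
  -0.5 * (outer(X[, 1], mx, "-")^2 + outer(X[, 2], my, "-")^2)
}

# All per-interval quantities the seven models need, vectorized over samples.
interval_quantities <- function(X, spec) {
  g <- spec$c_grid
  G <- length(g)
  n <- nrow(X)
  llL <- ll_sources(X, g, rep(0, G))
  llR <- ll_sources(X, rep(0, G), g)
  if (spec$strategy == "hierarchical" && spec$model_id != 5L) {
    iL <- max.col(llL, ties.method = "first")  # ties take the smaller c
    iR <- max.col(llR, ties.method = "first")
    dL <- llL[cbind(seq_len(n), iL)]
    dR <- llR[cbind(seq_len(n), iR)]
    pL <- 1 / (1 + exp(dR - dL))
  } else {
    sL <- row_lse(llL)
    sR <- row_lse(llR)
    pL <- 1 / (1 + exp(sR - sL))
    iL <- iR <- NULL
  }
  tie <- pL == 0.5
  choose_left <- pL > 0.5
  if (any(tie)) {
    choose_left[tie] <- stats::runif(sum(tie)) < 0.5
  }
  lp_chosen <- log(ifelse(choose_left, pL, 1 - pL))
  chat <- NULL
  if (!is.null(iL)) chat <- ifelse(choose_left, g[iL], g[iR])
  log1m_pn <- NULL
  if (spec$judgment == "visibility") {
    if (spec$model_id == 5L) {
      ll0 <- -0.5 * (X[, 1]^2 + X[, 2]^2)
      log_alt <- log((rowSums(exp(llL)) + rowSums(exp(llR))) / (2 * G))
      log_n <- ll0
    } else if (spec$model_id == 6L) {
      llN <- ll_sources(X, g / 2, g / 2)
      log_n <- row_lse(llN) - log(G)
      log_alt <- log((rowSums(exp(llL)) + rowSums(exp(llR))) / (2 * G))
    } else {  # model 7: everything at the chosen orientation's c-hat
      ii <- ifelse(choose_left, iL, iR)
      ch <- g[ii]
      log_n <- -0.5 * ((X[, 1] - ch / 2)^2 + (X[, 2] - ch / 2)^2)
      llLc <- llL[cbind(seq_len(n), ii)]
      llRc <- llR[cbind(seq_len(n), ii)]
      log_alt <- log(0.5 * exp(llLc) + 0.5 * exp(llRc))
    }
    log_alt <- pmax(log_alt, LOG_FLOOR)
    log_n <- pmax(log_n, LOG_FLOOR)
    m <- pmax(log_alt, log_n)
    log1m_pn <- log_alt - (m + log(exp(log_alt - m) + exp(log_n - m)))
  }
  list(choose_left = choose_left, lp_chosen = lp_chosen, chat = chat,
       log1m_pn = log1m_pn, p_left = pL)
}

#' Orientation decision for one evidence sample
#'
#' Computes the posterior over the two orientations (equal 0.5 priors; the
#' no-stimulus hypothesis has a null prior) from the model's candidate
#' sources over `c_grid`, marginalizing or conditioning on the most likely
#' strength per the model's strategy, and chooses the more probable
#' orientation. Exact ties are broken by a fair coin from the current RNG.
#'
#' @param spec An [observer_spec()].
#' @param d Numeric 2-vector of evidence.
#' @return List with `s_chosen`, `posterior` (of the chosen orientation),
#'   `p_left`, and `c_hat` (hierarchical models only, else `NULL`).
#' @export
orientation_decision <- function(spec, d) {
  q <- interval_quantities(matrix(d, nrow = 1), spec)
  list(s_chosen = if (q$choose_left) "left" else "right",
       posterior = exp(q$lp_chosen), p_left = q$p_left,
       c_hat = if (is.null(q$chat)) NULL else q$chat)
}

#' Interval decision for one trial
#'
#' Computes the log decision variable D for the trial: confidence models
#' compare the posterior of the chosen orientation between intervals,
#' `D = log p(S_chosen,OP | d_OP) - log p(S_chosen,OA | d_OA)`; visibility
#' models compare the posterior probability that each interval contained an
#' offset, `D = log(1 - p(N_OP|d_OP)) - log(1 - p(N_OA|d_OA))`. Gaussian
#' access noise of sd `spec$sigma_d` is added, and the OP interval is chosen
#' iff the noisy D exceeds 0 (D = 0 selects OA).
#'
#' @param spec An [observer_spec()].
#' @param d_op,d_oa Evidence 2-vectors for the two intervals.
#' @return List with per-interval orientation choices (`s_chosen_op`,
#'   `s_chosen_oa`, `c_hat_op`, `c_hat_oa`), `D`, `D_noisy`,
#'   `interval_choice` (`"OP"` or `"OA"`).
#' @export
interval_decision <- function(spec, d_op, d_oa) {
  qo <- interval_quantities(matrix(d_op, nrow = 1), spec)
  qa <- interval_quantities(matrix(d_oa, nrow = 1), spec)
  D <- if (spec$judgment == "confidence") {
    qo$lp_chosen - qa$lp_chosen
  } else {
    qo$log1m_pn - qa$log1m_pn
  }
  D_noisy <- inject_noise(D, spec$sigma_d)
  list(s_chosen_op = if (qo$choose_left) "left" else "right",
       s_chosen_oa = if (qa$choose_left) "left" else "right",
       c_hat_op = if (is.null(qo$chat)) NULL else qo$chat,
       c_hat_oa = if (is.null(qa$chat)) NULL else qa$chat,
       D = D, D_noisy = D_noisy,
       interval_choice = if (D_noisy > 0) "OP" else "OA")
}

#' Add access noise to a decision variable
#'
#' `D_noisy = D + delta`, `delta ~ Normal(0, sigma_d)`. The orientation
#' choice is untouched: sigma_D degrades only the interval judgment.
#'
#' @param D Decision variable (vectorized).
#' @param sigma_d Nonnegative noise sd.
#' @return Numeric of the same length as `D`.
#' @export
inject_noise <- function(D, sigma_d) {
  if (sigma_d < 0) stop("sigma_d must be nonnegative", call. = FALSE)
  if (sigma_d == 0) return(D)
  D + stats::rnorm(length(D), 0, sigma_d)
}

#' Simulate many trials of one observer at one evidence strength
#'
#' Vectorized simulation used by the prediction tables and the synthetic
#' data generator. Returns the per-trial orientation choices of both
#' intervals and the noise-free decision variable D, so that interval
#' choices at any sigma_D can be derived afterwards with common random
#' numbers.
#'
#' @param spec An [observer_spec()].
#' @param c Evidence strength.
#' @param true_orientation Character vector (`"left"`/`"right"`) of length
#'   `n_sim`, or `NULL` to draw balanced-random orientations.
#' @param n_sim Number of trials when `true_orientation` is `NULL`.
#' @return Data frame with `true_orientation`, `s_chosen_op`,
#'   `s_chosen_oa`, `ori_correct`, `D`.
#' @export
simulate_observer_trials <- function(spec, c, true_orientation = NULL,
                                     n_sim = NULL) {
  if (is.null(true_orientation)) {
    stopifnot(!is.null(n_sim))
    true_orientation <- ifelse(stats::runif(n_sim) < 0.5, "left", "right")
  }
  n <- length(true_orientation)
  is_left <- true_orientation == "left"
  mu_l <- source_mean(spec$placement, "left", c)
  mu_r <- source_mean(spec$placement, "right", c)
  mu_n <- source_mean(spec$placement, "neutral", c)
  X_op <- matrix(stats::rnorm(2 * n), ncol = 2)
  X_op[, 1] <- X_op[, 1] + ifelse(is_left, mu_l[1], mu_r[1])
  X_op[, 2] <- X_op[, 2] + ifelse(is_left, mu_l[2], mu_r[2])
  X_oa <- matrix(stats::rnorm(2 * n), ncol = 2)
  X_oa[, 1] <- X_oa[, 1] + mu_n[1]
  X_oa[, 2] <- X_oa[, 2] + mu_n[2]
  qo <- interval_quantities(X_op, spec)
  qa <- interval_quantities(X_oa, spec)
  D <- if (spec$judgment == "confidence") qo$lp_chosen - qa$lp_chosen
       else qo$log1m_pn - qa$log1m_pn
  s_op <- ifelse(qo$choose_left, "left", "right")
  data.frame(true_orientation = true_orientation,
             s_chosen_op = s_op,
             s_chosen_oa = ifelse(qa$choose_left, "left", "right"),
             ori_correct = s_op == true_orientation,
             D = D)
}

#' Default sigma_D simulation grid for a model family
#'
#' Confidence models use 0 to 1 in steps of 0.01; visibility models, whose
#' decision variable is sturdier against this noise, use 0 to 10 in steps
#' of 0.1.
#'
#' @param judgment `"confidence"` or `"visibility"`.
#' @return Numeric vector of sigma_D values.
#' @export
default_sigma_grid <- function(judgment = c("confidence", "visibility")) {
  judgment <- match.arg(judgment)
  if (judgment == "confidence") seq(0, 1, by = 0.01) else seq(0, 10, by = 0.1)
}

#' Monte-Carlo joint-outcome prediction table
#'
#' For every evidence strength in `c_values`, simulates `n_sim` trials once
#' and derives, for every `sigma_d` in `sigma_values`, the joint probability
#' of the four outcomes (orientation correct x interval correct: `p11`,
#' `p10`, `p01`, `p00`). Common random numbers are used across sigma values
#' at fixed c — the same evidence samples and the same standard-normal noise
#' draws, scaled by sigma — so the orientation-correct marginal is
#' bit-identical across sigma.
#'
#' @param spec An [observer_spec()].
#' @param c_values Evidence strengths (defaults to the observer's `c_grid`).
#' @param sigma_values sigma_D grid (default per model family).
#' @param n_sim Trials per c cell.
#' @param seed Integer master seed; each c gets a derived sub-stream.
#' @return A `prediction_table`: list with `spec`, `c_values`,
#'   `sigma_values`, `n_sim`, `seed`, and `p`, an array of dim
#'   `c(4, length(c_values), length(sigma_values))`.
#' @export
simulate_prediction_table <- function(spec, c_values = spec$c_grid,
                                      sigma_values =
                                        default_sigma_grid(spec$judgment),
                                      n_sim = 1e5, seed = 1) {
  stopifnot(n_sim >= 1)
  nC <- length(c_values)
  nS <- length(sigma_values)
  p <- array(NA_real_, dim = c(4, nC, nS),
             dimnames = list(c("p11", "p10", "p01", "p00"), NULL, NULL))
  ori_p <- numeric(nC)
  for (ci in seq_len(nC)) {
    withr::with_seed(derive_seed(seed, ci), {
      sim <- simulate_observer_trials(spec, c_values[ci], n_sim = n_sim)
      z <- stats::rnorm(n_sim)
    })
    ori <- sim$ori_correct
    ori_p[ci] <- sum(ori) / n_sim  # sigma-invariant by construction
    for (si in seq_len(nS)) {
      int_ok <- (sim$D + sigma_values[si] * z) > 0
      p[, ci, si] <- c(sum(ori & int_ok), sum(ori & !int_ok),
                       sum(!ori & int_ok), sum(!ori & !int_ok)) / n_sim
    }
  }
  structure(list(spec = spec, c_values = c_values,
                 sigma_values = sigma_values, n_sim = n_sim, seed = seed,
                 p = p, ori_p = ori_p),
            class = "prediction_table")
}

#' Joint-outcome probabilities at one (c, sigma) cell
#'
#' @param table A `prediction_table`.
#' @param c,sigma_d Values present in the table's grids.
#' @return Named numeric vector `p11`, `p10`, `p01`, `p00`.
#' @export
pt_cell <- function(table, c, sigma_d) {
  ci <- match(TRUE, abs(table$c_values - c) < 1e-9)
  si <- match(TRUE, abs(table$sigma_values - sigma_d) < 1e-9)
  if (is.na(ci) || is.na(si)) {
    stop("(c, sigma_d) not on the simulated grids", call. = FALSE)
  }
  table$p[, ci, si]
}

#' Orientation-correct marginal of a prediction table
#'
#' Identical across sigma values by construction (common random numbers).
#'
#' @param table A `prediction_table`.
#' @return Numeric vector over `c_values`.
#' @export
pt_ori_correct <- function(table) {
  table$ori_p
}

#' Serialize a prediction table to a columnar data frame
#'
#' @param table A `prediction_table`.
#' @return Data frame with columns `model_id`, `c`, `sigma_d`, `p11`,
#'   `p10`, `p01`, `p00`, `n_sim`, `seed`.
#' @export
prediction_table_df <- function(table) {
  nC <- length(table$c_values)
  nS <- length(table$sigma_values)
  grid <- expand.grid(ci = seq_len(nC), si = seq_len(nS))
  slice <- function(cell) {
    matrix(table$p[cell, , ], nC, nS)[cbind(grid$ci, grid$si)]
  }
  data.frame(model_id = table$spec$model_id,
             c = table$c_values[grid$ci],
             sigma_d = table$sigma_values[grid$si],
             p11 = slice("p11"), p10 = slice("p10"),
             p01 = slice("p01"), p00 = slice("p00"),
             n_sim = table$n_sim, seed = table$seed)
}

#' Write a prediction table as CSV
#'
#' @param table A `prediction_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(table, path) {
  utils::write.csv(prediction_table_df(table), path, row.names = FALSE)
  invisible(path)
}
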