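# Fixtures built in code. All randomness is seeded at the call site.

# One hand-written trial row.
trial_row <- function(pid = "P01", task = "masked", level = 1,
                      ori = "left", op = "first",
                      r_op = "left", r_oa = "right", r_int = "first",
                      session = 1, block = 1) {
  lev <- condition_levels(task)
  data.frame(participant_id = pid, task = task, level_index = level,
             level_value = lev$physical_value[level],
             offset_orientation = ori, op_interval = op,
             resp_orientation_op = r_op, resp_orientation_oa = r_oa,
             resp_interval = r_int, session = session, block = block)
}

# Eight trials, two per joint (orientation-correct x interval-correct) cell,
# split evenly over OP-first and OP-second.
toy_eight_trials <- function() {
  mk <- function(ori_ok, int_ok, op) {
    trial_row(ori = "left", op = op,
              r_op = if (ori_ok) "left" else "right",
              r_int = if (int_ok) op else setdiff(c("first", "second"), op))
  }
  out <- rbind(mk(TRUE, TRUE, "first"), mk(TRUE, TRUE, "second"),
               mk(TRUE, FALSE, "first"), mk(TRUE, FALSE, "second"),
               mk(FALSE, TRUE, "first"), mk(FALSE, TRUE, "second"),
               mk(FALSE, FALSE, "first"), mk(FALSE, FALSE, "second"))
  vernier2ifc:::validate_trials(out)
}

# Summaries with chosen joint counts for one participant at one level.
summary_from_counts <- function(n11, n10, n01, n00, pid = "P01",
                                level = 1, task = "masked") {
  lev <- condition_levels(task)
  out <- data.frame(participant_id = pid, task = task, level_index = level,
                    level_value = lev$physical_value[level],
                    n = n11 + n10 + n01 + n00,
                    n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  for (col in c("n", "n11", "n10", "n01", "n00")) {
    out[[paste0(col, "_first")]] <- out[[col]]
    out[[paste0(col, "_second")]] <- 0
  }
  class(out) <- c("level_summaries", "data.frame")
  out
}

# Small synthetic dataset for structural tests.
small_trials <- function(seed = 42, n_participants = 3, trials = 24,
                         sigma_d = 0, model_id = 3, task = "masked") {
  truth <- ground_truth(task = task, model_id = model_id,
                        n_participants = n_participants,
                        sigma_d = sigma_d, trials_per_level = trials,
                        seed = seed)
  generate_dataset(truth, seed = seed)
}

# Independent brute-force orientation posterior (left) for the marginalizing
# strategy: plain sum of bivariate normal densities over the candidate grid.
oracle_p_left_marg <- function(d, grid) {
  sL <- sum(stats::dnorm(d[1], grid, 1) * stats::dnorm(d[2], 0, 1))
  sR <- sum(stats::dnorm(d[1], 0, 1) * stats::dnorm(d[2], grid, 1))
  sL / (sL + sR)
}

# Same for the hierarchical strategy: per-orientation max-density c, then
# posterior from the two densities at their own c-hat.
oracle_p_left_hier <- function(d, grid) {
  dl <- stats::dnorm(d[1], grid, 1) * stats::dnorm(d[2], 0, 1)
  dr <- stats::dnorm(d[1], 0, 1) * stats::dnorm(d[2], grid, 1)
  max(dl) / (max(dl) + max(dr))
}
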