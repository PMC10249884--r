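# Independent oracles and small fixture builders used across the suite.

# Exhaustive-enumeration forward oracle: posterior over the final context
# given a cue sequence, obtained by summing the joint probability over every
# possible context path (3^T of them). Deliberately brute-force and
# independent of the package's sequential filter.
path_sum_posterior <- function(cues, h, kappa,
                               labels = c(0, 2 * pi / 3, 4 * pi / 3)) {
  Tn <- length(cues)
  paths <- as.matrix(expand.grid(rep(list(1:3), Tn)))
  lik <- function(x, j) exp(kappa * cos(x - labels[j]))
  post <- numeric(3)
  for (r in seq_len(nrow(paths))) {
    p <- 1 / 3
    for (t in seq_len(Tn)) {
      if (t > 1) p <- p * if (paths[r, t] == paths[r, t - 1]) 1 - h else h / 2
      p <- p * lik(cues[t], paths[r, t])
    }
    post[paths[r, Tn]] <- post[paths[r, Tn]] + p
  }
  post / sum(post)
}

# Sequential filtered posterior built only from the exported single-trial
# operations (cue_likelihood / update_context_posterior / predict_next_belief).
filtered_posterior <- function(cues, obs_cfg) {
  Tm <- transition_matrix(obs_cfg$assumed_hazard, 3)
  b <- rep(1 / 3, 3)
  for (t in seq_along(cues)) {
    prior <- predict_next_belief(b, Tm)
    b <- update_context_posterior(prior, cue_likelihood(cues[t], obs_cfg))
  }
  b
}

# Small labeled dataset whose context bias grows with trials since switch:
# clockwise log-odds get an extra context-aligned term scaled by min(S, 5).
make_dynamic_bias_dataset <- function(n = 20000, slope = 0.15, seed = 1) {
  cfg <- task_config(n_trials = n, hazard = 0.425, cue_mode = "categorical")
  s <- simulate_task(cfg, seed = seed)
  set.seed(seed + 1)
  eta <- 0.4 * s$orientation_deg + slope * pmin(s$s_count, 5) * s$context
  s$choice <- ifelse(runif(n) < plogis(eta), 1L, -1L)
  class(s) <- c("choice_dataset", "data.frame")
  s
}
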