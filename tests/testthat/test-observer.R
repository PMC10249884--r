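obs_cfg <- function(...) {
  defaults <- list(context_pmfs = default_context_pmfs(),
                   orientations = seq(-7.5, 7.5, by = 2.5),
                   assumed_noise = c(high = 2, low = 5),
                   assumed_kappa = 1.5)
  args <- utils::modifyList(defaults, list(...))
  do.call(observer_config, args)
}

test_that("transition matrix has the hazard structure", {
  expect_equal(transition_matrix(0, 3), diag(3))
  expect_equal(transition_matrix(2 / 3, 3), matrix(1 / 3, 3, 3))
  m <- transition_matrix(0.2, 3)
  expect_equal(diag(m), rep(0.8, 3))
  expect_equal(m[1, 2], 0.1)
  expect_equal(rowSums(transition_matrix(0.37, 5)), rep(1, 5))
  expect_error(transition_matrix(0.2, 1), "N")
})

test_that("cue likelihood peaks at the cued context and degrades gracefully", {
  cfg <- obs_cfg()
  # kappa = 0: circular uniform for every context
  cfg0 <- obs_cfg(assumed_kappa = 0)
  expect_equal(cue_likelihood(1.0, cfg0), rep(1 / (2 * pi), 3))
  # cue exactly at a label is maximal for that context
  for (j in 1:3) {
    lik <- cue_likelihood(cfg$context_labels[j], cfg)
    expect_equal(which.max(lik), j)
  }
  # midpoint between two labels: equal likelihood for the two
  mid <- mean(cfg$context_labels[1:2])
  lik <- cue_likelihood(mid, cfg)
  expect_equal(lik[1], lik[2], tolerance = 1e-12)
  # categorical pattern
  cfgc <- obs_cfg(cue_mode = "categorical", assumed_validity = 0.8)
  expect_equal(cue_likelihood(0, cfgc), c(0.1, 0.8, 0.1))
})

test_that("belief updates renormalize, absorb, and reject degenerate input", {
  u <- rep(1 / 3, 3)
  expect_equal(update_context_posterior(u, c(2, 2, 2)), u)
  expect_equal(update_context_posterior(c(1, 0, 0), c(0.5, 9, 9)), c(1, 0, 0))
  post <- update_context_posterior(c(0.2, 0.5, 0.3), c(0.1, 0.4, 0.01))
  expect_equal(sum(post), 1, tolerance = 1e-12)
  expect_error(update_context_posterior(c(1, 0, 0), c(0, 1, 1)), "degenerate")
})

test_that("stimulus prior is the belief-weighted mixture of context pmfs", {
  pm <- default_context_pmfs()
  expect_equal(stimulus_prior(c(0, 1, 0), pm), unname(pm["0", ]))
  mix <- stimulus_prior(c(0.5, 0, 0.5), pm)
  expect_equal(mix, unname((pm["-1", ] + pm["1", ]) / 2))
  # uniform belief over mirror-symmetric pmfs gives a symmetric prior
  sym <- stimulus_prior(rep(1 / 3, 3), pm)
  expect_equal(sym, rev(sym))
})

test_that("orientation posterior matches direct arithmetic and its limits", {
  ori <- seq(-7.5, 7.5, by = 2.5)
  u <- rep(1 / 7, 7)
  # direct product oracle at y = 5, scale = 10
  expected <- u * dnorm(5, ori, 10)
  expected <- expected / sum(expected)
  expect_equal(orientation_posterior(5, u, ori, 10), expected, tolerance = 1e-12)
  # symmetric at y = 0
  p0 <- orientation_posterior(0, u, ori, 3)
  expect_equal(p0, rev(p0))
  # flat-likelihood limit returns the prior
  pr <- c(0.05, 0.1, 0.15, 0.2, 0.25, 0.15, 0.1)
  expect_equal(orientation_posterior(2.5, pr, ori, 1e7), pr, tolerance = 1e-8)
  # log-space evaluation survives extreme measurements
  pex <- orientation_posterior(1e4, u, ori, 2)
  expect_false(any(is.nan(pex)))
  expect_equal(sum(pex), 1, tolerance = 1e-10)
  expect_error(orientation_posterior(0, u, ori, 0), "noise_scale")
})

test_that("decision rule reads out posterior mass on clockwise orientations", {
  ori <- seq(-7.5, 7.5, by = 2.5)
  all_cw <- c(0, 0, 0, 0, 0.2, 0.3, 0.5)
  d <- decide(all_cw, ori)
  expect_equal(d$p_cw, 1)
  expect_equal(d$choice, 1L)
  point_ccw <- c(0, 0, 1, 0, 0, 0, 0)  # mass at -2.5
  expect_equal(decide(point_ccw, ori)$choice, -1L)
  # symmetric posterior with mass at zero: the literal exclude rule tips
  # counter-clockwise, the split rule is a fair tie
  symm <- c(0.1, 0.1, 0.2, 0.2, 0.2, 0.1, 0.1)
  dx <- decide(symm, ori, zero_mass = "exclude")
  expect_lt(dx$p_cw, 0.5)
  expect_equal(dx$choice, -1L)
  expect_equal(decide(symm, ori, zero_mass = "split")$p_cw, 0.5)
})

test_that("belief propagation applies the assumed dynamics", {
  expect_equal(predict_next_belief(c(0.2, 0.3, 0.5), transition_matrix(0, 3)),
               c(0.2, 0.3, 0.5))
  expect_equal(predict_next_belief(c(0.9, 0.05, 0.05), transition_matrix(2 / 3, 3)),
               rep(1 / 3, 3))
  expect_equal(predict_next_belief(c(1, 0, 0), transition_matrix(0.2, 3)),
               c(0.8, 0.1, 0.1))
})

test_that("sequential filtering equals the exhaustive path-sum oracle", {
  set.seed(31)
  for (rep in 1:3) {
    cues <- runif(5, 0, 2 * pi)
    h <- c(0.1, 0.3, 0.425)[rep]
    cfg <- obs_cfg(assumed_hazard = h, assumed_kappa = 1.2)
    expect_equal(filtered_posterior(cues, cfg),
                 path_sum_posterior(cues, h, 1.2),
                 tolerance = 1e-10)
  }
})

test_that("observer variants encode the knowledge ladder", {
  task <- ladder_task_config(n_trials = 2000)
  expect_error(make_model_variant(5, task), "1:4")
  v1 <- make_model_variant(1, task)
  v3 <- make_model_variant(3, task)
  v4 <- make_model_variant(4, task)
  # variant 1: uniform stimulus pmfs and pooled noise
  expect_true(all(v1$context_pmfs == 1 / 7))
  expect_equal(unname(v1$assumed_noise), rep(sqrt(mean(c(10, 20)^2)), 2))
  # variants 1-3 carry a flat prior (hazard 2/3); variant 4 the task hazard
  expect_equal(v3$assumed_hazard, 2 / 3)
  expect_equal(v4$assumed_hazard, 0.2)

  seq_ <- simulate_task(task, seed = 32)
  y <- sample_measurements(seq_$orientation_deg, seq_$contrast, task, seed = 33)
  # variant 1 decides by the sign of the measurement
  tr1 <- run_observer(seq_, v1, measurements = y)
  nonzero_y <- y != 0
  expect_identical(tr1$choice[nonzero_y], ifelse(y[nonzero_y] > 0, 1L, -1L))
  # variant 4 with assumed hazard 2/3 reproduces variant 3 trial-for-trial
  v4flat <- make_model_variant(4, task, assumed_hazard = 2 / 3)
  tr3 <- run_observer(seq_, v3, measurements = y)
  tr4 <- run_observer(seq_, v4flat, measurements = y)
  expect_identical(tr3$choice, tr4$choice)
  expect_equal(tr3$p_cw, tr4$p_cw, tolerance = 1e-12)
})

test_that("run_observer scores vertical stimuli at half credit and is exact at zero noise", {
  task <- task_config(n_trials = 3000, hazard = 0.2, cue_kappa = 1.5,
                      gen_noise = c(high = 1e-9, low = 1e-9))
  v1 <- make_model_variant(1, task)
  seq_ <- simulate_task(task, seed = 34)
  y <- sample_measurements(seq_$orientation_deg, seq_$contrast, task, seed = 35)
  tr <- run_observer(seq_, v1, measurements = y)
  nz <- seq_$orientation_deg != 0
  expect_true(all(tr$correct[nz] == 1))
  expect_true(all(tr$correct[!nz] == 0.5))
  expect_error(run_observer(seq_, v1, measurements = y[-1]), "length")

  # every stored belief lies on the simplex
  b <- as.matrix(tr[, c("belief_neg", "belief_unif", "belief_pos")])
  expect_true(all(abs(rowSums(b) - 1) < 1e-10))
  expect_true(all(b >= 0))

  # full trace: every stored distribution renormalizes to 1
  trf <- run_observer(seq_[1:200, ], v1, measurements = y[1:200],
                      keep_pmfs = TRUE)
  for (a in c("prior_belief", "stimulus_prior", "orientation_posterior")) {
    m <- attr(trf, a)
    expect_equal(nrow(m), 200L)
    expect_true(all(abs(rowSums(m) - 1) < 1e-10))
  }
})
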