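glm_sequence <- function(n = 4000, seed = 71) {
  simulate_task(task_config(n_trials = n, hazard = 0.425), seed = seed)
}

test_that("bias function is 0.5 at S = 0 or in the uniform context and saturates", {
  expect_equal(bias_function(0, 1, 2.7), 0.5)
  expect_equal(bias_function(0, -1, -3), 0.5)
  expect_equal(bias_function(7, 0, 1.4), 0.5)
  expect_equal(bias_function(1e4, 1, 1), 0, tolerance = 1e-12)
  expect_equal(bias_function(1e4, -1, 1), 1, tolerance = 1e-12)
  expect_equal(bias_function(1e4, 1, -1), 1, tolerance = 1e-12)
})

test_that("design matrix encodes the six regressors with block-wise history resets", {
  seq_ <- glm_sequence(500)
  d <- generate_glm_observer_choices(seq_, default_recovery_observers()$rising,
                                     seed = 72)
  des <- build_design(d, gamma = 0.4)
  expect_identical(colnames(des$X),
                   c("intercept", "theta", "theta_high", "context", "bias_f",
                     "prev_resp", "prev_theta"))
  first_of_block <- !duplicated(d$block)
  expect_true(all(des$X[first_of_block, "prev_resp"] == 0))
  expect_true(all(des$X[first_of_block, "prev_theta"] == 0))
  later <- which(!first_of_block)
  expect_equal(des$X[later, "prev_resp"], as.numeric(d$choice[later - 1]))
  low <- d$contrast == "low"
  expect_true(all(des$X[low, "theta_high"] == 0))
  unif <- d$context == 0
  expect_true(all(des$X[unif, "context"] == 0))
  expect_true(all(des$X[unif, "bias_f"] == 0.5))
  expect_equal(des$z, as.numeric(d$choice == 1))
})

test_that("fixed-gamma logistic fit is a maximum-likelihood convex fit", {
  seq_ <- glm_sequence(8000, seed = 73)
  # responses independent of everything: weights near zero, intercept at
  # logit of the mean response rate
  d <- seq_
  set.seed(74)
  d$choice <- ifelse(runif(nrow(d)) < 0.6, 1L, -1L)
  class(d) <- c("choice_dataset", "data.frame")
  fit <- fit_fixed_gamma(d, gamma = 0.5)
  expect_equal(unname(fit$weights["intercept"]), qlogis(mean(d$choice == 1)),
               tolerance = 0.12)
  expect_true(all(abs(fit$weights[-1]) < 0.1))

  # recovery of known weights at the generating gamma
  truth <- default_recovery_observers()$rising
  d2 <- generate_glm_observer_choices(glm_sequence(10000, seed = 75), truth,
                                      seed = 76)
  fit2 <- fit_fixed_gamma(d2, gamma = truth$gamma)
  expect_equal(unname(fit2$weights["theta"]), truth$w_theta, tolerance = 0.05)
  expect_equal(unname(fit2$weights["prev_resp"]), truth$w_r, tolerance = 0.12)
  expect_equal(unname(fit2$weights["context"]), truth$w_C, tolerance = 0.25)

  # optimality: the fit's likelihood dominates the generating weights
  des <- build_design(d2, truth$gamma)
  w_true <- c(truth$w_alpha, truth$w_theta, truth$w_e, truth$w_C, truth$w_S,
              truth$w_r, truth$w_p)
  eta <- as.vector(des$X %*% w_true)
  ll_true <- sum(des$z * eta - log1p(exp(eta)))
  expect_gte(fit2$logLik, ll_true)

  # a collinear design is rejected: all-low-contrast data zero out theta_high
  d3 <- d2[d2$contrast == "low", ]
  expect_error(fit_fixed_gamma(d3, gamma = 0.4), "rank deficient")
})

test_that("two-step grid search maximizes the gamma profile", {
  truth <- default_recovery_observers()$rising
  d <- generate_glm_observer_choices(glm_sequence(4000, seed = 77), truth,
                                     seed = 78)
  fit <- fit_dynamic_glm(d)
  # refinement never loses to the coarse grid
  expect_gte(fit$logLik, max(fit$profile$logLik) - 1e-9)
  # profile is finite and continuous-looking over the whole grid
  expect_true(all(is.finite(fit$profile$logLik)))

  # null generator (w_S = 0): dynamic and static fits tie in likelihood
  flat <- default_recovery_observers()$flat
  d0 <- generate_glm_observer_choices(glm_sequence(4000, seed = 79), flat,
                                      seed = 80)
  fit0 <- fit_dynamic_glm(d0)
  des0 <- build_design(d0, 0)
  Xs <- des0$X[, colnames(des0$X) != "bias_f"]
  static <- fit_fixed_gamma(list(X = Xs, z = des0$z))
  expect_gte(fit0$logLik, static$logLik - 1e-6)
  expect_lt(fit0$logLik - static$logLik, 3)
})

test_that("model-implied bias curve follows the closed form and the fitted predictor", {
  p <- glm_params(w_alpha = 0.1, w_theta = 0.25, w_e = 0.2, w_C = 0.3,
                  w_S = 0.8, w_r = 0.2, w_p = 0.05, gamma = 0.7)
  cv <- predict_bias_curve(p, D_e = 1, S_range = 0:10)
  expect_equal(cv$bias[1], -p$w_C / (p$w_theta + p$w_e))
  # logistic limit for gamma > 0
  far <- predict_bias_curve(p, D_e = 1, S_range = 1000)$bias
  expect_equal(far, (-p$w_C + 0.5 * p$w_S) / (p$w_theta + p$w_e),
               tolerance = 1e-10)
  # constant curve when the bias weight vanishes
  p0 <- glm_params(w_theta = 0.25, w_e = 0.2, w_C = 0.3, gamma = 1.2)
  expect_equal(var(predict_bias_curve(p0, 1, 0:10)$bias), 0)
  expect_equal(bias_change_10_vs_0(p0, 1), 0)

  # bias curve equals the PSE difference between clockwise and uniform context
  expect_equal(cv$bias, glm_pse(p, 0:10, C = 1) - glm_pse(p, 0:10, C = 0),
               tolerance = 1e-12)
  # PSE zeroes the linear predictor (history terms zero)
  for (S in c(1, 4, 9)) {
    th <- glm_pse(p, S, C = 1, D_e = 0)
    eta <- p$w_alpha + p$w_theta * th + p$w_C + p$w_S * bias_function(S, 1, p$gamma)
    expect_equal(eta, 0, tolerance = 1e-10)
  }
  expect_error(predict_bias_curve(glm_params(w_theta = 0.2, w_e = -0.2), D_e = 1),
               "zero orientation")
})

test_that("simulated GLM observers follow their weights and seeds", {
  seq_ <- glm_sequence(5000, seed = 81)
  # all weights zero: coin flips
  coin <- generate_glm_observer_choices(seq_, glm_params(w_theta = 0, w_e = 0),
                                        seed = 82)
  expect_equal(mean(coin$choice == 1), 0.5, tolerance = 0.02)
  # dominant orientation weight: choice matches sign of the stimulus
  det <- generate_glm_observer_choices(seq_, glm_params(w_theta = 50, w_e = 0),
                                       seed = 83)
  nz <- det$orientation_deg != 0
  expect_true(all(det$choice[nz] == sign(det$orientation_deg[nz])))
  # bit-reproducible
  expect_identical(generate_glm_observer_choices(seq_, glm_params(), seed = 84),
                   generate_glm_observer_choices(seq_, glm_params(), seed = 84))
})

test_that("dynamic-vs-static cross-validation trains early and tests late trials", {
  truth <- glm_params(w_alpha = 0, w_theta = 0.22, w_e = 0.22, w_C = 0.1,
                      w_S = 1.5, w_r = 0.3, w_p = 0, gamma = 0.4)
  d <- generate_glm_observer_choices(glm_sequence(8000, seed = 85), truth,
                                     seed = 86)
  cvr <- cv_dynamic_vs_static(d)
  expect_equal(cvr$n_train + cvr$n_test, nrow(d))
  expect_gt(cvr$dynamic, cvr$static)

  # static generator: the dynamic model cannot do better than about even
  flat <- default_recovery_observers()$flat
  d0 <- generate_glm_observer_choices(glm_sequence(8000, seed = 87), flat,
                                      seed = 88)
  cv0 <- cv_dynamic_vs_static(d0)
  expect_lt(cv0$dynamic - cv0$static, 3)

  d_no5 <- d[d$s_count <= 4, ]
  expect_error(cv_dynamic_vs_static(d_no5), "empty test set")
})

test_that("AIC comparison reports parameter counts and favors the generating model", {
  truth <- glm_params(w_alpha = 0, w_theta = 0.22, w_e = 0.22, w_C = 0.1,
                      w_S = 1.2, w_r = 0.5, w_p = 0.05, gamma = 0.4)
  d <- generate_glm_observer_choices(glm_sequence(5000, seed = 89), truth,
                                     seed = 90)
  tab <- aic_vs_sdt(d, seed = 91)
  expect_identical(tab$model, c("dynamic_glm", "sdt_full"))
  expect_identical(tab$k, c(8L, 6L))
  expect_lt(tab$AIC[1], tab$AIC[2])
})
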