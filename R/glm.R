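#' Dynamic GLM parameters
#'
#' Weights of the dynamic Bernoulli GLM: the probability of a clockwise choice
#' is the logistic transform of six linearly combined regressors plus an
#' intercept. Regressors: stimulus orientation (deg), orientation times a
#' high-contrast dummy, context code, the nonlinear bias function
#' `f(S, C) = 1 / (1 + exp(gamma * S * C))` of the trials-since-switch count,
#' the previous response (+1/-1), and the previous orientation (deg). History
#' regressors are 0 on the first trial of each block.
#'
#' @param w_alpha intercept.
#' @param w_theta orientation weight at low contrast (per deg).
#' @param w_e additional orientation weight at high contrast (per deg).
#' @param w_C context weight.
#' @param w_S bias-function weight.
#' @param w_r previous-response weight.
#' @param w_p previous-orientation weight (per deg).
#' @param gamma bias-function shape parameter.
#' @return An object of class `glm_params`.
#' @export
glm_params <- function(w_alpha = 0, w_theta = 0.25, w_e = 0.25, w_C = 0,
                       w_S = 0, w_r = 0, w_p = 0, gamma = 0) {
  p <- list(w_alpha = w_alpha, w_theta = w_theta, w_e = w_e, w_C = w_C,
            w_S = w_S, w_r = w_r, w_p = w_p, gamma = gamma)
  if (!all(vapply(p, function(x) is.numeric(x) && is.finite(x), logical(1))))
    stop("all GLM parameters must be finite numbers", call. = FALSE)
  structure(p, class = "glm_params")
}

#' Nonlinear trials-since-switch bias function
#'
#' `f(S, C) = 1 / (1 + exp(gamma * S * C))`. At `S = 0` or in the uniform
#' context (`C = 0`) the function equals 0.5, so the regressor only carries
#' information once trials accumulate within a skewed context; `gamma`
#' controls how fast (and in which direction) it departs from 0.5.
#'
#' @param S trials since the last context switch (>= 0).
#' @param C context code in \{-1, 0, 1\}.
#' @param gamma shape parameter.
#' @return Values in (0, 1), vectorized.
#' @export
bias_function <- function(S, C, gamma) {
  1 / (1 + exp(gamma * S * C))
}

#' Build the dynamic GLM design matrix
#'
#' @param data a `choice_dataset` with `s_count` and `block`.
#' @param gamma bias-function shape used for the `f(S, C)` column.
#' @return List with `X` (n x 7 matrix: intercept, theta, theta_high,
#'   context, bias_f, prev_resp, prev_theta) and `z` (0/1 response,
#'   1 = clockwise), or `z = NULL` for unlabeled sequences.
#' @export
build_design <- function(data, gamma = 0) {
  if (!"s_count" %in% names(data)) stop("dataset lacks `s_count`", call. = FALSE)
  n <- nrow(data)
  theta <- data$orientation_deg
  block <- if ("block" %in% names(data)) data$block else rep(1L, n)
  new_block <- c(TRUE, block[-1L] != block[-n])
  prev_resp <- c(0, if ("choice" %in% names(data)) data$choice[-n] else rep(0, n - 1L))
  prev_theta <- c(0, theta[-n])
  prev_resp[new_block] <- 0
  prev_theta[new_block] <- 0
  X <- cbind(intercept = 1,
             theta = theta,
             theta_high = theta * (data$contrast == "high"),
             context = as.numeric(data$context),
             bias_f = bias_function(data$s_count, data$context, gamma),
             prev_resp = prev_resp,
             prev_theta = prev_theta)
  z <- if ("choice" %in% names(data) && !all(is.na(data$choice)))
    as.numeric(data$choice == 1) else NULL
  list(X = X, z = z)
}

#' Simulate choices from the dynamic GLM
#'
#' Generates choices sequentially: each trial's linear predictor uses the
#' *generated* previous response (reset at block boundaries), the logistic
#' transform gives the clockwise probability, and the choice is drawn as a
#' Bernoulli variable.
#'
#' @param sequence a `trial_sequence` with `s_count` and `block`.
#' @param params a [glm_params()].
#' @param seed optional integer seed.
#' @return A `choice_dataset`.
#' @export
generate_glm_observer_choices <- function(sequence, params, seed = NULL) {
  with_seed(seed, {
    n <- nrow(sequence)
    theta <- sequence$orientation_deg
    static <- params$w_alpha +
      params$w_theta * theta +
      params$w_e * theta * (sequence$contrast == "high") +
      params$w_C * as.numeric(sequence$context) +
      params$w_S * bias_function(sequence$s_count, sequence$context, params$gamma)
    block <- if ("block" %in% names(sequence)) sequence$block else rep(1L, n)
    u <- stats::runif(n)
    choice <- integer(n)
    prev_r <- 0
    prev_t <- 0
    for (t in seq_len(n)) {
      if (t > 1L && block[t] != block[t - 1L]) { prev_r <- 0; prev_t <- 0 }
      p <- stats::plogis(static[t] + params$w_r * prev_r + params$w_p * prev_t)
      choice[t] <- if (u[t] < p) 1L else -1L
      prev_r <- choice[t]
      prev_t <- theta[t]
    }
    out <- sequence
    out$choice <- choice
    class(out) <- c("choice_dataset", "data.frame")
    out
  })
}

glm_loglik <- function(X, z, w) {
  eta <- as.vector(X %*% w)
  # numerically stable: log(1 + e^eta) = max(eta, 0) + log1p(e^-|eta|)
  sum(z * eta - pmax(eta, 0) - log1p(exp(-abs(eta))))
}

#' Fit the GLM weights at a fixed bias-function shape
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm.fit()]) for a
#' given `gamma`. The design is checked for full rank; complete separation is
#' flagged and refit with weights bounded to `[-15, 15]`.
#'
#' @param data a `choice_dataset`, or a list `(X, z)` from [build_design()].
#' @param gamma bias-function shape.
#' @return List with `weights` (named length-7 vector), `logLik`,
#'   `separation` flag.
#' @export
fit_fixed_gamma <- function(data, gamma = 0) {
  d <- if (is.list(data) && !is.data.frame(data) && !is.null(data$X)) data
  else build_design(data, gamma)
  X <- d$X
  z <- d$z
  if (is.null(z)) stop("dataset has no choices to fit", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (collinear regressors)", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(X, z, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 100L)))
  w <- stats::coef(fit)
  mu <- fit$fitted.values
  separation <- any(mu < 1e-10 | mu > 1 - 1e-10) && any(abs(w) > 20)
  if (separation) {
    nll <- function(ww) -glm_loglik(X, z, ww)
    gr <- function(ww) -as.vector(t(X) %*% (z - stats::plogis(as.vector(X %*% ww))))
    opt <- stats::optim(pmin(15, pmax(-15, w)), nll, gr, method = "L-BFGS-B",
                        lower = rep(-15, ncol(X)), upper = rep(15, ncol(X)))
    w <- opt$par
  }
  names(w) <- colnames(X)
  list(weights = w, logLik = glm_loglik(X, z, w), separation = separation)
}

#' Default two-step grid for the bias-function shape
#'
#' Coarse grid: 0 plus 20 log-spaced magnitudes in `[0.01, 5]` of each sign
#' (41 points).
#'
#' @return Sorted numeric vector.
#' @export
default_gamma_grid <- function() {
  mag <- exp(seq(log(0.01), log(5), length.out = 20L))
  sort(c(-mag, 0, mag))
}

#' Fit the dynamic GLM by two-step grid search
#'
#' The weights are a convex logistic-regression problem at fixed `gamma`, so
#' the profile likelihood over `gamma` is maximized by grid search: first over
#' the coarse grid, then over a 21-point refinement spanning the two coarse
#' neighbors of the optimum.
#'
#' @param data a `choice_dataset`.
#' @param gamma_grid coarse grid (default [default_gamma_grid()]).
#' @param refine number of refinement points.
#' @return List with `params` (a [glm_params()]), `logLik`, `k` (8),
#'   `profile` (data.frame of gamma vs logLik over the coarse grid).
#' @export
fit_dynamic_glm <- function(data, gamma_grid = default_gamma_grid(), refine = 21L) {
  if (!length(gamma_grid)) stop("`gamma_grid` must be nonempty", call. = FALSE)
  d0 <- build_design(data, 0)
  eval_gamma <- function(g) {
    if (g == 0) {
      # f(S, C) is constant 0.5 at gamma = 0: w_S is absorbed by the
      # intercept, so fit the nested static model and report w_S = 0
      Xs <- d0$X[, colnames(d0$X) != "bias_f"]
      fit <- fit_fixed_gamma(list(X = Xs, z = d0$z))
      w <- append(fit$weights, c(bias_f = 0), after = 4L)
      return(list(weights = w, logLik = fit$logLik, separation = fit$separation))
    }
    d0$X[, "bias_f"] <- bias_function(data$s_count, data$context, g)
    fit_fixed_gamma(d0)
  }
  coarse <- lapply(gamma_grid, eval_gamma)
  ll <- vapply(coarse, `[[`, numeric(1), "logLik")
  j <- which.max(ll)
  lo <- gamma_grid[max(1L, j - 1L)]
  hi <- gamma_grid[min(length(gamma_grid), j + 1L)]
  fine_grid <- seq(lo, hi, length.out = refine)
  fine <- lapply(fine_grid, eval_gamma)
  llf <- vapply(fine, `[[`, numeric(1), "logLik")
  jf <- which.max(llf)
  best <- if (llf[jf] >= ll[j]) list(g = fine_grid[jf], fit = fine[[jf]])
  else list(g = gamma_grid[j], fit = coarse[[j]])
  w <- best$fit$weights
  list(params = glm_params(w_alpha = w[["intercept"]], w_theta = w[["theta"]],
                           w_e = w[["theta_high"]], w_C = w[["context"]],
                           w_S = w[["bias_f"]], w_r = w[["prev_resp"]],
                           w_p = w[["prev_theta"]], gamma = best$g),
       logLik = best$fit$logLik, k = 8L,
       separation = best$fit$separation,
       profile = data.frame(gamma = gamma_grid, logLik = ll))
}

#' Model-implied PSE of the dynamic GLM
#'
#' Orientation at which the linear predictor is zero (50% clockwise), with
#' history terms set to zero:
#' `PSE(S, C) = -(w_C C + w_S f(S, C) + w_alpha) / (w_theta + w_e D_e)`.
#'
#' @param params a [glm_params()].
#' @param S trials since switch.
#' @param C context code.
#' @param D_e 1 for high contrast, 0 for low.
#' @return PSE in degrees, vectorized over `S`.
#' @export
glm_pse <- function(params, S, C, D_e = 1) {
  den <- params$w_theta + params$w_e * D_e
  if (abs(den) < 1e-12) stop("undefined PSE: zero orientation sensitivity", call. = FALSE)
  -(params$w_C * C + params$w_S * bias_function(S, C, params$gamma) + params$w_alpha) / den
}

#' Model-implied bias curve over trials since a context switch
#'
#' The difference of the model PSE between the positively skewed (clockwise)
#' and uniform contexts with history terms set to zero:
#' `bias(S) = (-w_C + w_S (0.5 - 1/(1 + exp(gamma S)))) / (w_theta + w_e D_e)`.
#'
#' @param params a [glm_params()].
#' @param D_e 1 for high contrast, 0 for low.
#' @param S_range integer S values to evaluate.
#' @return data.frame with `S` and `bias` (deg).
#' @export
predict_bias_curve <- function(params, D_e = 1, S_range = 0:10) {
  den <- params$w_theta + params$w_e * D_e
  if (abs(den) < 1e-12) stop("undefined bias: zero orientation sensitivity", call. = FALSE)
  bias <- (-params$w_C + params$w_S * (0.5 - 1 / (1 + exp(params$gamma * S_range)))) / den
  data.frame(S = S_range, bias = bias)
}

#' Change in model-implied bias after ten same-context trials
#'
#' `predict_bias_curve` evaluated at `S = 10` minus at `S = 0` (history terms
#' zero), per contrast.
#'
#' @param params a [glm_params()].
#' @param D_e 1 for high contrast, 0 for low.
#' @return Difference in degrees.
#' @export
bias_change_10_vs_0 <- function(params, D_e = 1) {
  b <- predict_bias_curve(params, D_e, S_range = c(0L, 10L))
  b$bias[2L] - b$bias[1L]
}

#' Parameter-recovery experiment for the dynamic GLM
#'
#' Simulates choice data from known parameter sets on a common trial
#' sequence, refits each simulated dataset, and reports recovery of the
#' history weights and of the model-implied bias curve. The replicate refits
#' are parametric-bootstrap samples from the generating model, so their
#' spread provides the confidence band against which the ground-truth curve
#' is compared.
#'
#' @param sequence a `trial_sequence` (typically test-phase-like).
#' @param params_list named list of [glm_params()] (e.g. rising/flat/falling
#'   observers sharing task weights).
#' @param n_rep simulated datasets per observer.
#' @param D_e contrast for the bias-curve readout.
#' @param S_range S values for the bias-curve readout.
#' @param conf band level (0.68 matches one-sigma error bars).
#' @param seed integer seed.
#' @param gamma_grid passed to [fit_dynamic_glm()].
#' @return List (one element per observer) with `truth`, `estimates` (matrix
#'   of refit parameters), `history` (data.frame: truth, mean, sd per history
#'   weight), and `curve` (data.frame: S, truth, mean, lo, hi, covered).
#' @export
recovery_experiment <- function(sequence, params_list, n_rep = 100L,
                                D_e = 1, S_range = 0:10, conf = 0.68,
                                seed = NULL, gamma_grid = default_gamma_grid()) {
  with_seed(seed, {
    lapply(params_list, function(truth) {
      est <- matrix(NA_real_, n_rep, 8L,
                    dimnames = list(NULL, names(unclass(truth))))
      curves <- matrix(NA_real_, n_rep, length(S_range))
      for (r in seq_len(n_rep)) {
        sim <- generate_glm_observer_choices(sequence, truth)
        fit <- fit_dynamic_glm(sim, gamma_grid = gamma_grid)
        est[r, ] <- unlist(unclass(fit$params))
        curves[r, ] <- predict_bias_curve(fit$params, D_e, S_range)$bias
      }
      hw <- c("w_r", "w_p")
      history <- data.frame(
        param = hw,
        truth = unlist(unclass(truth))[hw],
        mean = colMeans(est[, hw, drop = FALSE]),
        sd = apply(est[, hw, drop = FALSE], 2L, stats::sd))
      tb <- predict_bias_curve(truth, D_e, S_range)$bias
      lo <- apply(curves, 2L, stats::quantile, probs = 0.5 - conf / 2)
      hi <- apply(curves, 2L, stats::quantile, probs = 0.5 + conf / 2)
      curve <- data.frame(S = S_range, truth = tb,
                          mean = colMeans(curves), lo = lo, hi = hi,
                          covered = tb >= lo & tb <= hi)
      list(truth = truth, estimates = est, history = history, curve = curve)
    })
  })
}

#' Default model observers for the recovery experiment
#'
#' Three dynamic-GLM observers sharing the task weights (intercept 0,
#' orientation weight 0.22 per deg at low contrast, +0.22 at high contrast,
#' context weight 0.1) but differing in their reliance on history and in the
#' temporal evolution of their context bias: one whose aligned bias rises
#' with trials since a switch, one with a static bias, and one whose bias
#' falls. The orientation weights put ~75% clockwise choices at +2.5 deg high
#' contrast, and the bias swings span a few tenths of a degree to about one
#' degree, in the range seen in trained human observers.
#'
#' @return Named list of three [glm_params()]: `rising`, `flat`, `falling`.
#' @export
default_recovery_observers <- function() {
  shared <- list(w_alpha = 0, w_theta = 0.22, w_e = 0.22, w_C = 0.1)
  mk <- function(w_S, gamma, w_r, w_p)
    do.call(glm_params, c(shared, list(w_S = w_S, gamma = gamma,
                                       w_r = w_r, w_p = w_p)))
  list(rising = mk(0.8, 0.4, 0.5, 0.05),
       flat = mk(0, 0, 0.15, 0),
       falling = mk(-0.8, 0.4, -0.3, -0.05))
}

#' Cross-validate the dynamic against the static GLM
#'
#' Both models are trained on trials that occurred 1-4 trials after a context
#' switch and evaluated on trials that occurred 5 or more trials after a
#' switch. The static model is the dynamic model with the `f(S, C)` regressor
#' removed.
#'
#' @param data a `choice_dataset`.
#' @param gamma_grid passed to [fit_dynamic_glm()].
#' @return List with `dynamic` and `static` held-out total log-likelihoods,
#'   `n_train`, `n_test`.
#' @export
cv_dynamic_vs_static <- function(data, gamma_grid = default_gamma_grid()) {
  train <- data$s_count >= 1 & data$s_count <= 4
  test <- data$s_count >= 5
  if (!any(test)) stop("empty test set: no trials with s_count >= 5", call. = FALSE)
  dtrain <- data[train, ]
  dtest <- data[test, ]
  dyn <- fit_dynamic_glm(dtrain, gamma_grid = gamma_grid)
  ddyn <- build_design(dtest, dyn$params$gamma)
  w_dyn <- c(dyn$params$w_alpha, dyn$params$w_theta, dyn$params$w_e,
             dyn$params$w_C, dyn$params$w_S, dyn$params$w_r, dyn$params$w_p)
  dstat_tr <- build_design(dtrain, 0)
  Xs <- dstat_tr$X[, colnames(dstat_tr$X) != "bias_f"]
  stat_fit <- fit_fixed_gamma(list(X = Xs, z = dstat_tr$z))
  dstat_te <- build_design(dtest, 0)
  Xst <- dstat_te$X[, colnames(dstat_te$X) != "bias_f"]
  list(dynamic = glm_loglik(ddyn$X, ddyn$z, w_dyn),
       static = glm_loglik(Xst, dstat_te$z, stat_fit$weights),
       n_train = sum(train), n_test = sum(test))
}

#' AIC comparison of the dynamic GLM and the SDT model
#'
#' Fits both models to the same trials and reports `AIC = 2k - 2 lnL` with
#' the parameter counts stated explicitly (8 for the dynamic GLM: seven
#' weights plus the bias-function shape; 6 for the full SDT variant).
#'
#' @param data a `choice_dataset`.
#' @param seed seed for the SDT multi-start.
#' @return data.frame with `model`, `k`, `logLik`, `AIC`.
#' @export
aic_vs_sdt <- function(data, seed = NULL) {
  g <- fit_dynamic_glm(data)
  s <- fit_sdt(data, variant = "full", seed = seed)
  data.frame(model = c("dynamic_glm", "sdt_full"),
             k = c(g$k, s$k),
             logLik = c(g$logLik, s$logLik),
             AIC = c(2 * g$k - 2 * g$logLik, 2 * s$k - 2 * s$logLik))
}
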