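#' Context transition matrix
#'
#' Stochastic matrix with `1 - h` on the diagonal and `h / (N - 1)` off the
#' diagonal: the context stays with probability `1 - h` and otherwise moves to
#' one of the other `N - 1` contexts with equal probability.
#'
#' @param h hazard rate in `[0, 1]`.
#' @param N number of contexts (>= 2).
#' @return An `N x N` matrix whose rows sum to 1.
#' @export
transition_matrix <- function(h, N = 3L) {
  stopifnot_prob(h, "h")
  if (N < 2L) stop("`N` must be >= 2", call. = FALSE)
  m <- matrix(h / (N - 1), N, N)
  diag(m) <- 1 - h
  m
}

#' Observer configuration
#'
#' Specifies what the observer assumes about the generative process. The four
#' canonical variants are built by [make_model_variant()]; this constructor
#' exposes the knobs directly.
#'
#' Variants lacking knowledge of environmental dynamics are represented by an
#' assumed hazard of `(N-1)/N = 2/3`, for which the context prior carried to
#' the next trial is exactly flat; this makes "static" observers a special
#' case of the filtering loop.
#'
#' @param context_pmfs assumed 3 x K matrix of context-specific orientation
#'   distributions (uniform rows for observers that ignore context).
#' @param orientations orientation grid (deg).
#' @param assumed_noise named `c(high=, low=)` noise scale (deg); equal
#'   entries encode a single pooled noise level.
#' @param assumed_hazard assumed per-trial switch probability.
#' @param cue_mode `"von_mises"` or `"categorical"`.
#' @param assumed_kappa assumed cue concentration (von Mises mode).
#' @param assumed_validity assumed cue validity (categorical mode).
#' @param context_labels angular labels of the contexts (radians).
#' @param zero_mass how posterior mass on the vertical stimulus (0 deg) enters
#'   the clockwise probability: `"split"` counts half of it (default),
#'   `"exclude"` drops it (the literal reading of the decision rule).
#' @param scoring accuracy scoring of vertical stimuli, which received random
#'   feedback in the task: `"expected"` credits 0.5, `"bernoulli"` draws it.
#' @param tie_break_seed seed for the fair coin at exactly `p_cw = 0.5`.
#' @return An object of class `observer_config`.
#' @export
observer_config <- function(context_pmfs,
                            orientations,
                            assumed_noise,
                            assumed_hazard = 2 / 3,
                            cue_mode = c("von_mises", "categorical"),
                            assumed_kappa = 0.4,
                            assumed_validity = 0.8,
                            context_labels = c(0, 2 * pi / 3, 4 * pi / 3),
                            zero_mass = c("split", "exclude"),
                            scoring = c("expected", "bernoulli"),
                            tie_break_seed = NULL) {
  cue_mode <- match.arg(cue_mode)
  stopifnot_prob(assumed_hazard, "assumed_hazard")
  if (!all(c("high", "low") %in% names(assumed_noise)) || any(assumed_noise <= 0))
    stop("`assumed_noise` must be positive and named c(high=, low=)", call. = FALSE)
  structure(
    list(context_pmfs = context_pmfs, orientations = orientations,
         assumed_noise = assumed_noise[c("high", "low")],
         assumed_hazard = assumed_hazard, cue_mode = cue_mode,
         assumed_kappa = assumed_kappa, assumed_validity = assumed_validity,
         context_labels = context_labels,
         zero_mass = match.arg(zero_mass), scoring = match.arg(scoring),
         tie_break_seed = tie_break_seed),
    class = "observer_config")
}

#' Build one of the four knowledge-ladder observer variants
#'
#' Variant 1 has only general knowledge of perceptual ambiguity: a single
#' pooled sensory-noise level (the root mean square of the two generative
#' contrast scales), a uniform stimulus distribution for every context, and a
#' flat context prior on every trial. Variant 2 adds the context-specific
#' stimulus distributions and the cue reliability; variant 3 adds
#' contrast-specific sensory noise; variant 4 adds the context transition
#' dynamics (an assumed hazard rate replacing the flat per-trial prior).
#'
#' @param k variant number 1-4.
#' @param config the generative [task_config()] the observer is matched to.
#' @param assumed_hazard hazard assumed by variant 4 (defaults to the
#'   generative hazard).
#' @param assumed_kappa cue concentration assumed by variants 2-4 (defaults to
#'   the generative value).
#' @param ... passed to [observer_config()] (e.g. `zero_mass`, `scoring`).
#' @return An `observer_config`.
#' @export
make_model_variant <- function(k, config,
                               assumed_hazard = config$hazard,
                               assumed_kappa = config$cue_kappa, ...) {
  if (!k %in% 1:4) stop("variant `k` must be in 1:4", call. = FALSE)
  K <- length(config$orientations)
  uniform_pmfs <- matrix(1 / K, 3L, K,
                         dimnames = dimnames(config$context_pmfs))
  pooled <- sqrt(mean(config$gen_noise^2))
  observer_config(
    context_pmfs = if (k >= 2) config$context_pmfs else uniform_pmfs,
    orientations = config$orientations,
    assumed_noise = if (k >= 3) config$gen_noise else c(high = pooled, low = pooled),
    assumed_hazard = if (k >= 4) assumed_hazard else 2 / 3,
    cue_mode = config$cue_mode,
    assumed_kappa = assumed_kappa,
    assumed_validity = config$cue_validity,
    context_labels = config$context_labels,
    ...)
}

#' Cue likelihood over contexts
#'
#' Likelihood of a single observed cue under each of the three contexts:
#' the von Mises density of the cue angle at each context's angular label, or
#' the `validity / (1 - validity)/2` pattern for a categorical cue.
#'
#' @param cue observed cue (angle in radians, or context code).
#' @param config an [observer_config()].
#' @return Numeric vector of length 3 (unnormalized likelihood).
#' @export
cue_likelihood <- function(cue, config) {
  if (config$cue_mode == "von_mises") {
    dvonmises(cue, mu = config$context_labels, kappa = config$assumed_kappa)
  } else {
    v <- config$assumed_validity
    ifelse(CONTEXT_CODES == cue, v, (1 - v) / 2)
  }
}

#' Update the context belief with a cue
#'
#' Elementwise product of the prior belief and the cue likelihood,
#' renormalized to the probability simplex.
#'
#' @param prior_belief probability vector over contexts.
#' @param cue_lik nonnegative likelihood vector.
#' @return Posterior belief (sums to 1).
#' @export
update_context_posterior <- function(prior_belief, cue_lik) {
  if (any(cue_lik < 0)) stop("cue likelihood must be nonnegative", call. = FALSE)
  p <- prior_belief * cue_lik
  s <- sum(p)
  if (s <= 0 || !is.finite(s))
    stop("degenerate belief update: prior and likelihood have no common support",
         call. = FALSE)
  p / s
}

#' Belief-weighted stimulus prior
#'
#' Mixture of the context-specific orientation distributions weighted by the
#' current context belief.
#'
#' @param belief probability vector over contexts.
#' @param context_pmfs 3 x K matrix of orientation distributions.
#' @return Probability vector over the orientation grid.
#' @export
stimulus_prior <- function(belief, context_pmfs) {
  as.vector(belief %*% context_pmfs)
}

#' Posterior over stimulus orientation
#'
#' Combines the stimulus prior with the Gaussian measurement likelihood at
#' each grid orientation. Computed in log space with max-subtraction, so
#' extreme measurements never underflow to an all-zero posterior.
#'
#' @param y noisy orientation measurement (deg).
#' @param prior_pmf prior over the orientation grid.
#' @param orientations the orientation grid (deg).
#' @param noise_scale Gaussian likelihood scale (SD, deg), > 0.
#' @return Posterior probability vector over the grid.
#' @export
orientation_posterior <- function(y, prior_pmf, orientations, noise_scale) {
  if (noise_scale <= 0) stop("`noise_scale` must be > 0", call. = FALSE)
  lw <- log(prior_pmf) - 0.5 * ((y - orientations) / noise_scale)^2
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

#' Decide clockwise vs counter-clockwise from an orientation posterior
#'
#' The clockwise probability is the posterior mass on positive orientations
#' (plus half the mass on 0 deg under the default `"split"` handling). The
#' choice is +1 if that probability exceeds 0.5, -1 if below, and a fair coin
#' at exactly 0.5.
#'
#' @param posterior posterior probability vector over the grid.
#' @param orientations the orientation grid (deg).
#' @param zero_mass `"split"` or `"exclude"` (see [observer_config()]).
#' @return List with `p_cw` and `choice` (+1/-1).
#' @export
decide <- function(posterior, orientations, zero_mass = c("split", "exclude")) {
  zero_mass <- match.arg(zero_mass)
  p_cw <- sum(posterior[orientations > 0])
  if (zero_mass == "split") p_cw <- p_cw + 0.5 * sum(posterior[orientations == 0])
  choice <- if (p_cw > 0.5) 1L else if (p_cw < 0.5) -1L else
    if (stats::runif(1) < 0.5) 1L else -1L
  list(p_cw = p_cw, choice = choice)
}

#' Propagate the context belief to the next trial
#'
#' @param posterior_belief belief after the current trial's cue update.
#' @param transition transition matrix from [transition_matrix()].
#' @return Prior belief for the next trial.
#' @export
predict_next_belief <- function(posterior_belief, transition) {
  as.vector(posterior_belief %*% transition)
}

# Vectorized cue log-likelihood matrix (n x 3) for a whole cue series.
cue_loglik_matrix <- function(cues, config) {
  n <- length(cues)
  if (config$cue_mode == "von_mises") {
    k <- config$assumed_kappa
    out <- matrix(0, n, 3L)
    for (j in 1:3) out[, j] <- k * cos(cues - config$context_labels[j])
    out
  } else {
    v <- config$assumed_validity
    out <- matrix(log((1 - v) / 2), n, 3L)
    for (j in 1:3) out[cues == CONTEXT_CODES[j], j] <- log(v)
    out
  }
}

# Sequential belief filtering over a whole cue series. Returns prior and
# posterior beliefs per trial (n x 3 each). The recursion is the only
# genuinely sequential part of the observer; everything else vectorizes.
filter_beliefs <- function(cues, config) {
  n <- length(cues)
  Tm <- transition_matrix(config$assumed_hazard, 3L)
  ll <- cue_loglik_matrix(cues, config)
  L <- exp(ll - row_max(ll))
  prior <- matrix(0, n, 3L)
  post <- matrix(0, n, 3L)
  b <- rep(1 / 3, 3)
  flat <- all(abs(Tm - 1 / 3) < 1e-15)
  if (flat) {
    # static observers: flat prior every trial, posterior is just the cue
    prior[] <- 1 / 3
    post <- L / 3
    post <- post / rowSums(post)
  } else {
    for (t in seq_len(n)) {
      pr <- as.vector(b %*% Tm)
      po <- pr * L[t, ]
      po <- po / sum(po)
      prior[t, ] <- pr
      post[t, ] <- po
      b <- po
    }
  }
  list(prior = prior, posterior = post)
}

#' Run an observer over a trial sequence
#'
#' Executes the full per-trial inference loop: update the context belief with
#' the cue, form the belief-weighted stimulus prior, combine it with the
#' Gaussian likelihood of the noisy measurement, read out the clockwise
#' probability, choose, and propagate the belief through the assumed context
#' dynamics. Accuracy is scored against the true orientation sign; vertical
#' stimuli (0 deg) received random feedback in the task and are credited 0.5
#' under the default `"expected"` scoring.
#'
#' @param sequence a `trial_sequence` from [simulate_task()].
#' @param config an [observer_config()] (e.g. from [make_model_variant()]).
#' @param measurements optional per-trial noisy measurements; drawn from the
#'   generative `task` config if omitted.
#' @param task the generative [task_config()]; required when `measurements`
#'   is `NULL`.
#' @param seed optional integer seed (measurement noise and tie-breaks).
#' @param keep_pmfs also store the per-trial prior beliefs, stimulus priors,
#'   and orientation posteriors as attributes (memory-heavy on long runs).
#' @return A data.frame of class `observer_trace` with per-trial posterior
#'   beliefs (`belief_neg`, `belief_unif`, `belief_pos`), `p_cw`, `choice`,
#'   and `correct`; overall accuracy in `attr(, "accuracy")`. With
#'   `keep_pmfs = TRUE`, attributes `prior_belief`, `stimulus_prior`, and
#'   `orientation_posterior` hold the per-trial distributions.
#' @export
run_observer <- function(sequence, config, measurements = NULL, task = NULL,
                         seed = NULL, keep_pmfs = FALSE) {
  with_seed(seed, {
    n <- nrow(sequence)
    if (is.null(measurements)) {
      if (is.null(task)) stop("supply `measurements` or the generative `task` config",
                              call. = FALSE)
      measurements <- sample_measurements(sequence$orientation_deg,
                                          sequence$contrast, task)
    }
    if (length(measurements) != n || length(sequence$cue) != n)
      stop("sequence, measurements and cues must have equal length", call. = FALSE)

    beliefs <- filter_beliefs(sequence$cue, config)
    ori <- config$orientations
    K <- length(ori)
    prior_stim <- beliefs$posterior %*% config$context_pmfs   # n x K
    sig <- unname(config$assumed_noise[sequence$contrast])
    lw <- log(prior_stim)
    for (k in seq_len(K)) lw[, k] <- lw[, k] - 0.5 * ((measurements - ori[k]) / sig)^2
    lw <- lw - row_max(lw)
    post <- exp(lw)
    post <- post / rowSums(post)

    p_cw <- rowSums(post[, ori > 0, drop = FALSE])
    if (config$zero_mass == "split" && any(ori == 0))
      p_cw <- p_cw + 0.5 * post[, ori == 0]
    choice <- ifelse(p_cw > 0.5, 1L, -1L)
    ties <- which(p_cw == 0.5)
    if (length(ties))
      choice[ties] <- with_seed(config$tie_break_seed,
                                ifelse(stats::runif(length(ties)) < 0.5, 1L, -1L))

    truth <- sequence$orientation_deg
    correct <- as.numeric(choice == sign(truth))
    vertical <- truth == 0
    correct[vertical] <- if (config$scoring == "expected") 0.5 else
      as.numeric(stats::runif(sum(vertical)) < 0.5)

    out <- data.frame(trial = seq_len(n),
                      belief_neg = beliefs$posterior[, 1L],
                      belief_unif = beliefs$posterior[, 2L],
                      belief_pos = beliefs$posterior[, 3L],
                      p_cw = p_cw, choice = choice, correct = correct)
    class(out) <- c("observer_trace", "data.frame")
    attr(out, "accuracy") <- mean(correct)
    if (keep_pmfs) {
      attr(out, "prior_belief") <- beliefs$prior
      attr(out, "stimulus_prior") <- prior_stim
      attr(out, "orientation_posterior") <- post
    }
    out
  })
}

#' Choice dataset from an observer trace
#'
#' Binds an observer's simulated choices onto the trial sequence, yielding the
#' table consumed by the bias, SDT, and GLM estimators.
#'
#' @param sequence the `trial_sequence` the observer ran on.
#' @param trace the matching `observer_trace`.
#' @return A data.frame of class `choice_dataset`.
#' @export
as_choice_dataset <- function(sequence, trace) {
  if (nrow(sequence) != nrow(trace)) stop("length mismatch", call. = FALSE)
  out <- sequence
  out$choice <- trace$choice
  class(out) <- c("choice_dataset", "data.frame")
  out
}
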