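#' Default context-specific orientation distributions
#'
#' Builds the three context distributions over the orientation grid. Mass
#' `1/K` (with `K` grid points) is placed on the vertical stimulus (0 deg) in
#' every context; the remainder is split between clockwise (positive) and
#' counter-clockwise (negative) orientations in ratio 70:30 for the positively
#' skewed context, 30:70 for the negatively skewed context, and 50:50 for the
#' uniform context, uniformly within each sign. This preserves the marginal
#' distribution of |orientation| across contexts (skew changes sign balance,
#' not difficulty) and yields baseline probabilities of a clockwise-correct
#' trial of 50/70/30% among non-vertical trials.
#'
#' @param orientations orientation grid in degrees; must be symmetric about 0
#'   and contain 0.
#' @return A 3 x K matrix of probabilities with rows named `"-1"`, `"0"`,
#'   `"1"` (context codes) and columns named by orientation.
#' @export
default_context_pmfs <- function(orientations = seq(-7.5, 7.5, by = 2.5)) {
  K <- length(orientations)
  if (!any(orientations == 0) || !setequal(orientations, -orientations))
    stop("`orientations` must be symmetric about 0 and contain 0", call. = FALSE)
  npos <- sum(orientations > 0)
  p0 <- 1 / K
  rest <- 1 - p0
  build <- function(pos_share) {
    p <- numeric(K)
    p[orientations == 0] <- p0
    p[orientations > 0] <- rest * pos_share / npos
    p[orientations < 0] <- rest * (1 - pos_share) / npos
    p
  }
  pmfs <- rbind(build(0.3), build(0.5), build(0.7))
  dimnames(pmfs) <- list(c("-1", "0", "1"), as.character(orientations))
  pmfs
}

#' Task configuration for the context-switching discrimination task
#'
#' Defines the generative process of the simulated experiment: a 3-state
#' Markov context chain with per-trial switch probability `hazard`,
#' context-specific orientation distributions over a fixed grid, two contrast
#' levels with contrast-dependent Gaussian measurement noise, and a
#' probabilistic context cue (either a categorical cue valid with probability
#' `cue_validity`, or an angular cue drawn from a von Mises distribution
#' around the active context's angular label with concentration `cue_kappa`).
#'
#' The experiment the generator emulates used a hazard of 6.3% in the training
#' phase and 42.5% in the test phase; the knowledge-ladder simulation used
#' 20%. Noise scales default to the test-phase observer-simulation values
#' (2 deg at high contrast, 5 deg at low contrast); [ladder_task_config()]
#' returns the knowledge-ladder settings (10/20 deg, kappa 1.5).
#'
#' @param n_trials number of trials.
#' @param hazard per-trial context switch probability in `[0, 1]`.
#' @param orientations orientation grid (deg).
#' @param context_pmfs 3 x K matrix of per-context orientation probabilities
#'   (rows: context codes -1, 0, +1).
#' @param gen_noise named numeric `c(high = , low = )`, Gaussian measurement
#'   noise scale (SD, deg) per contrast level.
#' @param cue_mode `"von_mises"` or `"categorical"`.
#' @param cue_validity probability the categorical cue equals the true context.
#' @param cue_kappa von Mises concentration of the angular cue.
#' @param context_labels angular labels (radians) of the three contexts,
#'   equally spaced by default so all pairs are equally confusable.
#' @param contrast_mode `"interleaved"` (independent fair draw per trial) or
#'   `"blocked"` (alternating runs of `contrast_block` trials).
#' @param contrast_block run length for blocked contrast.
#' @param block_length trials per block (history-reset boundaries).
#' @return An object of class `task_config`.
#' @seealso [simulate_task()], [ladder_task_config()]
#' @export
task_config <- function(n_trials = 1000L,
                        hazard = 0.425,
                        orientations = seq(-7.5, 7.5, by = 2.5),
                        context_pmfs = default_context_pmfs(orientations),
                        gen_noise = c(high = 2, low = 5),
                        cue_mode = c("von_mises", "categorical"),
                        cue_validity = 0.8,
                        cue_kappa = 0.4,
                        context_labels = c(0, 2 * pi / 3, 4 * pi / 3),
                        contrast_mode = c("interleaved", "blocked"),
                        contrast_block = 8L,
                        block_length = 48L) {
  cue_mode <- match.arg(cue_mode)
  contrast_mode <- match.arg(contrast_mode)
  stopifnot_prob(hazard, "hazard")
  stopifnot_prob(cue_validity, "cue_validity")
  if (cue_mode == "von_mises" && (is.null(cue_kappa) || is.na(cue_kappa) || cue_kappa < 0))
    stop("von Mises cue mode requires `cue_kappa` >= 0", call. = FALSE)
  if (!is.matrix(context_pmfs) || nrow(context_pmfs) != 3L ||
      ncol(context_pmfs) != length(orientations))
    stop("`context_pmfs` must be a 3 x length(orientations) matrix", call. = FALSE)
  if (any(abs(rowSums(context_pmfs) - 1) > 1e-12))
    stop("each context pmf must sum to 1 (tolerance 1e-12)", call. = FALSE)
  if (any(context_pmfs < 0)) stop("context pmfs must be nonnegative", call. = FALSE)
  if (!all(c("high", "low") %in% names(gen_noise)) || any(gen_noise <= 0))
    stop("`gen_noise` must be positive and named c(high=, low=)", call. = FALSE)
  if (length(context_labels) != 3L)
    stop("`context_labels` must give one angle per context", call. = FALSE)
  structure(
    list(n_trials = as.integer(n_trials), n_contexts = 3L, hazard = hazard,
         orientations = orientations, context_pmfs = context_pmfs,
         gen_noise = gen_noise[c("high", "low")], cue_mode = cue_mode,
         cue_validity = cue_validity, cue_kappa = cue_kappa,
         context_labels = context_labels, contrast_mode = contrast_mode,
         contrast_block = as.integer(contrast_block),
         block_length = as.integer(block_length)),
    class = "task_config")
}

#' Generative settings of the knowledge-ladder simulation
#'
#' Hazard 20%, cue concentration 1.5, measurement noise 10 deg (high contrast)
#' and 20 deg (low contrast) on the seven-point orientation grid.
#'
#' @param n_trials number of trials.
#' @return A `task_config`.
#' @export
ladder_task_config <- function(n_trials = 2e5) {
  task_config(n_trials = n_trials, hazard = 0.2,
              gen_noise = c(high = 10, low = 20), cue_kappa = 1.5)
}

#' Sample a Markov context chain
#'
#' The first trial's context is uniform over the three contexts; each
#' subsequent trial keeps the previous context with probability `1 - hazard`
#' and otherwise switches to one of the other two contexts with equal
#' probability `hazard / 2`.
#'
#' @param config a [task_config()].
#' @param seed optional integer seed.
#' @return Integer vector of context codes (-1, 0, +1) of length `n_trials`.
#' @export
sample_context_chain <- function(config, seed = NULL) {
  with_seed(seed, {
    n <- config$n_trials
    h <- config$hazard
    idx1 <- sample.int(3L, 1L)
    if (n == 1L) return(CONTEXT_CODES[idx1])
    sw <- stats::runif(n - 1L) < h
    swpos <- which(sw)                       # trial t = swpos + 1 switches
    step <- if (length(swpos)) sample.int(2L, length(swpos), replace = TRUE) else integer(0)
    states <- integer(length(swpos) + 1L)
    states[1L] <- idx1
    for (j in seq_along(swpos))
      states[j + 1L] <- ((states[j] - 1L + step[j]) %% 3L) + 1L
    lens <- diff(c(0L, swpos, n))
    CONTEXT_CODES[rep(states, lens)]
  })
}

#' Trials since the most recent context switch
#'
#' Counts, for every trial, the number of trials since the last context
#' switch, with the first trial of each context run (and the first trial of
#' the whole series) counted as 1.
#'
#' @param context vector of per-trial context codes.
#' @return Integer vector of the same length.
#' @export
annotate_trials_since_switch <- function(context) {
  if (length(context) == 0L) stop("empty context series", call. = FALSE)
  sequence(rle(as.vector(context))$lengths)
}

#' Length of the context run preceding the current one
#'
#' For every trial, the number of trials the chain spent in the previous
#' context (NA for trials in the first run of the series). Used for the
#' aligned-bias matrix over (trials since switch, prior run length).
#'
#' @param context vector of per-trial context codes.
#' @return Integer vector (NA within the first run).
#' @export
annotate_prev_run_length <- function(context) {
  r <- rle(as.vector(context))
  prev <- c(NA_integer_, r$lengths[-length(r$lengths)])
  rep(prev, r$lengths)
}

#' Sample stimulus orientations and contrasts
#'
#' Orientation is drawn from the active context's distribution each trial;
#' contrast is drawn independently with equal probability per level (or in
#' alternating blocks when the config says so).
#'
#' @param context per-trial context codes.
#' @param config a [task_config()].
#' @param seed optional integer seed.
#' @return A data.frame with columns `orientation_deg` and `contrast`.
#' @export
sample_stimuli <- function(context, config, seed = NULL) {
  with_seed(seed, {
    n <- length(context)
    ori <- numeric(n)
    for (code in CONTEXT_CODES) {
      m <- context == code
      if (any(m))
        ori[m] <- sample(config$orientations, sum(m), replace = TRUE,
                         prob = config$context_pmfs[code_to_index(code), ])
    }
    contrast <- if (config$contrast_mode == "interleaved") {
      sample(c("high", "low"), n, replace = TRUE)
    } else {
      lv <- sample(c("high", "low"))        # alternating runs, random start
      nb <- ceiling(n / config$contrast_block)
      rep(rep(lv, length.out = nb), each = config$contrast_block)[seq_len(n)]
    }
    data.frame(orientation_deg = ori, contrast = contrast)
  })
}

#' Sample context cues
#'
#' Categorical mode: the cue equals the true context code with probability
#' `cue_validity` and otherwise is uniform over the other two contexts.
#' von Mises mode: the cue is an angle drawn from a von Mises distribution
#' centered on the active context's angular label with concentration
#' `cue_kappa`.
#'
#' @param context per-trial context codes.
#' @param config a [task_config()].
#' @param seed optional integer seed.
#' @return Numeric vector: context codes (categorical) or angles in radians.
#' @export
sample_cues <- function(context, config, seed = NULL) {
  with_seed(seed, {
    n <- length(context)
    if (config$cue_mode == "categorical") {
      valid <- stats::runif(n) < config$cue_validity
      pick <- sample.int(2L, n, replace = TRUE)   # which of the other two
      idx <- code_to_index(context)
      other <- ((idx - 1L + pick) %% 3L) + 1L
      ifelse(valid, as.numeric(context), as.numeric(CONTEXT_CODES[other]))
    } else {
      mu <- config$context_labels[code_to_index(context)]
      rvonmises(n, mu = mu, kappa = config$cue_kappa)
    }
  })
}

#' Sample noisy orientation measurements
#'
#' The internal measurement is the true orientation plus Gaussian noise with
#' the contrast-specific scale (SD, deg).
#'
#' @param orientations per-trial true orientations (deg).
#' @param contrasts per-trial contrast labels (`"high"`/`"low"`).
#' @param config a [task_config()].
#' @param seed optional integer seed.
#' @return Numeric vector of measurements (deg).
#' @export
sample_measurements <- function(orientations, contrasts, config, seed = NULL) {
  with_seed(seed, {
    sd <- unname(config$gen_noise[contrasts])
    orientations + stats::rnorm(length(orientations), 0, sd)
  })
}

#' Simulate a full trial sequence
#'
#' Draws the context chain, stimuli, cues, and block structure, and annotates
#' trials since the most recent context switch.
#'
#' @param config a [task_config()].
#' @param seed optional integer seed.
#' @return A data.frame of class `trial_sequence` with columns `trial`,
#'   `block`, `context`, `orientation_deg`, `contrast`, `cue`, `s_count`.
#' @export
simulate_task <- function(config, seed = NULL) {
  with_seed(seed, {
    ctx <- sample_context_chain(config)
    stim <- sample_stimuli(ctx, config)
    cue <- sample_cues(ctx, config)
    n <- config$n_trials
    out <- data.frame(
      trial = seq_len(n),
      block = (seq_len(n) - 1L) %/% config$block_length + 1L,
      context = ctx,
      orientation_deg = stim$orientation_deg,
      contrast = stim$contrast,
      cue = cue,
      s_count = annotate_trials_since_switch(ctx))
    class(out) <- c("trial_sequence", "data.frame")
    out
  })
}

#' Write / read trial tables
#'
#' Trial tables are stored as plain CSV with the canonical header
#' `trial, block, context, orientation_deg, contrast, cue, s_count, choice`
#' (`choice` empty for unlabeled sequences).
#'
#' @param x a trial sequence or choice dataset.
#' @param path file path.
#' @return `read_trials` returns a data.frame (with `s_count` recomputed if
#'   absent); `write_trials` returns `path` invisibly.
#' @export
write_trials <- function(x, path) {
  cols <- c("trial", "block", "context", "orientation_deg", "contrast",
            "cue", "s_count", "choice")
  if (!"choice" %in% names(x)) x$choice <- NA_integer_
  utils::write.csv(x[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a task configuration as YAML or JSON
#'
#' Serializes every [task_config()] field (the context pmfs as a list of
#' per-context probability vectors). The format is chosen from the file
#' extension (`.yaml`/`.yml` or `.json`).
#'
#' @param config a [task_config()].
#' @param path file path.
#' @return `read_task_config` returns a validated `task_config`;
#'   `write_task_config` returns `path` invisibly.
#' @export
write_task_config <- function(config, path) {
  x <- unclass(config)
  x$gen_noise <- as.list(config$gen_noise)
  x$context_pmfs <- lapply(seq_len(3), function(i)
    as.numeric(config$context_pmfs[i, ]))
  names(x$context_pmfs) <- c("neg", "uniform", "pos")
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15L)
  } else {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), path)
  }
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(readLines(path))
  pm <- do.call(rbind, x$context_pmfs[c("neg", "uniform", "pos")])
  x$context_pmfs <- matrix(as.numeric(pm), nrow = 3,
                           dimnames = list(c("-1", "0", "1"),
                                           as.character(x$orientations)))
  x$gen_noise <- unlist(x$gen_noise)
  x$n_contexts <- NULL
  do.call(task_config, x)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.csv(path)
  if (!"s_count" %in% names(out))
    out$s_count <- annotate_trials_since_switch(out$context)
  class(out) <- c(if (!all(is.na(out$choice))) "choice_dataset" else "trial_sequence",
                  "data.frame")
  out
}
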