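# Metadata record attached to every reproduction output: seed, problem
# size, a content hash of the generating configuration, package version.
run_metadata <- function(seed, n_trials, config = NULL) {
  hash <- if (!is.null(config)) {
    tf <- tempfile()
    on.exit(unlink(tf), add = TRUE)
    writeLines(deparse(unclass(config)), tf)
    unname(tools::md5sum(tf))
  } else NA_character_
  list(seed = seed, n_trials = n_trials, config_hash = hash,
       package_version = as.character(utils::packageVersion("dynobs")))
}

#' Knowledge-ladder accuracy of the four observer variants
#'
#' Simulates the generative settings of the ladder experiment (hazard 20%,
#' cue concentration 1.5, measurement noise 10/20 deg by contrast) and runs
#' all four observer variants on the *same* stimuli, measurements, and cues,
#' so the per-variant accuracies and their pairwise differences are paired.
#'
#' @param n_trials number of simulated trials.
#' @param seed integer seed.
#' @param config generative settings (defaults to [ladder_task_config()]).
#' @param assumed_hazard hazard assumed by variant 4.
#' @return data.frame with one row per variant: `variant`, `accuracy`, `se`
#'   (Monte-Carlo SE), `step` (accuracy gain over the previous variant),
#'   `step_se` (paired SE of that gain). The simulated sequence and traces
#'   are attached as attributes `sequence` and `traces`.
#' @export
reproduce_ladder <- function(n_trials = 2e5, seed = NULL,
                             config = ladder_task_config(n_trials),
                             assumed_hazard = config$hazard) {
  with_seed(seed, {
    seq_ <- simulate_task(config)
    y <- sample_measurements(seq_$orientation_deg, seq_$contrast, config)
    traces <- lapply(1:4, function(k) {
      obs <- make_model_variant(k, config, assumed_hazard = assumed_hazard)
      run_observer(seq_, obs, measurements = y)
    })
    acc <- vapply(traces, attr, numeric(1), "accuracy")
    se <- vapply(traces, function(tr) stats::sd(tr$correct) / sqrt(nrow(tr)),
                 numeric(1))
    step <- c(NA, diff(acc))
    step_se <- c(NA, vapply(2:4, function(k) {
      d <- traces[[k]]$correct - traces[[k - 1L]]$correct
      stats::sd(d) / sqrt(length(d))
    }, numeric(1)))
    out <- data.frame(variant = 1:4, accuracy = acc, se = se,
                      step = step, step_se = step_se)
    attr(out, "sequence") <- seq_
    attr(out, "traces") <- traces
    attr(out, "metadata") <- run_metadata(seed, n_trials, config)
    out
  })
}

#' Run-length statistics of the context chain
#'
#' Mean number of trials since the most recent context switch (first
#' post-switch trial counted as 1), simulated and in closed form. Across
#' trials the count is geometric, `P(S = k) = h (1 - h)^(k - 1)`, so the
#' closed-form mean is `1 / h`.
#'
#' @param hazards vector of hazard rates.
#' @param n_trials trials per simulated chain.
#' @param seed integer seed.
#' @return data.frame with `hazard`, `mean_s` (simulated), `closed_form`.
#' @export
reproduce_run_length_stats <- function(hazards = c(0.063, 0.425),
                                       n_trials = 1e6, seed = NULL) {
  with_seed(seed, {
    mean_s <- vapply(hazards, function(h) {
      cfg <- task_config(n_trials = n_trials, hazard = h)
      mean(annotate_trials_since_switch(sample_context_chain(cfg)))
    }, numeric(1))
    out <- data.frame(hazard = hazards, mean_s = mean_s,
                      closed_form = 1 / hazards)
    attr(out, "metadata") <- run_metadata(seed, n_trials)
    out
  })
}

#' Aligned-bias curves of the dynamic observer under assumed-parameter sweeps
#'
#' Simulates the test-phase task (hazard 42.5%, noise 2/5 deg by contrast) and
#' computes aligned bias as a function of trials since a context switch for
#' the dynamic observer (variant 4) under a sweep of assumed hazard rates and
#' assumed cue concentrations, plus the static analogue (variant 3). The same
#' generated stimuli, measurements, and cues are shared across all observers.
#'
#' @param n_trials simulated trials.
#' @param seed integer seed.
#' @param assumed_h assumed hazard sweep (cue concentration fixed at
#'   `kappa_fixed`).
#' @param assumed_kappa assumed cue-concentration sweep (hazard fixed at
#'   `h_fixed`).
#' @param h_fixed,kappa_fixed anchors for the one-dimensional sweeps.
#' @param gen_kappa generative cue concentration.
#' @param contrast contrast level of the bias readout (`"low"` by default,
#'   where the broader likelihood makes the prior influence strongest).
#' @param s_max largest exact trials-since-switch bin.
#' @return List of `bias_curve` data.frames: `hazard_sweep` (named by assumed
#'   h), `kappa_sweep` (named by assumed kappa), and `static` (variant 3);
#'   plus `high_contrast`, the anchor setting read out at high contrast.
#' @export
reproduce_bias_surfaces <- function(n_trials = 1e6, seed = NULL,
                                    assumed_h = c(0.1, 0.2, 0.5),
                                    assumed_kappa = c(0.4, 0.2, 0.025),
                                    h_fixed = 0.1, kappa_fixed = 0.4,
                                    gen_kappa = 0.4,
                                    contrast = "low", s_max = 9L) {
  with_seed(seed, {
    cfg <- task_config(n_trials = n_trials, hazard = 0.425,
                       gen_noise = c(high = 2, low = 5), cue_kappa = gen_kappa)
    seq_ <- simulate_task(cfg)
    y <- sample_measurements(seq_$orientation_deg, seq_$contrast, cfg)
    curve_for <- function(obs, contrast_) {
      tr <- run_observer(seq_, obs, measurements = y)
      bias_by_trials_since_switch(as_choice_dataset(seq_, tr),
                                  contrast = contrast_, s_max = s_max)
    }
    hs <- lapply(assumed_h, function(h)
      curve_for(make_model_variant(4L, cfg, assumed_hazard = h,
                                   assumed_kappa = kappa_fixed), contrast))
    names(hs) <- assumed_h
    ks <- lapply(assumed_kappa, function(k)
      curve_for(make_model_variant(4L, cfg, assumed_hazard = h_fixed,
                                   assumed_kappa = k), contrast))
    names(ks) <- assumed_kappa
    anchor <- make_model_variant(4L, cfg, assumed_hazard = h_fixed,
                                 assumed_kappa = kappa_fixed)
    out <- list(hazard_sweep = hs,
                kappa_sweep = ks,
                static = curve_for(make_model_variant(3L, cfg,
                                                      assumed_kappa = kappa_fixed),
                                   contrast),
                high_contrast = curve_for(anchor, "high"))
    attr(out, "metadata") <- run_metadata(seed, n_trials, cfg)
    out
  })
}
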