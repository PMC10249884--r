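# dynobs

Tools for studying perceptual decision-making in *dynamically switching
environments*: a two-alternative forced-choice (2AFC) orientation task in
which a hidden context — one of three stimulus distributions (negatively
skewed, uniform, positively skewed) — switches between trials with hazard
rate *h*, and is signalled only by a probabilistic cue. The package is
aimed at psychophysicists and computational neuroscientists who want to
simulate such tasks, derive ideal-observer predictions, and fit descriptive
choice models with trial-history structure.

Four components:

* **Task generator** — Markov context chains (`sample_context_chain`),
  context-specific stimuli, von Mises or categorical context cues,
  contrast-dependent Gaussian measurement noise, and human-like choice
  processes (`simulate_task`, `generate_glm_observer_choices`,
  `generate_sdt_observer_choices`).
* **Hierarchical Bayesian ideal observer** — filters a belief
  *p(C<sub>t</sub> | cue history)* over contexts through the assumed
  transition dynamics (diagonal 1−h, off-diagonal h/2), mixes the context
  distributions into a stimulus prior, combines it with the measurement
  likelihood, and reads out *p(θ > 0)* (`run_observer`). Four variants
  ablate knowledge of the stimulus distributions, cue reliability,
  contrast-specific noise, and environmental dynamics
  (`make_model_variant`).
* **Psychometric bias estimation** — point of subjective equality (PSE) by
  logistic fit, aligned bias (the context-appropriate PSE shift relative to
  the uniform context), normalized bias, and aligned bias as a function of
  trials since a context switch (`estimate_pse`, `aligned_bias`,
  `bias_by_trials_since_switch`, `bias_matrix`).
* **Choice models** — a six-parameter Signal Detection Theory process model
  with per-contrast lapses, bootstrap CIs and variant comparison
  (`fit_sdt`, `bootstrap_sdt`, `compare_sdt_variants`), and a dynamic
  Bernoulli GLM whose bias regressor
  *f(S, C) = 1/(1 + e<sup>γSC</sup>)* captures the growth of context
  influence with trials since a switch, fitted by a two-step grid search
  over γ (`fit_dynamic_glm`, `predict_bias_curve`, `recovery_experiment`,
  `cv_dynamic_vs_static`, `aic_vs_sdt`).

The methods vignette (`vignettes/context-switching-models.Rmd`) documents
the models, their assumptions, and every numerical choice.

## Worked example

Accuracy of the four observer variants on the knowledge-ladder settings
(hazard 20%, cue concentration κ = 1.5, noise 10/20 deg by contrast), all
run on the same simulated measurements:

```r
library(dynobs)
ladder <- reproduce_ladder(n_trials = 2e5, seed = 101)
round(ladder, 4)
#>   variant accuracy    se   step step_se
#> 1       1   0.6238 0.001     NA      NA
#> 2       2   0.6332 0.001 0.0094   9e-04
#> 3       3   0.6432 0.001 0.0100   7e-04
#> 4       4   0.6493 0.001 0.0061   6e-04
```

The least-informed observer (variant 1: pooled noise, uniform stimulus
prior, no memory of context) is correct on 62.4% of trials; each added form
of knowledge — cue reliability plus context distributions, contrast-specific
noise, context-switch dynamics — buys roughly another percentage point
(`step`, with its paired Monte-Carlo SE). Knowing how often the world
changes is worth about as much as knowing the sensory noise level.

Recovery of a dynamic choice strategy from a 4,000-trial session: simulate
an observer whose context bias rises over trials since a switch, refit, and
compare the model-implied bias curve with the truth:

```r
seq_  <- simulate_task(task_config(n_trials = 4000, hazard = 0.425), seed = 1)
rec   <- recovery_experiment(seq_, default_recovery_observers()["rising"],
                             n_rep = 20, seed = 2)
rec$rising$history
#>     param truth       mean          sd
#> w_r   w_r  0.50 0.48880336 0.044852779
#> w_p   w_p  0.05 0.05019758 0.008525255
round(rec$rising$curve[c(2, 6, 11), ], 3)
#>     S  truth   mean     lo    hi covered
#> 2   1 -0.048 -0.078 -0.205 0.072       1
#> 6   5  0.465  0.449  0.279 0.698       1
#> 11 10  0.649  0.714  0.293 1.309       1
```

The history weights (previous response `w_r`, previous orientation `w_p`)
come back without systematic bias, and the true bias curve — rising by
about 0.7 deg over ten same-context trials at high contrast — lies inside
the 68% replicate band at every probed `S`.

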