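#' Signal Detection Theory process-model parameters
#'
#' Each trial yields a Gaussian orientation estimate centered on the true
#' orientation plus a context-specific constant, compared with a fixed
#' criterion (absorbed into `shift_uniform`, i.e. the criterion sits at 0).
#' The skewed contexts share one shift magnitude applied with the context's
#' sign. The estimate spread is contrast-specific, and on a lapse trial the
#' observer guesses with probability 0.5 regardless of the task variables.
#'
#' @param shift_uniform criterion/uniform-context constant (deg).
#' @param shift_context skew-context constant (deg), applied as
#'   `context * shift_context`.
#' @param sigma_high,sigma_low estimate spread per contrast (deg, > 0).
#' @param lapse_high,lapse_low lapse probability per contrast, in `[0, 0.5]`.
#' @return An object of class `sdt_params`.
#' @export
sdt_params <- function(shift_uniform = 0, shift_context = 0,
                       sigma_high = 1, sigma_low = 2,
                       lapse_high = 0, lapse_low = 0) {
  if (sigma_high <= 0 || sigma_low <= 0) stop("sigmas must be > 0", call. = FALSE)
  if (any(c(lapse_high, lapse_low) < 0) || any(c(lapse_high, lapse_low) > 0.5))
    stop("lapses must be in [0, 0.5]", call. = FALSE)
  structure(list(shift_uniform = shift_uniform, shift_context = shift_context,
                 sigma_high = sigma_high, sigma_low = sigma_low,
                 lapse_high = lapse_high, lapse_low = lapse_low),
            class = "sdt_params")
}

#' Clockwise-choice probability under the SDT model
#'
#' `p = lapse/2 + (1 - lapse) * pnorm((theta + shift_uniform +
#' context * shift_context) / sigma)`, with `lapse` and `sigma` taken from
#' the trial's contrast level. The orientation solving `p = 0.5` (at zero
#' lapse) is the model-implied PSE.
#'
#' @param theta orientation(s) in deg.
#' @param contrast contrast label(s), `"high"`/`"low"`.
#' @param context context code(s) in \{-1, 0, 1\}.
#' @param params an [sdt_params()].
#' @return Probability of a clockwise choice, vectorized.
#' @export
sdt_predict_p_cw <- function(theta, contrast, context, params) {
  hi <- contrast == "high"
  sigma <- ifelse(hi, params$sigma_high, params$sigma_low)
  lapse <- ifelse(hi, params$lapse_high, params$lapse_low)
  lapse / 2 + (1 - lapse) *
    stats::pnorm((theta + params$shift_uniform + context * params$shift_context) / sigma)
}

#' Simulate choices from the SDT model
#'
#' @param sequence a `trial_sequence`.
#' @param params an [sdt_params()].
#' @param seed optional integer seed.
#' @return A `choice_dataset` with Bernoulli choices (+1/-1).
#' @export
generate_sdt_observer_choices <- function(sequence, params, seed = NULL) {
  with_seed(seed, {
    p <- sdt_predict_p_cw(sequence$orientation_deg, sequence$contrast,
                          sequence$context, params)
    out <- sequence
    out$choice <- ifelse(stats::runif(nrow(sequence)) < p, 1L, -1L)
    class(out) <- c("choice_dataset", "data.frame")
    out
  })
}

# Binomial sufficient statistics: counts of clockwise choices per
# (orientation, contrast, context) cell. The likelihood depends on the data
# only through these, which makes repeated fitting (bootstrap, LOO) cheap.
sdt_cells <- function(data) {
  key <- interaction(data$orientation_deg, data$contrast, data$context,
                     drop = TRUE, lex.order = TRUE)
  idx <- as.integer(key)
  first <- !duplicated(idx)
  ord <- order(idx[first])
  cells <- data.frame(theta = data$orientation_deg[first][ord],
                      context = data$context[first][ord],
                      hi = (data$contrast == "high")[first][ord])
  cells$n <- tabulate(idx, nbins = nrow(cells))
  cells$k <- tabulate(idx[data$choice == 1], nbins = nrow(cells))
  attr(cells, "trial_cell") <- idx
  cells
}

# Full 6-parameter vector order used internally:
# (shift_uniform, shift_context, sigma_high, sigma_low, lapse_high, lapse_low)
sdt_unpack <- function(par, variant) {
  su <- par[1L]
  sc <- if (variant$n_shift == 2L) par[2L] else 0
  i <- 1L + (variant$n_shift == 2L)
  if (variant$n_sigma == 2L) {
    sh <- par[i + 1L]; sl <- par[i + 2L]; i <- i + 2L
  } else {
    sh <- sl <- par[i + 1L]; i <- i + 1L
  }
  lh <- par[i + 1L]; ll <- par[i + 2L]
  list(su = su, sc = sc, sh = sh, sl = sl, lh = lh, ll = ll)
}

sdt_cell_p <- function(q, cells) {
  sigma <- ifelse(cells$hi, q$sh, q$sl)
  lapse <- ifelse(cells$hi, q$lh, q$ll)
  z <- (cells$theta + q$su + cells$context * q$sc) / sigma
  list(p = lapse / 2 + (1 - lapse) * stats::pnorm(z), z = z,
       sigma = sigma, lapse = lapse)
}

sdt_nll <- function(par, cells, variant) {
  q <- sdt_unpack(par, variant)
  p <- pmin(1 - 1e-12, pmax(1e-12, sdt_cell_p(q, cells)$p))
  -sum(cells$k * log(p) + (cells$n - cells$k) * log(1 - p))
}

sdt_grad <- function(par, cells, variant) {
  q <- sdt_unpack(par, variant)
  cp <- sdt_cell_p(q, cells)
  p <- pmin(1 - 1e-12, pmax(1e-12, cp$p))
  dldp <- -(cells$k / p - (cells$n - cells$k) / (1 - p))
  phi <- stats::dnorm(cp$z)
  dp_su <- (1 - cp$lapse) * phi / cp$sigma
  dp_sc <- dp_su * cells$context
  dp_sigma <- -(1 - cp$lapse) * phi * cp$z / cp$sigma
  dp_lapse <- 0.5 - stats::pnorm(cp$z)
  g_su <- sum(dldp * dp_su)
  g_sc <- sum(dldp * dp_sc)
  g_sh <- sum(dldp * dp_sigma * cells$hi)
  g_sl <- sum(dldp * dp_sigma * !cells$hi)
  g_lh <- sum(dldp * dp_lapse * cells$hi)
  g_ll <- sum(dldp * dp_lapse * !cells$hi)
  g <- g_su
  if (variant$n_shift == 2L) g <- c(g, g_sc)
  g <- if (variant$n_sigma == 2L) c(g, g_sh, g_sl) else c(g, g_sh + g_sl)
  c(g, g_lh, g_ll)
}

# Multi-start bounded quasi-Newton fit on precomputed cell counts.
sdt_fit_from_cells <- function(cells, variant, starts, bd = sdt_bounds(variant)) {
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], sdt_nll, sdt_grad, cells = cells,
                   variant = variant, method = "L-BFGS-B",
                   lower = bd$lower, upper = bd$upper,
                   control = list(maxit = 500L, factr = 1e6)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  best
}

sdt_variant_spec <- function(variant) {
  known <- list(full = list(n_shift = 2L, n_sigma = 2L),
                one_shift = list(n_shift = 1L, n_sigma = 2L),
                one_sigma = list(n_shift = 2L, n_sigma = 1L),
                one_shift_one_sigma = list(n_shift = 1L, n_sigma = 1L))
  if (is.list(variant)) return(variant)
  if (!variant %in% names(known)) stop("unknown SDT variant", call. = FALSE)
  known[[variant]]
}

sdt_bounds <- function(variant) {
  lower <- c(-15, if (variant$n_shift == 2L) -15,
             rep(0.05, variant$n_sigma), 0, 0)
  upper <- c(15, if (variant$n_shift == 2L) 15,
             rep(60, variant$n_sigma), 0.5, 0.5)
  list(lower = lower, upper = upper)
}

#' Fit the SDT process model by maximum likelihood
#'
#' Bernoulli maximum likelihood on the (orientation, contrast, context) cell
#' counts, via bounded quasi-Newton optimization (L-BFGS-B with analytic
#' gradients) from multiple Latin-hypercube starting points. Variants differ
#' in whether the context shift and the spread are free per
#' condition: `"full"` (2 shifts x 2 spreads, 6 parameters), `"one_shift"`
#' (no context shift), `"one_sigma"` (pooled spread), `"one_shift_one_sigma"`.
#' Lapses are always per contrast.
#'
#' @param data a `choice_dataset`.
#' @param variant variant name or `list(n_shift=, n_sigma=)`.
#' @param n_starts number of random multi-starts.
#' @param start optional warm-start parameter vector (packed order).
#' @param seed seed for the start points.
#' @return List with `params` (an [sdt_params()]), `par` (packed vector),
#'   `logLik`, `k` (parameter count), `n`, `variant`, `convergence`.
#' @export
fit_sdt <- function(data, variant = "full", n_starts = 10L, start = NULL,
                    seed = NULL) {
  variant <- sdt_variant_spec(variant)
  cells <- sdt_cells(data)
  bd <- sdt_bounds(variant)
  npar <- length(bd$lower)
  starts <- with_seed(seed, {
    lh <- lhs::randomLHS(n_starts, npar)
    t(bd$lower + t(lh) * (bd$upper - bd$lower))
  })
  # keep sigma starts in a plausible range and lapses small
  sig_idx <- seq(1L + (variant$n_shift == 2L) + 1L, length.out = variant$n_sigma)
  starts[, sig_idx] <- 0.5 + starts[, sig_idx] / 60 * 10
  starts[, npar - 1L] <- starts[, npar - 1L] * 0.2
  starts[, npar] <- starts[, npar] * 0.2
  if (!is.null(start)) starts <- rbind(start, starts[seq_len(max(0L, n_starts - 1L)), , drop = FALSE])
  best <- sdt_fit_from_cells(cells, variant, starts, bd)
  if (is.null(best))
    stop("SDT fit failed to converge from all starting points", call. = FALSE)
  q <- sdt_unpack(best$par, variant)
  list(params = sdt_params(q$su, q$sc, q$sh, q$sl, q$lh, q$ll),
       par = best$par, logLik = -best$value, k = npar, n = nrow(data),
       variant = variant, convergence = best$convergence)
}

#' Nonparametric bootstrap confidence intervals for SDT parameters
#'
#' Resamples trials with replacement, refits (warm-started at the point
#' estimate), and reports percentile intervals at the 68% and 95% levels.
#'
#' @param data the `choice_dataset` that was fitted.
#' @param fit result of [fit_sdt()].
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @return List with `boot` (n_boot x k matrix of packed parameter vectors),
#'   `ci68`, `ci95` (2 x k matrices), and `n_fail`.
#' @export
bootstrap_sdt <- function(data, fit, n_boot = 1000L, seed = NULL) {
  with_seed(seed, {
    npar <- length(fit$par)
    boot <- matrix(NA_real_, n_boot, npar)
    n_fail <- 0L
    cells <- sdt_cells(data)
    trial_cell <- attr(cells, "trial_cell")
    cw <- data$choice == 1
    n <- nrow(data)
    nc <- nrow(cells)
    starts <- matrix(fit$par, nrow = 1L)
    for (b in seq_len(n_boot)) {
      s <- sample.int(n, n, replace = TRUE)
      cb <- cells
      cb$n <- tabulate(trial_cell[s], nbins = nc)
      cb$k <- tabulate(trial_cell[s][cw[s]], nbins = nc)
      rb <- sdt_fit_from_cells(cb, fit$variant, starts)
      if (is.null(rb)) n_fail <- n_fail + 1L else boot[b, ] <- rb$par
    }
    qfun <- function(lv) apply(boot, 2L, stats::quantile,
                               probs = c(0.5 - lv / 2, 0.5 + lv / 2), na.rm = TRUE)
    list(boot = boot, ci68 = qfun(0.68), ci95 = qfun(0.95), n_fail = n_fail)
  })
}

#' Compare SDT variants by held-out likelihood and AIC
#'
#' Subsampled leave-one-out cross-validation: for each of `n_holdout` randomly
#' chosen trials, the variant is refit (warm-started) on the remaining trials
#' and scored on the held-out trial; the table reports the average held-out
#' log-likelihood per variant together with `AIC = 2k - 2 lnL` from the full
#' fit.
#'
#' @param data a `choice_dataset`.
#' @param n_holdout number of leave-one-out folds to subsample.
#' @param seed integer seed (fold choice is deterministic given the seed).
#' @return data.frame with one row per variant: `variant`, `k`, `logLik`,
#'   `AIC`, `heldout_loglik`.
#' @export
compare_sdt_variants <- function(data, n_holdout = 200L, seed = NULL) {
  with_seed(seed, {
    variants <- c("full", "one_shift", "one_sigma", "one_shift_one_sigma")
    hold <- sample.int(nrow(data), min(n_holdout, nrow(data)))
    cells <- sdt_cells(data)
    trial_cell <- attr(cells, "trial_cell")
    out <- lapply(variants, function(v) {
      full <- fit_sdt(data, variant = v, n_starts = 10L, seed = NULL)
      vs <- sdt_variant_spec(v)
      ll <- vapply(hold, function(i) {
        cb <- cells
        j <- trial_cell[i]
        cb$n[j] <- cb$n[j] - 1L
        if (data$choice[i] == 1) cb$k[j] <- cb$k[j] - 1L
        f <- sdt_fit_from_cells(cb, vs, matrix(full$par, nrow = 1L))
        q <- sdt_unpack(f$par, vs)
        p <- sdt_predict_p_cw(data$orientation_deg[i], data$contrast[i],
                              data$context[i],
                              sdt_params(q$su, q$sc, q$sh, q$sl, q$lh, q$ll))
        p <- min(1 - 1e-12, max(1e-12, p))
        if (data$choice[i] == 1) log(p) else log(1 - p)
      }, numeric(1))
      data.frame(variant = v, k = full$k, logLik = full$logLik,
                 AIC = 2 * full$k - 2 * full$logLik,
                 heldout_loglik = mean(ll))
    })
    do.call(rbind, out)
  })
}
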