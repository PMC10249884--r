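#' Estimate the point of subjective equality
#'
#' Fits a two-parameter logistic (intercept + slope on orientation) to binary
#' choices and solves it at 50% clockwise. The PSE is the orientation at which
#' clockwise and counter-clockwise responses are equally likely; with choices
#' pulled toward clockwise the PSE moves to negative orientations.
#'
#' @param data data.frame with `orientation_deg` and `choice` (+1/-1), or
#'   aggregated columns `orientation_deg`, `n_cw`, `n`.
#' @return List with `pse` (deg), `slope` (per deg, on the logit scale),
#'   `intercept`, and `se` (delta-method standard error of the PSE).
#' @export
estimate_pse <- function(data) {
  if (all(c("n_cw", "n") %in% names(data))) {
    agg <- data
  } else {
    cw <- tapply(data$choice == 1, data$orientation_deg, sum)
    nn <- tapply(data$choice, data$orientation_deg, length)
    agg <- data.frame(orientation_deg = as.numeric(names(nn)),
                      n_cw = as.vector(cw), n = as.vector(nn))
  }
  if (nrow(agg) < 2L) stop("need >= 2 orientation levels", call. = FALSE)
  if (sum(agg$n_cw) == 0 || sum(agg$n_cw) == sum(agg$n))
    stop("undefined PSE: all choices identical", call. = FALSE)
  fit <- stats::glm(cbind(n_cw, n - n_cw) ~ orientation_deg,
                    family = stats::binomial(), data = agg)
  b <- stats::coef(fit)
  if (!is.finite(b[2L]) || b[2L] <= 0)
    stop("undefined PSE: non-positive psychometric slope", call. = FALSE)
  # delta method for -a/b
  V <- stats::vcov(fit)
  g <- c(-1 / b[2L], b[1L] / b[2L]^2)
  se <- sqrt(max(0, as.numeric(t(g) %*% V %*% g)))
  list(pse = unname(-b[1L] / b[2L]), slope = unname(b[2L]),
       intercept = unname(b[1L]), se = se)
}

#' Aligned bias from per-context PSEs
#'
#' The context-appropriate shift of the point of subjective equality, averaged
#' over the two skewed contexts relative to the uniform context:
#' `0.5 * ((PSE_uniform - PSE_pos) + (PSE_neg - PSE_uniform))`. Positive
#' values mean choices are pulled toward each context's more probable
#' response. `readout = "cw_vs_uniform"` instead uses only the positively
#' skewed (clockwise) context, `PSE_uniform - PSE_pos`.
#'
#' @param pse_by_context named numeric vector with entries `neg`, `uniform`,
#'   `pos` (PSEs in deg).
#' @param readout `"both_skews"` (default) or `"cw_vs_uniform"`.
#' @return Aligned bias in degrees.
#' @export
aligned_bias <- function(pse_by_context, readout = c("both_skews", "cw_vs_uniform")) {
  readout <- match.arg(readout)
  need <- c("neg", "uniform", "pos")
  if (!all(need %in% names(pse_by_context)) || is.na(pse_by_context["uniform"]))
    stop("PSEs for `neg`, `uniform`, and `pos` contexts are required", call. = FALSE)
  p <- pse_by_context
  if (readout == "both_skews")
    unname(0.5 * ((p["uniform"] - p["pos"]) + (p["neg"] - p["uniform"])))
  else
    unname(p["uniform"] - p["pos"])
}

#' Normalized aligned bias
#'
#' Aligned bias divided by the orientation uncertainty (the fitted spread of
#' the internal orientation estimate), giving a dimensionless effect size.
#'
#' @param aligned_bias_deg aligned bias (deg).
#' @param uncertainty_deg orientation uncertainty (deg), > 0.
#' @return Dimensionless ratio.
#' @export
normalized_bias <- function(aligned_bias_deg, uncertainty_deg) {
  if (!is.numeric(uncertainty_deg) || any(uncertainty_deg <= 0))
    stop("`uncertainty_deg` must be > 0", call. = FALSE)
  aligned_bias_deg / uncertainty_deg
}

# Cut s_count into the default bins 1..9 then "10+"; configurable via breaks.
bin_s_count <- function(s, s_max = 9L) {
  lab <- ifelse(s > s_max, paste0(s_max + 1L, "+"), as.character(s))
  factor(lab, levels = c(as.character(seq_len(s_max)), paste0(s_max + 1L, "+")))
}

# Aligned bias (and per-bin PSEs) for one subset of trials; NA + flag when a
# context cell is too sparse for a psychometric fit.
bias_of_subset <- function(data, min_per_context, readout) {
  pses <- ses <- c(neg = NA_real_, uniform = NA_real_, pos = NA_real_)
  for (j in 1:3) {
    sub <- data[data$context == CONTEXT_CODES[j], ]
    if (nrow(sub) < min_per_context) next
    fit <- tryCatch(estimate_pse(sub), error = function(e) NULL)
    if (!is.null(fit)) {
      pses[j] <- fit$pse
      ses[j] <- fit$se
    }
  }
  if (any(is.na(pses)))
    return(list(bias = NA_real_, se = NA_real_, flagged = TRUE))
  b <- aligned_bias(pses, readout)
  # 0.5*(PSE_neg - PSE_pos): uniform cancels in the default readout
  se <- if (readout == "both_skews") 0.5 * sqrt(ses["neg"]^2 + ses["pos"]^2) else
    sqrt(ses["uniform"]^2 + ses["pos"]^2)
  list(bias = b, se = unname(se), flagged = FALSE)
}

#' Aligned bias as a function of trials since a context switch
#'
#' Splits trials by the number of trials since the most recent context switch
#' (default bins: exact counts 1-9, then "10+"), estimates per-context PSEs
#' within each bin, and reads out the aligned bias. Bins with insufficient
#' data are flagged (`NA`) rather than extrapolated. Uncertainty per bin comes
#' from the delta-method PSE standard errors; a seeded nonparametric bootstrap
#' over trials is available via `n_boot`.
#'
#' @param data a `choice_dataset` annotated with `s_count`.
#' @param contrast optional contrast level to restrict to (`"low"`/`"high"`).
#' @param s_max largest exact bin; larger counts pool into `"s_max+1 +"`.
#' @param readout passed to [aligned_bias()].
#' @param min_per_context minimum trials per context cell for a fit.
#' @param n_boot bootstrap resamples for CIs (0 = delta-method only).
#' @param conf confidence level of the interval (0.68 matches one-sigma
#'   error bars).
#' @param seed bootstrap seed.
#' @return A data.frame of class `bias_curve`: `s_bin`, `n`, `bias`, `se`,
#'   `ci_lo`, `ci_hi`, `flagged`.
#' @export
bias_by_trials_since_switch <- function(data, contrast = NULL, s_max = 9L,
                                        readout = c("both_skews", "cw_vs_uniform"),
                                        min_per_context = 30L,
                                        n_boot = 0L, conf = 0.68, seed = NULL) {
  readout <- match.arg(readout)
  if (!"s_count" %in% names(data)) stop("dataset lacks `s_count`", call. = FALSE)
  if (!is.null(contrast)) data <- data[data$contrast == contrast, ]
  bins <- bin_s_count(data$s_count, s_max)
  lev <- levels(bins)
  out <- data.frame(s_bin = lev, n = as.vector(table(bins)),
                    bias = NA_real_, se = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_, flagged = TRUE,
                    stringsAsFactors = FALSE)
  z <- stats::qnorm(0.5 + conf / 2)
  for (i in seq_along(lev)) {
    sub <- data[bins == lev[i], ]
    res <- bias_of_subset(sub, min_per_context, readout)
    out$bias[i] <- res$bias
    out$se[i] <- res$se
    out$flagged[i] <- res$flagged
    if (!res$flagged) {
      if (n_boot > 0L) {
        bs <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
          idx <- sample.int(nrow(sub), nrow(sub), replace = TRUE)
          bias_of_subset(sub[idx, ], min_per_context, readout)$bias
        }, numeric(1)))
        qs <- stats::quantile(bs, c(0.5 - conf / 2, 0.5 + conf / 2), na.rm = TRUE)
        out$ci_lo[i] <- qs[1L]
        out$ci_hi[i] <- qs[2L]
      } else {
        out$ci_lo[i] <- res$bias - z * res$se
        out$ci_hi[i] <- res$bias + z * res$se
      }
    }
  }
  class(out) <- c("bias_curve", "data.frame")
  out
}

#' Aligned bias over trials-since-switch and preceding run length
#'
#' Cross-tabulates the aligned bias by the current count of trials since the
#' most recent switch (columns) and the length of the context run *before*
#' that switch (rows). Longer prior runs entrench the previous belief, so the
#' rise of bias after a switch is delayed (a weak effect). Sparse cells are
#' `NA`.
#'
#' @param data a `choice_dataset` (prev run lengths are computed from
#'   `context` if the `prev_run` column is absent).
#' @param contrast optional contrast restriction.
#' @param s_max,prev_max largest exact bin on each axis.
#' @param readout passed to [aligned_bias()].
#' @param min_per_context minimum trials per context cell.
#' @return Matrix of aligned bias, rows = prior run-length bins, columns =
#'   trials-since-switch bins.
#' @export
bias_matrix <- function(data, contrast = NULL, s_max = 6L, prev_max = 6L,
                        readout = c("both_skews", "cw_vs_uniform"),
                        min_per_context = 30L) {
  readout <- match.arg(readout)
  if (!"prev_run" %in% names(data)) data$prev_run <- annotate_prev_run_length(data$context)
  if (!is.null(contrast)) data <- data[data$contrast == contrast, ]
  data <- data[!is.na(data$prev_run), ]
  sb <- bin_s_count(data$s_count, s_max)
  pb <- bin_s_count(data$prev_run, prev_max)
  out <- matrix(NA_real_, nlevels(pb), nlevels(sb),
                dimnames = list(prev_run = levels(pb), s_count = levels(sb)))
  for (i in seq_len(nlevels(pb))) for (j in seq_len(nlevels(sb))) {
    sub <- data[pb == levels(pb)[i] & sb == levels(sb)[j], ]
    res <- bias_of_subset(sub, min_per_context, readout)
    out[i, j] <- res$bias
  }
  out
}

#' Wilcoxon utilities for group comparisons
#'
#' Thin wrappers around [stats::wilcox.test()] returning the statistic,
#' p-value, and the median (difference) being tested, as used for paired
#' within-cohort comparisons (`signed rank`) and between-group comparisons
#' (`rank sum`).
#'
#' @param x,y numeric vectors (for the signed-rank test, `y` optional paired
#'   values).
#' @param alternative `"two.sided"`, `"less"`, or `"greater"`.
#' @return List with `statistic`, `p_value`, and `median`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, alternative = "two.sided") {
  wt <- if (is.null(y)) stats::wilcox.test(x, alternative = alternative, exact = TRUE)
  else stats::wilcox.test(x, y, paired = TRUE, alternative = alternative, exact = TRUE)
  d <- if (is.null(y)) x else x - y
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median = stats::median(d))
}

#' @rdname wilcoxon_signed_rank
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  wt <- stats::wilcox.test(x, y, alternative = alternative, exact = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median = stats::median(x) - stats::median(y))
}
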