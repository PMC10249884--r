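#' @keywords internal
"_PACKAGE"

# Context codes used throughout: -1 (negatively skewed), 0 (uniform),
# +1 (positively skewed). Internal index = code + 2.
CONTEXT_CODES <- c(-1L, 0L, 1L)

code_to_index <- function(code) as.integer(code) + 2L

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the previous
#' RNG state so callers' random streams are unaffected. With `seed = NULL` the
#' expression simply uses the current RNG stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
}

# Row-wise maximum of a numeric matrix without apply() overhead.
row_max <- function(m) {
  out <- m[, 1L]
  for (k in seq_len(ncol(m))[-1L]) out <- pmax(out, m[, k])
  out
}

#' Sample from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler. Used for the angular context cue,
#' since the cue is modeled as the context's angular label perturbed by
#' circular noise with concentration `kappa`.
#'
#' @param n number of draws.
#' @param mu mean direction(s) in radians (scalar or length `n`).
#' @param kappa concentration parameter (>= 0); 0 gives the circular uniform.
#' @return Angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
  if (kappa < 1e-10) return((stats::runif(n, 0, 2 * pi) + mu) %% (2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nok <- sum(ok)
    if (nok > 0L) {
      out[got + seq_len(nok)] <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      got <- got + nok
    }
  }
  (out + mu) %% (2 * pi)
}

#' von Mises density
#'
#' @param x angle(s) in radians.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0).
#' @param log return log-density?
#' @return Density values; `kappa = 0` gives the circular uniform `1/(2*pi)`.
#' @export
dvonmises <- function(x, mu = 0, kappa = 1, log = FALSE) {
  if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
  # exponentially scaled Bessel avoids overflow at large kappa
  ld <- kappa * (cos(x - mu) - 1) - log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}
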