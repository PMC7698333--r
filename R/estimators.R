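#' Nonparametric tail-quantile estimators for limits of agreement
#'
#' All six estimators implemented here are L-statistics: linear combinations
#' `sum(W_i * X_(i))` of the order statistics of the paired differences, with
#' weight vectors that depend only on the sample size `n` and the target
#' probability `p`.  They differ in how mass is spread over the order
#' statistics near the target quantile:
#'
#' * `sq` -- sample quantile: interpolates the two order statistics flanking
#'   rank `p(n+1)`; only two observations get weight.
#' * `hd` -- Harrell-Davis: weights are increments of the regularized
#'   incomplete beta function `I_x(p(n+1), (1-p)(n+1))` over the grid `i/n`;
#'   every observation gets weight.
#' * `bp` -- Bernstein polynomial: binomial probabilities `B(i-1; n-1, p)`.
#' * `hdlc` -- Harrell-Davis on a level-crossing empirical distribution:
#'   as `hd` but the beta CDF is evaluated at unequal cumulative weights that
#'   give the boundary observations less mass than interior ones.
#' * `sv` -- first Sfakianakis-Verginis estimator: averaged adjacent binomial
#'   probabilities with boundary corrections designed for tail quantiles.
#' * `no` -- Navruz-Ozdemir estimator: binomial-probability weights with a
#'   different boundary correction.
#'
#' @name estimators
#' @keywords internal
NULL

ESTIMATOR_IDS <- c("sq", "hd", "bp", "hdlc", "sv", "no")

#' Sorted sample of paired differences
#'
#' Light container holding the order statistics of a numeric sample.  The
#' constructor sorts; all estimator code assumes sortedness.
#'
#' @param x numeric vector (non-missing, finite)
#' @return object of class `ordered_sample` with fields `values` (sorted)
#'   and `n`
#' @export
ordered_sample <- function(x) {
  stopifnot(is.numeric(x))
  x <- as.numeric(x)
  if (anyNA(x)) stop("ordered_sample: missing values not allowed", call. = FALSE)
  if (any(!is.finite(x))) stop("ordered_sample: non-finite values not allowed", call. = FALSE)
  if (length(x) < 1L) stop("ordered_sample: empty sample", call. = FALSE)
  structure(list(values = sort(x), n = length(x)), class = "ordered_sample")
}

#' @export
print.ordered_sample <- function(x, ...) {
  cat(sprintf("<ordered_sample> n = %d, range [%g, %g]\n",
              x$n, x$values[1L], x$values[x$n]))
  invisible(x)
}

as_ordered_sample <- function(x) {
  if (inherits(x, "ordered_sample")) x else ordered_sample(x)
}

check_prob <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L)
  if (!(p > 0 && p < 1)) stop("p must lie strictly between 0 and 1", call. = FALSE)
  p
}

match_estimator <- function(estimator, allow_ba = FALSE) {
  ids <- if (allow_ba) c("ba", ESTIMATOR_IDS) else ESTIMATOR_IDS
  est <- tolower(as.character(estimator))
  if (length(est) != 1L || !est %in% ids)
    stop(sprintf("unknown estimator '%s'; expected one of: %s",
                 estimator, paste(ids, collapse = ", ")), call. = FALSE)
  est
}

#' Minimum sample size at which an estimator is defined
#'
#' The sample-quantile estimator needs the flanking ranks `floor(p(n+1))`
#' and `floor(p(n+1)) + 1` to exist at every target probability, i.e.
#' `1 <= p(n+1) <= n`; at the LoA levels 0.025/0.975 this means `n >= 39`.
#' The Sfakianakis-Verginis and Navruz-Ozdemir formulas address
#' `X(1)..X(3)` and `X(n-2)..X(n)` as distinct terms, so `n >= 5` is
#' required.  The level-crossing weights need `n >= 2`.
#'
#' @param estimator estimator id (`ba`, `sq`, `hd`, `bp`, `hdlc`, `sv`, `no`)
#' @param probs target probabilities (default the LoA pair 0.025/0.975)
#' @return smallest valid `n`
#' @export
min_sample_size <- function(estimator, probs = c(0.025, 0.975)) {
  est <- match_estimator(estimator, allow_ba = TRUE)
  switch(est,
    ba = 2L,
    sq = {
      # need p(n+1) >= 1 and p(n+1) <= n for every target p; search from
      # just below the analytic bound to stay robust to float rounding
      ok <- function(n) all(probs * (n + 1) >= 1 & probs * (n + 1) <= n)
      n <- max(1L, as.integer(floor(max(1 / probs, probs / (1 - probs)))) - 2L)
      while (!ok(n)) n <- n + 1L
      as.integer(n)
    },
    hd = 1L,
    bp = 1L,
    hdlc = 2L,
    sv = 5L,
    no = 5L)
}

# ---- weight construction ---------------------------------------------------

#' Harrell-Davis weights
#'
#' `W_i = I_{i/n}(a, b) - I_{(i-1)/n}(a, b)` with `a = p(n+1)`,
#' `b = (1-p)(n+1)` and `I` the regularized incomplete beta function
#' (the Beta CDF), so the weights telescope to exactly 1.
#'
#' @param n sample size (>= 1)
#' @param p target probability in (0,1)
#' @return numeric weight vector of length `n`
#' @export
hd_weights <- function(n, p) {
  stopifnot(n >= 1)
  check_prob(p)
  a <- p * (n + 1)
  b <- (1 - p) * (n + 1)
  diff(stats::pbeta((0:n) / n, a, b))
}

#' Level-crossing empirical-distribution weights
#'
#' Re-weighted empirical distribution in which the two boundary observations
#' receive mass `(1/2) * (1 - (n-2)/sqrt(n(n-1)))` each and every interior
#' observation receives `1/sqrt(n(n-1))`; the weights sum to 1 exactly.
#'
#' @param n sample size (>= 2)
#' @return list with fields `w` (weights) and `q` (cumulative sums, `q[n] == 1`)
#' @export
lc_weights <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("lc_weights requires n >= 2", call. = FALSE)
  n <- as.integer(n)
  interior <- 1 / sqrt(n * (n - 1))
  boundary <- 0.5 * (1 - (n - 2) * interior)
  w <- rep(interior, n)
  w[c(1L, n)] <- boundary
  list(w = w, q = cumsum(w))
}

sq_weights <- function(n, p) {
  h <- p * (n + 1)
  if (h < 1 || h > n)
    stop(sprintf(paste0("sample quantile estimator undefined for n = %d at ",
                        "p = %g (needs 1 <= p(n+1) <= n, i.e. n >= %d)"),
                 n, p, min_sample_size("sq", p)), call. = FALSE)
  r <- floor(h)
  alpha <- h - r
  w <- numeric(n)
  w[r] <- 1 - alpha
  if (alpha > 0) w[r + 1L] <- alpha
  w
}

bp_weights <- function(n, p) {
  stopifnot(n >= 1)
  stats::dbinom(0:(n - 1L), n - 1L, p)
}

hdlc_weights <- function(n, p) {
  lc <- lc_weights(n)
  a <- p * (n + 1)
  b <- (1 - p) * (n + 1)
  diff(stats::pbeta(c(0, lc$q), a, b))
}

sv_weights <- function(n, p) {
  if (n < 5) stop("Sfakianakis-Verginis estimator requires n >= 5", call. = FALSE)
  B <- stats::dbinom(0:n, n, p)   # B[i+1] = B(i; n, p)
  w <- numeric(n)
  i <- 2:(n - 1L)
  w[i] <- (B[i + 1L] + B[i]) / 2
  w[1L] <- w[1L] + (2 * B[1L] + B[2L]) / 2
  w[2L] <- w[2L] + B[1L] / 2
  w[3L] <- w[3L] - B[1L] / 2
  w[n - 2L] <- w[n - 2L] - B[n + 1L] / 2
  w[n - 1L] <- w[n - 1L] + B[n + 1L] / 2
  w[n] <- w[n] + (2 * B[n + 1L] + B[n]) / 2
  w
}

no_weights <- function(n, p) {
  if (n < 5) stop("Navruz-Ozdemir estimator requires n >= 5", call. = FALSE)
  B <- stats::dbinom(0:n, n, p)   # B[i+1] = B(i; n, p)
  w <- numeric(n)
  i <- 1:(n - 2L)                 # central sum places mass on X(i+1)
  w[i + 1L] <- B[i + 1L] * (1 - p) + B[i + 2L] * p
  w[1L] <- w[1L] + B[1L] * 2 * p + B[2L] * p
  w[2L] <- w[2L] + B[1L] * (2 - 3 * p)
  w[3L] <- w[3L] - B[1L] * (1 - p)
  w[n - 2L] <- w[n - 2L] - B[n + 1L] * p
  w[n - 1L] <- w[n - 1L] + B[n + 1L] * (3 * p - 1)
  w[n] <- w[n] + B[n] * (1 - p) + B[n + 1L] * (2 - 2 * p)
  w
}

#' L-statistic weight vector of a quantile estimator
#'
#' Returns the coefficients `W_i` such that the estimate equals
#' `sum(W_i * X_(i))` over the order statistics.  Weights depend only on
#' `(n, p)`, so they can be computed once and reused across Monte-Carlo
#' replicates.  Every weight vector sums to 1.
#'
#' @param estimator one of `sq`, `hd`, `bp`, `hdlc`, `sv`, `no`
#' @inheritParams hd_weights
#' @return numeric vector of length `n`
#' @export
estimator_weights <- function(estimator, n, p) {
  est <- match_estimator(estimator)
  check_prob(p)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  n <- as.integer(n)
  if (n < min_sample_size(est, p))
    stop(sprintf("estimator '%s' requires n >= %d at p = %g (got n = %d)",
                 est, min_sample_size(est, p), p, n), call. = FALSE)
  switch(est,
    sq = sq_weights(n, p),
    hd = hd_weights(n, p),
    bp = bp_weights(n, p),
    hdlc = hdlc_weights(n, p),
    sv = sv_weights(n, p),
    no = no_weights(n, p))
}

# ---- quantile estimators ---------------------------------------------------

l_estimate <- function(sample, p, estimator) {
  s <- as_ordered_sample(sample)
  sum(estimator_weights(estimator, s$n, p) * s$values)
}

#' Sample-quantile estimator (two flanking order statistics)
#'
#' `SQ = (1 - alpha) * X(r) + alpha * X(r+1)` with `r = floor(p(n+1))` and
#' `alpha = p(n+1) - r`.  Undefined when `p(n+1) < 1` or `p(n+1) > n`; at
#' the LoA levels this requires `n >= 39`.
#'
#' @param sample numeric vector or [ordered_sample]
#' @param p target probability in (0,1)
#' @return quantile estimate
#' @export
sq_quantile <- function(sample, p) l_estimate(sample, p, "sq")

#' Harrell-Davis quantile estimator
#' @inheritParams sq_quantile
#' @return quantile estimate
#' @seealso [hd_weights()]
#' @export
hd_quantile <- function(sample, p) l_estimate(sample, p, "hd")

#' Bernstein-polynomial quantile estimator
#'
#' Weights the order statistics by binomial probabilities
#' `B(i-1; n-1, p)`.
#' @inheritParams sq_quantile
#' @return quantile estimate
#' @export
bp_quantile <- function(sample, p) l_estimate(sample, p, "bp")

#' Harrell-Davis estimator on a level-crossing empirical distribution
#' @inheritParams sq_quantile
#' @return quantile estimate
#' @seealso [lc_weights()]
#' @export
hdlc_quantile <- function(sample, p) l_estimate(sample, p, "hdlc")

#' Sfakianakis-Verginis (first form) quantile estimator
#' @inheritParams sq_quantile
#' @return quantile estimate
#' @export
sv_quantile <- function(sample, p) l_estimate(sample, p, "sv")

#' Navruz-Ozdemir quantile estimator
#' @inheritParams sq_quantile
#' @return quantile estimate
#' @export
no_quantile <- function(sample, p) l_estimate(sample, p, "no")

# ---- LoA pairing -----------------------------------------------------------

new_loa_pair <- function(lower, upper, estimator, n, bias = NULL) {
  structure(list(lower = lower, upper = upper, estimator = estimator,
                 n = n, bias = bias),
            class = "loa_pair")
}

#' @export
print.loa_pair <- function(x, ...) {
  cat(sprintf("Limits of agreement (%s, n = %d)\n", toupper(x$estimator), x$n))
  if (!is.null(x$bias)) cat(sprintf("  bias : %g\n", x$bias))
  cat(sprintf("  lower: %g\n  upper: %g\n", x$lower, x$upper))
  invisible(x)
}

#' Nonparametric limits of agreement from a sorted sample
#'
#' Evaluates the chosen estimator at the lower and upper LoA levels
#' (default 2.5% and 97.5%).  A crossed pair (lower > upper) is possible for
#' the boundary-corrected estimators on pathological samples; it is returned
#' as computed, with a warning, so that downstream coverage computations see
#' the event rather than a censored value.
#'
#' @param sample numeric vector or [ordered_sample] of paired differences
#' @param estimator one of `sq`, `hd`, `bp`, `hdlc`, `sv`, `no`
#' @param probs length-2 vector of target probabilities
#' @return a `loa_pair` with fields `lower`, `upper`, `estimator`, `n`
#' @export
estimate_loa <- function(sample, estimator, probs = c(0.025, 0.975)) {
  est <- match_estimator(estimator)
  s <- as_ordered_sample(sample)
  stopifnot(length(probs) == 2L, probs[1] < probs[2])
  lower <- l_estimate(s, probs[1], est)
  upper <- l_estimate(s, probs[2], est)
  if (lower > upper)
    warning(sprintf("crossed limits of agreement (%s): lower %g > upper %g",
                    est, lower, upper), call. = FALSE)
  new_loa_pair(lower, upper, est, s$n)
}
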