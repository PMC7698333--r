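# Independent oracles, deliberately avoiding the package's weight code paths.

# Harrell-Davis weights by numerical quadrature of the Beta(p(n+1),(1-p)(n+1))
# density over each cell of a partition of [0,1].  Shape parameters below 1
# make the density singular at an endpoint; those cells are integrated after
# the substitution s = (1-x)^b, which removes the singularity exactly.
quad_beta_cell <- function(a, b, lo, hi) {
  if (a < 1 && b >= 1) return(quad_beta_cell(b, a, 1 - hi, 1 - lo))
  if (b < 1) {
    f <- function(s) (1 - s^(1 / b))^(a - 1) / (b * beta(a, b))
    return(stats::integrate(f, (1 - hi)^b, (1 - lo)^b, rel.tol = 1e-12)$value)
  }
  stats::integrate(function(x) stats::dbeta(x, a, b), lo, hi,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}

quad_beta_weights <- function(n, p, breaks) {
  a <- p * (n + 1)
  b <- (1 - p) * (n + 1)
  vapply(seq_len(n), function(i) quad_beta_cell(a, b, breaks[i], breaks[i + 1L]),
         numeric(1))
}

quad_hd_weights <- function(n, p) quad_beta_weights(n, p, (0:n) / n)

quad_hdlc_weights <- function(n, p) {
  interior <- 1 / sqrt(n * (n - 1))
  w <- rep(interior, n)
  w[c(1L, n)] <- 0.5 * (1 - (n - 2) * interior)
  quad_beta_weights(n, p, c(0, cumsum(w)))
}

# Literal term-by-term transcriptions of the two boundary-corrected
# estimators, written as the running sums of their defining expressions.
transcribe_sv <- function(x, p) {
  x <- sort(x); n <- length(x)
  B <- function(i) stats::dbinom(i, n, p)
  total <- (2 * B(0) + B(1)) / 2 * x[1] +
    B(0) / 2 * x[2] -
    B(0) / 2 * x[3] -
    B(n) / 2 * x[n - 2] +
    B(n) / 2 * x[n - 1] +
    (2 * B(n) + B(n - 1)) / 2 * x[n]
  for (i in 2:(n - 1)) total <- total + (B(i) + B(i - 1)) / 2 * x[i]
  total
}

transcribe_no <- function(x, p) {
  x <- sort(x); n <- length(x)
  B <- function(i) stats::dbinom(i, n, p)
  total <- (B(0) * 2 * p + B(1) * p) * x[1] +
    B(0) * (2 - 3 * p) * x[2] -
    B(0) * (1 - p) * x[3] -
    B(n) * p * x[n - 2] +
    B(n) * (3 * p - 1) * x[n - 1] +
    (B(n - 1) * (1 - p) + B(n) * (2 - 2 * p)) * x[n]
  for (i in 1:(n - 2)) total <- total + (B(i) * (1 - p) + B(i + 1) * p) * x[i + 1]
  total
}

estimator_fun <- function(id) {
  switch(id, sq = sq_quantile, hd = hd_quantile, bp = bp_quantile,
         hdlc = hdlc_quantile, sv = sv_quantile, no = no_quantile)
}

NP_ESTIMATORS <- c("sq", "hd", "bp", "hdlc", "sv", "no")
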