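#' Reference distribution with exact CDF, quantile function and sampler
#'
#' A `dist_spec` bundles everything the coverage machinery needs about a
#' distribution of paired differences: a sampler for Monte-Carlo draws, the
#' exact cumulative distribution function used to turn limits of agreement
#' into a coverage probability, and the exact quantile function supplying
#' true 2.5%/97.5% quantiles for RMSE computation.
#'
#' @param name identifier (used in configs and output tables)
#' @param label human-readable label
#' @param params named list of distribution parameters
#' @param sampler function(n) returning n random draws
#' @param cdf vectorised distribution function
#' @param quantile vectorised quantile (inverse CDF) function
#' @return an object of class `dist_spec`
#' @export
dist_spec <- function(name, label, params, sampler, cdf, quantile) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(sampler), is.function(cdf), is.function(quantile))
  structure(list(name = name, label = label, params = params,
                 sampler = sampler, cdf = cdf, quantile = quantile),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<dist_spec> %s (%s)\n", x$label, pars))
  invisible(x)
}

#' The six reference distributions of the simulation study
#'
#' Returns the panel of distributions used to stress-test LoA estimators:
#' standard normal, lognormal (sdlog 1), Beta(2,5), Beta(2,2), chi-squared
#' with 4 degrees of freedom, and exponential with rate 1.  The panel mixes
#' symmetric, skewed, bounded and heavy-tailed shapes so that both tails of
#' the difference distribution are exercised.
#'
#' The lognormal log-mean is configurable: coverage probabilities are
#' invariant to it (all estimators are location-scale equivariant on the log
#' scale of the parameter), but RMSE values scale by `exp(meanlog)`.  The
#' default is 0.
#'
#' @param lognormal_meanlog log-scale mean of the lognormal member (default 0)
#' @return named list of six [dist_spec] objects
#' @export
study_distributions <- function(lognormal_meanlog = 0) {
  ml <- lognormal_meanlog
  specs <- list(
    dist_spec("normal", "Normal(0,1)", list(mean = 0, sd = 1),
              function(n) stats::rnorm(n),
              function(x) stats::pnorm(x),
              function(p) stats::qnorm(p)),
    dist_spec("lognormal", sprintf("Lognormal(%g,1)", ml),
              list(meanlog = ml, sdlog = 1),
              function(n) stats::rlnorm(n, meanlog = ml, sdlog = 1),
              function(x) stats::plnorm(x, meanlog = ml, sdlog = 1),
              function(p) stats::qlnorm(p, meanlog = ml, sdlog = 1)),
    dist_spec("beta_2_5", "Beta(2,5)", list(shape1 = 2, shape2 = 5, ncp = 0),
              function(n) stats::rbeta(n, 2, 5),
              function(x) stats::pbeta(x, 2, 5),
              function(p) stats::qbeta(p, 2, 5)),
    dist_spec("beta_2_2", "Beta(2,2)", list(shape1 = 2, shape2 = 2, ncp = 0),
              function(n) stats::rbeta(n, 2, 2),
              function(x) stats::pbeta(x, 2, 2),
              function(p) stats::qbeta(p, 2, 2)),
    dist_spec("chisq_4", "Chi-squared(4)", list(df = 4),
              function(n) stats::rchisq(n, df = 4),
              function(x) stats::pchisq(x, df = 4),
              function(p) stats::qchisq(p, df = 4)),
    dist_spec("exp_1", "Exponential(1)", list(rate = 1),
              function(n) stats::rexp(n, rate = 1),
              function(x) stats::pexp(x, rate = 1),
              function(p) stats::qexp(p, rate = 1))
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Resolve a distribution name to its specification
#'
#' @param x a `dist_spec` or one of the names accepted in configs:
#'   `normal`, `lognormal`, `beta_2_5`, `beta_2_2`, `chisq_4`, `exp_1`
#'   (case-insensitive)
#' @param lognormal_meanlog passed through to [study_distributions()]
#' @return a [dist_spec]
#' @export
as_dist_spec <- function(x, lognormal_meanlog = 0) {
  if (inherits(x, "dist_spec")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  specs <- study_distributions(lognormal_meanlog)
  key <- tolower(x)
  if (!key %in% names(specs))
    stop(sprintf("unknown distribution '%s'; expected one of: %s",
                 x, paste(names(specs), collapse = ", ")), call. = FALSE)
  specs[[key]]
}

#' Exact quantile of a reference distribution
#'
#' @param spec a [dist_spec] (or distribution name)
#' @param p probability in (0,1)
#' @return the exact inverse-CDF value
#' @export
true_quantile <- function(spec, p) {
  spec <- as_dist_spec(spec)
  stopifnot(all(p > 0 & p < 1))
  spec$quantile(p)
}
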