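#' Paired measurements from two methods
#'
#' Stores the two measurement series of a method-comparison study together
#' with their paired differences (`m1 - m2`) and pairwise means, the two
#' axes of a Bland-Altman plot.  Pairs with any missing entry are dropped
#' with a message.
#'
#' @param m1 numeric vector, method-1 measurements
#' @param m2 numeric vector, method-2 measurements (same length)
#' @return object of class `paired_data` with fields `m1`, `m2`, `diffs`,
#'   `means`, `n`, `n_dropped`
#' @export
paired_data <- function(m1, m2) {
  stopifnot(is.numeric(m1), is.numeric(m2))
  if (length(m1) != length(m2))
    stop("m1 and m2 must have equal length", call. = FALSE)
  keep <- stats::complete.cases(m1, m2)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("dropping %d incomplete pair(s)", n_dropped))
  m1 <- as.numeric(m1[keep]); m2 <- as.numeric(m2[keep])
  if (length(m1) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  structure(list(m1 = m1, m2 = m2, diffs = m1 - m2, means = (m1 + m2) / 2,
                 n = length(m1), n_dropped = n_dropped),
            class = "paired_data")
}

#' @export
print.paired_data <- function(x, ...) {
  cat(sprintf("<paired_data> n = %d pairs (%d dropped); bias %.4g, sd of differences %.4g\n",
              x$n, x$n_dropped, mean(x$diffs), stats::sd(x$diffs)))
  invisible(x)
}

#' Read paired measurements from a delimited text file
#'
#' Thin wrapper around [utils::read.table()] with delimiter and header
#' auto-detection.  Columns may be selected by name or 1-based index;
#' by default the first two numeric columns are used.
#'
#' @param file path to a CSV/TSV file with at least two numeric columns
#' @param columns length-2 vector of column names or indices (default: first
#'   two numeric columns)
#' @param header `TRUE`/`FALSE`, or `NA` to auto-detect
#' @param sep field separator, or `NA` to auto-detect from `,`, tab, `;`
#' @return a [paired_data] object
#' @export
read_paired_data <- function(file, columns = NULL, header = NA, sep = NA) {
  if (!file.exists(file)) stop(sprintf("file not found: %s", file), call. = FALSE)
  first <- readLines(file, n = 1L)
  if (is.na(sep)) {
    seps <- c(",", "\t", ";")
    counts <- vapply(seps, function(s) {
      m <- gregexpr(s, first, fixed = TRUE)[[1L]]
      if (m[1L] == -1L) 0L else length(m)
    }, 1L)
    sep <- if (max(counts) > 0) seps[[which.max(counts)]] else ""
  }
  if (is.na(header)) {
    fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
    header <- anyNA(suppressWarnings(as.numeric(fields)))
  }
  df <- utils::read.table(file, header = header, sep = sep,
                          stringsAsFactors = FALSE)
  if (is.null(columns)) {
    num <- which(vapply(df, is.numeric, TRUE))
    if (length(num) < 2L)
      stop("input needs at least two numeric columns", call. = FALSE)
    columns <- num[1:2]
  }
  paired_data(df[[columns[[1L]]]], df[[columns[[2L]]]])
}

#' Classical (parametric) Bland-Altman limits of agreement
#'
#' `bias +/- 1.96 * sd` of the paired differences, with the sample standard
#' deviation (n-1 denominator).  The multiplier is the conventional fixed
#' 1.96, not a t-quantile.  Valid as a 95% population interval only under
#' normally distributed differences.
#'
#' @param diffs numeric vector of paired differences (or a [paired_data])
#' @return a `loa_pair` with fields `lower`, `upper`, `bias`, `estimator = "ba"`
#' @export
ba_loa <- function(diffs) {
  if (inherits(diffs, "paired_data")) diffs <- diffs$diffs
  stopifnot(is.numeric(diffs))
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2L)
    stop("classical limits of agreement need at least 2 differences", call. = FALSE)
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  new_loa_pair(bias - 1.96 * s, bias + 1.96 * s, "ba", length(diffs), bias = bias)
}

#' Nonparametric limits of agreement
#'
#' Estimates the 2.5% and 97.5% quantiles of the paired differences with the
#' chosen L-statistic estimator; see [estimate_loa()].
#'
#' @param diffs numeric vector of paired differences (or a [paired_data])
#' @param estimator one of `sq`, `hd`, `bp`, `hdlc`, `sv`, `no`
#' @param probs target probabilities (default `c(0.025, 0.975)`)
#' @return a `loa_pair`
#' @export
nonparametric_loa <- function(diffs, estimator, probs = c(0.025, 0.975)) {
  if (inherits(diffs, "paired_data")) diffs <- diffs$diffs
  estimate_loa(diffs, estimator, probs)
}

#' Percentile-bootstrap confidence intervals for the limits of agreement
#'
#' Resamples the differences with replacement, recomputes the LoA pair on
#' each resample, and returns the percentile interval of the lower and upper
#' limit separately.  Resamples on which the estimator fails are redrawn and
#' counted (cannot occur for fixed `n` with the estimators shipped here, but
#' the contract is kept for extensions).
#'
#' @param diffs numeric vector of paired differences (or a [paired_data])
#' @param estimator `ba` or one of the nonparametric estimator ids
#' @param n_boot number of bootstrap resamples (>= 100; default 2000)
#' @param level confidence level in (0,1) (default 0.95)
#' @param seed integer seed; the global RNG state is restored afterwards
#' @param probs LoA quantile levels
#' @return object of class `loa_boot`: the point `loa_pair` plus
#'   `ci_lower` and `ci_upper` (each `c(lo, hi)`), `n_boot`, `level`,
#'   `n_rejected`
#' @export
bootstrap_loa_ci <- function(diffs, estimator, n_boot = 2000, level = 0.95,
                             seed = NULL, probs = c(0.025, 0.975)) {
  if (inherits(diffs, "paired_data")) diffs <- diffs$diffs
  stopifnot(is.numeric(diffs), n_boot >= 100, level > 0, level < 1)
  est <- match_estimator(estimator, allow_ba = TRUE)
  point <- if (est == "ba") ba_loa(diffs) else
    suppressWarnings(estimate_loa(diffs, est, probs))
  n <- length(diffs)

  run <- function() {
    lower <- numeric(n_boot); upper <- numeric(n_boot)
    n_rejected <- 0L
    one <- function() {
      repeat {
        res <- tryCatch({
          d <- diffs[sample.int(n, n, replace = TRUE)]
          if (est == "ba") ba_loa(d) else suppressWarnings(estimate_loa(d, est, probs))
        }, error = function(e) NULL)
        if (!is.null(res)) return(res)
        n_rejected <<- n_rejected + 1L
        if (n_rejected > 10L * n_boot)
          stop("bootstrap: too many failed resamples", call. = FALSE)
      }
    }
    for (b in seq_len(n_boot)) {
      fit <- one()
      lower[b] <- fit$lower; upper[b] <- fit$upper
    }
    alpha <- (1 - level) / 2
    structure(list(point = point,
                   ci_lower = unname(stats::quantile(lower, c(alpha, 1 - alpha))),
                   ci_upper = unname(stats::quantile(upper, c(alpha, 1 - alpha))),
                   n_boot = n_boot, level = level, seed = seed,
                   n_rejected = n_rejected),
              class = "loa_boot")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.loa_boot <- function(x, ...) {
  print(x$point)
  cat(sprintf("  %d%% percentile bootstrap (%d resamples%s):\n",
              round(100 * x$level), x$n_boot,
              if (is.null(x$seed)) "" else sprintf(", seed %s", x$seed)))
  cat(sprintf("    lower limit CI: [%g, %g]\n", x$ci_lower[1], x$ci_lower[2]))
  cat(sprintf("    upper limit CI: [%g, %g]\n", x$ci_upper[1], x$ci_upper[2]))
  if (x$n_rejected > 0) cat(sprintf("    (%d resample(s) rejected)\n", x$n_rejected))
  invisible(x)
}

#' Serialise a LoA result to a JSON-ready list
#'
#' @param x a `loa_pair` or `loa_boot`
#' @return named list with fields `estimator`, `n`, `lower`, `upper`, and
#'   when available `bias`, `ci_lower`, `ci_upper`, `n_boot`, `level`, `seed`
#' @export
loa_report <- function(x) {
  if (inherits(x, "loa_boot")) {
    out <- loa_report(x$point)
    out$ci_lower <- x$ci_lower
    out$ci_upper <- x$ci_upper
    out$n_boot <- x$n_boot
    out$level <- x$level
    if (!is.null(x$seed)) out$seed <- x$seed
    return(out)
  }
  stopifnot(inherits(x, "loa_pair"))
  out <- list(estimator = x$estimator, n = x$n,
              lower = x$lower, upper = x$upper)
  if (!is.null(x$bias)) out$bias <- x$bias
  out
}
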