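#' Coverage probability of a pair of limits of agreement
#'
#' The probability mass the reference distribution places between the
#' estimated limits, `F(upper) - F(lower)`, clamped to `[0, 1]`.  A crossed
#' pair (lower > upper) would give a negative difference; it is clamped to 0
#' since a negative value has no probability interpretation.
#'
#' @param spec a [dist_spec] or distribution name
#' @param loa a `loa_pair`, or a length-2 numeric `c(lower, upper)`
#' @return coverage probability in `[0, 1]`
#' @export
coverage <- function(spec, loa) {
  spec <- as_dist_spec(spec)
  if (inherits(loa, "loa_pair")) loa <- c(loa$lower, loa$upper)
  stopifnot(is.numeric(loa), length(loa) == 2L)
  clamp01(spec$cdf(loa[2L]) - spec$cdf(loa[1L]))
}

#' Simulate one scenario cell of the coverage study
#'
#' Draws `replicates` independent samples of size `n` from the reference
#' distribution, computes the limits of agreement on each with the chosen
#' estimator, and records the lower/upper estimates and the coverage
#' probability `F(upper) - F(lower)` of every replicate.
#'
#' The estimator weights depend only on `(n, p)`, so they are built once per
#' cell and applied to all replicates.  Each cell seeds its own RNG
#' substream derived from `(seed, distribution, n, estimator)`, making
#' results independent of the order in which cells are run; the global RNG
#' state is left untouched.
#'
#' @param spec a [dist_spec] or distribution name
#' @param n sample size per replicate
#' @param estimator `ba` or one of `sq`, `hd`, `bp`, `hdlc`, `sv`, `no`
#' @param replicates number of Monte-Carlo replicates
#' @param seed integer study seed
#' @param probs LoA quantile levels (default `c(0.025, 0.975)`)
#' @return object of class `scenario_result` with fields `distribution`,
#'   `n`, `estimator`, `replicates`, `lower`, `upper`, `coverage`,
#'   `n_crossed`, `n_failed`, `true_lower`, `true_upper`
#' @export
run_scenario <- function(spec, n, estimator, replicates, seed,
                         probs = c(0.025, 0.975)) {
  spec <- as_dist_spec(spec)
  est <- match_estimator(estimator, allow_ba = TRUE)
  stopifnot(replicates >= 1, n >= 2)
  n_min <- min_sample_size(est, probs)
  if (n < n_min)
    stop(sprintf("scenario invalid: estimator '%s' needs n >= %d (got %d)",
                 est, n_min, n), call. = FALSE)
  n <- as.integer(n); replicates <- as.integer(replicates)

  res <- with_seed(cell_seed(seed, spec$name, n, est), {
    x <- matrix(spec$sampler(n * replicates), nrow = n)
    if (est == "ba") {
      mu <- colMeans(x)
      s <- sqrt(colSums((x - rep(mu, each = n))^2) / (n - 1))
      list(lower = mu - 1.96 * s, upper = mu + 1.96 * s)
    } else {
      xs <- apply(x, 2L, sort)
      w_lo <- estimator_weights(est, n, probs[1L])
      w_up <- estimator_weights(est, n, probs[2L])
      list(lower = drop(crossprod(xs, w_lo)), upper = drop(crossprod(xs, w_up)))
    }
  })
  cov <- clamp01(spec$cdf(res$upper) - spec$cdf(res$lower))
  structure(list(distribution = spec$name, n = n, estimator = est,
                 replicates = replicates, probs = probs, seed = seed,
                 lower = res$lower, upper = res$upper, coverage = cov,
                 n_crossed = sum(res$lower > res$upper), n_failed = 0L,
                 true_lower = spec$quantile(probs[1L]),
                 true_upper = spec$quantile(probs[2L])),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s, n = %d, %s, %d replicates\n",
              x$distribution, x$n, toupper(x$estimator), x$replicates))
  s <- summarize_coverage(x)
  cat(sprintf("  coverage: mean %.4f, median %.4f, q25 %.4f, q05 %.4f\n",
              s$mean, s$median, s$q25, s$q05))
  if (x$n_crossed > 0) cat(sprintf("  crossed LoA in %d replicate(s)\n", x$n_crossed))
  invisible(x)
}

#' Summary statistics of a coverage distribution
#'
#' Quantiles use linear interpolation of order statistics
#' ([stats::quantile()] type 7).
#'
#' @param result a `scenario_result`, or a numeric vector of coverages
#' @return list with fields `q05`, `q25`, `median`, `mean`, `q75`
#' @export
summarize_coverage <- function(result) {
  cov <- if (inherits(result, "scenario_result")) result$coverage else result
  stopifnot(is.numeric(cov))
  if (length(cov) < 2L)
    stop("need at least 2 coverage values to summarise", call. = FALSE)
  q <- unname(stats::quantile(cov, c(0.05, 0.25, 0.5, 0.75), type = 7))
  list(q05 = q[1L], q25 = q[2L], median = q[3L], mean = mean(cov), q75 = q[4L])
}

#' Root-mean-squared error of the tail-quantile estimates
#'
#' RMSE of the per-replicate lower (2.5%) and upper (97.5%) limit estimates
#' against the exact distribution quantiles.  For the classical estimator
#' the "quantile estimate" is the corresponding parametric limit
#' `mean -/+ 1.96 sd`.
#'
#' @param result a `scenario_result`
#' @param spec optional [dist_spec]; defaults to the distribution recorded
#'   in `result`
#' @return list with fields `rmse_lower`, `rmse_upper`
#' @export
rmse <- function(result, spec = NULL) {
  stopifnot(inherits(result, "scenario_result"))
  if (is.null(spec)) {
    truth <- c(result$true_lower, result$true_upper)
  } else {
    spec <- as_dist_spec(spec)
    truth <- spec$quantile(result$probs)
  }
  list(rmse_lower = sqrt(mean((result$lower - truth[1L])^2)),
       rmse_upper = sqrt(mean((result$upper - truth[2L])^2)))
}

#' Mean absolute error of the tail-quantile estimates
#'
#' Companion to [rmse()]: the mean of `|estimate - true quantile|` per tail.
#' Tail-quantile estimates have markedly skewed error distributions, so the
#' two summaries differ (for roughly normal errors MAE is about 0.8 x RMSE);
#' MAE is the less outlier-sensitive of the two and both are reported by the
#' study engine.
#'
#' @inheritParams rmse
#' @return list with fields `mae_lower`, `mae_upper`
#' @export
mae <- function(result, spec = NULL) {
  stopifnot(inherits(result, "scenario_result"))
  if (is.null(spec)) {
    truth <- c(result$true_lower, result$true_upper)
  } else {
    spec <- as_dist_spec(spec)
    truth <- spec$quantile(result$probs)
  }
  list(mae_lower = mean(abs(result$lower - truth[1L])),
       mae_upper = mean(abs(result$upper - truth[2L])))
}

#' Worst-case 5% coverage quantile across distributions
#'
#' For a fixed (estimator, n), the minimum over the study distributions of
#' the 5% quantile of the coverage distribution — the headline robustness
#' figure of the study.  For the classical estimator the benchmark
#' convention is different: its value is the 5% quantile under the standard
#' normal distribution only.
#'
#' @param summaries list of coverage summaries (as from
#'   [summarize_coverage()]), one per distribution, named by distribution
#' @param estimator estimator id; `ba` triggers the normal-only convention
#' @return the minimum (or benchmark) q05
#' @export
min_q05_across_distributions <- function(summaries, estimator = "sq") {
  est <- match_estimator(estimator, allow_ba = TRUE)
  q05 <- vapply(summaries, function(s) s$q05, numeric(1))
  if (est == "ba") {
    if (!"normal" %in% names(summaries))
      stop("benchmark convention for 'ba' needs the normal distribution", call. = FALSE)
    return(unname(q05[["normal"]]))
  }
  min(q05)
}

# ---- study orchestration ---------------------------------------------------

#' Configuration of a full coverage study
#'
#' Defaults encode the reference design: all six distributions, the sample
#' size grid 50(50)200, 250(250)1000, all seven estimators (classical plus
#' six nonparametric), and 5000 replicates per cell.
#'
#' @param distributions character vector of distribution names
#' @param sample_sizes integer vector of per-replicate sample sizes
#' @param estimators character vector of estimator ids (may include `ba`)
#' @param replicates Monte-Carlo replicates per cell
#' @param seed integer study seed
#' @param lognormal_meanlog log-mean of the lognormal member
#' @return validated `study_config` object
#' @export
study_config <- function(distributions = names(study_distributions()),
                         sample_sizes = c(50, 100, 150, 200, 250, 500, 750, 1000),
                         estimators = c("ba", ESTIMATOR_IDS),
                         replicates = 5000,
                         seed = 1,
                         lognormal_meanlog = 0) {
  problems <- character()
  known <- names(study_distributions())
  bad <- setdiff(tolower(distributions), known)
  if (length(bad))
    problems <- c(problems, sprintf("unknown distribution(s): %s", paste(bad, collapse = ", ")))
  bad <- setdiff(tolower(estimators), c("ba", ESTIMATOR_IDS))
  if (length(bad))
    problems <- c(problems, sprintf("unknown estimator(s): %s", paste(bad, collapse = ", ")))
  if (!length(sample_sizes) || any(sample_sizes < 2) || any(sample_sizes != round(sample_sizes)))
    problems <- c(problems, "sample_sizes must be integers >= 2")
  if (length(replicates) != 1L || replicates < 1)
    problems <- c(problems, "replicates must be a positive integer")
  if (length(seed) != 1L || !is.finite(seed))
    problems <- c(problems, "seed must be a finite number")
  if (length(problems))
    stop(paste(c("invalid study configuration:", paste(" -", problems)),
               collapse = "\n"), call. = FALSE)
  structure(list(distributions = tolower(distributions),
                 sample_sizes = as.integer(sample_sizes),
                 estimators = tolower(estimators),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 lognormal_meanlog = as.numeric(lognormal_meanlog)),
            class = "study_config")
}

#' Read a study configuration from a YAML or JSON file
#'
#' Recognised fields are the arguments of [study_config()]; missing fields
#' take the defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return a `study_config`
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$estimators)) {
    # YAML 1.1 parses a bare `no` as boolean false; map it back
    est <- unlist(raw$estimators)
    est[tolower(as.character(est)) == "false"] <- "no"
    raw$estimators <- as.character(est)
  }
  known <- names(formals(study_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    warning(sprintf("ignoring unknown config field(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  do.call(study_config, raw[intersect(names(raw), known)])
}

#' Run the full Monte-Carlo coverage study
#'
#' Executes every (distribution, sample size, estimator) cell of the
#' configuration, skipping cells where the estimator is undefined at the
#' requested sample size (with a message).  Produces per-cell coverage
#' summaries and RMSEs, the worst-case q05 table, wide RMSE tables for both
#' tails, and boxplot statistics per cell.
#'
#' @param config a `study_config` (or a path to a config file)
#' @param out_dir optional directory; when given, results are written as
#'   CSVs plus a JSON run manifest via [write_study()]
#' @param quiet suppress progress messages
#' @return object of class `loa_study`: list with `config`, `cells`
#'   (data.frame, one row per cell), `table_q05`, `table_rmse_lower`,
#'   `table_rmse_upper`, `boxplot_data`, `skipped`
#' @export
run_study <- function(config = study_config(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  specs <- study_distributions(config$lognormal_meanlog)[config$distributions]

  cells <- list(); box <- list(); skipped <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  for (dist in config$distributions) {
    for (n in config$sample_sizes) {
      for (est in config$estimators) {
        n_min <- min_sample_size(est)
        if (n < n_min) {
          say("skip %s/n=%d/%s: needs n >= %d", dist, n, est, n_min)
          skipped[[length(skipped) + 1L]] <- data.frame(
            distribution = dist, n = n, estimator = est,
            reason = sprintf("needs n >= %d", n_min))
          next
        }
        res <- run_scenario(specs[[dist]], n, est, config$replicates, config$seed)
        s <- summarize_coverage(res)
        e <- rmse(res)
        a <- mae(res)
        if (res$n_crossed > 0)
          say("crossed LoA in %d replicate(s): %s/n=%d/%s",
              res$n_crossed, dist, n, est)
        cells[[length(cells) + 1L]] <- data.frame(
          distribution = dist, n = n, estimator = est,
          replicates = config$replicates,
          q05 = s$q05, q25 = s$q25, median = s$median,
          mean = s$mean, q75 = s$q75,
          rmse_lower = e$rmse_lower, rmse_upper = e$rmse_upper,
          mae_lower = a$mae_lower, mae_upper = a$mae_upper,
          n_crossed = res$n_crossed)
        bs <- grDevices::boxplot.stats(res$coverage)
        box[[length(box) + 1L]] <- data.frame(
          distribution = dist, n = n, estimator = est,
          whisker_low = bs$stats[1L], q25 = bs$stats[2L],
          median = bs$stats[3L], q75 = bs$stats[4L],
          whisker_high = bs$stats[5L], mean = s$mean,
          n_outliers = length(bs$out))
      }
    }
  }
  if (!length(cells)) stop("study produced no valid cells", call. = FALSE)
  cells <- do.call(rbind, cells)
  study <- structure(list(
    config = config,
    cells = cells,
    table_q05 = q05_table(cells, config),
    table_rmse_lower = rmse_table(cells, "rmse_lower"),
    table_rmse_upper = rmse_table(cells, "rmse_upper"),
    boxplot_data = do.call(rbind, box),
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL
  ), class = "loa_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

# worst-case q05 per (estimator, n); benchmark convention for "ba"
q05_table <- function(cells, config) {
  ests <- intersect(config$estimators, unique(cells$estimator))
  ns <- sort(unique(cells$n))
  rows <- lapply(ests, function(est) {
    vals <- vapply(ns, function(n) {
      sub <- cells[cells$estimator == est & cells$n == n, ]
      if (!nrow(sub)) return(NA_real_)
      if (est == "ba") {
        if (!"normal" %in% sub$distribution) return(NA_real_)
        sub$q05[sub$distribution == "normal"]
      } else min(sub$q05)
    }, numeric(1))
    stats::setNames(data.frame(estimator = est, t(vals)), c("estimator", paste0("n", ns)))
  })
  do.call(rbind, rows)
}

rmse_table <- function(cells, column) {
  dists <- unique(cells$distribution)
  key <- cells[order(cells$n, match(cells$estimator, unique(cells$estimator))), ]
  combos <- unique(key[, c("n", "estimator")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    n <- combos$n[i]; est <- combos$estimator[i]
    vals <- vapply(dists, function(d) {
      v <- cells[cells$n == n & cells$estimator == est & cells$distribution == d, column]
      if (length(v)) v else NA_real_
    }, numeric(1))
    stats::setNames(data.frame(n = n, estimator = est, t(vals)),
                    c("n", "estimator", dists))
  })
  do.call(rbind, rows)
}

#' @export
print.loa_study <- function(x, ...) {
  cat(sprintf("<loa_study> %d cells (%d distributions x %d sample sizes x %d estimators), %d replicates each\n",
              nrow(x$cells), length(x$config$distributions),
              length(x$config$sample_sizes), length(x$config$estimators),
              x$config$replicates))
  cat("Worst-case 5% coverage quantiles (benchmark convention for 'ba'):\n")
  print(x$table_q05, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Boxplots of the coverage distributions
#'
#' Draws one box per distribution from the stored boxplot statistics, for a
#' chosen estimator and sample size, with the nominal 0.95 level marked.
#'
#' @param x a `loa_study`
#' @param estimator estimator id to display
#' @param n sample size to display (default: smallest in the study)
#' @param ... passed to [graphics::bxp()]
#' @return invisibly, the `bxp` statistics matrix
#' @export
plot.loa_study <- function(x, estimator = x$config$estimators[1L],
                           n = min(x$config$sample_sizes), ...) {
  est <- match_estimator(estimator, allow_ba = TRUE)
  sub <- x$boxplot_data[x$boxplot_data$estimator == est & x$boxplot_data$n == n, ]
  if (!nrow(sub)) stop("no cells for this estimator/sample size", call. = FALSE)
  stats_mat <- t(as.matrix(sub[, c("whisker_low", "q25", "median", "q75", "whisker_high")]))
  z <- list(stats = stats_mat, n = rep(x$config$replicates, nrow(sub)),
            conf = NULL, out = numeric(), group = numeric(), names = sub$distribution)
  graphics::bxp(z, main = sprintf("Coverage of %s limits, n = %d", toupper(est), n),
                ylab = "coverage probability", ...)
  graphics::abline(h = 0.95, lty = 2)
  invisible(stats_mat)
}

#' Write study results and a run manifest to a directory
#'
#' Emits `cells.csv`, `table_q05.csv`, `table_rmse_lower.csv`,
#' `table_rmse_upper.csv`, `boxplot_data.csv` and `manifest.json`.  The
#' manifest records the configuration, seed, package version and file list;
#' re-running [run_study()] with the manifest's configuration reproduces the
#' CSVs byte-identically.
#'
#' @param study a `loa_study`
#' @param out_dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "loa_study"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(cells = study$cells, table_q05 = study$table_q05,
                 table_rmse_lower = study$table_rmse_lower,
                 table_rmse_upper = study$table_rmse_upper,
                 boxplot_data = study$boxplot_data)
  paths <- character()
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], path, row.names = FALSE)
    paths <- c(paths, path)
  }
  manifest <- list(
    config = unclass(study$config),
    package = "nploa",
    version = as.character(utils::packageVersion("nploa")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = basename(paths))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, mpath))
}
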