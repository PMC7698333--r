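test_that("sample-quantile estimator interpolates the flanking order statistics", {
  expect_identical(sq_quantile(c(10, 20, 30), 0.5), 20)
  # rank arithmetic by hand: r = floor(p(n+1)), alpha = p(n+1) - r
  expect_equal(sq_quantile(1:100, 0.975), 98.475)
  expect_equal(sq_quantile(1:100, 0.025), 2.525)
  # input need not be pre-sorted
  expect_equal(sq_quantile(sample(1:100), 0.975), 98.475)
})

test_that("sample-quantile estimator errors when the flanking ranks do not exist", {
  expect_error(sq_quantile(rnorm(30), 0.025), "n >= 39")
  expect_error(sq_quantile(1:38, 0.025), "n >= 39")
  expect_silent(sq_quantile(1:39, 0.025))
  expect_identical(min_sample_size("sq"), 39L)
})

test_that("Harrell-Davis weights match independent beta-density quadrature", {
  for (case in list(c(50, 0.975), c(50, 0.025), c(20, 0.5), c(7, 0.1))) {
    n <- case[1]; p <- case[2]
    expect_lt(max(abs(hd_weights(n, p) - quad_hd_weights(n, p))), 1e-8)
  }
  expect_equal(hd_weights(2, 0.5), c(0.5, 0.5))
  expect_equal(hd_quantile(c(1, 3), 0.5), 2)
  expect_equal(hd_quantile(c(1, 2, 3, 4), 0.5), 2.5)
  expect_equal(hd_quantile(1:50, 0.025), sum(quad_hd_weights(50, 0.025) * (1:50)),
               tolerance = 1e-10)
})

test_that("Bernstein-polynomial weights are the binomial pmf on n-1 trials", {
  expect_equal(bp_quantile(c(1, 3), 0.5), 2)
  # B(i; 2, 0.5) = (0.25, 0.5, 0.25) by hand
  expect_equal(bp_quantile(c(1, 2, 3), 0.5), 2)
  expect_equal(estimator_weights("bp", 3, 0.5), c(0.25, 0.5, 0.25))
})

test_that("level-crossing weights down-weight the boundary and sum to one", {
  lc <- lc_weights(4)
  expect_equal(lc$w[c(1, 4)], rep(0.5 * (1 - 2 / sqrt(12)), 2))
  expect_equal(lc$w[2:3], rep(1 / sqrt(12), 2))
  for (n in c(2, 3, 10, 57, 1000)) {
    lc <- lc_weights(n)
    expect_equal(sum(lc$w), 1, tolerance = 1e-12)
    expect_true(all(diff(lc$q) > 0))
    expect_equal(lc$q[n], 1, tolerance = 1e-12)
    expect_equal(lc$w[1], lc$w[n])
    if (n > 3) expect_equal(length(unique(round(lc$w[2:(n - 1)], 15))), 1L)
  }
  expect_error(lc_weights(1), "n >= 2")
})

test_that("level-crossing Harrell-Davis estimator matches quadrature at the shifted knots", {
  expect_equal(hdlc_quantile(c(-2, -1, 1, 2), 0.5), 0)
  for (case in list(c(20, 0.975), c(20, 0.025), c(12, 0.5))) {
    n <- case[1]; p <- case[2]
    expect_lt(max(abs(estimator_weights("hdlc", n, p) - quad_hdlc_weights(n, p))), 1e-8)
  }
})

test_that("boundary-corrected estimators equal their term-by-term transcriptions", {
  set.seed(42)
  for (x in list(1:10, rnorm(25), rexp(50))) {
    for (p in c(0.025, 0.3, 0.975)) {
      expect_equal(sv_quantile(x, p), transcribe_sv(x, p), tolerance = 1e-12)
      expect_equal(no_quantile(x, p), transcribe_no(x, p), tolerance = 1e-12)
    }
  }
  expect_equal(sv_quantile(1:5, 0.5), 3)
  expect_equal(no_quantile(1:5, 0.5), 3)
  expect_error(sv_quantile(1:4, 0.5), "n >= 5")
  expect_error(no_quantile(1:4, 0.5), "n >= 5")
})

test_that("every weight vector sums to one and stays finite on the (n, p) grid", {
  for (n in c(5L, 10L, 40L, 50L, 100L, 1000L)) {
    for (p in c(0.01, 0.025, 0.5, 0.975, 0.99)) {
      for (est in NP_ESTIMATORS) {
        if (n < min_sample_size(est, p)) next
        w <- estimator_weights(est, n, p)
        expect_length(w, n)
        expect_true(all(is.finite(w)), label = sprintf("%s n=%d p=%g finite", est, n, p))
        expect_lt(abs(sum(w) - 1), 1e-10, label = sprintf("%s n=%d p=%g sum", est, n, p))
      }
    }
  }
})

test_that("estimators are location-scale equivariant and symmetric at the median", {
  set.seed(7)
  x <- rnorm(60)
  a <- 2.5; b <- -3
  for (est in NP_ESTIMATORS) {
    f <- estimator_fun(est)
    for (p in c(0.025, 0.5, 0.975)) {
      expect_equal(f(a * x + b, p), a * f(x, p) + b, tolerance = 1e-9,
                   label = sprintf("%s equivariance p=%g", est, p))
    }
    # symmetric sample about 1.5
    s <- 1.5 + c(-2, -1, -0.2, 0, 0.2, 1, 2)
    expect_equal(f(s, 0.5), 1.5, tolerance = 1e-9,
                 label = sprintf("%s symmetry", est))
  }
})

test_that("tail estimates become more accurate as the sample grows", {
  set.seed(2024)
  reps <- 500
  truth <- 0.975  # Uniform(0,1) quantile
  for (est in NP_ESTIMATORS) {
    maes <- vapply(c(50, 200, 1000), function(n) {
      w <- estimator_weights(est, n, 0.975)
      errs <- vapply(seq_len(reps), function(r) {
        sum(w * sort(runif(n))) - truth
      }, numeric(1))
      mean(abs(errs))
    }, numeric(1))
    expect_true(all(diff(maes) < 0), label = sprintf("%s MAE decreasing: %s",
                                                     est, paste(signif(maes, 3), collapse = " ")))
  }
})

test_that("estimate_loa pairs the 2.5% and 97.5% estimates", {
  pair <- estimate_loa(1:100, "sq")
  expect_s3_class(pair, "loa_pair")
  expect_equal(pair$lower, 2.525)
  expect_equal(pair$upper, 98.475)

  const <- estimate_loa(rep(0, 50), "sq")
  expect_identical(c(const$lower, const$upper), c(0, 0))

  hd <- estimate_loa(1:100, "hd")
  expect_equal(hd$lower, sum(quad_hd_weights(100, 0.025) * (1:100)), tolerance = 1e-8)
  expect_equal(hd$upper, sum(quad_hd_weights(100, 0.975) * (1:100)), tolerance = 1e-8)
})
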