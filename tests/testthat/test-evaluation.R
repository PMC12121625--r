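test_that("error metrics match hand computation and degenerate rules", {
  m <- error_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$mae, 0); expect_equal(m$rmse, 0); expect_equal(m$r2, 1)

  m2 <- error_metrics(c(0, 2), c(0, 0))
  expect_equal(m2$mae, 1)
  expect_equal(m2$rmse, sqrt(2))

  expect_true(is.na(error_metrics(c(2, 2, 2), c(1, 2, 3))$r2))
  expect_true(is.na(error_metrics(3, 5)$r2))
  expect_error(error_metrics(1:3, 1:2), "equal nonzero length")
})

test_that("MAE never exceeds RMSE, with equality only for equal absolute errors", {
  set.seed(6)
  for (i in 1:30) {
    p <- rnorm(10); r <- rnorm(10)
    m <- error_metrics(p, r)
    expect_lte(m$mae, m$rmse + 1e-12)
  }
  eq <- error_metrics(c(1, -1, 1) + 5, c(5, 5, 5))
  expect_equal(eq$mae, eq$rmse)
})

test_that("permutation test separates signal from chance pairing", {
  set.seed(9)
  ref <- rnorm(20, sd = 2)
  pred <- ref + rnorm(20, sd = 0.2)
  pt <- permutation_test(pred, ref, n_perm = 2000, seed = 4)
  expect_lt(pt$mae_percentile, 0.01)   # observed MAE below >99% of permuted
  expect_lt(pt$rmse_percentile, 0.01)
  expect_error(permutation_test(1:2, 1:2), "at least 3")
  expect_error(permutation_test(pred, ref, n_perm = 0), "n_perm")
})

test_that("permutation percentile is roughly uniform under the null", {
  set.seed(10)
  pcts <- vapply(1:100, function(i) {
    permutation_test(rnorm(10), rnorm(10), n_perm = 200, seed = i)$mae_percentile
  }, numeric(1))
  # null calibration: mean percentile near 0.5, spread over the unit interval
  expect_equal(mean(pcts), 0.5, tolerance = 0.12)
  expect_gt(sum(pcts < 0.25), 10)
  expect_gt(sum(pcts > 0.75), 10)
})

test_that("replicate tables validate their structure", {
  df <- data.frame(transformation = rep(c("a", "b"), each = 3),
                   replicate = rep(1:3, 2), value = rnorm(6),
                   reference = rep(c(0, 1), each = 3))
  tab <- replicate_table(df)
  expect_named(tab$values, c("a", "b"))
  expect_equal(unname(tab$reference), c(0, 1))
  df$reference[1] <- 99
  expect_error(replicate_table(df), "single finite reference")
  expect_error(replicate_table(data.frame(x = 1)), "columns")
})

test_that("batch resampling spread shrinks with batch size and degenerates at the extreme", {
  tab <- make_replicate_table(n_transform = 8, n_rep = 10, noise = 1, seed = 3)
  iqr <- vapply(c(1, 3, 6), function(k) {
    IQR(batch_resample(tab, k, n_samples = 1500, seed = 5)$mae)
  }, numeric(1))
  expect_true(all(diff(iqr) < 0))

  # full batch: a single deterministic combination, zero spread
  full <- batch_resample(tab, 10, n_samples = 1500, seed = 5)
  expect_equal(length(full$mae), 1L)
  means <- vapply(tab$values, mean, numeric(1))
  expect_equal(full$mae, error_metrics(means, tab$reference)$mae)
  expect_identical(batch_resample(tab, 10, seed = 1)$mae,
                   batch_resample(tab, 10, seed = 2)$mae)

  # every sample respects MAE <= RMSE and R2 <= 1
  d <- batch_resample(tab, 2, n_samples = 500, seed = 8)
  expect_true(all(d$mae <= d$rmse + 1e-12))
  expect_true(all(d$r2 <= 1 + 1e-12, na.rm = TRUE))
  expect_error(batch_resample(tab, 11), "batch_size")
})

test_that("truncation analysis reproduces the full estimate and exposes transient bias", {
  sched <- trapezoid_schedule(c(0, 0.5, 1))
  make_rep <- function(seed, kind = "iid_gaussian", ...) {
    lapply(1:3, function(i) {
      s <- make_sampler(generator_spec(kind, mean = i, seed = seed * 10 + i, ...))
      gradient_series(s$extend(2), 0.001, lambda_value = sched$lambdas[i])
    })
  }
  reps <- lapply(1:3, make_rep)
  out <- truncation_analysis(reps, sched, times = c(1, 2, 3))
  expect_equal(out$used_ns, c(1, 2, 2))  # clamped to the available data
  # the final truncation point equals the untruncated estimate
  full_dg <- mean(vapply(reps, function(rep) {
    means <- vapply(rep, function(s) {
      eq <- detect_equilibration(s); mean(subsample(s, eq)$values)
    }, numeric(1))
    ti_integrate(sched, means)$delta_g
  }, numeric(1)))
  expect_equal(out$dg_mean[3], full_dg, tolerance = 1e-10)
  expect_equal(out$dg_mean[2], out$dg_mean[3], tolerance = 1e-10)

  # a 1 ns transient biases early truncation more than late truncation
  reps_tr <- lapply(1:4, function(r) {
    lapply(1:3, function(i) {
      s <- make_sampler(generator_spec("transient", mean = i,
                                      transient_height = 10,
                                      transient_length = 1,
                                      seed = 100 + r * 10 + i))
      gradient_series(s$extend(5), 0.001, lambda_value = sched$lambdas[i])
    })
  })
  out_tr <- truncation_analysis(reps_tr, sched, times = c(0.5, 5))
  truth <- ti_integrate(sched, c(1, 2, 3))$delta_g
  expect_gt(abs(out_tr$dg_mean[1] - truth), abs(out_tr$dg_mean[2] - truth))
  expect_error(truncation_analysis(reps, sched, times = 0.001),
               "truncation")
})

test_that("savings accounting is the complement of the budget fraction", {
  expect_equal(savings(120, 120), 0)
  expect_equal(savings(18, 120), 0.85)
  expect_equal(savings(30, 60), 0.5)
  expect_equal(savings(150, 120), -0.25)  # over budget
  expect_error(savings(10, 0), "baseline")
})
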