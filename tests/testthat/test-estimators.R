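# Published lambda schedules for the 9- and 12-window protocols.
nodes9 <- c(0.01592, 0.08198, 0.19331, 0.33787, 0.5,
            0.66213, 0.80669, 0.91802, 0.98408)
nodes12 <- c(0.00922, 0.04794, 0.11505, 0.20634, 0.31608, 0.43738,
             0.56262, 0.68392, 0.79366, 0.88495, 0.95206, 0.99078)

test_that("Gauss-Legendre schedules reproduce the published lambda nodes", {
  expect_equal(round(gauss_legendre_schedule(9)$lambdas, 5), nodes9)
  expect_equal(round(gauss_legendre_schedule(12)$lambdas, 5), nodes12)
  expect_error(gauss_legendre_schedule(0), "positive integer")
})

test_that("Gauss-Legendre schedules are symmetric with unit weight sum", {
  for (n in c(2, 5, 9, 12)) {
    sch <- gauss_legendre_schedule(n)
    expect_equal(sch$lambdas + rev(sch$lambdas), rep(1, n), tolerance = 1e-12)
    expect_equal(sum(sch$weights), 1, tolerance = 1e-12)
    expect_true(all(sch$weights > 0))
  }
  sch2 <- gauss_legendre_schedule(2)
  expect_equal(sch2$lambdas, 0.5 + c(-1, 1) / (2 * sqrt(3)), tolerance = 1e-12)
  expect_equal(sch2$weights, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("n-point Gauss-Legendre is exact to degree 2n - 1 against adaptive integration", {
  for (n in c(3, 9, 12)) {
    sch <- gauss_legendre_schedule(n)
    for (deg in c(0, 1, n, 2 * n - 1)) {
      truth <- stats::integrate(function(x) x^deg, 0, 1,
                                rel.tol = 1e-12)$value
      expect_equal(sum(sch$weights * sch$lambdas^deg), truth,
                   tolerance = 1e-10, info = sprintf("n=%d deg=%d", n, deg))
    }
  }
  # degree 2n exceeds the exactness guarantee
  sch <- gauss_legendre_schedule(3)
  expect_gt(abs(sum(sch$weights * sch$lambdas^6) - 1 / 7), 1e-8)
})

test_that("trapezoid schedules integrate linear means exactly", {
  # the published 7-node restraint-addition schedule
  sch <- trapezoid_schedule(c(0.0, 0.05, 0.1, 0.2, 0.3, 0.5, 1.0))
  expect_false(sch$truncated)
  expect_equal(ti_integrate(sch, 2 * sch$lambdas)$delta_g, 1.0,
               tolerance = 1e-12)
  expect_equal(ti_integrate(sch, sch$lambdas)$delta_g, 0.5,
               tolerance = 1e-12)
  # two endpoints, constant mean
  expect_equal(ti_integrate(trapezoid_schedule(c(0, 1)), c(3, 3))$delta_g, 3)
  expect_error(trapezoid_schedule(c(0.5, 0.2)), "strictly increasing")
  expect_error(trapezoid_schedule(c(0.2, 0.2)), "strictly increasing")
})

test_that("the nine equal windows are flagged as a truncated-domain schedule", {
  sch <- trapezoid_schedule(seq(0.1, 0.9, by = 0.1))
  expect_true(sch$truncated)
  expect_equal(sum(sch$weights), 0.8, tolerance = 1e-12)
})

test_that("bootstrap mean recovers central-limit scaling", {
  expect_equal(bootstrap_mean(rep(5, 100), n_boot = 200, seed = 1),
               list(mean = 5, std_err = 0))
  s <- make_sampler(generator_spec("iid_gaussian", seed = 14))
  x <- s$extend(10)  # N = 10000, sigma = 1
  bm <- bootstrap_mean(x, n_boot = 1000, seed = 2)
  expect_equal(bm$mean, mean(x))
  expect_equal(bm$std_err, 1 / sqrt(10000), tolerance = 0.2)
  # two-point series: exhaustive resamples {0,0},{0,2},{2,0},{2,2} -> SD sqrt(1/2)
  bm2 <- bootstrap_mean(c(0, 2), n_boot = 20000, seed = 3)
  expect_equal(bm2$mean, 1)
  expect_equal(bm2$std_err, sqrt(0.5), tolerance = 0.05)
  expect_error(bootstrap_mean(1), "at least 2")
  expect_error(bootstrap_mean(c(1, 2), n_boot = 10), "n_boot")
})

test_that("integration is linear in the window means and propagates errors", {
  sch <- gauss_legendre_schedule(9)
  m1 <- rnorm(9); m2 <- rnorm(9)
  r1 <- ti_integrate(sch, m1)$delta_g
  r2 <- ti_integrate(sch, m2)$delta_g
  expect_equal(ti_integrate(sch, 2 * m1 + 3 * m2)$delta_g, 2 * r1 + 3 * r2,
               tolerance = 1e-12)
  # cubic means: 9-point rule is exact for degree 3
  expect_equal(ti_integrate(sch, sch$lambdas^3)$delta_g, 0.25,
               tolerance = 1e-12)
  errs <- runif(9)
  expect_equal(ti_integrate(sch, m1, errs)$std_err,
               sqrt(sum(sch$weights^2 * errs^2)), tolerance = 1e-12)
  expect_error(ti_integrate(sch, m1[1:3]), "length")
})

test_that("relative binding cycles subtract the water leg from the protein leg", {
  expect_equal(rbfe_assemble(3.87, 4.91)$ddg, -1.04)
  expect_equal(rbfe_assemble(-6.61, -5.01)$ddg, -1.60)
  expect_equal(rbfe_assemble(2.5, 2.5)$ddg, 0)
  expect_error(rbfe_assemble(Inf, 0), "finite")
})

test_that("absolute binding cycles follow the published component tables", {
  expect_equal(abfe_assemble(17.32, 2.02, 31.02, -7.51)$dg_bind, -8.21,
               tolerance = 1e-10)
  expect_equal(abfe_assemble(17.10, 1.68, 31.42, -7.50)$dg_bind, -8.50,
               tolerance = 1e-10)
  expect_equal(abfe_assemble(0, 0, 0, 0)$dg_bind, 0)
})

test_that("the back-computed analytic term is constant across all published cycle rows", {
  rows <- abfe_reference_rows()
  # dg_bind = solv - vb_add - prot - analytic  =>  analytic backs out per row
  backed <- rows$solvated - rows$restraint - rows$complex - rows$overall
  expect_lte(max(backed) - min(backed), 0.03)
  # and matches the stiff-spring analytic value for the reported restraint
  # strengths at a representative geometry
  p <- boresch_parameters(5, pi / 2, pi / 2, 10, 10, 10, 20, 20, 20)
  expect_equal(boresch_analytic(p), mean(backed), tolerance = 0.05)
})

test_that("analytic restraint release matches the numerical configurational integral", {
  grid <- list(
    list(r0 = 5, kr = 10, kth = c(10, 10), kph = c(20, 20, 20)),   # PLpro-style
    list(r0 = 5, kr = 4, kth = c(20, 20), kph = c(40, 40, 40)),    # lysozyme-style
    list(r0 = 8, kr = 25, kth = c(50, 30), kph = c(60, 80, 100)),
    list(r0 = 3, kr = 15, kth = c(40, 40), kph = c(30, 30, 30))
  )
  for (g in grid) {
    p <- boresch_parameters(g$r0, pi / 2, 1.9, g$kr, g$kth[1], g$kth[2],
                            g$kph[1], g$kph[2], g$kph[3])
    expect_equal(boresch_analytic(p), boresch_oracle(p), tolerance = 0.05,
                 info = sprintf("r0=%g kr=%g", g$r0, g$kr))
  }
})

test_that("doubling all six force constants shifts the release term by -3RT ln 2", {
  tc <- thermo_constants()
  p1 <- boresch_parameters(5, pi / 2, pi / 2, 4, 20, 20, 40, 40, 40, tc)
  p2 <- boresch_parameters(5, pi / 2, pi / 2, 8, 40, 40, 80, 80, 80, tc)
  expect_equal(boresch_analytic(p2) - boresch_analytic(p1),
               -3 * tc$R * tc$T * log(2), tolerance = 1e-10)
  expect_error(boresch_parameters(5, 0, pi / 2, 1, 1, 1, 1, 1, 1), "angles")
  expect_error(boresch_parameters(-1, pi / 2, pi / 2, 1, 1, 1, 1, 1, 1), "r0")
})
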