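test_that("constant drive keeps the cascade at its fixed point", {
  kin <- default_kinetic_truth()
  tr <- closed_form_step(kin, 5000, 5000, seq(0, 400, by = 20))
  expect_equal(tr$p, rep(5000, nrow(tr)), tolerance = 1e-13)
  expect_equal(tr$g, rep(5000, nrow(tr)), tolerance = 1e-13)
  expect_equal(tr$G, rep(5000, nrow(tr)), tolerance = 1e-13)
})

test_that("the delayed output holds at c0 until the delay elapses", {
  kin <- kinetic_params(0.05, 0.08, 0.02, 25)
  tr <- closed_form_step(kin, 1000, 50000, c(0, 5, 12, 24.999, 25))
  expect_equal(tr$g, rep(1000, 5))
  expect_equal(tr$G, rep(1000, 5))
  # but the production-rate state already responds
  expect_gt(tr$p[2], 1000)
})

test_that("fast maturation collapses to a delayed single exponential", {
  # kg, kd -> Inf, tau = 0: G(t) = c1 + (c0 - c1) exp(-kp t)
  kin <- kinetic_params(0.03, 5e3, 1e4, 0)
  tt <- seq(1, 300, by = 10)
  G <- closed_form_step(kin, 100, 10000, tt)$G
  expect_equal(G, 10000 + (100 - 10000) * exp(-0.03 * tt), tolerance = 1e-3)

  expect_equal(half_time(kin, 100, 10000), log(2) / 0.03, tolerance = 1e-2)
  kin15 <- kinetic_params(0.03, 5e3, 1e4, 15)
  expect_equal(half_time(kin15, 100, 10000), 15 + log(2) / 0.03, tolerance = 1e-2)
})

test_that("a delay purely time-shifts the steady-state step response", {
  k0 <- kinetic_params(0.04, 0.07, 0.02, 0)
  ka <- kinetic_params(0.04, 0.07, 0.02, 18)
  tt <- seq(0, 400, by = 7)
  g0 <- closed_form_step(k0, 300, 9000, tt)
  ga <- closed_form_step(ka, 300, 9000, tt + 18)
  expect_equal(ga$G, g0$G, tolerance = 1e-10)
  expect_equal(ga$g, g0$g, tolerance = 1e-10)
})

test_that("step responses are monotone and converge to the final drive", {
  set.seed(300)
  for (i in 1:15) {
    kin <- kinetic_params(runif(1, 0.005, 0.2), runif(1, 0.005, 0.2),
                          runif(1, 0.005, 0.2), runif(1, 0, 30))
    up <- closed_form_step(kin, 500, 50000, seq(0, 600, by = 5))
    expect_true(all(diff(up$G) >= -1e-9))
    down <- closed_form_step(kin, 50000, 500, seq(0, 600, by = 5))
    expect_true(all(diff(down$G) <= 1e-9))
    horizon <- kin$tau + 12 / min(kin$kp, kin$kg, kin$kd)
    expect_lt(abs(closed_form_step(kin, 500, 50000, horizon)$G - 50000) / 50000, 0.01)
  }
})

test_that("near-repeated rates take the confluent route consistently", {
  base <- c(0.03, 0.05)
  tt <- seq(0, 500, by = 25)
  exact <- closed_form_step(kinetic_params(base[1], base[2], base[2] * (1 + 1e-4), 10),
                            1000, 80000, tt)
  conf <- closed_form_step(kinetic_params(base[1], base[2], base[2] * (1 + 1e-8), 10),
                           1000, 80000, tt)
  expect_equal(conf$G, exact$G, tolerance = 1e-3)
  # fully repeated rates are finite and monotone
  rep3 <- closed_form_step(kinetic_params(0.04, 0.04, 0.04, 5), 1000, 80000, tt)
  expect_true(all(is.finite(rep3$G)))
  expect_true(all(diff(rep3$G) >= 0))
})

test_that("numeric delay integration matches the closed form", {
  set.seed(123)
  for (i in 1:10) {
    kin <- kinetic_params(runif(1, 0.005, 0.2), runif(1, 0.005, 0.2),
                          runif(1, 0.005, 0.2), runif(1, 0, 30))
    tt <- seq(0, 600, by = 12)
    cf <- closed_form_step(kin, 2000, 108700, tt)
    nm <- simulate_step(kin, 2000, 108700, tt)
    expect_lt(max(abs(cf$G - nm$G) / pmax(abs(cf$G), 1)), 1e-6)
    expect_lt(max(abs(cf$g - nm$g) / pmax(abs(cf$g), 1)), 1e-6)
  }
  expect_error(simulate_step(default_kinetic_truth(), 100, 200, c(0, 10, 10)),
               "strictly increasing")
})

test_that("noise-free timecourses are fit back to the generating trajectory", {
  truth <- default_kinetic_truth()
  boundary <- list(y0 = 2000, dy = 106700)
  tt <- seq(0, 600, by = 25)
  tc <- data.frame(time = tt, replicate = "day1",
                   y = closed_form_step(truth, 2000, 108700, tt)$G)
  fit <- fit_kinetics(tc, direction = "on", boundary = boundary)
  expect_true(fit$converged)
  # rates are exchangeable in G, so score the recovered trajectory and t1/2
  G_hat <- closed_form_step(fit$estimates, 2000, 108700, tt)$G
  expect_lt(max(abs(G_hat - tc$y) / tc$y), 1e-6)
  expect_equal(fit$half_time, half_time(truth, 2000, 108700), tolerance = 1e-4)
  expect_true(fit$estimates$kg <= fit$estimates$kd)
  expect_identical(fit$symmetry$exchangeable, c("kg", "kd"))
})

test_that("half-times recover within 5% from noisy replicate timecourses", {
  truth <- default_kinetic_truth()
  t_half_true <- half_time(truth, 2000, 108700)
  des <- step_design(truth, 2000, 108700, n_replicates = 3,
                     replicate_cv = 0.05, seed = 60)
  d <- gen_step_experiment(des)
  fit <- fit_kinetics(d, direction = "on", boundary = list(y0 = 2000, dy = 106700))
  expect_lt(abs(fit$half_time - t_half_true) / t_half_true, 0.05)
})

test_that("kinetic fitting rejects degenerate inputs", {
  tc <- data.frame(time = seq(0, 100, 20), replicate = "d1", y = rep(100, 6))
  expect_error(fit_kinetics(tc, "on", boundary = list(y0 = 500, dy = 0)),
               "flat signal")
  expect_error(fit_kinetics(tc[1:4, ], "on", boundary = list(y0 = 5, dy = 100)),
               "6 distinct")
  tc$y[2] <- -1
  expect_error(fit_kinetics(tc, "on", boundary = list(y0 = 5, dy = 100)),
               "non-positive")
  expect_error(half_time(default_kinetic_truth(), 100, 100), "no transition")
  expect_error(half_time(default_kinetic_truth(), 100, 200, horizon = 16),
               "horizon")
})
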