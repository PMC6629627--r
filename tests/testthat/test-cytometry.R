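test_that("density gate honors the exact count contract and identity at fraction 1", {
  ev <- gen_events(event_gen_spec(10, 100, seed = 4))
  expect_equal(nrow(density_gate(ev, 1.0)), 10)
  expect_equal(as.data.frame(density_gate(ev, 1.0))[, c("fsc", "ssc", "fl1")],
               as.data.frame(ev)[, c("fsc", "ssc", "fl1")])
  expect_equal(nrow(density_gate(ev, 0.5)), 5)

  # property: count contract across fractions and sizes
  for (n in c(7, 33, 501)) {
    evn <- gen_events(event_gen_spec(n, 100, seed = n))
    for (f in c(0.1, 0.33, 0.5, 0.77, 1)) {
      expect_equal(nrow(density_gate(evn, f)), max(1, round(f * n)))
    }
  }
  expect_error(density_gate(ev, 0), "fraction")
  expect_error(density_gate(ev, 1.5), "fraction")
})

test_that("density gate retains the dense cluster against a uniform background", {
  ev <- gen_events(event_gen_spec(2000, 100, scatter_spread = 0.08,
                                  background_fraction = 0.1, seed = 21))
  # generator emits cluster events first, then background
  gated <- density_gate(ev, 0.5)
  n_cluster <- 2000 - round(0.1 * 2000)
  from_cluster <- mean(gated$event_id <= n_cluster)
  expect_gte(from_cluster, 0.99)

  # oracle: exact pairwise product-Gaussian KDE ranking on a small sample
  sm <- gen_events(event_gen_spec(300, 100, scatter_spread = 0.08,
                                  background_fraction = 0.2, seed = 22))
  hx <- MASS::bandwidth.nrd(sm$fsc); hy <- MASS::bandwidth.nrd(sm$ssc)
  dens <- exact_kde_at(sm$fsc, sm$ssc, hx, hy)
  oracle_keep <- sort(order(-dens, seq_len(300))[1:150])
  got <- density_gate(sm, 0.5)$event_id
  expect_gte(length(intersect(got, oracle_keep)) / 150, 0.95)
})

test_that("bead calibration recovers identity and generator mappings", {
  vals <- c(1e2, 1e3, 1e4, 1e5, 1e6)
  ident <- gen_bead_sample(vals, channel_gain = 1, peak_cv = 1e-6,
                           events_per_peak = 300, seed = 9)
  cal <- fit_bead_calibration(ident$events, vals)
  expect_lt(abs(cal$slope - 1), 1e-6)
  expect_lt(abs(cal$intercept), 1e-6)

  bs <- gen_bead_sample(c(792, 2079, 6588, 16471, 47497, 137049),
                        channel_gain = 0.05, peak_cv = 0.05,
                        events_per_peak = 1000, seed = 10)
  cal2 <- fit_bead_calibration(bs$events, bs$truth$peak_true_values)
  gain_hat <- 10^(-cal2$intercept / cal2$slope)
  expect_lt(abs(gain_hat - 0.05) / 0.05, 0.05)
  expect_lt(abs(cal2$slope - 1), 0.05)

  expect_error(fit_bead_calibration(bs$events, 1000), "at least 2")
  # asking for more peaks than the histogram has modes names the count found
  expect_error(fit_bead_calibration(ident$events, c(vals, 1e7, 1e8)),
               "found \\d+ mode")
})

test_that("MEFL conversion is an interpolating, single-shot state transition", {
  vals <- c(1e2, 1e3, 1e4, 1e5)
  bs <- gen_bead_sample(vals, channel_gain = 0.1, peak_cv = 0.03,
                        events_per_peak = 800, seed = 12)
  cal <- fit_bead_calibration(bs$events, vals)

  # events sitting at a bead peak map to that peak's assigned value
  at_peaks <- event_table(data.frame(fsc = 1, ssc = 1,
                                     fl1 = cal$peak_channel_positions),
                          units = "au", calibration_state = "raw")
  mapped <- to_mefl(at_peaks, cal)
  expect_equal(log10(mapped$fl1), log10(vals),
               tolerance = sqrt(cal$residual) + 1e-8)

  expect_error(to_mefl(mapped, cal), "twice")

  # identity calibration leaves values unchanged
  ident <- gen_bead_sample(vals, channel_gain = 1, peak_cv = 1e-6,
                           events_per_peak = 200, seed = 13)
  cal_id <- fit_bead_calibration(ident$events, vals)
  ev <- event_table(data.frame(fsc = 1, ssc = 1, fl1 = c(50, 5000, 5e5)),
                    units = "au", calibration_state = "raw")
  expect_equal(to_mefl(ev, cal_id)$fl1, c(50, 5000, 5e5), tolerance = 1e-5)
})

test_that("sample medians follow the documented conventions", {
  mk <- function(v) event_table(data.frame(fsc = 1, ssc = 1, fl1 = v),
                                units = "MEFL", calibration_state = "calibrated")
  expect_equal(summarize_sample(mk(c(1, 2, 3))), 2)
  expect_equal(summarize_sample(mk(c(1, 2, 3, 4))), 2.5)
  ev <- gen_events(event_gen_spec(1e5, 1000, seed = 30))
  expect_lt(abs(summarize_sample(ev) - 1000) / 1000, 0.01)
})

test_that("autofluorescence subtraction is sample minus control with unit checks", {
  expect_equal(subtract_autofluorescence(1100, 100), 1000)
  expect_equal(subtract_autofluorescence(100, 100), 0)
  expect_error(subtract_autofluorescence(1100, 100, units = "MEFL",
                                         control_units = "MEAP"), "unit mismatch")

  # generator round-trip: reporter 500 over autofluorescence 80
  smp <- gen_events(event_gen_spec(3e4, 500, autofluorescence_median = 80, seed = 31))
  ctl <- gen_events(event_gen_spec(3e4, 0, autofluorescence_median = 80, seed = 32))
  rep_fl <- subtract_autofluorescence(summarize_sample(smp), summarize_sample(ctl))
  expect_lt(abs(rep_fl - 500) / 500, 0.05)
})

test_that("detection rule handles zero signal and degenerate spread", {
  expect_false(detect(c(0, 0, 0))$detected)
  d <- detect(c(10, 10, 10))
  expect_true(d$detected)
  expect_equal(d$p_value, 0)
  expect_true(d$degenerate)
  expect_error(detect(5), "2 replicates")
  # negative-mean degenerate case
  expect_equal(detect(c(-3, -3, -3))$p_value, 1)
})

test_that("welch_test matches the reference implementation to 1e-10", {
  set.seed(77)
  for (i in 1:50) {
    a <- rnorm(sample(2:9, 1), mean = runif(1, -2, 2), sd = runif(1, 0.2, 3))
    b <- rnorm(sample(2:9, 1), mean = runif(1, -2, 2), sd = runif(1, 0.2, 3))
    got <- welch_test(a, b)
    ref <- t.test(a, b, var.equal = FALSE)
    expect_lt(abs(got$t - unname(ref$statistic)), 1e-10)
    expect_lt(abs(got$df - unname(ref$parameter)), 1e-10)
    expect_lt(abs(got$p_value - ref$p.value), 1e-10)
  }
  ident <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)
  expect_equal(welch_test(c(5, 5), c(5, 5))$p_value, 1)  # constant-group limit
  expect_equal(welch_test(c(6, 6), c(5, 5))$p_value, 0)
  expect_error(welch_test(1, c(1, 2)), ">= 2")
})

test_that("fold change supports by-day pairing and error propagation", {
  eq <- fold_change(c(3, 3, 3), c(3, 3, 3))
  expect_equal(eq$mean, 1)
  expect_equal(eq$sd, 0)

  fc <- fold_change(c(20, 22, 18), c(2, 2, 2))
  expect_equal(fc$mean, 10)
  expect_equal(fc$sd, 1)  # per-day ratios 10, 11, 9

  rm <- fold_change(c(20, 22, 18), c(2, 2, 2), pairing = "ratio_of_means")
  expect_equal(rm$mean, 10)
  expect_equal(rm$sd, 10 * sqrt((sd(c(20, 22, 18)) / 20)^2 + 0))

  expect_error(fold_change(c(1, 2), c(0, 1)), "strictly positive")
  expect_error(fold_change(c(1, 2, 3), c(1, 2)), "equal replicate")

  # synthetic green/red pairs at a known ratio of 70
  set.seed(55)
  est <- replicate(50, {
    red <- 1500 * rlnorm(3, 0, sqrt(log(1 + 0.15^2)))
    green <- 70 * 1500 * rlnorm(3, 0, sqrt(log(1 + 0.15^2)))
    fold_change(green, red)$mean
  })
  expect_lt(abs(median(est) - 70) / 70, 0.15)
})
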