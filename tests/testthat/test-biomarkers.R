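test_that("APD on the synthetic ramp AP matches the closed form", {
  tr <- make_synthetic_trace()  # peak 40, rest -85, 300 ms linear fall
  expect_equal(apd(tr, 0.9), 270, tolerance = 1e-6)
  expect_equal(apd(tr, 0.5), 150, tolerance = 1e-6)
  expect_equal(triangulation(tr), 120, tolerance = 1e-6)
  # small fractions shrink toward zero
  expect_equal(apd(tr, 0.01), 3, tolerance = 1e-6)
  expect_lt(apd(tr, 0.001), 1)
})

test_that("APD is monotone in the repolarization fraction", {
  tr <- make_synthetic_trace()
  fr <- seq(0.1, 0.95, by = 0.05)
  vals <- vapply(fr, function(q) apd(tr, q), numeric(1))
  expect_true(all(diff(vals) >= 0))
  # and triangulation is nonnegative on a monotone-repolarizing trace
  expect_gte(triangulation(tr), 0)
})

test_that("square AP has zero triangulation; failure to repolarize errors", {
  t <- seq(0, 400, by = 0.5)
  V <- ifelse(t < 280, 40, -85)
  V[t == 0] <- -85  # pre-stimulus sample
  sq <- ap_trace(t, V, CL = 400, stim_onset = 0.5)
  expect_lt(triangulation(sq), 1)
  never <- ap_trace(t, rep(40, length(t)), CL = 400, stim_onset = 0)
  expect_error(apd(never, 0.9), "repolarization failure")
})

test_that("markers are stable under time-grid refinement", {
  tr1 <- make_synthetic_trace(dt = 1)
  tr2 <- make_synthetic_trace(dt = 0.05)
  expect_lt(abs(apd(tr1, 0.9) - apd(tr2, 0.9)), 0.05)
  ca1 <- ca_levels(tr1); ca2 <- ca_levels(tr2)
  expect_lt(abs(ca1["systolic"] - ca2["systolic"]), 1e-6)
})

test_that("calcium levels: closed-form peak, constant trace, missing series", {
  tr <- make_synthetic_trace(dt = 0.01)   # fine grid to hit the peak at s=50
  ca <- ca_levels(tr)
  expect_equal(unname(ca["systolic"]), 7e-4, tolerance = 1e-6)
  expect_equal(unname(ca["diastolic"]), 1e-4, tolerance = 1e-9)
  flat <- ap_trace(0:100, rep(-80, 101), Cai = rep(2e-4, 101), CL = 100)
  expect_equal(unname(diff(ca_levels(flat))), 0)
  no_ca <- ap_trace(0:100, rep(-80, 101), CL = 100)
  expect_true(all(is.na(ca_levels(no_ca))))
})

test_that("the one-cycle potassium integral is a trapezoid rule", {
  t <- seq(0, 1000, by = 0.5)
  zero <- ap_trace(t, rep(-80, length(t)),
                   currents = data.frame(IKr = rep(0, length(t))), CL = 1000)
  expect_equal(iktot_integral(zero), 0)
  const <- ap_trace(t, rep(-80, length(t)),
                    currents = data.frame(IKr = rep(1, length(t))), CL = 1000)
  expect_equal(iktot_integral(const), 1000)
  no_cur <- ap_trace(t, rep(-80, length(t)), CL = 1000)
  expect_error(iktot_integral(no_cur), "current")
  # refinement oracle on a toy-model trace: refining the default 0.02 ms
  # grid tenfold changes the integral by less than 1e-4 relative
  m <- toy_model_cached()
  p1 <- steady_state_pacing(m, 1000, 3, final_out_dt = 0.02)
  p2 <- steady_state_pacing(m, 1000, 3, final_out_dt = 0.002)
  i1 <- iktot_integral(p1$trace); i2 <- iktot_integral(p2$trace)
  expect_lt(abs(i1 - i2) / max(abs(i2), 1), 1e-4)
})

test_that("biexponential fit recovers tau_slow from synthetic series", {
  clean <- make_adaptation_series()   # tau_fast 10 s, tau_slow 90 s
  fit <- fit_adaptation(clean$t, clean$apd90)
  expect_lt(abs(fit$tau_slow - 90) / 90, 0.01)
  expect_lt(abs(fit$tau_fast - 10) / 10, 0.01)
  expect_true(fit$tau_fast < fit$tau_slow)
  expect_true(fit$identifiable)
  # single-exponential input: tau_slow recovered, fast amplitude negligible
  single <- make_adaptation_series(A_fast = 0)
  fs <- fit_adaptation(single$t, single$apd90)
  expect_lt(abs(fs$tau_slow - 90) / 90, 0.01)
  expect_lt(abs(fs$A_fast), 1)
  # flat series: slow amplitude below 1 ms flags unidentifiable
  flat <- data.frame(t = seq(0, 480, by = 0.6), apd90 = 250)
  ff <- fit_adaptation(flat)
  expect_false(ff$identifiable)
  expect_error(fit_adaptation(1:10, rnorm(10)), "at least")
})

test_that("tau_slow recovery under noise: 5% median over a parameter grid", {
  errs <- c()
  for (tf in c(5, 15)) for (ts in c(70, 90, 110)) {
    for (seed in 1:3) {
      s <- make_adaptation_series(tau_fast = tf, tau_slow = ts, sigma = 0.5,
                                  seed = seed * 100 + tf)
      fit <- fit_adaptation(s$t, s$apd90)
      errs <- c(errs, abs(fit$tau_slow - ts) / ts)
    }
  }
  expect_lt(median(errs), 0.05)
})

test_that("trace CSV round trip reproduces the closed-form markers", {
  tr <- make_synthetic_trace()
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(tr), f, row.names = FALSE)
  mk <- markers_from_csv(f, CL = 1000, stim_onset = 10)
  expect_equal(mk$apd90, 270, tolerance = 1e-6)
  expect_equal(mk$triangulation, 120, tolerance = 1e-6)
})
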