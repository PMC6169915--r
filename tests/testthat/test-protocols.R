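test_that("beat accounting: one record per delivered stimulus", {
  m <- toy_model_cached()
  p1 <- steady_state_pacing(m, 1000, n_beats = 1)
  expect_equal(nrow(p1$beats), 1)
  p5 <- steady_state_pacing(m, 800, n_beats = 5, per_beat_markers = TRUE)
  expect_equal(nrow(p5$beats), 5)
  expect_equal(p5$beats$beat, 1:5)
  expect_equal(p5$beats$onset, (0:4) * 800)
  expect_true(all(is.finite(p5$beats$apd90)))
})

test_that("pacing approaches a quasi-steady state and stays captured", {
  p <- toy_short_pacing()   # 30 beats, CL 1000
  expect_true(p$capture)
  apd_last <- tail(p$beats$apd90, 1)
  expect_gt(apd_last, 50)    # a real AP, not a stimulus artefact
  expect_lt(apd_last, 500)
  # late-beat potassium budget changes slowly (homeostasis approach)
  ints <- p$beats$iktot_integral
  expect_lt(abs(ints[30] - ints[29]), abs(ints[2] - ints[1]) + 0.5)
})

test_that("potassium bookkeeping: delta Ki equals -kappa_K * integral", {
  m <- toy_model_cached()
  p <- toy_short_pacing()
  kK <- m$params[["kappa_K"]]
  ki0 <- m$state0[["Ki"]]
  ki_pred <- ki0 - kK * cumsum(p$beats$iktot_integral)
  expect_equal(p$beats$ki_end, ki_pred, tolerance = 1e-6)
})

test_that("raising G_K1 breaks the one-cycle potassium balance", {
  m <- toy_model_cached()
  base_int <- tail(toy_short_pacing()$beats$iktot_integral, 1)
  m2 <- m; m2$params[["G_K1"]] <- m$params[["G_K1"]] * 1.3
  p2 <- steady_state_pacing(m2, 1000, 30, per_beat_markers = FALSE)
  expect_gt(abs(tail(p2$beats$iktot_integral, 1)), abs(base_int))
})

test_that("restart consistency: chunked pacing equals one longer run", {
  m <- toy_model_cached()
  p_a <- steady_state_pacing(m, 500, 6, per_beat_markers = FALSE)
  # manual two-stage run through the same machinery
  out1 <- sim_segment(m, m$state0, 3, 500)
  y_mid <- out1[nrow(out1), -1]
  p_b <- steady_state_pacing(m, 500, 3, per_beat_markers = FALSE, y0 = y_mid)
  expect_equal(tail(p_b$beats$ki_end, 1), tail(p_a$beats$ki_end, 1),
               tolerance = 1e-6)
  expect_equal(tail(p_b$beats$apd90, 1), tail(p_a$beats$apd90, 1),
               tolerance = 0.05)
})

test_that("determinism: identical runs give identical beat series", {
  m <- toy_model_cached()
  p1 <- steady_state_pacing(m, 1000, 5, per_beat_markers = TRUE)
  p2 <- steady_state_pacing(m, 1000, 5, per_beat_markers = TRUE)
  expect_identical(p1$beats, p2$beats)
})

test_that("rate adaptation: APD90 drops after the switch; null switch is flat", {
  m <- toy_model_cached()
  bs <- rate_adaptation_protocol(m, n_pre = 30, n_post = 40)
  expect_equal(nrow(bs), 70)
  pre_last <- tail(bs$apd90[bs$phase == "pre"], 1)
  post_first <- bs$apd90[bs$phase == "post"][2]  # first full post-switch beat
  expect_lt(post_first, pre_last)
  # onset clock: switch at 0
  expect_lt(max(bs$onset_s[bs$phase == "pre"]), 0)
  expect_equal(min(bs$onset_s[bs$phase == "post"]), 0)
  # null protocol: same CL on both sides leaves APD90 flat
  bs0 <- rate_adaptation_protocol(m, CL_pre = 1000, CL_post = 1000,
                                  n_pre = 20, n_post = 20)
  post <- bs0$apd90[bs0$phase == "post"]
  expect_lt(max(post) - min(post), 0.1)
})

test_that("default adaptation protocol counts are 480 + 800 beats", {
  # arithmetic of 8 minutes at each CL; checked on the formals, not by
  # running a quarter-hour simulation
  f <- formals(rate_adaptation_protocol)
  expect_equal(eval(f$n_pre) * eval(f$CL_pre) / 1000, 480)
  expect_equal(eval(f$n_post), 800)
  expect_equal(eval(f$n_post) * eval(f$CL_post) / 1000 / 60, 8)
})

test_that("Ko step: depolarization when raised, hyperpolarization when lowered", {
  m <- toy_model_cached()
  up <- ko_step_unstimulated(m, 4.4, 6.6, settle_ms = 5000,
                             observe_ms = 1000)
  expect_gt(up$V_ss, up$V_start)
  expect_gt(up$t90, 0)
  expect_lt(up$t90, 1000)
  dn <- ko_step_unstimulated(m, 5.4, 3.0, settle_ms = 5000,
                             observe_ms = 1000)
  expect_lt(dn$V_ss, dn$V_start)
  # null step: defined as zero with a warning
  expect_warning(
    z <- ko_step_unstimulated(m, 5.4, 5.4, settle_ms = 20000,
                              observe_ms = 500),
    "no membrane-potential transition")
  expect_equal(z$t90, 0)
})

test_that("restitution: normalization identity, rate direction, alternans flag", {
  m <- toy_model_cached()
  r1 <- restitution(m, 1000, n_beats = 10)
  expect_equal(r1$apd90_norm, 1)
  r <- restitution(m, c(600, 1000, 2000), n_beats = 20)
  expect_true(all(r$excitable))
  expect_true(all(diff(r$apd90[order(r$CL)]) >= 0))
  # inexcitable cycle lengths are flagged, not errors
  weak <- m; weak$params[["stim_amp"]] <- -2
  rw <- restitution(weak, 1000, n_beats = 3)
  expect_false(rw$excitable[1])
  expect_true(is.na(rw$apd90[1]))
})
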