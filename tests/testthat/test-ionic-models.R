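test_that("ik_tot implements the potassium budget with the pump factor -2", {
  expect_equal(ik_tot(currents_record()), 0)
  expect_equal(ik_tot(currents_record(INaK = 1)), -2)
  expect_equal(ik_tot(currents_record(Ito = 1, IKr = 1, IKs = 1, IK1 = 1,
                                      ICaK = 1, IKp = 1, INaK = 1)), 4)
  # non-potassium currents do not enter
  expect_equal(ik_tot(currents_record(ICaL = 5, Incx = 3, IClbk = -2)), 0)
  # stimulus charge is assigned to potassium
  expect_equal(ik_tot(currents_record(Istim = -40)), -40)
  # data-frame (time series) input is vectorized
  df <- data.frame(IKr = c(1, 2), INaK = c(1, 0.5))
  expect_equal(ik_tot(df), c(-1, 1))
})

test_that("ki_derivative has the right scale and antisymmetry", {
  expect_equal(ki_derivative(0, 1, 1, 1), 0)
  # toy conversion factor kappa_K = Cmem/(Vmyo*Frdy) = 6e-5
  expect_equal(ki_derivative(1, Cmem = 6e-5, Vmyo = 1, Frdy = 1), -6e-5)
  x <- seq(-3, 3, by = 0.7)
  expect_equal(ki_derivative(x, 1, 2, 3), -ki_derivative(-x, 1, 2, 3))
  expect_error(ki_derivative(1, 1, 0, 1), "positive")
})

test_that("toy RHS satisfies its structural identities", {
  m <- toy_model_cached()
  # at V = E_K all potassium driving-force currents vanish
  Ki <- 138; Ko <- 5.4
  EK <- 26.71 * log(Ko / Ki)
  st <- c(V = EK, f = 0.5, n = 0.5, Cai = 2e-4, Ki = Ki, qK = 0)
  r <- toy_rhs(0, st, m$params)
  expect_equal(unname(r$currents[["IKr"]]), 0, tolerance = 1e-12)
  expect_equal(unname(r$currents[["IK1"]]), 0, tolerance = 1e-12)
  expect_equal(unname(r$currents[["IKp"]]), 0, tolerance = 1e-12)
  # dKi/dt = -kappa_K * ik_tot holds at random states
  set.seed(3)
  for (i in 1:10) {
    st <- c(V = runif(1, -95, 35), f = runif(1), n = runif(1),
            Cai = runif(1, 5e-5, 1e-3), Ki = runif(1, 110, 150), qK = 0)
    r <- toy_rhs(0, st, m$params, stim = sample(c(0, -40), 1))
    expect_equal(unname(r$deriv[["Ki"]]),
                 -m$params[["kappa_K"]] * ik_tot(r$currents),
                 tolerance = 1e-12)
    expect_equal(unname(r$deriv[["qK"]]), ik_tot(r$currents),
                 tolerance = 1e-12)
  }
  expect_error(toy_rhs(0, c(V = -80, f = 1, n = 0, Cai = 1e-4, Ki = -1,
                            qK = 0), m$params), "positive")
})

test_that("compiled and R right-hand sides integrate identically", {
  mc <- toy_model_cached()
  mr <- toy_ventricular_model(use_compiled = FALSE)
  st <- c(V = -70, f = 0.9, n = 0.1, Cai = 3e-4, Ki = 140, qK = 0)
  oc <- sim_segment(mc, st, 2, 400, times = seq(0, 800, by = 5))
  or <- sim_segment(mr, st, 2, 400, times = seq(0, 800, by = 5))
  expect_lt(max(abs(oc - or)), 1e-6)
})

test_that("the unstimulated toy model settles to a stable rest state", {
  m <- toy_model_cached()
  out <- sim_segment(m, n_beats = 1, CL = 10000, stim_on = FALSE,
                     times = seq(0, 10000, by = 500))
  V <- out[, "V"]
  # settles: last two seconds move by less than a microvolt-scale amount
  expect_lt(abs(V[length(V)] - V[length(V) - 4]), 1e-3)
  expect_true(all(out[, "f"] >= 0 & out[, "f"] <= 1))
  expect_true(all(out[, "n"] >= 0 & out[, "n"] <= 1))
  # the rest potential sits in the neighbourhood of the potassium Nernst
  # potential (held slightly depolarized by the background leak)
  EK <- 26.71 * log(m$params[["Ko"]] / out[nrow(out), "Ki"])
  expect_lt(V[length(V)], EK + 8)
  expect_gt(V[length(V)], EK - 10)
})

test_that("apply_conductances scales the named parameters and nothing else", {
  m <- toy_model_cached()
  sp <- decision_space(c("G_Ca", "G_K1"), unname(m$params[c("G_Ca", "G_K1")]))
  m0 <- apply_conductances(m, c(0, 0), sp)
  expect_equal(m0$params, m$params)
  m2 <- apply_conductances(m, c(20 * log10(2), -20 * log10(2)), sp)
  expect_equal(unname(m2$params[["G_Ca"]]), unname(m$params[["G_Ca"]]) * 2,
               tolerance = 1e-12)
  expect_equal(unname(m2$params[["G_K1"]]), unname(m$params[["G_K1"]]) / 2,
               tolerance = 1e-12)
  expect_equal(m2$params[setdiff(names(m2$params), c("G_Ca", "G_K1"))],
               m$params[setdiff(names(m$params), c("G_Ca", "G_K1"))])
  # the original model object is untouched
  expect_equal(m$params[["G_Ca"]], 0.18)
  bad <- decision_space("G_nonexistent", 1)
  expect_error(apply_conductances(m, 0, bad), "valid names")
})

test_that("gates remain in [0,1] during paced activity", {
  m <- toy_model_cached()
  out <- sim_segment(m, n_beats = 3, CL = 500,
                     times = seq(0, 1500, by = 0.5))
  expect_true(all(out[, "f"] >= -1e-9 & out[, "f"] <= 1 + 1e-9))
  expect_true(all(out[, "n"] >= -1e-9 & out[, "n"] <= 1 + 1e-9))
})
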