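test_that("percent change and the sensitivity convention", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(130, 100), 30)
  expect_equal(percent_change(70, 100), -30)
  expect_true(is.na(percent_change(5, 0)))
  # unit elasticity gives S = 100 for any a under the adopted convention
  for (a in c(0.1, 0.3, 0.5))
    expect_equal(sensitivity_index(100 * a, -100 * a, a), 100)
  expect_equal(sensitivity_index(30, -30, 0.3, "literal"), 1e4)
  expect_equal(sensitivity_index(10, 10, 0.3), 0)
  # antisymmetry under swapping the perturbed runs
  expect_equal(sensitivity_index(25, -18, 0.3),
               -sensitivity_index(-18, 25, 0.3))
})

test_that("linear evaluator gives exactly 100%; absent conductance gives 0", {
  ev <- function(mult) c(p_linear = 3 * mult[["g1"]] * 10,
                         p_null = 42,
                         p_mixed = 5 * mult[["g1"]] + mult[["g2"]]^2)
  sm <- run_sensitivity(ev, c("g1", "g2", "g_absent"), a = 0.3)
  expect_equal(sm$S["g1", "p_linear"], 100)
  expect_equal(sm$S["g_absent", "p_linear"], 0)
  expect_equal(sm$S["g2", "p_linear"], 0)
  expect_equal(unname(sm$S[, "p_null"]), c(0, 0, 0))
  expect_false(any(sm$failed))
})

test_that("evaluation bookkeeping: 2n+1 calls; failures are isolated", {
  calls <- 0
  ev <- function(mult) {
    calls <<- calls + 1
    if (mult[["g2"]] > 1) stop("boom")
    c(p = mult[["g1"]])
  }
  sm <- run_sensitivity(ev, c("g1", "g2"), a = 0.3)
  expect_equal(calls, 2 * 2 + 1)
  expect_true(sm$failed[["g2"]])
  expect_false(sm$failed[["g1"]])
  expect_true(is.na(sm$S["g2", "p"]))
  expect_equal(sm$S["g1", "p"], 100)
})

test_that("toy model: more delayed-rectifier current shortens the APD", {
  m <- toy_model_cached()
  sm <- run_sensitivity(m, c("G_K", "G_Ca"), a = 0.3, n_beats = 30)
  expect_lt(sm$S["G_K", "apd90"], 0)
  expect_gt(sm$S["G_Ca", "apd90"], 0)  # calcium current prolongs the AP
  # determinism of the ranking across reruns
  sm2 <- run_sensitivity(m, c("G_K", "G_Ca"), a = 0.3, n_beats = 30)
  expect_equal(sm$S, sm2$S)
})

test_that("column normalization maps into [0,1] with a unique maximum", {
  S <- matrix(c(-50, 25, 0,
                10, -10, 5,
                0, 0, 0), nrow = 3, byrow = FALSE,
              dimnames = list(c("a", "b", "c"), c("p1", "p2", "p3")))
  N <- normalize_sensitivity(S)
  expect_true(all(N >= 0 & N <= 1))
  expect_equal(sum(N[, "p1"] == 1), 1)
  expect_equal(sum(N[, "p2"] == 1), 1)   # tie on |S|: first row wins
  expect_equal(which(N[, "p2"] == 1), c(a = 1))
  expect_equal(unname(N[, "p3"]), c(0, 0, 0))  # all-zero column
})

test_that("decision-variable selection applies the dominance exclusion rule", {
  S <- matrix(c(400, -150, 60, 20,     # objective column
                -20, 10, 5, 0,
                -130, 8, 6, 2),        # g1 dominates p2 uniquely
              nrow = 4,
              dimnames = list(c("g1", "g2", "g3", "g4"),
                              c("iktot_integral", "p1", "p2")))
  sel <- select_decision_variables(S_matrix(S), dominance = 100,
                                   compensation = 30)
  expect_equal(sel$ranking, c("g1", "g2", "g3", "g4"))
  expect_true("g1" %in% names(sel$excluded))
  expect_equal(sel$selected, c("g2", "g3", "g4"))
  # with a compensating variable the exclusion lifts
  S2 <- S; S2["g2", "p2"] <- 80
  sel2 <- select_decision_variables(S_matrix(S2), dominance = 100,
                                    compensation = 30)
  expect_length(sel2$excluded, 0)
  # all-zero matrix: empty selection with a warning
  S0 <- S * 0
  expect_warning(sel0 <- select_decision_variables(S_matrix(S0)), "zero")
  expect_length(sel0$selected, 0)
})
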