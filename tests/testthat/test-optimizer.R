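test_that("a quadratic evaluator converges with exact surrogates", {
  sp <- decision_space(c("x1", "x2"), c(1, 1))
  cs <- constraint_spec("m1", 280, 320)
  ev <- quadratic_evaluator(c(0.5, -0.25))
  pr <- optimization_problem(sp, cs, trust_region_params(max_iterations = 10))
  res <- run_optimization(pr, ev)
  expect_equal(unname(res$x), c(0.5, -0.25), tolerance = 1e-3)
  # exactness: every recorded ratio of the first accepted iteration is 1
  r1 <- res$iterations[[1]]
  expect_true(r1$flgTR)
  expect_equal(r1$rho0, 1, tolerance = 1e-6)
  expect_equal(unname(r1$rho_j), rep(1, length(r1$rho_j)), tolerance = 1e-6)
  expect_true(res$termination %in% c("step-size", "gradient"))
})

test_that("trust ratios are 1 for every degree-<=2 evaluator (surface exactness)", {
  set.seed(11)
  sp <- decision_space(c("x1", "x2", "x3"), c(1, 1, 1))
  for (rep in 1:3) {
    a <- rnorm(3); B <- crossprod(matrix(rnorm(9), 3))
    ev <- function(X) {
      X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
      list(f = drop(X %*% a) + rowSums((X %*% B) * X),
           M = cbind(m1 = 300 + drop(X %*% c(1, -2, 0.5))))
    }
    pr <- optimization_problem(sp, constraint_spec("m1", 250, 350),
                               trust_region_params(max_iterations = 4))
    res <- run_optimization(pr, ev)
    for (it in res$iterations) {
      expect_equal(it$rho0, 1, tolerance = 1e-6)
      expect_equal(unname(it$rho_j), rep(1, length(it$rho_j)),
                   tolerance = 1e-6)
    }
  }
})

test_that("the true objective is non-increasing along accepted iterates", {
  ap <- analytic_problem()
  pr <- optimization_problem(ap$space, ap$constraints)
  res <- run_optimization(pr, ap$evaluator)
  f_acc <- c(res$iterations[[1]]$f_k,
             vapply(Filter(function(r) r$flgTR, res$iterations),
                    `[[`, numeric(1), "f_star"))
  expect_true(all(diff(f_acc) <= 1e-12))
  # radius bookkeeping: delta never exceeds the cap
  deltas <- vapply(res$iterations, `[[`, numeric(1), "delta")
  expect_true(all(deltas <= pr$trust$delta_max + 1e-12))
})

test_that("analytic problem solution matches the brute-force grid oracle", {
  ap <- analytic_problem()
  pr <- optimization_problem(ap$space, ap$constraints)
  res <- run_optimization(pr, ap$evaluator)
  # coarse oracle for the routine test run (the acceptance suite uses 1e-3)
  orc <- grid_oracle(ap, resolution = 1e-2)
  expect_lte(res$f, orc$f_opt + 1e-3)
  g <- constraint_transform(res$markers, ap$constraints$mCR,
                            ap$constraints$mRR)
  expect_true(all(g <= 1e-9))
})

test_that("failed database points are dropped; total failure aborts", {
  sp <- decision_space(c("x1", "x2"), c(1, 1))
  ev_fail <- function(X) {
    X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
    f <- rowSums(X^2)
    f[X[, 1] > 1.9 & X[, 2] > 1.9] <- NA_real_   # one corner fails
    list(f = f, M = NULL)
  }
  pr <- optimization_problem(sp, NULL, trust_region_params(max_iterations = 2))
  expect_warning(res <- run_optimization(pr, ev_fail), "dropped")
  expect_s3_class(res, "rsa_optimization")
  ev_allfail <- function(X) list(f = rep(NA_real_, nrow(X)), M = NULL)
  expect_error(suppressWarnings(run_optimization(pr, ev_allfail)))
})

test_that("iteration log has the documented columns and CSV/JSON outputs", {
  ap <- analytic_problem()
  pr <- optimization_problem(ap$space, ap$constraints,
                             trust_region_params(max_iterations = 3))
  dir <- withr::local_tempdir()
  res <- run_optimization(pr, ap$evaluator, log_dir = dir)
  expect_true(file.exists(file.path(dir, "iterations.csv")))
  expect_true(file.exists(file.path(dir, "database_00.csv")))
  expect_true(file.exists(file.path(dir, "result.json")))
  log <- read.csv(file.path(dir, "iterations.csv"))
  expect_true(all(c("k", "delta", "f", "rho0", "flgTR", "x_x1", "m_m1",
                    "rho_m1") %in% names(log)))
  js <- jsonlite::read_json(file.path(dir, "result.json"))
  expect_equal(js$termination, res$termination)
  expect_equal(unlist(js$x), res$x, tolerance = 1e-9)
})
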