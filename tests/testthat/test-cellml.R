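toy_map <- c(IKr = "IK", IK1 = "IK1", INaK = "INaK", IKp = "IKp",
             ICaL = "ICa", IClbk = "IClbk")

test_that("toy model round-trips through CellML to 1e-10", {
  m <- toy_ventricular_model()
  f <- withr::local_tempfile(fileext = ".cellml")
  write_cellml(m, f)
  cm <- load_cellml_model(f, current_map = toy_map)
  expect_equal(names(cm$state0), names(m$state0))
  expect_equal(cm$state0, m$state0)
  set.seed(21)
  for (i in 1:8) {
    st <- c(V = runif(1, -95, 30), f = runif(1), n = runif(1),
            Cai = runif(1, 5e-5, 1e-3), Ki = runif(1, 115, 150), qK = 0)
    stim <- sample(c(0, -40), 1)
    r_ref <- toy_rhs(0, st, m$params, stim = stim)
    r_cm <- cm$rhs(0, st, cm$params[names(cm$params) %in%
                                      setdiff(names(cm$params),
                                              c("stim_amp", "stim_dur"))],
                   stim = stim)
    expect_equal(unname(r_cm$deriv[names(r_ref$deriv)]),
                 unname(r_ref$deriv), tolerance = 1e-10)
    expect_equal(ik_tot(r_cm$currents), ik_tot(r_ref$currents),
                 tolerance = 1e-10)
  }
})

test_that("an imported model integrates like the compiled one", {
  m <- toy_ventricular_model()
  f <- withr::local_tempfile(fileext = ".cellml")
  write_cellml(m, f)
  cm <- load_cellml_model(f, current_map = toy_map)
  st <- m$state0
  oc <- sim_segment(m, st, 1, 500, times = seq(0, 500, by = 10))
  or <- sim_segment(cm, st, 1, 500, times = seq(0, 500, by = 10))
  expect_lt(max(abs(oc[, "V"] - or[, "V"])), 1e-4)
})

test_that("a current map naming unknown variables is rejected", {
  m <- toy_ventricular_model()
  f <- withr::local_tempfile(fileext = ".cellml")
  write_cellml(m, f)
  expect_error(load_cellml_model(f, current_map = c(INaK = "I_not_there")),
               "I_not_there")
  expect_error(load_cellml_model("no/such/file.cellml"), "no such file")
})

# Minimal constant-potassium model written in code: dV/dt = -G_L*(V - E_K)
# with Ki a parameter, plus pump and rectifier variables for the budget.
const_ki_cellml <- function(path) {
  writeLines(c(
    '<?xml version="1.0"?>',
    '<model name="const_ki" xmlns="http://www.cellml.org/cellml/1.1#">',
    '  <component name="main">',
    '    <variable name="time"/>',
    '    <variable name="V" initial_value="-80"/>',
    '    <variable name="Ki" initial_value="140"/>',
    '    <variable name="Ko" initial_value="5.4"/>',
    '    <variable name="G_L" initial_value="0.1"/>',
    '    <variable name="Istim" initial_value="0"/>',
    '    <variable name="EK"/>',
    '    <variable name="IK1"/>',
    '    <variable name="INaK"/>',
    '    <math xmlns="http://www.w3.org/1998/Math/MathML">',
    '      <apply><eq/><ci>EK</ci><apply><times/><cn>26.71</cn><apply><ln/><apply><divide/><ci>Ko</ci><ci>Ki</ci></apply></apply></apply></apply>',
    '      <apply><eq/><ci>IK1</ci><apply><times/><ci>G_L</ci><apply><minus/><ci>V</ci><ci>EK</ci></apply></apply></apply>',
    '      <apply><eq/><ci>INaK</ci><cn>0.2</cn></apply>',
    '      <apply><eq/><apply><diff/><bvar><ci>time</ci></bvar><ci>V</ci></apply><apply><minus/><apply><plus/><ci>IK1</ci><ci>INaK</ci><ci>Istim</ci></apply></apply></apply>',
    '    </math>',
    '  </component>',
    '</model>'), path)
  path
}

test_that("potassium augmentation promotes the parameter to a state", {
  f <- withr::local_tempfile(fileext = ".cellml")
  const_ki_cellml(f)
  cm <- load_cellml_model(f, current_map = c(IK1 = "IK1", INaK = "INaK"))
  expect_equal(length(cm$state0), 1)
  expect_true("Ki" %in% names(cm$params))
  aug <- add_ki_dynamics(cm, "Ki", kappa = 6e-5)
  expect_equal(length(aug$state0), 2)           # exactly one more state
  expect_false("Ki" %in% names(aug$params))
  expect_equal(unname(aug$state0[["Ki"]]), 140)
  # the added derivative follows the budget: dKi = -kappa * (IK1 - 2*INaK)
  st <- c(V = -80, Ki = 140)
  r <- aug$rhs(0, st, aug$params[setdiff(names(aug$params),
                                         c("stim_amp", "stim_dur"))])
  EK <- 26.71 * log(5.4 / 140)
  IK1 <- 0.1 * (-80 - EK)
  expect_equal(unname(r$deriv[["Ki"]]), -6e-5 * (IK1 - 2 * 0.2),
               tolerance = 1e-12)
})

test_that("augmentation requires the pump in the current map", {
  f <- withr::local_tempfile(fileext = ".cellml")
  const_ki_cellml(f)
  cm <- load_cellml_model(f, current_map = c(IK1 = "IK1"))
  expect_error(add_ki_dynamics(cm, "Ki", kappa = 6e-5), "INaK")
  cm2 <- load_cellml_model(f, current_map = c(IK1 = "IK1", INaK = "INaK"))
  expect_error(add_ki_dynamics(cm2, "NotAParam", kappa = 1), "NotAParam")
})
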