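#' Toy ventricular cell model
#'
#' A deliberately small ventricular action-potential model with five membrane
#' currents, intracellular calcium and potassium dynamics, built so every
#' stage of the calibration pipeline is testable without external model
#' files.  States: membrane potential `V` (mV), L-type calcium inactivation
#' gate `f`, delayed-rectifier activation gate `n`, `Cai` (mM), `Ki` (mM) and
#' a bookkeeping state `qK`, the running integral of the total potassium
#' current (ms*pA/pF), which makes per-beat potassium budgets exact to solver
#' tolerance.
#'
#' Currents: an L-type-like calcium current `I_Ca` (instantaneous activation
#' `d_inf`, gated inactivation `f`), a delayed-rectifier potassium current
#' `I_K`, an inward-rectifier `I_K1`, a sodium-potassium pump `I_NaK`, a
#' plateau potassium current `I_Kp`, and a background chloride leak
#' `I_Clbk = G_Clbk*(V - E_Clbk)`.  The leak holds the resting potential
#' slightly above the potassium Nernst potential so that the resting
#' inward-rectifier current is outward and one-cycle potassium balance is
#' attainable — the same structural role the background chloride current
#' plays in published human ventricular models.  Intracellular potassium
#' follows `dKi/dt = -kappa_K * I_K,tot` with
#' `I_K,tot = I_K + I_K1 + I_Kp - 2*I_NaK + I_stim`.
#'
#' The default stimulus is -40 pA/pF for 2 ms, the smallest round pulse that
#' robustly triggers the calcium upstroke (the model has no fast sodium
#' current, so the stimulus itself must carry the membrane to about -10 mV
#' where `d_inf` activates).
#'
#' @param params named list/vector overriding default parameters.
#' @param use_compiled integrate through the compiled right-hand side
#'   (default); the pure-R right-hand side [toy_rhs()] is always available
#'   and is asserted identical in the tests.
#' @return an object of class `ionic_model`.
#' @export
toy_ventricular_model <- function(params = NULL, use_compiled = TRUE) {
  p <- c(G_Ca = 0.18, G_K = 0.12, G_K1 = 0.30, G_NaK = 1.4, G_Kp = 0.010,
         G_Clbk = 0.031, E_Clbk = -30,
         tau_f = 150, tau_n = 250, tau_Ca = 60,
         k_conv = 1.5e-6, kappa_K = 6.0e-5,
         Ko = 5.4, Ca_rest = 1e-4, E_Ca = 60,
         stim_amp = -40, stim_dur = 2)
  if (!is.null(params)) {
    params <- unlist(params)
    unknown <- setdiff(names(params), names(p))
    if (length(unknown))
      stop("toy_ventricular_model: unknown parameter(s): ",
           paste(unknown, collapse = ", "))
    p[names(params)] <- params
  }
  structure(list(
    name = "toy_ventricular",
    state0 = c(V = -86, f = 1, n = 0, Cai = 1e-4, Ki = 138, qK = 0),
    params = p,
    conductances = c("G_Ca", "G_K", "G_K1", "G_NaK", "G_Kp", "G_Clbk"),
    Ko_param = "Ko",
    atol = c(V = 1e-6, f = 1e-9, n = 1e-9, Cai = 1e-9, Ki = 1e-9, qK = 1e-6),
    rtol = 1e-6,
    rhs = toy_rhs,
    currents_fun = toy_currents,
    compiled = if (use_compiled)
      list(dllname = "condcal", func = "toy_derivs", initfunc = "toy_init")),
    class = "ionic_model")
}

#' Toy model right-hand side (reference R implementation)
#'
#' Pure-R evaluation of the toy model equations; the compiled version used
#' for integration must agree with this function to near machine precision.
#'
#' @param t time (ms); only used for the stimulus window when `stim` is NULL.
#' @param state named state vector (`V`, `f`, `n`, `Cai`, `Ki`, optionally
#'   `qK`).
#' @param params named parameter vector as in [toy_ventricular_model()].
#' @param stim stimulus current density (pA/pF) at this instant; 0 when
#'   unstimulated.
#' @return `list(deriv, currents)` with the named derivative vector and a
#'   [currents_record()].
#' @export
toy_rhs <- function(t, state, params, stim = 0) {
  V <- state[["V"]]; f <- state[["f"]]; n <- state[["n"]]
  Cai <- state[["Cai"]]; Ki <- state[["Ki"]]
  p <- params
  if (Ki <= 0 || p[["Ko"]] <= 0)
    stop("toy_rhs: potassium concentrations must be positive (Nernst log)")
  EK <- 26.71 * log(p[["Ko"]] / Ki)
  dinf <- 1 / (1 + exp(-(V + 10) / 6))
  finf <- 1 / (1 + exp((V + 25) / 6))
  ninf <- 1 / (1 + exp(-(V - 5) / 9))
  k1inf <- 1 / (1 + exp((V - EK - 12) / 12))
  ICa <- p[["G_Ca"]] * dinf * f * (V - p[["E_Ca"]])
  IK <- p[["G_K"]] * n * (V - EK)
  IK1 <- p[["G_K1"]] * k1inf * (V - EK)
  INaK <- p[["G_NaK"]] * (p[["Ko"]] / (p[["Ko"]] + 1.5)) /
    (1 + exp(-(V + 80) / 25))
  IKp <- p[["G_Kp"]] * (V - EK) / (1 + exp((7.488 - V) / 5.98))
  IClbk <- p[["G_Clbk"]] * (V - p[["E_Clbk"]])
  cr <- currents_record(IKr = IK, IK1 = IK1, INaK = INaK, IKp = IKp,
                        ICaL = ICa, IClbk = IClbk, Istim = stim)
  IKtot <- ik_tot(cr)
  deriv <- c(V = -(ICa + IK + IK1 + INaK + IKp + IClbk + stim),
             f = (finf - f) / p[["tau_f"]],
             n = (ninf - n) / p[["tau_n"]],
             Cai = -p[["k_conv"]] * ICa - (Cai - p[["Ca_rest"]]) / p[["tau_Ca"]],
             Ki = -p[["kappa_K"]] * IKtot,
             qK = IKtot)
  list(deriv = deriv, currents = cr)
}

#' Vectorized toy-model currents on a simulated trajectory
#'
#' @param states matrix/data frame with columns `V`, `f`, `n`, `Cai`, `Ki`.
#' @param params toy parameter vector.
#' @param stim stimulus current at each row (scalar or vector).
#' @return data frame of current densities with the standard slot names.
#' @export
toy_currents <- function(states, params, stim = 0) {
  V <- states[, "V"]; n <- states[, "n"]; f <- states[, "f"]
  Ki <- states[, "Ki"]
  p <- params
  EK <- 26.71 * log(p[["Ko"]] / Ki)
  dinf <- 1 / (1 + exp(-(V + 10) / 6))
  k1inf <- 1 / (1 + exp((V - EK - 12) / 12))
  data.frame(
    ICaL = p[["G_Ca"]] * dinf * f * (V - p[["E_Ca"]]),
    IKr = p[["G_K"]] * n * (V - EK),
    IK1 = p[["G_K1"]] * k1inf * (V - EK),
    INaK = p[["G_NaK"]] * (p[["Ko"]] / (p[["Ko"]] + 1.5)) /
      (1 + exp(-(V + 80) / 25)),
    IKp = p[["G_Kp"]] * (V - EK) / (1 + exp((7.488 - V) / 5.98)),
    IClbk = p[["G_Clbk"]] * (V - p[["E_Clbk"]]),
    Istim = stim)
}

#' Apply scaled conductances to a model
#'
#' Returns an independent copy of the model in which each decision
#' conductance is set to `G0 * 10^(x/20)`; all other parameters are left
#' untouched.
#'
#' @param model an `ionic_model`.
#' @param x scaled conductance vector (one entry per decision variable).
#' @param space the [decision_space()] naming the conductances and their
#'   baselines `G0`.
#' @return the configured model.
#' @export
apply_conductances <- function(model, x, space) {
  stopifnot(inherits(model, "ionic_model"), inherits(space, "decision_space"))
  unknown <- setdiff(space$names, names(model$params))
  if (length(unknown))
    stop("apply_conductances: unknown conductance(s) ",
         paste(unknown, collapse = ", "), "; valid names: ",
         paste(intersect(model$conductances, names(model$params)),
               collapse = ", "))
  x <- rep_len(as.numeric(x), length(space$names))
  model$params[space$names] <- unscale_conductance(x, unname(space$G0))
  model
}

#' Set the extracellular potassium level of a model
#'
#' @param model an `ionic_model`.
#' @param Ko new extracellular potassium concentration (mM, positive).
#' @return the configured model.
#' @export
set_ko <- function(model, Ko) {
  stopifnot(inherits(model, "ionic_model"), Ko > 0)
  model$params[[model$Ko_param]] <- Ko
  model
}

#' @export
print.ionic_model <- function(x, ...) {
  cat("Ionic model:", x$name, "(", length(x$state0), "states )\n")
  cat("  conductances:", paste(x$conductances, collapse = ", "), "\n")
  cat("  integration:", if (!is.null(x$compiled)) "compiled" else "R", "\n")
  invisible(x)
}
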