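## Synthetic generators and oracle problems.  Everything here is
## deterministic given seeds and built in code; the generators define the
## study conditions the tests and the acceptance checks run under.

#' Analytic constrained test problem
#'
#' A closed-form optimization problem structurally mirroring the
#' conductance-calibration problem: a quartic objective
#' `f(x) = (1 + 0.5*x1 - 0.3*x2)^4` (a squared squared-integral analogue,
#' flat-bottomed along a line), two marker functions
#' `m1 = 300 + 10*x1 + 5*x2 + x1*x2` with band `[280, 310]` and
#' `m2 = 80 - 4*x1 + 2*x2^2` with band `[44, 112]`, and bounds
#' `[-6.0206, 6.0206]^2`.  The baseline `x = 0` is feasible.
#'
#' @return list of class `analytic_problem`: `space`, `constraints`, `f`,
#'   `markers` (both vectorized over rows) and `evaluator` satisfying the
#'   [run_optimization()] contract.
#' @export
analytic_problem <- function() {
  space <- decision_space(c("x1", "x2"), c(1, 1))
  constraints <- constraint_spec(c("m1", "m2"), c(280, 44), c(310, 112))
  f <- function(X) {
    X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
    (1 + 0.5 * X[, 1] - 0.3 * X[, 2])^4
  }
  markers <- function(X) {
    X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
    cbind(m1 = 300 + 10 * X[, 1] + 5 * X[, 2] + X[, 1] * X[, 2],
          m2 = 80 - 4 * X[, 1] + 2 * X[, 2]^2)
  }
  structure(list(space = space, constraints = constraints, f = f,
                 markers = markers,
                 evaluator = function(X) list(f = f(X), M = markers(X))),
            class = "analytic_problem")
}

#' Brute-force grid oracle for a closed-form problem
#'
#' Exhaustively evaluates the true objective on a uniform grid over the
#' bounds, keeps the feasible points (all markers inside their bands) and
#' returns the best.  Serves as ground truth for [run_optimization()];
#' refining the resolution can never increase the reported optimum.
#'
#' @param problem an [analytic_problem()]-like list (`space`, `f`, and
#'   optionally `constraints` + `markers`).
#' @param resolution grid spacing in scaled units.
#' @return list: `x_opt`, `f_opt`, `n_feasible`, `n_grid`.
#' @export
grid_oracle <- function(problem, resolution = 1e-3) {
  stopifnot(resolution > 0)
  sp <- problem$space
  n <- length(sp$names)
  axes <- lapply(seq_len(n), function(i)
    seq(sp$xL[i], sp$xU[i], by = resolution))
  if (n != 2)
    stop("grid_oracle: implemented for two-variable problems")
  x2 <- axes[[2]]
  best_f <- Inf; best_x <- NULL; n_feas <- 0
  block <- 64L
  i <- 1L
  n1 <- length(axes[[1]])
  while (i <= n1) {
    x1 <- axes[[1]][i:min(n1, i + block - 1L)]
    X <- cbind(rep(x1, each = length(x2)), rep(x2, length(x1)))
    keep <- rep(TRUE, nrow(X))
    if (!is.null(problem$constraints)) {
      M <- problem$markers(X)
      cs <- problem$constraints
      for (j in seq_along(cs$names))
        keep <- keep & M[, j] >= cs$mLL[j] & M[, j] <= cs$mUU[j]
    }
    n_feas <- n_feas + sum(keep)
    if (any(keep)) {
      fv <- problem$f(X[keep, , drop = FALSE])
      w <- which.min(fv)
      if (fv[w] < best_f) { best_f <- fv[w]; best_x <- X[keep, , drop = FALSE][w, ] }
    }
    i <- i + block
  }
  if (is.null(best_x))
    stop("grid_oracle: no feasible point at this resolution")
  list(x_opt = setNames(best_x, sp$names), f_opt = best_f,
       n_feasible = n_feas, n_grid = prod(lengths(axes)))
}

#' Synthetic action-potential trace with closed-form markers
#'
#' A piecewise AP: resting potential until the stimulus onset, an
#' instantaneous rise to the peak, a linear fall back to rest over
#' `fall_ms`, and rest until the cycle ends.  By construction
#' `APD_q = q * fall_ms` for any repolarization fraction `q` (linear
#' interpolation is exact on the ramp).  The calcium transient is
#' `Ca_rest + Ca_amp * (s/50) * exp(1 - s/50)` (s = ms since onset), whose
#' maximum `Ca_rest + Ca_amp` occurs at s = 50.
#'
#' @param peak,rest peak and resting potential, mV.
#' @param fall_ms duration of the linear repolarization ramp.
#' @param onset stimulus time on the trace clock, ms.
#' @param CL cycle length, ms.
#' @param dt sample spacing, ms.
#' @param ca include the calcium transient?
#' @param Ca_rest,Ca_amp calcium baseline and amplitude, mM.
#' @return an [ap_trace()].
#' @export
make_synthetic_trace <- function(peak = 40, rest = -85, fall_ms = 300,
                                 onset = 10, CL = 1000, dt = 0.5,
                                 ca = TRUE, Ca_rest = 1e-4, Ca_amp = 6e-4) {
  if (peak <= rest) stop("make_synthetic_trace: need peak > rest")
  time <- sort(unique(c(seq(0, CL, by = dt), onset, onset + fall_ms)))
  s <- time - onset
  V <- ifelse(s < 0, rest,
              ifelse(s <= fall_ms, peak - (peak - rest) * s / fall_ms, rest))
  Cai <- if (ca)
    ifelse(s < 0, Ca_rest, Ca_rest + Ca_amp * (s / 50) * exp(1 - s / 50))
  ap_trace(time, V, Cai = Cai, CL = CL, stim_onset = onset, stim_dur = 1)
}

#' Synthetic biexponential APD-adaptation beat series
#'
#' `apd90(t) = y_inf + A_fast*exp(-t/tau_fast) + A_slow*exp(-t/tau_slow)`
#' sampled at a fixed beat spacing with optional additive Gaussian noise;
#' bitwise-reproducible for a fixed seed (the global RNG state is restored).
#'
#' @param y_inf,A_fast,tau_fast,A_slow,tau_slow curve parameters (times in
#'   seconds, amplitudes in ms); requires `tau_fast < tau_slow`.
#' @param sigma noise standard deviation, ms.
#' @param seed RNG seed used when `sigma > 0`.
#' @param spacing beat spacing, s.
#' @param duration series length, s.
#' @return data frame with columns `t` (s) and `apd90` (ms).
#' @export
make_adaptation_series <- function(y_inf = 250, A_fast = 15, tau_fast = 10,
                                   A_slow = 25, tau_slow = 90, sigma = 0,
                                   seed = NULL, spacing = 0.6,
                                   duration = 480) {
  if (tau_fast >= tau_slow)
    stop("make_adaptation_series: need tau_fast < tau_slow")
  t <- seq(0, duration, by = spacing)
  y <- y_inf + A_fast * exp(-t / tau_fast) + A_slow * exp(-t / tau_slow)
  if (sigma > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
    }
    y <- y + rnorm(length(t), 0, sigma)
  }
  data.frame(t = t, apd90 = y)
}

#' Toy-model conductance-calibration scenario
#'
#' The desk-scale analogue of the full calibration workflow: baseline
#' markers of the toy ventricular model are computed once, the admissible
#' marker bands are set to baseline +/-10% (+/-15% for calcium levels), the
#' model's conductances are then perturbed (default: `G_K1` x1.3 and `G_Ca`
#' x0.85, which breaks one-cycle potassium balance), and the returned
#' problem asks the optimizer to drive the squared one-cycle integral of
#' the total potassium current back toward zero subject to the bands, with
#' decision variables `G_Ca`, `G_K`, `G_K1`, `G_NaK`.
#'
#' The scaling baselines `G0` are the perturbed conductances, so the
#' optimizer starts at `x = 0` (the broken model).  The slow
#' rate-adaptation constant is not among the constraints: the toy model has
#' no identifiable slow adaptation component (its fitted slow amplitude is
#' far below the 1 ms identifiability threshold), so the band would be
#' meaningless; the adaptation machinery is exercised on synthetic series
#' instead.
#'
#' @param perturbation named positive multipliers applied to the baseline
#'   conductances.
#' @param n_beats steady-state beat count per protocol (300 in the
#'   desk-scale profile; 3000 reproduces the reference protocol).
#' @param band_frac,ca_band_frac relative half-widths of the marker bands.
#' @param trust [trust_region_params()] for the problem.
#' @param workers evaluator workers.
#' @return list of class `toy_scenario`: `problem`, `evaluator`,
#'   `baseline_markers`, `baseline_integral`, `model` (perturbed),
#'   `model_baseline`.
#' @export
make_toy_scenario <- function(perturbation = c(G_K1 = 1.3, G_Ca = 0.85),
                              n_beats = 300, band_frac = 0.10,
                              ca_band_frac = 0.15,
                              trust = trust_region_params(),
                              workers = 1L) {
  if (any(perturbation <= 0))
    stop("make_toy_scenario: perturbation multipliers must be positive")
  base <- toy_ventricular_model()
  if (length(setdiff(names(perturbation), names(base$params))))
    stop("make_toy_scenario: unknown conductance in perturbation")
  ref <- .point_markers(base, n_beats, n_beats)
  mk <- ref$markers
  frac <- ifelse(grepl("^ca_", names(mk)), ca_band_frac, band_frac)
  lo <- mk - frac * abs(mk)
  hi <- mk + frac * abs(mk)
  constraints <- constraint_spec(names(mk), lo, hi)

  pert <- base
  pert$params[names(perturbation)] <-
    pert$params[names(perturbation)] * perturbation
  chk <- steady_state_pacing(pert, 1000, n_beats = 3,
                             per_beat_markers = FALSE, final_out_dt = 0.5)
  if (!chk$capture)
    stop("make_toy_scenario: perturbed model is inexcitable")

  vars <- c("G_Ca", "G_K", "G_K1", "G_NaK")
  space <- decision_space(vars, unname(pert$params[vars]))
  evaluator <- batch_evaluator(pert, space, n_beats_1hz = n_beats,
                               n_beats_05hz = n_beats, workers = workers)
  problem <- optimization_problem(space, constraints, trust)
  structure(list(problem = problem, evaluator = evaluator,
                 baseline_markers = mk, baseline_integral = ref$integral,
                 model = pert, model_baseline = base,
                 n_beats = n_beats),
            class = "toy_scenario")
}
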