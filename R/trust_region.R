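#' Trust-region ratio of true to surrogate improvement
#'
#' `rho = (true_new - true_old) / (surr_new - surr_old)`.  A ratio near 1
#' means the surrogate predicted the change in the true function well.  When
#' the surrogate change is below the guard the ratio is defined as 1 if the
#' true change is also below the guard (both functions flat), otherwise as
#' signed infinity.
#'
#' @param true_old,true_new true function values at the iterate and candidate.
#' @param surr_old,surr_new surrogate values at the same points.
#' @param guard degenerate-denominator guard (default `1e-12`).
#' @return the ratio, possibly `Inf`/`-Inf`.
#' @export
trust_ratio <- function(true_old, true_new, surr_old, surr_new,
                        guard = 1e-12) {
  num <- true_new - true_old
  den <- surr_new - surr_old
  if (abs(den) < guard) {
    if (abs(num) < guard) return(1)
    return(sign(num) * Inf)
  }
  num / den
}

#' Step acceptance test
#'
#' A candidate is accepted when the objective trust ratio is positive and
#' either (i) the true constraints are all feasible at the candidate, or
#' (ii) every constraint trust ratio lies within `rho_L` of 1 (the surrogate
#' constraints are trustworthy even though the point is infeasible).
#'
#' @param rho0 objective trust ratio.
#' @param rho_constraints numeric vector of marker trust ratios (may be
#'   empty).
#' @param g_true transformed true constraint values at the candidate
#'   (feasible when all `<= 0`; may be empty).
#' @param rho_L acceptance band half-width, default 0.25.
#' @return logical flag: accept the step?
#' @export
accept_step <- function(rho0, rho_constraints = numeric(), g_true = numeric(),
                        rho_L = 0.25) {
  if (!is.finite(rho0) && is.nan(rho0)) return(FALSE)
  rho0 > 0 && (all(g_true <= 0) || all(abs(rho_constraints - 1) <= rho_L))
}

#' Trust-region radius update
#'
#' Rejected steps shrink the radius to `0.25 * delta`; accepted interior
#' steps keep it; accepted steps that hit the trust-region boundary double
#' it, capped at `delta_max`.
#'
#' @param delta current radius (> 0).
#' @param accepted logical acceptance flag.
#' @param on_boundary logical: did the step reach the trust-region boundary
#'   (infinity norm equal to `delta`)?
#' @param delta_max radius cap.
#' @return the next radius.
#' @export
update_radius <- function(delta, accepted, on_boundary, delta_max = Inf) {
  stopifnot(delta > 0)
  if (!accepted) return(0.25 * delta)
  if (!on_boundary) return(delta)
  min(2 * delta, delta_max)
}
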