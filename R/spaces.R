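#' Decision space of scaled conductances
#'
#' Describes which conductances the optimizer may move, their baseline values
#' (the `G0` of the scaling `x = 20*log10(G/G0)`) and box bounds in scaled
#' units.  The default bounds `[-6.0206, 6.0206]` allow each conductance to
#' range between half and twice its baseline.
#'
#' @param names character vector of unique conductance identifiers; these must
#'   match parameter names of the model being calibrated.
#' @param G0 positive baseline conductances, recycled to `length(names)`.
#' @param xL,xU lower/upper bounds in scaled units, recycled; `xL < xU`.
#' @return an object of class `decision_space`.
#' @export
decision_space <- function(names, G0, xL = -20 * log10(2), xU = 20 * log10(2)) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("decision_space: 'names' must be unique")
  n <- length(names)
  G0 <- rep_len(as.numeric(G0), n)
  xL <- rep_len(as.numeric(xL), n)
  xU <- rep_len(as.numeric(xU), n)
  if (any(!is.finite(G0)) || any(G0 <= 0))
    stop("decision_space: 'G0' must be positive")
  if (any(xL >= xU)) stop("decision_space: need xL < xU elementwise")
  structure(list(names = names, G0 = setNames(G0, names),
                 xL = setNames(xL, names), xU = setNames(xU, names)),
            class = "decision_space")
}

#' @export
print.decision_space <- function(x, ...) {
  cat("Decision space (", length(x$names), " scaled conductances)\n", sep = "")
  print(data.frame(G0 = x$G0, xL = x$xL, xU = x$xU))
  invisible(x)
}

#' Marker constraint bands
#'
#' Admissible ranges for the constrained electrophysiological markers.  Bands
#' `[lower, upper]` are stored together with the derived center
#' `mCR = (upper+lower)/2` and half-range `mRR = (upper-lower)/2` used by
#' [constraint_transform()].
#'
#' @param names character vector of marker names.
#' @param lower,upper numeric band limits, `lower < upper` elementwise.
#' @return an object of class `constraint_spec`.
#' @export
constraint_spec <- function(names, lower, upper) {
  names <- as.character(names)
  n <- length(names)
  lower <- rep_len(as.numeric(lower), n)
  upper <- rep_len(as.numeric(upper), n)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("constraint_spec: need finite lower < upper elementwise")
  structure(list(names = names,
                 mLL = setNames(lower, names), mUU = setNames(upper, names),
                 mCR = setNames((upper + lower) / 2, names),
                 mRR = setNames((upper - lower) / 2, names)),
            class = "constraint_spec")
}

#' @export
print.constraint_spec <- function(x, ...) {
  cat("Marker constraints (", length(x$names), ")\n", sep = "")
  print(data.frame(lower = x$mLL, upper = x$mUU, center = x$mCR,
                   half_range = x$mRR))
  invisible(x)
}

#' Trust-region management parameters
#'
#' @param delta0 initial trust-region radius (scaled units).
#' @param delta_max radius cap.
#' @param rho_L half-width of the acceptance band for constraint trust ratios
#'   (`|rho_j - 1| <= rho_L`); 0.25 by default.
#' @param tol_step solution tolerance: stop when an accepted step is shorter
#'   than this.
#' @param tol_grad gradient tolerance on the surrogate Lagrangian.
#' @param tol_radius stop when the radius falls below this.
#' @param max_iterations iteration cap.
#' @param ratio_guard degenerate-denominator guard for trust ratios.
#' @return an object of class `trust_region_params`.
#' @export
trust_region_params <- function(delta0 = 2.0, delta_max = 6.0, rho_L = 0.25,
                                tol_step = 1e-3, tol_grad = 1e-3,
                                tol_radius = 1e-3, max_iterations = 20L,
                                ratio_guard = 1e-12) {
  stopifnot(delta0 > 0, delta0 <= delta_max, rho_L > 0, rho_L < 1,
            tol_step > 0, tol_grad > 0, tol_radius > 0, max_iterations >= 1)
  structure(list(delta0 = delta0, delta_max = delta_max, rho_L = rho_L,
                 tol_step = tol_step, tol_grad = tol_grad,
                 tol_radius = tol_radius,
                 max_iterations = as.integer(max_iterations),
                 ratio_guard = ratio_guard),
            class = "trust_region_params")
}
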