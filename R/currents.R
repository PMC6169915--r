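.current_slots <- c("Ito", "IKr", "IKs", "IK1", "INaK", "ICaK", "IKp",
                    "Istim", "ICaL", "Incx", "IClbk")

#' Membrane current record
#'
#' A named vector of current densities (pA/pF) with fixed slots for the
#' currents entering the potassium budget plus the other standard membrane
#' currents; absent currents are zero.
#'
#' @param ... named current densities; unknown names are kept as
#'   model-specific extras.
#' @return a named numeric vector of class `currents_record`.
#' @export
currents_record <- function(...) {
  args <- c(...)
  out <- setNames(numeric(length(.current_slots)), .current_slots)
  if (length(args)) {
    if (is.null(names(args)) || any(names(args) == ""))
      stop("currents_record: all currents must be named")
    out[names(args)] <- args
  }
  structure(out, class = "currents_record")
}

#' Total potassium current density
#'
#' Sums all potassium-carrying currents and the stimulus current:
#' `I_K,tot = Ito + IKr + IKs + IK1 - 2*INaK + ICaK + IKp + Istim`.
#' The sodium–potassium pump imports two potassium ions per cycle, hence the
#' factor -2; the stimulus charge is assigned to potassium so that pacing
#' does not create an artefactual ion drift.
#'
#' Accepts a single [currents_record()] (returns a scalar) or a data frame /
#' matrix of current time series (returns a vector).
#'
#' @param currents a `currents_record`, or a data frame/matrix with columns
#'   named after the current slots (missing columns contribute zero).
#' @return total potassium current density, pA/pF.
#' @export
ik_tot <- function(currents) {
  get0 <- function(nm) {
    if (is.data.frame(currents) || is.matrix(currents)) {
      if (nm %in% colnames(currents)) currents[, nm] else 0
    } else {
      if (nm %in% names(currents)) unname(currents[[nm]]) else 0
    }
  }
  get0("Ito") + get0("IKr") + get0("IKs") + get0("IK1") - 2 * get0("INaK") +
    get0("ICaK") + get0("IKp") + get0("Istim")
}

#' Intracellular potassium derivative from the total potassium current
#'
#' `d[K+]i/dt = -IKtot * Cmem / (Vmyo * Frdy)`: a net outward (positive)
#' potassium current lowers the intracellular concentration.
#'
#' @param IKtot total potassium current density, pA/pF.
#' @param Cmem membrane capacitance.
#' @param Vmyo bulk cytosol volume.
#' @param Frdy Faraday constant.
#' @return d\[K+\]i/dt in mM/ms (for consistent units of the constants).
#' @export
ki_derivative <- function(IKtot, Cmem, Vmyo, Frdy) {
  if (Vmyo <= 0 || Frdy <= 0)
    stop("ki_derivative: 'Vmyo' and 'Frdy' must be positive")
  -IKtot * Cmem / (Vmyo * Frdy)
}
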