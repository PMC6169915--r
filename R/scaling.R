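#' Conductance scaling between natural and decibel-like units
#'
#' Decision variables are carried in the dimensionless scaled form
#' `x = 20 * log10(G / G0)`, so that conductances differing by orders of
#' magnitude share a common scale: `x = 0` is the baseline, `x = +6.0206`
#' doubles a conductance and `x = -6.0206` halves it.
#'
#' @param G conductance value(s), natural model units; must be positive.
#' @param G0 baseline conductance(s), same units; must be positive.
#' @param x scaled value(s).
#' @return `scale_conductance` returns the scaled value(s) `x`;
#'   `unscale_conductance` returns conductance(s) `G0 * 10^(x/20)`.
#' @examples
#' scale_conductance(2, 1)        # ~ 6.0206
#' unscale_conductance(-20, 1)    # 0.1
#' @export
scale_conductance <- function(G, G0) {
  if (any(!is.finite(G)) || any(G <= 0))
    stop("scale_conductance: 'G' must be positive and finite")
  if (any(!is.finite(G0)) || any(G0 <= 0))
    stop("scale_conductance: 'G0' must be positive and finite")
  20 * log10(G / G0)
}

#' @rdname scale_conductance
#' @export
unscale_conductance <- function(x, G0) {
  if (any(!is.finite(G0)) || any(G0 <= 0))
    stop("unscale_conductance: 'G0' must be positive and finite")
  G0 * 10^(x / 20)
}

#' Transform a marker value into a normalized inequality constraint
#'
#' Maps a marker with admissible band `[mCR - mRR, mCR + mRR]` into
#' `g = |m - mCR| / mRR - 1`, so that `g <= 0` exactly when the marker lies
#' inside its band, `g = -1` at the band center and `g = 0` on the edges.
#'
#' @param m marker value(s).
#' @param mCR band center.
#' @param mRR band half-range; must be positive.
#' @return the constraint value(s) `g`.
#' @export
constraint_transform <- function(m, mCR, mRR) {
  if (any(!is.finite(mRR)) || any(mRR <= 0))
    stop("constraint_transform: 'mRR' must be positive")
  abs(m - mCR) / mRR - 1
}
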