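#' Full factorial sampling database
#'
#' Generates the `levels^n` Cartesian grid of equally spaced values per axis
#' spanning `[center_i - half_width, center_i + half_width]`, clipped to the
#' global bounds of the decision space.  With an odd number of levels the grid
#' contains the center point.  This is the sampling design on which the
#' response surfaces are fitted; with the infinity-norm trust region the
#' database and the trust region coincide geometrically.
#'
#' @param space a [decision_space()].
#' @param center numeric vector, scaled units; the current iterate.
#' @param half_width positive trust-region radius.
#' @param levels number of levels per axis (>= 2); 3 by default.
#' @return a numeric matrix with `levels^n` rows and one column per variable.
#' @examples
#' sp <- decision_space(c("a", "b"), c(1, 1))
#' nrow(full_factorial(sp, c(0, 0), 1))  # 9
#' @export
full_factorial <- function(space, center, half_width, levels = 3L) {
  stopifnot(inherits(space, "decision_space"))
  levels <- as.integer(levels)
  if (levels < 2L) stop("full_factorial: 'levels' must be >= 2")
  if (!is.finite(half_width) || half_width <= 0)
    stop("full_factorial: 'half_width' must be positive")
  n <- length(space$names)
  center <- rep_len(as.numeric(center), n)
  axes <- lapply(seq_len(n), function(i) {
    v <- seq(center[i] - half_width, center[i] + half_width,
             length.out = levels)
    pmin(pmax(v, space$xL[i]), space$xU[i])
  })
  X <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(X) <- list(NULL, space$names)
  X
}
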