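#' @keywords internal
#' @noRd
quad_term_index <- function(n) {
  # column order of the full quadratic basis: 1, z_i, z_i^2, z_i*z_j (i<j)
  cross <- if (n >= 2) t(utils::combn(n, 2)) else matrix(0L, 0, 2)
  list(n_coef = 1L + 2L * n + nrow(cross), cross = cross)
}

#' @keywords internal
#' @noRd
quad_design <- function(Z) {
  n <- ncol(Z)
  ti <- quad_term_index(n)
  D <- cbind(1, Z, Z^2)
  if (nrow(ti$cross)) {
    cr <- vapply(seq_len(nrow(ti$cross)), function(k)
      Z[, ti$cross[k, 1]] * Z[, ti$cross[k, 2]], numeric(nrow(Z)))
    D <- cbind(D, matrix(cr, nrow = nrow(Z)))
  }
  vn <- colnames(Z)
  if (is.null(vn)) vn <- paste0("x", seq_len(n))
  colnames(D) <- c("(Intercept)", vn, paste0(vn, "^2"),
                   if (nrow(ti$cross))
                     paste0(vn[ti$cross[, 1]], ":", vn[ti$cross[, 2]]))
  D
}

#' Fit a full second-order polynomial response surface
#'
#' Ordinary least squares fit of the complete quadratic basis (intercept,
#' linear, pure quadratic and cross terms; `1 + 2n + n(n-1)/2` coefficients)
#' to scalar responses sampled on a database.  For conditioning, regressors
#' are centered on `center` and divided by `scale` before the solve; the
#' affine map is stored with the surface so evaluation is in original scaled
#' units.
#'
#' @param X sample matrix (rows = points, columns = variables), scaled units.
#' @param y numeric response vector, one value per row of `X`.
#' @param center centering point for conditioning; defaults to column means.
#' @param scale positive scalar divisor; defaults to the largest half-range
#'   of the sample.
#' @return an object of class `response_surface` with elements `beta`
#'   (named coefficients on the conditioned basis), `center`, `scale`, `n`.
#' @export
fit_quadratic_rsa <- function(X, y, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    stop("fit_quadratic_rsa: row count of 'X' and length of 'y' differ")
  n <- ncol(X)
  ti <- quad_term_index(n)
  if (nrow(X) < ti$n_coef)
    stop(sprintf("fit_quadratic_rsa: %d sample points cannot identify %d coefficients",
                 nrow(X), ti$n_coef))
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- max(apply(X, 2, function(v) diff(range(v)) / 2))
    if (!is.finite(scale) || scale <= 0) scale <- 1
  }
  Z <- sweep(X, 2, center) / scale
  colnames(Z) <- colnames(X)
  D <- quad_design(Z)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[-qrD$pivot[seq_len(qrD$rank)]]
    stop("fit_quadratic_rsa: rank-deficient design; unidentifiable terms: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrD, y)
  structure(list(beta = beta, center = as.numeric(center), scale = scale,
                 n = n, cross = ti$cross,
                 varnames = colnames(D)[2:(n + 1)]),
            class = "response_surface")
}

#' Evaluate a response surface
#'
#' @param object a `response_surface`.
#' @param x a numeric vector (one point) or matrix (rows = points).
#' @param ... unused.
#' @return predicted value(s).
#' @export
predict.response_surface <- function(object, x, ...) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  Z <- sweep(X, 2, object$center) / object$scale
  colnames(Z) <- object$varnames
  drop(quad_design(Z) %*% object$beta)
}

#' Analytic gradient of a response surface
#'
#' Differentiates the stored polynomial coefficients; no numerical
#' differentiation is involved.
#'
#' @param rs a `response_surface`.
#' @param x evaluation point (numeric vector, original scaled units).
#' @return the gradient vector with respect to `x`.
#' @export
rs_gradient <- function(rs, x) {
  n <- rs$n
  z <- (as.numeric(x) - rs$center) / rs$scale
  b_lin <- rs$beta[2:(n + 1)]
  b_quad <- rs$beta[(n + 2):(2 * n + 1)]
  g <- b_lin + 2 * b_quad * z
  if (nrow(rs$cross)) {
    b_cr <- rs$beta[(2 * n + 2):length(rs$beta)]
    for (k in seq_len(nrow(rs$cross))) {
      i <- rs$cross[k, 1]; j <- rs$cross[k, 2]
      g[i] <- g[i] + b_cr[k] * z[j]
      g[j] <- g[j] + b_cr[k] * z[i]
    }
  }
  unname(g) / rs$scale
}

#' Affine image of a response surface
#'
#' Returns the surface of `a * f(x) + b`; used to turn fitted marker surfaces
#' into normalized constraint surfaces without refitting.
#'
#' @param rs a `response_surface`.
#' @param a,b scalars.
#' @return a `response_surface`.
#' @export
rs_affine <- function(rs, a = 1, b = 0) {
  rs$beta <- rs$beta * a
  rs$beta[1] <- rs$beta[1] + b
  rs
}

#' @export
print.response_surface <- function(x, ...) {
  cat("Second-order response surface in", x$n, "variables\n")
  print(round(x$beta, 6))
  invisible(x)
}
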