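#' Solve the surrogate trust-region subproblem
#'
#' Minimizes a fitted objective surface subject to fitted constraint surfaces
#' `g_j(x) <= 0`, the trust-region box `|x - center|_inf <= radius` and the
#' global bounds of the decision space.  Quadratic surfaces can be nonconvex,
#' so a bound-constrained quasi-Newton solve (with analytic polynomial
#' gradients) is restarted from five deterministic points: the box center and
#' four corners chosen by a fixed alternating rule.  Inequality constraints
#' are handled by an augmented Lagrangian, whose multipliers are returned.
#'
#' If no point satisfying all surrogate constraints is found, the minimizer
#' of the aggregate constraint violation is returned and flagged infeasible.
#'
#' @param f_rsa objective `response_surface`.
#' @param g_rsa list of constraint `response_surface`s (`<= 0` convention);
#'   may be empty.
#' @param center current iterate (numeric vector, scaled units).
#' @param radius trust-region radius.
#' @param space a [decision_space()] providing global bounds.
#' @param feas_tol feasibility tolerance on surrogate constraints.
#' @return a list with `x` (the subproblem solution), `value` (surrogate
#'   objective there), `lambda` (multipliers, one per constraint surface),
#'   `feasible` (logical) and `max_violation`.
#' @export
solve_trust_subproblem <- function(f_rsa, g_rsa = list(), center, radius,
                                   space, feas_tol = 1e-6) {
  stopifnot(inherits(f_rsa, "response_surface"), radius > 0)
  n <- f_rsa$n
  center <- rep_len(as.numeric(center), n)
  lo <- pmax(unname(space$xL), center - radius)
  hi <- pmin(unname(space$xU), center + radius)
  if (any(lo > hi)) stop("solve_trust_subproblem: empty box (center outside bounds?)")

  starts <- .subproblem_starts(lo, hi, center)
  m <- length(g_rsa)

  fobj <- function(x) predict(f_rsa, x)
  fgrad <- function(x) rs_gradient(f_rsa, x)
  gvals <- function(x) if (m) vapply(g_rsa, predict, numeric(1), x = x) else numeric()

  if (m == 0L) {
    best <- NULL
    for (s in starts) {
      o <- optim(s, fobj, fgrad, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = 200, factr = 1e4))
      if (is.null(best) || o$value < best$value) best <- o
    }
    return(list(x = .clip(best$par, lo, hi), value = best$value,
                lambda = numeric(), feasible = TRUE, max_violation = 0))
  }

  run_alm <- function(x0) {
    lambda <- numeric(m)
    mu <- 10
    x <- x0
    viol_prev <- Inf
    for (outer in 1:15) {
      aug <- function(x) {
        g <- gvals(x)
        s <- pmax(0, lambda + mu * g)
        fobj(x) + sum(s^2 - lambda^2) / (2 * mu)
      }
      aug_grad <- function(x) {
        g <- gvals(x)
        s <- pmax(0, lambda + mu * g)
        gr <- fgrad(x)
        for (j in seq_len(m))
          if (s[j] > 0) gr <- gr + s[j] * rs_gradient(g_rsa[[j]], x)
        gr
      }
      o <- optim(x, aug, aug_grad, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = 200, factr = 1e4))
      x <- o$par
      g <- gvals(x)
      lambda <- pmax(0, lambda + mu * g)
      viol <- max(0, g)
      if (viol < 1e-9 && outer > 2) break
      if (viol > 0.25 * viol_prev) mu <- min(mu * 4, 1e8)
      viol_prev <- viol
    }
    list(x = .clip(x, lo, hi), value = fobj(x), lambda = lambda,
         max_violation = max(0, gvals(x)))
  }

  sols <- lapply(starts, run_alm)
  feas <- vapply(sols, function(s) s$max_violation <= feas_tol, logical(1))
  if (any(feas)) {
    vals <- vapply(sols, `[[`, numeric(1), "value")
    vals[!feas] <- Inf
    b <- sols[[which.min(vals)]]
    return(list(x = b$x, value = b$value, lambda = b$lambda, feasible = TRUE,
                max_violation = b$max_violation))
  }
  # no surrogate-feasible point found: minimize the aggregate violation
  vsq <- function(x) sum(pmax(0, gvals(x))^2)
  vsq_grad <- function(x) {
    g <- gvals(x)
    gr <- numeric(n)
    for (j in seq_len(m))
      if (g[j] > 0) gr <- gr + 2 * g[j] * rs_gradient(g_rsa[[j]], x)
    gr
  }
  best <- NULL
  for (s in starts) {
    o <- optim(s, vsq, vsq_grad, method = "L-BFGS-B", lower = lo, upper = hi,
               control = list(maxit = 200, factr = 1e4))
    if (is.null(best) || o$value < best$value) best <- o
  }
  lam <- sols[[which.min(vapply(sols, `[[`, numeric(1), "max_violation"))]]$lambda
  x <- .clip(best$par, lo, hi)
  list(x = x, value = fobj(x), lambda = lam, feasible = FALSE,
       max_violation = max(0, gvals(x)))
}

#' @keywords internal
#' @noRd
.subproblem_starts <- function(lo, hi, center) {
  n <- length(lo)
  alt1 <- ifelse(seq_len(n) %% 2 == 1, lo, hi)
  alt2 <- ifelse(seq_len(n) %% 2 == 1, hi, lo)
  starts <- list(.clip(center, lo, hi), lo, hi, alt1, alt2)
  unique(starts)
}

#' @keywords internal
#' @noRd
.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Analytic gradient of the surrogate Lagrangian
#'
#' Gradient of `phi(x) = f(x) + sum_j lambda_j * g_j(x)` evaluated from the
#' stored polynomial coefficients of the surfaces.  Used for the
#' gradient-based termination test.
#'
#' @param f_rsa objective `response_surface`.
#' @param g_rsa list of constraint (or marker) `response_surface`s.
#' @param lambda multipliers, one per surface in `g_rsa`.
#' @param x evaluation point.
#' @return the gradient vector.
#' @export
lagrangian_gradient <- function(f_rsa, g_rsa, lambda, x) {
  if (length(lambda) != length(g_rsa))
    stop("lagrangian_gradient: 'lambda' length must match 'g_rsa'")
  g <- rs_gradient(f_rsa, x)
  for (j in seq_along(g_rsa))
    g <- g + lambda[j] * rs_gradient(g_rsa[[j]], x)
  g
}
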