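#' Define a constrained conductance-calibration problem
#'
#' Bundles the decision space, marker constraint bands, trust-region
#' parameters, starting point and sampling design for [run_optimization()].
#'
#' @param space a [decision_space()].
#' @param constraints a [constraint_spec()] or `NULL` for an unconstrained
#'   problem.
#' @param trust a [trust_region_params()].
#' @param x0 starting point in scaled units (default: the baseline, all
#'   zeros).
#' @param levels factorial levels per axis for the database (default 3).
#' @return an object of class `optimization_problem`.
#' @export
optimization_problem <- function(space, constraints = NULL,
                                 trust = trust_region_params(),
                                 x0 = NULL, levels = 3L) {
  stopifnot(inherits(space, "decision_space"),
            is.null(constraints) || inherits(constraints, "constraint_spec"),
            inherits(trust, "trust_region_params"))
  n <- length(space$names)
  if (is.null(x0)) x0 <- numeric(n)
  x0 <- rep_len(as.numeric(x0), n)
  if (any(x0 < space$xL - 1e-12) || any(x0 > space$xU + 1e-12))
    stop("optimization_problem: 'x0' violates the bounds")
  structure(list(space = space, constraints = constraints, trust = trust,
                 x0 = setNames(x0, space$names), levels = as.integer(levels)),
            class = "optimization_problem")
}

#' @keywords internal
#' @noRd
.call_evaluator <- function(evaluator, X, marker_names) {
  ev <- evaluator(X)
  if (is.data.frame(ev)) ev <- list(f = ev$f, M = as.matrix(ev[marker_names]))
  f <- as.numeric(ev$f)
  M <- ev$M
  if (length(f) != nrow(X))
    stop("evaluator returned ", length(f), " objective values for ",
         nrow(X), " points")
  if (length(marker_names)) {
    M <- as.matrix(M)
    if (nrow(M) != nrow(X)) stop("evaluator marker rows do not match points")
    if (!is.null(colnames(M))) {
      missing <- setdiff(marker_names, colnames(M))
      if (length(missing))
        stop("evaluator is missing markers: ", paste(missing, collapse = ", "))
      M <- M[, marker_names, drop = FALSE]
    } else if (ncol(M) != length(marker_names)) {
      stop("evaluator marker columns do not match the constraint spec")
    }
  } else {
    M <- matrix(numeric(), nrow(X), 0)
  }
  list(f = f, M = M)
}

#' Run the trust-region response-surface optimization
#'
#' Executes the calibration loop: build a full factorial database around the
#' current iterate, fit second-order response surfaces for the objective and
#' every constrained marker, minimize the surrogate problem inside the trust
#' region, evaluate the true functions at the candidate, test the trust
#' ratios, accept or reject, update the radius, and stop on one of the
#' termination criteria (accepted step shorter than `tol_step`, surrogate
#' Lagrangian gradient below `tol_grad` after acceptance, radius below
#' `tol_radius`, or the iteration cap).
#'
#' The evaluator is called once with the whole database (a batch that may be
#' computed in parallel) and once with the single candidate point.  Database
#' points at which the evaluator returns non-finite values are dropped with a
#' warning; a candidate failure rejects the step.
#'
#' @param problem an [optimization_problem()].
#' @param evaluator `function(X)` mapping a matrix of scaled points (one row
#'   per point) to `list(f = <numeric>, M = <matrix>)`, where `M` has one
#'   column per constrained marker (named as in the constraint spec).
#' @param log_dir optional directory; when given, writes `iterations.csv`,
#'   per-iteration `database_<k>.csv` files, and `result.json`.
#' @param verbose print one line per iteration.
#' @return an object of class `rsa_optimization`: final scaled point and
#'   natural-unit conductances, termination reason, per-iteration records,
#'   final marker vector and an iteration log data frame.
#' @export
run_optimization <- function(problem, evaluator, log_dir = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(problem, "optimization_problem"))
  sp <- problem$space
  cs <- problem$constraints
  tr <- problem$trust
  n <- length(sp$names)
  mnames <- if (is.null(cs)) character() else cs$names
  m <- length(mnames)

  x_k <- unname(problem$x0)
  delta <- tr$delta0
  f_k <- NA_real_
  M_k <- setNames(rep(NA_real_, m), mnames)
  history <- list()
  termination <- NULL
  n_eval <- 0L

  if (!is.null(log_dir) && !dir.exists(log_dir))
    dir.create(log_dir, recursive = TRUE)

  for (k in seq_len(tr$max_iterations) - 1L) {
    ## Database around the current iterate (rebuilt after rejections too,
    ## with the shrunken radius)
    X <- full_factorial(sp, x_k, delta, problem$levels)
    if (!any(apply(X, 1, function(r) max(abs(r - x_k)) < 1e-12)))
      X <- rbind(X, x_k)
    X <- X[!duplicated(round(X, 12)), , drop = FALSE]
    ev <- .call_evaluator(evaluator, X, mnames)
    n_eval <- n_eval + nrow(X)
    ok <- is.finite(ev$f)
    if (m) ok <- ok & apply(ev$M, 1, function(r) all(is.finite(r)))
    if (!all(ok)) {
      warning(sum(!ok), " database point(s) dropped (evaluator failure)")
      X <- X[ok, , drop = FALSE]; ev$f <- ev$f[ok]
      ev$M <- ev$M[ok, , drop = FALSE]
    }
    if (!is.null(log_dir)) {
      db <- data.frame(X, f = ev$f, check.names = FALSE)
      if (m) db <- cbind(db, ev$M)
      write.csv(db, file.path(log_dir, sprintf("database_%02d.csv", k)),
                row.names = FALSE)
    }

    ic <- which(apply(X, 1, function(r) max(abs(r - x_k)) < 1e-12))[1]
    if (is.na(ic)) stop("iteration ", k, ": center point lost from database")
    f_k <- ev$f[ic]
    if (m) M_k <- setNames(ev$M[ic, ], mnames)

    ## Surrogates: objective + one surface per marker, conditioned on the box
    f_rsa <- fit_quadratic_rsa(X, ev$f, center = x_k, scale = delta)
    m_rsa <- lapply(seq_len(m), function(j)
      fit_quadratic_rsa(X, ev$M[, j], center = x_k, scale = delta))
    g_rsa <- list()
    if (m) {
      for (j in seq_len(m)) {
        g_rsa[[2 * j - 1]] <- rs_affine(m_rsa[[j]], 1 / cs$mRR[j],
                                        -cs$mUU[j] / cs$mRR[j])
        g_rsa[[2 * j]] <- rs_affine(m_rsa[[j]], -1 / cs$mRR[j],
                                    cs$mLL[j] / cs$mRR[j])
      }
    }

    sub <- solve_trust_subproblem(f_rsa, g_rsa, x_k, delta, sp)
    x_star <- sub$x

    ## Map the two one-sided multipliers per marker onto the marker itself:
    ## phi = f + sum_j lambda_j * m_j
    lambda_m <- if (m) vapply(seq_len(m), function(j)
      (sub$lambda[2 * j - 1] - sub$lambda[2 * j]) / cs$mRR[j],
      numeric(1)) else numeric()

    cand <- .call_evaluator(evaluator, matrix(x_star, nrow = 1,
                                              dimnames = list(NULL, sp$names)),
                            mnames)
    n_eval <- n_eval + 1L
    f_new <- cand$f[1]
    M_new <- if (m) setNames(cand$M[1, ], mnames) else numeric()
    cand_ok <- is.finite(f_new) && all(is.finite(M_new))
    if (!cand_ok) warning("iteration ", k, ": candidate evaluation failed; step rejected")

    surr_old <- predict(f_rsa, x_k)
    surr_new <- predict(f_rsa, x_star)
    rho0 <- trust_ratio(f_k, f_new, surr_old, surr_new, tr$ratio_guard)
    rho_j <- if (m) vapply(seq_len(m), function(j)
      trust_ratio(M_k[j], M_new[j], predict(m_rsa[[j]], x_k),
                  predict(m_rsa[[j]], x_star), tr$ratio_guard),
      numeric(1)) else numeric()
    g_true <- if (m) constraint_transform(M_new, cs$mCR, cs$mRR) else numeric()

    accepted <- cand_ok && accept_step(rho0, rho_j, g_true, tr$rho_L)
    step_len <- max(abs(x_star - x_k))
    on_boundary <- step_len >= delta * (1 - 1e-8)
    delta_next <- update_radius(delta, accepted, on_boundary, tr$delta_max)

    rec <- list(k = k, x_k = setNames(x_k, sp$names),
                x_star = setNames(x_star, sp$names),
                delta = delta, rho0 = rho0,
                rho_j = setNames(rho_j, mnames),
                flgTR = accepted, f_k = f_k, f_star = f_new,
                M_k = M_k, M_star = M_new, g_true = g_true,
                lambda = setNames(lambda_m, mnames),
                subproblem_feasible = sub$feasible)
    history[[length(history) + 1]] <- rec
    if (verbose)
      message(sprintf("k=%d delta=%.4g f=%.6g -> %.6g rho0=%.3g %s",
                      k, delta, f_k, f_new, rho0,
                      if (accepted) "accept" else "reject"))

    if (accepted) {
      x_next <- x_star
      f_k <- f_new
      M_k <- M_new
    } else {
      x_next <- x_k
    }

    ## Termination (checked on the post-update state)
    grad_phi <- lagrangian_gradient(f_rsa, m_rsa, lambda_m, x_next)
    if (accepted && step_len < tr$tol_step) {
      termination <- "step-size"
    } else if (accepted && sqrt(sum(grad_phi^2)) < tr$tol_grad) {
      termination <- "gradient"
    } else if (delta_next < tr$tol_radius) {
      termination <- "radius"
    }
    x_k <- x_next
    delta <- delta_next
    if (!is.null(termination)) break
  }
  if (is.null(termination)) termination <- "max-iterations"

  G_final <- unscale_conductance(x_k, unname(sp$G0))
  res <- structure(list(
    x = setNames(x_k, sp$names),
    conductances = setNames(G_final, sp$names),
    percent_change = setNames(100 * (G_final / unname(sp$G0) - 1), sp$names),
    f = f_k, markers = M_k, termination = termination,
    iterations = history, n_evaluations = n_eval,
    log = .iteration_log(history, sp$names, mnames, termination)),
    class = "rsa_optimization")

  if (!is.null(log_dir)) {
    write.csv(res$log, file.path(log_dir, "iterations.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(x = as.list(res$x), conductances = as.list(res$conductances),
           percent_change = as.list(res$percent_change),
           objective = res$f, markers = as.list(res$markers),
           termination = res$termination,
           n_iterations = length(history), n_evaluations = n_eval),
      file.path(log_dir, "result.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @keywords internal
#' @noRd
.iteration_log <- function(history, vnames, mnames, termination = "") {
  if (!length(history)) return(data.frame())
  out <- do.call(rbind, lapply(history, function(r) {
    row <- data.frame(k = r$k, delta = r$delta, f = r$f_k, f_star = r$f_star,
                      rho0 = r$rho0, flgTR = r$flgTR,
                      subproblem_feasible = r$subproblem_feasible)
    for (i in seq_along(vnames)) row[[paste0("x_", vnames[i])]] <- r$x_k[i]
    for (i in seq_along(vnames)) row[[paste0("xstar_", vnames[i])]] <- r$x_star[i]
    for (j in seq_along(mnames)) {
      row[[paste0("m_", mnames[j])]] <- r$M_star[j]
      row[[paste0("rho_", mnames[j])]] <- r$rho_j[j]
    }
    row
  }))
  out$termination <- c(rep("", nrow(out) - 1), termination)
  out
}

#' @export
print.rsa_optimization <- function(x, ...) {
  cat("Trust-region RSA optimization\n")
  cat("  iterations:", length(x$iterations),
      " evaluations:", x$n_evaluations, "\n")
  cat("  termination:", x$termination, "\n")
  cat("  final objective:", format(x$f, digits = 6), "\n")
  cat("  scaled solution:\n")
  print(round(x$x, 4))
  cat("  conductance change (%):\n")
  print(round(x$percent_change, 2))
  if (length(x$markers)) {
    cat("  final markers:\n")
    print(signif(x$markers, 6))
  }
  invisible(x)
}
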