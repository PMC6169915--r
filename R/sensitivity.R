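#' Percentage change of a property under a perturbed conductance
#'
#' `D = (M_pa - M_control) / M_control * 100`.  A zero control value makes
#' the sensitivity undefined; the entry is returned as `NA` (flagged, not an
#' error).
#'
#' @param M_pa property value with the conductance perturbed.
#' @param M_control property value under control conditions.
#' @return percentage change (vectorized).
#' @export
percent_change <- function(M_pa, M_control) {
  out <- (M_pa - M_control) / M_control * 100
  out[M_control == 0] <- NA_real_
  out
}

#' One-at-a-time sensitivity index
#'
#' `S = (D_plus - D_minus) / (2a)` under the default `"unit"` convention, in
#' which a property scaling proportionally with the conductance (unit
#' elasticity) gives `S = 100`% for any perturbation fraction `a`.  The
#' `"literal"` convention multiplies by a further factor 100; it is provided
#' for auditing against formulations that report the raw ratio of
#' percentages, but its magnitudes (10,000% at unit elasticity) are not the
#' ones quoted alongside published sensitivity analyses.
#'
#' @param D_plus,D_minus percentage changes at `+a` and `-a`.
#' @param a perturbation fraction (e.g. 0.3 for +/-30%).
#' @param convention `"unit"` (default) or `"literal"`.
#' @return sensitivity in percent (vectorized).
#' @export
sensitivity_index <- function(D_plus, D_minus, a = 0.3,
                              convention = c("unit", "literal")) {
  stopifnot(a > 0)
  convention <- match.arg(convention)
  s <- (D_plus - D_minus) / (2 * a)
  if (convention == "literal") s <- s * 100
  s
}

#' One-at-a-time conductance sensitivity analysis
#'
#' Varies each conductance by `+/-a` (30% by default), one at a time, and
#' tabulates the percentage change and sensitivity of every property.
#' Requires `2 * n_conductances + 1` full property evaluations (control plus
#' two per conductance).
#'
#' @param evaluate either an `ionic_model` (sensitivities of the standard
#'   marker set plus the one-cycle potassium-current integral are computed
#'   via the pacing protocols), or a function mapping a named vector of
#'   conductance multipliers to a named numeric property vector.
#' @param conductances character vector of conductances to perturb.
#' @param a perturbation fraction.
#' @param convention see [sensitivity_index()].
#' @param n_beats steady-state beat count when `evaluate` is a model.
#' @return object of class `sensitivity_matrix`: matrices `S`, `D_plus`,
#'   `D_minus` (rows = conductances, columns = properties), `M_control`,
#'   `a`, `failed` (logical vector per conductance).
#' @export
run_sensitivity <- function(evaluate, conductances, a = 0.3,
                            convention = c("unit", "literal"),
                            n_beats = 300) {
  convention <- match.arg(convention)
  if (inherits(evaluate, "ionic_model")) {
    model <- evaluate
    evaluate <- function(mult) {
      m <- model
      m$params[names(mult)] <- m$params[names(mult)] * mult
      r <- .point_markers(m, n_beats, n_beats)
      c(r$markers, iktot_integral = r$integral)
    }
  }
  base_mult <- setNames(rep(1, length(conductances)), conductances)
  M_control <- evaluate(base_mult)
  props <- names(M_control)
  n <- length(conductances)
  D_plus <- D_minus <- matrix(NA_real_, n, length(props),
                              dimnames = list(conductances, props))
  failed <- setNames(logical(n), conductances)
  for (i in seq_len(n)) {
    for (sgn in c(1, -1)) {
      mult <- base_mult
      mult[i] <- 1 + sgn * a
      M <- tryCatch(evaluate(mult), error = function(e) NULL)
      if (is.null(M)) { failed[i] <- TRUE; next }
      D <- percent_change(M[props], M_control)
      if (sgn > 0) D_plus[i, ] <- D else D_minus[i, ] <- D
    }
  }
  S <- sensitivity_index(D_plus, D_minus, a, convention)
  structure(list(S = S, D_plus = D_plus, D_minus = D_minus,
                 M_control = M_control, a = a, convention = convention,
                 failed = failed),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat("One-at-a-time sensitivity (a = ", x$a * 100, "%, ",
      x$convention, " convention)\n", sep = "")
  print(round(x$S, 2))
  invisible(x)
}

#' Column-relative normalization for heatmap rendering
#'
#' Scales each property column of the sensitivity matrix by its maximum
#' absolute entry, mapping it into `[0, 1]` with exactly one entry equal to
#' 1 (ties broken in favour of the first row; later tied entries are nudged
#' below 1 by a negligible amount so the maximum is unique).
#'
#' @param sm a `sensitivity_matrix` or a plain numeric matrix.
#' @return the normalized matrix.
#' @export
normalize_sensitivity <- function(sm) {
  S <- if (inherits(sm, "sensitivity_matrix")) sm$S else sm
  A <- abs(S)
  apply_col <- function(v) {
    mx <- max(v, na.rm = TRUE)
    if (!is.finite(mx) || mx == 0) return(rep(0, length(v)))
    w <- v / mx
    ones <- which(w == 1)
    if (length(ones) > 1) w[ones[-1]] <- 1 - 1e-12
    w
  }
  out <- apply(A, 2, apply_col)
  dimnames(out) <- dimnames(S)
  out
}

#' Render the sensitivity matrix as a heatmap
#'
#' Column-normalized absolute sensitivities on a blue scale (light = the
#' dominant conductance for that property), with the absolute percentage
#' printed in each cell.
#'
#' @param sm a `sensitivity_matrix`.
#' @param file optional PNG path; plots to the active device otherwise.
#' @return the normalized matrix, invisibly.
#' @export
sensitivity_heatmap <- function(sm, file = NULL) {
  N <- normalize_sensitivity(sm)
  S <- sm$S
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::colorRampPalette(c("#08306B", "#FFFFFF"))(100)
  graphics::image(seq_len(ncol(N)), seq_len(nrow(N)), t(N[rev(seq_len(nrow(N))), , drop = FALSE]),
                  col = pal, axes = FALSE, xlab = "", ylab = "", zlim = c(0, 1))
  graphics::axis(1, seq_len(ncol(N)), colnames(N), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(N)), rev(rownames(N)), las = 2, cex.axis = 0.8)
  for (i in seq_len(nrow(N))) for (j in seq_len(ncol(N)))
    graphics::text(j, nrow(N) + 1 - i,
                   sprintf("%s%.0f", if (!is.na(S[i, j]) && S[i, j] < 0) "-" else "",
                           abs(S[i, j])),
                   cex = 0.7,
                   col = if (N[i, j] > 0.5) "black" else "white")
  invisible(N)
}

#' Rank and select decision variables from a sensitivity matrix
#'
#' Ranks conductances by absolute sensitivity of the objective property and
#' applies an exclusion rule formalizing the practice of discarding a
#' conductance that uniquely dominates some marker: a candidate is excluded
#' when its absolute sensitivity on a non-objective property exceeds
#' `dominance` while every other candidate stays below `compensation` on
#' that property (no other decision variable could counterbalance the
#' side effect).
#'
#' @param sm a `sensitivity_matrix`.
#' @param objective column name of the objective property (default the
#'   potassium-current integral).
#' @param k optional number of variables to keep after exclusion.
#' @param dominance,compensation rule thresholds, percent.
#' @return list: `selected` (ordered names), `excluded` (named character of
#'   reasons), `ranking`, `scores`.
#' @export
select_decision_variables <- function(sm, objective = "iktot_integral",
                                      k = NULL, dominance = 100,
                                      compensation = 30) {
  stopifnot(inherits(sm, "sensitivity_matrix"))
  S <- sm$S
  if (!objective %in% colnames(S))
    stop("select_decision_variables: objective property '", objective,
         "' not in the matrix")
  scores <- abs(S[, objective])
  if (all(scores == 0 | is.na(scores))) {
    warning("select_decision_variables: all sensitivities are zero")
    return(list(selected = character(), excluded = character(),
                ranking = character(), scores = scores))
  }
  ranking <- names(sort(scores, decreasing = TRUE))
  others <- setdiff(colnames(S), objective)
  excluded <- character()
  for (p in ranking) {
    for (mcol in others) {
      sp <- abs(S[p, mcol])
      if (is.na(sp) || sp < dominance) next
      rest <- abs(S[setdiff(ranking, p), mcol])
      if (all(is.na(rest) | rest < compensation)) {
        excluded[p] <- sprintf("dominates %s (|S| = %.1f%%) with no compensating variable",
                               mcol, sp)
        break
      }
    }
  }
  selected <- setdiff(ranking, names(excluded))
  if (!is.null(k)) selected <- head(selected, k)
  list(selected = selected, excluded = excluded, ranking = ranking,
       scores = scores)
}
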