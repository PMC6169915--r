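# Shared fixtures built in code.

toy_model_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- toy_ventricular_model()
    m
  }
})

# A short paced run reused by several tests (30 beats, sparse).
toy_short_pacing <- local({
  p <- NULL
  function() {
    if (is.null(p))
      p <<- steady_state_pacing(toy_model_cached(), CL = 1000, n_beats = 30,
                                per_beat_markers = FALSE)
    p
  }
})

# Wrap a plain S matrix as a sensitivity_matrix object.
S_matrix <- function(S) {
  structure(list(S = S, D_plus = S * 0.3, D_minus = -S * 0.3,
                 M_control = setNames(rep(1, ncol(S)), colnames(S)),
                 a = 0.3, convention = "unit",
                 failed = setNames(rep(FALSE, nrow(S)), rownames(S))),
            class = "sensitivity_matrix")
}

# Quadratic evaluator factory: exact-surrogate case for the optimizer.
quadratic_evaluator <- function(c1 = c(0.5, -0.25), Q = diag(2)) {
  function(X) {
    X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
    d <- sweep(X, 2, c1)
    list(f = rowSums((d %*% Q) * d),
         M = cbind(m1 = 300 + 2 * X[, 1] + X[, 2]))
  }
}
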