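## Batch evaluator: maps scaled conductance points to (objective, markers)
## by running the stimulation protocols on a configured model.  Points are
## independent, so a batch may run on several workers; aggregation order is
## by row, independent of the worker count.

#' @keywords internal
#' @noRd
.point_markers <- function(model, n_beats_1hz, n_beats_05hz,
                           final_out_dt = 0.02,
                           adaptation = NULL) {
  p1 <- steady_state_pacing(model, CL = 1000, n_beats = n_beats_1hz,
                            per_beat_markers = FALSE,
                            final_out_dt = final_out_dt)
  p2 <- steady_state_pacing(model, CL = 2000, n_beats = n_beats_05hz,
                            per_beat_markers = FALSE,
                            final_out_dt = final_out_dt)
  last1 <- p1$beats[nrow(p1$beats), ]
  ca1 <- ca_levels(p1$trace)
  ca2 <- ca_levels(p2$trace)
  mk <- c(apd90 = last1$apd90,
          triangulation = last1$apd90 - last1$apd50,
          ca_sys_1hz = unname(ca1["systolic"]),
          ca_dia_1hz = unname(ca1["diastolic"]),
          ca_sys_05hz = unname(ca2["systolic"]),
          ca_dia_05hz = unname(ca2["diastolic"]))
  if (!is.null(adaptation)) {
    bs <- rate_adaptation_protocol(model, n_pre = adaptation$n_pre,
                                   n_post = adaptation$n_post)
    post <- bs[bs$phase == "post", ]
    fit <- tryCatch(fit_adaptation(post$onset_s, post$apd90),
                    error = function(e) NULL)
    mk["tau_slow"] <- if (!is.null(fit)) fit$tau_slow else NA_real_
  }
  list(markers = mk, integral = last1$iktot_integral,
       ki_end = last1$ki_end, capture = p1$capture && p2$capture)
}

#' Build a batch evaluator over a model and decision space
#'
#' Returns a function satisfying the [run_optimization()] evaluator
#' contract: given a matrix of scaled conductance points (one row each) it
#' runs, per point, steady-state pacing at CL 1000 and 2000 ms on the model
#' configured with those conductances, and reports the squared one-cycle
#' integral of the total potassium current (the objective) together with
#' the marker vector.  Optionally runs the rate-adaptation protocol to add
#' the `tau_slow` marker.  Points are evaluated independently (in parallel
#' when `workers > 1`) and results are returned in row order regardless of
#' the worker count; a failed point yields `NA`s, which the optimizer drops
#' with a warning.
#'
#' @param model base `ionic_model`.
#' @param space [decision_space()]; its `G0` are the baselines of the
#'   scaling.
#' @param n_beats_1hz,n_beats_05hz beat counts for the two steady-state
#'   protocols (3000 for the reference protocol; 300 for the desk-scale
#'   profile).
#' @param adaptation `NULL`, or `list(n_pre=, n_post=)` to run the abrupt
#'   CL-change protocol and report `tau_slow`.
#' @param workers parallel workers for database batches.
#' @return `function(X) -> list(f, M)`.
#' @export
batch_evaluator <- function(model, space, n_beats_1hz = 300,
                            n_beats_05hz = 300, adaptation = NULL,
                            workers = 1L) {
  force(model); force(space)
  mnames <- c("apd90", "triangulation", "ca_sys_1hz", "ca_dia_1hz",
              "ca_sys_05hz", "ca_dia_05hz",
              if (!is.null(adaptation)) "tau_slow")
  function(X) {
    X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
    if (nrow(X) == 0L)
      return(list(f = numeric(),
                  M = matrix(numeric(), 0, length(mnames),
                             dimnames = list(NULL, mnames))))
    eval_one <- function(i) {
      tryCatch({
        m <- apply_conductances(model, X[i, ], space)
        r <- .point_markers(m, n_beats_1hz, n_beats_05hz,
                            adaptation = adaptation)
        c(r$integral^2, r$markers)
      }, error = function(e) rep(NA_real_, 1 + length(mnames)))
    }
    rows <- if (workers > 1L && .Platform$OS.type == "unix") {
      parallel::mclapply(seq_len(nrow(X)), eval_one, mc.cores = workers,
                         mc.preschedule = TRUE)
    } else {
      lapply(seq_len(nrow(X)), eval_one)
    }
    R <- do.call(rbind, rows)
    list(f = R[, 1],
         M = matrix(R[, -1, drop = FALSE], nrow(X), length(mnames),
                    dimnames = list(NULL, mnames)))
  }
}
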