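## Integration core: stiff adaptive integration (lsoda, BDF when stiff) of
## ionic models, with the pacing stimulus handled as exact segment boundaries
## through integrator events so the adaptive solver never steps across a
## stimulus edge.

#' @keywords internal
#' @noRd
.toy_parms <- function(model, CL, stim_on) {
  p <- model$params
  c(p[["G_Ca"]], p[["G_K"]], p[["G_K1"]], p[["G_NaK"]], p[["G_Kp"]],
    p[["G_Clbk"]], p[["E_Clbk"]], p[["tau_f"]], p[["tau_n"]], p[["tau_Ca"]],
    p[["k_conv"]], p[["kappa_K"]], p[["Ko"]], p[["Ca_rest"]], p[["E_Ca"]],
    p[["stim_amp"]], p[["stim_dur"]], CL, 0, as.numeric(stim_on))
}

#' @keywords internal
#' @noRd
.model_atol <- function(model) {
  if (!is.null(model$atol)) unname(model$atol[names(model$state0)])
  else rep(1e-9, length(model$state0))
}

#' Integrate an ionic model over one stimulation segment
#'
#' Low-level integration of `n_beats` consecutive cycles of length `CL`
#' starting at a stimulus onset (or an unstimulated interval when
#' `stim_on = FALSE`).  Stimulus on/off edges are passed to the solver as
#' events so integration restarts exactly at the discontinuities.
#'
#' @param model an `ionic_model`.
#' @param y0 initial state (defaults to the model's).
#' @param n_beats number of cycles.
#' @param CL cycle length, ms.
#' @param stim_on deliver stimuli?
#' @param times output times (ms, segment-local); default: the segment
#'   boundaries only.
#' @return the `deSolve` output matrix (time + states).
#' @export
sim_segment <- function(model, y0 = NULL, n_beats = 1L, CL = 1000,
                        stim_on = TRUE, times = NULL) {
  stopifnot(inherits(model, "ionic_model"))
  if (is.null(y0)) y0 <- model$state0
  dur <- model$params[["stim_dur"]]
  if (stim_on && CL <= dur)
    stop("sim_segment: cycle length must exceed the stimulus duration")
  t_end <- n_beats * CL
  onsets <- (seq_len(n_beats) - 1L) * CL
  edges <- if (stim_on) sort(c(onsets, onsets + dur)) else numeric()
  if (is.null(times)) times <- c(onsets, t_end)
  times <- sort(unique(c(times, edges, 0, t_end)))
  atol <- .model_atol(model)
  rtol <- if (!is.null(model$rtol)) model$rtol else 1e-6
  ev <- if (length(edges))
    list(data = data.frame(var = names(model$state0)[1], time = edges,
                           value = 0, method = "add"))
  if (!is.null(model$compiled)) {
    out <- deSolve::ode(y = y0, times = times, func = model$compiled$func,
                        parms = .toy_parms(model, CL, stim_on),
                        dllname = model$compiled$dllname,
                        initfunc = model$compiled$initfunc,
                        method = "lsoda", rtol = rtol, atol = atol,
                        events = ev, maxsteps = 50000)
  } else {
    amp <- model$params[["stim_amp"]]
    rhsfun <- function(t, y, parms) {
      stim <- if (stim_on && (t %% CL) < dur) amp else 0
      list(unname(model$rhs(t, y, model$params, stim = stim)$deriv))
    }
    out <- deSolve::ode(y = y0, times = times, func = rhsfun, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol,
                        events = ev, maxsteps = 50000)
  }
  if (attr(out, "istate")[1] < 0)
    stop("sim_segment: integration failed (istate ",
         attr(out, "istate")[1], ")")
  out
}

#' @keywords internal
#' @noRd
.stim_series <- function(model, time, CL, stim_on = TRUE) {
  if (!stim_on) return(rep(0, length(time)))
  dur <- model$params[["stim_dur"]]
  ifelse((time %% CL) < dur, model$params[["stim_amp"]], 0)
}

#' Assemble an action-potential trace
#'
#' @param time time grid, ms (strictly increasing).
#' @param V membrane potential, mV.
#' @param Cai,Ki optional concentration series, mM.
#' @param currents optional data frame of current densities (columns named
#'   as in [currents_record()]).
#' @param CL cycle length, ms.
#' @param stim_onset stimulus delivery time on this grid, ms.
#' @param stim_dur stimulus duration, ms.
#' @return a data frame of class `ap_trace`.
#' @export
ap_trace <- function(time, V, Cai = NULL, Ki = NULL, currents = NULL,
                     CL = NA_real_, stim_onset = 0, stim_dur = NA_real_) {
  if (any(diff(time) <= 0)) stop("ap_trace: time must be strictly increasing")
  df <- data.frame(time = time, V = V)
  if (!is.null(Cai)) df$Cai <- Cai
  if (!is.null(Ki)) df$Ki <- Ki
  if (!is.null(currents)) df <- cbind(df, currents)
  structure(df, CL = CL, stim_onset = stim_onset, stim_dur = stim_dur,
            class = c("ap_trace", "data.frame"))
}

#' @keywords internal
#' @noRd
.trace_from_out <- function(model, out, CL, stim_on = TRUE) {
  time <- out[, 1]
  stim <- .stim_series(model, time, CL, stim_on)
  cur <- if (!is.null(model$currents_fun))
    model$currents_fun(out[, -1, drop = FALSE], model$params, stim = stim)
  ap_trace(time, out[, "V"],
           Cai = if ("Cai" %in% colnames(out)) out[, "Cai"],
           Ki = if ("Ki" %in% colnames(out)) out[, "Ki"],
           currents = cur, CL = CL, stim_onset = 0,
           stim_dur = model$params[["stim_dur"]])
}
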