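## Stimulation protocols.  All pacing is chunked: long trains are integrated
## a few hundred beats at a time (restart at a beat onset is exact up to
## solver tolerance), so memory stays bounded even for paper-scale
## 3000-beat trains.

#' @keywords internal
#' @noRd
.beat_rows <- function(out, onsets) {
  vapply(onsets, function(o) which.min(abs(out[, 1] - o)), integer(1))
}

#' @keywords internal
#' @noRd
.chunk_beat_records <- function(model, out, n_beats, CL, dense) {
  onsets <- (seq_len(n_beats) - 1L) * CL
  marks <- .beat_rows(out, c(onsets, n_beats * CL))
  has_qk <- "qK" %in% colnames(out)
  rec <- data.frame(beat = seq_len(n_beats), onset = onsets,
                    apd90 = NA_real_, apd50 = NA_real_,
                    ca_sys = NA_real_, ca_dia = NA_real_,
                    ki_end = if ("Ki" %in% colnames(out))
                      out[marks[-1], "Ki"] else NA_real_,
                    iktot_integral = if (has_qk)
                      diff(out[marks, "qK"]) else NA_real_)
  if (dense) {
    t <- out[, 1]; V <- out[, "V"]
    for (b in seq_len(n_beats)) {
      i0 <- marks[b]; i1 <- marks[b + 1]
      idx <- i0:i1
      rec$apd90[b] <- .apd_core(t[idx], V[idx], onsets[b], 0.9)
      rec$apd50[b] <- .apd_core(t[idx], V[idx], onsets[b], 0.5)
      if ("Cai" %in% colnames(out)) {
        rec$ca_sys[b] <- max(out[idx, "Cai"])
        rec$ca_dia[b] <- min(out[idx, "Cai"])
      }
    }
  }
  rec
}

#' Steady-state pacing protocol
#'
#' Delivers a train of stimuli at a fixed cycle length from the model's
#' initial state and returns the per-beat series together with the final
#' beat as a densely sampled trace (0.02 ms grid by default) carrying the
#' current time courses for marker and potassium-budget computation.
#'
#' @param model an `ionic_model`.
#' @param CL cycle length, ms.
#' @param n_beats number of stimuli (3000 reproduces the reference
#'   steady-state protocol; tests use scaled-down counts).
#' @param per_beat_markers compute APD and calcium markers for every beat
#'   (needs dense output per beat, `out_dt` grid); when `FALSE`, only the
#'   per-beat potassium budget and end-of-beat state are recorded and the
#'   run is considerably faster.
#' @param out_dt dense output step for intermediate beats, ms.
#' @param final_out_dt output step for the final-beat trace, ms.
#' @param y0 initial state override.
#' @return list of class `pacing_result`: `beats` (one record per delivered
#'   stimulus), `trace` (final-beat [ap_trace()]), `capture` (did the final
#'   beat elicit an AP reaching -20 mV within 50 ms of the stimulus?).
#' @export
steady_state_pacing <- function(model, CL = 1000, n_beats = 3000,
                                per_beat_markers = FALSE, out_dt = 0.5,
                                final_out_dt = 0.02, y0 = NULL) {
  stopifnot(inherits(model, "ionic_model"), n_beats >= 1)
  y <- if (is.null(y0)) model$state0 else y0
  beats <- list()
  done <- 0L
  rows_per_beat <- if (per_beat_markers) CL / out_dt else 2
  chunk <- max(1L, min(500L, as.integer(floor(250000 / rows_per_beat))))
  while (done < n_beats - 1L) {
    nb <- min(chunk, n_beats - 1L - done)
    times <- if (per_beat_markers) seq(0, nb * CL, by = out_dt) else NULL
    out <- tryCatch(
      sim_segment(model, y, nb, CL, stim_on = TRUE, times = times),
      error = function(e) stop("steady_state_pacing: integration failed at beat ",
                               done + 1L, ": ", conditionMessage(e)))
    rec <- .chunk_beat_records(model, out, nb, CL, per_beat_markers)
    rec$beat <- rec$beat + done
    rec$onset <- rec$onset + done * CL
    beats[[length(beats) + 1L]] <- rec
    y <- out[nrow(out), -1]
    done <- done + nb
  }
  ## final beat, densely sampled
  out_f <- tryCatch(
    sim_segment(model, y, 1L, CL, stim_on = TRUE,
                times = seq(0, CL, by = final_out_dt)),
    error = function(e) stop("steady_state_pacing: integration failed at beat ",
                             n_beats, ": ", conditionMessage(e)))
  trace <- .trace_from_out(model, out_f, CL)
  rec <- .chunk_beat_records(model, out_f, 1L, CL, dense = TRUE)
  rec$beat <- n_beats
  rec$onset <- (n_beats - 1L) * CL
  beats[[length(beats) + 1L]] <- rec
  within50 <- out_f[, 1] <= 50
  capture <- max(out_f[within50, "V"]) > -20
  structure(list(beats = do.call(rbind, beats), trace = trace,
                 capture = capture, CL = CL),
            class = "pacing_result")
}

#' @export
print.pacing_result <- function(x, ...) {
  nb <- nrow(x$beats)
  cat("Pacing result: ", nb, " beats at CL ", x$CL, " ms",
      if (!x$capture) " [loss of capture]", "\n", sep = "")
  last <- x$beats[nb, ]
  cat(sprintf("  final beat: APD90=%.2f ms, Ki=%.4f mM, one-cycle IKtot integral=%.4g ms*pA/pF\n",
              last$apd90, last$ki_end, last$iktot_integral))
  invisible(x)
}

#' Abrupt cycle-length change (rate adaptation) protocol
#'
#' Paces at one cycle length, switches abruptly to a second one, and records
#' APD90 for every beat with onset times relative to the switch.  The
#' default counts correspond to 8 minutes at CL 1000 ms (480 beats) followed
#' by 8 minutes at CL 600 ms (800 beats).
#'
#' @param model an `ionic_model`.
#' @param CL_pre,CL_post cycle lengths before/after the switch, ms.
#' @param n_pre,n_post beat counts per segment.
#' @param out_dt dense output step for APD extraction, ms.
#' @return data frame of class `beat_series`: `beat`, `phase`
#'   (`"pre"`/`"post"`), `CL`, `onset_s` (seconds, 0 = switch), `apd90`,
#'   `ki_end`, `iktot_integral`.
#' @export
rate_adaptation_protocol <- function(model, CL_pre = 1000, CL_post = 600,
                                     n_pre = 480, n_post = 800,
                                     out_dt = 0.25) {
  run_phase <- function(y, CL, n_beats, t_offset_ms, phase) {
    recs <- list()
    done <- 0L
    chunk <- max(1L, as.integer(floor(250000 / (CL / out_dt))))
    while (done < n_beats) {
      nb <- min(chunk, n_beats - done)
      out <- sim_segment(model, y, nb, CL, stim_on = TRUE,
                         times = seq(0, nb * CL, by = out_dt))
      rec <- .chunk_beat_records(model, out, nb, CL, dense = TRUE)
      rec$beat <- rec$beat + done
      rec$onset_s <- (rec$onset + t_offset_ms + done * CL) / 1000
      rec$phase <- phase
      rec$CL <- CL
      recs[[length(recs) + 1L]] <- rec
      y <- out[nrow(out), -1]
      done <- done + nb
    }
    list(df = do.call(rbind, recs), y = y)
  }
  pre <- run_phase(model$state0, CL_pre, n_pre, -n_pre * CL_pre, "pre")
  post <- run_phase(pre$y, CL_post, n_post, 0, "post")
  df <- rbind(pre$df, post$df)
  df <- df[c("beat", "phase", "CL", "onset_s", "apd90", "apd50",
             "ki_end", "iktot_integral")]
  structure(df, class = c("beat_series", "data.frame"),
            switch_s = 0, CL_pre = CL_pre, CL_post = CL_post)
}

#' Extracellular-potassium step on an unstimulated cell
#'
#' Lets the unstimulated cell settle at one extracellular potassium level,
#' steps the level at `t = 0`, and reports the membrane-potential time
#' course together with `t90`, the time to reach 90% of the transition from
#' the pre-step steady potential to the post-step steady potential (read at
#' `observe_ms`).
#'
#' @param model an `ionic_model`.
#' @param Ko_from,Ko_to extracellular potassium levels, mM (positive).
#' @param settle_ms settling time at `Ko_from`.
#' @param observe_ms observation window after the step.
#' @param out_dt output step during observation, ms.
#' @return list: `time`, `V`, `t90` (ms), `V_start`, `V_ss`, `Ki_end`,
#'   `ambiguous` (TRUE when the 90% level is crossed more than once or there
#'   is no transition).
#' @export
ko_step_unstimulated <- function(model, Ko_from, Ko_to, settle_ms = 20000,
                                 observe_ms = 2000, out_dt = 0.05) {
  stopifnot(Ko_from > 0, Ko_to > 0)
  m1 <- set_ko(model, Ko_from)
  out0 <- sim_segment(m1, model$state0, 1L, settle_ms, stim_on = FALSE,
                      times = c(0, settle_ms))
  y <- out0[nrow(out0), -1]
  m2 <- set_ko(model, Ko_to)
  out <- sim_segment(m2, y, 1L, observe_ms, stim_on = FALSE,
                     times = seq(0, observe_ms, by = out_dt))
  time <- out[, 1]; V <- out[, "V"]
  V_start <- unname(y["V"]); V_ss <- V[length(V)]
  ## deadband: residual settling drift must not masquerade as a step response
  if (abs(V_ss - V_start) < 0.05) {
    warning("ko_step_unstimulated: no membrane-potential transition; t90 = 0")
    return(list(time = time, V = V, t90 = 0, V_start = V_start, V_ss = V_ss,
                Ki_end = unname(out[nrow(out), "Ki"]), ambiguous = TRUE))
  }
  target <- V_start + 0.9 * (V_ss - V_start)
  s <- sign(V_ss - V_start)
  reached <- which(s * (V - target) >= 0)
  crossings <- which(diff(sign(V - target)) != 0)
  ambiguous <- length(crossings) > 1
  if (ambiguous)
    warning("ko_step_unstimulated: non-monotone approach; first crossing reported")
  i <- reached[1]
  t90 <- if (i == 1) 0 else
    time[i - 1] + (target - V[i - 1]) / (V[i] - V[i - 1]) *
      (time[i] - time[i - 1])
  list(time = time, V = V, t90 = t90, V_start = V_start, V_ss = V_ss,
       Ki_end = unname(out[nrow(out), "Ki"]), ambiguous = ambiguous)
}

#' APD restitution across cycle lengths
#'
#' Paces to steady state at each cycle length and reports the last-beat
#' APD90, its value normalized to the CL = 1000 ms entry, and a beat-to-beat
#' alternans flag (`|APD90(last) - APD90(last-1)| > 1` ms).  Cycle lengths
#' at which the stimulus fails to elicit an AP are marked inexcitable rather
#' than failing the run.
#'
#' @param model an `ionic_model`.
#' @param CL_list cycle lengths, ms.
#' @param n_beats beats per cycle length (3000 for the reference protocol).
#' @param out_dt dense output step for the final two beats, ms.
#' @return data frame: `CL`, `apd90`, `apd90_prev`, `apd90_norm`,
#'   `alternans`, `excitable`.
#' @export
restitution <- function(model, CL_list, n_beats = 3000, out_dt = 0.1) {
  stopifnot(length(CL_list) >= 1)
  rows <- lapply(CL_list, function(CL) {
    res <- tryCatch({
      y <- if (n_beats > 2) {
        out <- sim_segment(model, model$state0, n_beats - 2L, CL,
                           stim_on = TRUE)
        out[nrow(out), -1]
      } else model$state0
      nb2 <- min(n_beats, 2L)
      out2 <- sim_segment(model, y, nb2, CL, stim_on = TRUE,
                          times = seq(0, nb2 * CL, by = out_dt))
      rec <- .chunk_beat_records(model, out2, nb2, CL, dense = TRUE)
      upstroke <- max(out2[out2[, 1] %% CL <= 50, "V"]) > -20
      apd_last <- rec$apd90[nb2]
      apd_prev <- if (nb2 == 2) rec$apd90[1] else NA_real_
      excitable <- upstroke && is.finite(apd_last)
      data.frame(CL = CL,
                 apd90 = if (excitable) apd_last else NA_real_,
                 apd90_prev = if (excitable) apd_prev else NA_real_,
                 alternans = excitable && is.finite(apd_prev) &&
                   abs(apd_last - apd_prev) > 1,
                 excitable = excitable)
    }, error = function(e)
      data.frame(CL = CL, apd90 = NA_real_, apd90_prev = NA_real_,
                 alternans = FALSE, excitable = FALSE))
    res
  })
  df <- do.call(rbind, rows)
  ref <- df$apd90[match(1000, df$CL)]
  if (is.na(ref) && !1000 %in% df$CL)
    warning("restitution: CL = 1000 ms not in the list; normalized APD90 is NA")
  df$apd90_norm <- df$apd90 / ref
  df
}
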