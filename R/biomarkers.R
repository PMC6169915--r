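#' @keywords internal
#' @noRd
.apd_core <- function(time, V, onset, fraction, v_rest = NULL) {
  ## V_rest is read 1 ms before the stimulus; if the trace starts at the
  ## stimulus the first sample is used.
  if (is.null(v_rest)) {
    t_rest <- onset - 1
    v_rest <- if (t_rest <= time[1]) V[1] else
      approx(time, V, xout = t_rest, rule = 2)$y
  }
  post <- which(time >= onset)
  if (!length(post)) return(NA_real_)
  ip <- post[which.max(V[post])]
  v_peak <- V[ip]
  thr <- v_peak - fraction * (v_peak - v_rest)
  idx <- which(V <= thr & seq_along(V) > ip)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (i == 1) return(time[1] - onset)
  t_cross <- time[i - 1] +
    (thr - V[i - 1]) / (V[i] - V[i - 1]) * (time[i] - time[i - 1])
  t_cross - onset
}

#' Action-potential duration at a repolarization fraction
#'
#' `APD` is the time from stimulus delivery to the first downward crossing of
#' `V_peak - fraction * (V_peak - V_rest)` after the peak, with linear
#' interpolation between samples.  `V_rest` is the potential 1 ms before the
#' stimulus; `V_peak` the maximum over the beat.
#'
#' @param trace an [ap_trace()] covering one beat with its stimulus onset.
#' @param fraction repolarization fraction in (0, 1); 0.9 for APD90.
#' @return duration in ms.
#' @export
apd <- function(trace, fraction = 0.9) {
  stopifnot(inherits(trace, "ap_trace"), fraction > 0, fraction < 1)
  onset <- attr(trace, "stim_onset")
  out <- .apd_core(trace$time, trace$V, onset, fraction)
  if (is.na(out))
    stop("apd: repolarization failure (no crossing of the ",
         fraction * 100, "% threshold before the end of the trace)")
  out
}

#' AP triangulation
#'
#' Difference between the durations at 90% and 50% repolarization; a shape
#' marker of late repolarization (large values = triangular, pro-arrhythmic).
#'
#' @param trace an [ap_trace()].
#' @return triangulation in ms.
#' @export
triangulation <- function(trace) {
  apd(trace, 0.9) - apd(trace, 0.5)
}

#' Systolic and diastolic calcium levels over a beat
#'
#' @param trace an [ap_trace()]; if it carries no `Cai` series the marker is
#'   reported unavailable (`NA`s) rather than raising an error.
#' @return named vector `c(systolic, diastolic)` in the trace's calcium
#'   units.
#' @export
ca_levels <- function(trace) {
  if (!"Cai" %in% names(trace))
    return(c(systolic = NA_real_, diastolic = NA_real_))
  c(systolic = max(trace$Cai), diastolic = min(trace$Cai))
}

#' One-cycle integral of the total potassium current
#'
#' Trapezoidal integral of [ik_tot()] over the trace; the optimization
#' objective is the square of this quantity.
#'
#' @param trace an [ap_trace()] covering one cycle and carrying current
#'   columns.
#' @return integral in ms*pA/pF.
#' @export
iktot_integral <- function(trace) {
  if (!any(c("IKr", "IK1", "INaK", "IKs", "Ito", "IKp") %in% names(trace)))
    stop("iktot_integral: the trace carries no current series")
  y <- ik_tot(as.data.frame(trace))
  t <- trace$time
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Biexponential fit of APD rate adaptation
#'
#' Fits `APD90(t) = y_inf + A_fast*exp(-t/tau_fast) + A_slow*exp(-t/tau_slow)`
#' to a post-switch beat series by nonlinear least squares, restarted from a
#' deterministic grid of time-constant initializations
#' (`tau_fast` in 2, 10, 30 s; `tau_slow` in 60, 90, 120 s); the best
#' residual wins and the time constants are ordered so `tau_fast < tau_slow`.
#' The slow constant is the rate-adaptation marker; it is flagged
#' unidentifiable when `|A_slow|` is below 1 ms.
#'
#' @param t time since the cycle-length switch, seconds (or a data frame
#'   with columns `t` and `apd90`).
#' @param apd90 per-beat APD90 values, ms.
#' @param min_points minimum number of post-switch beats (default 30).
#' @return an object of class `adaptation_fit`: `y_inf`, `A_fast`,
#'   `tau_fast`, `A_slow`, `tau_slow` (seconds), `residual_norm`,
#'   `identifiable`.
#' @export
fit_adaptation <- function(t, apd90 = NULL, min_points = 30L) {
  if (is.data.frame(t)) { apd90 <- t$apd90; t <- t$t }
  keep <- is.finite(t) & is.finite(apd90)
  t <- t[keep]; apd90 <- apd90[keep]
  if (length(t) < min_points)
    stop("fit_adaptation: need at least ", min_points, " post-switch beats")
  df <- data.frame(t = t, y = apd90)
  mkfit <- function(yi, Af, tf, As, ts, rss) {
    structure(list(y_inf = yi, A_fast = Af, tau_fast = tf,
                   A_slow = As, tau_slow = ts,
                   residual_norm = sqrt(rss),
                   identifiable = abs(As) >= 1),
              class = "adaptation_fit")
  }
  if (stats::sd(apd90) < 1e-6)  # flat series: nothing to fit
    return(mkfit(mean(apd90), 0, 10, 0, 90, 0))
  y_inf0 <- mean(tail(apd90, max(5L, length(apd90) %/% 10)))
  A0 <- mean(head(apd90, 3)) - y_inf0
  best <- NULL
  for (tf0 in c(2, 10, 30)) for (ts0 in c(60, 90, 120)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ yi + Af * exp(-t / tf) + As * exp(-t / ts),
        data = df,
        start = list(yi = y_inf0, Af = A0 / 2, tf = tf0, As = A0 / 2,
                     ts = ts0),
        lower = c(-Inf, -Inf, 1e-3, -Inf, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  ## single-exponential reference fit: when the biexponential collapses to
  ## one time constant (amplitude split between equal taus) the single
  ## exponential is the canonical representation
  single <- tryCatch(
    minpack.lm::nlsLM(y ~ yi + As * exp(-t / ts), data = df,
                      start = list(yi = y_inf0, As = A0, ts = 90),
                      lower = c(-Inf, -Inf, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(best) && is.null(single))
    stop("fit_adaptation: no converged fit from any initialization ",
         "(n = ", nrow(df), ", sd = ", signif(stats::sd(apd90), 3), ")")
  rss_single <- if (!is.null(single)) sum(stats::resid(single)^2) else Inf
  if (is.null(best) ||
      rss_single <= best$rss * (1 + 1e-6) + 1e-12) {
    cs <- coef(single)
    return(mkfit(unname(cs[["yi"]]), 0, unname(cs[["ts"]]) / 10,
                 unname(cs[["As"]]), unname(cs[["ts"]]), rss_single))
  }
  cf <- coef(best$fit)
  if (cf[["tf"]] > cf[["ts"]]) # order the exponentials: fast first
    cf <- c(yi = cf[["yi"]], Af = cf[["As"]], tf = cf[["ts"]],
            As = cf[["Af"]], ts = cf[["tf"]])
  mkfit(unname(cf[["yi"]]), unname(cf[["Af"]]), unname(cf[["tf"]]),
        unname(cf[["As"]]), unname(cf[["ts"]]), best$rss)
}

#' @export
print.adaptation_fit <- function(x, ...) {
  cat(sprintf(
    "APD adaptation fit: y_inf=%.2f ms, A_fast=%.2f ms (tau=%.2f s), A_slow=%.2f ms (tau=%.2f s)%s\n",
    x$y_inf, x$A_fast, x$tau_fast, x$A_slow, x$tau_slow,
    if (!x$identifiable) " [tau_slow unidentifiable: |A_slow| < 1 ms]" else ""))
  invisible(x)
}

#' Read a trace from delimited text and compute its markers
#'
#' Standalone marker extraction for precomputed traces: expects columns
#' `time` and `V`, optionally `Cai`, `Ki` and current columns.
#'
#' @param path CSV file path.
#' @param CL cycle length, ms (defaults to the trace span).
#' @param stim_onset stimulus time on the trace's clock; when `NULL`
#'   (default) it is inferred as the time of the steepest upstroke, the
#'   standard convention for traces whose stimulus timing is not recorded.
#' @return named list of markers.
#' @export
markers_from_csv <- function(path, CL = NULL, stim_onset = NULL) {
  df <- read.csv(path)
  if (!all(c("time", "V") %in% names(df)))
    stop("markers_from_csv: need at least 'time' and 'V' columns")
  if (is.null(CL)) CL <- diff(range(df$time))
  if (is.null(stim_onset)) {
    slope <- diff(df$V) / diff(df$time)
    stim_onset <- df$time[which.max(slope) + 1L]
  }
  extra <- setdiff(names(df), c("time", "V", "Cai", "Ki"))
  tr <- ap_trace(df$time, df$V, Cai = df$Cai, Ki = df$Ki,
                 currents = if (length(extra)) df[extra],
                 CL = CL, stim_onset = stim_onset)
  ca <- ca_levels(tr)
  list(apd90 = apd(tr, 0.9), apd50 = apd(tr, 0.5),
       triangulation = triangulation(tr),
       ca_systolic = unname(ca["systolic"]),
       ca_diastolic = unname(ca["diastolic"]),
       iktot_integral = if (length(extra)) iktot_integral(tr) else NA_real_)
}
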