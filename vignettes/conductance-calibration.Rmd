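---
title: "Calibrating cardiac ionic conductances with trust-region response surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating cardiac ionic conductances with trust-region response surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condcal)
```

## The problem

Action-potential (AP) models of cardiac myocytes are systems of stiff ODEs
whose ionic current conductances often cannot be identified from
voltage-clamp experiments alone.  When a model is extended — here, when
intracellular potassium \([K^+]_i\) is promoted from a constant to a dynamic
state — the pre-existing conductance values generally leave the potassium
fluxes unbalanced, so \([K^+]_i\) drifts beat after beat.  Restoring
homeostasis without destroying the model's electrophysiological behaviour is
a constrained optimization problem:

\[
\min_x \Big(\int_{CL} I_{K,tot}(x)\,dt\Big)^2
\quad \text{s.t.} \quad m_{LL} \le m(x) \le m_{UU}, \quad x^L \le x \le x^U,
\]

where \(x_i = 20\log_{10}(G_i/G_i^0)\) are the decision conductances on a
decibel-like scale (so \(\pm 6.0206\) means halving/doubling),
\(I_{K,tot} = I_{to} + I_{Kr} + I_{Ks} + I_{K1} - 2 I_{NaK} + I_{CaK} +
I_{Kp} + I_{stim}\) is the net potassium-carrying current over one paced
cycle, and \(m(x)\) is a vector of electrophysiological markers (APD90,
triangulation, calcium transient levels at two pacing rates, and the slow
APD rate-adaptation constant \(\tau_{slow}\)) confined to experimental
bands.  Each marker band \([m_{LL}, m_{UU}]\) is normalized into a single
inequality \(g_j(x) = |m_j(x) - m_{j,CR}|/m_{j,RR} - 1 \le 0\) about its
center \(m_{CR}\) and half-range \(m_{RR}\).

Evaluating \(f\) and \(m\) at one point means pacing the cell model to
steady state under several protocols — minutes of CPU per point — so the
optimizer must be frugal with evaluations and embarrassingly parallel where
it can be.

## The algorithm

Each iteration \(k\) proceeds as follows.

1. **Database.** Sample the objective and every marker on a full factorial
   design (3 levels per axis by default, \(3^n\) points) spanning the box
   \(x^k \pm \Delta^k\), clipped to the global bounds.  All points are
   independent: the evaluator receives them as one batch.
2. **Response surfaces.** Fit full second-order polynomials (intercept,
   linear, pure quadratic, cross terms; \(1 + 2n + n(n-1)/2\) coefficients)
   by ordinary least squares to \(f\) and to each marker.  Regressors are
   centered on \(x^k\) and scaled by \(\Delta^k\) before the solve, and the
   affine map is stored with the surface, so conditioning does not depend on
   where the trust region currently sits.
3. **Subproblem.** Minimize the objective surface subject to the marker
   surfaces (two one-sided constraints per band), the trust box
   \(\|x - x^k\|_\infty \le \Delta^k\) and the global bounds.  Quadratic
   surrogates can be nonconvex, so a bound-constrained quasi-Newton solver
   with analytic polynomial gradients is restarted from five deterministic
   points (center plus four alternating corners); inequality constraints are
   handled by an augmented Lagrangian whose multipliers are kept.
4. **Trust test.** Evaluate the true functions at the candidate \(x^{k,*}\)
   (a second, single-point batch) and form the ratios
   \(\rho_0 = \frac{f(x^{k,*})-f(x^k)}{\tilde f(x^{k,*})-\tilde f(x^k)}\)
   and likewise \(\rho_j\) per marker.  The step is accepted when
   \(\rho_0 > 0\) and either the true constraints are feasible at the
   candidate or every \(|\rho_j - 1| \le \rho_L\) (default 0.25).
5. **Radius.** Rejected: \(\Delta \leftarrow 0.25\,\Delta\) (and the
   database is rebuilt around the unchanged iterate).  Accepted interior
   step: \(\Delta\) unchanged.  Accepted step on the box boundary:
   \(\Delta \leftarrow \min(2\Delta, \Delta_{max})\).
6. **Termination.** Stop when an accepted step is shorter than \(\delta_1\),
   when the gradient of the surrogate Lagrangian
   \(\phi = \tilde f + \sum_j \lambda_j \tilde m_j\) falls below
   \(\delta_2\) after an accepted step, when \(\Delta < \delta_3\), or at
   the iteration cap.

Defaults (exposed in `trust_region_params()`): \(\Delta^0 = 2\),
\(\Delta_{max} = 6\), \(\rho_L = 0.25\),
\(\delta_1 = \delta_2 = \delta_3 = 10^{-3}\), 20 iterations, bounds
\(\pm 6.0206\) (conductance factor ½–2).  Degenerate trust ratios (surrogate
change below \(10^{-12}\)) are defined as 1 when the true change is also
negligible, else signed infinity.

Two design points deserve a note.  The trust region is a box (infinity
norm), not a ball: the factorial database then coincides geometrically with
the region the surrogate is trusted in.  And when \(0 < \rho_0 < 1\) without
acceptance, the radius is simply kept/shrunk per the rule above — the
alternative of re-centering the surfaces on the rejected candidate couples
the database to unaccepted points and was deliberately not implemented.

## The toy ventricular model

The bundled cell model is intentionally small — five membrane currents, five
states plus one bookkeeping state — but structurally faithful to the models
this machinery targets:

* \(I_{Ca}\): L-type-like calcium current, instantaneous activation
  (midpoint −10 mV), gated inactivation `f` (\(\tau_f\) = 150 ms);
* \(I_K\): delayed-rectifier potassium current, activation `n`
  (\(\tau_n\) = 250 ms);
* \(I_{K1}\): inward rectifier with a voltage/Nernst-dependent gate;
* \(I_{NaK}\): sodium–potassium pump (imports 2 K⁺ per cycle, hence the
  −2 in \(I_{K,tot}\));
* \(I_{Kp}\): plateau potassium current;
* \(I_{Cl,bk}\): a background chloride leak \(G_{Cl,bk}(V - E_{Cl,bk})\).

The leak is essential, not decorative: without any inward background
current the resting potential would sit *below* \(E_K\), the resting
inward-rectifier current would be inward, and the cell would import
\(\approx 3 I_{NaK}\) worth of potassium every quiescent millisecond — an
imbalance (about −1000 ms·pA/pF per cycle) that no admissible conductance
change can cancel.  This mirrors real human-ventricular models, where the
background chloride current is among the strongest regulators of potassium
balance.  \(G_{Cl,bk} = 0.031\) was chosen once so that the baseline
one-cycle integral is small (≈ −3 ms·pA/pF) but not zero.

Intracellular potassium obeys \(dK_i/dt = -\kappa_K I_{K,tot}\) with
\(\kappa_K = C_{mem}/(V_{myo} F) = 6\times10^{-5}\)
mM·(pA/pF)⁻¹·ms⁻¹, and the stimulus charge is booked as potassium — the
same convention as the budget above — so pacing itself cannot create
artificial drift.  A sixth state `qK` integrates \(I_{K,tot}\) alongside
the solution, which makes per-beat potassium budgets exact to solver
tolerance without dense output; the identity
\(\Delta K_i = -\kappa_K \Delta q_K\) holds to the integrator tolerance and
is asserted in the tests.

The default stimulus is −40 pA/pF for 2 ms.  The model has no fast sodium
current, so the stimulus itself must carry the membrane from rest (≈ −84 mV)
to the calcium activation threshold (≈ −10 mV); weaker pulses (e.g. half
this charge) fail to elicit an AP at all.  The default initial state
(V = −86 mV) is deliberately not the settled rest point (≈ −84 mV with the
leak); protocols settle it within the first beats.

## Numerical choices

* Integration: `deSolve::ode` with `lsoda` (adaptive, switches to BDF when
  stiff), relative tolerance \(10^{-6}\), absolute tolerances \(10^{-6}\)
  for voltage and \(10^{-9}\) for gates and concentrations, compiled C
  right-hand side for the toy model (a pure-R reference implementation is
  asserted identical in the tests).
* Stimulus edges are passed to the solver as events, so the adaptive
  stepper restarts exactly at each discontinuity and never smears a pulse.
* Long trains are integrated in chunks of a few hundred beats; restart at a
  beat onset is exact up to solver tolerance (asserted), and memory stays
  bounded at paper-scale 3000-beat protocols.
* Traces for marker extraction use a 0.02 ms output grid; APD thresholds
  are located by linear interpolation between samples.  AP onset is defined
  at stimulus delivery (robust for slow upstrokes); for external traces
  without stimulus annotation, onset falls back to the steepest-upstroke
  convention.
* The biexponential adaptation fit is restarted from a deterministic
  3 × 3 grid of time-constant initializations; a single-exponential
  reference fit is preferred when it matches the best biexponential
  residual (the degenerate equal-\(\tau\) split), and \(\tau_{slow}\) is
  flagged unidentifiable when \(|A_{slow}| < 1\) ms.

## The sensitivity convention

One-at-a-time ±30% conductance perturbations give percentage changes
\(D_{\pm}\) and the index \(S = (D_{+a} - D_{-a})/(2a)\), under which a
property scaling proportionally with its conductance yields exactly
\(S = 100\%\) — the convention matching the magnitudes customarily quoted
for such analyses (hundreds of percent for dominant conductances).  A
formulation that additionally multiplies by 100 exists in the literature;
it yields 10,000% at unit elasticity and is available as
`convention = "literal"` for auditing, but it is not the default.
`select_decision_variables()` turns the narrative practice of discarding a
conductance that uniquely dominates some marker into a mechanical rule with
two thresholds (dominance 100%, compensation 30% by default).

## What the toy scenario does and does not show

`make_toy_scenario()` computes baseline markers (steady-state pacing, 300
beats at CL 1000 and 2000 ms), sets bands at baseline ±10% (±15% for
calcium), multiplies \(G_{K1}\) by 1.3 and \(G_{Ca}\) by 0.85 — which moves
the one-cycle potassium integral from ≈ −3 to ≈ +15 ms·pA/pF — and asks the
optimizer to re-balance with decision variables
\(\{G_{Ca}, G_K, G_{K1}, G_{NaK}\}\).  The calibration drives the integral
below \(5\times10^{-2}\) in magnitude with all bands satisfied within
roughly 15 trust-region iterations (a few minutes of CPU at the 300-beat
profile).

\(\tau_{slow}\) is *not* constrained in this scenario: the toy model's APD
adapts within two beats of a cycle-length switch and its fitted slow
amplitude is far below the 1 ms identifiability threshold, so a band on it
would be noise.  The fitting machinery is instead validated on synthetic
biexponential series with known constants.  More generally, passing the toy
scenario demonstrates that the optimizer, protocols and markers compose
correctly — it does not certify behaviour on stiff 40-state human
ventricular models, whose calcium subsystems, slow adaptation dynamics and
evaluation costs are far richer.  The 300-beat "steady state" is a
desk-scale stand-in for the reference 3000-beat protocol (both are config
knobs; `n_beats = 3000` reproduces the reference conditions at ~10× cost).

## Known limitations

* The CellML adapter reads a flat single/multi-component subset (content
  MathML with arithmetic, `exp`/`ln`/`abs`, no units, no imports or
  encapsulation); it round-trips the bundled model and comparably
  structured documents, not arbitrary repository files.
* The subproblem solver is a multi-start augmented Lagrangian, not a global
  optimizer; with strongly multimodal surrogates the kept solution is the
  best of five deterministic starts.
* Equality constraints are carried in the formulation but unused (none are
  defined for this application).
* Tissue-level propagation (fibers, conduction velocity) is out of scope;
  all protocols are single-cell.
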