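---
title: "Kinematic models of diastole: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematic models of diastole: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diastkin)
```

## The physiology and the two models

During diastole the left ventricle first relaxes at constant volume
(isovolumic relaxation, IVR) and then, once ventricular pressure falls below
atrial pressure and the mitral valve opens (MVO), fills rapidly by elastic
recoil — mechanical suction. The ventricular pressure contour is smooth and
continuous across MVO, so the force the chamber generates at the end of IVR
and the force that launches early rapid filling are two views of one
physiologic process. `diastkin` implements the two kinematic models that
quantify each side, inverts both from per-beat recordings, and tests the
continuity prediction that the two model-derived forces are linearly related
across beats.

**E-wave (PDF) model.** Early filling is modelled as recoil from rest of a
unit-mass damped oscillator,

$$\ddot x + c\,\dot x + k\,x = 0, \qquad x(0) = x_o,\ \dot x(0) = 0,$$

whose speed $|\dot x(t)|$ is fitted to the transmitral Doppler E-wave
maximum-velocity envelope. The parameters are chamber stiffness $k$
(s$^{-2}$), viscoelasticity/relaxation $c$ (s$^{-1}$), and the initial load
$x_o$ (cm), all per unit mass. Derived indexes: the initial force (and peak
atrioventricular pressure-gradient analogue) $F_i = k\,x_o$ (cm/s$^2$), the
stored elastic energy $\tfrac12 k x_o^2$, the peak velocity, and the damping
regime ($c^2 \lessgtr 4k$).

**IVR (Chung) model.** Isovolumic pressure decay obeys the same second-order
kinematics in pressure,

$$\ddot P + \frac{1}{\mu}\,\dot P + E_k\,(P - P_\infty) = 0,$$

with elastic parameter $E_k$ (s$^{-2}$), relaxation parameter $\mu$ (s) and
pressure asymptote $P_\infty$ (mmHg, unconstrained in sign — negative
asymptotes are physiologic). In the pressure phase plane ($dP/dt$ vs $P$)
this model spans the whole observed range of IVR morphologies: as
$\mu \to 0$ with $\mu E_k$ fixed it collapses to the Weiss mono-exponential
(a straight phase-plane line of slope $-\mu E_k = -1/\tau$), while larger
$4\mu^2 E_k$ produces the curvilinear segments that the logistic model fits,
including the region before the $dP/dt$ minimum that neither comparator can
represent. Both comparators are provided (`weiss_tau`, `logistic_tau`).

**The force pair.** At the end of IVR the terminal force is pressure times
the effective mitral valve area, $F_t = P_\mathrm{MVO}\cdot\mathrm{MVA}$,
with $P_\mathrm{MVO}$ approximated by LVEDP (left-atrial pressure is not
recorded at routine catheterization) and MVA treated as the constant
4 cm$^2$. At the start of filling the initial force is $F_i = k\,x_o$.
Continuity of the pressure contour across MVO predicts the per-beat pairs
$(F_i, F_t)$ fall on a line, which `regress_forces` estimates per subject
and pooled.

### Units and orientation

$F_t$ is reported in mmHg·cm$^2$ (optionally dyn, 1 mmHg = 1333.22
dyn/cm$^2$); $F_i$ is per unit mass in cm/s$^2$ internally and m/s$^2$
(÷100) in pipeline output. Because an absolute-pressure force and a per-mass
force are regressed against each other, the slope magnitude depends on the
declared unit pair; the correlation does not. Every result row therefore
carries a `unit_convention` tag, and mixing conventions in one regression is
an error.

Both regression orientations are first class: `ft_on_fi` fits
$F_t = \alpha F_i + b$, `fi_on_ft` fits the reverse; $R$ is identical.
In the synthetic cohort the generator scatters $F_i$ conditional on $F_t$
(see below), so the orientation whose OLS consistently recovers the
generating line is `fi_on_ft` — regressing the noisy variable on the clean
one — and the pipeline's recovery analysis converts that fit back to
$(\alpha, b)$. With scatter on the predictor instead, OLS attenuates the
slope (classical errors-in-variables), which is worth remembering when
interpreting either orientation on real data.

## Inversion: estimator design

Both inverse problems are solved with Levenberg-Marquardt
(`minpack.lm::nls.lm`, `ftol = ptol = 1e-15`, up to 500 polish iterations).

* **`fit_pdf`** minimizes velocity residuals over $(k, c, x_o)$ with bound
  constraints ($k > 0$, $c, x_o \ge 0$). Starting values come from moment
  heuristics: $x_o$ from the velocity-time integral, $k$ from the lobe
  duration as an undamped quarter-wave, $c$ from peak asymmetry; a small
  damping grid of restarts is tried if the first attempt stalls. For
  noiseless model-generated contours the recovery is exact to optimizer
  tolerance and independent of the start.

* **`fit_chung`** minimizes a weighted joint residual over the $P(t)$ and
  $dP/dt$ channels for $(E_k, \mu, P_\infty)$, optionally also the window
  initial conditions $(P_0, \dot P_0)$ (`fit_ics = TRUE`). Under noise the
  objective is multi-modal — an undamped quarter-cosine can mimic a
  near-critical decay, and the flat valley $\mu E_k \approx$ const. traps
  local optimizers — so the fit always multi-starts across damping regimes
  plus two "Weiss-informed" starts whose decay rate comes from the
  phase-plane OLS slope, keeps the best exploration result, and polishes it
  at full precision.

### Channel weighting

The two channels differ by orders of magnitude in scale, and the measured
$dP/dt$ is not an independent recording but a Savitzky-Golay transform of
the same pressure samples. The default weighting (`weighting = "noise"`) is
therefore generalized-least-squares-flavoured: the pressure-noise sd is
estimated from robust fourth differences of the window samples (the
signal's own contribution is $O(P''''\,\Delta t^4)$, negligible), and the
derivative channel's noise sd is that estimate times the differentiator's
white-noise gain, which `differentiate` attaches to its output. Two
degenerate regimes are handled explicitly:

* essentially noiseless samples (estimated sd below 0.02 mmHg): the derived
  channel then carries only stencil bias and no information beyond $P$
  itself, so the pressure channel alone is fitted and exact solutions are
  recovered exactly;
* a derivative channel of unknown provenance (no attached noise gain, e.g.
  an externally measured $dP/dt$): the fallback equalizes the two channels'
  sample variances; explicit numeric `weights` override everything.

The mildly smoothed fit channel is deliberate: it acts as a regularizer
along the $(E_k, \mu)$ likelihood ridge and reduces the skew of $\hat\mu$
at realistic noise without affecting the noiseless limit.

### Window extraction

`extract_ivr_segment` implements both window conventions on 0-based,
half-open indices. The Chung-mode window opens at the first post-peak
sample where $dP/dt$ falls below a configurable fraction (default 25%) of
the $dP/dt$ minimum — i.e. at pressures above the pressure of the minimum,
so the curved pre-minimum region is included — and closes after the last
sample with $P \ge$ LVEDP. The Weiss-mode window opens at the $dP/dt$
minimum itself and closes just above LVEDP (default margin 1 mmHg). The
Chung window always contains the Weiss window. Samples within one stencil
half-width of the trace ends are excluded from minimum location, because
one-sided differentiation stencils amplify noise severely there.

In the per-beat pipeline driver (`fit_ivr_beats`) the derivative used to
*locate* the window is smoothed harder (default window 31 samples) than the
default reporting derivative (window 11): a threshold crossing on a noisy
derivative is biased early by first passage, and Monte-Carlo profiling
showed this location jitter, not the fit itself, dominated the bias of
$\hat\mu$. The fit channel uses an intermediate window (21). All three are
arguments.

## The synthetic cohort

`cohort_spec`/`sample_cohort`/`render_beat` generate cohorts with the
structure of the validation study: 20 subjects, 15 beats each, subject-level
parameter means drawn from truncated normal distributions with the study's
summary statistics ($x_o$ 9.6 ± 1.6 cm, $k$ 211 ± 44 s$^{-2}$, $c$ 16.6 ±
4.1 s$^{-1}$, $E_k$ 1552 ± 763 s$^{-2}$, $\mu$ 13 ± 9 ms, LVEDP 16 ± 4
mmHg, HR 63 ± 6 bpm), and within-subject beat-to-beat jitter at 5% CV — a
declared assumption, since beat-to-beat variability is not quantified in
the source summary.

Design choices that deserve justification:

* **Coupling at the force level.** Each beat's $F_t$ is fixed by its drawn
  LVEDP ($F_t = \mathrm{LVEDP}\cdot 4$); $F_i$ is then set from the
  continuity line $F_i = (F_t - b)/\alpha + \varepsilon$ (defaults
  $\alpha = 1.62$, $b = 1.32$) and the E-wave load re-derived as
  $x_o = 100\,F_i/k$. The hypothesis under test lives at the force level,
  so that is where the generator imposes it. A consequence: the realized
  $x_o$ marginal is determined by LVEDP, $k$ and the coupling rather than
  matching its nominal table entry — one cannot impose both.
* **Calibrated scatter.** With scatter on $F_i\mid F_t$, the pooled
  correlation is $R = (1 + \alpha^2\sigma^2/\mathrm{Var}\,F_t)^{-1/2}$.
  The default $\sigma$ inverts this at the target $R = 0.80$ using the
  LVEDP-implied $\mathrm{Var}\,F_t$; it is stored in the spec, not
  hard-coded downstream.
* **Decay rendered from rest at end-systolic pressure.** The IVR segment
  starts at a drawn $P_{es} \sim N(90, 10)$ mmHg (aortic-valve-closure
  pressure) with $\dot P(0) = 0$, preceded by a gentle raised-cosine
  end-ejection shoulder (6 mmHg over 80 ms) whose peak $|dP/dt|$ stays far
  below any physiologic decay minimum, and ends a few mmHg below LVEDP so
  noisy traces still cross it. Starting the decay near 2×LVEDP instead
  would leave a ~16 mmHg, ~40 ms segment whose Cramér-Rao bound at 0.5 mmHg
  noise exceeds 100% relative sd for $E_k$ and $\mu$ — an unidentifiable
  inverse problem — besides being the wrong physiology: IVR begins at
  aortic-valve closure, far above 2×LVEDP.
* **Feasibility screening.** Subject draws whose model decay would not
  reach LVEDP within about one cardiac cycle (possible in the far left tail
  of the wide $E_k$ distribution) are rejected and re-drawn, with the count
  recorded. This trims the infeasible tail of the $E_k$/$\mu$ marginals by
  a few percent; the unscreened parameters ($k$, $c$, LVEDP, HR) retain
  their nominal moments, which is what the statistical-fidelity test
  checks.
* **Beat count.** The validation cohort averaged ~15 beats/subject (308
  total); a constant 15 gives 300. The spec of the cohort is a parameter,
  not a reproduction target.

What the generator does *not* emulate: A-waves and E-A merging, respiratory
and RR-interval variation, baseline drift and catheter artefacts,
quantization, or any dependence structure between the PDF and Chung
parameters beyond the force coupling. Passing recovery tests on these
cohorts therefore demonstrates correctness of the estimators under the
stated noise model, not robustness to every clinical artefact.

## Numerical choices

* Damping-regime classification treats $|c^2 - 4k| \le 10^{-9}k$ as
  critical and evaluates each regime's closed form (`sin/ω`, `sinh/β`,
  `t·e^{-ct/2}`), which are continuous across the boundary; the overdamped
  branch uses expanded exponentials so the deep Weiss limit
  ($\mu \to 10^{-6}$ s) stays finite.
* A pure exponential input determines only the slow eigenvalue of the decay
  equation ($a - \sqrt{a^2 - E_k}$ with $a = 1/2\mu$), not $(E_k, \mu)$
  separately: any $\mu$ with $E_k = (1/\mu - 1/\tau)/\tau$ reproduces it
  exactly. Tests of the exponential limit therefore assert the eigenvalue.
* Flat contours, constant pressure, windows without a closable LVEDP
  crossing, non-uniform sampling, and missing metadata all raise named
  errors; windows lacking pre-minimum samples warn that the model's
  distinguishing region is missing.
* Problem sizes in the test-suite and acceptance script — 50-draw
  forward-fidelity sweeps, 100-replicate Monte-Carlo recovery, one
  20×15-beat cohort — were chosen as the smallest sizes at which the
  Monte-Carlo standard errors are comfortably below the tolerances being
  asserted.

## Limitations

Terminal force uses the LVEDP proxy for $P_\mathrm{MVO}$ and a constant
MVA, inheriting both approximations. Per-subject regressions on synthetic
cohorts have low within-subject $R$ by construction (5% CV beat jitter
against the calibrated between-subject scatter); matching the per-subject
correlation structure of real data would require a within-subject coupling
model the source statistics do not constrain. The Chung inverse problem is
intrinsically ill-conditioned on short, low-amplitude windows; diagnostics
(`converged`, RMSE per channel, reason codes) should be consulted before
interpreting per-beat $E_k$, $\mu$ on real recordings.
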