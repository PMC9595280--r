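---
title: "A hemodynamics-driven model of third heart sound generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hemodynamics-driven model of third heart sound generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s3sim)
```

The third heart sound (S3) is a low-frequency, early-diastolic sound heard
during rapid ventricular filling: in young and exercising hearts, and in
heart failure with preserved ejection fraction (HFpEF), atrioventricular
(AV) valve regurgitation and septal shunts.  `s3sim` implements the
ventricular theory of S3 genesis as a closed physics chain: a
lumped-parameter circulation produces per-millisecond pressures, volumes,
valve flows and effective valve areas; at the peak of early-diastolic AV
inflow, the momentum of the blood column entering over one 1 ms snapshot
is transferred by perfectly inelastic collision to the *cardiohemic mass*
(ventricular free wall plus cavity blood); the resulting free vibration of
a one-degree-of-freedom mass--spring--dashpot system is the single-sided
S3.  The left- and right-sided waveforms are summed, and the sum is
analysed as a phonocardiographic signal.

# The vibration model

Each ventricle contributes an oscillator

$$M \ddot{x} + c\,\dot{x} + k\,x = 0, \qquad
x(0) = 0,\quad \dot x(0) = V_a,$$

with $M = M_{ch} + m$.  The cardiohemic mass is
$M_{ch} = m_{myo} + m_{bld}$, with $m_{myo}$ the ventricular wall volume
times the myocardial density 1055 kg/m³ and $m_{bld}$ the instantaneous
cavity blood volume times the blood density 1050 kg/m³.  The exciting
momentum comes from the inflow snapshot at the trigger instant:
$m = Q\,\Delta t\,\rho_{bld}$ with $\Delta t$ = 1 ms, and
$v = Q/A_{valve}$; conservation of momentum across the inelastic impact
(the wall is at rest at the trigger moment, $V_b = 0$) gives

$$V_a = \frac{m\,v}{M_{ch} + m}.$$

The analytic underdamped solution

$$x(t) = \frac{m\,v}{(M_{ch}+m)\,\omega_d}\;
e^{-\zeta\omega_n t}\,\sin(\omega_d t),$$

with $\zeta = c/2\sqrt{k M}$, $\omega_n = \sqrt{k/M}$,
$\omega_d = \omega_n\sqrt{1-\zeta^2}$, is sampled at 1 kHz until its
envelope decays below 1 % of the peak or 200 ms.  Coefficients are frozen
at the trigger instant: the analytic solution is the constant-coefficient
one, and the test suite verifies it against an independent Runge--Kutta
integration of the differential equation to $10^{-9}$ relative accuracy.

## Trigger rule

The model is activated at the peak of the early-diastolic E wave,
restricted to the window between peak ventricular activation and atrial
activation onset so the atrial (A) wave can never trigger it.  Because the
package gives the AV valves blood-column inertance (below), peak inflow
coincides with the zero crossing of the net transvalvular driving
pressure: at that moment no net force accelerates the inflow, the column
begins to decelerate, and the system is exactly in the free-vibration
state the model assumes.  A quasi-steady valve law cannot produce this
coincidence (flow would peak where the *gradient* peaks), which is why the
inertial closure is used.

## Spring and damper

The paper-level statement "k derives from myocardial stiffness" leaves two
choices open: which stiffness, and what geometric conversion from
elastance (pressure/volume) to a spring constant (force/length).  The
package uses

$$k = \kappa\; S(V_{ed})\; A_{e\!f\!f}^2, \qquad
S(V_{ed}) = E_{ed}\,e^{(V_{ed}-V_0)/V_s},$$

where $S(V_{ed})$ is the slope of the passive end-diastolic
pressure--volume relation **at the ventricle's operating end-diastolic
volume**, converted to Pa/m³, and
$A_{e\!f\!f} = (36\pi)^{1/3} V^{2/3}$ is the sphere-equivalent endocardial
area at the trigger instant ($E_{ed} A^2$ has units N/m).  Evaluating the
stiffness at the operating point matters: volume-overloaded ventricles
(regurgitation, shunts) operate higher on the nonlinear passive curve and
are therefore stiffer, which is the mechanism that raises S3 frequency in
those conditions; a constant-elastance variant cannot express it and was
rejected during development (it predicts *falling* right-sided S3
frequency with worsening tricuspid regurgitation, because the regurgitant
ventricle is at a *low* volume at the E-wave peak).  Stiffness evaluated
at the instantaneous impact-time volume was rejected for the same reason.

The single dimensionless scale $\kappa$ is calibrated **once**: it is
chosen so the reference (healthy rest) left-ventricular S3 damped
resonance lands at 27 Hz, the centre of the low-frequency S3 band, then
frozen (`s3_kappa()`; value 1.9832).  Every condition-to-condition change
in frequency or amplitude is thereafter driven purely by hemodynamics and
geometry.

A literal reading of "damping is 10 % of the spring factor" is
dimensionally inconsistent (N·s/m vs N/m) and would make the oscillator
heavily overdamped --- no oscillatory S3 at all.  The package reads the
10 % as a fraction of *critical* damping:
$c = 0.1 \cdot 2\sqrt{kM}$, i.e. $\zeta = 0.1$, which yields the damped,
few-cycle transients seen in phonocardiograms.

# The circulation surrogate

The hemodynamic driver is a compact closed-loop 0D circulation, not a
reimplementation of any larger model: four time-varying elastance chambers
(LA, LV, RA, RV), four valves, systemic and pulmonary RC windkessel beds,
and an optional septal orifice.  Chamber pressure is
$P = a(t)\,E_{max}(V - V_{0a}) + E_{ed}V_s\,(e^{(V-V_{0p})/V_s}-1)$, with a
raised-cosine activation rising over 30 % of the cycle (10 % for the
atria, onset at 85 % of the cycle) and exponential relaxation with time
constant $\tau$ (45 ms ventricular, 40 ms atrial at rest).  Valves obey
$\Delta p = R_{lin}q + \tfrac{\rho}{2A^2}q|q|$ with a flow-direction
dependent area (forward area reduced by stenosis; leak fraction of the
open area against the gradient); the two AV valves additionally carry an
inertance $\rho L/A$ with an effective blood-column length of 1.5 cm, so
mitral and tricuspid flow are state variables with realistic E/A-wave
dynamics.  Fixed-step RK4 at 0.25 ms (outputs each 1 ms) integrates the
ten states; total blood volume is conserved to machine precision by
construction, and the steady state is declared when the beat-to-beat
relative change of all states falls below $10^{-4}$ (cap 200 beats).

Reference parameters describe a generic resting adult: aortic pressure
~113/70 mmHg, stroke volume ~71 mL at 70 bpm, LV wall 140 mL, RV wall
60 mL, mitral/tricuspid/aortic/pulmonary areas 5/6/3/3.5 cm².  They were
fixed once, from textbook hemodynamics, before any acceptance measurement.

## Homeostatic regulation

All conditions are regulated to a mean arterial pressure of 91 mmHg and
the condition's cardiac-output target by multiplicative proportional
updates of exactly two quantities between steady-state runs: systemic
peripheral resistance (targets pressure, gain exponent 0.7) and total
circulating volume (targets output, gain exponent 0.5, applied to the
venous reservoir, per-step change capped at ±15--18 %).  Convergence is
declared inside the contract tolerances (internally |MAP−91| ≤ 0.35 mmHg,
|CO−target| ≤ 0.7 %); non-convergence raises a regulation failure carrying
the last iterate.

## The condition protocol

Diseases modify the baseline set exactly as the severity sweeps
prescribe: aging multiplies ventricular $E_{ed}$ and $\tau$ by
$1+0.02\,s$ ($s$ = 1..6); mitral/tricuspid regurgitation leaves 8--14 %
(2 % steps) of the valve area open against the gradient; stenosis narrows
the forward area by 50--80 % (10 % steps); atrial/ventricular septal
defects open a 6--12 mm orifice (2 mm steps); HFpEF raises LV $\tau$ by
80 % in all grades and LV $E_{ed}$ by 0/75/130 % for grades I--III.

Exercise raises the cardiac-output target from 5 to 14 L/min in 3 L/min
steps with heart rate interpolated linearly from 70 to 130 bpm.
Chronotropy alone cannot reach 14 L/min at a regulated MAP of 91 mmHg: at
130 bpm the diastolic window is ~0.2 s and a 108 mL stroke volume would
demand venous pressures above 40 mmHg.  The exercise mapping therefore
includes sympathetic drive, scaling every chamber's active elastance by
$1+(HR-70)/60$ and dividing its relaxation constant by the same factor ---
doubled inotropy and halved relaxation time at peak exercise, within the
physiological range reported for healthy adults.  The scaling applies
equally when a disease is run at an exercise operating point, so
disease-versus-exercise comparisons remain internally consistent.

# Acoustic analysis

The combined S3 is the sample-wise sum of the LV and RV waveforms, each
placed at its own trigger time on the common cycle axis, without
rescaling (equal interside weighting; no evidence supports another
choice).  The band-energy spectrum low-passes at 300 Hz (6th-order
zero-phase Butterworth), applies a Hann window, zero-pads to at least
0.5 Hz resolution, and integrates the magnitude spectrum over 15 Hz bands
by the trapezoidal rule, normalising by the total so band energies sum to
one; the dominant frequency is the spectral argmax below the cutoff.
Phonocardiogram preprocessing follows the standard recipe: resample to
1 kHz, zero-phase band-pass 25--400 Hz (4th-order Butterworth), then
despike by moving-window median clipping (20 ms window, 5 robust standard
deviations) --- the despiking method itself is a package choice, as is the
Hann/zero-padding detail of the spectrum.

Integrated loudness follows ITU-R BS.1770 / EBU R 128: K-weighting with
the standardised 48 kHz biquads (signals are upsampled to 48 kHz
internally; the 1 kHz rate is kept for spectra), mean square over 400 ms
blocks with 75 % overlap, the −0.691 dB offset, a −70 LUFS absolute gate
and a relative gate 10 LU below the ungated level.  Because LUFS is
gain-dependent and the physical displacements are of order $10^{-5}$ m,
all conditions share one fixed physical-to-digital gain
(`s3_gain()` = 2×10⁴ per metre) so loudness differences across conditions
and exercise levels are meaningful; the absolute LUFS numbers have no
physical meaning.  Signals shorter than one gating block are zero-padded
to 400 ms.

# Numerical choices and degenerate inputs

* Cycle length is rounded to an integer number of milliseconds, so the
  realised heart rate can differ from the request by <0.1 %.
* A competent (non-leaking) AV valve clamps retrograde flow to zero after
  each integration substep; regurgitant valves integrate through the leak
  area instead.
* A negative or non-finite compartment volume aborts the beat with an
  integration-failure error; an E-wave peak below 1 mL/s raises a
  "no trigger" condition for that side.
* $\zeta \ge 1$ (possible only with non-default damping policies) is
  refused by the waveform sampler unless the aperiodic closed form is
  explicitly requested.
* The momentum identity $(M_{ch}+m)V_a = m\,v$ holds to machine precision
  for every impact event; the test suite asserts it across all conditions.

# What the simulations do and do not show

All inputs are synthetic: the circulation surrogate emulates the
*hemodynamic regimes* of the study conditions (operating pressures,
E-wave augmentation and delay, volume overload, shunt flows) rather than
any patient.  It omits, among other things: wall-motion mechanics and
regional function, pericardial constraint, valve leaflet dynamics,
baroreflex within a beat, respiratory variation, thoracic transmission
and ambient noise.  Passing trend tests therefore demonstrates that the
vibration model responds to hemodynamic changes with the correct signs
and plausible magnitudes --- not that the synthesized sounds match any
individual recording.  One protocol cell is genuinely infeasible: severe
mitral stenosis (80 % narrowing) cannot sustain 14 L/min at MAP 91 mmHg,
so the grid records a regulation failure for that cell, mirroring the
exercise limitation of severe stenosis.

Problem sizes used throughout the examples and tests: one cardiac cycle
is ~857 samples at 1 ms; a full condition pipeline (adaptation included)
runs in ~0.3 s; the complete condition × exercise grid (~110 adapted
simulations) in about one minute.

# A worked reference run

```{r, eval = FALSE}
library(s3sim)
res <- run_condition(condition_config())
res
#> <condition_result> reference (severity 1): MAP 91.2 mmHg, CO 5.02 L/min
#>      side     peak_amp dominant_freq onset_ms  loudness
#>        LV 4.904345e-06      26.85547      420 -43.63648
#>        RV 4.259826e-06      27.34375      366 -45.60803
#>  combined 4.259826e-06      22.46094      366 -44.33706
```

The left-sided S3 starts at the mitral E-wave peak (420 ms after
ventricular activation onset), the right-sided one earlier (366 ms); each
oscillates near 27 Hz.  In the summed two-ventricle signal the two
closely spaced lines interfere, so the spectral argmax of the *combined*
signal sits a few hertz below the single-sided peaks; about 88 % of its
band energy lies below 60 Hz.
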