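---
title: "Models and methods behind wristexo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wristexo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristexo)
```

wristexo models the two phases of rehabilitation after a distal radius
fracture (DRF) as supported by wearable wrist exoskeletons: the early
*fixation* phase, in which the reduced fracture end must be held stable
while limited joint motion is permitted, and the later *resistance
training* phase, in which wrist motion is loaded elastically to rebuild
muscle strength. Around these sit the monitoring analyses such devices
rely on — repetition counting and range-of-motion (ROM) extraction from
joint-angle traces, and muscle-activation quantification from surface
EMG — plus synthetic generators that stand in for human recordings.

This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where a choice was genuinely
open.

## Fracture-end friction statics

The fracture plane is treated as an inclined frictional contact. With a
contact force of magnitude $N$ pressing the fragments together and a
fracture line inclined at $\alpha$, the normal and tangential components
are $N\cos\alpha$ and $N\sin\alpha$; without fixation the fragment is
stable iff $\tan\alpha \le f$, the classical friction cone. An external
fixation force $G$ applied across the fracture adds $G\sin\alpha$ to the
friction-generating load and removes $G\cos\alpha$ from the tangential
drive, so stability becomes

$$N\sin\alpha - G\cos\alpha \le f\,(N\cos\alpha + G\sin\alpha),$$

equivalently $\tan\alpha_{max} = (fN+G)/(N-fG)$. Two consequences are
tested as properties: $\alpha_{max} \ge \arctan f$ always (fixation can
only help), and $\alpha_{max}$ is non-decreasing in $G$.

The analysis is scalar: forces are magnitudes resolved along and across
the fracture line, with no vector fracture model, no tissue mechanics,
and no way to estimate $N$, $G$ or $f$ from imaging — these are inputs.
When $N - fG \le 0$ the inequality holds for every inclination below
$90^\circ$; rather than erroring, `max_stable_angle()` returns a result
tagged `bounded = FALSE`. Angles are degrees at every user-facing
boundary and radians internally.

## Planar Lagrangian model of resisted wrist rotation

The hand is a point mass $m$ at distance $d$ from the wrist joint, which
sits at the end of a forearm of length $l_1$; $\theta$ is the rotation
from the neutral (forearm-aligned) pose, extension positive. A linear
spring of stiffness $k$ connects a hand anchor at distance $l_3$ from
the joint to a forearm anchor offset $l_4$ from the forearm axis, slack
at $\theta = 0$. The energies are

$$E_k = \tfrac12 m d^2\dot\theta^2,\qquad
  E_{p1} = m g d \sin\theta,\qquad
  E_{p2} = \tfrac12 k\,\Delta x(\theta)^2,$$

with the elongation obtained from the anchor coordinates,

$$\Delta x = \sqrt{l_1^2+l_3^2+l_4^2 - 2l_1l_3\sin\theta -
  2l_3l_4\cos\theta} - \sqrt{l_1^2+(l_3-l_4)^2}.$$

The Euler–Lagrange equations give the free joint torque
$T_1 = m d^2\ddot\theta + m g d\cos\theta$ and, with the spring, an
extra term $T_e = k\,\Delta x\,\mathrm{d}\Delta x/\mathrm{d}\theta$ so
that $T_2 = T_1 + T_e$ *identically* — the implementation computes
`T2` as that sum, and the test suite verifies $T_e$ against a
central-difference derivative of $E_{p2}$ (step $10^{-6}$ rad, agreement
to $10^{-6}$ of the torque scale over $\theta \in [-75^\circ, 70^\circ]$)
and checks energy bookkeeping on a trajectory integrated with `deSolve`.
The chain-rule form of $T_e$ is taken as ground truth because it is
forced by the Lagrangian derivation; any hand-expanded variant must
agree with it.

The model is single-DOF and planar by construction; it does not couple
flexion/extension with deviation and makes no muscle-force claims. No
standard anthropometric parameter set exists for this geometry, so the
defaults (`m` 0.4 kg, `d` 0.08 m, `l1` 0.25 m, `l3` 0.05 m, `l4`
0.03 m, `g` 9.81 m/s²) were chosen once as a plausible adult
configuration and used unchanged by all examples and tests. A hand
length `l2` can be stored for bookkeeping but enters no equation.

## Rope-spring resistance device kinematics

The resistance training device (RTD) loads the wrist through four
rope-spring kits: each rope leaves a pulley outlet $A$ on the forearm
module, crosses the wrist, and ends at an anchor $B$ on the hand module
in series with an extension spring. The 2-DOF wrist is modelled with
modified Denavit–Hartenberg parameters: joint 1 is flexion/extension
about the base $z$ axis, joint 2 is radial/ulnar deviation, reached
through a link twist of $-\pi/2$ and a constant joint offset of
$-\pi/2$ (`rtd_dh_table()`). The closed-form forearm-to-hand rotation is
verified against the explicit product of the two link transforms to
$10^{-12}$ over $10^4$ random poses.

Kit elongation is the distance $\lVert R(\theta_1,\theta_2) B - A\rVert$
minus its neutral-pose value. Conventions, fixed after deliberate
choice:

* **Anchor frames.** Both anchor coordinate sets describe the *neutral
  pose in the base frame*; the hand anchor is mapped into the hand frame
  through the inverse neutral transform before being driven by the
  kinematics (`b_frame = "base"`, the default). The alternative reading
  — hand anchors given directly in hand-frame coordinates — is kept
  available via `b_frame = "hand"`, but the base-frame reading is the
  one under which the four kits behave as the device intends (kits 1–2
  tension under flexion, 3–4 under extension, 1–3 under radial, 2–4
  under ulnar deviation, and the mirror symmetries hold exactly).
* **Signs.** $\theta_1 < 0$ is flexion (ROM $-75^\circ$ to $+70^\circ$);
  $\theta_2 > 0$ is radial deviation (ROM $-35^\circ$ ulnar to
  $+20^\circ$ radial). The $\theta_2$ sign is chosen so that the
  radially tensioned pair is kits 1 and 3, consistent with the kit
  layout.
* **Sweep mode.** The "available" resistance of a pattern is
  $F = 2 k x_{max}$ over the pattern's motion. By default
  (`sweep = "axis"`) the pattern's own axis is swept from neutral to its
  ROM extreme with the other axis at zero — what a pure single-pattern
  exercise realises. `sweep = "grid"` instead maximises over the full
  2-D ROM; it upper-bounds the force but couples flexion/extension
  excursion into the deviation patterns, which can overstate a pure
  deviation exercise several-fold, so it is not the default.
* **Slack ropes.** Negative elongations are reported as such by
  `kit_elongation()` (useful for geometry checks) but clamp to zero
  force in `group_force()`: a bent kit transmits nothing.
* **Units.** Geometry is mm throughout the kinematics; forces are N
  after an explicit mm-to-m conversion at the force step.

Spring rates come from the standard helical-spring formula
$k = G d^4 / (8 n D^3)$ with catalogue units (GPa, mm) in and N/m out.
The built-in low/high spring pair (wire 0.8 mm vs 1.0 mm, same coil
geometry) has a stiffness ratio of $(1.0/0.8)^4 \approx 2.44$, so the
high-resistance force column is 2.44 times the low one; pattern-to-
pattern force *ratios* are pure geometry and spring-independent, which
the suite checks. The listed shear modulus of the device's springs
(200 GPa) is used as given even though it is high for spring steel;
changing it rescales all forces linearly and nothing else.

## Motion monitoring

**Repetition counting** uses a hysteresis state machine: the counter
arms when the angle rises strictly above the upper threshold and
registers exactly one repetition when the armed trace falls strictly
below the lower threshold, then resets. "Falls below the lower
threshold" is deliberately interpreted as crossing *below* the bound:
the built-in threshold table contains negative lower bounds (e.g.
shoulder flexion/extension (30, $-30$)), which only make sense as a
return/overshoot requirement of a reciprocating motion. There is no
debouncing window — crossings have single-sample resolution — but a
minimum-duration flag is available (default 0 s). The count is invariant
to resampling and to amplitude-preserving time warps, and can never
exceed the number of upward crossings of the upper threshold.

**ROM extraction** reports the global minimum/maximum and per-repetition
peak excursions. Segmentation uses the lower threshold when one applies;
wrist traces have no counting thresholds, so they segment at upward zero
crossings with a $\pm 3^\circ$ deadband to keep sensor noise from
splitting segments. A segment still open at the end of a trace never
returned below the segmentation level and is not counted as a completed
repetition. Functional-ROM compliance compares directional excursions
against the functional limits (flexion 40°, extension 40°, radial 10°,
ulnar 20°; anatomical limits 75/70/20/35°).

**Relative joint angles** are computed from two segment orientations
(hand and forearm) given as intrinsic Z-Y-X Euler triplets in a shared
reference: the relative rotation $R_f^\top R_h$ is decomposed back into
Z-Y-X components and the requested component returned. Inputs with
relative pitch within $10^{-6}$ of $\pm 90^\circ$ are gimbal-degenerate;
the yaw/roll split is then conventional (roll set to zero) and the
result is flagged. Orientation estimation from raw inertial data is out
of scope — orientations are taken as given.

## Surface-EMG pipeline

**Denoising** is an orthogonal discrete wavelet transform with the
Daubechies db4 basis, decomposition level 2, soft thresholding of the
detail coefficients, and reconstruction. The transform uses circular
(periodized) convolution, which keeps it exactly orthogonal and
length-preserving; inputs whose length is not a multiple of $2^{level}$
are reflect-padded and truncated after reconstruction. The analysis
filters and a frozen level-2 decomposition are pinned against an
independent wavelet implementation in the test suite. The thresholding
rule — the part a denoising specification usually leaves open — is the
de facto standard: universal threshold $\sigma\sqrt{2\ln N}$ with
$\sigma$ estimated as $\mathrm{MAD}/0.6745$ of the finest-level details.
Soft shrinkage only contracts coefficients, so output energy never
exceeds input energy, and rectified area can only decrease.

Wavelet shrinkage presumes the clean signal and the noise separate in
scale: at 1000 Hz sampling, level 2 targets the 125–500 Hz detail bands.
A signal whose own spectrum fills those bands (as a flat 20–450 Hz
carrier does) cannot be separated from white noise there by any
coefficient shrinkage, and the noise estimate itself becomes
signal-contaminated; the denoising-improves-RMSE tests therefore use
surrogate records with a 20–150 Hz carrier, the regime real forearm sEMG
(dominant energy 50–150 Hz) actually occupies. This is a statement about
what the property *can* demonstrate, not a tuning of the method.

**iEMG**, the activation index, is the trapezoidal integral of the
rectified signal over a window, in mV·s. The window mean is subtracted
before rectification by default (`dc_remove = TRUE`) so an electrode DC
offset does not inflate the index; closed-form checks (constant signal
→ $cT$; 50 Hz sine of amplitude $A$ over $T$ → $2AT/\pi$) hold to
$10^{-3}$ relative. Integration is over the full record by default;
per-repetition windows can be formed from the burst segmentation when
burst-wise indices are wanted. iEMG is absolutely homogeneous
($\mathrm{iEMG}(cv) = |c|\,\mathrm{iEMG}(v)$), which is what makes the
condition comparison meaningful: per-condition percent increases are
$100(v/v_{none} - 1)$ against the no-resistance baseline, and subject
summaries report mean and sample standard deviation ($n-1$).

## Synthetic data: what it emulates and what it does not

**Angle traces** are reciprocating waveforms: each repetition is a
raised-cosine positive lobe followed by a mirrored negative lobe, so the
trace reaches $+A_i$ then $-A_i$ smoothly with zero end-point
derivative, plus Gaussian sensor noise (default SD 0.5°, a realistic
orientation-sensor figure). The half-compliant counting protocol
(`counting_protocol_config()`) generates ten repetitions of which the
first five peak 15° above the pattern's upper threshold and the last
five peak 5° below it — compliance is encoded purely by amplitude — and
the counter must report exactly five for every pattern.

**Surrogate sEMG** is amplitude-modulated band-limited Gaussian noise:
a carrier confined to 20–450 Hz by FFT masking, modulated by
per-repetition raised-cosine envelopes (default five 1 s bursts
separated by 1 s of rest), plus white noise. Defaults were fixed once:
base envelope 0.5 mV (a typical submaximal surface recording), additive
noise 0.005 mV RMS (5 µV — the baseline noise of a good electrode/
amplifier chain), and condition envelope scales (1.0, 1.3, 1.9) to
mirror a none < low < high activation ordering without claiming any
subject-specific percentages. Records for different conditions under
the same seed share the carrier and noise realisation, so the envelope
scale is the only difference between conditions.

The surrogate deliberately targets only the properties the analyses
consume — burst timing, envelope scale, noise floor, bandwidth. It has
no motor-unit structure, no within-band spectral shaping, no fatigue
drift, no movement artefacts, and is stationary within a burst. Passing
round-trip tests therefore demonstrates that the pipeline recovers what
it is designed to measure from signals with the assumed statistical
structure, not that it is robust to everything real electrodes produce.

All randomness flows through explicit integer seeds and a local RNG
scope, so generation never perturbs the caller's random stream and
fixed-seed outputs are byte-reproducible (the fixture bundle test checks
this literally).

## Numerical choices and problem sizes

* ROM sweeps run at 1° resolution; the elongation surfaces are smooth
  (adjacent-cell jumps below 2 mm at 1°), so finer grids change the
  tabulated forces only in the fourth digit.
* The transform-identity check uses $10^4$ random poses; Monte-Carlo
  recovery tests use 20 seeds, which puts the standard error of the
  recovered percent increases well below the 3-point tolerance asserted.
* Trapezoidal integration is used for all time integrals; closed-form
  checks of the rectified sine sample at 10 kHz because the rectified
  cusps dominate the quadrature error at coarser steps.
* Strict inequalities everywhere in threshold logic; boundary equality
  (a sample exactly at a threshold) does not trigger a crossing, and a
  repetition equaling the functional-ROM limit exactly passes
  compliance ($\ge$).

## Known limitations

The fixation statics cannot tell a user what $N$, $G$ and $f$ are for a
patient. The Lagrangian model is planar and single-DOF. The device
kinematics ignore pulley friction, rope stretch and cable routing, and
stop at force magnitude — no torque about the joint is derived from kit
forces. Monitoring assumes orientations are already estimated. The sEMG
stage makes no claim about onset detection, fatigue or frequency-domain
features, and synthetic percent-increase recoveries say nothing about
any particular human subject's values.
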