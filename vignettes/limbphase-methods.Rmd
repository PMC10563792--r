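---
title: "Phase shift, limb scaling and muscle timing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase shift, limb scaling and muscle timing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbphase)
```

## The model and its assumptions

A limb is one rigid segment of length $L$ rotating about a hinge, driven by
an antagonistic actuator pair acting through a moment arm $r$.  The joint
has intrinsic linear stiffness $k_{elas}$ and damping $c$; the principle of
virtual work converts both to rotational coefficients by multiplication
with $r^2$.  Two gait phases are modelled:

* **swing** — the leg hangs from the hip and carries only itself; the
  gravitational moment $m_L g\, l_{com}\,\theta$ restores the leg towards
  vertical and therefore adds to the elastic stiffness;
* **stance** — the leg pivots about the planted foot and carries the body,
  concentrated as a point mass $m_B$ at the hip; gravity now tips the
  system away from vertical and is subtracted from the stiffness, which can
  make the effective stiffness negative.

For the prescribed sinusoid $\theta = \Theta\sin\omega t$ the actuator
moment is $M = J_{eff}\ddot\theta + c_{eff}\dot\theta + k_{eff}\theta$ and
leads the angle by $\phi = \mathrm{atan2}(c_{eff}\omega,\; k_{eff} -
J_{eff}\omega^2)$, folded into $[0^\circ, 180^\circ]$.  Positive $\phi$
means the moment leads; the package never reports negative phases.
Dominance labels are computed from the four **moment amplitudes**
($J\omega^2\Theta$, $c\omega\Theta$, $k_{r,elas}\Theta$,
$k_{r,grav}\Theta$), not energies; both coincide on the plateaus and the
amplitude reading matches the force-balance language used for the
crossover analysis.  Stabilising gravity is grouped with the quasi-static
(elastic) regime, destabilising gravity with the kinetic (inertial) one.
Ties between amplitudes are measure-zero and broken by the fixed priority
inertial > gravitational > elastic > viscous.

Assumptions worth keeping in mind: small-angle linearised gravity (the
default 1-radian sweep is at the edge of that approximation; an optional
$\sin\theta$ gravity is available in the perturbation simulator); a
constant moment arm (a good approximation for sweeps under about 30
degrees); no muscle contraction dynamics (the model asks which forces
resist actuator work, not how muscle produces it); no aerodynamic drag; a
single rigid segment.

## Allometric scaling and the calibrated defaults

The scaling laws are $m_L = a_m L^3$ (mass with volume), $l_{com} =
f_{com} L$, $J_L = m_L (f_{gyr} L)^2$, $k_{elas} = a_k L$, $c = a_c
L^{d}$ with $d = 1$ (damping, like stiffness, proportional to length — a
relationship recoverable from data with `fit_power_law()`), $r = f_r L$,
and $m_B = \rho_B\, m_L$.

The geometric fractions are fixed by the uniform-rod idealisation:
$f_{com} = 1/2$, $f_{gyr} = 1/\sqrt3$.  Three prefactors are not fixed by
geometry — $a_k$, $a_c$ and the body-to-limb mass ratio $\rho_B$ — and
only the ratios $u_k = a_k f_r^2 / a_m$ and $u_c = a_c f_r^2 / a_m$
(together with $\rho_B$) enter any phase shift, crossover, classification
or normalised envelope.  `default_laws()` obtains them by solving, in
closed form, the linear system pinned by three landscape landmarks:

1. the passive stance stability boundary $k_{r,elas}(L) =
   k_{r,grav,stance}(L)$ sits at $L = 10^{-2}$ m — which is equally the
   stance handover from quasi-static to kinetic dominance at $T = 1$ s,
   since at that period both viscous and inertial amplitudes are
   subdominant there;
2. the stance phase shift at $L = 5\times10^{-3}$ m, $T = 0.7$ s equals
   exactly $45^\circ$ (the viscous moment balances the *net* restoring
   moment; because the destabilising gravitational term at 5 mm is half
   the elastic term, strict amplitude equality $c\omega = k_{r,elas}$ and
   $\phi = 45^\circ$ cannot hold simultaneously — the package calibrates
   the phase, which is the measurable quantity);
3. the swing balance between the joint-intrinsic group (elastic + viscous,
   $\propto L^3$) and the mass-driven group (gravitational + inertial,
   $\propto L^4, L^5$) at $T = 1$ s sits at $L = 2\times10^{-1}$ m.

Solving these yields $\rho_B \approx 11.0$ — one limb weighing about 9% of
the body, a physiologically sensible value for a quadruped foreleg, which
we take as corroboration of the anchor set: perturbing any anchor by an
order of magnitude drives $\rho_B$ negative or absurd.  The remaining
constants set absolute units only and are fixed at reasonable magnitudes
($a_m = 20\ \mathrm{kg\,m^{-3}}$, $f_r = 0.1$); rescaling them moves
torques and energies but not a single phase, crossover, classification or
normalised envelope (this invariance is tested).

```{r}
default_laws()
```

With these defaults the swing crossover falls at 0.2 m, the stance
quasi-static-to-kinetic transition and the passive stability boundary at
1 cm — stance "goes kinetic" at much shorter lengths than swing because the
body's weight, not the leg's inertia, is what overwhelms the springs.

## Work loops and the energy partition

`work_loop()` samples one steady cycle exactly (closed-form derivatives, no
integrator).  Net actuator work per cycle equals the enclosed loop area
$\oint M\,d\theta$; for the linear model this is $\pi c_{eff}\omega
\Theta^2$, and the trapezoid-integrated area agrees with the closed form to
0.5% from 64 samples per cycle upwards (default 1024).  The conservative
terms net to zero over a cycle, so the partition reports their **peak**
stored energies ($\tfrac12 J\omega^2\Theta^2$ kinetic, $\tfrac12
k_{r,elas}\Theta^2$ elastic, $\pm\tfrac12 k_{r,grav}\Theta^2$
gravitational, signed by stability) alongside the dissipated energy, and
normalises the four magnitudes to fractions.  Cycle-level partitions only:
a per-sample attribution of mixed-region loops is deliberately not
offered, as no unique rule exists.

## Perturbation protocol and classification

`simulate_perturbation()` drives the limb with the inverse-dynamics moment
(so the pre-perturbation motion is the steady sinusoid to integrator
precision) and adds a constant torque equal to 20% of the peak steady
actuation for half a cycle, starting at a positive-going zero crossing
after five settled cycles — the onset phase is fixed to make every run
reproducible; no random numbers are used anywhere in the simulator.
Integration uses deSolve's Radau IIA (adaptive implicit Runge–Kutta,
rtol $10^{-8}$, atol $10^{-10}$); for underdamped cases whose natural
period exceeds the drive period the output grid is densified so the
ringing stays resolved.  Stance runs are truncated at $|\theta| = \pi/2$
and flagged unstable (the animal falls); swing runs are never truncated,
a hanging pendulum being free to pass horizontal.

Two classifiers must agree: the analytic rule ($k_{eff} \le 0$ unstable,
else $\zeta = c_{eff}/2\sqrt{J_{eff}k_{eff}}$ under/overdamped at
$\zeta = 1$) and a model-free rule applied to the simulated deviation
$\delta(t)$ from the steady sinusoid (growth or truncation → unstable;
at least two sign changes while above 5% of the post-perturbation maximum
→ ringing → underdamped).  The sign-change threshold means responses very
close to $\zeta = 1$ are intrinsically ambiguous to the trace-based rule;
the agreement grid avoids that measure-zero boundary.  The energy
bookkeeping of a perturbation is stated on deviation coordinates: the
perturbation's work on $\dot\delta$ equals $c_{eff}\int\dot\delta^2 dt$
once the deviation has decayed (the raw "injected equals extra dissipated"
phrasing is not an identity, because the steady actuator also exchanges
work with the perturbed trajectory).

## Gait kinematics and EMG prediction

For stride predictions the joint retracts from $+\Theta$ to $-\Theta$
during stance and protracts back during swing, each half following a
minimum-jerk quintic, so position, velocity and acceleration are continuous
(velocity and acceleration zero) at touch-down and lift-off.  The quintic
was chosen over lower-order profiles because impulsive accelerations at
the transitions would alias into spurious torque spikes; the true
within-stride waveforms of real animals are not prescribed by the model,
so only burst-pattern features, not trace shapes, are treated as testable.
The coefficient swap at the transitions is instantaneous: at lift-off the
destabilising gravitational stiffness simply disappears from the moment
balance, which at small scales is precisely what produces the
late-stance/early-swing retractor burst (the unloaded elastic joint would
otherwise snap the leg forward).

Torque is split by sign into retractor (negative, retraction-directed) and
protractor (positive) channels — no cocontraction can be represented —
then each channel is advanced circularly by the 50-ms electromechanical
delay (an integer number of samples, so shifting back is exact) and
normalised to its own stride maximum.  Presets: horse (stance 0.74 s,
swing 0.44 s, $L = 1$ m) and stick insect (1-Hz stride, 70% duty,
$L = 10^{-2}$ m); the preset lengths are the scales at which the ablation
contrast is sharpest, the sweep amplitude stays at the 1-radian default.
Burst detection thresholds at 10% of the channel peak.

One known limitation follows from the stance model carrying the full body:
at horse scale, stance torques exceed swing torques roughly twenty-fold, so
the early-swing protractor lobe — visible in the torque trace at about 4%
of the stride peak — does not register as a burst at the 10% threshold.
The late-stance protractor burst, the late-swing retractor reactivation,
the horse ablation invariance and the stick-insect ablation sensitivity
are all robustly reproduced.  Any rest-to-rest stance profile shares this
property (its peak acceleration is bounded below by $4\cdot2\Theta/
T_{stance}^2$), so it is a structural feature of the kinematic contract,
not of the quintic choice.

## What the synthetic damping data do and do not show

`generate_damping_fixture()` draws lengths log-uniformly over three decades
and perturbs $c = a L^b$ with lognormal noise ($\sigma_{\log} = 0.2$,
matching the scatter of published joint-damping measurements across
species).  Recovery of $b$ by log–log least squares within $\pm0.15$ at
$n = 30$ demonstrates estimator correctness, not that real joints obey the
law — the fixture has no species-level structure, no measurement-method
bias, and homoskedastic log-noise.  The same caveat applies to every
synthetic test here: passing shows the machinery is faithful to the model,
not that the model captures any particular animal.

## Numerical choices

* Crossovers and the stability boundary: bisection on $\log_{10} L$ to a
  relative tolerance of $10^{-6}$; an explicit "no crossover in range"
  error when the bracket does not change sign.
* Degenerate input: an exactly undamped context driven at its resonance has
  no defined phase; it is reported as an error rather than a value.
* The landscape grid default is $200\times200$ log-spaced points over
  $L\in[10^{-4},10]$ m, $T\in[10^{-3},10^2]$ s, spanning walking animals
  from fruit fly to horse with smooth 10-degree contours.  Test and
  acceptance runs use $5\times5$ grids and a few hundred perturbation
  cycles, sizes chosen so the whole suite completes in a few minutes while
  still crossing all three regions.
* Trace-based phase extraction uses FFT circular cross-correlation with
  parabolic peak interpolation; on 2048-sample cycles it agrees with the
  closed form to well under $0.1^\circ$.

```{r, fig.width = 6, fig.height = 5}
ls <- phase_landscape(10^seq(-4, 1, length.out = 60),
                      10^seq(-3, 2, length.out = 60), "swing")
plot(ls)
```
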