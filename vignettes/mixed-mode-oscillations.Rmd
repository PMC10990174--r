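---
title: "Mixed-mode oscillations under cAMP modulation: model, reduction and geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-mode oscillations under cAMP modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(camposc)
```

This vignette is the package's account of the science it implements: the
conductance-based model, the choices behind its numerical treatment, the
multiple-timescale reduction, and the folded-node geometry that explains
mixed-mode oscillations (MMOs). Code chunks are illustrative; the test
suite and `scripts/acceptance.R` execute every quantitative claim made
here.

## The model

The membrane potential `V` of a cortical pyramidal neuron obeys

$$C_m \frac{dV}{dt} = -I_{NaF} - I_{NaP} - I_{KS} - I_L - I_{HCN} - I_M + I_{App},$$

with a fast transient Na⁺ current (instantaneous activation $m_\infty^3$,
inactivation gate $h$), a persistent Na⁺ current ($n_\infty^3$,
instantaneous), a slow K⁺ current (gate $s$), an ohmic leak, an HCN
("h-") current (gate $r$) and an M-type K⁺ current (gate $w$, reversal at
$E_K$). Gates relax as $dp/dt = (p_\infty(V) - p)/\tau_p(V)$ with
$p_\infty = \alpha_p/(\alpha_p+\beta_p)$ and
$\tau_p = 1/(\phi_p(\alpha_p+\beta_p))$, where $\phi_p = Q_p^{(T -
T_{ref})/10}$ corrects the rates from the temperature at which each
channel family was characterized (20 °C for the Na⁺/K⁺ rates, 35 °C for
HCN) to the working temperature of 37 °C. The M gate has an explicit
sigmoidal steady state (half-activation −35 mV, slope 10 mV) and a
bell-shaped time constant peaking near 93 ms; no temperature factor is
published for it, so none is applied.

Intracellular cAMP enters as a binary flag. When raised it (i) adds
increments $\Delta g_{HCN}$ and $\Delta g_M$ to the HCN and M
conductances and (ii) shifts the HCN half-activation offset from
103.5 mV to 95 mV (direct cyclic-nucleotide binding). The M-current
reversal potential is the K⁺ Nernst potential everywhere; a distinct
symbol sometimes used for it in slow-variable notation is treated as an
alias of $E_K$.

Default parameters (`neuron_parameters()`) are the study values:
$g_{NaF} = 1000$, $g_{NaP} = 1$, $g_{KS} = 40$, $g_L = 11.3$,
$g_{HCN} = 23$, $g_M = 50$, $\Delta g_{HCN} = 12$, $\Delta g_M = 50$
mS/cm², $C_m = 0.9$ μF/cm², $E_{Na} = 50$, $E_K = -84$, $E_L = -83.38$,
$E_{HCN} = -50$ mV. Eight presets (`condition_params()`) translate drug
combinations into parameter rows: control, the A2aR agonist CGS21680
(cAMP = 1), HCN block by ZD7288 ($g_{HCN} = \Delta g_{HCN} = 0$), M block
by XE991 ($g_M = \Delta g_M = 0$), their combinations with CGS, Forskolin
(as CGS), and Forskolin + Linopirdine ($\Delta g_M = 20$).

### Numerical treatment

The reference integrator is fixed-step 4th-order Runge–Kutta at
`dt = 0.001` ms, implemented in compiled code; stored output is thinned to
a 0.01 ms grid, ample for event detection. A high-accuracy adaptive
integrator (deSolve) serves as an independent cross-check: on a 50 ms
control run at 300 μA/cm² the two agree to well under 0.1 mV. The rate
expressions of the form $a(V + \theta)/(1 - e^{-(V+\theta)/k})$ have
removable singularities, which are resolved by their analytic series
limits rather than by ε-offsets, so the right-hand side is exactly
continuous and the same closed forms can be differentiated analytically
for the Jacobians and the fold algebra.

Initial conditions are not part of the published protocol; the package
starts at $V_0 = -70$ mV with all gates at steady state, i.e. near the
hyperpolarized attracting sheet of the critical manifold, and discards a
350 ms transient before analysis.

### Events, regimes and firing frequency

Local maxima of $V(t)$ with topographic prominence ≥ 1 mV are events;
peaks reaching −20 mV are action potentials (LAOs), the rest are
subthreshold oscillations (SAOs). The −20 mV threshold sits between spike
overshoot (above 0 mV) and SAOs (below −40 mV) and is insensitive to
±10 mV changes. For *regime classification* the prominence filter is
lowered to 0.05 mV: near the edges of the MMO band the genuine SAOs have
sub-millivolt amplitude (e.g. in the control condition between roughly 95
and 137 μA/cm²), and a 1 mV filter would misclassify those currents as
regular spiking; 0.05 mV is still several orders of magnitude above
integrator error, and pure spiking runs show no spurious events at that
level. Regimes: `silent` (no LAO), `MMO` (LAOs and SAOs), `spiking`
(LAOs only). Regime boundaries over applied current are located by a
coarse scan (step 10–20 μA/cm²) plus bisection to ±1 μA/cm²; halving the
time step moves them by less than 1 μA/cm². Classification uses a
1000 ms horizon analysing the final 500 ms, long enough to resolve MMO
periods of over 100 ms.

Firing frequency counts LAOs per second after the transient (SAOs carry
no spike). The f–I machinery uses a 1350 ms horizon so the counting
window is a full second. At very strong drive the spike amplitude
declines continuously and oscillations eventually die in a
depolarization block; `firing_upper_limit()` therefore bisects the death
of sustained oscillations of any amplitude, which is what the upper end
of the firing range refers to — a fixed −20 mV peak criterion would cut
the shrinking spikes off ~100 μA/cm² earlier.

## Reduction to the 3D slow-fast subsystem

During subthreshold oscillations the timescales separate as
$\tau_V \ll \tau_h, \tau_s \ll \tau_r, \tau_w$ (the package reports
$\tau_V = C_m/g_{tot}$ with $g_{tot}$ the sum of instantaneous chord
conductances — a definition chosen here, as none is published — and the
simulated maxima over SAO segments satisfy $\tau_V/\tau_s < 0.004$ and
$\tau_s/\tau_w < 0.2$). The super-slow gates are frozen at their time
averages over [350, 450] ms of a 5D run, after the rescaling

$$\tilde w = \left(1 + cAMP\,\frac{\Delta g_M}{g_M}\right) w,\qquad
  \tilde r = \left(1 + cAMP\,\frac{\Delta g_{HCN}}{g_{HCN}}\right) r,$$

which absorbs the cAMP flag: the reduced model
$C_m dV/dt = \ldots - g_{HCN}\tilde r(V - E_{HCN}) - g_M\tilde w(V-E_K)
+ I_{App}$, with $h$ and $s$ dynamic, is independent of cAMP by
construction. Projected onto the $(\tilde w, \tilde r)$ plane, 5D
trajectories hug a straight line $\tilde r = m\tilde w + q$, fitted by
ordinary least squares of $\tilde r$ on $\tilde w$ ($\tilde w$ is the
bifurcation parameter of interest). Averages are trapezoidal on the
stored grid; shifting the window start by +50 ms changes them by well
under 5%.

A caution established while building the package: the *block structure*
of the reduced model's MMOs (how many SAOs follow each LAO burst) is
hypersensitive to the frozen $(\tilde w, \tilde r)$ — perturbations of
1–3% move the attractor across different periodic signatures. The robust,
reproducible statements are structural: at elevated cAMP and
250 μA/cm² the full model fires two spikes per block and the reduced
model one; at 300 μA/cm² the reduced model fires two-spike blocks with 3
or 4 SAOs. Exact signature strings should not be over-interpreted, in
either direction.

## Bifurcation structure

Where interactive continuation software was the classical tool, the
package uses deterministic, testable replacements:

* **Equilibria**: at an equilibrium $h = h_\infty(V)$, $s = s_\infty(V)$,
  so the equilibrium voltage solves a scalar current balance, bracketed
  on a fine grid and polished by Brent's method; stability comes from the
  analytic 3×3 Jacobian. Along a constraint line the frozen gates are
  continuation parameters; the line may legitimately cross
  $\tilde r = 0$ and slightly negative values are admitted there.
* **Hopf points**: bisection of the real part of the complex eigenvalue
  pair along $\tilde w$ (to 10⁻⁵). A simulation oracle agrees: perturbed
  equilibria spiral out below the located point and decay above it, with
  the growth/decay boundary within 10⁻³ of the eigenvalue answer.
* **Attractor scans**: long transient-discarded 3D runs classified by
  event content (`equilibrium`, `SAO-cycle`, `LAO-cycle`, `MMO`), with
  the MMO onset — the discontinuous jump from plain relaxation cycling to
  the MMO/chaotic attractor — bisected to 10⁻⁴ in $\tilde w$.
* **Period doubling**: Floquet multipliers from the monodromy matrix,
  integrated with the variational equations along a cycle converged on a
  Poincaré section.
  The section is anchored at the afterhyperpolarization trough, where
  the flow is slow and interpolated crossings are accurate; the trivial
  multiplier is then recovered to better than 10⁻³.
  `pd1_on_line()` bisects the onset of spike-height alternation, because
  past the doubling the simulation-based cycle finder lands on the
  period-two orbit, whose multipliers (products over both loops) are
  positive again; the Floquet route then verifies that the multiplier
  approaches −1 just left of the located point. On the control line at
  300 μA/cm² the doubling sits at $\tilde w \approx 0.1995$, just left of
  the MMO onset at $\tilde w \approx 0.1996$, consistent with the
  MMO attractor appearing slightly beyond the first period doubling.

The two-parameter map in (applied current, $\Delta g_M$) compares the
stimulated (cAMP = 1) and control MMO intervals as the M-conductance
increment varies; `dgm_threshold()` bisects the increment at which the
stimulated upper endpoint first exceeds the control one (endpoints
refined to ±0.25 μA/cm²). In this package's attractor-based construction
the crossing falls near 9.7 mS/cm²; a region boundary drawn from
period-doubling continuation instead of the attractor jump would place it
slightly higher.

## Geometry of the MMOs

The critical manifold of the 3D subsystem is an explicit graph
$s = \gamma(V, h)$, decomposed as
$\gamma = \gamma_0 + \gamma_{\tilde r} + \gamma_{\tilde w} +
\gamma_{\tilde r\theta}$ with constant shifts
$-(g_{HCN}/g_{KS})\tilde r$ and $-(g_M/g_{KS})\tilde w$ and a
driving-force correction $\propto (E_{HCN}-E_K)/(V-E_K)$. The fold
condition $\partial f/\partial V = 0$ on the manifold solves for
$h = \psi(V) = \psi_0 + \psi_r$ with $\psi_r \propto \tilde r$; the
printed form of $\psi_0$ is bracket-ambiguous in the source material, and
the package implements the version derived directly from the fold
condition, verified by the identity $|\partial f/\partial V| < 10^{-8}$
along the traced branches (the residual is in fact ~10⁻¹³). The fold
splits the manifold into a hyperpolarized attracting sheet, a repelling
sheet, and a depolarized attracting sheet.

The desingularized reduced flow (time rescaled by the fast
linearization, which reverses orientation on the repelling sheet) has
*ordinary* singularities — the 3D equilibria, recovered independently as
roots of $\gamma(V, h_\infty(V)) = s_\infty(V)$ — and *folded*
singularities on the fold, classified by the 2×2 Jacobian. At elevated
cAMP and 250 μA/cm² the hyperpolarized fold carries a folded node with
eigenvalue ratio $\mu \approx 0.014$, robust to ±5% changes of the frozen
gates; the strong canard is integrated from the node along the strong
eigendirection.

### Canards and rotational sectors

The slow manifolds are reconstructed by evolving seed lines: forward
orbits from the hyperpolarized attracting sheet trace the attracting slow
manifold, backward orbits from the depolarized sheet trace the repelling
one, both terminated on a section plane perpendicular to the $s$-axis
offset 1–5% of the local $s$-range from the node on its approach side
(`sigma_offset`). Two numerical facts shape the implementation. First,
backward orbits that miss the repelling manifold diverge genuinely; they
are counted and reported as lost seeds (the surviving fraction traces the
manifold; backward seeds are placed at funnel-matched $s$ values by
inverting the linear $h$-dependence of $\gamma$). Second, the attracting
family contracts so strongly along its travel that the projected
curve-intersection construction of canards degenerates below resolvable
width. The canards are therefore located by brute-force bisection on the
seed line: the number of subthreshold rotations an orbit performs before
its spike is a staircase in the seed coordinate, and each unit step *is*
a canard $\xi_i$ (boundary between rotational sectors $R_i$ and
$R_{i+1}$). The singular-limit strong canard crosses the seed section
within 0.01 of the staircase's first step, an independent check of the
construction.

The coordinate that organizes the funnel is the super-slow gate $s$
itself: $V$ and $h$ relax quickly onto the slow manifold while $s$ is
preserved, so a point's sector is read off by comparing its $s$ at the
seed section with the canard values. `rotational_sectors()` applies this
to every post-spike pass of a simulated trajectory through the section
and compares the predicted SAO count with the measured one. At elevated
cAMP this reproduces the return mechanism exactly: at 250 μA/cm² every
return lands in the predicted sector (alternating low- and high-order
sectors), and at 300 μA/cm² the returns alternate between landing
*outside* the strong canard (a regular jump, hence a second consecutive
spike with no SAOs) and landing in sectors $R_3$/$R_4$ (3–4 SAOs) —
matched return-by-return by the simulation apart from occasional
entries within ~10⁻⁴ of a sector boundary.

## Problem sizes and determinism

Everything in the package is deterministic — there is no random number
generation anywhere; scans and bisections are fixed-grid. The analyses
use: 1000 ms horizons (last 500 ms analysed) for regime classification,
1350 ms for firing-frequency points, 1500 ms for 3D attractor
classification, 450 ms for the averaging runs, coarse grids of 10–20
μA/cm² with bisection to ±1 (±0.25 for the increment threshold), and
60-seed families for the manifold reconstruction. These sizes resolve
every boundary the package reports to the stated precision while keeping
a full reproduction run in the minutes range.

## Known limitations

* cAMP is binary; no explicit second-messenger kinetics, no channel
  noise, no spatial structure.
* The regime taxonomy is attractor-based; near boundaries with very long
  transients the label carries a low-confidence flag rather than a
  guarantee.
* MMO signature strings of the reduced model are hypersensitive to the
  frozen gates (see above) and are reported as block structure, not as
  exact strings.
* Unstable periodic orbits are not continued; saddle-node-of-cycles
  structure is only visible as hysteresis in attractor scans, and the
  period-doubling cascade is located only at its first doubling.
* The eigenvalue ratio of the folded node bounds the maximal SAO number
  in theory; the package counts rotations numerically instead of using
  that bound.
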