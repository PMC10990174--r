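# camposc

Mixed-mode oscillations in a cAMP-modulated cortical pyramidal neuron
model.

Cortical layer-5 pyramidal neurons can fire in *mixed-mode oscillations*
(MMOs): bursts of full action potentials (large-amplitude oscillations,
LAOs) interleaved with small subthreshold oscillations (SAOs). Adenosine
A2a-receptor signalling raises intracellular cAMP, which increases the
open probability of HCN channels (by direct binding) and of M-type
KCNQ/Kv7 potassium channels (via PKA), and thereby switches the firing
pattern. `camposc` implements a five-variable Hodgkin–Huxley-type model of
this system and the dynamical-systems machinery that explains it, for
computational neuroscientists studying multiple-timescale firing patterns
and in-silico channel pharmacology.

The membrane equation is

    Cm dV/dt = −I_NaF − I_NaP − I_KS − I_L − I_HCN − I_M + I_App

with instantaneous activation m∞³(V), n∞³(V) for the fast and persistent
Na⁺ currents and first-order gates h (Na⁺ inactivation), s (slow K⁺),
r (HCN) and w (M), each with dp/dt = (p∞(V) − p)/τ_p(V). cAMP enters as a
binary flag: it adds Δg_HCN and Δg_M to the HCN and M conductances and
shifts the HCN half-activation. Eight drug-condition presets translate the
underlying pharmacology (CGS21680, ZD7288, XE991, Forskolin, Linopirdine)
into parameter sets.

On top of the model the package provides:

* fixed-step RK4 integration (dt = 0.001 ms) in compiled code, event
  detection, MMO signatures, firing-frequency (f–I) curves and
  silent/MMO/spiking regime scans over applied current;
* the reduction to a 3D slow-fast subsystem by freezing the super-slow
  gates at their scaled time averages (w̃, r̃), including the constraint
  line r̃ = m·w̃ + q;
* bifurcation analysis of the 3D subsystem: equilibria and eigenvalues,
  Hopf points, Floquet multipliers and period doubling, attractor scans
  and two-parameter regime maps;
* the geometric singular perturbation toolkit: the critical manifold
  s = γ(V, h) in closed form, fold curves h = ψ(V), the desingularized
  reduced flow, folded-node detection and classification, canard orbits
  and rotational sectors that predict SAO counts.

## Worked example

```r
library(camposc)

# control vs elevated cAMP at 300 uA/cm^2
p_ctrl <- condition_params("Ctrl", IApp = 300)
p_cgs  <- condition_params("CGS",  IApp = 300)

classify_regime(p_ctrl, 300)   # "spiking"
classify_regime(p_cgs, 300)    # "MMO"

# the control MMO window over applied current
mmo_interval(condition_params("Ctrl"), I_range = c(40, 260), coarse = 20)
#> [1]  80.625 223.125

# reduce the elevated-cAMP cell at 250 uA/cm^2 and inspect the geometry
red <- reduce_model(condition_params("CGS", IApp = 250))
round(c(red$w_tilde, red$r_tilde), 4)
#> [1] 0.1883 0.0825

fs <- folded_singularities(red$params, red$w_tilde, red$r_tilde)
fs[[1]]$class      # "folded node"
round(fs[[1]]$mu, 4)
#> [1] 0.0138
```

The control neuron fires regularly at 300 µA/cm²; with cAMP elevated the
same current yields MMOs. The control MMO window [81, 223] µA/cm² is the
current range in which both LAOs and SAOs persist. The reduction freezes
the scaled M and HCN gates at (w̃, r̃) ≈ (0.188, 0.083), where the
desingularized reduced flow has a folded node with eigenvalue ratio
µ ≈ 0.014 — the organizing center that produces the SAOs.

A thin command-line wrapper over these functions is installed with the
package (`inst/cli/camposc`), with verbs `simulate`, `events`, `ff`,
`intervals`, `reduce`, `bif1p`, `bif2p`, `geometry` and `reproduce`;
`run_recipe()` drives the figure-level experiment bundles from R.

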