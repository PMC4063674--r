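# hcosweep

Conductance screens and correlation analysis for a leech-heartbeat
half-center oscillator model.

## The problem

Rhythmic alternating bursting in the leech heartbeat central pattern
generator arises from two mutually inhibitory heart interneurons — a
half-center oscillator (HCO). The same functional rhythm can be produced by
widely different combinations of membrane and synaptic conductances, which
raises a concrete question: *which* parameter combinations sustain
functional and realistic bursting, and are any parameters co-regulated
(linearly correlated) across the population of working solutions?

`hcosweep` is for computational neuroscientists who want to answer such
questions by brute force: it simulates a conductance-based two-cell HCO
model, screens a grid over eight key parameters, classifies every model
instance from its spike trains, and analyses the classified populations for
parameter correlations.

## The model and the screen

Each cell is a single-compartment Hodgkin–Huxley-type leech heart
interneuron with eight voltage-gated currents (fast and persistent Na⁺,
fast and slow low-threshold Ca²⁺, hyperpolarization-activated cation,
delayed-rectifier, persistent and fast transient K⁺), leak, and two
inhibitory synaptic mechanisms (graded, driven by a presynaptic Ca pool,
and spike-mediated, a normalized difference-of-exponentials conductance per
presynaptic spike, scaled by a modulation variable):

C dV/dt = −(Σ I_ion + I_Leak + I_SynG + I_SynS − I_inject),
dx/dt = (x∞(V) − x)/τ_x(V) for every gating variable x.

The screen varies ḡ_SynS, ḡ_SynG, ḡ_P, ḡ_K2, ḡ_h, ḡ_CaS, ḡ_Leak at
0–175% of canonical in 25% steps and E_Leak over −70…−50 mV (8⁷ × 5 =
10,485,760 grid points; 163,840 of them isolated, i.e. both synapses zero).
Every instance starts from one shared state (the canonical model run for
200 s, one cell bursting, the other inhibited), settles for 100 s, and is
recorded for 100 s. Instances are classified as HCO / burster /
silent / spiking / plateau / irregular / bistable-suspect, with *realistic*
HCOs and bursters additionally matching living-system ranges (period
5–15 s, spike frequency 8–25 Hz, duty cycle 50–70% for HCOs). Analyses
include centered PCA with main-component selection (cumulative variance >
95%), 3D orthogonal-distance-regression lines (centroid + first principal
component), two-sample Kolmogorov–Smirnov tests on per-axis level
distributions, and one-parameter "family" partitions that quantify period
sensitivity along single conductances.

The integrator is a C++ fixed-step exponential-Euler kernel (0.1 ms) with
in-step spike detection, cross-validated in the test suite against an
adaptive `deSolve` backend on the identical equations.

## Worked example

```r
library(hcosweep)

# the canonical model: warm up 200 s, settle 100 s, record 100 s
ics <- canonical_initial_conditions()
tr  <- simulate_instance(param_vector(), ics)
cl  <- classify_trace(tr)
attr(cl, "metrics")
#> <hco_metrics>
#>   A: 10 bursts; period 9.03 s (CV 0.007); 12.8 Hz; duty 49.1%
#>   B: 11 bursts; period 9.02 s (CV 0.010); 13.0 Hz; duty 51.0%
#>   phase: 0.501
cl$category   # "HCO"
cl$realistic  # TRUE
```

The canonical HCO bursts in alternation (phase 0.50) with a 9 s period,
~13 Hz intraburst spike frequency and a duty cycle of 50% — inside
the realistic bands throughout, with a minimum membrane potential near
−59.5 mV during the inhibited phase.

A sweep over a sub-grid, stored and queried like a database:

```r
g <- grid_spec(fix = list(CaS = 100, h = 100, SynS = 0, SynG = 0))
grid_size(g)                       # 2560 isolated instances
rep <- run_sweep(g, "iso_store")   # resumable; minutes on one CPU
rep                                # counts per activity category
bursters <- query_group(hco_store("iso_store"), "burster")

# correlation analytics on the burster population
pca_group(build_analysis_matrix(bursters)[, c("P", "K2", "Leak", "E_Leak")])
odr_line_3d(build_analysis_matrix(bursters)[, c("P", "K2", "Leak")])
ks_two_sample(bursters$Leak[bursters$realistic],
              bursters$Leak[!bursters$realistic])
family_report(bursters, "K2")
```

`odr_line_3d()` returns the total-least-squares line through the burster
cloud in (ḡ_P, ḡ_K2, ḡ_Leak) space; a direction close to the space
diagonal means the three conductances co-vary — the linear correlation the
screen is designed to expose.

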