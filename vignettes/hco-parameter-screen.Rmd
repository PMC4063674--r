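---
title: "Screening a half-center oscillator's conductance space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening a half-center oscillator's conductance space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcosweep)
```

## The model

`hcosweep` simulates a half-center oscillator (HCO): two identical
single-compartment leech heart-interneuron models coupled by reciprocal
inhibition. Each cell carries eight Hodgkin–Huxley-type voltage-gated
currents — fast Na⁺ ($I_{Na}$), persistent Na⁺ ($I_P$), fast and slow
low-threshold Ca²⁺ ($I_{CaF}$, $I_{CaS}$), a hyperpolarization-activated
cation current ($I_h$), a delayed rectifier ($I_{K1}$), a persistent K⁺
current ($I_{K2}$), a fast transient K⁺ current ($I_{KA}$) — plus leak, and
two inhibitory synaptic mechanisms: graded transmission driven by a
presynaptic Ca pool integrating the low-threshold Ca currents, and
spike-mediated transmission in which each presynaptic spike launches a
difference-of-exponentials conductance (rise 2 ms, decay 11 ms, normalized
to unit peak) scaled by a slow modulation variable $M$. The membrane
equation per cell is

$$C \frac{dV}{dt} = -\Big(\sum_{ion} I_{ion} + I_{Leak} + I_{SynG} + I_{SynS} - I_{inject}\Big),$$

with $C = 0.5$ nF, $I_{inject} = 0$ throughout, every gate following
first-order kinetics $\dot x = (x_\infty(V) - x)/\tau_x(V)$ with Boltzmann
steady states $x_\infty = 1/(1+e^{a(V+b)})$ and sigmoidal time constants
(three gates use special closed forms with $1/\cosh$ terms; the h-current
steady state has a two-exponential denominator). The full constant set ships
as a YAML resource (`inst/extdata/hco_model.yaml`); internals are SI
(volts, seconds, siemens, farads), matching the volt-scale constants the
gating table is written in.

The canonical parameter set ($\bar g_{CaS}=3.2$, $\bar g_h=4$, $\bar g_P=7$,
$\bar g_{K2}=80$, $\bar g_{Leak}=8$, $\bar g_{SynS}=60$, $\bar g_{SynG}=30$,
$\bar g_{Na}=200$, $\bar g_{CaF}=5$, $\bar g_{K1}=100$, $\bar g_{KA}=80$ nS;
$E_{Leak}=-60$ mV) produces rhythmic alternating bursting. Under the default
integration settings the canonical instance measures a period of about 9.0 s,
a mean intraburst spike frequency of about 12.9 Hz, a duty cycle just above
50%, a relative phase of 0.50, and a minimum membrane potential near
−59.5 mV.

## The screen

The screen varies eight parameters: the maximal conductances of the two
synapses and of $I_P$, $I_{K2}$, $I_h$, $I_{CaS}$ and leak at 0, 25, 50, 75,
100, 125, 150, 175% of canonical, and $E_{Leak}$ at −70 … −50 mV in 5 mV
steps — $8^7 \times 5 = 10{,}485{,}760$ grid points, of which
$8^5 \times 5 = 163{,}840$ are isolated (both synapses at zero). The
protocol is fixed: the canonical model is integrated for 200 s to produce
one shared, asymmetric initial state (one cell bursting, the other
inhibited); each instance then runs 100 s to settle and a further 100 s from
which spike times and voltage statistics are recorded.

`run_sweep()` executes any sub-grid of this space, appending classified
records to a store in chunks, so interrupted sweeps resume and completed
sweeps are idempotent. The two canonical-restricted screens (2,560 instances
each: $\bar g_{CaS}$, $\bar g_h$ — and for the coupled grid both synapses —
pinned at 100%) run in minutes; the full isolated grid is a multi-hour
single-CPU job and the full coupled grid a cluster-scale one, both reachable
through the same resumable call.

## Numerical choices

The production integrator is a fixed-step exponential-Euler kernel
(`src/hco_kernel.cpp`), the scheme traditionally used for this model family:
every state equation is linear in its own variable given the rest of the
state, so each variable is advanced by its exact exponential relaxation
toward its instantaneous equilibrium. The default step is 0.1 ms. Gating
steady states and per-step decay factors are tabulated on a 0.1 mV grid and
linearly interpolated; spike events are detected inside the step loop at the
upward crossing of −20 mV (the classification threshold), with the peak
refined by parabolic interpolation; the spike-triggered synaptic sum is
carried by two exponential trace variables, making its cost independent of
the spike history (events effectively leave the sum once the synaptic
function decays below 10⁻⁶ of peak). Two further choices are worth noting:

* **Step size.** 0.1 ms was validated by a convergence test: halving the
  step changes the canonical instance's period and spike frequency by less
  than 1%. Spike *peak amplitude* converges to ~1.8 mV and is the most
  step-sensitive observable.
* **Quiescence short-circuit.** When both cells sit at a numerical fixed
  point (voltage band below 1 nV over ten consecutive 0.1 s blocks) the rest
  of the run is constant and is fast-forwarded. A cell drifting toward a
  burst moves orders of magnitude more than 1 nV per block, so oscillating
  instances can never trigger it. This cuts sweeps dominated by silent
  instances by roughly half.

An adaptive verification backend (`deSolve::lsodar` on the identical
R-level right-hand side, with root-finding at the spike threshold driving
the synaptic events) cross-checks the kernel: over a 2 s canonical window
the two backends produce the same spike count with spike times within
0.5 ms. The kernel, not the adaptive solver, is the default because it is
the scheme this model family was originally integrated with, it is two
orders of magnitude faster, and the stiff 0.1 ms Na activation gate is
handled exactly by the exponential update.

## Classification

The activity definitions are applied verbatim: a spike is an upward
crossing of −20 mV (time and amplitude at the following peak); a burst
needs at least three spikes and a 1 s minimum inter-burst interval; the
cycle period is the interval between middle spikes of consecutive bursts
(even-count bursts use the lower middle spike); duty cycle is mean burst
duration over mean period; phase is the per-cycle delay of B's burst middle
within A's cycle, averaged. An HCO requires both cells to burst regularly
(≥ 2 bursts in the trailing 40 s of the recorded window, spike-amplitude CV
< 0.07 within every burst, period CV < 0.05) with mean phase in the open
interval (0.45, 0.55) and at least one synaptic conductance nonzero; a
burster is an isolated instance whose twin cells both burst regularly.
Realistic instances additionally need a period of 5–15 s and spike frequency
of 8–25 Hz, plus a 50–70% duty cycle for HCOs (closed bounds). Isolated
non-bursters receive operational sub-labels (silent: no spikes; spiking:
spikes but no bursts; plateau: > 5 s continuously above −20 mV; irregular:
bursts failing the CV rules; bistable-suspect: the twins settle on different
activity types).

Two measurement decisions were forced by the data rather than genuinely
open:

* **Spike amplitude.** Model spikes peak near 0 mV (canonical mean
  +1.8 mV), so the coefficient of variation of raw peak potentials is
  numerically unstable (division by a near-zero mean) and would reject even
  the canonical model. Amplitudes therefore enter the CV as height above
  the −20 mV detection threshold, which is stable and classifies the
  canonical instance as a realistic HCO.
* **Window-edge bursts.** A burst truncated by the recorded window (first
  spike within 1 s of the window start or last spike within 1 s of its end)
  has unverifiable bounds and corrupts duration and period statistics — the
  partial first burst alone drags the canonical duty cycle from ~50.5% to
  47.5%. Such bursts are excluded from the metrics.

## What reproduces, and what is boundary-limited

The combinatorics and all structural invariants reproduce exactly. On the
canonical-restricted screens this implementation finds the published
populations at the right order of magnitude but not at count-level
equality: the group counts concentrate near classification boundaries, so
small differences in integrator, in the (unpublished) warm-up initial state
and in measurement conventions move tens of instances across the lines.
Three observations characterize the gap:

* The coupled restricted screen yields ~400 HCOs; the duty-cycle
  distribution of these HCOs is packed between 45% and 53%, so the 50%
  lower realism bound sits on a knife edge — one duty percentage point
  moves ~40 instances in or out of the realistic group.
* Isolated instances are frequently multistable (the twin cells of dozens
  of instances settle on different attractors from the two shared initial
  states), so the burster census is sensitive to the exact warm-up state.
* Rule-level diagnostics show the amplitude-CV and trailing-40 s rules
  dominate rejections; a differently anchored amplitude measure shifts the
  HCO count by tens of instances in either direction.

The synthetic-data generators close this gap for the analysis stages: they
produce parameter clouds with a known embedded direction and noise,
two-neuron traces with known period/duty/phase/amplitude structure, and
instance tables with known family censuses, and every analysis stage is
required (in the test suite) to recover those ground truths — PCA direction
within 1° at $\sigma = 0.01$, classifier metrics within one sample, family
censuses exactly. What the generators deliberately do not emulate is model
dynamics: they are stereotyped waveforms and Gaussian clouds, so passing
these tests validates the measurement and analysis pipeline, not the
differential equations (which are validated against closed forms, the
adaptive backend, and convergence tests instead).

## Analyses

`pca_group()` performs centered, unscaled PCA (conductances as fractions of
canonical, $E_{Leak}$ in volts — which is why its coefficients are small on
the volt scale); variance fractions are unaffected by the covariance
divisor convention. The *main components* are the smallest leading set with
cumulative variance above 95%. `odr_line_3d()` fits the total-least-squares
line (centroid plus leading eigenvector of the multiplicity-weighted
scatter), which the tests verify to beat random and numerically optimized
alternative directions. `ks_two_sample()` computes the exact tie-aware ECDF
sup-difference with the classical asymptotic p-value using the
small-sample-corrected argument $(\sqrt n + 0.12 + 0.11/\sqrt n)k$.
`partition_families()`/`family_report()` quantify single-parameter
robustness: families are instances identical in all swept parameters but
one, and the period change of a family is the period of its last member
minus its first after ascending sort.

Component signs are fixed (largest-magnitude coefficient negative) for
cross-run comparability; boundary comparisons are closed on stated bounds
("period between 5–15 s" includes 5 and 15) while strict wording ("less
than 0.07") stays strict, and the phase range (0.45–0.55) is read as open.

## Problem sizes used in the checks

The acceptance checks run, from scratch: the grid combinatorics (instant),
the canonical instance (one 400 s integration), both canonical-restricted
screens (2 × 2,560 instances × 200 s each, minutes on one CPU thanks to the
kernel and the quiescence short-circuit), and the correlation analytics on
the resulting burster population. The full isolated sweep (163,840
instances) and coupled analyses are out of desk scale by three and six
orders of magnitude respectively and are left to `run_sweep()` resumption
on larger budgets.

## Known limitations

* The model is single-compartment and deterministic: no morphology,
  temperature dependence, or channel noise.
* Group counts near classification boundaries are integrator- and
  IC-sensitive (see above); cross-implementation count equality at the
  single-instance level should not be expected.
* The graded-transmission pool constants are the least-constrained part of
  the transcription; they affect only coupled (HCO) dynamics.
* Phases of *decoupled* twin cells are frozen history, not an interaction:
  the relative-phase criterion is meaningful only for coupled instances and
  is applied only there.
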