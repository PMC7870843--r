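---
title: "Models and methods: resource competition in coupled bistable switch circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The system

The package models a family of synthetic gene circuits built from two
self-activating modules hosted in *E. coli*. Module 1 is the AraC arm:
AraC activates its own promoter when bound to L-arabinose, and the arm is
reported by GFP. Module 2 is the LuxR arm: LuxR activates the Plux promoter
when bound to the quorum signal C6 homoserine lactone, reported by RFP. Both
reporters carry degradation tags, so protein removal lumps active
degradation and dilution into a single first-order rate. In the cascading
design the modules activate each other: module 1 synthesizes C6 (via LuxI),
driving module 2, and module 2 can feed back on module 1. In the separated
design both links are cut and each module answers only to its external
inducer. Because both modules draw on one shared pool of gene-expression
machinery, they also inhibit each other indirectly; the package's central
question is what this hidden coupling does to the circuit's multistability
and its cell-fate transitions.

Throughout the package a cell's fate is the quadrant of its expression
state, written **(RFP, GFP)**: `HL` means RFP-high/GFP-low (module 2 won),
`LH` means GFP-high (module 1 won), `HH` is coactivation, `LL` is the
uninduced state. The letter order follows the flow-cytometry convention of
naming the red channel first; it is worth internalizing once, since every
fate table in the package uses it.

# The deterministic model

The state is $(m_1, m_2)$, the activity-weighted expression level of each
module in arbitrary concentration units. Each module's promoter activity is

$$a_i = \beta_i + (1-\beta_i)\, h(x_i; K_i, n_i), \qquad
  h(x; K, n) = \frac{x^n}{K^n + x^n},$$

with leak $\beta_i$, threshold $K_i$ and Hill coefficient $n_i$. The
effective self-activation inputs carry the induction and the links:

$$x_1 = m_1\, u_A\, (1 + c_{21} m_2), \qquad
  x_2 = m_2\, (u_C + c_{12}\, m_1\, u_A\, g_{tet}),$$

where $u_A, u_C \in [0,1)$ are Hill responses of the external doses
(L-arabinose and C6), $c_{12}, c_{21}$ are the link weights, and $g_{tet}$
is the TetR relief factor of the hybrid variant
($g_{tet} = 1/(1 + \mathrm{tetR\_strength}/(1 + (d_{aTc}/K_t)^{n_t}))$,
equal to 1 in all other variants). The link from module 1 to module 2 runs
through the arabinose-dependent promoter that drives C6 synthesis, so it
carries the active-AraC fraction $u_A$: without L-arabinose the link is
silent, which is what the no-arabinose control of the hybrid circuit
requires.

A shared resource pool rescales production. One-strain circuits see

$$R = \frac{1}{1 + \lambda_1 a_1 + \lambda_2 a_2}$$

for both modules — activity of either module depletes what the other can
draw — while the two-strain circuit hosts each module in its own cell and
each sees only its own demand, $R_i = 1/(1+\lambda_i a_i)$. The dynamics are

$$\frac{dm_i}{dt} = \kappa\, \alpha_i\, R_i\, a_i - \delta_i m_i,$$

with $\kappa$ a plasmid copy-number multiplier. Production is bounded, so
the box $[0, \kappa\alpha_i/\delta_i]$ is forward-invariant; all grids and
lattices are sized from it. Doses are piecewise-constant step inputs at
their addition times (no uptake kinetics), mirroring bolus additions to a
culture, and C6 synthesis by module 1 is folded into the $c_{12} m_1 u_A$
term rather than modelled as a separate species, keeping the phase plane
two-dimensional.

## What the calibrated presets encode

Model parameters ship as frozen presets (one YAML block per variant in
`inst/extdata/presets.yaml`), calibrated once by coarse numerical search so
that each variant reproduces its reference topology and not revisited:

* **Ideal circuit** (`CBS_IDEAL`, $\lambda = 0$): with a weak
  module-1-to-2 link and strong reverse link, three stable states
  {LL, LH, HH}; with the weights flipped, {LL, HL, HH}; with balanced
  weights, {LL, HH}. The two tristable regimes are the two stepwise
  transition paths the cascading design intends.
* **One-strain competition circuit** (`CBS_COMPETITION`): three stable
  states {LL, LH, HL} — the coactivation state is destroyed and replaced
  by a second single-winner state. Two calibration facts deserve emphasis.
  First, this topology forces a strongly asymmetric leak:
  the losing module in a winner state must sit below its own switching
  threshold even while the winner's link input drives it, which requires
  the module-2 (Plux) leak to be roughly two orders of magnitude below the
  module-1 leak ($\beta_2 = 2\times10^{-4}$ vs $\beta_1 = 0.013$). Second,
  a sharp module-2 response ($n_2 = 4$) keeps basal Plux expression from
  responding to the link input in the GFP-high state, which would
  otherwise put a small spurious upturn at the high-GFP end of the
  dose–response curve.
* **Separated switches** (`SBS_COMPETITION`): both links zero, moderate
  competition ($\lambda = 1$), both inducers just below saturation at the
  printed reference doses (9.5×10⁻⁴ % L-ara, 5×10⁻⁸ M C6), with the C6
  response slightly ahead of the L-ara response there. At those doses the
  circuit holds three stable states — two single-winner states and
  coactivation — and from the uninduced state the outcome is decided by a
  stochastic race.
* **Hybrid TetR variant** (`CBS_HYBRID_TETR`): the module-1-to-2 weight is
  multiplied by the TetR relief, about 0.1 without aTc and 1 at saturating
  aTc, with half-maximal relief at 20 ng/ml.
* **Two-strain circuit** (`TWO_STRAIN_CBS`): no reverse link (AraC cannot
  cross cell boundaries), per-strain pools. Along an L-arabinose ladder the
  population moves LL → HL → HH: coactivation survives because the
  strains do not share machinery.

Units are arbitrary expression units and hours; induction constants are in
the experimental dose units. The default 16 h horizon matches the overnight
induction window of the underlying experiments.

## A structural limitation, stated plainly

In this two-variable reduction the drive on module 2 is monotone in $m_1$
at every instant. A consequence we verified both analytically and by a
random search over ~1200 parameter sets: no parameterization lets module 2
win the race *from the uninduced state* at a moderate L-arabinose dose
while module 1 wins at a high dose. That dynamic winner flip along a
single-inducer ladder presumably requires the C6 pool itself as a third,
slowly accumulating state variable, which this model family deliberately
reduces away. The package therefore treats the one-strain circuit's
{LL, LH, HL} tristability as a static (phase-plane) statement, and its
simulated dose–response reproduces the negative two-phase RFP-vs-GFP
trade-off through the resource-load decline of module 2's basal expression
rather than through deactivation of a previously activated module-2 switch.
The winner flip *is* dynamically reproduced where the model supports it:
along the aTc axis of the hybrid variant (the link strength, not the
inducer, is swept) and along the addition-time axis of the sequential
protocol.

# Phase-plane analysis

Nullclines are traced per slice by sign-change bracketing plus `uniroot`
refinement and linked into branches; a branch-count change of two along the
opposing axis marks a fold (saddle-node), and folds are named positionally
(`SN1`, `SN2`, …) against the scanned variable. Fixed points come from a
sign-pattern scan over a grid refined by damped Newton iterations,
deduplicated at 10⁻⁴ of the box and classified by the eigenvalues of a
central-difference Jacobian; real parts within 10⁻⁶ (scaled by the removal
rate) of zero raise a marginality error rather than a silent
classification. One numerical point matters in this model class: leak-level
states sit three to five orders of magnitude below activated states, so all
scan grids are *graded* — a uniform grid augmented with log-spaced points
down to 10⁻⁶ of the box — and the brute-force oracle used in the tests
grades its axes the same way, since a uniform 500×500 scan simply cannot
see those roots.

Fate thresholds per axis are the midpoint between the lowest and highest
stable-attractor coordinate, applied only when the attractors genuinely
separate (spread above 20% of the axis bound; the naive midpoint of two
nearly-equal coordinates would split a single cluster), with a
quarter-bound fallback otherwise.

Separatrices are stable manifolds of saddles, traced by integrating the
unit-speed time-reversed flow from a 10⁻⁶-box offset along the stable
eigenvector, clipped at the box. Basin partitions are validated
dynamically: points straddling a separatrix must flow to different
attractors.

# Stochastic simulation and the master equation

The single-cell model is the 4-channel reaction network — production and
first-order removal of each module protein — at system size $\Omega$
(molecules per concentration unit), with propensities evaluated at
concentrations $N/\Omega$ through the same activity and resource functions
as the ODE. Simulation is the exact direct-method algorithm (implemented in
C++, driven by R's RNG so `set.seed` governs everything); dose steps are
handled by truncating the pending waiting time at the epoch boundary and
redrawing, which is exact by memorylessness. No tau-leaping and no
translational bursting: the networks are tiny, exactness is cheap, and the
provided information gives no burst parameters (burst size defaults to a
single-step production). Population runs derive per-cell seeds from a
master seed by a fixed counter scheme
($(s + 1000003\,i) \bmod (2^{31}-1)$ for cell $i$), so each cell is
reproducible in isolation and the ensemble is order-independent.

The default $\Omega = 5$ puts activated states near 400–500 molecules:
clearly bimodal populations with visible but not overwhelming noise. The
chemical master equation uses the same propensities on a truncated count
lattice (reflecting boundary; the zeroed boundary production rate is
reported as a mass-leak diagnostic) and solves $Qp = 0$ by a sparse direct
factorization with a power-iteration fallback on the uniformized chain; the
residual tolerance is 10⁻¹⁰. The quasi-potential is $U = -\ln\max(p,
10^{-30})$, with wells detected after a 3×3 mean smoothing and matched to
deterministic attractors by nearest neighbor. Landscape computations use a
smaller system size than population simulation — $\Omega = 0.8$ in the
scenarios — which keeps the lattice at desk scale (the spirit of a
coarse-grained landscape) while preserving the well structure; the
SSA-vs-CME agreement check runs at $\Omega = 0.15$ with a 200 h horizon,
chosen so the chain genuinely mixes between wells within the simulated
window (at large $\Omega$ the wells are deep and a finite-horizon endpoint
ensemble reflects the initial basin race, not the stationary law).

# Fate maps and population analysis

Dose-space maps integrate the ODE from the uninduced state $(0,0)$ — the
analogue of diluting an uninduced overnight culture — to 16 h per grid
point and classify terminal states; a trajectory that moved more than 1% of
the box over the second half of the window is labelled `UNSETTLED` and
excluded from region counts (such points concentrate near basin
boundaries). Stochastic-mode maps take the majority fate over 32 SSA
replicates, with ties broken toward the lexicographically earlier label
under a warning. Dose axes default to four log-spaced decades bracketing
the printed reference doses.

The synthetic flow-cytometry generator adds three layers on top of the
endpoint states: extrinsic noise (mean-corrected multiplicative log-normal
perturbations, CV 0.15 by default, on the production and removal rates),
an instrument model (channel = autofluorescence floor 100 + gain 50 per
expression unit, log-normal measurement noise CV 0.2, log-normal FSC-A
with FSC-H/FSC-A near 1 for singlets), and a 5% injected doublet fraction
(doubled scatter and summed fluorescence at a depressed ratio) so that
FSC-A/FSC-H gating has something real to remove. Gains and floors were
chosen so activated and basal clusters separate by at least a decade on the
log scale, as in bench flow data; none of these values is a fitted
biological claim. The generator reproduces the noise-induced fate
splitting of a genuinely stochastic population (bimodality appears even at
zero extrinsic CV) but not spectral spillover, instrument drift, or cell
division and partitioning noise — so passing tests say nothing about
those aspects of real data.

The plate-reader analogue reports blank-subtracted mean channels per dose,
normalized to each channel's maximum over the sweep. The two-phase fit is
a continuous hinge $y = b_0 + b_1 x + b_2 (x-c)_+$ with the breakpoint
searched over interior x-quantiles (5th–95th percentile, single-percentile
steps) and 1-vs-2 segments selected by BIC; the hinge must improve BIC by
more than 2 (positive evidence) so that plain noisy lines essentially never
elect a spurious breakpoint — BIC alone, being scale-invariant, admits a
few percent of false positives at any noise level.

# Problem sizes

The shipped scenarios and tests use: 120-per-axis graded scan grids
(500-per-axis in the brute-force oracle), 20×20 dose maps, 200-cell SSA
fate ensembles at $\Omega = 5$, 10⁴-cell endpoint ensembles at
$\Omega = 0.15$ for the stationary comparison, 48-point dose–response
ladders, 500-cell-per-strain mixtures over 7 doses, and CME lattices up to
roughly 100×60. The complete suite runs in a couple of minutes on one
core.

# Known limitations

Beyond the structural point above: removal rates lump degradation and
dilution, so growth-rate feedback on circuit state is out of scope; there
is no mRNA layer and no mechanistic ribosome/RNAP allocation model (the
resource fraction is the standard effective sequestration form); the
two-strain single-cell simulation treats the partner module's level as the
shared coculture C6 field seen by each cell, which ignores strain-ratio
dynamics; and fold thresholds are reported against the scanned parameter
positionally rather than tied to a specific inducer axis.
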