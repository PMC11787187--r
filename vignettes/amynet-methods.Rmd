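---
title: "Models and methods in amynet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in amynet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amynet)
```

`amynet` simulates the aggregation of amyloid-β (Aβ42) across three levels
of description — a closed in vitro reaction, a single brain region with
clearance, and a brain-scale network — and layers antibody therapeutics on
top. This vignette records the models, their assumptions, the numerical
choices, and the limits of what the bundled synthetic data can show.

## The model hierarchy

### Closed in vitro kinetics

Aggregates are tracked by size: `p_i` is the molar concentration of
`i`-mers, with the dimer as the smallest nucleus. Three processes suffice
to describe Aβ42 mass build-up in buffer: a constant (heterogeneous,
surface-catalysed) primary nucleation source `k_n`; elongation at both
fibril ends, `2 k₊ m p_i`, which moves an aggregate up one size class per
monomer added; and monomer-dependent secondary nucleation on aggregate
surfaces, `k₂ σ(m) m² M`, saturating through
`σ(m) = K_m / (K_m + m²)`. Depolymerisation, fragmentation and
fibril–fibril association are omitted — for Aβ42 at these conditions they
are subdominant. Total mass `m + M` is conserved, so the toxic mass `M(t)`
rises sigmoidally from zero to the initial monomer pool `m₀`.

The first two moments `(P, M)` close exactly under these kinetics, giving
a three-variable system that is the workhorse for halftime analysis.
Linearizing around the unseeded state with `m = m₀ − M` yields growth
coefficients `a = k₂ m₀² K_m/(K_m + m₀²)` and `b = 2 m₀ k₊ + a`, the
early-time growth rate `a + √(ab)`, and a closed-form halftime
(`halftime_linear()`); in the regime `m₀² ≫ K_m` this simplifies to
`τ ≈ log(k₂ K_m m₀/k_n + 2)/√(2 k₊ k₂ K_m m₀)`. Sweeping each rate
constant over four orders of magnitude shows the halftime responds most
strongly to elongation (square-root dependence), then secondary
nucleation, and only logarithmically to primary nucleation.

### The single-region in vivo model

In tissue, three changes apply. Monomer production is homeostatically
regulated, so `m ≡ m₀` is held constant. Secondary nucleation saturates
with respect to the accumulated mass rather than the monomer pool,
`σ(M) = K_M/(K_M + M²)`, with `K_M = K_m` by default. And aggregates are
removed by first-order clearance at per-size rates `λ_i` — enzymatic
degradation, cellular uptake, glymphatic and vascular efflux lumped into
one rate. Primary nucleation becomes homogeneous (`k_n m²`); for seeded
runs it is negligible and disabled by default, which makes the empty state
an exact fixed point.

With constant clearance the moments close again and the system has a
transcritical bifurcation: above
`λ_crit = k₂ m₀² + √(k₂ m₀³ (k₂ m₀ + 2 k₊))` the aggregate-free state is
stable (a healthy region clears any seed); below it a nonzero equilibrium

$$M_2 = \frac{\sqrt{K_M(-\lambda^2 + 2\lambda k_2 m_0^2 + 2 k_+ k_2
m_0^3)}}{\lambda}$$

takes over. Two algebraically inequivalent arrangements of the radicand in
the `λ_crit` expression circulate in the literature; the form above is the
one whose zero coincides with the vanishing of the `M₂` radicand and with
the numerically observed bifurcation (`bifurcation_search()` brackets it
by bisection over simulated outcomes to 0.01% here), so it is the one
implemented. Note `λ_crit` does not involve `K_M`, while `M₂ ∝ √K_M`: the
saturation constant sets the allowable local load, not the threshold.

For arbitrary size-dependent clearance the steady state obeys
`p*_i = δ_i p*_{i−1}` with `δ_i = 2k₊m₀/(λ_i + 2k₊m₀)`, so
`p*_i = Δ_i p*_2` (cumulative products) and, writing
`Δ = Σ k Δ_k`, the dimer balance solves in closed form to
`p*_2 = √K_M √(k₂ m₀² Δ − λ₂ − 2k₊m₀) / (Δ √(λ₂ + 2k₊m₀))`. A point worth
recording: this closed form is *exact* including the σ(M) saturation —
substituting `M* = Δ p*₂` into the dimer balance eliminates σ
algebraically — so no numerical solve is needed for the fixed point, and
for constant clearance it reproduces `M₂` identically. Existence requires
the decay of `Δ_i` (C1), convergence of `Δ` (C2) and positivity of the
radicand (C3); `equilibrium_distribution()` reports which condition fails.

Closed-form critical rates are also provided for clearance growing
(`λ_i = iλ₀`) and shrinking (`λ_i = λ₀/i`) with size; the latter is
`2a(a + 4k₂m₀²)/(a + k₂m₀²) ≈ 2a` with `a = 2k₊m₀`. The `iλ₀` form is
carried as printed in the source literature despite a dimensional
blemish in its numerator; the numerical bifurcation search is the
recommended cross-check for that variant.

### Clearance damage

Toxic mass degrades clearance: `dλ_i/dt = β M (μ_i − λ_i)` relaxes each
rate monotonically from its initial value toward a basal capacity `μ_i`.
The long-run fate is decided by `μ` relative to `λ_crit`
(`classify_regime()`): a basal capacity above critical ultimately clears
the region even as clearance erodes; below critical, erosion drives the
region through the bifurcation into sigmoidal invasion. Homogeneous
primary nucleation is kept on by default in this module — it is the slow
seed source that makes unseeded tissue erode at all. No recovery
(`dλ/dt > 0`) mechanism is modeled.

### Network transport

Regions are nodes of a weighted connectome; aggregate exchange along
axonal bundles is modeled as graph diffusion with the unnormalized
Laplacian `L = diag(A·1) − A`, the only Laplacian that conserves mass and
produces no flux between equal concentrations. Size class `i` moves with
coefficient `ρ_i`, either constant or `ρ₀/i³` (diffusivity falling as the
cube of molecular weight — large fibrils essentially do not move).
Monomers move by diffusion only, so a uniform monomer field stays
constant, preserving the single-region assumptions at every node. With
uniform parameters and a uniform seed the network reduces exactly to the
single-region model; with a localized seed, invasion propagates by graph
distance, nuclei (dimers) being the effective infectious agent, and the
order of invasion is insensitive to the diffusion law. Invasion times are
defined as the first crossing of half the node's saturation mass
(`invasion_metrics()`, threshold configurable).

Two network integrators are provided. The size-resolved one covers any
clearance rule and size-dependent diffusion. The moment-level one
(constant clearance, size-independent ρ) avoids size truncation entirely;
it is the tool of choice at low clearance rates, where the equilibrium
mean aggregate size `2k₊m₀/λ` (6000 at `λ = 10` in reference units) makes
any practical size-resolved truncation meaningless.

### Therapeutics

Monoclonal antibodies enter in two ways. Binding to fibril surfaces
inhibits secondary nucleation, modeled as `k̃₂ = Δk k₂` with `Δk ∈ [0,1]`
(the strongest reported dose of aducanumab corresponds to a 69%
reduction); this lowers `λ_crit` across all clearance variants, so a
patient whose clearance sits between the treated and untreated thresholds
transitions to the healthy regime on drug — the central therapeutic
observation of this model family. Antibody-mediated removal adds a
clearance increment `λ_drug = L·C_p` proportional to plasma concentration;
with equally spaced doses and single-exponential elimination the clearance
profile is `λ(t) = λ_drug e^{−A(t mod B)} + λ_a`, and
`integrated_dose()` gives its accumulated increment over a trial horizon
in closed form (the budget `C_max`, a proxy for dose-limiting toxicity
such as ARIA). `simulate_dosing()` integrates the moment system cycle by
cycle until the periodic steady state, and `optimize_regime()` minimizes
the cycle-averaged mass `M̄` over `(B, λ_drug)` at fixed budget — the
constraint is linear in `λ_drug`, so each grid value of `B` determines its
dose directly and the optimization is a deterministic one-dimensional
sweep. The optimum is always the most frequent dosing (`B` at its lower
bound), but `M̄` varies weakly along the budget contour, quantifying the
modest cost of patient-friendlier spacing.

Time units in this module: kinetic rates are per hour, dosing parameters
(`A = 1`, `B`, `t_max = 28`) are used in the same nominal unit as printed.
Because the kinetic relaxation toward `M₂(λ)` is fast relative to any
inter-dose interval of interest, the cycle-averaged mass depends only on
the shape of the `λ(t)` profile, and this convention reproduces the
published strategy comparisons; the tests verify the quasi-static
tracking of `M₂(λ(t))` directly.

## Numerical choices

* **Truncation.** Size-resolved systems are cut at `N` with a reflecting
  boundary: elongation out of size `N` is disabled, and the corresponding
  monomer consumption is removed, so conservation holds exactly at any
  `N`. A runtime diagnostic fails the run if the top two size classes ever
  carry more than 1% of the toxic mass. The elongation terms advect a
  front through size space at `2k₊m` sizes per hour, so `N` must cover
  both the equilibrium tail and the transient front; defaults are
  `N = 200` (in vitro) and `N = 300` (in vivo), with tests and examples
  choosing `N` and concentrations so the diagnostic passes. Full in vitro
  saturation at the reference `m₀ = 3` μM produces mean sizes near 10³ and
  is run at moment level instead.
* **Fixed points at matched truncation.** `equilibrium_distribution()`
  mirrors the simulator's reflecting boundary by default (its last size
  balance is `p*_N = (2k₊m₀/λ_N) p*_{N−1}`), making it the exact steady
  state of the truncated ODE system; `boundary = "infinite"` completes
  `Δ` with the analytic geometric tail (exact whenever `λ_i` is constant
  beyond some size) and is used for window-targeting analyses, where the
  background clearance is weak and the tail long.
* **Integrators.** Size-resolved systems use `lsoda`; moment-level
  systems use `vode` (BDF), which is robust on the long post-saturation
  plateaus where step-type switching can stall. Tolerances are
  `rtol = 1e-8`, `atol = 1e-12·m₀`, recorded in every trajectory's
  metadata.
* **Negativity.** The advected size-front leaves small oscillatory
  undershoots around zero (mass conservation is unaffected, at ~1e-13
  relative). Values down to `−1e-4·m₀` are clipped to zero (with a warning
  above `1e-8·m₀`); anything larger aborts the run as unreliable.
* **Monomer exhaustion in vitro.** The constant nucleation source
  requires free monomer; integrating it past monomer exhaustion would
  drive `m` linearly negative. The simulators therefore throttle the
  source continuously by `m/(m + w)` with `w = 1e-6·m₀`; `rhs_invitro()`
  itself is the unregularized right-hand side.
* **Periodic steady state.** Dosing simulations restart the integrator at
  each dose (the profile is discontinuous there), require at least 20
  cycles, and declare steady state when successive cycle maxima agree to
  `1e-6` relative; the final cycle is re-integrated on a fine grid
  (≥ 500 points per day) and averaged by the trapezoidal rule with a
  half-grid refinement check at `1e-4`.
* **Bifurcation search.** A tiny dimer seed (`1e-8·m₀`) either doubles or
  decays over a unit-time probe; bisection on `λ` to `1e-4` relative
  width. Near the threshold the leading eigenvalue crosses zero linearly
  in `λ`, so a unit probe resolves the transition sharply at these rates.

## Size-interval targeting: standing mass vs flux blocking

Raising clearance on a size window `n₀ ≤ i ≤ n₁` lowers the equilibrium
toxic mass most when the window sits at the smallest sizes. Two mechanisms
must be distinguished. The *standing* equilibrium mass in an interval,
`Σ k Δ_k p*₂`, actually peaks near size `2k₊m₀/λ` — far above the
oligomer range for any subcritical `λ` with the reference kinetics — so a
static removal argument favors *higher* windows there
(`compare_interval_targets()` reports these sums). The therapeutic
ordering comes instead from flux blocking: every aggregate grows through
the small sizes, so a window at the bottom of the size axis intercepts the
entire growth flux (in the recurrence, `δ_i → 0` inside the window
suppresses everything above it, and a window starting at the dimer removes
the aggregated state altogether). `interval_mass_reduction()` quantifies
this, and it is the basis of the small-size-targeting conclusion.

## The synthetic connectome, and what the tests do not show

Real brain networks come from tractography; this package deliberately does
not process imaging data. `generate_connectome()` draws a Watts–Strogatz
small-world graph (high clustering, short paths — the regime in which
secondary infection follows primary infection quickly), assigns
heavy-tailed log-normal edge weights as a stand-in for streamline counts,
attaches one very weakly connected peripheral node (`"frontal_pole"`) so a
lowest-connectivity region exists, and labels nodes with anatomical-style
names so seeding conventions (posterior cingulate, entorhinal cortex) map
onto fixtures. Defaults: 40 core nodes, mean degree 6, rewiring
probability 0.1, log-normal(0, 0.75) weights — a scientist's notion of a
plausible reduced connectome, fixed once. Everything is deterministic
given the RNG seed.

Consequently the network results here demonstrate *mechanisms* — invasion
ordered by graph distance, insensitivity to the diffusion law, peripheral
regions invaded last — not anatomical predictions. Regional invasion
sequences for a real brain require a real connectome, which can be
supplied as a CSV edge list or GraphML file (`read_edgelist()`,
`read_graphml()`). Likewise, the antibody inhibition levels are inputs
taken from published in vitro assays, not outputs of this model, and the
dose–toxicity budget `C_max` is a proxy, not a pharmacokinetic model of
ARIA risk.

## Known limitations

* Aggregates are distinguished by size only; no structural polymorphism,
  and the nucleus is fixed at the dimer.
* Clearance only decays under damage; no recovery or treatment-induced
  restoration of intrinsic clearance.
* Monomer concentration is constant (no production modulation), and
  fragmentation/depolymerisation are absent, as in the underlying kinetic
  calibration.
* The subcritical `λ₀/i` clearance variant has power-law equilibrium
  tails with exponents barely above 1 near its critical point; no
  desk-scale truncation represents them faithfully, so quantitative
  statements for that variant rest on its closed forms and on
  supercritical checks.
* Problem sizes in the tests (truncations of 100–600, networks of 4–21
  nodes, reduced in vitro concentrations for size-resolved saturation
  runs) are chosen so every run satisfies the truncation diagnostic; they
  exercise the full code paths at moderate scale.
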