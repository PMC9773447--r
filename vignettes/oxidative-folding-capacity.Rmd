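---
title: "Modelling oxidative folding demand and capacity in E. coli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxidative folding demand and capacity in E. coli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbfold)
```

## The question and the model

Disulfide bonds in *E. coli* are formed in the periplasm by the Dsb
system. `dsbfold` quantifies the *demand* side of this system — how
many disulfide bonds the cell must form per unit time to keep its own
proteome doubling — and the *supply* side — the minimal apparent
kinetics the Dsb enzymes must provide — and from their difference
predicts spare capacity for recombinant disulfide-bonded products.

The kinetic core is a mass-action ODE network over substrate pools and
enzyme redox states. Substrates of each folding-difficulty category
`c` enter unfolded (`UF`) at rate `v_c`, are oxidised by `DsbAo` with
apparent association constant `k45_c`, and land in the folded (`FP`)
or misfolded (`MFP`) pool with probability `p_c` / `1 − p_c`, where
`p = 1, 0.5, 0` for cat1/cat2/cat3: a protein with only the two
bonding cysteines cannot mispair, one with extra cysteines but a
consecutive-cysteine bond mispairs half the time, and a
non-consecutive bond is assumed never to oxidise correctly on the
first pass. Misfolded substrate engages the pooled isomerases
(`DsbCGr`, constant `k678_c`); each engagement is a futile cycle with
probability `f_futile = 1/3`, a successful isomerisation to `FP` with
probability `f_success`, or a reduction back to `UF` with probability
`f_reduce` — only the reduction branch oxidises the isomerase, which
is recycled by DsbD (`k9`) and ultimately thioredoxin (`k10`). DsbA is
recycled by DsbB (`k3`) and DsbB by quinone (`k2`). Quinone and
thioredoxin are clamped boundary pools, so `k2` and `k10` are
pseudo-first-order; there are no explicit enzyme–substrate complexes
(the constants are *apparent* association constants; saturation
kinetics are out of scope). The futile branch is represented
explicitly with no net state change, so isomerase engagement (and any
future occupancy accounting) includes it instead of silently rescaling
`k678`.

Only the non-futile split is genuinely open: with the futile fraction
fixed at 1/3, we default the remainder to `f_success = f_reduce = 1/3`
each, configurable in every entry point.

Each redox pair (DsbAo/DsbAr, DsbBo/DsbBr, DsbCGr/DsbCGo, DsbDr/DsbDo)
is a conserved moiety. We integrate only the active form and derive
the partner from the conserved total, so conservation holds to machine
precision by construction, and the reduced system is smaller and less
stiff. Trajectories come from `deSolve::ode` (lsoda) with relative
tolerance `1e-8` and absolute tolerance `1e-9` times the largest
initial concentration.

### Units

Concentrations are molecules per cell and time is in minutes, matching
the per-minute pseudo-first-order rates of the per-condition rate
table. `assoc_to_model_units()` converts M⁻¹s⁻¹ constants using the
growth-rate-dependent cell volume and a periplasmic volume fraction
(default 0.2). The literature DsbA estimate of roughly 4000 copies per
cell corresponds to ~2.7 µM on a whole-cell basis and ~13 µM on a
periplasmic basis; because the source calculations do not state which
volume they used, both are supported (`compartment_fraction`) and
neither is asserted as canonical.

## Demand, influx and the doubling-time criterion

Folding demand is the abundance-weighted bond count per category:
`Σ (bonds per protein × copies per cell)`, over the periplasmic subset
("secreted" and "secreted outer membrane" annotations). Counting rules:
alternative partners of a single cysteine collapse to one bond (we
count the largest simultaneously formable set, by exact maximum
matching on the small per-protein bond graph), a cysteine bonded to
its own position on another copy of the protein counts 0.5, and
inter-protein bonds (cat4) are tabulated but excluded from kinetic
demand. "Consecutive" means adjacent in the protein's ordered cysteine
list; a protein carrying bonds of several categories takes its hardest
intramolecular category for demand accounting, with per-bond
categories retained. One published breakdown of 174 periplasmic bonds
lists 140 consecutive, 12 non-consecutive and 22 "intramolecular";
since 140 + 12 + 22 = 174, we read the third group as *intermolecular*
and flag the wording discrepancy here rather than in code.

At steady state growth dilution sets the minimum synthesis rate
`v_c = µ·N_c` for a category pool of `N_c` bonds per cell. Over one
generation `t_d = ln 2 / µ` that influx supplies `ln 2 · N` bonds, so
we define one *proteome-equivalent* of folded output as `ln 2 × ΣN_c`;
with unconstrained enzymes the model's proteome doubling time then
equals the reported `ln 2 / µ` exactly, which is the analytic anchor
for the 5%-slack criterion.

A condition is *feasible* under a parameter set when (i) every
substrate species' accumulation fraction — the unfolded plus misfolded
pool divided by cumulative synthesis — is at most 0.5% at one reported
doubling time, and (ii) the proteome doubling time is at most 5% above
the reported one. Feasibility simulations start from closed-form
quasi-steady substrate pools (`UF* = J_ox/(k45·A_tot)` and the
matching isomerase balance, capped at one doubling's synthesis so
degenerate candidates stay integrable) and run to **2×** the reported
doubling time: accumulation is evaluated at `t_d`, but measuring a
doubling time up to `1.05·t_d` requires integrating past `t_d`.

## Inferring minimal rate constants

The published procedure reduces kinetic values gradually until one of
the two criteria breaks. Within that loose prescription the schedule
is ours, and one natural candidate fails: *sequential* per-parameter
minimisation (cyclic coordinate descent) lets the first parameter in
the cycle absorb the entire feasibility slack, after which every later
parameter is pinned at its ceiling — an order-dependent, degenerate
answer that also breaks parameter recovery on synthetic ground truth.
We therefore use a two-stage deterministic schedule:

1. **Independent minima.** Each constant is bisected (relative
   tolerance 1%) to the smallest feasible value with all other
   constants at their biochemical ceilings (1e6 M⁻¹s⁻¹ for association
   constants, 1e3 min⁻¹ for the first-order `k2`/`k10`). This is each
   reaction's minimal requirement, and it can only be at or below any
   jointly feasible value of that constant.
2. **Joint restoration.** A single slack multiplier λ ≥ 1 on the
   stage-one minima is bisected to the smallest value for which the
   full parameter set passes both criteria simultaneously (λ is
   typically 2–4).

The result is deterministic, restart-stable and order-independent;
conditions that fail even at ceiling rates (for example with DsbA
absent) raise an error naming the binding constraint. Reported
pseudo-first-order rates multiply each constant with its partner pool:
`R3 = k3·[DsbB]`, `R4/R5 = k45·[DsbA]`, `R6–8 = k678·[DsbC+DsbG]`;
`R2 = k2` is already first-order. Summary rows use the median, the
max/min fold range, and Q3/Q1 with linear-interpolation (type-7)
quartiles — the IQR row depends on this convention, so it is fixed
here.

Because minimal constants depend on the input proteomes and on the
search schedule, individual per-condition values are not expected to
reproduce any external table exactly; the summary statistics of the
bundled published table, the chemostat growth-rate correlation, and
the recovery/monotonicity properties on synthetic ground truth are the
reproducible quantities.

### Steady states, and when they do not exist

For this network the steady-state chain fluxes are pinned by synthesis
alone (`J_ox = v/(1 − f_reduce(1−p)/(f_success+f_reduce))` per
category, with matching isomerase and electron-transfer fluxes), so
`steady_state()` solves the state in closed form and certifies it with
a damped log-space Newton polish using the analytic Jacobian. A
consequence worth knowing: at *minimal* inferred rates a true steady
state need not exist — the DsbD chain may sit below its existence
bound `k10·D_tot ≥ J_red` while the slowly growing misfolded pool
still passes the 0.5%-at-one-doubling criterion. `steady_state()`
raises a "no steady state" error in that case, and flux-balance
properties are checked at generously feasible parameter sets.

## Recombinant capacity

A recombinant disulfide-bonded product is modelled as one extra
substrate species carrying a single bond of a chosen category, with
the host's constants and enzyme levels frozen (no regulatory
adaptation). `capacity_scan()` bisects the recombinant synthesis rate
to the largest value at which every *native* species stays under the
0.5% accumulation threshold (whether the recombinant's own
accumulation also counts is a switch, off by default), and reports it
as a percent of total protein synthesis `µ·(total copies)`. The upper
search bound is 10× total native synthesis; a scan that is feasible
even there is returned capped and flagged. Because inferred constants
are minimal, capacity at those constants is near zero by construction;
the analysis scripts therefore also scan at multiples of the minimal
constants, which is the regime where condition-to-condition
differences become visible.

## The synthetic generator

`synthetic_spec()` fixes the study conditions: growth rates anywhere
in the calibrated 0.1–1.9 h⁻¹ window; a log-normal abundance spectrum
(σ = 2 on the natural-log scale, a standard shape for proteome
abundance distributions) rescaled so the total equals the theoretical
protein count `3e6 µm⁻³ × cell volume`; Dsb enzymes injected at their
reported mean levels (DsbA 696, DsbB 139, DsbC 144, DsbD 29, DsbG 27
ppm); a disulfide sub-proteome of 80 proteins carrying 2% of total
protein copies (a periplasmic-scale share) with the observed
two-thirds/0.23/0.10 category mix; and three evidence pseudo-sources
whose detection probability is logistic in log abundance, reproducing
the empirical pattern that sources agree better on highly expressed
proteins. Ground-truth rate constants are built from closed-form
necessity estimates times a slack factor of 6 and are verified
feasible by simulation before a fixture is emitted. Everything is a
pure function of `(spec, seed)`.

What the generator does *not* emulate: correlated measurement error
between proteomes, protein turnover beyond growth dilution, condition-
dependent regulation of Dsb expression, saturation kinetics, and the
heterogeneous schemas of real supplementary tables. Passing tests on
synthetic data therefore demonstrate correctness of the computations
and the stated model properties, not biological accuracy of any
specific rate value.

## Numerical choices and problem sizes

- Bisections (rate search, capacity scan) run to 1% relative
  tolerance; all searches are deterministic.
- Feasibility trajectories use 61 grid points over 2 doubling times;
  accumulation is linearly interpolated at `t_d`.
- The test suite and the acceptance script use 20 seeded conditions
  spanning µ = 0.1–1.9 h⁻¹ with 1000-protein proteomes — sizes chosen
  so the full study re-runs in minutes on a laptop while every
  property is exercised across the growth-rate range.
- Degenerate inputs: all-zero proteomes, zero-synthesis categories,
  absent enzymes and zero-variance correlations raise errors or return
  defined values (documented per function) rather than NaN.

## Limitations

Apparent constants are lower bounds on biochemical constants, not
estimates of them; the model has no explicit enzyme–substrate
complexes, no Sec-translocon or chaperone limits, no sulfenic-acid
chemistry, and treats the isomerase pool DsbC+DsbG as one moiety.
Capacity predictions inherit all of these simplifications and the
no-adaptation assumption, and should be read comparatively across
conditions rather than as absolute yields.
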