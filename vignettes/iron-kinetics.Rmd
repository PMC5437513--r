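---
title: "Modelling whole-body iron kinetics with ferrokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-body iron kinetics with ferrokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferrokin)
```

## The model

`ferrokin` describes the distribution of iron across the mouse body as a
system of ordinary differential equations, one per chemical pool. Seven
compartments carry volume (bone marrow 2.1e-4 L, duodenum 3.9e-5 L,
liver 1.2e-3 L, plasma 1.3e-3 L, RBC 7.9e-4 L, rest of body 2.0e-2 L,
spleen 6.7e-5 L); an eighth, volume-less "outside" pool accumulates
excreted iron and is tracked in amount (mol) rather than concentration.
Plasma resolves molecular detail — non-transferrin-bound iron (NTBI),
apo-transferrin, mono- and di-ferric transferrin, and hepcidin — while
each organ lumps its entire iron content into a single pool.

Iron moves through five reaction families:

1. **Dietary influx**: a constant flux `vDiet * V_duo` into the duodenum.
   Modelling meals as a time-averaged continuous rate gives the system a
   well-defined steady state; a discrete-meal schedule could be emulated
   by switching `vDiet` between integration segments, but is untested
   against data.
2. **Ferroportin export** from duodenum, liver, spleen and rest into
   plasma NTBI, with saturable kinetics
   `V * Volume * S / ((Km + S + Ic) * (1 + Hep/Ki))`. The competitive
   term `Ic` is the isotopic twin of the substrate (both forms share one
   transporter); hepcidin inhibits non-competitively, equivalent to
   removing transporter molecules. `Km` and `Ki` are protein properties
   shared by all four reactions; the four limiting rates `V*` are
   tissue properties estimated separately.
3. **Transferrin loading**: irreversible second-order mass action
   (`NTBI + Tf -> Fe1Tf`, `NTBI + Fe1Tf -> Fe2Tf`, and every labeled
   combination). Irreversibility reflects the sub-femtomolar dissociation
   constant of ferric transferrin. Competition between labeled and
   unlabeled NTBI for free transferrin emerges from writing all six
   combinations explicitly.
4. **Transferrin-mediated import** into bone marrow, liver, duodenum and
   rest: first order in each transferrin-iron species with one rate
   constant per organ, returning apo-transferrin to plasma; di-ferric
   transferrin delivers two iron ions (the mixed species one of each
   label). Receptor saturation is deliberately not modelled.
5. **Erythroid cycling and loss**: bone marrow to RBC (`kInRBC`), bone
   marrow to spleen (`kBMSpleen`, macrophage destruction of immature
   cells), RBC to spleen (`vRBCSpleen`, erythrocyte death), duodenal
   sloughing (`kDuoLoss`) and skin/hair loss from rest (`kRestOut`) into
   the outside pool. RBCs acquire no iron directly from plasma.

The radioactive tracer (⁵⁹Fe) is represented by duplicating every iron
species and reaction, with identical rate constants (no kinetic isotope
effect) and competitive coupling where both forms share a carrier.
Hepcidin itself has constant synthesis (`kHepSyn`) and first-order decay
(`kHepDeg`) with no tracer twin and no feedback from iron — diet and
disease protocols act by changing `kHepSyn` (and `vDiet`) only, which is
exactly the hypothesis the model exists to test.

All fluxes are computed in extensive units (mol/day) because transport
reactions couple compartments of different volume; each ODE divides the
signed flux sum by its species' home volume. Two structural identities
follow: total transferrin is conserved, and total iron (counting
di-ferric transferrin twice and including the outside pools) grows at
exactly `vDiet * V_duo`. The test suite asserts both along simulated
trajectories, together with tracer conservation after injection.

## Parameters, units, defaults

Concentrations are molar, volumes litres, time days everywhere,
including on disk. Two printed-unit ambiguities are resolved in favour
of dimensional consistency: the ferroportin limiting rates `V*` and the
dietary rate `vDiet` are treated as molar/day, multiplied by the source
compartment volume to yield mol/day (the alternative reading, mol/day as
absolute rates, implies gram-scale daily iron fluxes in a 2 mg system).
Tracer fractions are invariant to this convention.

The ten published adequate-diet estimates are available as
`published_params(1..10)`; column 6 — RBC transition time 42.5 days,
transferrin saturation 47% — is the package default. Three constants are
not part of that table and were set as follows:

* `kHepDeg = 1/day` and `kHepSyn = 23e-9 M/day`, giving the reported
  23 nM circulating hepcidin at the adequate diet.
* `Ki = 0.973 nM`. This is a genuine calibration choice: the steady
  state of the whole system is controlled by the hepcidin inhibition
  factor `1 + Hep/Ki`, and flux balance with the published rate
  constants requires that factor to be ≈25 — with `Ki` of the order of
  the circulating level (factor ≈2), ferroportin export outruns the
  loss pathways, transferrin saturates completely and NTBI grows without
  bound. The default is the root of
  `TotalFe(quasi steady state; Ki) = 2.20 mg`, the printed total body
  iron of the canonical set; it simultaneously reproduces the reported
  transferrin saturation (46.7% vs 47%) and NTBI (33.1 nM vs 33 nM),
  which suggests it is close to the (unpublished) deposited value. All
  three constants are exposed in `iron_params()` and can be overridden,
  e.g. from a parameterization retrieved from a model repository.

## Simulation protocols

A de-novo lead-in of 5000 days from empty iron pools (transferrin fully
apo, hepcidin at its steady level) brings the unlabeled system to quasi
steady state; diet experiments re-equilibrate for 35 days from the
stored adequate state, matching the 5-week dietary conditioning of the
underlying experimental design. The tracer pulse adds labeled NTBI to
plasma; the default dose is 1e-6 of the plasma iron amount. The labeled
subsystem is linear in the dose at a fixed background, so fractions of
dose are dose-independent; the default is chosen small enough that this
holds to 1e-6 (at 1e-4 of plasma iron the labeled NTBI pulse is no
longer negligible against the ~33 nM circulating NTBI and the fractions
shift at the 1e-4 level).

Integration uses a stiff solver (lsoda) over a compiled right-hand side
at relative tolerance 1e-8 and absolute tolerance 1e-12. The labeled
pools live ~6 orders of magnitude below the unlabeled ones, so tracer
simulations use a per-species absolute tolerance scaled to the dose
(`tracer_atol()`); without it the tracer subsystem would be integrated
at the noise floor of the solver. Rounding-level negative undershoot is
clipped to zero; anything beyond 1e3 times the absolute tolerance warns.
The default observation grid
`{0.01, 0.04, 0.17, 0.5, 1, 2, 4, 7, 10, 14, 21, 28}` days spans the
fast plasma clearance (hours) and the slow erythroid phase (weeks); the
original sampling times are not published.

The reaction network also exists as an explicit data structure
(`build_model()$reactions`) with a reference evaluator `model_rhs()`;
the compiled derivatives are tested against it at random states, and the
SBML export writes its kinetic laws from the same structure.

## Calibration

The objective is the unweighted sum of squared residuals between
simulated and observed fractions of dose over all pools and times
(optionally 1/sd² weighted; the unweighted form matches the magnitude of
published objective values, ~0.02 over 96 residuals). The constraint
keeps total body iron at the tracer-injection state within 1.8–2.2 mg —
total iron is not conserved by the model, so without the constraint the
background is unidentified from fraction-of-dose data.

The global search is a (μ, λ) evolution strategy with stochastic ranking
(`sres_optimize()`), the algorithm class reported to handle this
nonlinearly constrained problem best, followed by a monotone
Hooke–Jeeves polish. Rate constants are searched as log10 values with
default bounds two decades either side of the baseline: the constants
span ten orders of magnitude. Published-scale SRES settings (λ = 200,
μ = 30, Pf = 0.45, 250 generations) are the function defaults; the test
suite runs reduced budgets (λ = 60–100, 40–100 generations), which
recover the two identifiable constants (`kInRBC`, `kRestOut`, published
CVs under 5%) to within 10% from 5%-noise synthetic data while the
weakly identified constants (ferroportin `V`s, `Km`; published CVs
160–190%) roam, mirroring the published identifiability structure.
`vDiet` is pinned during adequate-diet fits (dietary influx is set to
its physiological value precisely to reduce unidentifiability) but can
be freed. Joint multi-diet fits share every parameter except `vDiet`
and `kHepSyn` per diet; freeing any other per-diet parameter is
rejected, because "hepcidin plus diet is enough" is the hypothesis under
test. Ensembles are compared parameter-wise by Welch's two-sample t-test
on log10 values (the pairing of runs between ensembles is not
meaningful, hence unpaired).

Model selection among feasible fits minimizes the distance between the
RBC transition time — pool content over throughput at steady state,
computed by flux bookkeeping and equal to `1/vRBCSpleen` for the
single-exit RBC pool — and the 40-day mean lifetime of mouse
erythrocytes, with ties broken by the lower objective.

## The synthetic-data generator

`generate_tracer_data()` emulates the structure of the radioiron
distribution experiment: lead-in, optional 35-day diet switch,
injection, sampling of the 8 reported pool fractions at the default
grid, then multiplicative Gaussian noise with a chosen CV (default
scenarios use 5%), truncated at zero, with `sd = cv * mean` recorded.
What it does *not* emulate: the original animal-level replication
(several mice per time point), possibly non-proportional measurement
error, and any real sampling schedule — so passing recovery tests shows
the estimation machinery is sound under the stated noise model, not that
the original data are reproduced. Deficient and rich synthetic scenarios
scale `(vDiet, kHepSyn)` by (0.25, 0.5) and (4, 1.35); these are
illustrative stand-ins (the factor 1.35 echoes the reported ~35%
hepcidin rise under the rich diet), not published refit values, which
exist only in the deposited model files.

## What the model reproduces, and what it cannot

With the canonical constants the package reproduces, from scratch: the
adequate-diet steady state (2.2 mg body iron, 47% transferrin
saturation, 23 nM hepcidin, 33 nM NTBI, excretion 8.2 µg/day balancing
influx); the RBC transition times of the published ensemble
(1/vRBCSpleen: 42.5, 12.0, 35.3 days for sets 6, 1, 7); and the anemia
of chronic disease under five-fold hepcidin — iron falls ~3-fold in
plasma, bone marrow and RBC, ~1.5-fold in rest of body and 2-fold in
total, accumulates ~7-fold in the duodenum and ~2-fold in liver and
spleen, with a sharp spleen overshoot inside 50 days and a slower liver
peak near 160 days.

The peak bone-marrow tracer fraction computes to 54.6% of dose. The
narrative figure of "up to 60%" sits between this instantaneous peak and
the asymptotic marrow share of plasma iron turnover,
`kInBM / (kInDuo + kInLiver + kInBM + kInRest)` = 63.2%: the marrow
already exports iron to RBC while it fills, so its content never reaches
its uptake share. Both numbers are reported; the package does not
resolve which one the prose meant.

Structural negatives are part of the model's purpose. On rich-diet-like
data whose truth includes a liver-uptake increase, refits restricted to
the two hepcidin-hypothesis knobs over-predict RBC label and
under-predict liver label — the documented failure mode implicating
additional regulation of `kInLiver`, `kInRBC` and `kRestOut` under iron
loading. Suppressing hepcidin does not produce preferential liver
loading, i.e. hemochromatosis is *not* reproduced; the test suite checks
this absence as expected behaviour.

## Numerical and design notes

* Label symmetry (swapping all starred and unstarred pools commutes with
  the dynamics) holds exactly for the reaction network; the dietary
  influx necessarily breaks it, feeding unlabeled iron only, so the
  property is tested with `vDiet = 0`.
* Integration failures inside the optimizer return a large penalty
  (1e6) instead of erroring, so pathological parameter regions are
  routed around; the solver's own diagnostics are suppressed there.
* Fe2Tf import uses the same per-organ rate constant as Fe1Tf import
  (one `kIn` per organ is published), and no statistical factor of 2 is
  applied to second-site binding: constants are used exactly as fitted.
* Derived quantities on a fit object (total iron, saturation, transition
  time) are recomputed from the returned parameters, never cached from
  the search.
* Problem sizes in the shipped tests: recovery fits use λ = 100 over
  100 generations on 96 synthetic observations; refit stages use λ = 30
  over 25 generations in 1–2 dimensions. Published-scale budgets are
  the documented defaults of `fit_tracer()`.

## Limitations

Each organ is one well-mixed pool: no ferritin, heme or labile iron
subpools, no transferrin-receptor saturation, no IRE/IRP intracellular
regulation, and hepcidin does not respond to iron status (its synthesis
rate is an input, not a controlled variable). The rest-of-body pool
aggregates ten anatomically distinct organs. These simplifications are
inherited deliberately: the package's purpose is to make the
hepcidin-only regulation hypothesis — and its quantitative failure under
iron loading — reproducible and testable.
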