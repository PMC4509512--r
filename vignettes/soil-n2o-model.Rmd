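---
title: "Modelling soil nitrification, denitrification and nitrogenous gas emission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling soil nitrification, denitrification and nitrogenous gas emission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilngas)
```

## The problem

Nitrous oxide from agricultural soils is produced by two microbial
pathways that run in different micro-environments of the same soil
layer: autotrophic nitrification (NH~4~^+^ → NO~3~^-^, with minor NO and
N~2~O byproducts) in aerobic microsites, and heterotrophic
denitrification (NO~3~^-^ → NO~2~^-^ → NO → N~2~O → N~2~) in anaerobic
microsites. `soilngas` simulates both at a daily time step over a
layered soil profile, tracks every nitrogen pool with an exact
mass-balance ledger, and partitions the gaseous intermediates between
emission and retention. Simpler first-order schemes can estimate total
denitrification but cannot speciate the emitted gas mix; the package
keeps such a scheme as its `legacy` mode precisely to expose that
contrast.

Heterotrophic nitrification, nitrifier denitrification and
chemo-denitrification are deliberately out of scope: they matter in
special settings but are minor pathways in fertilised agricultural
soils, and no parameters are carried for them.

## The model

### Aeration partitioning

The anaerobic fraction $f_r$ of each layer is a linear ramp in
water-filled pore space (WFPS $= \theta / (1 - \rho_d/\rho_s)$) between
two thresholds (defaults 0.6 and 0.9). Every substrate pool is split
as $(1-f_r)$ to the aerobic fraction (feeding nitrification) and $f_r$
to the anaerobic fraction (feeding the reduction chain). Because the
microsite volume splits along with the substrate mass, concentrations
entering the rate laws are whole-layer concentrations (pool mass /
layer thickness); the partitioned *masses* act only as availability
caps.

### Nitrifiers

Nitrifier biomass $M_b$ (gC m^-2^) evolves by
$$n_g = \gamma_{gn} f(T)\, f(W)\, f_n(pH)\, f_n(DOC)\, f(NO_3)\, M_b,
\qquad n_d = d_{dn} f(T) f(W) f_n(pH) f_n(DOC) M_b,
\qquad r_r = (1/\varepsilon_n - 1) M_b,$$
with $M_b' = M_b + n_g - n_d - r_r$ floored at zero. Two oddities of
this formulation are kept as published: growth is keyed to the
*nitrate* response (a config switch `nitrifier_growth_substrate = nh4`
offers the substrate reading), and maintenance respiration carries no
environmental modifier. The nitrification flux is
$n_n = n_{nmax} f(T) f(W) f_n(pH) f(NH_4) M_b$, capped at the aerobic
NH~4~^+^ available that day. Fractions $\phi_{NO}$ and $\phi_{N_2O}$
of $n_n$ may be routed to NO and N~2~O; both default to 0 because no
calibrated values exist, so nitrification-sourced N~2~O must be opted
into — this is stated prominently because it changes what a control
treatment can emit.

### Denitrifiers

A single denitrifier biomass $B_d$ hosts four reducer guilds
(NO~3~^-^, NO~2~^-^, NO, N~2~O), each with its own maximum growth rate,
yield $Y_{N_i}$, maintenance coefficient $M_{N_i}$ and pH curve. Guild
growth follows competitive Michaelis–Menten kinetics,
$$d_{g,i} = \gamma_{gd,i}\, f_d(DOC)\, f_{d,i}(N_i)\, f_{d,i}(pH)\, f(T)\, B_d,$$
and oxide consumption is growth-linked demand plus maintenance weighted
by the oxide's share of all N oxides (the electron-acceptor
competition):
$$d_{c,i} = d_{g,i}/Y_{N_i} + M_{N_i}\,(N_i/N_{total})\, f(T)\, f_{d,i}(pH)\, B_d.$$
The parenthesisation of the second term is ambiguous in its source;
the package resolves it with $B_d$ multiplying only the maintenance
term, since $d_{g,i}$ already contains $B_d$ — the dimensionally
consistent reading. Biomass bookkeeping uses
$d_{dd} = M_c Y_c B_d$ and $r_c = d_{dg}/Y_c + M_c B_d$; respiration is
a carbon flux, not a biomass sink, so $B_d' = B_d + d_{dg} - d_{dd}$.

The four-guild chain is itself a resolved ambiguity: the source
equation enumerates three steps while its parameter table prints four
growth rates, four yields and four maintenance coefficients, and the
process diagram shows a four-step chain — four guilds are implemented
because parameters exist for four steps. Half-saturation constants for
the oxides are not published; the nitrate constant (16.65 gN m^-3^) is
reused for all four, configurably.

### Daily sequencing and its consequences

Each day runs one explicit pass, per layer: environment update →
management events → nitrification → reduction chain → gas emission →
biomass update → housekeeping (prescribed uptake, slurry-N
mineralisation, DOC relaxation). Within the chain, all rates are
computed from beginning-of-day concentrations; the product of step $i$
feeds pool $i+1$ the same day, and each step's consumption is capped at
its initial pool plus same-day inflow. When a cap binds, the guild's
growth is scaled by the same ratio (growth-linked consumption cannot
exceed the oxide actually reduced).

Two consequences are worth knowing. First, the scheme is explicit
Euler with availability caps instead of sub-stepping; caps are logged
(`ngas_log_entries()`) so stiffness is visible rather than silent.
Second, because demand is computed from beginning-of-day
concentrations, a guild whose oxide pool was empty at dawn consumes
nothing that day even if upstream production fills it: an isolated
single wet day therefore reduces NO~3~^-^ through NO~2~^-^ to NO but
produces almost no N~2~O, and sustained N~2~O emission requires
multi-day anaerobic spells. That is a property of the daily explicit
scheme, not a bug, and it disappears under persistent wetness.

### Response functions

* **Temperature**: $Q_{10}^{(T - T_{ref})/10}$ per process. $Q_{10}$
  values and reference temperatures are not published; defaults are
  2.0 and 20 °C, configurable per process.
* **Moisture (nitrification)**: inside WFPS 0.3–0.75 the factor is
  $\min(1, -11.25\,W^2 + 11.75\,W - 1.9)$, outside it the constant 0.6.
  The two discontinuities at the window edges (0.6125 vs 0.6 at 0.3;
  0.584375 vs 0.6 at 0.75) are properties of the adopted form and are
  asserted exactly in the tests. No separate moisture function exists
  for denitrification: moisture acts on it only through $f_r$, as
  printed; this is flagged because users sometimes expect otherwise.
* **Substrate**: Michaelis–Menten, $S/(k_m + S)$, with $k_m$ 9.45
  gC m^-3^ (DOC), 16.65 and 18.53 gN m^-3^ (nitrate, ammonium).
* **pH**: the exact published curve coefficients exist only as
  figures, so the package ships parametric defaults honouring the
  documented qualitative constraints — the nitrifier curve is a
  logistic that is ≤ 0.05 at pH 4 (nitrification is only detectable
  above pH 4) and ≥ 0.95 across the 6.6–7.5 optimum; the guild curves
  are piecewise-linear with editable knot tables, the N~2~O-reducer
  curve most acid-suppressed (the best-established qualitative pH
  effect), the NO-reducer curve weakly peaked because published reports
  disagree on direction. Digitised curves can replace any default via
  `load_ph_knots()`.

### Gas transport

The escape fraction of dissolved NO and N~2~O is a transparent linear
air-filled-porosity model, $\mathrm{clamp}(c_{gas}(1-W), 0, 1)$, with
N~2~ always escaping fully; retained gas stays in the layer's dissolved
pool where the next day's chain can reduce it further. Gas escapes only
from the layer where it was produced — inter-layer gas diffusion is out
of scope, and the interface is shaped so a full
adsorption/diffusion scheme can replace the linear model without
touching callers. Nitrification-derived NO/N~2~O enters the same
dissolved pools as chain products.

## Mass balance

A ledger tracks fertiliser and deposition inputs against emitted NO,
N~2~O, N~2~, prescribed uptake and (in legacy mode) bulk denitrified N.
Closure is asserted after **every** simulated day at 1×10^-9^ relative;
a violation is a hard failure with a diagnostic dump, because a
process model that leaks nitrogen silently is worse than one that
stops. Microbial biomass is carbon-denominated, so growth and death do
not touch the N ledger; dead biomass goes to a tracked carbon sink
(with an optional recycle fraction to DOC, default 0) since the full
carbon cycle is out of scope. Plant uptake and DOC replenishment are
prescribed forcings for the same reason: uptake defaults to 0 and DOC
relaxes first-order towards a configurable target concentration
(defaults: 15 gC m^-3^, rate 0.1 d^-1^ — a soil where microbial
consumption does not permanently exhaust the labile C supply).

## Evaluation statistics and calibration

`evaluate_fit()` computes the seven-statistic suite (R, RMSE as % of
the observed mean, modelling efficiency EF, coefficient of
determination CD, relative error RE, mean deviation MD with its paired
t, maximum error ME). RE excludes zero observations — the term is
undefined there, and zeros are frequent in flux series — and reports
how many were excluded. The 95 %-confidence companions RMSE~95~ and
RE~95~ are computed from user-supplied per-observation CI half-widths
as $(100/\bar{O})\sqrt{\overline{ci^2}}$ and $(100/n')\sum ci_i/O_i$;
the replicate structure behind published confidence statistics is not
described anywhere, so this is an interpretation and is labelled as
such.

`calibrate()` minimises the RMSE between observed and simulated daily
N~2~O flux by repeated model runs, using a compact seeded rand/1/bin
differential-evolution optimizer (pluggable: any function with the
`de_optimize` signature can replace it). A zero-generation budget
returns the initial set unchanged. The package's parameter-recovery
test regenerates observations from a known nitrate-reducer growth rate
(13.65 d^-1^) and recovers it within 10 % from bounds [1, 30] — in
practice the recovery is essentially exact — using a 60-day,
single-layer experiment with ten-daily fertiliser pulses at WFPS 0.75,
sized so the whole calibration runs in well under a minute.

## The synthetic forcing generator

Because no weather record or field observations ship with the package,
all study conditions come from `bush_fixture()` and
`generate_forcing()`: a cut grassland on an imperfectly drained clay
loam with acid topsoil (pH 4.6), twelve layers (eight of 0.025 m, then
0.15, 0.45, 0.35 and 0.2 m), tabulated initial C/N pools to 0.35 m, and
three treatments — an unfertilised control, ammonium nitrate (11
applications, 1998–2003, 12 or 10 gN m^-2^ each, half ammoniacal) and
cattle slurry (9 applications, with the organic fraction entering a
slow-release pool mineralising at 0.02 d^-1^). All rates pass through
the tested kg ha^-1^ → g m^-2^ conversion. The forcing emulates the
site's climate normals: temperature sinusoid between 3.8 °C (January)
and 13.3 °C (July) with 1.5 °C daily noise, damped into depth with a
1 m e-folding; rainfall as Bernoulli(0.5) × Exponential(4.65 mm),
matching an 849 mm annual total; soil moisture from a single bucket
(fill over a 300 mm root zone, drainage 0.05 d^-1^ towards a 0.12
residual, saturation 0.47). The slow drainage constant reflects the
imperfect natural drainage of a gleysol: mean WFPS ≈ 0.65 with
saturated spells, the regime in which denitrification actually runs.

What the generator does **not** emulate: real weather autocorrelation
beyond the bucket's memory, evapotranspiration seasonality, vertical
water redistribution (every layer shares the bucket water content),
snow, or the actual 1998–2004 Scottish record. Passing tests therefore
demonstrate internal correctness — kinetics, conservation, qualitative
response structure — not agreement with field measurements, which
would require the unpublished observation series.

## Numerical choices and degenerate inputs

* Pools are areal masses (g m^-2^ per layer); kinetics divide by layer
  thickness for concentrations (g m^-3^). A source-unit prefix
  inconsistency (kg vs g per m^3^) is resolved gram-scale throughout,
  consistent with the gram-scale Michaelis constants and yields.
* Measured $\theta$ above the porosity estimate is clipped to WFPS 1
  and logged, not rejected — field data routinely exceed porosity
  estimates.
* pH outside [3, 9] clamps to the endpoint value (curves are only
  constrained inside); unknown curve ids, guilds or gases are errors.
* Biomass floors at zero with the deficit logged; oxide pools are
  protected by the availability caps, and a negative pool after a chain
  update is an internal invariant failure, not a warning.
* Parameter files serialise numerics at full double precision, so
  save/load round-trips are bit-identical (asserted in tests).
* Zero observed variance makes R undefined (returned `NA`, flagged);
  zero `n_total` short-circuits consumption to zero.

## Known limitations

* No inter-layer transport of water, heat, solutes or gas: layer
  states are driven entirely by forcing. Leaching losses are absent,
  so fertiliser N not emitted or taken up accumulates in the profile.
* Nitrifier growth consumes no N and denitrifier growth consumes no
  tracked C (growth is C-denominated against an implicit DOC supply);
  the ledger is therefore an N ledger with a C side-channel, not a
  coupled C–N budget.
* The legacy mode shares the microbial mode's response functions,
  which is a modelling choice — its originals are not printed.
* Published validation statistics for the original field experiment
  cannot be reproduced here: the observation series was never
  published. The evaluation suite is validated against brute-force
  recomputation instead.

## Problem sizes used by the test suite

The shipped tests run a 3-year, 12-layer fertilised simulation for the
conservation criterion (about 3 s), 90-day two-layer runs for the
dose-response and wetness properties, and the 60-day single-layer
calibration experiment (about 15 s); these sizes were chosen as the
smallest that exercise multi-year management schedules, biomass
dynamics and identifiable calibration, and the whole suite completes in
under a minute.
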