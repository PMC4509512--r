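# soilngas

Daily simulation of soil nitrification, denitrification and nitrogenous
gas (NO, N₂O, N₂) emissions from a layered soil profile, for soil
biogeochemists and greenhouse-gas modellers who need a standalone,
mass-conserving implementation of the microbial-growth approach —
together with the seven-statistic model-evaluation suite and a
calibration harness.

## The model in brief

Each soil layer is split by its water-filled pore space
(WFPS = θ / (1 − ρ_d/ρ_s)) into an aerobic fraction hosting autotrophic
nitrification and an anaerobic fraction *f_r* hosting the four-step
denitrification chain NO₃⁻ → NO₂⁻ → NO → N₂O → N₂.

Nitrifier biomass *M_b* grows, dies and respires explicitly:

    n_g = γ_gn f(T) f(W) f_n(pH) f_n(DOC) f(NO₃) M_b
    n_d = d_dn f(T) f(W) f_n(pH) f_n(DOC) M_b
    r_r = (1/ε_n − 1) M_b,          M_b' = M_b + n_g − n_d − r_r

and nitrifies at `n_n = n_nmax f(T) f(W) f_n(pH) f(NH₄) M_b`, capped by
the aerobic NH₄⁺ pool. Four denitrifier guilds share one biomass *B_d*
and compete for electron acceptors by competitive Michaelis–Menten
kinetics:

    d_g,i = γ_gd,i f_d(DOC) f_d,i(N_i) f_d,i(pH) f(T) B_d
    d_c,i = d_g,i / Y_Ni + M_Ni (N_i / N_total) f(T) f_d,i(pH) B_d

with biomass bookkeeping `d_dd = M_c Y_c B_d`,
`r_c = d_dg/Y_c + M_c B_d`. Substrate responses are Michaelis–Menten
(k_m = 9.45 gC m⁻³ for DOC, 16.65 and 18.53 gN m⁻³ for nitrate and
ammonium), temperature is Q₁₀, the nitrification moisture response is a
capped quadratic in WFPS, and pH acts through an editable curve family.
Dissolved NO and N₂O split daily between emission (a linear
air-filled-porosity escape model) and retention for further reduction;
N₂ always escapes. An N mass-balance ledger is checked to 1e-9 relative
after every simulated day. A `legacy` mode reproduces the older
first-order formulation that cannot speciate the gas mix.

All parameters ship with calibrated defaults (`default_parameters()`)
and are addressable by dotted names
(e.g. `denitrifier.guilds.no3.gamma_gd` = 13.65 d⁻¹).

See `vignettes/soil-n2o-model.Rmd` for the full account of the science,
the numerical scheme and the design choices.

## Worked example

Simulate one year of an ammonium-nitrate-fertilised temperate grassland
from the bundled fixture, against its unfertilised control:

```r
library(soilngas)

fx      <- bush_fixture()
spec    <- fx$forcing_spec
spec$years      <- 1
spec$seed       <- 42L
spec$start_date <- as.Date("1999-01-01")

forcing <- generate_forcing(spec, fx$thicknesses)
profile <- init_profile(fx$thicknesses, fx$soil_props, fx$init_pools)

an   <- fx$management$an[fx$management$an$date %in% forcing$dates, ]
ctrl <- fx$management$control[fx$management$control$date %in% forcing$dates, ]

run_an   <- run_simulation(profile, forcing, an)
run_ctrl <- run_simulation(profile, forcing, ctrl)
print(run_an)
#> <ngas_run> 365 days
#>   cumulative emissions (gN m^-2): NO 2.65, N2O 3.309, N2 11.48
#>   nitrified N: 0.0002799 gN m^-2; fertiliser N applied: 24 gN m^-2

emission_factor(run_an$summary$cum_n2o, run_ctrl$summary$cum_n2o,
                run_an$ledger$fertiliser)
#> [1] 8.522226
```

Reading the numbers: the two spring/summer applications (12 gN m⁻²
each, half ammoniacal) drive 3.3 gN m⁻² of N₂O-N over the year against
1.3 gN m⁻² from the control, an emission factor of 8.5 % of applied N —
far above the 1 % IPCC default, as expected for a wet, imperfectly
drained grassland where most reduced N leaves as N₂ and N₂O.
Nitrified N is tiny because the acid topsoil (pH 4.6) nearly shuts the
nitrifier pH response. `run_an$fluxes` holds the daily per-gas series;
`ledger_residual(run_an$ledger, run_an$profile)` is ~1e-15 gN m⁻².

Calibration against observations (here, recovering a known truth):

```r
fit <- calibrate(profile, forcing, an, default_parameters(),
                 observed = run_an$fluxes$n2o_flux,
                 parameters = "denitrifier.guilds.no3.gamma_gd",
                 lower = 1, upper = 30, n_gen = 12, n_pop = 8, seed = 42)
fit$par
```

## Files and command line

Forcing, management schedules, soil profiles and initial pools are
plain CSV (`write_forcing()` / `read_forcing()`,
`write_management()` / `read_management()`; headers documented on those
functions). Run configurations and parameter files are a flat, ordered
`key: value` text dialect — unknown keys are an error, and numeric
round-trips are bit-identical (`write_params_file()` /
`load_params_file()`, `load_config()`). pH response curves can be
replaced from two-column knot tables (`load_ph_knots()`; example in
`inst/extdata/ph_knots_example.csv`).

A thin CLI wraps the same functions (`inst/cli/soilngas`; on an
installed package, `system.file("cli", "soilngas", package =
"soilngas")`):

```sh
soilngas gen-forcing --template bush --seed 1 --years 1 --out runs/
soilngas simulate    --config run.cfg --mode microbial --out runs/out
soilngas evaluate    --obs obs.csv --sim sim.csv
soilngas calibrate   --config run.cfg --obs obs.csv \
                     --params denitrifier.guilds.no3.gamma_gd --lower 1 --upper 30
```

Exit codes: 0 ok, 1 validation error, 2 runtime invariant failure.

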