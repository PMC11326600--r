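# sarcosim

Stochastic-mechanical simulation of a half-sarcomere with a three-state
actomyosin cross-bridge cycle whose kinetics depend *independently* on
[ATP] and on the [ADP][Pi] product.

Muscle models that tie cross-bridge kinetics to the single ratio
[ATP]/([ADP][Pi]) cannot distinguish ATP starvation from product
accumulation, yet rigor, ischemia and fatigue move these concentrations
independently. `sarcosim` implements a spatially explicit, two-filament
half-sarcomere in which ATP binding and ADP/Pi release happen at different
transitions of the cycle, so each rate constant carries only the metabolite
relevant to it. It is aimed at muscle biophysicists and modellers who want
force, duty-ratio and ATP-consumption predictions across metabolite
conditions, with a closed-form one-myosin steady state as a fast analytic
surrogate.

## The model

**Mechanics.** Nodes of the thin (actin) and thick (myosin) filaments,
plus Z-line and M-line, form a 1-D chain of Hookean springs (filament
segments, titin, an external substrate spring, and one spring per bound
cross-bridge whose rest length shortens by the power-stroke distance d_ps
in the post-stroke state). After every chemical transition the equilibrium
positions solve the linear force balance

    K p = v

by direct dense solve. Titin bears force only in extension.

**Kinetics.** Each myosin head cycles through detached (1, M.ADP.Pi),
attached pre-stroke (2, A.M.ADP.Pi) and attached post-stroke (3, A.M)
states. With strain s = x_m − x_a − b0 and β = 1/kBT:

    k12 = k_bind exp(−β k_xb s²/4)        k21 = k12/K12
    k23 = k23_cap                         k32 = k23/K23   (∝ [ADP][Pi])
    k31 = K31 k_ATP0                      k13 = k_ATP0    (k31 ∝ [ATP])

Detailed balance around the cycle leaves the strain-independent identity

    (k12 k23 k31)/(k21 k32 k13) = [ATP]/([ADP][Pi]) · exp(ΔG_hyd/kBT)

**Stochastics.** Fixed-step kinetic Monte Carlo (dt = 1e-5 s), at most one
transition per head per step with probability 1 − exp(−k dt), heads visited
in a fresh random permutation, mechanics re-solved each transition step.

**Analytics.** The one-myosin steady state has closed-form weights
P1, P2, P3; duty ratio P3/(P1+P2+P3); ATP rate (k31 P3 − k13 P1)/(P1+P2+P3),
with strain collapsed onto a single effective sliding distance (ESD).
`fit_esd()` inverts this surrogate against simulated duty-ratio grids.

## Worked example

```r
library(sarcosim)

params <- sarcomere_params()          # published constants, standard [ATP]=5 mM
lat    <- reference_lattice(params, "one-myosin")
trace  <- simulate_sarcomere(lat, params, sim_config(duration = 1, seed = 3))
glance(trace)
#> # A tibble: 1 × 9
#>   duty_ratio average_force peak_force_raw peak_force_smooth plateau_atp_rate
#>        <dbl>         <dbl>          <dbl>             <dbl>            <dbl>
#> 1    0.00287       0.00599           3.00             0.231             21.1
#> # ℹ 4 more variables: net_atp_rate <dbl>, esd <dbl>, n_hydrolysis <int>, ...
```

The single head spends ~0.3% of its time post-stroke (state 3), each stroke
holds ~3 pN against the substrate spring (`peak_force_raw`), and hydrolysis
proceeds at ~21 ATP/s after the initial transient. The realized sliding
distance per stroke (`esd`, here 6.0 nm) falls 1 nm short of the unloaded
power-stroke distance because the cross-bridge keeps ~1 nm of extension
against the series compliance.

Compare with the analytic surrogate and fit the ESD to a simulated grid:

```r
steady_state(params, esd = 6)         # closed-form duty ratio ~0.0036

sw <- run_sweep(params,
                atp_values   = 10^seq(-7, -1, length.out = 5),
                adppi_values = 10^seq(-12, -4, length.out = 5),
                geometry = "one-myosin", replicates = 10,
                config = sim_config(duration = 1), master_seed = 1)
fit_esd(sw$points, params)
#> <esd_fit> ESD = 6.448 nm (mean squared log-duty error 0.05835 over 25 cells)

autoplot(trace)                       # force trace with 12 ms smoothing
plot_concentration_grid(sw$points)    # duty-ratio phase diagram
```

A command-line front end for the same operations (simulate, sweep,
analytic-grid, compare) ships in `inst/cli/sarcosim.R`.

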