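# microrelease

Compartmental modelling of water uptake and protein release from
calcium-alginate hydrogel microparticles, built for controlled-release and
biomaterials work where a freeze-dried, protein-loaded particle is dropped
into a release medium and two things happen at once: the particle swells, and
the payload diffuses out. The package models, fits and cross-validates both
processes, for lactoferrin-loaded alginate microgels and any chemically
similar carrier that can be described by the same lumped-compartment picture.

## The model

**Swelling.** The adsorbed-liquid volume inside a particle relaxes
first-order toward its maximum swelling volume:

```
dV_ads/dt = k_v (V_max − V_ads),   V_ads(0) = V_ads0
⇒ V_ads(t) = V_max − (V_max − V_ads0) e^(−k_v t)
```

with `k_v` (1/min) the swelling constant and `V_max = V_h · W_s` the
hydration capacity times the dry charge.

**Release.** Protein moves through three compartments — solid matrix,
adsorbed liquid inside the particle, external bulk — across two films in
series:

```
J_sl = β_sl (C_s / H − C_ads)        solid → adsorbed liquid
J_ll = β_ll (C_ads − C_b)            adsorbed liquid → bulk

dV_ads/dt = +k_v (V_max − V_ads)     dn_s/dt   = −J_sl · V_ads
dV_b/dt   = −k_v (V_max − V_ads)     dn_ads/dt = +(J_sl − J_ll) · V_ads
                                     dn_b/dt   = +J_ll · V_ads
```

`H` is the solid/liquid partition constant (`C_s = H · C_ads` at
equilibrium), and `β_sl`, `β_ll` (1/min) the two film mass-transfer
coefficients. The default mole balance conserves protein exactly; an
`as_printed` variant with the adsorbed-phase balance written as
`dn_ads/dt = (J_ll − J_sl) V_ads` is retained behind a flag to document that
that sign convention loses moles whenever the two fluxes differ. An optional
dissolution event at `t_dissolve` sends all protein still in the particle to
the bulk and freezes the system.

Without dissolution the system has a closed-form endpoint
(`equilibrium_state()`): one common liquid concentration
`c = N / (H V_s + V_max + V_b∞)`, which the integrator is checked against.

## Worked example

```r
library(microrelease)

# fit the swelling constant to the packaged weight-vs-time series
fit <- fit_kv(example_swelling_weights())
tidy(fit)
#> # A tibble: 1 × 5
#>   term  estimate lower upper at_bound
#>   <chr>    <dbl> <dbl> <dbl> <lgl>
#> 1 k_v    0.00295    NA    NA FALSE

# simulate the 40 cm^3 stirred release run and check its endpoint
b1 <- example_batches()$batch1
traj <- simulate_release(b1, times = c(0, 1, 5, 30, 20000))
round(traj$release_fraction, 4)
#> [1] 0.0000 0.6364 0.9936 0.9998 0.9976
equilibrium_state(b1)$bulk_fraction
#> [1] 0.9976125

# batch summary of encapsulation efficiencies
summarize_batches(example_encapsulation()$EE_pct)
#> # A tibble: 1 × 5
#>       n  mean    sd mean_display sd_display
#>   <int> <dbl> <dbl>        <dbl>      <dbl>
#> 1     5  65.8  8.29         65.8        8.3
```

The fitted `k_v ≈ 0.00295 1/min` says the particle covers ~95% of its
swelling in about 17 h. The release fraction climbs to ~0.99 within minutes
(the liquid–liquid film, `β_ll ≈ 1 /min`, is fast), overshoots slightly, and
settles at the partition equilibrium 0.9976 — swelling keeps pulling a little
liquid (and protein) back into the particle for hours. The batch summary
reports the mean and sample SD of the five packaged encapsulation
efficiencies.

A thin command-line binding ships at `inst/scripts/microrelease`
(subcommands `simulate-release`, `fit-swelling`, `fit-release`, `validate`,
`generate`, `metrics`); every run writes a `run_manifest.json` next to its
outputs.

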