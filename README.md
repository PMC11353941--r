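# vdwsolv

Solvation thermodynamics from the van der Waals model of liquids.

## What it computes, and for whom

Why is dissolving a small nonpolar molecule in water so unfavourable,
and why does the unfavourability show up as entropy at room temperature
rather than enthalpy? `vdwsolv` is for physical chemists and students of
the hydrophobic effect who want the *analytic* answer that the van der
Waals picture of a liquid provides — every quantity in closed form, every
term with a transparent physical meaning — rather than a simulation.

The package computes the **Ben-Naim solvation Gibbs free energy**
ΔG• — the coupling work of transferring a solute from a fixed position
in the ideal gas to a fixed position in the liquid — for a hard-sphere
solute with optional attractions, at infinite dilution in a van der
Waals fluid:

    ΔG• = −RT·ln(1 − ξ₁) + RT·ρ₁b₂/(1 − ξ₁) − 2√(a₁a₂)/v₁
          └──────────── ΔG_c ─────────────┘   └── ΔG_a ──┘

where ρ₁ = N_Av/v₁ is the solvent number density, ξ₁ = ρ₁b₁ its packing
fraction, and b = (πσ³/6)/0.64 converts a hard-sphere diameter σ into a
repulsive volume via the random-close-packing occupancy 0.64. Each
sub-process (cavity creation, attraction switching) is further split
into enthalpy and entropy, and the cavity entropy into an
excluded-volume part ΔS_x = −ΔG_c/T (always negative) and a structural
reorganization part ΔS_nx = ΔH_c/T (proportional to the expansivity
α_P and exactly enthalpy-compensated, so it never moves ΔG).

Alongside the infinite-dilution calculators there is a
finite-composition binary-mixture model (partition-function Helmholtz
energy, analytic chemical potentials, finite-difference oracles), a
built-in property table for eight common liquids at 25 °C, liberation
(molar-volume transfer) free energies, temperature scans, CSV I/O,
broom-style `tidy()`/`glance()` methods and `autoplot()` figures, and a
command-line front end (`inst/cli/vdwsolv.R`).

## Worked example

Cavity-creation thermodynamics of a xenon-sized (σ = 4 Å) solute in the
eight built-in liquids at 298.15 K:

```r
library(vdwsolv)
cavity_thermo(builtin_solvents())
#> # A tibble: 8 × 8
#>   name         T   xi1  dG_c  dH_c    dS_c  dS_x dS_nx
#>   <chr>    <dbl> <dbl> <dbl> <dbl>   <dbl> <dbl> <dbl>
#> 1 water     298. 0.599 13.0   2.34 -35.9   -43.7  7.85
#> 2 methanol  298. 0.680  8.81  8.49  -1.07  -29.6 28.5
#> 3 ethanol   298. 0.735  8.32  8.39   0.233 -27.9 28.1
#> 4 CCl4      298. 0.786  7.58  9.74   7.25  -25.4 32.7
#> 5 n-hexane  298. 0.777  6.37  8.50   7.14  -21.4 28.5
#> 6 n-decane  298. 0.892  9.23 16.7   25.1   -31.0 56.1
#> 7 c-hexane  298. 0.808  7.85 10.9   10.2   -26.3 36.5
#> 8 benzene   298. 0.802  8.43 12.0   11.8   -28.3 40.1
```

Reading the water row: opening the cavity costs ΔG_c = 13.0 kJ/mol —
the largest of the eight liquids, because water's tiny molecules give
it the highest number density — yet almost none of that cost is
enthalpic (ΔH_c = 2.3 kJ/mol, the smallest of the eight, because
water's low α_P means little structural response). The cost is carried
by entropy: ΔS_c = −35.9 J/K/mol, the sum of a large excluded-volume
loss (ΔS_x = −43.7) and a small reorganization gain (ΔS_nx = +7.9).
In the organic liquids the reorganization gain overwhelms the
excluded-volume loss and ΔS_c turns positive — the classic signature
separating water from ordinary solvents.

Adding attractions and summarising with broom verbs:

```r
solv <- builtin_solvents()[c(1, 5), ]
solv$a_attr <- c(900, 2400)              # kJ cm^3 mol^-2
res <- solvate(solv, a_solute = 1500)
dplyr::select(res, name, dG_star, dG_c, dG_a, dS_c, dS_a)
#> # A tibble: 2 × 6
#>   name     dG_star  dG_c   dG_a   dS_c  dS_a
#>   <chr>      <dbl> <dbl>  <dbl>  <dbl> <dbl>
#> 1 water     -116.  13.0  -129.  -35.9  -33.1
#> 2 n-hexane   -22.5  6.37  -28.8   7.14 -40.1
glance(res)
#> # A tibble: 1 × 6
#>   n_solvents     T b_solute n_with_attraction dG_star_min dG_star_max
#> 1          2  298.     52.4                 2       -116.       -22.5
```

`tidy(res)` returns the same result in long form (one row per solvent
per term); `autoplot(res)` and `plot_entropy_decomposition(res)` draw
the free-energy and entropy decompositions, and
`temperature_scan()` + `autoplot()` show the compensation structure
across temperature.

The liberation term the Ben-Naim convention removes:

```r
liberation_free_energy(ideal_gas_molar_volume(298.15, 1), 18.07)
#> 17.88   # kJ/mol, ideal gas (1 atm) -> water
liberation_free_energy(131.62, 18.07)
#> 4.92    # kJ/mol, n-hexane -> water
```

## Command line

```sh
Rscript inst/cli/vdwsolv.R compare --mode printed
Rscript inst/cli/vdwsolv.R cavity --solvent water --format json
Rscript inst/cli/vdwsolv.R scan --solvent n-decane --Tmin 278 --Tmax 368
```

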