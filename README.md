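# voidpart

Monte Carlo partitioning of crystal unit-cell volume into occupied
**network** and unoccupied **void** space, with an equation-of-state layer
that turns variable-pressure series of those components into network, void
and overall bulk moduli, detects volume discontinuities at phase
transitions, and flags premonitory deviations before them.

The package is aimed at high-pressure crystallographers and anyone
analyzing how molecular crystals respond to compression (or, with the same
machinery, temperature or guest uptake). The central idea: the unit-cell
volume *V* of a molecular crystal splits into the network volume
*V*<sub>net</sub> — all points within the van der Waals radius of at least
one atom — and the interstitial void volume
*V*<sub>void</sub> = *V* − *V*<sub>net</sub>. Throwing *n* uniform random
points into the cell and counting the *n*<sub>net</sub> that land inside
the sphere union gives

> *V*<sub>net</sub> = (*n*<sub>net</sub>/*n*) · *V*,  *V*<sub>void</sub> = *V* − *V*<sub>net</sub>

with precision improving as √*n*. Voids are far softer than the contact
network, and the two component bulk moduli combine into the overall bulk
modulus through the packing coefficient *x* = *V*<sub>net</sub>/*V* by
reciprocal mixing:

> 1/*K* = *x*/*K*<sub>net</sub> + (1 − *x*)/*K*<sub>void</sub>

Because *K*<sub>void</sub> (typically 2–5 GPa) is an order of magnitude
below *K*<sub>net</sub> (typically 40–150 GPa), the void term dominates —
which is why molecular solids cluster into a narrow 5–20 GPa band of
overall bulk moduli.

## What's inside

* **Structure preparation** — `read_cif()`, `expand_to_cell()`,
  `normalize_xh()` (neutron X–H normalization), `assign_radii()` (Alvarez
  van der Waals radii, editable CSV), `padded_atom_list()` (periodic
  images that can reach the cell, correct for triclinic cells).
* **Monte Carlo engine** — `run_volume()` with iterative precision control
  (population σ(V_net)/V_net target, default 0.1%, 3–10 runs of 10⁶
  points), `propagate_uncertainty()` (coordinate-su perturbation over 100
  models), `fragment_volume()`, `packing_coefficient()`,
  `export_occupancy_map()` (Gaussian cube).
* **Equation of state** — Birch–Murnaghan (2nd/3rd order) and Vinet
  families: `eos_pressure()`, `eos_volume()`, `fit_eos()` (weighted NLS in
  pressure, broom-style `tidy()`/`glance()`/`augment()`),
  `numeric_bulk_modulus()` (model-free K = −V dP/dV),
  `compose_bulk_modulus()` and `propagate_partition_error()`.
* **Series analysis** — `pressure_series()`, `scale_to_Z()`,
  `piecewise_fit()` (break scan with information-criterion guard),
  `premonitory_scan()`; `autoplot()` methods for series, fits and break
  reports.
* **Synthetic fixtures** — `make_structure()` (sphere packings with
  closed-form volumes), `make_series()` (EoS-generated pressure series,
  optional two-phase joins), `perturb_models()`; fixtures round-trip
  through genuine CIF files.
* **CLI** — a thin `voidpart` script (`exec/voidpart`) with subcommands
  `volume`, `eos`, `compose`, `series`, `synth`.

## Worked example

```r
library(voidpart)

# four touching spheres on an fcc lattice: packing fraction pi/sqrt(18)
s <- make_structure("fcc_touching", r = 1.5)
res <- run_volume(s, sampler_config(seed = 7))
res
#> <volume_result> V=76.368  V_net=56.536(0.032)  V_void=19.832 A^3  x=0.7403  [3 x 1e+06 pts, converged]
```

The sampler reached σ(V_net)/V_net < 0.1% in the minimum three runs of a
million points; the estimate 56.536(32) Å³ brackets the closed-form union
volume 56.549 Å³, and the packing coefficient 0.7403 matches π/√18 =
0.74048 within one standard deviation.

```r
# a synthetic compression series whose network stiffness drops at 4.5 GPa
ser <- make_series("two_phase_series", pressures = seq(0, 7, length.out = 21),
  net  = list(family = "bm2", v0 = 120, k0 = 121),
  net2 = list(family = "bm2", k0 = 83),
  void = list(family = "vinet", v0 = 40, k0 = 2.9, kprime = 7),
  break_p = 4.5, step_net = 0.78, noise_sd = 0.05, seed = 1)
piecewise_fit(ser, "net", "bm2")
#> <break_report net/BM2> break at 4.375 GPa; K0 123.04 -> 82.92 GPa; delta V = 0.741 A^3
```

The scan recovers the constructed transition: break within one grid step
of 4.5 GPa, segment moduli 123(2) → 83(1) GPa against the generating
121 → 83 GPa, and the 0.78 Å³ volume step within the fit uncertainty.

```r
# compose an overall bulk modulus from typical component values
propagate_partition_error(100, 5, 3.2, 0.4, 0.75)
#> # A tibble: 1 × 6
#>   k_overall sigma_k rel_err_k rel_err_net rel_err_void method
#>       <dbl>   <dbl>     <dbl>       <dbl>        <dbl> <chr>
#> 1      11.7    1.33     0.114        0.05        0.125 analytic
```

A stiff network of 100(5) GPa and a soft void of 3.2(4) GPa at packing
coefficient 0.75 compose to 11.7(13) GPa overall; the 11% relative error
is dominated by the 12.5% void-modulus error, illustrating why void
stiffness controls the result.

See `vignettes/void-partitioning.Rmd` for the full account of the model,
parameter choices and design decisions.

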