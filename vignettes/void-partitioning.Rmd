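---
title: "Partitioning crystal volume into network and void: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning crystal volume into network and void: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(voidpart)
```

## The model

A molecular crystal's unit-cell volume $V$ splits into the *network*
volume $V_{\mathrm{net}}$ — every point lying within the van der Waals
radius of at least one atom, i.e. the molecules together with their
contact network — and the complementary interstitial *void* volume
$V_{\mathrm{void}} = V - V_{\mathrm{net}}$. The partition is estimated by
Monte Carlo integration: $n$ points are drawn uniformly in fractional
coordinates, each point is tested against the van der Waals spheres of
the cell contents and of every periodic image whose sphere can reach the
cell, and

$$V_{\mathrm{net}} = \frac{n_{\mathrm{net}}}{n}\,V, \qquad
  V_{\mathrm{void}} = V - V_{\mathrm{net}}.$$

Because the void volume is defined by subtraction, conservation
$V_{\mathrm{net}} + V_{\mathrm{void}} = V$ holds exactly for every
result, and the estimator's relative precision improves as $\sqrt{n}$.

The occupied fraction is the packing coefficient
$x = V_{\mathrm{net}}/V$, typically 0.6–0.8 for molecular crystals at
ambient pressure.

Applying the bulk-modulus definition $K = -V(\partial P/\partial V)_T$
separately to the component volumes and using
$V = V_{\mathrm{net}} + V_{\mathrm{void}}$ gives the reciprocal-mixing
relation

$$\frac{1}{K} = \frac{x}{K_{\mathrm{net}}} + \frac{1-x}{K_{\mathrm{void}}},$$

implemented by `compose_bulk_modulus()`. The component moduli have no
independent thermodynamic status — they are defined by the van der Waals
partition — but because $K_{\mathrm{void}} \ll K_{\mathrm{net}}$ the
overall modulus is dominated by the void term, which is why the narrow
range of void moduli (a few GPa) pins molecular solids into a narrow
overall range even when network moduli vary by a factor of four.

## Structure preparation

`read_cif()` parses a core-dictionary CIF (cell, symmetry operators,
atom sites with parenthesis-notation standard uncertainties, occupancy,
disorder flags, $Z$, ambient pressure). Sites with partial occupancy or
a disorder assembly are rejected in `strict` mode, mirroring the
curation applied to survey data; permissive mode keeps the
ordered/major component with a warning. `expand_to_cell()` applies the
operators, wraps every image into $[0,1)$ and removes duplicates closer
than 0.05 Å — below any physical bond length, above coordinate
rounding.

`normalize_xh()` corrects the systematic foreshortening of X-ray
hydrogen positions by moving each H along its existing X→H direction to
a neutron-derived target distance. The shipped targets (C–H 1.089 Å,
N–H 1.015 Å, O–H 0.993 Å, B–H 1.185 Å) are the conventional
normalization values used by crystallographic database software; bonds
are detected as separations below 1.2 × the covalent-radius sum
(Cordero radii). Both tables are editable CSVs under `inst/extdata`.
Since no consensus criterion exists for detecting X-ray provenance from
a CIF alone, normalization is applied when the caller asks for it (the
CLI flag `--no-normalize` disables it).

Van der Waals radii are the Alvarez compilation, also shipped as an
editable CSV. A missing element is a hard error rather than a silent
default, since a wrong radius biases every volume downstream.

`padded_atom_list()` adds the periodic images whose spheres can reach
the cell. The textbook fractional criterion
($|x| < R_{\max}/a$, etc.) is exact only for orthogonal cells; this
implementation measures the slab against the perpendicular cell heights
computed from the reciprocal axes, a superset of the fractional rule
that remains correct for oblique cells at negligible cost. Tests verify
the padded list against an exhaustive 27-neighbor-cell enumeration on
random triclinic structures.

## Sampler parameters

`sampler_config()` exposes the knobs that matter:

* `n_points` (default $10^6$) — points per run. A million points reach
  the default precision target in the minimum three runs for typical
  molecular densities ($x \approx 0.6$–0.8); sparse structures need
  more.
* `target_rel_sigma` (default 0.001) — the convergence target for
  $\sigma(V_{\mathrm{net}})/V_{\mathrm{net}}$, i.e. 0.1%.
* `min_runs` / `max_runs` (3 / 10) — independent repeats. The spread is
  summarized by the **population** standard deviation over runs (divide
  by $n_{\mathrm{runs}}$, not $n_{\mathrm{runs}}-1$): the quantity of
  interest is the reproducibility of a single run, which does not shrink
  with more repeats, only becomes better defined. If the target is not
  met by `max_runs` the result is returned with `converged = FALSE` and
  a warning advising a larger `n_points` — never an exception, since the
  estimate itself is still unbiased.
* `seed` — a master seed from which per-run substreams are derived, so
  a result is bit-reproducible regardless of where the convergence loop
  stops.

A point exactly on a sphere surface counts as network. The set has
measure zero, but fixing the tie keeps classification deterministic.

```{r}
s <- make_structure("fcc_touching", r = 1.5)
res <- run_volume(s, sampler_config(n_points = 1e5, seed = 1,
                                    target_rel_sigma = 0.005))
glance(res)
```

Coordinate precision is propagated by a second Monte Carlo layer
(`propagate_uncertainty()`): 100 structural models (the conventional
choice) are generated by perturbing each fractional coordinate with an
independent Gaussian deviate of standard deviation equal to its su, one
sampling pass is run per model, and the mean and population standard
deviation of the resulting distribution are reported. Only atomic
coordinates are perturbed; cell-parameter su propagation is deliberately
out of scope of the default path. When all su values are zero the spread
reflects pure Monte Carlo reproducibility, so at the 0.1% target the
propagated spread is dominated by the sampler itself — only low-precision
structures or much tighter targets make the coordinate term significant.

`fragment_volume()` measures isolated (non-periodic) sphere unions in
the Cartesian bounding box of the subset inflated by the subset radii,
scaled to the number of molecules. Because van der Waals surfaces of
neighboring molecules interpenetrate, per-molecule volumes of
interacting subsets are smaller than isolated-molecule volumes, and
fragment volumes are not additive.

## Equation-of-state layer

Network volumes are usually well described by second- or third-order
Birch–Murnaghan forms; the much softer voids are better served by the
Vinet form, as is usual for soft solids under strong compression.
`fit_eos()` minimizes residuals in pressure at the observed volumes
(the convention of dedicated EoS-fitting software), weighted by
$1/\sigma_P^2$ when pressure uncertainties are supplied and unweighted
otherwise — the choice of weighting is not standardized in the
literature, so the default is the simplest defensible one. Starting
values are $V_0$ just above the largest observed volume, $K_0$ from a
secant estimate of $-V\,\Delta P/\Delta V$, and $K' = 4$
(Birch–Murnaghan) or 6 (Vinet); these are robust for both soft
($K_0 \sim 2$ GPa) and stiff ($K_0 \sim 150$ GPa) series. Noise-free
synthetic series are recovered to $10^{-6}$ relative in all three
families.

Where no standard form fits — typically immediately after a transition —
`numeric_bulk_modulus()` provides a model-free fallback:
$K = -V\,(\mathrm{d}P/\mathrm{d}V)$ by three-point Lagrange central
differences, exact for locally quadratic $P(V)$ and second-order
accurate on smooth series (observed order ≈ 1.9 under grid refinement
in the tests).

First-order error propagation through the reciprocal-mixing relation
uses the exact partial derivatives
$\partial K/\partial K_{\mathrm{net}} = K^2 x / K_{\mathrm{net}}^2$ and
$\partial K/\partial K_{\mathrm{void}} = K^2 (1-x) / K_{\mathrm{void}}^2$;
a Gaussian Monte Carlo alternative cross-checks the linearization
(they agree within 5% for typical inputs).

```{r}
propagate_partition_error(100, 5, 3.2, 0.4, 0.75)
```

## Series analysis

`pressure_series()` collects per-pressure partitions; `scale_to_Z()`
divides all volumes by the per-record number of formula units so that
series remain comparable across transitions where $Z$ changes.

Transitions are located by `piecewise_fit()`. Published analyses
typically identify the break visually; here the choice is formalized:
every midpoint between consecutive pressures that leaves both segments
enough points is tried, the break minimizing the total residual sum is
retained, and the two-segment model must additionally beat the
single-segment fit on a small-sample corrected information criterion
(AICc) in which the break position counts as a parameter. On
single-phase synthetic series with realistic noise the false-positive
rate of this rule is well below 5% (measured over 200 seeds in the
acceptance tests). Two regimes behave differently:

* a first-order-like transition (volume step at the break) pins the
  break to within one grid spacing;
* a second-order-like change of gradient with a continuous join leaves
  the boundary points genuinely ambiguous between segments — the tests
  hold the location to two–three grid spacings there, which is the
  method's actual resolving power, and the segment moduli are still
  recovered within their fit uncertainties.

`premonitory_scan()` fits a leading window (by default the points
before the first scanned break, else five points — the customary floor
for an EoS fit) and flags later observations deviating from the
extrapolated volume by more than `k_sigma` (default 3) combined standard
deviations, fit-prediction variance and measurement sigma added in
quadrature; no standard criterion exists, so the quadrature combination
is the package's own. The deviation sign is reported because the
physically interesting premonitory signature is volumes falling *below*
the extrapolation at the top of the pressure range.

## The synthetic generator

`make_structure()` builds analytic sphere-packing fixtures — a single
sphere, an overlapping or disjoint pair (lens-subtraction closed form),
a face-centered-cubic cell of touching spheres (packing fraction
$\pi/\sqrt{18}$), and random-atom cells — each carrying its closed-form
network volume. `make_series()` builds pressure series that follow
stated EoS parameter sets exactly, optionally with Gaussian noise and a
two-phase join in which the second segment's $V_0$ is solved from
continuity minus a stated volume step. Fixtures are emitted as genuine
CIF files with a matching radii table, so the entire input path —
parsing, symmetry expansion, radius assignment, padding — is exercised,
not just in-memory objects.

What the generator emulates: sphere-union geometry, Poisson sampling
statistics, coordinate-precision perturbation, EoS-governed compression
with stiffness contrasts of the size seen in real transitions
(network moduli dropping from ~120 to ~80 GPa), noise at the level the
sampler itself produces at its default target (≈0.04–0.1% of the
network volume). What it does not emulate: real molecular shape (fused
sphere counts are small), refinement pathologies such as spurious bond
shortening in Rietveld series, systematic offsets between merged
studies, and anisotropic strain. Passing tests therefore validate the
estimator and the fitting machinery, not the crystallography of any
particular compound.

Test and acceptance problem sizes were chosen to keep the full suite in
a few minutes while leaving the statistics meaningful: $10^6$ points for
closed-form agreement and convergence checks, $10^4$–$10^6$ for the
$\sqrt{n}$ law with 20 repeats per size, 50 replicates for noisy EoS
recovery, 10 per transition contrast, and 200 null series for the
false-positive rate.

## Numerical choices and degenerate inputs

* Duplicate symmetry images are removed at 0.05 Å (minimum-image
  Cartesian distance); first occurrence wins, so expansion is
  deterministic and idempotent.
* An empty atom list classifies every point as void, with a warning.
* `fit_eos()` refuses series with fewer points than free parameters
  plus one; `piecewise_fit()` returns a single-segment report rather
  than fitting under-determined segments; recommended survey-style
  curation (drop series with fewer than five points) is available as the
  fit floor but not forced on user data.
* Non-monotone volume–pressure input to `numeric_bulk_modulus()` is an
  error naming the offending indices, since $K$ is undefined there.
* `eos_volume()` inverts the pressure relations by bisection on
  $[10^{-3} V_0, V_0]$, which is safe because all implemented forms are
  strictly monotone in that range for positive moduli.

## Known limitations

* Constant ambient-pressure van der Waals radii are used at every
  pressure; at tens of GPa the apparent packing coefficient tends to 1
  and overlap between surfaces is hidden in the network volume.
* No rolling-probe "accessible surface" mode and no Voronoi or
  promolecule partitioning: the partition here is the point-in-sphere-
  union definition, which samples crevices a finite probe misses but is
  not comparable number-for-number with probe-based void volumes.
* Molecule perception is limited to X–H bond detection; fragment
  subsets must be supplied by the caller as index groups.
* Disordered structures are handled only by rejection or
  major-component selection, not by occupancy-weighted sampling.
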