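# cdhfold

Folding thermodynamics, mechanics and interaction networks of the
cadherin-23 EC1 domain.

Cadherin-23 is the upper filament of the hair-cell tip link that converts
sound-induced tension into the electrical signal of hearing. A single
point mutation, S47P, in its outermost extracellular domain (EC1) causes
progressive hearing loss without visibly changing the crystal structure.
`cdhfold` is an R toolbox for the computational analyses that explain how:
it quantifies how the mutation lowers thermodynamic stability, slows
folding by two orders of magnitude, rewires hydrogen-bond networks and
backbone correlations, and reroutes mechanical unfolding onto a low-force
pathway. It is written for protein biophysicists who want these analyses
reproducible, testable and scriptable end-to-end.

## What is inside

* **Structures and contacts** — a fixed-column PDB reader/writer,
  Kabsch superposition (`superpose_rmsd()`), and the two native
  contact-map flavors: Cα 8 Å / side-chain 5.2 Å pairs for the pulling
  model (`native_contacts_sop()`), heavy-atom 6 Å pairs with atomic
  multiplicities and pH-7 charges for the folding model
  (`native_contacts_wsme()`).
* **bWSME folding landscape** — the block Wako–Saitô–Muñoz–Eaton
  Ising model: the 1 + C(n+1,2) + 2·C(n+1,4) single/double-island state
  space (105,316 states for 34 blocks; 8,847,804 at residue level), a
  Hamiltonian with van der Waals, Debye–Hückel electrostatic, solvation
  and secondary-structure-dependent entropy terms, heat-capacity curves,
  DSC fitting (`fit_dsc()`), and free-energy profiles and surfaces over
  the structured-blocks order parameter.
* **SOP pulling simulator** — a self-organized-polymer model (FENE
  backbone + native Lennard-Jones wells, εh = 1.5 kcal/mol) with an
  overdamped Langevin integrator in C++, constant-velocity cantilever
  pulling (35 pN/nm), rupture detection, worm-like-chain contour-length
  gains, and shearing/unzipping pathway classification against the
  observed cluster centers.
* **Equilibrium & kinetics** — melt normalization to unfolded fraction,
  Tm/Cm from derivative maxima, deterministic multistart bi-exponential
  stopped-flow fits, chevron extrapolation to water, amplitude-crossover
  detection.
* **Networks & correlations** — hydrogen-bond persistence networks with
  the critical-persistence (largest-cluster collapse) analysis, and
  circular cross-correlation maps of backbone dihedrals with Z > 2.5
  filtering and differential (WT − mutant) maps.
* **Synthetic data** — seeded generators for every input (toy
  structures with brute-force contact truth, β-sandwich-like contact
  maps, thermograms, melts, stopped-flow traces, dihedral series with
  planted correlations, H-bond event streams, WLC force-extension
  curves), so the full pipeline runs and is validated without any
  download.

All user-facing functions take and return tibbles where the data are
tabular; fitted objects have `tidy()`/`glance()` methods and result types
have `autoplot()` methods.

## Worked example

Fit bi-exponential folding kinetics for synthetic wild-type and mutant
traces generated at their zero-denaturant rates, then compare:

```r
library(cdhfold)

wt  <- fit_biexponential(make_kinetic_trace(93.7, 9.9, noise = 0.02, seed = 1))
mut <- fit_biexponential(make_kinetic_trace(6.2, 0.4, noise = 0.02, seed = 2))
wt
#> <biexp_fit> k_fast = 92.05 /s, k_slow = 9.457 /s (A = 0.608 / 0.391)
mut
#> <biexp_fit> k_fast = 6.135 /s, k_slow = 0.4014 /s (A = 0.598 / 0.402)
round(wt$k_fast / mut$k_fast, 1)
#> [1] 15
```

The recovered rates sit within a few percent of the generating values at
2% noise, and the fast-phase fold change reproduces the 15× deceleration
of the mutant. The same objects tidy into tables
(`glance(wt)` gives one row with rates, amplitude fraction 0.609 and RMS
residual 0.0196).

Build the folding landscape of a 102-residue EC1-like domain with the
wild-type calorimetric parameters:

```r
cm  <- synth_contact_map(102, "wt", seed = 1)   # synthetic beta-sandwich map
sys <- wsme_system(cm, attr(cm, "ss"), wsme_parameters())
sys
#> <wsme_system> 102 residues, 34 blocks, 105316 microstates

cp <- heat_capacity_curve(sys, seq(290, 380, 0.5))
attr(cp, "Tm")
#> [1] 349

prof <- free_energy_profile(sys, T = attr(cp, "Tm"))
attr(prof, "minima")
#> # A tibble: 6 x 3
#>       n  F_kJ label
#>   <int> <dbl> <chr>
#> 1     0  0    U
#> 2    15 99.2  I
#> 3    21 94.0  I
#> 4    25 71.8  I
#> 5    28 38.2  I
#> 6    33  1.88 N
autoplot(prof)   # or autoplot(cp), autoplot(free_energy_surface(sys))
```

The model melts cooperatively near 349 K and shows a multi-state profile
with partially structured intermediates between the unfolded (U) and
native (N) basins — the qualitative landscape the folding analysis builds
on. With the mutant parameter set and the `"s47p"` contact-map variant
the transition shifts down by roughly 15 K.

See `vignette("cdh23-folding-methods")` for the models, parameter
conventions, numerical choices and the limits of synthetic validation.

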