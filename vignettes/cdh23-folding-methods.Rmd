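---
title: "Models and methods: folding, mechanics and interaction networks of Cdh23 EC1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: folding, mechanics and interaction networks of Cdh23 EC1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

The outermost extracellular domain (EC1) of cadherin-23, the upper filament
of the hair-cell tip link, carries the S47P point mutation associated with
progressive hearing loss. The mutation barely changes the crystal
structure, yet the mutant is thermodynamically less stable, folds two
orders of magnitude more slowly, and prefers a low-force mechanical
unfolding pathway. `cdhfold` implements the quantitative machinery needed
to dissect that phenotype: an Ising-like statistical-mechanical folding
model fit to calorimetry, a coarse-grained force-pulling simulator with
rupture and pathway analysis, equilibrium and kinetic unfolding analysis,
and trajectory statistics (dihedral circular correlations, hydrogen-bond
persistence networks). A seeded synthetic-data module emulates every input
so the whole pipeline runs and is validated offline.

This vignette is the package's methods reference: the models, their
assumptions, the tunable parameters with units and defaults, the numerical
choices, and the limits of what the synthetic validation can show.

## 1. Native contact maps

Two contact definitions feed the two models:

* **SOP flavor** (`native_contacts_sop()`): residues i, j with
  `|i - j| >= 3` are in contact if their C-alpha atoms are closer than 8 A
  or any pair of side-chain heavy atoms (all non-hydrogens except N, CA,
  C, O) is closer than 5.2 A. The stored native distance is the
  C-alpha-C-alpha distance, which parameterizes the attractive wells of
  the pulling model. Glycine contributes only the C-alpha test.
* **WSME flavor** (`native_contacts_wsme()`): residues with
  `|i - j| >= 2` are in contact if any two heavy atoms are closer than
  6 A, and the map records the *number* of heavy-atom pairs under the
  cutoff. This multiplicity matters: the model's van der Waals energy is
  tens of J/mol per atomic contact, so the ~10^4 atomic contacts of a
  compact ~100-residue domain supply the hundreds of kJ/mol that balance
  the conformational entropy. Counting residue pairs instead would make
  the stated energy scale meaningless.

Charges for the electrostatic term follow the simplest defensible pH 7
rule: Asp/Glu -1, Lys/Arg +1, histidine and the termini neutral. There is
no pKa model; the rule is configurable by editing the charge vector
attached to the map.

Superposition (`superpose_rmsd()`) is the Kabsch SVD solution with a
reflection guard, pairing atoms by renumbered residue index on the
intersection of the two structures - the right convention for comparing
two crystal forms of almost (but not exactly) the same construct. Which
residues enter the published C-alpha RMSD of the two EC1 crystal forms is
not recorded anywhere we know of; the index-intersection rule is this
package's choice.

Secondary-structure classes (`assign_secondary_structure()`) exist only to
pick each residue's conformational-entropy class: `strand_or_helix` for
non-Gly/non-Pro residues whose phi/psi sit in the canonical helix
(phi in [-100, -30], psi in [-80, -5]) or strand (phi in [-180, -90],
psi in [90, 180]) basins for at least two consecutive residues,
`coil_or_glycine` otherwise, `proline` always. A user table overrides the
dihedral assignment (prolines stay prolines).

## 2. The block WSME folding model

The Wako-Saito-Munoz-Eaton model assigns each residue a binary
folded/unfolded status; native interactions contribute only when the whole
intervening stretch is folded. The block variant (bWSME) groups three
consecutive residues into one unit, reducing a 102-residue chain to 34
blocks. The state space kept here is the single-sequence approximation
(one folded island), the double-sequence approximation (two disjoint
islands separated by at least one unfolded block), and each two-island
state duplicated with a flag `w` that switches the cross-island
interactions on. The count is

    1 + C(n+1, 2) + 2 C(n+1, 4)

which gives 105,316 states for 34 blocks and 8,847,804 for 102
single-residue units - the only reading of the state space that reproduces
both of those published counts, which is why the `w`-duplication is built
into `enumerate_microstates()` rather than left as an option.

A microstate's free energy, relative to the fully unfolded state (exactly
zero by construction), is

    F = n_c [xi + dCp ((T - T_ref) - T ln(T/T_ref))] + E_DH
        - T * sum_folded dS_class

where `n_c` is the number of *licensed* atomic contacts (both residues in
folded islands; cross-island contacts only when `w` is on), `xi` the van
der Waals energy per atomic contact, the `dCp` term a standard
liquid-hydrocarbon-like solvation free energy with reference temperature
`T_ref`, and `E_DH` a Debye-Hueckel screened Coulomb sum,
`332.0636 q_i q_j exp(-kappa r0) / (eps_eff r0)` kcal/mol converted to
J/mol, over licensed contacts whose partners are both charged. The
enthalpy `H` keeps the contact terms (`n_c (xi + dCp (T - T_ref)) + E_DH`)
and drops the entropy.

Parameters (`wsme_parameters()`), defaults = the wild-type calorimetric
fit values:

| parameter | default | units |
|---|---|---|
| `xi` | -62.8 | J/mol per atomic contact |
| `dS_strand_helix` | -19.5 | J/mol/K per residue |
| `dS_coil_gly` | -25.6 | J/mol/K per residue |
| `dS_pro` | 0 | J/mol/K per residue |
| `dCp_cont` | -0.68 | J/mol/K per atomic contact |
| `ionic_mM` | 20 | mM |
| `pH` | 7 | - |
| `T_ref` | 385 | K |
| `eps_eff` | 29 | - |

`T_ref` and `eps_eff` are not published for this system; the defaults
follow the conventions of the bWSME literature and are configurable. The
Debye screening length is computed from the ionic strength and temperature
with the effective dielectric, `kappa^2 = 2 N_A e^2 I / (eps0 eps_eff kB T)`.
Because the electrostatics conventions are the least constrained part of
the model, quantities that depend on them (absolute barrier heights,
intermediate positions) should be read with corresponding caution.

**Implementation.** Licensed contact counts and folded entropies are
island-interval sums, evaluated for all 10^5 states at once with
two-dimensional prefix sums over block-level matrices (O(1) per state);
the few charged contact pairs get an explicit state-by-pair licensing
matrix so the temperature-dependent screening can be re-applied cheaply.
Populations always go through log-sum-exp (`partition_function()`), which
is exact for the probabilities and immune to overflow between 250 and
400 K. An exhaustive oracle - every binary block string, filtered to at
most two islands, scored by plain loops - agrees with the engine to
1e-10 in the partition function and in every order-parameter bin for
systems up to 12 blocks (see `tests/testthat/`).

**Observables.** `heat_capacity_curve()` differentiates the ensemble mean
enthalpy by central differences on a <= 0.5 K grid. `fit_dsc()` fits the
model to an experimental thermogram over a chosen free-parameter subset
(`xi` and/or the entropies) after subtracting a linear pre-transition
baseline; optimization is a deterministic coarse grid followed by Brent
(one parameter) or Nelder-Mead (several), with an `at_bound` flag rather
than silent clipping. `free_energy_profile()` bins states by the number of
structured blocks, `F(n) = -RT log sum exp(-F_m/RT)`, shifts the minimum
to zero, labels discrete local minima U/I/N by position, and reports the
maxima between adjacent minima as barriers; barrier heights are invariant
to the global shift. `free_energy_surface()` does the same over (blocks
folded in the N-half, blocks folded in the C-half), the coordinate pair
that shows C-first folding of the intermediate; its bins and the 1-D bins
both re-sum to the same partition function to 1e-10. The evaluation
temperature defaults to 310 K and is explicit in every call - the
published profiles do not state theirs.

Desk-scale validation uses a synthetic contact map
(`synth_contact_map()`), not the crystal structures: nine strands with
antiparallel pairings, local backbone contacts, and core packing topped up
to ~225 incident atomic contacts per residue - the density of compact
globular domains (~28 heavy-atom neighbours within 6 A per atom, ~8 heavy
atoms per residue). With the wild-type parameter defaults this map melts
cooperatively inside the experimental window with a multi-state profile,
which is what makes the parameter-recovery tests meaningful. The `"s47p"`
variant derives from the same base map (as the two nearly identical
crystal forms do), thinning contacts around position 47 and converting it
to proline; it melts ~10-15 K lower. What these tests show is that the
engine and fitter are self-consistent and identifiable under realistic
packing statistics; they cannot show agreement with the real EC1
structures, which would require the deposited coordinates
(`read_structure()` + `native_contacts_wsme()` accept them directly when
available).

## 3. The SOP pulling model

The self-organized polymer model is one bead per residue at the C-alpha
position:

    V_T = V_FENE + V_NB^ATT + V_NB^REP
    V_FENE  = -sum (k R0^2 / 2) ln(1 - (r - r0)^2 / R0^2)
    V_ATT   = sum_native eh [ (r0/r)^12 - 2 (r0/r)^6 ]
    V_REP   = sum_{i,i+2} el (sigma13/r)^6 + sum_non-native el (sigma/r)^6

with `eh = 1.5` kcal/mol for both variants and the standard literature
constants where unpublished: `k = 20` kcal/mol/A^2, `R0 = 2` A,
`el = 1` kcal/mol, `sigma = sigma13 = 3.8` A (all configurable through
`sop_parameters()`). At the native coordinates `V_FENE` is exactly zero
and `V_ATT` is exactly `-eh` per native pair; analytic forces match
central differences to better than 1e-5 relative.

Dynamics (`run_pulling()`, `run_dynamics()`) is first-order overdamped
Langevin: `x += (dt/zeta) F + sqrt(2 kB T dt / zeta) eta`. Defaults:
`T = 300 K`, friction `zeta = 50` kcal mol^-1 ps A^-2, and
`dt = 0.04 zeta / k_FENE = 0.1 ps` - the stiffest relaxation time in the
system is the FENE bond (`zeta/k = 2.5 ps`), and the FENE nonlinearity
raises the effective stiffness under load, hence the safety margin. A
step guard aborts with diagnostics if any bead moves more than 2 A in one
step or a bond leaves the FENE domain. The thermal noise comes from an
internal Mersenne Twister with Box-Muller normals, so a given seed gives
a bit-identical trajectory on any platform; every result object records
its seed.

Pulling fixes the N-terminal bead and attaches a cantilever spring
(35 pN/nm = 0.0504 kcal/mol/A^2 by default) to the C-terminal bead, with
the anchor moving at constant speed along the native N-to-C vector. The
recorded force is `k_spring` times the anchor-minus-bead displacement
projected on that axis, reported in both kcal/mol/A and pN
(1 kcal/mol/A = 69.479 pN). Because crystal coordinates are not exact
minima of the soft non-native repulsions, pulls start from an L-BFGS
energy minimum (`sop_minimize()`) unless explicit start coordinates are
given; `equilibrate()` generates thermalized starting ensembles with
derived per-replica seeds and flags replicas that lost more than 20% of
their native contacts.

**Desk scale.** The published protocol (2.5 um/s for 48 ms per
trajectory, 100 replicas) is about 10^6 times more simulation time than a
test suite can spend. The package therefore validates the simulator at
10^4-10^5 um/s on a 16-residue hairpin fixture with 2-10 replicas, where
every claim is a physics consistency check rather than a literature
number: forces vs numerical gradients, zero-temperature quiescence from a
minimized start (coordinates conserved to < 1e-3 A over 10^6 steps, with
the cantilever force staying below 1e-6 pN), monotone increase of rupture
force with speed, and the contour-length audit below. The published speed
is simply a `pulling_config()` setting away, at the corresponding cost.

## 4. Rupture detection, contour lengths, pathways

`detect_ruptures()` smooths the force with a Savitzky-Golay filter
(window 51 samples by default; wider for slow desk-scale pulls), takes
local maxima above a noise floor of median + 4 MAD *of the raw trace*
(smoothing shrinks the MAD of pure noise, which would make the floor
meaningless), and requires a drop of at least 30% of the peak before the
next retained peak; candidates without an intervening drop are merged
into the higher one. The implementation is checked against a literal
restatement of that rule as a stepwise scan.

`contour_length_gain()` fits the interpolated worm-like-chain force law
(persistence length fixed, 0.4 nm default - a polypeptide value) to the
rising edge before and after each rupture; `dLc` is the difference of
successive fitted contour lengths. On planted multi-segment WLC traces
(`make_wlc_trace()`) the planted gains of 10.90 and 13.67 nm are
recovered to +-0.1 nm. On *simulated* SOP traces, however, WLC
extrapolation systematically inflates the contour by 8-13%: the FENE
bonds stretch by F/k (~5% at 200-300 pN) and the freely jointed bead
chain is not a 0.4 nm WLC. The chain-geometry consistency check in the
acceptance tests therefore reads extensions directly - the smoothed
extension when the final edge first reaches a 200 pN reference force -
and compares the total gain with the geometric bound
`(N-1) x 0.38 nm - native end-to-end distance`, which it matches within
10% across seeds. A `method = "raw"` peak-to-peak mode is available for
the same reason.

`classify_pathway()` assigns the classifying (second) rupture to the
low-force unzipping or high-force shearing pathway by nearest center in
standardized (peak force, dLc) space. The default centers are the two
observed pathway centers, (2.41 kcal/mol/A, 10.90 nm) and
(3.75 kcal/mol/A, 13.67 nm); `refit = TRUE` re-estimates them by 2-means
seeded from those defaults (hence deterministic). Exact ties go to the
low-force pathway. `contact_map_evolution()` marks a native contact
present in a frame when its distance is below 1.25 times the native
distance, and reports per-frame native fraction and per-pair lifetimes.

## 5. Equilibrium melts

`fraction_unfolded()` maps a raw melt signal onto the unfolded fraction
`alpha = (theta_T - theta_f) / (theta_u - theta_f)` - 0 at the folded
baseline, 1 at the unfolded one. (The compact one-line form of this
normalization sometimes printed, with `theta_u` in the numerator,
evaluates to -1 at the folded baseline; the definition of alpha as the
unfolded fraction fixes the intent, and that is what is implemented.)
Baselines are supplied constants or linear fits to the outer 15% of the
curve; values are clipped to [-0.05, 1.05] with flags. The midpoint
(`midpoint_from_derivative()`) is the vertex of a least-squares parabola
through the central-difference derivative peak and its two neighbours on
each side, normalized to unit maximum, with the half-width at 90% of the
peak as the uncertainty. On synthetic two-state melts the thermal
midpoint is recovered to 0.3 K and a planted 0.6 M chemical-midpoint
difference to +-0.05 M at 0.2% signal noise; precision degrades roughly
linearly with the noise-to-grid ratio. Whether the published "Cm of
0.6 M" is the mutant's absolute midpoint or the wild-type-minus-mutant
difference is ambiguous; the recovery test treats it as the difference,
as a property of this package's test design, not a claim about the
original measurement.

## 6. Stopped-flow kinetics

`fit_biexponential()` fits `A_f exp(-k_f t) + A_s exp(-k_s t) + c` after
discarding samples before the 3 ms mixing dead time (the free offset
absorbs the unobserved burst). Initialization is deterministic: a 5x5
log-spaced rate grid solved by linear least squares for the amplitudes,
then Levenberg-Marquardt from the best node. Rates are labelled
`k_fast > k_slow`; a fit that a single exponential matches within 1% of
the residual is flagged degenerate and reports the single rate. Rate
recovery at 2% noise is better than 5% RMSE for rate ratios >= 5; below a
ratio of ~3 the two phases trade amplitude and errors grow - the
degenerate flag is the guard. `fit_chevron()` is ordinary least squares
of ln k on denaturant (the observed dependence is linear); two points
give an exact line with a warning, three or more give standard errors.
`amplitude_crossover()` linearly interpolates the concentration where the
fast-phase amplitude fraction crosses one half, returning `NA` when no
crossing occurs in range (the mutant's phenotype). Amplitude fractions
are `|A_f| / (|A_f| + |A_s|)`.

## 7. Dihedral circular correlations

`circular_correlation()` implements the Jammalamadaka-SenGupta
coefficient: Pearson correlation of the series `sin(x - xbar)` with
circular means as centers (the identity with `cor()` of the sin-centered
series is asserted in tests). It is invariant to rigid rotation of either
series, lies in [-1, 1], and is reported as `NA` (never 0) for series
whose centered sine variance is below 1e-6. The alternative Fisher-Lee
form was considered and not included: the cited convention for this
analysis family is the Jammalamadaka-SenGupta form, and carrying two
conventions invites silent mismatches.

`correlation_map()` computes the coefficient for all dihedral pairs, then
standardizes the *absolute* coefficients against the full matrix -
including the unit diagonal - and keeps pairs with Z > 2.5. The Z
population is the one genuinely open convention here. Standardizing only
the off-diagonal absolute values makes the threshold a ~2% false-positive
rule by construction (the 2.5-sigma tail of a half-normal), which
contradicts the observed behavior this filter is meant to reproduce:
null maps that come out empty and planted pairs that are retained alone.
Anchoring the scale with the diagonal makes the filter conservative in
exactly that way, and that is the convention adopted; on 100 seeded null
maps (20 uniform dihedrals x 5000 frames) the retention rate is far below
1.5% of pairs, while a planted pair of strength 0.8 among 50 independent
dihedrals is retained uniquely. Residue-level maps take the maximum
absolute coefficient over the up to four phi/psi combinations per residue
pair. `differential_map()` is the elementwise `|r_a| - |r_b|`, exactly
antisymmetric under argument swap.

The dihedral generator (`make_dihedral_series()`) draws base angles from
von Mises distributions with concentration 2 (basin-like fluctuations of
roughly +-40 degrees) and plants correlated pairs as base plus von Mises
noise. The noise concentration is inverted in closed form from the target
coefficient, including the sine-variance attenuation of the broadened
partner; planted strengths are honoured to +-0.05. With a *uniform* base
the sample circular means are degenerate and the coefficient of a planted
pair is attenuated by an arbitrary rotation - a property of the statistic,
not a bug - so calibration targets are only promised for concentrated
bases, and uniform angles are reserved for null simulations.

## 8. Hydrogen-bond persistence networks

`detect_hbonds()` is a plain geometric detector so the pipeline can run
end-to-end on coordinates: donor and acceptor heavy atoms (backbone
amides and carbonyls plus the usual side-chain N/O groups) within 3.5 A
with a donor-H...acceptor angle of at least 120 degrees when hydrogens
are present, or a stricter 3.3 A distance-only rule without them. It
stands in for heavier interaction-analysis tooling and is validated on
planted-occupancy synthetic trajectories, not against any external
program's output.

Persistence is the fraction of frames a donor-acceptor pair is present.
`persistence_network()` keeps bonds at or above a threshold (0.25 by
default - the transient-bond cutoff); `critical_persistence()` scans the
threshold, records the largest connected component of the residue graph
at each value, and reports the threshold at the steepest drop (the last
value before the largest collapse), so a network built to fragment at
0.25 yields exactly 0.25. The curve is non-increasing by construction; a
flat curve gives `NA` with a warning rather than an arbitrary number.

## 9. Reproducibility and problem sizes

Every stochastic function takes a seed and derives independent
sub-streams from it (generator outputs are byte-identical under
regeneration; simulation seeds are recorded in their outputs). The test
suite builds all fixtures in code: a 16-residue ideal-geometry hairpin
(strands at phi/psi = -150/150, a type-I'-like turn chosen so the strands
pair without clashes), a 12-residue helix, a two-chain sheet, and the
synthetic contact maps, thermograms, traces and event tables described
above. Problem sizes were chosen so the whole suite validates every
module deeply in a few minutes of CPU: 8-12 block systems for exhaustive
oracle comparisons (the state count grows as n^4, and 12 blocks already
exercises every licensing case), the full 34-block system for count,
fitting and profile checks, 16-bead pulling with 10^5-10^6 steps, and
100-seed null simulations for the correlation filter.

## 10. Known limitations

* The bWSME electrostatics conventions (`eps_eff`, `T_ref`, the
  screened-Coulomb distance set) are the model family's defaults, not
  system-specific fits; conclusions that hinge on them (absolute barrier
  heights, exact intermediate positions) carry that uncertainty.
* The synthetic contact map reproduces packing *statistics*, not the real
  EC1 topology; desk-scale tests demonstrate engine correctness and
  parameter identifiability, not agreement with the deposited structures.
* Desk-scale pulling speeds are far above the experimental regime, so
  rupture forces are drag-inflated and pathway statistics at those speeds
  are not comparable with published fractions; the printed protocol is
  available but costs hours to days per ensemble.
* WLC contour extrapolation on FENE bead chains is biased high by bond
  elasticity; use the raw extension readouts for geometric audits.
* The hydrogen-bond detector has no energetic or angular-preference
  model beyond the single angle cutoff, and microsecond all-atom
  observables (real persistence values, real correlation maps) are out of
  its reach by design.
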