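---
title: "Modelling far-red photosystem II: excitons, spectral tuning, and charge separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling far-red photosystem II: excitons, spectral tuning, and charge separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frlpsii)
```

## The problem

Conventional photosystem II (WL-PSII) is built around chlorophyll *a* and
absorbs out to roughly 685 nm, the classical "red limit" of oxygenic
photosynthesis.  Some cyanobacteria acclimated to far-red light express an
isoform (FRL-PSII) in which a handful of pigments are replaced by
chlorophyll *d* and *f*, shifting absorption to 715–725 nm while still
driving water oxidation.  The interesting physics sits in the reaction
center (RC): six chlorin pigments (the P_D1/P_D2 special pair, the accessory
Chl_D1/Chl_D2, and the two pheophytins) whose site energies, mutual
excitonic couplings, and redox potentials together decide where the lowest
excitation sits, how delocalized it is, and whether charge separation
remains downhill when the photon energy drops by ~0.1 eV.

This package is the analysis layer for that question.  The expensive
upstream quantities — vertical excitation energies (VEEs) from correlated
quantum chemistry, fragment-based excitonic couplings, Poisson–Boltzmann
redox shifts — are *inputs*, shipped as curated fixtures
(`psii_fixtures()`) or supplied as delimited tables.  The package owns
everything downstream: the Frenkel exciton Hamiltonian and its analysis,
spectral synthesis with static disorder, the exact bookkeeping that
decomposes spectral tuning into strain/electrostatic/coupling components,
redox bookkeeping of charge-separated states, and a master-equation model of
the charge-separation cascade.

## The exciton model

The site basis is one Qy excitation per pigment.  The Hamiltonian is

$$ H = \sum_i \epsilon_i |i\rangle\langle i| + \sum_{i \ne j} V_{ij} |i\rangle\langle j| $$

with site energies $\epsilon_i$ in eV on the diagonal and couplings
$V_{ij}$ off-diagonal.  Internally everything is eV; wavenumbers appear only
at I/O boundaries (1 eV = 8065.544 cm⁻¹) and wavelengths via
$\lambda = 1239.84193\,/\,E$.

`diagonalize()` returns ascending eigenvalues, sign-fixed eigenvectors
(largest-magnitude coefficient positive, ties to the lowest site index),
participation ratios $1/\sum_i c_{ki}^4$, and — when site dipoles are known —
oscillator strengths
$f_k = 4.702\times10^{-7}\,\tilde E_k(\text{cm}^{-1})\,|\vec\mu_k|^2$ with
$\vec\mu_k = \sum_i c_{ki}\,\mu_i\hat\mu_i$.  States with $f<10^{-4}$ are
labelled dark.  Two invariants are enforced and property-tested: trace
conservation ($\sum_k E_k = \sum_i \epsilon_i$) and the dipole-strength sum
rule ($\sum_k|\vec\mu_k|^2 = \sum_i \mu_i^2$).

### Couplings from structure

When no tabulated coupling is available, `point_dipole_coupling()` provides
the standard geometric estimate

$$ V = 5034.1\, f\,\kappa\,\mu_1\mu_2 / R^3 \quad (\text{cm}^{-1}), $$

with dipole magnitudes in Debye, the centre–centre distance $R$ in Å, and
$\kappa = \hat\mu_1\cdot\hat\mu_2 - 3(\hat\mu_1\cdot\hat R)(\hat\mu_2\cdot\hat R)$.
Choices worth stating:

* **Dipole axis.** The Qy axis is the NB→ND nitrogen axis (PDB chlorophyll
  convention; the N21/N23 dialect is accepted automatically), signed from NB
  to ND so the orientation is deterministic.
* **Dipole magnitude.** 4.0 D for every chlorin type by default.  Reliable
  in-protein Qy magnitudes for Chl *d*/*f* are not available from our input
  tables, so this is a documented placeholder, overridable per chem type —
  not a fitted value.
* **Screening.** $f = 0.72$, a standard empirical dielectric screening for
  pigment–protein couplings; overridable.
* **Validity.** The estimator refuses centre distances ≤ 2 Å, where the
  point-dipole picture has no meaning.  It is an order-of-magnitude tool;
  the shipped model fixtures use the tabulated couplings (97, 105, 77, and
  180/192 cm⁻¹), not this estimate.

### The model fixtures

The tabulated site-energy tables list one value for the coupled P_D1/P_D2
pair.  We assign that value to *both* P diagonals when building systems;
this preserves the pair-vs-Chl_D1 gap arithmetic exactly, which is what the
fixtures are for.  The individual P_D1/P_D2 site energies are not separately
available, so the 3-site fixtures should not be over-interpreted as a full
6-pigment Hamiltonian.  For the two P_D2-substitution models the tabulated
coupling is a range, 180–192 cm⁻¹ across the Chl *a*/*d* and *a*/*f* pairs;
the fixtures assign the endpoints (180 to Chl *d* @ P_D2, 192 to
Chl *f* @ P_D2).

## Spectra

`broaden()` turns a stick spectrum into a sum of area-normalised Gaussians,
so integrated intensity equals summed oscillator strength (quadrature error
below 0.5% on the default grid).  The default FWHM of 0.06 eV reproduces
Q-band-like visual widths; the upstream calculations do not prescribe a
lineshape, so Gaussian is a package choice.  The default grid is
1.4–2.2 eV in 2000 points (~0.4 meV spacing), which also sets the
resolution of peak-based operations.

`ensemble_spectrum()` emulates snapshot averaging with i.i.d. Gaussian
static disorder on the site energies (diagonal disorder only; the inputs
give no basis for an off-diagonal disorder model).  The generator draws one
seeded stream, so results are bit-reproducible, and it records the
per-realization lowest exciton energy so the realized disorder width can be
checked against the nominal σ.

`align_to_reference()` implements the presentational convention of aligning
a computed spectrum at a reference band — in practice the 674 nm
special-pair feature.  It is a rigid translation toward the *nearest* local
maximum (ties toward higher energy); the applied shift is recorded in the
metadata and never applied silently.  The magnitude of the shift is an
output, not a target.

## The tuning ledger

The decomposition is exact telescoping over four VEE evaluations of the same
pigment: gas phase at gas-phase geometry, gas phase at protein geometry,
protein-embedded monomer, and coupled multimer:

* strain = VEE(gas @ protein geometry) − VEE(gas @ gas geometry)
* electrostatic = VEE(protein monomer) − VEE(gas @ protein geometry)
* coupling/polarization = VEE(multimer) − VEE(protein monomer)

The three components sum to the total shift by construction (tested to
1e−12), the map is linear in its inputs, and `make_vee_set()` is its exact
right-inverse.  Sign convention: negative = redshifting, with a ±0.001 eV
neutrality band (below the reporting precision of the tabulated
components).

Fixture details: the Chl *d* quadruple embeds the tabulated components
(−0.006, −0.003, −0.032 eV) on a synthetic 1.910 eV gas-phase baseline.
For Chl *f* only strain (+0.021 eV) and electrostatics (+0.056 eV) are
tabulated; its coupling/polarization component is set to zero and the
baseline (1.820 eV) chosen so the protein-embedded value lands on the
tabulated 1.897 eV site energy.  Aligned ledger totals are produced only
when the user supplies an alignment shift, since that magnitude is not a
tabulated input.

## Charge separation

### Energetics

`ct_state_energy()` books radical-pair energies relative to a white-light
reference: $E = E_{ref} - \Delta E_{ox}/1000$ with the oxidation-potential
shift in mV.  Two caveats are deliberately surfaced rather than resolved:

* The reference (1.715 eV for the first radical pair) is back-computed so
  that the reported level scheme (1.72 eV excited state → 1.57 eV radical
  pair under a +145 mV shift) closes; it is not itself a tabulated number.
* The sign convention is the reported *bookkeeping* — an increased
  donor-site oxidation potential booked as stabilization of the
  charge-separated state.  Electrochemically one would expect the opposite
  sign for the cation; the returned value carries a `sign_convention`
  attribute flagging this.

### Kinetics

The cascade is a five-state chain: S1 (1.72 eV) → ChlD1⁺ PheoD1⁻ (1.57 eV)
→ (P_D1P_D2)⁺ Q_A⁻ (1.45 eV) → Mn_ox Q_A⁻ (1.35 eV) → Mn_ox Q_B⁻
(1.25 eV).  The 1.45 and 1.35 eV intermediates are interpolations between
the 1.57 and 1.25 eV anchors.  Forward rates
(3.0e11, 3.47e9, 1.0e7, 2.31e3 s⁻¹) are a *calibration* to the
well-established PSII charge-transfer kinetics — ~0.2 ns to form the
(P_D1P_D2)⁺/Q_A⁻ state and ~300 µs to the final state, rate-limited by the
slow Q_A → Q_B step — not first-principles predictions.  Backward rates
follow detailed balance, $k_{back} = k_{fwd}\exp(\Delta G/k_BT)$ at
298.15 K ($k_BT$ = 0.025693 eV), which guarantees Boltzmann stationary
distributions (property-tested on random ladders).  `marcus_rate()` exposes
the nonadiabatic closed form for building networks from ($\lambda$, V)
pairs, but the default network uses the calibrated rate table directly,
because halftimes, not Marcus parameters, are the available anchors.

The WL comparison network swaps the flagged parameters only: excited state
at 1.82 eV (the ~0.10 eV higher photon energy of the white-light system)
and the first radical pair at the 1.715 eV reference, with the same
calibrated rates — no WL-specific halftime is claimed.

Propagation evaluates $P(t) = e^{Gt}P(0)$ with scaling-and-squaring matrix
exponentials at every point of a log-spaced grid (default 1e−13 to 1e−1 s,
400 points).  With rates spanning 8+ orders of magnitude the problem is
stiff for explicit integrators, while the matrix exponential of a 5×5
generator is exact to machine precision; population conservation holds to
~1e−15.  Halftimes are read off the population curves: formation is the
first crossing of half the global maximum, decay the first crossing after
the maximum, both interpolated linearly in log-time between grid points
(populations on a log grid are locally near-linear in log t; at the default
grid density the interpolation error is well under the 5% tolerances used
in the tests).

## The synthetic generators

`make_pigment_cluster()` builds idealized planar chlorins — Mg, four
pyrrole nitrogens at 2.05 Å, sixteen ring carbons — placed on a line at a
configurable spacing with seeded random rigid rotations, and writes a PDB
that round-trips through `read_pigments()` at file precision (1e−3 Å).
This exercises every geometry/coupling code path but does **not** emulate
real chlorophyll conformations, substituents, phytyl tails, or protein
surroundings: passing geometry tests says the operations are correct, not
that the idealized rings are realistic pigments.  Similarly the disorder
generator produces uncorrelated Gaussian site-energy noise, not the
correlated, non-Gaussian fluctuations of real trajectories, and
`make_network()` produces monotone energy ladders.  Generator defaults
(σ = 0.02 eV disorder, ~10 Å spacings, rates spanning decades) are chosen
as typical magnitudes for chlorin pigment clusters; all seeds are explicit
arguments and each generator consumes a single private RNG stream.

Test problem sizes are deliberately modest — ensembles of 2000 monomer
realizations for the disorder-width check, 25-member ensembles for
determinism, 400-point time grids — chosen so the statistical tolerances
(±10% on σ at n = 2000, 5% on halftimes) are comfortably resolved.

## Degenerate inputs and error policy

Unit columns are mandatory in every table — the inputs mix eV, cm⁻¹, nm and
mV, so nothing is unit-guessed.  Asymmetric coupling inputs are an error,
never silently averaged.  Zero-length dipole axes, sub-2 Å centre
distances, grids that do not span the sticks, spectra without local maxima,
negative rates, non-simplex initial populations, and never-populated states
all fail loudly with the offending entity named.  Pheophytins (no Mg) fall
back to the macrocycle centroid for centre distances, with the fallback
flagged on the return value.

## Limitations

* No transition-density or fragment-based coupling calculation; tabulated
  couplings are consumed, the point-dipole estimator is geometric only.
* No charge-transfer states in the exciton Hamiltonian, no vibronic
  structure, no CD spectra, no temperature-dependent lineshapes.
* The 3-site fixtures inherit the pair-energy-on-both-diagonals
  approximation described above.
* The kinetic model is a rate-table calibration with detailed balance; it
  contains no microscopic electron-transfer parameters beyond the optional
  Marcus constructor.
* Single-structure geometry only: ensemble-averaged inter-pigment distances
  from dynamics are out of scope, so dynamical quantities (hydrogen-bond
  occupancies, water exchange) are not modelled.
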