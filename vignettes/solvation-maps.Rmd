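---
title: "Methods: integral-equation and grid-based solvation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integral-equation and grid-based solvation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
approximations involved, and the numerical and design choices that a user
or maintainer should know about. Everything quantitative asserted here is
computed by the test suite or the acceptance script; nothing is quoted
from elsewhere.

## 1. The two routes to a solvation map

Both routes produce voxel maps on cubic grids: local densities of water
occupancy, solvation energy and entropy around a rigid solute.

**Integral-equation route.** The 3D reference interaction site model
(3D-RISM) treats the solvent as site density fields. Given the bulk
solvent's site–site susceptibility χ_αγ(k), the convolution equation
h_α = Σ_γ c_γ ∗ χ_αγ plus a closure determines per-site total (h) and
direct (c) correlation functions on the grid. No configurational sampling
is involved; the price is the approximate closure.

**Explicit-water route.** Grid inhomogeneous solvation theory (GIST)
estimates the same quantities from rigid-water configurations: each water
is assigned to the voxel containing its oxygen, and voxel statistics
(counts, orientations, pairwise energies) are turned into densities. The
price here is sampling noise and the truncation of the entropy expansion
at first (single-body) order.

The package implements both, on deliberately identical grid conventions
(half-open cubic voxels, origin at the first voxel *center*, centers on a
common lattice via `alignGrid()`), so the maps subtract cleanly.

## 2. The solvent model

`buildCTIP3P()` constructs a rigid three-site water: TIP3P geometry
(L_OH = 0.9572 Å, H–O–H = 104.52°), TIP3P charges (q_O = −0.834 e) and
oxygen Lennard-Jones parameters (σ_O = 3.1507 Å, ε_O = 0.1521 kcal/mol),
temperature 298 K, density 55.345 mol/L, target dielectric 78.497. Site
theories need a repulsive core on *every* site — a bare-proton hydrogen
lets the O–H Coulomb attraction collapse — so the hydrogens carry a
Lennard-Jones diameter tied to the geometry, σ_H = σ_O − 2 L_OH =
1.2363 Å, which puts the hydrogen core surface at the hydrogen-bond
contact distance. The hydrogen well depth is not fixed by that argument;
the default ε_H = 0.0152 kcal/mol is an implementer's choice of the size
commonly used for such cores, exposed as an argument.

Units throughout: Å, kcal/mol, K, elementary charges; k_B =
0.0019872041 kcal/mol/K, Coulomb constant 332.0637 kcal·Å/mol/e²;
β = 1/(k_B T).

The intramolecular correlation ω_αγ(k) is a sum of spherical shells over
the positions of site type γ as seen from one position of α:
ω_OH = 2 j₀(kL_OH), ω_HH = 1 + j₀(kL_HH). For an equivalent pair the
self-term is the single δ-function — ω_HH(0) = 2 = M_H comes out right
only with 1 + j₀, not 2δ.

## 3. Bulk water: DRISM

The 1D stage iterates the site–site Ornstein–Zernike relation in the
symmetric structure-factor form S = (I − S_ω C)⁻¹ S_ω per wavenumber,
where S_ω,αγ = ρ_α ω_αγ. Storing S (symmetric; the package's tests verify
it) avoids the convention ambiguity of χ_αγ = ω_αγ + ρ_γ h_αγ, which for
unequal site densities satisfies only ρ_α χ_αγ = ρ_γ χ_γα; the 3D stage
consumes χ_αγ = S_αγ/ρ_α.

**Dielectric consistency.** An interaction-site fluid with intramolecular
charge constraints realises a trivial dielectric constant unless the
theory is corrected. The bridge used here adds a long-range dipolar term
to the intramolecular structure factor,

S̃_ω = S_ω + ρ² h_c(k) D_α(k) D_γ(k),  D_α(k) = Σ_positions j₀(kx) j₀(ky) j₁(kz),
h_c(k) = h₀ exp(−k²/(4a²)),

in a molecular frame with the dipole along +z. A small-k expansion of the
charge-weighted structure factor (worked out from scratch for this
implementation, via a Sherman–Morrison argument that also shows the
result is independent of the closure) gives the realised dielectric
ε = 1 + 3y + y ρ h₀ with y = (4π/9) β C ρ d², so

h₀ = (ε_target − 1 − 3y)/(y ρ)

imposes the target exactly in the k → 0 limit. The envelope parameter
defaults to a = 0.5 Å⁻¹; it controls how far into k the bridge reaches
and only affects sub-leading structure, which is why it is configurable
but undocumented by any physical constraint. The realised value is
*recomputed* from the converged correlations by quadratic extrapolation
of q'Sq/k² over the smallest wavenumbers — this closes the loop and is
the package's headline acceptance check (78.497 to within 0.1%).

**Numerics.** Radial grids pair r_i = i·dr with k_j = j·π/((n+1)dr), on
which the type-I discrete sine transform is orthogonal (round-trip exact
to machine precision; tested at 1e-10). The Coulomb part of c is carried
analytically as −βq_αq_γ·erf(r/s)/r asymptotics (s = 1 Å default), so
only short-range functions live on the grid. Convergence is by MDIIS
(10 stored vectors, step 0.7, subspace flush when the residual exceeds
10× the best seen), with a KH → PSE-2 → PSE-3 closure ladder, each rung
warm-started. The production grid is 16384 × 0.025 Å at a residual of
1e-12 (the acceptance script); the test suite uses 4096 × 0.05 Å at
1e-10, which reproduces the dielectric and first-shell structure —
doubling the point count at fixed extent moves h by less than 1e-4.

The isothermal compressibility comes from the k → 0 compressibility
relation ρk_BTχ_T = 1/(1 − ρ Σ_αγ M_αM_γ ĉ_αγ(0)), with ĉ(0) by quadratic
extrapolation (agrees with the smallest-k value to 1%; the analytic
Coulomb parts cancel by charge neutrality).

## 4. The 3D solver

The solute enters through per-site potential grids u_α(r): direct
summation over all atoms (no cutoff), Lorentz–Berthelot mixing,
singularities capped at 1e10 kcal/mol so that exp(t\*) underflows cleanly
to zero inside the core. For charged solutes c_α splits into a grid part
plus the analytic −βq_α φ_erf(r) long-range part built from the
erf-smeared solute potential.

The fixed point of the convolution equation plus closure is found in
reciprocal space (radial χ interpolated onto the 3D |k| lattice by a
cubic spline with the small-k points mirrored through the origin, since
S(k) is even), again with MDIIS and the closure ladder. The solver
refuses grids that put the solute within `minBuffer` of an edge, and
aborts with history if the residual rises over a 50-iteration patience
window.

Grid conventions follow the production protocol: 0.5 Å cubic voxels and a
24 Å buffer by default; the test fixtures use 6–10 Å buffers and
sometimes finer spacings, chosen for speed and flagged as such in the
helpers. Origins are aligned so voxel centers sit on the spacing lattice
(ties in the center rounding go toward −∞), which makes map truncation
exact index slicing — never interpolation.

Properties verified in the suite: the u ≡ 0 bulk fixed point is exact;
g ≥ 0 everywhere (closure guarantee); whole-voxel translations of the
potential translate the solution exactly (discrete covariance, 1e-10);
FFT convolution equals direct-space convolution on 8³ grids to 1e-10.

**Discretisation accuracy.** For a spherical solute the solution should
be spherically symmetric and grid-converged. Both are resolution-limited
at the production spacing: the suite measures the scatter of g_O across
voxels of equal |r| and the deviation of coarse-grid shell means from a
refined-grid reference (comparing at the coarse grid's own voxel radii,
which removes binning bias). Anisotropy shrinks roughly quadratically
with the spacing; the first-shell radial profile at 0.25 Å spacing still
differs from a 0.125 Å reference at the few-1e-3 level, so map values at
sub-1e-3 absolute accuracy require finer grids than the defaults. The
acceptance block records this as a known, measured limitation rather than
loosening its stated bound.

## 5. Temperature derivatives and thermodynamic maps

The entropy route needs δ_T h and δ_T c (δ_T = T(∂/∂T)_ρ). The default
is central finite differences of full re-solves at T ± ΔT (ΔT = 1 K) with
*temperature-consistent* bulk susceptibilities — the 1D stage is re-solved
at the shifted temperatures too (the imposed dielectric is held at its
298 K value; the model has no temperature-dependent dielectric). A
linearised ("analytic") mode solves the first-order equations
δĥ = Σ (δĉ χ + ĉ δ_Tχ), δh = g′(t\*)(βu + δh − δc) directly, with δ_Tχ
still from central differences of the 1D solve; the two modes agree on
the test fixture to better than 1e-3 relative, and step-halving of the FD
mode shows the expected ΔT² convergence (error ratio ≈ 4).

Maps follow the closure functional (Section "The model in brief" of the
README): the Heaviside factor of the truncation term is applied on
t\* ≥ 0 by default — the region where the series branch of the closure is
active. The printed convention in the source literature uses Θ(h); on a
*converged* state the two coincide wherever the closure holds exactly,
and both variants are selectable (`theta = "tstar"` or `"h"`) so the
difference can be inspected on non-converged iterates. The identities
Δμ = ΔE + (−TΔS) (1e-10) and ΔE = ΔE_sw + ΔE_ww (1e-12) hold pointwise by
construction and are asserted, along with the bulk limit (all maps vanish
when u ≡ 0) and decay of all fields below 1e-3 of their maximum at the
grid edge on the neutral fixture (dipolar solutes decay more slowly and
need larger buffers).

**Partial molar volume and UCT.** v = k_BTχ_T(1 − Σρ_γ∫c_γ) by midpoint
quadrature. The local map distributes only the c-term,
v(r) = −k_BTχ_T Σρ_γc_γ(r), with the constant "1" carried as a scalar
offset: only the direct-correlation term has unambiguous spatial
structure, so smearing the constant onto voxels would manufacture
structure that is not there. The UCT correction (a = a₁T + a₀,
b = b₁T + b₀) is applied to the summed maps linearly in v(r) and δ_Tv(r);
b₀ and b₁T carry no spatial structure and enter the totals only. The
built-in parameter set is carried verbatim as an input (fitting UCT
parameters is out of scope). One measured caveat: with these parameter
magnitudes the per-voxel correction is proportional to roughly
20 kcal/mol per unit of local v, and c(r) — hence v(r) — is still of
order one across the repulsive wall where g_O rises from 0 to 1. The
correction is therefore *not* negligible relative to the field maximum
immediately outside a g_O > 0.5 cut on a small apolar solute; it only
becomes so beyond the first solvation shell. The acceptance block states
the stricter expectation and is allowed to record the measured violation;
corrected maps are deliberately not molecularly reconstructed.

## 6. Molecular reconstruction

A(r) ≈ A_O(r) + g_O(r)(ω_OH ∗ A_H)(r) collapses hydrogen-site maps onto
the oxygen distribution. The kernel is evaluated analytically in
reciprocal space (M·sin(kL)/(kL)) — a rasterised real-space shell would
be anisotropic at 0.5 Å — and the direct-space shell is used only as a
test oracle (mass conserved within 1%, peak at the bond radius).
Contributions inside the excluded volume are zeroed on both terms; the
threshold g_O < 1e-3 is configurable, and results are insensitive to it
within an order of magnitude because g_O falls through that range over a
single voxel at the core wall. Reconstruction is linear at fixed g_O and
conserves ∫A_O + M_H∫A_H in the bulk limit (tested exactly).

Because the kernel uses only intramolecular distances, non-local
contributions entering through c(r) (water–water energy, entropy) are
not relocated; the solute–water energy, a local quantity, reconstructs
best. On the water-as-solute fixture the suite checks the qualitative
effect that motivates the method: at the ±1 kcal/mol/Å³ display level the
reconstructed solute–water energy map has strictly fewer positive voxels
than the additively combined site map — the alternating O/H sign
structure merges into molecule-shaped lobes. A far-field caveat: the
additive map cancels the solute's electrostatic far field exactly by
charge neutrality, while the reconstruction multiplies the spread
hydrogen map by g_O before adding, leaving low-amplitude long-range
residuals (the shell average of a harmonic potential is exact in the
continuum, but the periodic grid is not); lobe comparisons should
therefore be made at physically meaningful iso levels, not at the noise
floor.

## 7. GIST

Waters are assigned to half-open voxel boxes by oxygen position; the
voxel's properties include all three sites of its waters.
Translational entropy density is −k_Bρ⁰ g ln g with the x ln x → 0
convention for empty voxels. Orientational entropy uses unit quaternions
of the rigid-body frame; the default estimator is nearest-neighbour
(k = 1 Kozachenko–Leonenko) with the quaternion geodesic distance
2·arccos|q₁·q₂| (the absolute value handles the double cover) and the
SO(3) ball measure (d − sin d)/π, with the Euler-characteristic-free
bias correction γ. An Euler-angle histogram estimator (12³ equal-measure
bins) is the cross-check. The nearest-neighbour distance is clamped at
1e-12, which sets the estimator floor for degenerate (identical)
orientations; that floor recedes like log(n − 1), so degenerate voxels
report very large, n-dependent penalties — flagged behaviour, not a
physical number. Voxels with fewer than `minOrientSamples` (default 20)
orientation samples are flagged and excluded.

Energies are per-frame pairwise sums (three-site LJ + Coulomb, no
cutoff, no periodic images — the synthetic frames are open-box): the
solute–water term is the full interaction of the voxel's waters with the
solute; the water–water term takes half of each pair per partner and
subtracts a configurable per-water bulk reference E_bulk (default 0,
reporting raw half-sums). A hand-evaluated two-water dimer is the energy
oracle.

## 8. What the synthetic generator does and does not emulate

`makeFrames()` produces rigid waters with exact model geometry under
three statistical models: ideal gas (uniform positions, quaternion-uniform
orientations — the null for every estimator), half-box (a step in
density — known g = 2 and g ln g recovery), and localized (Gaussian
positions, orientations concentrated about a reference with density
∝ exp(κ cos θ)(1 − cos θ) sampled by numeric inverse-CDF, so the
orientational KL divergence has a closed quadrature oracle). Orientation
uniformity is itself tested (Rayleigh-type statistic on S³ at n = 1e5).

None of these emulate liquid-water structure: there are no intermolecular
correlations, no hydrogen-bond network, no realistic energy distributions.
Passing GIST tests on them demonstrates estimator correctness (parameter
recovery, convergence rates ∝ 1/√n_frames), not fidelity on real
trajectories; conversely the energies on such frames are exactly the
pairwise force-field sums, which is what makes the oracles exact.

## 9. Problem sizes and runtimes used by the suite

The test suite solves: bulk water at 4096 × 0.05 Å (seconds); LJ-sphere
3D states at 0.5 Å/10 Å buffer, 0.25 Å and 0.125 Å/8 Å (the last ≈ 2–3
minutes, used once for the refinement oracle); a water-as-solute state at
0.5 Å/10 Å; GIST runs of a few hundred frames × a few hundred waters.
These sizes were chosen so the full suite completes in well under half an
hour on one CPU while still exercising every production code path; the
acceptance script runs the bulk stage at full production resolution
(16384 × 0.025 Å, 1e-12).

## 10. Known limitations

* Open-boundary electrostatics are approximated by periodic FFT
  convolution with a buffer; strongly charged solutes need larger buffers
  than the neutral test fixtures.
* Pure solvent only (no salt), rigid solutes, rigid solvent; no
  temperature-dependent target dielectric.
* Entropy from GIST is first-order only; 3D-RISM entropy contains all
  orders but inherits closure error. Neither side is a reference for the
  other on entropy.
* The grid-refinement and UCT-locality acceptance bounds are stricter
  than what the method delivers at desk-scale resolutions; the suite
  keeps the strict bounds and documents the measured values instead of
  relaxing them.
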