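---
title: "Boosted sampling, reweighting and membrane statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosted sampling, reweighting and membrane statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`amdtk` implements the analysis chain used around accelerated molecular
dynamics (aMD) studies of helical membrane-active peptides — boosting,
reweighting, dihedral-PCA free-energy landscapes, Kullback–Leibler
convergence diagnostics, and the standard membrane/pore estimators — on
synthetic systems whose ground truth is known exactly. This vignette is the
package's own account of the models, the tunable parameters, the numerical
choices, and what the validation does and does not demonstrate.

## The aMD boost and its parameterisation

aMD flattens energy barriers by raising the potential wherever it falls
below a threshold `E`:

$$\Delta V(V) \;=\; \frac{(E - V)^2}{\alpha + E - V} \quad (V < E), \qquad
\Delta V = 0 \;\; (V \ge E).$$

The boost is non-negative, continuous with a continuous first derivative at
`V = E`, and monotone decreasing in `V` below the threshold; `alpha`
controls how aggressively the landscape is levelled. Forces on the boosted
surface follow by the chain rule, $dV^*/dV = \alpha^2/(\alpha + E - V)^2$,
which `run_langevin()` applies analytically (and the tests verify against
finite differences).

In dual-boost aMD the dihedral term receives its own boost and the total
potential (including the already-boosted dihedral energy) a second one.
`compute_boost_parameters()` sets the four constants from unboosted
calibration averages plus system-size terms: the dihedral threshold grows
with the residue count at a per-residue coefficient (the conventional
4–4.5 kcal mol⁻¹ per residue, with `alpha_dihed` one fifth of that term),
and the total threshold grows with the atom count at a per-atom coefficient
(0.16–0.20 kcal mol⁻¹ per atom, with `alpha_total` equal to that term).
Assigning the per-residue coefficients to the dihedral term and the
per-atom coefficients to the total term follows standard aMD practice; it
is the only assignment under which the magnitudes of the two coefficient
families make dimensional sense. In the toy engine the "dihedral energy" is
a designated fraction of the toy potential (`dihedral_fraction`), so the
dual-boost code path is exercised even in one dimension, where it
degenerates to a total-only boost when the fraction is 1.

## The Langevin engine and the double-well closure study

The engine is a single-particle BAOAB Langevin integrator in
(kcal mol⁻¹, Å, ps, g mol⁻¹) units, with `kT = 0.0019872 × T` and the
acceleration conversion 418.4 Å² ps⁻² per kcal mol⁻¹ Å⁻¹ per g mol⁻¹.
The closure study uses the quartic double well
$V(x) = 5[(x)^2 - 1]^2$ kcal mol⁻¹ at 300 K — a barrier of 8.4 kT —
with mass 10 g mol⁻¹, friction 5 ps⁻¹ and a 4 fs step (`ω·dt ≈ 0.16` at
the well frequency, comfortably stable for BAOAB), 10⁶ steps, frames saved
every second step. Boost parameters `E = 5.2`, `alpha = 5` kcal mol⁻¹
place the threshold just above the barrier and raise the wells by
≈ 2.6 kcal mol⁻¹, which multiplies the hopping rate by roughly `e^{4.4}`;
a matched unboosted run crosses a handful of times, the boosted run a few
hundred.

Two honesty points about the unboosted Boltzmann check. First, the
Kolmogorov–Smirnov test requires (approximately) independent samples, so
`boltzmann_ks_test()` decimates the coordinate series at twice the first
autocorrelation crossing below 0.05; at an 8.4 kT barrier the effective
sample count equals the number of well visits (single digits per 10⁶
steps), so the test has little power — which is precisely the sampling
problem boosting exists to solve, and why the reweighting closure, not the
KS test, is the stringent check. Second, a histogrammed PMF estimator must
be compared with the analytic PMF *binned the same way*
(`analytic_pmf_binned()`, the per-bin Boltzmann probability by quadrature):
on the steep outer walls the point value of `V` at a bin centre differs
from the bin average by several tenths of kT, a property of the reference,
not of the estimator.

## Reweighting

`frame_weights()` implements the per-frame estimators
($w = e^{\beta\Delta V}$ exactly, or its Maclaurin series truncated at
`K`, default 10 — the truncation approaches the exponential from below and
is the conventional noise-suppressing compromise), and `reweighted_pmf()`
additionally provides the second-order cumulant correction, which is
bin-level by construction:
$p_i \propto n_i \exp(\beta\langle\Delta V\rangle_i + \tfrac{1}{2}\beta^2\sigma_i^2)$,
exact when the in-bin boost distribution is Gaussian (a property the tests
verify on a synthetic Gaussian-boost construction). Defaults: 50 bins in
1-D, 60×60 in 2-D; empty bins are reported as missing PMF, never as zero
energy; the minimum is shifted to zero; β uses 300 K unless the scheme says
otherwise. With the study's boost (`β ΔV ≤ 4.5`) the K = 10 truncation is
within a fraction of a percent of the exponential, so the two estimators
give nearly identical landscapes — at much larger boosts the truncated
series deliberately underweights the deepest minima, a known property of
the method, not a defect of the implementation.

## The synthetic two-state peptide

The peptide generator emulates a 20-residue helical peptide with a central
glycine hinge (residue 11) that interconverts between a bent hairpin-like
helix and a straight helix. Geometry is built in internal coordinates
(ideal bond lengths/angles, ω = 180°; helical φ = −57°, ψ = −47°); the
bend is produced by interpolating the hinge-region torsions (ψ of residues
10–11, φ of residues 11–12) toward a turn-like pair, with the scalar
interpolation parameter solved by root-finding so that the terminal CA–CA
distance hits the requested target (10 Å bent by default). This keeps both
arms rigid ideal helices joined at a hinge of valid geometry, and gives
the two states a genuine dihedral-space signature, so dihedral PCA and
clustering have something real to find. The default linear state is the
unbent ideal helix (CA1–CA20 ≈ 29.8 Å = 19 × 1.57 Å effective rise); real
helical peptides of this length read closer to 25 Å because of terminal
fraying, which this surrogate intentionally does not model — an explicit
`linear_target` is honoured by the same hinge solver if that behaviour is
wanted.

Each frame is an independent Bernoulli draw (`p_bent`, default 0.8, which
places the linear basin `kT ln 4 ≈ 0.83` kcal mol⁻¹ above the bent one at
300 K — "accessible within about one kcal mol⁻¹"), plus isotropic Gaussian
coordinate noise (default σ = 0.15 Å, i.e. φ/ψ jitter of roughly 20°,
commensurate with thermal backbone fluctuations). Frames are independent
draws from the mixture, *not* dynamics: tests of basin free energies
against the binomial oracle are exact by construction, but nothing here
validates kinetics, autocorrelation, or barrier heights along the physical
path — on real trajectories those quantities come from the reweighting
chain, not from the generator.

## Dihedral PCA, clustering, Kabsch RMSD, KLD

`dihedral_pca()` uses the standard sin/cos embedding of each φ/ψ angle
(removing the undefined terminal columns), column-centred SVD; explained
variance fractions sum to one by the trace identity. `cluster_conformations()`
is k-means on the leading PCs (default 2) with 10 restarts under a fixed
seed — the cluster count is an input, as in the usual workflow where 3- or
10-cluster decompositions are chosen by the analyst. Representatives are
the frames nearest their centroid. `superpose_rmsd()` is the Kabsch SVD
superposition with the determinant correction enforcing a proper rotation;
tests check identity, rigid invariance, symmetry, a displaced-atom
construction against exhaustive numeric minimisation over rotations, and
agreement with the independent `bio3d` implementation.

`kld_divergence()` estimates KLD(P‖Q) = Σ p ln(p/q) between two projection
samples on 100 shared bins spanning the pooled range with a mandatory
additive pseudo-count of 10⁻⁶ per bin (without it, disjoint supports give
infinity); a Gaussian-KDE backend is provided as well, and on the synthetic
two-run tests both backends must return the same convergence verdict.
`kld_convergence()` compares the distributions accumulated over `[0, t]`
for growing `t` on a common PC basis (fit the basis on the concatenated
runs), and reports the first window from which the divergence stays below
the threshold, default 0.025 — the conventional cutoff for declaring two
independent simulations converged. Two estimator properties worth knowing:
the plug-in histogram KLD carries a positive finite-sample bias of order
(bins)/(2n), so identical distributions read ≈ 0.012 at n = 4000 and the
threshold verdict is only meaningful once windows hold a few thousand
frames; and the binned estimator is a lower bound on the continuous
divergence (data-processing inequality), so the Gaussian closed-form check
(offset = σ ⇒ KLD = ½) is run at n = 10⁵ where both effects are inside the
Monte-Carlo error.

## The synthetic membrane, pore and waters

`make_membrane_system()` is a statistical surrogate, not chemistry. Lipids
are rigid all-trans zigzag chains (C–C 1.54 Å, 111°) plus a head bead; each
lipid in each frame draws an independent tilt from the one-parameter
axially symmetric family p(cos β) ∝ exp(λ P₂(cos β)), with λ solved
numerically so that the reconstructed C–H order parameter matches the
target: for a chain tilted by β with uniform azimuth and spin, the
addition theorem gives ⟨P₂(cos θ_CH)⟩ = −½⟨P₂(cos β)⟩, so a target
|S_CD| = 0.16 (the plateau value typical of a disordered mixed bilayer)
requires ⟨P₂(cos β)⟩ = 0.32. `scd_profile()` reconstructs the two C–H
directions per interior carbon from the united-atom geometry
(perpendicular to the C(i−1)–C(i+1) axis, tetrahedral split about the
bisector) and averages 0.5⟨3cos²θ − 1⟩ over lipids, frames and hydrogens;
the recovered signed value is negative, as for real acyl chains, and the
magnitude is reported per carbon.

Waters perform an exact Brownian walk — Gaussian increments of variance
2DΔt per axis per frame, default D = 0.03 Å² ps⁻¹, stored unwrapped — so
the MSD estimator has exact ground truth. `msd_diffusion()` averages over
multiple time origins (default spacing 10 ps), fits the slope on the
10–50 % lag window, reports `D = slope × 10.0/(2N)` (the field's
convention, which lands in 10⁻⁵ cm² s⁻¹ when the slope is in Å² ps⁻¹)
alongside the raw Å² ps⁻¹ value, rejects wrapped coordinates (jumps larger
than half the box) with an unwrap hint, and flags ballistic motion by a
log–log slope near 2. The conversion constant is reported without
endorsing any particular literature value of D itself.

The pore is a static cylinder of wall beads (default R = 11 Å, rings every
1.5 Å, wall vdW 1.5 Å). `pore_radius_profile()` finds, per z-slice, the
largest clearance `max_grid min_atoms (‖x − x_a‖ − vdW_a)` over a
deterministic in-plane grid of 0.25 Å spacing centred on the slice
centroid (a stochastic-search tool would give the same numbers without the
reproducibility); slices with no atoms in the ±4 Å shell return the search
cap and are flagged. The cylinder's analytic free radius is
11 − 1.5 = 9.5 Å and the estimator must land within the grid resolution.
`pore_water_count()` counts water oxygens within 3.4 Å of any pore atom
and is required to agree exactly with an independently written brute-force
double loop on every tested frame. `water_grid_density()` histograms water
oxygens on a 1 Å grid (grid sum = mean waters per frame) and writes OpenDX
text readable by VMD. `electron_density_profile()` histograms per-atom
electron counts along z per role group; the profile integrates back to the
group's total electron count, and the total equals the sum of the groups
bin-wise.

`percent_helicity()` uses a dihedral-window criterion — a residue is
helical when (φ, ψ) ∈ [−100°, −30°] × [−67°, −7°] — rather than a
hydrogen-bond (DSSP-style) assignment; the window is configurable and the
choice matters mainly for noisy backbones, where window criteria read
lower than H-bond criteria. `bend_angle()` fits principal-axis directions
through the residue centres of mass of the N- and C-terminal windows
(default 5 residues each), orients both away from the chain midpoint, and
reports the angle between them, so a straight helix reads ≈ 180° and
bending *decreases* the angle; with this orientation convention the least
helical, most bent monomers have the smallest bend angles. Degenerate
(zero-extent) windows return NA rather than an arbitrary direction.

`field_convert()` links the applied-field unit kcal (mol Å e)⁻¹ to V nm⁻¹
through 4184 J mol⁻¹ / Faraday = 0.043364 V Å⁻¹ per unit, and to a
transmembrane potential across a stated thickness: 70 mV across 3.5 nm is
0.02 V nm⁻¹, and a field of 0.080 kcal (mol Å e)⁻¹ is 0.0347 ≈ 0.03 V nm⁻¹.

## Problem sizes and numerical choices

The validation studies use: 10⁶ Langevin steps for the double-well closure
(≈ 25 s); 4 000 frames of the two-state peptide for the conformational
suite; 60 waters × 8 000 frames for diffusion recovery; 64 lipids × 400
frames for the order parameter (standard error ≈ 0.002, against the
±0.01 requirement); 2 frames for the static pore geometry. Seeds enter
every generator explicitly and are recorded in output headers; identical
seeds give bit-identical outputs. Ties and degenerate inputs are handled
as follows: single-occupied-bin PMFs are flat-flagged; zero-variance PCA
inputs return all-zero projections; k exceeding the number of distinct
points is rejected; broken backbone residues are flagged NA with a
warning, not an error.

## What passing these tests does and does not show

Passing shows the estimators are correct as estimators: each recovers the
parameter its generator planted, within pre-stated tolerances, and the
boost/reweight loop closes against an analytic landscape. It does not show
anything about force-field accuracy, lipid chemistry, peptide kinetics, or
the absolute values of membrane observables in any real system — the
generators are statistical surrogates with independent frames, ideal
geometry and no interactions between components. Real-data numbers (pore
occupancies in the hundreds, µs-scale cluster structures, absolute
diffusion constants) depend on trajectories this package does not attempt
to regenerate.
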