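---
title: "Models and methods behind grooveflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grooveflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grooveflow)
```

grooveflow analyzes the conformational cycle of the hydrophilic,
membrane-facing groove of TMEM16-family lipid scramblases. The groove can
be exposed to the membrane (lipid-conductive), occluded from it by a
repositioning of TM4 against TM6 (an intermediate that can still conduct
ions), or closed. This vignette documents the models implemented, the
parameters that matter, the numerical choices, what the synthetic
generators do and do not emulate, and the package's known limitations.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Geometric substrate

Structures are atom tables parsed from fixed-width PDB or whitespace PQR
records. Alternate locations collapse to the highest-occupancy conformer
(ties to altloc "A") so all geometry is single-conformer and
deterministic. Hydrogens are kept on read but excluded by every "heavy"
atom class, which lets one code path serve both deposited models (no H)
and MD-derived frames (with H). Van der Waals radii come from a built-in
Bondi-style element table (overridable); PQR radii take precedence when
present. For glycine, `sidechain_heavy` selections fall back to Cα — the
sidechain terminus convention — instead of erroring, and the fallback is
logged. Coordinates are Å throughout; the membrane normal is +z; the
channel coordinate is zeroed at the Q436 Cα whenever that residue exists
in the analyzed chain.

Superposition uses the Kabsch SVD construction with a determinant
correction, so rotations are always proper. `region_rmsd` superposes
exactly the named atoms and by default errors on residues missing from
either structure; `on_missing = "trim"` restricts to the common residues,
which is required when comparing against cryo-EM models with unresolved
segments. The whole-TM helix ranges used for such comparisons are not
published alongside the RMSD figures they support, so
`tm_helix_ranges()` ships editable defaults derived from the X-ray
structure's helix annotations; they are config, not ground truth.

## Groove features and state labels

Five distances carry the slow conformational signal: minimal heavy-atom
T333–Y439 and Y439–R432 distances, E313–R432 and E318–R432 under a
Glu-O×Arg-N rule, and the V337–V447 Cα–Cα distance. "Carbonyl oxygen of
Glu" is chemically ambiguous (backbone O vs the carboxylate); the default
is the sidechain carboxylate pair OE1/OE2 — the atoms that actually form
the extracellular-gate salt bridges — with `glu_oxygens = "backbone"`
available; the choice is never silently reinterpreted.

State labels are pure threshold functions: occluded iff the Cα–Cα
distance is ≤ 8.5 Å (the boundary value classifies as occluded, a
documented tie rule), TM3/TM4 engaged iff the minimal L302–I343 distance
is ≤ 3.5 Å, direct V337/V447 contact iff their minimal distance is
< 2.5 Å (strict, matching the "< 2.5 Å" phrasing). Water membership uses
an inclusive 3 Å rule against the sidechains of the 34 groove-lining
residues; lipid head/tail penetration uses an inclusive 5 Å rule against
the 9 interior residues, normalized by the total non-hydrogen atoms of
head or tail. The head/tail split for real phospholipids follows the
glycerol/carbonyl boundary; the built-in toy lipid uses 2 labelled head
and 8 tail pseudo-atoms to exercise the same normalization. The
T381/Q436 slab count is one operation with a region-name parameter
because the literature calls that slab both the "extracellular vestibule"
and the "central region"; the plane residues are recorded in the output.
Distances are computed without periodic wrapping: deposited models and
toy fixtures are not periodic, and MD input is assumed imaged.

## tICA

Given mean-free features X(t), the instantaneous covariance
C = ⟨XXᵀ⟩ and the lagged covariance C_TL(τ) = ⟨X(t)Xᵀ(t+τ)⟩ define the
generalized eigenproblem C_TL V = C V Λ whose leading eigenvectors are
the slowest linear coordinates. Numerical choices: C_TL is symmetrized
(guaranteeing a real spectrum — standard practice the source analyses
leave implicit); the problem is solved by whitening with truncation of
C-eigendirections below 1e-8 of the largest (stability under collinear
features); eigenpairs are sorted by descending eigenvalue with the
largest-magnitude loading of each eigenvector made positive (a
deterministic sign). Multiple trajectories — including the two protomers
of a dimer, which are analyzed separately — contribute (t, t+τ) pairs per
trajectory only, never across boundaries. The lag τ is not a published
constant; the default is 50 frames and every output echoes it.

Microstates are k-means with k-means++ initialization under an explicit
seed (the discretization algorithm behind the published landscapes is
delegated to prior work and unspecified; k-means is the simplest
reproducible choice, default k = 8 to match the number of discussed
microstates, and clusters are reported by population rank because any
mapping to published microstate numbering is presentation-dependent).
The 2D landscape is a normalized histogram with −ln p masked at empty
bins.

On the two-state synthetic world the leading eigenvalue estimates
exp(−(k12+k21)τ). Two statistical points the tests account for
explicitly: (i) the white-noise criterion band 3/√T is a per-direction
3σ band, while the leading tICA eigenvalue maximizes over d directions
and therefore sits near that band in any single realization (about
2.6/√T on average for d = 5); the acceptance test checks the mean over
five canonical replicates against the stated band rather than gambling
on one draw. (ii) Emission noise attenuates the leading eigenvalue by
a = q/(1+q) with q = ¼·Σ(Δᵢ/σᵢ)² (state separation over noise; ≈ 0.9921
for the default generator), so the implied timescale τ/(−ln λ₁) carries
a noise floor of −ln a ≈ 0.0079. Where the signal 2kτ dwarfs that floor
the plain 1/(2k) recovery band holds; at the extreme setting
k = 0.001/frame with τ = 10 the floor alone biases the timescale by
~30%, and the property test checks the attenuation-corrected closed
form τ/(2kτ − ln a) there instead — with medians over replicate series,
because ~400 effective samples leave single-run scatter comparable to
the band.

## Pore profiling

At each slice z along the channel axis the profiler maximizes
r(c) = min_i(|c − x_i| − R_i) over in-plane centres c, i.e. the largest
sphere that fits without entering any vdW sphere — the same objective as
the classic sphere-probe (HOLE) method. The optimizer is multi-start
Nelder–Mead (8 seeded random restarts around the previous slice's
centre) rather than the original Monte-Carlo annealing: the same
objective, reproducible under a seed. Default step 0.25 Å. Because the
exact radius set and sampling of the published profiles are unavailable,
comparisons against printed values carry a documented ±0.2 Å tolerance;
comparisons in this package's tests are against constructed toys
(analytic by ring geometry) and an exhaustive 0.1 Å grid oracle. For toy
pores built from atom rings, the honest analytic reference between ring
planes is the nearest-ring clearance min_i √(R_i² + (z − z_i)²) − a, not
the smooth-surface formula R(z) − a; `analytic_pore_radius()` implements
the former, and the distinction matters wherever the wall slope is
appreciable. The pore region used to mask electrostatics exports is all
grid points within the profiled radius at their height and farther than
2.5 Å from every atom.

## Electrostatics

The linearized Poisson–Boltzmann equation ∇·(ε∇φ) − ε_w κ² φ = −4πρ
(Gaussian units; Å, e; φ converted to kcal/(mol·e) via 332.0637) is
discretized with node-centred ε, harmonic-mean face dielectrics,
trilinear charge spreading, and solved by SOR with a near-optimal
relaxation factor. Dielectric geometry: protein interior (vdW-inflated
atoms; no solvent-excluded surface — simpler and deterministic at
ε_P = 2) at ε = 2; a membrane slab of 26 Å hydrophobic core (ε = 2)
flanked by 8 Å headgroup bands (ε = 30); an 18 Å-radius solvent cylinder
(ε = 80) about the groove axis overriding the slab. Mobile ions
(150 mM monovalent by default) are excluded from the protein and the
membrane bands but allowed in the cylinder and bulk; κ comes from the
Debye length at a configured temperature (default 298.15 K — the source
calculations do not state one). Boundary faces carry the
Debye-screened Coulomb sum of the source charges. Convergence is a max
per-sweep update below tolerance (default 1e-4 kcal/(mol·e)); failure to
converge is an error carrying the residual history. Default spacing
0.8 Å, padding 15 Å.

The solver is verified against the Coulomb and Debye–Hückel closed forms
(within 5% on the 5–15 Å shell at 0.5 Å spacing), linearity and
charge-scaling identities, grid-refinement monotonicity, and screening
monotonicity in ionic strength. Because the published potentials used a
force-field charge set and grid parameters that are not reproducible
here, comparisons to published potential figures are qualitative
(sign and shape along the pore axis) and are not numeric targets. A
minimal bundled charge convention (formal charges) exists for structures
without PQR input; it is a stand-in, not CHARMM.

## Scrambling-assay kinetics

After dithionite addition, protein-free liposomes quench as
L + (1−L)e^{−γt}; proteoliposomes follow the coupled
reduction/flipping system

dF_out/dt = −(γ+β)F_out + αF_in, dF_in/dt = βF_out − αF_in,

started from the scrambling steady state (α, β)/(α+β), whose closed form
is the published biexponential with λ₁λ₂ = αγ and λ₁+λ₂ = −(α+β+γ); the
total signal mixes the pools by f0 and satisfies F(0) = 1 identically.
Note the rate-labelling consequence of that eigenstructure: α is the
rate replenishing the outer leaflet (in→out). Degenerate branches are
handled analytically with an ε-switch (default 1e-8/s): as α→0 the pool
starts all-inner and never decays (F → f0(L+(1−L)e^{−γt}) + (1−f0));
as β→0 it starts all-outer and decays as a single e^{−γt} (in both
cases the printed closed form divides by a vanishing D(α+β)); a repeated
eigenvalue uses the defective-matrix solution e^{λt}(I + (A−λI)t).
Branch continuity at the switches is tested to 1e-6.

Fitting is bounded nonlinear least squares over (f0, α, β) with L and γ
fixed (they are experimentally determined quantities), multi-start with
the best SSE kept. The parameters are optimized through a smooth
scaled-logistic map onto their boxes (f0 ∈ [0,1], rates ∈ [1e-6, 10]/s)
with Nelder–Mead: a quasi-Newton box solver can stall in a spurious
f0 = 1 corner where the rate gradients vanish, which the smooth
parameterization removes. Traces are normalized to the pre-dithionite
mean when the metadata provides the addition time; fits on already
normalized traces are accepted and the normalization state is logged.
When the fitted α reaches 5γ the result carries an identifiability flag:
scrambling faster than the quench cannot be resolved, only bounded — the
regime in which published wild-type rates were constrained rather than
fitted. The slow protein-free leak is reported from a linear tail fit
and deliberately not folded into the forward model (it is orders of
magnitude below protein-mediated rates for typical constructs); a
γ-inflation correction exists behind a flag. Batch QC flags fits whose
control condition falls outside 3 SD of the reference mean, and never
deletes data silently.

The flux-assay active fraction is A = 100(1 − ΔCl/ΔCl_PF), clipped to
[0, 100] with a warning when measurement noise pushes it outside. Fold
changes against a reference rate are labelled with the categorical bands
used for scrambling phenotypes; values exactly on a band edge are
reported as "≥" rather than ">".

## The synthetic world

The generators state a fixed world; their defaults were chosen once and
are not tuned against test outcomes:

- `make_two_state_series`: a two-state Markov jump process (exact
  discrete-time sampling, so the indicator autocorrelation is exactly
  exp(−(k12+k21)τ)) observed through Gaussian noise. Default state means
  are the open/occluded values of the five features suggested by the
  structural literature (e.g. Cα–Cα 12.5 vs 7.5 Å; gate distances
  4.9→8.9 and 4.5→12.3 Å) with 0.5 Å per-feature noise — a realistic
  thermal fluctuation scale for inter-residue distances. What it does
  not emulate: more than two states, non-Markovian kinetics, or
  feature-noise correlations; a green tICA test establishes estimator
  correctness, not anything about real trajectories.
- `make_toy_groove`: a ring of residues carrying the groove numbering
  (302…513) with minimal sidechains, plus waters and 2+8-atom toy
  lipids at exactly requested positions (clash-checked at 0.5 Å). It
  exercises the metric code paths verbatim but is not a protein fold.
- `make_pore_toy`: cylinder/hourglass atom-ring pores with closed-form
  clearance radii.
- `make_trace_set`: the forward model plus Gaussian noise at the assay's
  3 Hz sampling; default noise SD 0.005 of normalized fluorescence,
  typical of plate-reader traces.
- `make_point_charge_system`: uniform-dielectric point charges for the
  solver's analytic limits, with a ≥ 2 Debye-length margin precondition.

## Known limitations

- No mmCIF, no cryo-EM map handling, no force-field assignment, no MD.
- The deposited-structure acceptance measurements need the PDB files
  locally; in offline environments that criterion fails by design
  rather than being skipped, and `measure_deposited_targets()` runs the
  real measurement the moment the files are supplied.
- LPBE: single-grid SOR only (no multigrid, no nonlinear PBE); protein
  surface is vdW-inflated rather than solvent-excluded.
- Pore profiling returns per-slice maxima along a fixed axis; strongly
  tilted or branched channels would need a curved-axis extension.
- The bundled formal-charge table is a documented stand-in for a real
  force-field charge assignment.
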