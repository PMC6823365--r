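# grooveflow

Analysis toolkit for the membrane-facing hydrophilic groove of TMEM16-family
lipid scramblases — the pathway through which these proteins flip
phospholipids between bilayer leaflets and, in some conformations, conduct
ions. The package reimplements, as reusable and tested R code, the
computational assays used to characterize transitions of the groove between
membrane-exposed, occluded (intermediate) and ion-conductive states:

- **Structure & trajectory I/O** (`read_structure`, `read_trajectory`,
  `select_atoms`, `superpose`, `region_rmsd`): fixed-width PDB/PQR parsing,
  Kabsch superposition, backbone RMSD over named helix ranges.
- **Groove metrics** (`groove_feature_vector`, `classify_groove`,
  `count_region_waters`, `lipid_penetration`): the five slow distance
  features (minimal T333–Y439 and Y439–R432 distances, the E313/E318–R432
  carboxylate-O to guanidinium-N distances, the V337–V447 Cα–Cα distance),
  the 8.5 Å occlusion cutoff, 3 Å groove-water and 5 Å lipid-penetration
  rules, and the T381/Q436 vestibule slab count.
- **tICA** (`fit_tica`, `project_tica`, `cluster_microstates`,
  `density_landscape`): solves the generalized eigenproblem
  `C_TL(τ) V = C V Λ` of the time-lagged vs instantaneous feature
  covariances by symmetrization and whitening; k-means++ microstates and
  −ln p landscapes in the space of the two leading tICs.
- **Pore profiling** (`profile_pore`, `min_pore`, `pore_region_points`):
  HOLE-style sphere-probe radius `r(z) = max_c min_i (|c − x_i| − R_i)`
  per slice along the channel coordinate (Z = 0 at the Q436 Cα).
- **Electrostatics** (`build_maps`, `solve_lpbe`, `ep_profile`,
  `write_opendx`): finite-difference linearized Poisson–Boltzmann
  `∇·(ε∇φ) − ε_w κ² φ = −4πρ` with the membrane-slab dielectric model
  (ε_P = 2, 26 Å core ε = 2, 8 Å headgroup bands ε = 30, an 18 Å
  ion-accessible solvent cylinder, 150 mM monovalent salt).
- **Scrambling-assay kinetics** (`ftot`, `fit_scrambling`, `fit_leak`,
  `flux_active_fraction`): the dithionite-quench forward model
  `F(t) = f0(L + (1−L)e^{−γt}) + (1−f0)·[biexponential pool]` with
  eigenvalues `λ_{1,2} = −((α+β+γ) ∓ √((α+β+γ)² − 4αγ))/2`, bounded
  multi-start fitting of (f0, α, β), leak estimation, and the flux-assay
  active fraction `A = 100(1 − ΔCl/ΔCl_PF)`.
- **Synthetic data** (`make_two_state_series`, `make_toy_groove`,
  `make_pore_toy`, `make_trace_set`, `make_point_charge_system`): generators
  with known ground truth so every stage is verifiable without MD or
  cryo-EM inputs.

## Worked example

```r
library(grooveflow)

# two-state groove dynamics -> tICA -> microstates
ts <- make_two_state_series(n_frames = 200000, k12 = 0.005, k21 = 0.005,
                            seed = 1)
m  <- fit_tica(ts$features, tau = 50)
m$eigenvalues[1]          # 0.620 vs exp(-2*0.005*50) = 0.607
implied_timescale(m, 1)   # 104.6 frames vs true 1/(2k) = 100

# sphere-probe profile of an hourglass toy pore
hg <- make_pore_toy("hourglass", waist_radius = 4.45, atom_radius = 3.0)
pr <- profile_pore(hg, seed_point = c(0, 0, 0), z_range = c(-5, 5),
                   chain = "P")
min_pore(pr)              # r_min = 1.45 A at z = 0 (= 4.45 - 3.0)

# scrambling kinetics round trip
p  <- scrambling_params(f0 = 0.3, alpha = 0.01, beta = 0.005, gamma = 2,
                        L_i_PF = 0.5)
tr <- simulate_trace(p, seq(0, 600, by = 1/3), noise_sd = 0.005, seed = 2)
fit_scrambling(tr, L_i_PF = 0.5, gamma = 2)
#> <fit_result> f0=0.300 alpha=0.009929 beta=0.004963 (SSE 0.0452)
```

The printed numbers above are what the code produces under those seeds:
the leading tICA eigenvalue estimates the state-exchange autocorrelation
`exp(-(k12+k21)τ)`, the pore minimum equals the waist clearance of the
constructed geometry, and the fitted rate constants recover the generator's
α and β to well within the noise-limited uncertainty.

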