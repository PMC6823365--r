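#' Two-state feature time series
#'
#' Hidden two-state Markov jump process (rates in 1/frame) observed through
#' d-dimensional Gaussian emissions, emulating a slow open/occluded exchange
#' measured by distance features plus fast thermal noise. The chain is the
#' exact discrete-time sampling of the continuous-time jump process, so the
#' state indicator autocorrelation at lag tau is exp(-(k12+k21) tau).
#'
#' @param k12,k21 exchange rates (state 1 -> 2 and 2 -> 1), 1/frame.
#' @param mu_open,mu_occluded feature mean vectors (Angstrom) for states 1/2.
#' @param noise_sd per-feature emission noise SD (recycled).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return list with `features` (T x d matrix) and `states` (integer 1/2).
#' @export
make_two_state_series <- function(n_frames, k12 = 0.005, k21 = 0.005,
                                  mu_open = c(8.0, 6.0, 4.9, 4.5, 12.5),
                                  mu_occluded = c(3.5, 4.0, 8.9, 12.3, 7.5),
                                  noise_sd = 0.5, seed = 1) {
  stopifnot(k12 > 0, k21 > 0, length(mu_open) == length(mu_occluded))
  d <- length(mu_open)
  noise_sd <- rep_len(noise_sd, d)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  k <- k12 + k21
  if (n_frames < 10 / k) {
    warning("n_frames < 10/(k12+k21): the slow mode is undersampled")
  }
  # exact one-frame transition probabilities of the two-state jump process
  p12 <- (k12 / k) * (1 - exp(-k))
  p21 <- (k21 / k) * (1 - exp(-k))
  with_private_seed(seed, {
    states <- integer(n_frames)
    states[1] <- if (runif(1) < k21 / k) 1L else 2L  # stationary start
    u <- runif(n_frames - 1)
    for (t in 2:n_frames) {
      states[t] <- if (states[t - 1] == 1L) {
        if (u[t - 1] < p12) 2L else 1L
      } else {
        if (u[t - 1] < p21) 1L else 2L
      }
    }
    mu <- rbind(mu_open, mu_occluded)
    features <- mu[states, , drop = FALSE] +
      matrix(rnorm(n_frames * d, sd = rep(noise_sd, each = n_frames)),
             n_frames, d)
    colnames(features) <- c("d_T333_Y439", "d_Y439_R432", "d_E313_R432",
                            "d_E318_R432", "d_V337_V447_CA")[seq_len(d)]
    list(features = features, states = states,
         rates = c(k12 = k12, k21 = k21), seed = seed)
  })
}

# ---------------------------------------------------------------------------
# Toy groove structures

# Minimal sidechain atom sets (beyond the backbone) per residue type used in
# the toy builder. Offsets are from CA, roughly along the sidechain direction.
.TOY_SIDECHAINS <- list(
  GLU = list(names = c("CB", "CG", "CD", "OE1", "OE2"),
             offsets = rbind(c(1.5, 0, 0), c(2.5, 0.8, 0), c(3.8, 0.9, 0),
                             c(4.5, 0.2, 0.6), c(4.4, 1.9, -0.4))),
  ARG = list(names = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
             offsets = rbind(c(1.5, 0, 0), c(2.5, 0.8, 0), c(3.9, 0.8, 0),
                             c(4.8, 1.8, 0), c(6.1, 1.8, 0),
                             c(6.8, 0.7, 0.3), c(6.8, 2.9, -0.3))),
  TYR = list(names = c("CB", "CG", "CD1", "CE1", "CZ", "OH"),
             offsets = rbind(c(1.5, 0, 0), c(2.6, 0.7, 0), c(3.3, 1.2, 1.0),
                             c(4.6, 1.6, 1.0), c(5.2, 1.5, -0.1),
                             c(6.5, 1.9, -0.2))),
  GLN = list(names = c("CB", "CG", "CD", "OE1", "NE2"),
             offsets = rbind(c(1.5, 0, 0), c(2.5, 0.8, 0), c(3.8, 0.9, 0),
                             c(4.5, 0.2, 0.6), c(4.4, 1.9, -0.4))),
  default = list(names = c("CB", "CG"),
                 offsets = rbind(c(1.5, 0, 0), c(2.5, 0.6, 0)))
)

.TOY_RESIDUE_NAMES <- c(
  "302" = "LEU", "306" = "THR", "310" = "SER", "313" = "GLU", "318" = "GLU",
  "333" = "THR", "336" = "SER", "337" = "VAL", "340" = "ALA", "341" = "SER",
  "343" = "ILE", "344" = "THR", "347" = "LEU", "348" = "SER", "352" = "THR",
  "367" = "SER", "370" = "THR", "371" = "SER", "374" = "THR", "377" = "ASN",
  "378" = "SER", "381" = "THR", "382" = "SER", "385" = "THR", "432" = "ARG",
  "436" = "GLN", "439" = "TYR", "440" = "SER", "443" = "THR", "444" = "SER",
  "447" = "VAL", "451" = "THR", "455" = "SER", "499" = "THR", "501" = "SER",
  "505" = "ARG", "509" = "THR", "513" = "SER")

.toy_residue_atoms <- function(number, resname, ca, inward = c(-1, 0, 0)) {
  inward <- inward / sqrt(sum(inward^2))
  # local frame: sidechain grows along `inward`
  e1 <- inward
  e2 <- if (abs(e1[3]) < 0.9) {
    v <- c(-e1[2], e1[1], 0); v / sqrt(sum(v^2))
  } else c(1, 0, 0)
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  bb <- rbind(N = c(-0.9, 1.0, 0), CA = c(0, 0, 0),
              C = c(0.9, -1.0, 0.3), O = c(0.7, -2.2, 0.3))
  sc <- if (resname %in% names(.TOY_SIDECHAINS)) {
    .TOY_SIDECHAINS[[resname]]
  } else .TOY_SIDECHAINS$default
  nm <- c(rownames(bb), sc$names)
  off <- rbind(bb, sc$offsets)
  world <- t(apply(off, 1, function(o) ca + o[1] * e1 + o[2] * e2 + o[3] * e3))
  data.frame(atom_name = nm, residue_name = resname, chain_id = "A",
             residue_number = number, x = world[, 1], y = world[, 2],
             z = world[, 3], element = substr(nm, 1, 1),
             stringsAsFactors = FALSE)
}

#' Toy groove structure
#'
#' Builds a small protein-like structure carrying the groove residue
#' numbering used by the feature metrics (302...513), arranged as an open
#' ring of residues around the z axis, plus optional waters and toy lipids.
#' Individual atoms (or residue CA anchor positions) can be pinned to exact
#' coordinates so boundary geometries are constructible.
#'
#' @param ca_positions optional named list/vector overrides: names are
#'   residue numbers (as character), values length-3 CA coordinates.
#' @param atom_overrides optional data.frame with columns
#'   `residue_number, atom_name, x, y, z` pinning single atoms after layout.
#' @param waters optional N x 3 matrix of water oxygen positions (HOH).
#' @param lipids optional list; each element a list with `head` (2 x 3) and
#'   `tail` (8 x 3) coordinate matrices for one toy lipid.
#' @param radius ring radius (Angstrom) of the default residue layout.
#' @param residues integer vector of residue numbers to build (default: all
#'   groove-lining plus the feature residues).
#' @return a [gf_structure()].
#' @export
make_toy_groove <- function(ca_positions = NULL, atom_overrides = NULL,
                            waters = NULL, lipids = NULL, radius = 9,
                            residues = as.integer(names(.TOY_RESIDUE_NAMES))) {
  residues <- sort(unique(as.integer(residues)))
  n <- length(residues)
  ang <- seq(0, 1.6 * pi, length.out = n)
  zs <- seq(-12, 12, length.out = n)
  rows <- list()
  for (i in seq_len(n)) {
    num <- residues[i]
    resname <- .TOY_RESIDUE_NAMES[[as.character(num)]]
    if (is.null(resname)) resname <- "ALA"
    ca <- c(radius * cos(ang[i]), radius * sin(ang[i]), zs[i])
    if (!is.null(ca_positions) &&
        !is.null(ca_positions[[as.character(num)]])) {
      ca <- as.numeric(ca_positions[[as.character(num)]])
    }
    inward <- c(-ca[1], -ca[2], 0)
    if (sum(inward^2) < 1e-9) inward <- c(-1, 0, 0)
    rows[[i]] <- .toy_residue_atoms(num, resname, ca, inward)
  }
  atoms <- do.call(rbind, rows)
  if (!is.null(atom_overrides)) {
    for (i in seq_len(nrow(atom_overrides))) {
      o <- atom_overrides[i, ]
      j <- which(atoms$residue_number == o$residue_number &
                 atoms$atom_name == o$atom_name)
      if (length(j) != 1) {
        stop(sprintf("atom override %d/%s matches %d atoms",
                     o$residue_number, o$atom_name, length(j)))
      }
      atoms$x[j] <- o$x; atoms$y[j] <- o$y; atoms$z[j] <- o$z
    }
  }
  hetero <- list()
  if (!is.null(waters)) {
    waters <- as.matrix(waters)
    hetero[[length(hetero) + 1]] <- data.frame(
      atom_name = "O", residue_name = "HOH", chain_id = "W",
      residue_number = 1000L + seq_len(nrow(waters)),
      x = waters[, 1], y = waters[, 2], z = waters[, 3], element = "O",
      stringsAsFactors = FALSE)
  }
  if (!is.null(lipids)) {
    for (li in seq_along(lipids)) {
      lp <- lipids[[li]]
      head_m <- as.matrix(lp$head); tail_m <- as.matrix(lp$tail)
      if (nrow(head_m) != 2 || nrow(tail_m) != 8) {
        stop("toy lipids use 2 head and 8 tail pseudo-atoms")
      }
      hetero[[length(hetero) + 1]] <- data.frame(
        atom_name = c("PH1", "PH2", paste0("CT", 1:8)),
        residue_name = "TLP", chain_id = "L",
        residue_number = 2000L + li,
        x = c(head_m[, 1], tail_m[, 1]), y = c(head_m[, 2], tail_m[, 2]),
        z = c(head_m[, 3], tail_m[, 3]),
        element = c("P", "O", rep("C", 8)), stringsAsFactors = FALSE)
    }
  }
  if (length(hetero)) {
    het <- do.call(rbind, hetero)
    # clash check among placed hetero atoms (< 0.5 A)
    if (nrow(het) > 1) {
      hm <- as.matrix(het[, c("x", "y", "z")])
      dd <- as.matrix(stats::dist(hm))
      diag(dd) <- Inf
      if (min(dd) < 0.5) {
        stop(sprintf("hetero-atom placement clash: %.3f A < 0.5 A", min(dd)))
      }
    }
    atoms <- rbind(atoms, het)
  }
  atoms$serial <- seq_len(nrow(atoms))
  gf_structure(atoms, title = "synthetic toy groove")
}

# ---------------------------------------------------------------------------
# Toy pores

#' Toy pore structure (cylinder or hourglass)
#'
#' Atoms arranged in rings about the z axis whose inner surface realizes a
#' known analytic pore-radius profile: a cylinder of constant radius, or an
#' hourglass with quadratic flare `R(z) = waist_radius + flare * z^2`.
#'
#' @param shape `"cylinder"` or `"hourglass"`.
#' @param ring_radius cylinder ring radius (centre of atoms), Angstrom.
#' @param waist_radius hourglass ring radius at z = 0.
#' @param flare hourglass quadratic coefficient (1/Angstrom).
#' @param atom_radius vdW radius assigned to every ring atom.
#' @param z_range,ring_spacing axial extent and spacing of rings.
#' @param atoms_per_ring ring discretization.
#' @return a [gf_structure()] whose analytic pore radius is
#'   `ring_radius - atom_radius` (cylinder) or
#'   `waist_radius + flare z^2 - atom_radius` (hourglass).
#' @export
make_pore_toy <- function(shape = c("cylinder", "hourglass"),
                          ring_radius = 6.0, waist_radius = 4.45,
                          flare = 0.05, atom_radius = 1.7,
                          z_range = c(-10, 10), ring_spacing = 0.5,
                          atoms_per_ring = 24) {
  shape <- match.arg(shape)
  zs <- seq(z_range[1], z_range[2], by = ring_spacing)
  Rz <- switch(shape,
               cylinder = rep(ring_radius, length(zs)),
               hourglass = waist_radius + flare * zs^2)
  if (any(Rz <= atom_radius)) {
    stop("ring radius must exceed atom radius everywhere (empty pore)")
  }
  th <- seq(0, 2 * pi, length.out = atoms_per_ring + 1)[-(atoms_per_ring + 1)]
  rows <- lapply(seq_along(zs), function(i) {
    data.frame(atom_name = "C", residue_name = "RNG", chain_id = "P",
               residue_number = i, icode = sprintf("%d", seq_along(th) %% 10),
               x = Rz[i] * cos(th), y = Rz[i] * sin(th), z = zs[i],
               element = "C", stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  # unique atom names within each ring residue
  atoms$atom_name <- paste0("C", rep(seq_along(th), length(zs)))
  atoms$icode <- ""
  atoms$vdw_radius <- atom_radius
  atoms$serial <- seq_len(nrow(atoms))
  st <- gf_structure(atoms, title = sprintf("synthetic %s pore", shape))
  attr(st, "analytic") <- list(shape = shape, zs = zs, ring_radius = Rz,
                               atom_radius = atom_radius,
                               radius = Rz - atom_radius)
  st
}

#' Exact pore radius of a toy pore
#'
#' Closed-form clearance radius of a [make_pore_toy()] structure at height
#' `z` for a probe centred on the axis: the minimum over rings of
#' `sqrt(R_i^2 + (z - z_i)^2) - atom_radius`. At ring planes this equals
#' the smooth-surface value `R(z) - atom_radius`; between rings (or where
#' the wall is steep) the nearest ring dominates, which is the true
#' geometry of the discrete object.
#'
#' @param toy a structure from [make_pore_toy()].
#' @param z height(s) along the axis, Angstrom.
#' @return clearance radius (vectorized over `z`).
#' @export
analytic_pore_radius <- function(toy, z) {
  an <- attr(toy, "analytic")
  if (is.null(an)) stop("not a make_pore_toy() structure")
  vapply(z, function(zz) {
    min(sqrt(an$ring_radius^2 + (zz - an$zs)^2)) - an$atom_radius
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Fluorescence traces

#' Simulated dithionite-assay trace set
#'
#' Evaluates the scrambling forward model at `times` for each parameter set
#' and adds i.i.d. Gaussian noise; reproducible under `seed`.
#'
#' @param param_table list of [scrambling_params()] objects (or a single one).
#' @param times sampling times (s), strictly increasing.
#' @param noise_sd Gaussian noise SD on normalized fluorescence.
#' @param seed RNG seed.
#' @return list of `gf_trace` objects (see [simulate_trace()]).
#' @export
make_trace_set <- function(param_table, times, noise_sd = 0.005, seed = 1) {
  if (inherits(param_table, "scrambling_params")) {
    param_table <- list(param_table)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  lapply(seq_along(param_table), function(i) {
    simulate_trace(param_table[[i]], times, noise_sd = noise_sd,
                   seed = seed + i - 1L)
  })
}

# ---------------------------------------------------------------------------
# Point-charge systems for electrostatics limit tests

#' Point-charge system in uniform solvent
#'
#' A PQR-style structure of point charges in a uniform dielectric (no
#' membrane slab), for Coulomb / Debye-Hueckel limit tests of the LPBE
#' solver. With salt present, charges must sit at least two Debye lengths
#' from every box face so the analytic boundary condition is accurate.
#'
#' @param charges data.frame with columns `x, y, z, q` (Angstrom, e).
#' @param box half-width of the cubic solve box (Angstrom).
#' @param salt_mM monovalent ionic strength, mM.
#' @param temperature Kelvin (Debye length).
#' @param radius vdW radius given to the charge-carrying pseudo-atoms.
#' @return list with `structure` (a `gf_structure`), `spec`
#'   (a [membrane_dielectric_spec()] with the membrane disabled) and `box`.
#' @export
make_point_charge_system <- function(charges, box = 20, salt_mM = 0,
                                     temperature = 298.15, radius = 1.5) {
  stopifnot(all(c("x", "y", "z", "q") %in% names(charges)))
  if (salt_mM > 0) {
    ld <- debye_length(salt_mM, eps = 80, temperature = temperature)
    margin <- box - max(abs(as.matrix(charges[, c("x", "y", "z")])))
    if (margin < 2 * ld) {
      stop(sprintf("charges within 2 Debye lengths (%.1f A) of box faces",
                   2 * ld))
    }
  }
  n <- nrow(charges)
  atoms <- data.frame(atom_name = paste0("Q", seq_len(n)),
                      residue_name = "ION", chain_id = "Q",
                      residue_number = seq_len(n),
                      x = charges$x, y = charges$y, z = charges$z,
                      element = "C", vdw_radius = radius,
                      partial_charge = charges$q, stringsAsFactors = FALSE)
  spec <- membrane_dielectric_spec(membrane = FALSE, eps_protein = 80,
                                   ionic_strength_mM = salt_mM,
                                   temperature = temperature)
  list(structure = gf_structure(atoms, title = "synthetic point charges"),
       spec = spec, box = box)
}
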