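# Coulomb constant, kcal * Angstrom / (mol * e^2)
.KCOUL <- 332.0637

#' Debye screening length
#'
#' `lambda_D = sqrt(eps eps0 kB T / (2 NA e^2 I))` for a monovalent salt.
#'
#' @param ionic_strength_mM ionic strength, mM.
#' @param eps relative dielectric of the solvent.
#' @param temperature Kelvin.
#' @return Debye length in Angstrom (`Inf` at zero salt).
#' @export
debye_length <- function(ionic_strength_mM, eps = 80, temperature = 298.15) {
  if (ionic_strength_mM <= 0) return(Inf)
  eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  e <- 1.602176634e-19; NA_ <- 6.02214076e23
  I <- ionic_strength_mM  # mM == mol/m^3
  sqrt(eps * eps0 * kB * temperature / (2 * NA_ * e^2 * I)) * 1e10
}

#' Membrane-slab dielectric specification
#'
#' The continuum model for electrostatics of a membrane protein: protein
#' interior at `eps_protein`; a hydrophobic slab core of `core_thickness`
#' at `eps_core` flanked by two headgroup bands of `headgroup_thickness`
#' at `eps_head`; solvent at `eps_water` carrying `ionic_strength_mM` of
#' monovalent mobile ions. A cylindrical hole of `hole_radius` about the
#' groove axis carries solvent dielectric and is ion-accessible; ions are
#' excluded from the protein and the rest of the membrane region.
#'
#' @param eps_protein,eps_core,eps_head,eps_water dielectric constants.
#' @param core_thickness,headgroup_thickness slab band thicknesses, Angstrom.
#' @param hole_radius cylinder radius, Angstrom.
#' @param hole_center x/y centre of the cylinder.
#' @param ionic_strength_mM monovalent salt, mM.
#' @param temperature Kelvin (enters the Debye length only).
#' @param membrane_center_z slab centre along z, Angstrom.
#' @param membrane logical; `FALSE` turns the whole slab off (uniform
#'   solvent outside the protein).
#' @return list of class `membrane_dielectric_spec`.
#' @export
membrane_dielectric_spec <- function(eps_protein = 2, core_thickness = 26,
                                     eps_core = 2, headgroup_thickness = 8,
                                     eps_head = 30, eps_water = 80,
                                     hole_radius = 18, hole_center = c(0, 0),
                                     ionic_strength_mM = 150,
                                     temperature = 298.15,
                                     membrane_center_z = 0, membrane = TRUE) {
  stopifnot(core_thickness > 0, headgroup_thickness > 0,
            all(c(eps_protein, eps_core, eps_head, eps_water) >= 1))
  structure(list(eps_protein = eps_protein, core_thickness = core_thickness,
                 eps_core = eps_core, headgroup_thickness = headgroup_thickness,
                 eps_head = eps_head, eps_water = eps_water,
                 hole_radius = hole_radius, hole_center = hole_center,
                 ionic_strength_mM = ionic_strength_mM,
                 temperature = temperature,
                 membrane_center_z = membrane_center_z, membrane = membrane),
            class = "membrane_dielectric_spec")
}

#' Build dielectric, screening and charge maps
#'
#' Populates the node-centred epsilon map (protein interior by vdW-inflated
#' atoms, slab bands by |z - centre|, the solvent cylinder overriding the
#' slab), the Debye screening map (positive only in ion-accessible solvent:
#' outside protein and outside the membrane bands, or inside the cylinder),
#' and the charge map (trilinear spreading of `partial_charge`).
#'
#' @param structure a `gf_structure` with partial charges (PQR input) for a
#'   charged solute; zero-charge structures are allowed.
#' @param spec a [membrane_dielectric_spec()].
#' @param spacing grid spacing, Angstrom (warn above 1.5).
#' @param padding box padding beyond the structure extent, Angstrom.
#' @param box optional explicit half-width: grid spans [-box, box]^3.
#' @return object of class `ep_grid` with `origin`, `spacing`, `dims`,
#'   arrays `eps`, `kappa2` (Angstrom^-2, already times eps_water),
#'   `charge` (e per node), and `phi = NULL` until solved.
#' @export
build_maps <- function(structure, spec, spacing = 0.8, padding = 15,
                       box = NULL) {
  if (spacing > 1.5) warning("grid spacing > 1.5 A is too coarse for reliable potentials")
  xyz <- atom_coords(structure)
  if (is.null(box)) {
    lo <- apply(xyz, 2, min) - padding
    hi <- apply(xyz, 2, max) + padding
  } else {
    lo <- rep(-box, 3); hi <- rep(box, 3)
  }
  dims <- pmax(as.integer(ceiling((hi - lo) / spacing)) + 1L, 2L)
  origin <- lo
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  eps <- array(spec$eps_water, dims)
  ion_ok <- array(TRUE, dims)
  gx <- origin[1] + (seq_len(nx) - 1) * spacing
  gy <- origin[2] + (seq_len(ny) - 1) * spacing
  gz <- origin[3] + (seq_len(nz) - 1) * spacing
  if (isTRUE(spec$membrane)) {
    dz <- abs(gz - spec$membrane_center_z)
    core <- dz <= spec$core_thickness / 2
    headb <- dz > spec$core_thickness / 2 &
      dz <= spec$core_thickness / 2 + spec$headgroup_thickness
    r2 <- outer((gx - spec$hole_center[1])^2, (gy - spec$hole_center[2])^2, "+")
    in_hole <- r2 <= spec$hole_radius^2
    for (k in seq_len(nz)) {
      if (core[k]) {
        sl <- matrix(spec$eps_core, nx, ny)
        sl[in_hole] <- spec$eps_water
        eps[, , k] <- sl
        ion_ok[, , k] <- in_hole   # ions only inside the cylinder
      } else if (headb[k]) {
        sl <- matrix(spec$eps_head, nx, ny)
        sl[in_hole] <- spec$eps_water
        eps[, , k] <- sl
        ion_ok[, , k] <- in_hole
      }
    }
    if (!any(xyz[, 3] >= spec$membrane_center_z - spec$core_thickness / 2 &
             xyz[, 3] <= spec$membrane_center_z + spec$core_thickness / 2)) {
      warning("structure does not intersect the membrane slab")
    }
  }
  # protein interior: nodes within the vdW sphere of any atom
  R <- structure$atoms$vdw_radius
  for (i in seq_len(nrow(xyz))) {
    ix <- which(abs(gx - xyz[i, 1]) <= R[i])
    iy <- which(abs(gy - xyz[i, 2]) <= R[i])
    iz <- which(abs(gz - xyz[i, 3]) <= R[i])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - xyz[i, 1])^2
    dy2 <- (gy[iy] - xyz[i, 2])^2
    dz2 <- (gz[iz] - xyz[i, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    inside <- d2 <= R[i]^2
    if (any(inside)) {
      blk_e <- eps[ix, iy, iz, drop = FALSE]; blk_e[inside] <- spec$eps_protein
      eps[ix, iy, iz] <- blk_e
      blk_i <- ion_ok[ix, iy, iz, drop = FALSE]; blk_i[inside] <- FALSE
      ion_ok[ix, iy, iz] <- blk_i
    }
  }
  ld <- debye_length(spec$ionic_strength_mM, spec$eps_water, spec$temperature)
  kap2 <- array(0, dims)
  if (is.finite(ld)) kap2[ion_ok] <- spec$eps_water / ld^2
  # charge spreading (trilinear)
  charge <- array(0, dims)
  q <- structure$atoms$partial_charge
  qi <- which(!is.na(q) & q != 0)
  for (i in qi) {
    fx <- (xyz[i, 1] - origin[1]) / spacing
    fy <- (xyz[i, 2] - origin[2]) / spacing
    fz <- (xyz[i, 3] - origin[3]) / spacing
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    if (i0 < 0 || j0 < 0 || k0 < 0 ||
        i0 >= nx - 1 || j0 >= ny - 1 || k0 >= nz - 1) {
      stop("charged atom outside (or on the face of) the grid")
    }
    wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      w <- (if (a) wx else 1 - wx) * (if (b) wy else 1 - wy) *
        (if (cc) wz else 1 - wz)
      charge[i0 + a + 1, j0 + b + 1, k0 + cc + 1] <-
        charge[i0 + a + 1, j0 + b + 1, k0 + cc + 1] + w * q[i]
    }
  }
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 eps = eps, kappa2 = kap2, charge = charge, phi = NULL,
                 spec = spec,
                 charges = cbind(xyz[qi, , drop = FALSE], q = q[qi])),
            class = "ep_grid")
}

#' Solve the linearized Poisson-Boltzmann equation
#'
#' Finite-difference LPBE `div(eps grad phi) - eps_w kappa^2 phi = -4 pi rho`
#' (Gaussian convention, lengths in Angstrom, charges in e) solved by SOR
#' with harmonic-mean face dielectrics; Debye-screened Coulomb boundary
#' conditions on the box faces. Errors with the residual history if the
#' iteration does not converge.
#'
#' @param grid an `ep_grid` from [build_maps()].
#' @param tol convergence threshold on the max potential update per sweep,
#'   kcal/(mol e).
#' @param max_iter sweep cap.
#' @param omega SOR relaxation factor; default near-optimal for the grid.
#' @return the grid with `phi` (3D array, kcal/(mol e)), `iterations` and
#'   `residual_history` populated.
#' @export
solve_lpbe <- function(grid, tol = 1e-4, max_iter = 20000, omega = NULL) {
  dims <- grid$dims
  if (is.null(omega)) omega <- 2 / (1 + sin(pi / max(dims)))
  phi <- array(0, dims)
  ld <- debye_length(grid$spec$ionic_strength_mM, grid$spec$eps_water,
                     grid$spec$temperature)
  kappa <- if (is.finite(ld)) 1 / ld else 0
  # Dirichlet faces: screened Coulomb sum over source charges
  if (!is.null(grid$charges) && nrow(grid$charges)) {
    phi <- .apply_face_bc(phi, grid, kappa)
  }
  src <- 4 * pi * grid$charge / grid$spacing
  res <- .lpbe_sor_cpp(as.numeric(phi), as.numeric(grid$eps),
                       as.numeric(grid$kappa2) * grid$spacing^2,
                       as.numeric(src), as.integer(dims),
                       omega, tol / .KCOUL, as.integer(max_iter))
  if (!res$converged) {
    stop(sprintf("LPBE SOR did not converge in %d sweeps (last update %.3g); residual history tail: %s",
                 res$iterations, res$max_update * .KCOUL,
                 paste(sprintf("%.3g", utils::tail(res$residual_history, 5) * .KCOUL),
                       collapse = ", ")))
  }
  grid$phi <- array(res$phi * .KCOUL, dims)
  grid$iterations <- res$iterations
  grid$residual_history <- res$residual_history * .KCOUL
  grid
}

.apply_face_bc <- function(phi, grid, kappa) {
  dims <- grid$dims
  gx <- grid$origin[1] + (seq_len(dims[1]) - 1) * grid$spacing
  gy <- grid$origin[2] + (seq_len(dims[2]) - 1) * grid$spacing
  gz <- grid$origin[3] + (seq_len(dims[3]) - 1) * grid$spacing
  ch <- grid$charges
  eps_w <- grid$spec$eps_water
  bc_plane <- function(xs, ys, zs) {
    # grid of points over two varying axes at a fixed third coordinate
    pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    v <- numeric(nrow(pts))
    for (j in seq_len(nrow(ch))) {
      r <- sqrt((pts[, 1] - ch[j, 1])^2 + (pts[, 2] - ch[j, 2])^2 +
                (pts[, 3] - ch[j, 3])^2)
      r <- pmax(r, 1e-6)
      v <- v + ch[j, "q"] * exp(-kappa * r) / (eps_w * r)
    }
    v
  }
  phi[1, , ] <- bc_plane(gx[1], gy, gz)
  phi[dims[1], , ] <- bc_plane(gx[dims[1]], gy, gz)
  phi[, 1, ] <- matrix(bc_plane(gx, gy[1], gz), dims[1], dims[3])
  phi[, dims[2], ] <- matrix(bc_plane(gx, gy[dims[2]], gz), dims[1], dims[3])
  phi[, , 1] <- matrix(bc_plane(gx, gy, gz[1]), dims[1], dims[2])
  phi[, , dims[3]] <- matrix(bc_plane(gx, gy, gz[dims[3]]), dims[1], dims[2])
  phi
}

#' Trilinear interpolation of the solved potential
#'
#' @param grid a solved `ep_grid`.
#' @param points N x 3 matrix of query points (Angstrom).
#' @return numeric vector of potentials, kcal/(mol e).
#' @export
interp_phi <- function(grid, points) {
  if (is.null(grid$phi)) stop("grid not solved; call solve_lpbe() first")
  points <- matrix(as.numeric(points), ncol = 3)
  f <- sweep(points, 2, grid$origin) / grid$spacing
  out <- numeric(nrow(points))
  dims <- grid$dims
  for (n in seq_len(nrow(points))) {
    i0 <- floor(f[n, 1]); j0 <- floor(f[n, 2]); k0 <- floor(f[n, 3])
    if (i0 < 0 || j0 < 0 || k0 < 0 ||
        i0 >= dims[1] - 1 || j0 >= dims[2] - 1 || k0 >= dims[3] - 1) {
      stop("query point outside the grid")
    }
    w <- f[n, ] - c(i0, j0, k0)
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      wt <- (if (a) w[1] else 1 - w[1]) * (if (b) w[2] else 1 - w[2]) *
        (if (cc) w[3] else 1 - w[3])
      acc <- acc + wt * grid$phi[i0 + a + 1, j0 + b + 1, k0 + cc + 1]
    }
    out[n] <- acc
  }
  out
}

#' Electrostatic potential profile along the pore axis
#'
#' Potential interpolated at each pore-centre sample, ordered by decreasing
#' channel coordinate (extracellular to intracellular direction); landmarks
#' from the profile are carried through. Optionally the potential is
#' averaged over the pore-region points of each slice.
#'
#' @param grid a solved `ep_grid`.
#' @param profile a `pore_profile` of the same structure.
#' @param average_region optional pore-region point matrix (from
#'   [pore_region_points()]); when given, per-slice averages over those
#'   points replace the centreline values.
#' @return data.frame with `z` (channel coordinate) and `phi`, decreasing z;
#'   landmarks attached as an attribute.
#' @export
ep_profile <- function(grid, profile, average_region = NULL) {
  s <- profile$samples[is.finite(profile$samples$radius), ]
  pts <- cbind(s$x, s$y, s$z_abs)
  phi <- interp_phi(grid, pts)
  out <- data.frame(z = s$z, phi = phi)
  if (!is.null(average_region) && nrow(average_region)) {
    rot <- .rotation_to_z(profile$axis)
    reg <- average_region %*% t(rot)
    vphi <- interp_phi(grid, average_region)
    zi <- findInterval(reg[, 3], s$z_abs - profile$step / 2,
                       all.inside = TRUE)
    agg <- tapply(vphi, zi, mean)
    out$phi[as.integer(names(agg))] <- as.numeric(agg)
  }
  out <- out[order(out$z, decreasing = TRUE), ]
  rownames(out) <- NULL
  attr(out, "landmarks") <- profile$landmarks
  out
}

#' Export clipped potential values over the pore region
#'
#' Masked grid export for surface colouring: potential at each pore-region
#' point, clipped to `range` (default [-1, 1] kcal/(mol e)).
#'
#' @param grid a solved `ep_grid`.
#' @param mask_points matrix of pore-region points.
#' @param range clipping range, kcal/(mol e).
#' @return data.frame `x, y, z, phi` with one row per mask point (possibly
#'   zero rows, with a note).
#' @export
ep_isorange_surface <- function(grid, mask_points, range = c(-1, 1)) {
  if (is.null(mask_points) || !nrow(mask_points)) {
    .gf_log("empty pore-region mask: nothing to export")
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      phi = numeric(0)))
  }
  phi <- interp_phi(grid, mask_points)
  phi <- pmin(pmax(phi, range[1]), range[2])
  data.frame(x = mask_points[, 1], y = mask_points[, 2],
             z = mask_points[, 3], phi = phi)
}

#' Write a solved potential grid in OpenDX scalar format
#'
#' @param grid a solved `ep_grid`.
#' @param path output path.
#' @export
write_opendx <- function(grid, path) {
  if (is.null(grid$phi)) stop("grid not solved")
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6g %.6g %.6g", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.6g 0 0", grid$spacing),
    sprintf("delta 0 %.6g 0", grid$spacing),
    sprintf("delta 0 0 %.6g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX order: z fastest
  vals <- as.numeric(aperm(grid$phi, c(3, 2, 1)))
  idx <- seq(1, length(vals), by = 3)
  lines <- vapply(idx, function(i) {
    paste(sprintf("%.6e", vals[i:min(i + 2, length(vals))]), collapse = " ")
  }, character(1))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
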