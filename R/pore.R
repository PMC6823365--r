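#' Sphere-probe pore-radius profile
#'
#' HOLE-style profiling: at each slice along the channel axis the centre of
#' the largest sphere that fits without overlapping any atom's vdW sphere is
#' found by maximizing `r(c) = min_i (|c - x_i| - R_i)` over the slice
#' plane, with multi-start local search warm-started from the previous
#' slice's centre. Works on any axis; internally the structure is rotated so
#' the axis is +z.
#'
#' @param structure a `gf_structure` with vdW radii assigned.
#' @param seed_point a point inside the pathway (3-vector). Default: the
#'   V337/V447 Calpha midpoint when those residues exist, else the centroid.
#' @param axis channel axis direction (unit vector not required), default +z.
#' @param z_range axial window (along `axis`, absolute coordinates) to
#'   profile; default covers the structure extent minus the probe cap.
#' @param step slice spacing, Angstrom.
#' @param n_starts random restarts per slice in addition to the warm start.
#' @param seed RNG seed for the restarts.
#' @param max_radius radius cap (sphere considered to have escaped).
#' @param chain protomer chain for the default seed point and landmarks.
#' @return object of class `pore_profile`: data.frame `samples` with
#'   `z` (channel coordinate, 0 at the Q436 Calpha when present),
#'   `z_abs`, `x`, `y` (centre), `radius`, `flagged`; plus `step`,
#'   `landmarks` (named z of Q436/Y439/V447 Calpha where present).
#' @export
profile_pore <- function(structure, seed_point = NULL, axis = c(0, 0, 1),
                         z_range = NULL, step = 0.25, n_starts = 8,
                         seed = 1, max_radius = 12, chain = "A") {
  a <- structure$atoms
  xyz <- atom_coords(structure)
  R <- a$vdw_radius
  axis <- axis / sqrt(sum(axis^2))
  rot <- .rotation_to_z(axis)
  xyzr <- xyz %*% t(rot)
  if (is.null(seed_point)) {
    seed_point <- .default_seed_point(structure, chain)
  }
  sp <- as.numeric(seed_point %*% t(rot))
  if (is.null(z_range)) {
    z_range <- range(xyzr[, 3]) + c(2, -2)
  }
  zs <- sort(unique(c(seq(sp[3], z_range[1], by = -step),
                      seq(sp[3], z_range[2], by = step))))
  r0 <- .pore_radius_at(sp[1:2], sp[3], xyzr, R)
  if (r0 <= 0) stop("seed point lies inside an atom (radius <= 0)")
  i0 <- which.min(abs(zs - sp[3]))
  n <- length(zs)
  cx <- cy <- rad <- rep(NA_real_, n)
  with_private_seed(seed, {
    res0 <- .optimize_slice(sp[1:2], zs[i0], xyzr, R, n_starts, max_radius)
    cx[i0] <- res0$c[1]; cy[i0] <- res0$c[2]; rad[i0] <- res0$r
    for (dir in c(1L, -1L)) {
      idx <- if (dir == 1L) seq(i0 + 1L, n) else seq(i0 - 1L, 1L)
      if (i0 + dir < 1 || i0 + dir > n) next
      prev <- c(cx[i0], cy[i0])
      for (i in idx) {
        res <- .optimize_slice(prev, zs[i], xyzr, R, n_starts, max_radius)
        cx[i] <- res$c[1]; cy[i] <- res$c[2]; rad[i] <- res$r
        prev <- res$c
      }
    }
  })
  flagged <- c(FALSE, abs(diff(rad)) > 5)
  # channel coordinate: zero at Q436 Calpha when present
  z0 <- tryCatch({
    ca <- atom_coords(structure, select_atoms(structure, chain, 436L, "CA"))
    as.numeric(ca %*% t(rot))[3]
  }, error = function(e) 0)
  landmarks <- c(Q436 = NA_real_, Y439 = NA_real_, V447 = NA_real_)
  for (nm in names(landmarks)) {
    num <- as.integer(substring(nm, 2))
    landmarks[nm] <- tryCatch({
      ca <- atom_coords(structure, select_atoms(structure, chain, num, "CA"))
      as.numeric(ca %*% t(rot))[3] - z0
    }, error = function(e) NA_real_)
  }
  samples <- data.frame(z = zs - z0, z_abs = zs, x = cx, y = cy,
                        radius = rad, flagged = flagged)
  structure(list(samples = samples, step = step, axis = axis,
                 landmarks = landmarks, anchor = "Q436:CA", z0_abs = z0),
            class = "pore_profile")
}

.default_seed_point <- function(structure, chain) {
  mid <- tryCatch({
    c1 <- atom_coords(structure, select_atoms(structure, chain, 337L, "CA"))
    c2 <- atom_coords(structure, select_atoms(structure, chain, 447L, "CA"))
    as.numeric((c1 + c2) / 2)
  }, error = function(e) NULL)
  if (!is.null(mid)) mid else colMeans(atom_coords(structure))
}

.rotation_to_z <- function(axis) {
  z <- c(0, 0, 1)
  v <- c(axis[2] * z[3] - axis[3] * z[2],
         axis[3] * z[1] - axis[1] * z[3],
         axis[1] * z[2] - axis[2] * z[1])
  s <- sqrt(sum(v^2)); cth <- sum(axis * z)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # axis = -z: flip about x
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

# clearance radius at in-plane centre c2 = (x, y), slice height z
.pore_radius_at <- function(c2, z, xyz, R, zwin = 20) {
  near <- abs(xyz[, 3] - z) <= zwin
  dx <- xyz[near, 1] - c2[1]; dy <- xyz[near, 2] - c2[2]
  dz <- xyz[near, 3] - z
  min(sqrt(dx * dx + dy * dy + dz * dz) - R[near])
}

.optimize_slice <- function(start, z, xyz, R, n_starts, max_radius) {
  near <- abs(xyz[, 3] - z) <= max_radius + max(R) + 1
  sub <- xyz[near, , drop = FALSE]; Rs <- R[near]
  if (!nrow(sub)) return(list(c = start, r = max_radius))
  obj <- function(c2) {
    dx <- sub[, 1] - c2[1]; dy <- sub[, 2] - c2[2]; dz <- sub[, 3] - z
    -min(sqrt(dx * dx + dy * dy + dz * dz) - Rs)
  }
  best <- NULL
  starts <- rbind(start,
                  matrix(rep(start, each = n_starts), n_starts, 2) +
                    matrix(stats::rnorm(2 * n_starts, sd = 0.8), n_starts, 2))
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
    # polish with a small-step coordinate refinement
    o2 <- stats::optim(o$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 200, reltol = 1e-12))
    if (is.null(best) || o2$value < best$value) best <- o2
  }
  r <- min(-best$value, max_radius)
  list(c = as.numeric(best$par), r = r)
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf("<pore_profile> %d slices, step %.2f A, min radius %.2f A\n",
              nrow(x$samples), x$step, min(x$samples$radius, na.rm = TRUE)))
  invisible(x)
}

#' Pore minimum (constriction)
#'
#' Exact minimum radius over the profile samples in a channel-coordinate
#' window, with the constriction position and the corresponding diameter.
#'
#' @param profile a `pore_profile`.
#' @param z_window optional `c(lo, hi)` channel-coordinate window.
#' @return list with `z_min`, `r_min`, `diameter`.
#' @export
min_pore <- function(profile, z_window = NULL) {
  s <- profile$samples
  if (!is.null(z_window)) {
    s <- s[s$z >= z_window[1] & s$z <= z_window[2], ]
  }
  s <- s[is.finite(s$radius), ]
  if (!nrow(s)) stop("no profile samples in window")
  i <- which.min(s$radius)
  list(z_min = s$z[i], r_min = s$radius[i], diameter = 2 * s$radius[i])
}

#' Pore-region grid points
#'
#' All grid points lying within the profiled pore (inside `radius(z)` of the
#' slice centre at their height) but farther than `clearance` (default
#' 2.5 A) from every protein atom; the point set used to mask electrostatic
#' potential exports to the pore region.
#'
#' @param structure the profiled `gf_structure`.
#' @param profile a `pore_profile` of that structure.
#' @param grid_spacing point spacing, Angstrom.
#' @param clearance minimum distance from any atom, Angstrom.
#' @return matrix of 3D points (possibly 0 rows).
#' @export
pore_region_points <- function(structure, profile, grid_spacing = 0.5,
                               clearance = 2.5) {
  s <- profile$samples[is.finite(profile$samples$radius), ]
  if (!nrow(s)) return(matrix(numeric(0), 0, 3))
  rot <- .rotation_to_z(profile$axis)
  xyzr <- atom_coords(structure) %*% t(rot)
  R <- structure$atoms$vdw_radius
  pts <- list()
  xs_all <- seq(min(s$x - s$radius), max(s$x + s$radius), by = grid_spacing)
  ys_all <- seq(min(s$y - s$radius), max(s$y + s$radius), by = grid_spacing)
  zs <- seq(min(s$z_abs), max(s$z_abs), by = grid_spacing)
  for (z in zs) {
    i <- which.min(abs(s$z_abs - z))
    rad <- s$radius[i]
    if (!is.finite(rad) || rad <= 0) next
    g <- expand.grid(x = xs_all, y = ys_all)
    inside <- (g$x - s$x[i])^2 + (g$y - s$y[i])^2 <= rad^2
    g <- g[inside, , drop = FALSE]
    if (!nrow(g)) next
    p <- cbind(g$x, g$y, z)
    d2 <- .cross_dist2(p, xyzr)
    ok <- apply(d2, 1, min) > clearance^2
    if (any(ok)) pts[[length(pts) + 1]] <- p[ok, , drop = FALSE]
  }
  if (!length(pts)) return(matrix(numeric(0), 0, 3))
  out <- do.call(rbind, pts)
  # back to the original frame
  out %*% rot
}
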