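# Independent oracles used across the suite. Each is deliberately a
# different algorithm from the implementation it checks.

# Horn's quaternion method for optimal superposition RMSD (oracle for the
# SVD-based Kabsch implementation).
quaternion_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(P, Q)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  n <- nrow(P)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / n
  sqrt(max(msd, 0))
}

# Closed-form solution of the two-leaflet reduction/flipping ODE
#   dF_out/dt = -(g + b) F_out + a F_in,  dF_in/dt = b F_out - a F_in
# from the scrambling steady state (a, b)/(a + b), mixed with the
# protein-free pool by f0. Uses LAPACK eigen-decomposition: independent of
# the hand-coded closed form in ftot().
ode_ftot_oracle <- function(t, f0, a, b, g, L) {
  A <- matrix(c(-(g + b), b, a, -a), 2, 2)
  x0 <- c(a, b) / (a + b)
  e <- eigen(A)
  c0 <- solve(e$vectors, x0)
  pro <- vapply(t, function(tt) {
    sum(Re(e$vectors %*% (c0 * exp(e$values * tt))))
  }, numeric(1))
  f0 * (L + (1 - L) * exp(-g * t)) + (1 - f0) * pro
}

# Step-doubling classical RK4 integration of the same ODE (validates the
# eigen oracle itself on a subset of draws).
rk4_ftot_oracle <- function(t_grid, f0, a, b, g, L, dt = 1e-3) {
  A <- matrix(c(-(g + b), b, a, -a), 2, 2)
  x <- c(a, b) / (a + b)
  out <- numeric(length(t_grid))
  ti <- 0; j <- 1
  if (t_grid[1] == 0) { out[1] <- 1; j <- 2 }
  tmax <- max(t_grid)
  while (ti < tmax - 1e-12 && j <= length(t_grid)) {
    h <- min(dt, t_grid[j] - ti)
    k1 <- A %*% x
    k2 <- A %*% (x + h / 2 * k1)
    k3 <- A %*% (x + h / 2 * k2)
    k4 <- A %*% (x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    ti <- ti + h
    if (abs(ti - t_grid[j]) < 1e-12) {
      out[j] <- f0 * (L + (1 - L) * exp(-g * ti)) + (1 - f0) * sum(x)
      j <- j + 1
    }
  }
  out
}

# Exhaustive sphere-fit oracle: best clearance radius over a 2D grid of
# candidate centres in the slice plane (grid step `h`).
brute_pore_radius <- function(structure, z, xy_half = 2.5, h = 0.1,
                              center = c(0, 0)) {
  xyz <- atom_coords(structure)
  R <- structure$atoms$vdw_radius
  xs <- seq(center[1] - xy_half, center[1] + xy_half, by = h)
  ys <- seq(center[2] - xy_half, center[2] + xy_half, by = h)
  best <- -Inf
  for (x in xs) {
    dx2 <- (xyz[, 1] - x)^2
    for (y in ys) {
      r <- min(sqrt(dx2 + (xyz[, 2] - y)^2 + (xyz[, 3] - z)^2) - R)
      if (r > best) best <- r
    }
  }
  best
}

# O(n*m) brute-force minimum distance between two atom index sets.
brute_min_dist <- function(structure, idx_a, idx_b) {
  ca <- atom_coords(structure, idx_a)
  cb <- atom_coords(structure, idx_b)
  best <- Inf
  for (i in seq_len(nrow(ca))) {
    d <- sqrt(colSums((t(cb) - ca[i, ])^2))
    best <- min(best, min(d))
  }
  best
}

# random draws over the physically plausible assay parameter space
random_params <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(f0 = runif(n, 0.05, 0.95),
             a = 10^runif(n, -3, 0.5),
             b = 10^runif(n, -3, 0.5),
             g = runif(n, 0.5, 4),
             L = runif(n, 0.3, 0.7))
}

# random proper rotation matrix
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_transform_structure <- function(st, R = random_rotation(),
                                      shift = rnorm(3, sd = 5)) {
  set_coords(st, sweep(atom_coords(st) %*% t(R), 2, shift, "+"))
}

# toy groove with the feature residues pinned at controlled distances
controlled_toy_groove <- function(...) {
  make_toy_groove(ca_positions = list(
    "337" = c(0, 0, 0), "447" = c(10, 0, 0),
    "333" = c(0, 6, -3), "439" = c(8, 6, -3),
    "432" = c(12, 8, 2), "313" = c(20, 8, 2), "318" = c(24, 12, 2),
    "302" = c(-8, -6, 0), "343" = c(-2, -8, 0)), ...)
}
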