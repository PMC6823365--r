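grid_node <- function(grid, p) {
  idx <- round((p - grid$origin) / grid$spacing) + 1
  list(eps = grid$eps[idx[1], idx[2], idx[3]],
       kappa2 = grid$kappa2[idx[1], idx[2], idx[3]])
}

test_that("membrane map assigns dielectric bands, hole and ion access", {
  atoms <- data.frame(atom_name = "C1", residue_name = "ION", chain_id = "Q",
                      residue_number = 1L, x = 0, y = 0, z = 40,
                      element = "C", vdw_radius = 1.5, partial_charge = 0)
  st <- gf_structure(atoms)   # far from the slab: triggers the warning too
  spec <- membrane_dielectric_spec()
  expect_warning(g <- build_maps(st, spec, spacing = 1, box = 50),
                 "does not intersect")
  # slab mid-height inside the 18 A cylinder: water dielectric, ions allowed
  n <- grid_node(g, c(5, 0, 0))
  expect_equal(n$eps, 80)
  expect_gt(n$kappa2, 0)
  # headgroup band outside the cylinder: eps 30, no ions
  n <- grid_node(g, c(30, 0, 15))
  expect_equal(n$eps, 30)
  expect_equal(n$kappa2, 0)
  # hydrophobic core outside the cylinder: eps 2, no ions
  n <- grid_node(g, c(30, 0, 0))
  expect_equal(n$eps, 2)
  expect_equal(n$kappa2, 0)
  # bulk solvent above the slab: eps 80 with ions
  n <- grid_node(g, c(30, 0, 30))
  expect_equal(n$eps, 80)
  expect_gt(n$kappa2, 0)
  # protein interior: protein dielectric, ion-excluded
  spec2 <- membrane_dielectric_spec(membrane = FALSE)
  atoms$z <- 0
  g2 <- build_maps(gf_structure(atoms), spec2, spacing = 0.5, box = 8)
  n <- grid_node(g2, c(0, 0, 0))
  expect_equal(n$eps, 2)
  expect_equal(n$kappa2, 0)
  # membrane off: uniform water everywhere away from the atom
  n <- grid_node(g2, c(5, 5, 5))
  expect_equal(n$eps, 80)
})

test_that("zero charge solves to an identically zero potential", {
  atoms <- data.frame(atom_name = "C1", residue_name = "ION", chain_id = "Q",
                      residue_number = 1L, x = 0, y = 0, z = 0,
                      element = "C", vdw_radius = 1.0, partial_charge = 0)
  spec <- membrane_dielectric_spec(membrane = FALSE, eps_protein = 80,
                                   ionic_strength_mM = 0)
  g <- build_maps(gf_structure(atoms), spec, spacing = 1, box = 10)
  g <- solve_lpbe(g)
  expect_true(all(g$phi == 0))
})

test_that("Coulomb limit within 5% on the 5-15 A shell", {
  sys <- make_point_charge_system(data.frame(x = 0, y = 0, z = 0, q = 1),
                                  box = 18, salt_mM = 0)
  g <- solve_lpbe(build_maps(sys$structure, sys$spec, spacing = 0.5,
                             box = sys$box))
  set.seed(131)
  for (r in c(5, 10, 15)) {
    u <- matrix(rnorm(60), 20, 3); u <- u / sqrt(rowSums(u^2))
    phi <- interp_phi(g, u * r)
    ref <- 332.0637 / (80 * r)
    expect_lt(max(abs(phi / ref - 1)), 0.05)
  }
})

test_that("Debye-Hueckel screened limit within 5%", {
  sys <- make_point_charge_system(data.frame(x = 0, y = 0, z = 0, q = 1),
                                  box = 18, salt_mM = 150)
  g <- solve_lpbe(build_maps(sys$structure, sys$spec, spacing = 0.5,
                             box = sys$box))
  kap <- 1 / debye_length(150)
  set.seed(137)
  for (r in c(5, 10, 15)) {
    u <- matrix(rnorm(60), 20, 3); u <- u / sqrt(rowSums(u^2))
    phi <- interp_phi(g, u * r)
    ref <- 332.0637 * exp(-kap * r) / (80 * r)
    expect_lt(max(abs(phi / ref - 1)), 0.05)
  }
})

test_that("linearity and charge-scaling identities hold", {
  mk <- function(q1, q2) {
    ch <- data.frame(x = c(-3, 3), y = 0, z = 0, q = c(q1, q2))
    ch <- ch[ch$q != 0, , drop = FALSE]
    sys <- make_point_charge_system(ch, box = 12, salt_mM = 0)
    solve_lpbe(build_maps(sys$structure, sys$spec, spacing = 0.6,
                          box = sys$box), tol = 1e-5)
  }
  ga <- mk(1, 0); gb <- mk(0, -0.5); gab <- mk(1, -0.5)
  expect_lt(max(abs(gab$phi - (ga$phi + gb$phi))), 2e-3)
  g2 <- mk(2, -1)
  expect_lt(max(abs(g2$phi - 2 * gab$phi)), 2e-3)
})

test_that("Coulomb-limit error decreases under grid refinement", {
  err_at <- function(h) {
    sys <- make_point_charge_system(data.frame(x = 0, y = 0, z = 0, q = 1),
                                    box = 10, salt_mM = 0)
    g <- solve_lpbe(build_maps(sys$structure, sys$spec, spacing = h,
                               box = sys$box))
    set.seed(139)
    u <- matrix(rnorm(90), 30, 3); u <- u / sqrt(rowSums(u^2))
    pts <- u * 6
    max(abs(interp_phi(g, pts) / (332.0637 / (80 * 6)) - 1))
  }
  errs <- vapply(c(1.0, 0.5, 1 / 3), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("more salt means more screening everywhere in solvent", {
  phis <- lapply(c(0, 150, 600), function(s) {
    sys <- make_point_charge_system(data.frame(x = 0, y = 0, z = 0, q = 1),
                                    box = 20, salt_mM = s)
    g <- solve_lpbe(build_maps(sys$structure, sys$spec, spacing = 0.8,
                               box = sys$box))
    interp_phi(g, rbind(c(6, 0, 0), c(0, 9, 0), c(0, 0, 12)))
  })
  expect_true(all(phis[[2]] < phis[[1]]))
  expect_true(all(phis[[3]] < phis[[2]]))
})

test_that("EP profile reads the pore axis and honours symmetry", {
  cyl <- make_pore_toy("cylinder", ring_radius = 6, atom_radius = 1.7,
                       z_range = c(-6, 6))
  pr <- profile_pore(cyl, seed_point = c(0, 0, 0), z_range = c(-4, 4),
                     step = 1, chain = "P")
  # uniform synthetic potential: flat profile at that value
  sys0 <- make_point_charge_system(data.frame(x = 0, y = 0, z = 0, q = 0),
                                   box = 12, salt_mM = 0)
  g <- build_maps(sys0$structure, sys0$spec, spacing = 1, box = 12)
  g$phi <- array(0.75, g$dims)
  prof <- ep_profile(g, pr)
  expect_true(all(prof$phi == 0.75))
  expect_true(all(diff(prof$z) < 0))  # EC -> IC ordering
  # +/- pair mirrored about z = 0: antisymmetric potential along the axis
  sysp <- make_point_charge_system(data.frame(x = 0, y = 0, z = c(4, -4),
                                              q = c(1, -1)),
                                   box = 14, salt_mM = 0)
  gp <- solve_lpbe(build_maps(sysp$structure, sysp$spec, spacing = 0.5,
                              box = sysp$box), tol = 1e-5)
  zq <- seq(-8, 8, by = 1)
  phi_axis <- interp_phi(gp, cbind(1.2, 0, zq))
  expect_equal(phi_axis, -rev(phi_axis), tolerance = 1e-2)
  # toy pore lined by positive charges: positive potential along the span
  lined <- cyl
  lined$atoms$partial_charge <- 0.1
  sysl <- list(structure = lined,
               spec = membrane_dielectric_spec(membrane = FALSE,
                                               ionic_strength_mM = 0))
  gl <- solve_lpbe(build_maps(sysl$structure, sysl$spec, spacing = 0.8,
                              padding = 8))
  prof_l <- ep_profile(gl, pr)
  expect_true(all(prof_l$phi > 0))
})

test_that("isorange export clips, masks and counts", {
  sys <- make_point_charge_system(data.frame(x = 0, y = 0, z = 0, q = 5),
                                  box = 10, salt_mM = 0)
  g <- solve_lpbe(build_maps(sys$structure, sys$spec, spacing = 0.8,
                             box = sys$box))
  pts <- rbind(c(3, 0, 0), c(0, 5, 0), c(0, 0, 7))
  exp_surf <- ep_isorange_surface(g, pts, range = c(-1, 1))
  expect_equal(nrow(exp_surf), nrow(pts))  # count equals mask cardinality
  expect_true(all(exp_surf$phi <= 1 & exp_surf$phi >= -1))
  expect_gt(interp_phi(g, rbind(c(3, 0, 0))), 1)  # clipping was real
  empty <- ep_isorange_surface(g, matrix(numeric(0), 0, 3))
  expect_equal(nrow(empty), 0)
})

test_that("non-convergence raises an error carrying the residual history", {
  sys <- make_point_charge_system(data.frame(x = 0, y = 0, z = 0, q = 1),
                                  box = 10, salt_mM = 0)
  g <- build_maps(sys$structure, sys$spec, spacing = 0.8, box = sys$box)
  expect_error(solve_lpbe(g, tol = 1e-10, max_iter = 3), "converge")
})

test_that("OpenDX export round-trips header and values", {
  sys <- make_point_charge_system(data.frame(x = 0, y = 0, z = 0, q = 1),
                                  box = 6, salt_mM = 0)
  g <- solve_lpbe(build_maps(sys$structure, sys$spec, spacing = 1,
                             box = sys$box))
  f <- withr::local_tempfile(fileext = ".dx")
  write_opendx(g, f)
  lines <- readLines(f)
  expect_match(lines[1], sprintf("counts %d %d %d", g$dims[1], g$dims[2],
                                 g$dims[3]))
  dat <- as.numeric(unlist(strsplit(trimws(
    lines[8:(7 + ceiling(prod(g$dims) / 3))]), "\\s+")))
  expect_equal(length(dat), prod(g$dims))
  expect_equal(dat[1], g$phi[1, 1, 1], tolerance = 1e-5)
})
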