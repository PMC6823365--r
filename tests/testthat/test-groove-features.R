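test_that("minimal residue distance is exact and matches brute force", {
  atoms <- data.frame(
    atom_name = c("CA", "CA"), residue_name = c("ALA", "ALA"),
    chain_id = "A", residue_number = c(1L, 2L),
    x = c(0, 4), y = 0, z = 0, element = "C")
  st <- gf_structure(atoms)
  expect_equal(min_residue_distance(st, c("A", 1), c("A", 2)), 4.0)

  set.seed(21)
  for (rep in 1:10) {
    st <- rigid_transform_structure(controlled_toy_groove())
    a <- st$atoms
    for (pair in list(c(333L, 439L), c(302L, 343L), c(337L, 447L))) {
      ia <- which(a$residue_number == pair[1] & toupper(a$element) != "H")
      ib <- which(a$residue_number == pair[2] & toupper(a$element) != "H")
      expect_equal(min_residue_distance(st, c("A", pair[1]), c("A", pair[2])),
                   brute_min_dist(st, ia, ib), tolerance = 1e-12)
    }
  }
})

test_that("engaged TM3/TM4 lock geometry classifies at 3.2 A", {
  # place an I343 sidechain atom exactly 3.2 A beyond the x-extreme L302 atom
  st0 <- make_toy_groove(ca_positions = list("302" = c(0, 0, 0),
                                             "343" = c(40, 0, 0)))
  a302 <- st0$atoms[st0$atoms$residue_number == 302, ]
  ext <- a302[which.max(a302$x), ]
  st <- make_toy_groove(
    ca_positions = list("302" = c(0, 0, 0), "343" = c(40, 0, 0)),
    atom_overrides = data.frame(residue_number = 343L, atom_name = "CG",
                                x = ext$x + 3.2, y = ext$y, z = ext$z))
  d <- min_residue_distance(st, c("A", 302), c("A", 343))
  expect_equal(d, 3.2, tolerance = 1e-9)
  expect_true(classify_groove(st)$tm3_tm4_engaged)  # 3.2 <= 3.5
})

test_that("Glu-O/Arg-N rule takes the minimum over the configured sets", {
  st <- make_toy_groove(
    ca_positions = list("313" = c(0, 0, 0), "432" = c(30, 0, 0)),
    atom_overrides = data.frame(
      residue_number = c(313L, 313L, 432L, 432L, 432L),
      atom_name = c("OE1", "OE2", "NH1", "NE", "NH2"),
      x = c(27.0, 20.0, 30.0, 33.0, 33.0), y = c(0, 0, 0, 3, -3), z = 0))
  expect_equal(glu_arg_distance(st, c("A", 313), c("A", 432)), 3.0,
               tolerance = 1e-9)
  # truncated sidechain: clear error naming the atoms
  st2 <- controlled_toy_groove()
  st2$atoms <- st2$atoms[!(st2$atoms$residue_number == 313 &
                           st2$atoms$atom_name %in% c("OE1", "OE2")), ]
  st2 <- gf_structure(st2$atoms)
  expect_error(glu_arg_distance(st2, c("A", 313), c("A", 432)), "OE1")
})

test_that("feature vector matches hand-computed controlled geometry", {
  ov <- data.frame(
    residue_number = c(333L, 439L, 313L, 318L, 432L, 432L),
    atom_name = c("CB", "OH", "OE1", "OE1", "NH1", "NH2"),
    x = c(0, 5, 20, 28, 24, 23), y = c(0, 0, 5, 8, 5, 9), z = 0)
  st <- make_toy_groove(
    ca_positions = list("337" = c(0, -20, 0), "447" = c(9, -20, 0)),
    atom_overrides = ov)
  fv <- groove_feature_vector(st)
  a <- st$atoms
  # feature 1/2 must be <= the pinned-pair distances; compute by brute force
  for (nm in names(fv)) expect_gt(fv[[nm]], 0)
  i333 <- which(a$residue_number == 333 & toupper(a$element) != "H")
  i439 <- which(a$residue_number == 439 & toupper(a$element) != "H")
  expect_equal(unname(fv["d_T333_Y439"]), brute_min_dist(st, i333, i439),
               tolerance = 1e-12)
  expect_equal(unname(fv["d_E313_R432"]), 4.0, tolerance = 1e-9)  # (20,5)-(24,5)
  expect_equal(unname(fv["d_E318_R432"]), 5.0, tolerance = 1e-9)  # (28,8)-(24,5)
  expect_equal(unname(fv["d_V337_V447_CA"]), 9.0, tolerance = 1e-9)
})

test_that("features are invariant under rigid motion of the frame", {
  st <- controlled_toy_groove()
  fv <- groove_feature_vector(st)
  set.seed(31)
  for (i in 1:5) {
    st2 <- rigid_transform_structure(st)
    expect_equal(unclass(groove_feature_vector(st2)), unclass(fv),
                 tolerance = 1e-9)
  }
})

test_that("occlusion cutoff applies the documented boundary rule", {
  mk <- function(d) make_toy_groove(ca_positions = list(
    "337" = c(0, 0, 0), "447" = c(d, 0, 0)))
  expect_true(classify_groove(mk(7.0))$occluded)
  expect_true(classify_groove(mk(8.5))$occluded)   # boundary -> occluded
  expect_false(classify_groove(mk(12.0))$occluded)
})

test_that("water counting honours the 3 A rule and the slab planes", {
  st0 <- make_toy_groove()
  cb <- st0$atoms[st0$atoms$residue_number == 306 &
                  st0$atoms$atom_name == "CB", ]
  near <- c(cb$x, cb$y + 2.9, cb$z)
  far_w <- c(60, 60, 0)
  stw <- make_toy_groove(waters = rbind(near, far_w))
  res <- count_region_waters(stw, "groove")
  expect_equal(res$count, 1L)
  # far from every listed sidechain: not counted
  stf <- make_toy_groove(waters = rbind(far_w))
  expect_equal(count_region_waters(stf, "groove")$count, 0L)
  # slab: waters planted between the T381/Q436 Calpha planes
  z381 <- st0$atoms$z[st0$atoms$residue_number == 381 &
                      st0$atoms$atom_name == "CA"]
  z436 <- st0$atoms$z[st0$atoms$residue_number == 436 &
                      st0$atoms$atom_name == "CA"]
  zin <- seq(min(z381, z436), max(z381, z436), length.out = 12)
  ws <- cbind(40, seq(0, 22, length.out = 12), zin)
  sts <- make_toy_groove(waters = ws)
  slab <- count_region_waters(sts, "slab")
  expect_equal(slab$count, 12L)
  # brute-force z-window oracle agrees
  wz <- sts$atoms$z[sts$atoms$residue_name == "HOH"]
  expect_equal(slab$count, sum(wz >= min(z381, z436) & wz <= max(z381, z436)))
})

test_that("enlarging radii never decreases counts or fractions", {
  set.seed(41)
  ws <- cbind(runif(30, -12, 12), runif(30, -12, 12), runif(30, -14, 14))
  st <- make_toy_groove(waters = ws)
  c3 <- count_region_waters(st, "groove", radius = 3)$count
  c4 <- count_region_waters(st, "groove", radius = 4)$count
  expect_gte(c4, c3)
})

test_that("lipid penetration fractions and brute-force agreement", {
  st0 <- make_toy_groove()
  # fully outside
  lip_out <- list(list(head = rbind(c(60, 60, 0), c(60, 61, 0)),
                       tail = cbind(60, 62:69, 0)))
  res <- lipid_penetration(make_toy_groove(lipids = lip_out))
  expect_equal(res$head_fraction, 0)
  expect_equal(res$tail_fraction, 0)
  # exactly half the tail within 5 A of an interior sidechain
  cb <- st0$atoms[st0$atoms$residue_number == 505 &
                  st0$atoms$atom_name == "CB", ]
  near4 <- cbind(cb$x + seq(0.6, 2.4, by = 0.6), cb$y, cb$z)
  far4 <- cbind(60, 60 + seq(1, 4), 0)
  lip_half <- list(list(head = rbind(c(60, 50, 0), c(60, 51, 0)),
                        tail = rbind(near4, far4)))
  res2 <- lipid_penetration(make_toy_groove(lipids = lip_half))
  expect_equal(res2$tail_fraction, 0.5)
  expect_equal(res2$head_fraction, 0)
  # brute-force agreement on a random frame
  set.seed(51)
  st <- make_toy_groove(lipids = list(list(
    head = rbind(c(10, 4, 1), c(10, 5, 1)),
    tail = cbind(runif(8, -6, 10), runif(8, -6, 10), runif(8, -8, 8)))))
  res3 <- lipid_penetration(st)
  a <- st$atoms
  sel <- select_atoms(st, "A", intersect(GROOVE_INTERIOR_RESIDUES,
                                         a$residue_number), "sidechain_heavy")
  sc <- atom_coords(st, sel)
  ti <- which(a$residue_name == "TLP" & grepl("^CT", a$atom_name))
  frac <- mean(vapply(ti, function(i) {
    min(sqrt(colSums((t(sc) - c(a$x[i], a$y[i], a$z[i]))^2))) <= 5
  }, logical(1)))
  expect_equal(res3$tail_fraction, frac, tolerance = 1e-12)
  # unknown lipid residue errors with the supported list
  bad <- st0
  bad$atoms <- rbind(bad$atoms, data.frame(
    serial = max(bad$atoms$serial) + 1, atom_name = "C1", altloc = "",
    residue_name = "DOPC", chain_id = "L", residue_number = 3000L,
    icode = "", x = 50, y = 50, z = 0, occupancy = 1, element = "C",
    vdw_radius = 1.7, partial_charge = NA_real_))
  bad <- gf_structure(bad$atoms)
  expect_error(lipid_penetration(bad), "DOPC")
})

test_that("scripted occluded/open label sequences are recovered exactly", {
  script <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  frames <- lapply(script, function(occ) {
    d <- if (occ) 7.5 else 12.5
    atom_coords(make_toy_groove(ca_positions = list(
      "337" = c(0, 0, 0), "447" = c(d, 0, 0))))
  })
  st <- make_toy_groove(ca_positions = list("337" = c(0, 0, 0),
                                            "447" = c(7.5, 0, 0)))
  tr <- new_trajectory(st, frames)
  feats <- trajectory_features(tr, hydration = FALSE, lipids = FALSE)
  expect_identical(feats$occluded, script)
})
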