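#' Minimal inter-residue distance
#'
#' Exact minimum distance over all atom pairs of the chosen class between two
#' residues ("the closest pair of atoms"). Heavy atoms by default so the same
#' rule serves deposited structures (no hydrogens) and MD frames; set
#' `include_hydrogens = TRUE` to reproduce an all-atom convention.
#'
#' @param structure a `gf_structure` (one frame).
#' @param resA,resB length-2 vectors `c(chain, residue_number)`.
#' @param atom_class atom class for both residues (see [select_atoms()]).
#' @param include_hydrogens include hydrogens (only meaningful with
#'   `atom_class = "all"`).
#' @return distance in Angstrom.
#' @export
min_residue_distance <- function(structure, resA, resB,
                                 atom_class = "heavy",
                                 include_hydrogens = FALSE) {
  if (include_hydrogens && atom_class == "heavy") atom_class <- "all"
  sa <- select_atoms(structure, resA[1], as.integer(resA[2]), atom_class)
  sb <- select_atoms(structure, resB[1], as.integer(resB[2]), atom_class)
  ca <- atom_coords(structure, sa)
  cb <- atom_coords(structure, sb)
  sqrt(min(.cross_dist2(ca, cb)))
}

# squared distances between two coordinate sets (n x 3, m x 3) -> n x m
.cross_dist2 <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Glu-O / Arg-N salt-bridge distance
#'
#' Distance between a glutamate oxygen and an arginine sidechain nitrogen,
#' taken as the minimum over the configured oxygen set times N (NE, NH1,
#' NH2). The default oxygen set is the sidechain carboxylate (OE1/OE2);
#' `glu_oxygens = "backbone"` uses the backbone carbonyl O instead (the
#' literal reading of "carbonyl oxygen") without silent reinterpretation.
#'
#' @param structure a `gf_structure`.
#' @param glu,arg length-2 vectors `c(chain, residue_number)`.
#' @param glu_oxygens `"carboxylate"` (OE1/OE2, default) or `"backbone"` (O).
#' @return distance in Angstrom.
#' @export
glu_arg_distance <- function(structure, glu, arg,
                             glu_oxygens = c("carboxylate", "backbone")) {
  glu_oxygens <- match.arg(glu_oxygens)
  a <- structure$atoms
  o_names <- if (glu_oxygens == "carboxylate") c("OE1", "OE2") else "O"
  n_names <- c("NE", "NH1", "NH2")
  gi <- which(a$chain_id == glu[1] &
              a$residue_number == as.integer(glu[2]) &
              a$atom_name %in% o_names)
  ri <- which(a$chain_id == arg[1] &
              a$residue_number == as.integer(arg[2]) &
              a$atom_name %in% n_names)
  if (!length(gi) || !length(ri)) {
    stop(sprintf("required atoms absent: Glu %s/%s needs {%s}, Arg %s/%s needs {%s}",
                 glu[1], glu[2], paste(o_names, collapse = ","),
                 arg[1], arg[2], paste(n_names, collapse = ",")))
  }
  sqrt(min(.cross_dist2(atom_coords(structure, gi),
                        atom_coords(structure, ri))))
}

#' Five-feature groove state vector
#'
#' The five distances spanning the slow conformational coordinates of the
#' groove: (1) minimal T333-Y439; (2) minimal Y439-R432; (3) E313-R432 and
#' (4) E318-R432 by the Glu-O/Arg-N rule; (5) the V337-V447 Calpha-Calpha
#' distance.
#'
#' @param structure a `gf_structure` (one frame).
#' @param chain protomer chain, default "A".
#' @inheritParams glu_arg_distance
#' @return named numeric vector of 5 distances (Angstrom), class
#'   `groove_features`.
#' @export
groove_feature_vector <- function(structure, chain = "A",
                                  glu_oxygens = "carboxylate") {
  v <- c(
    d_T333_Y439 = min_residue_distance(structure, c(chain, 333), c(chain, 439)),
    d_Y439_R432 = min_residue_distance(structure, c(chain, 439), c(chain, 432)),
    d_E313_R432 = glu_arg_distance(structure, c(chain, 313), c(chain, 432),
                                   glu_oxygens = glu_oxygens),
    d_E318_R432 = glu_arg_distance(structure, c(chain, 318), c(chain, 432),
                                   glu_oxygens = glu_oxygens),
    d_V337_V447_CA = {
      ca1 <- atom_coords(structure, select_atoms(structure, chain, 337, "CA"))
      ca2 <- atom_coords(structure, select_atoms(structure, chain, 447, "CA"))
      sqrt(sum((ca1 - ca2)^2))
    })
  if (any(!is.finite(v)) || any(v <= 0)) stop("invalid feature distances")
  class(v) <- c("groove_features", "numeric")
  v
}

#' Groove-state labels for one frame
#'
#' Deterministic cutoff rules: `occluded` iff the V337-V447 Calpha distance
#' is <= 8.5 A (boundary value classified occluded); `tm3_tm4_engaged` iff
#' the minimal L302-I343 distance is <= 3.5 A; `direct_contact` iff the
#' minimal V337-V447 distance is < 2.5 A.
#'
#' @param structure a `gf_structure`.
#' @param chain protomer chain.
#' @param features optionally a precomputed [groove_feature_vector()] (used
#'   for the Calpha cutoff; the other two distances are measured from the
#'   frame).
#' @return list with logicals `occluded`, `tm3_tm4_engaged`,
#'   `direct_contact` and the distances used.
#' @export
classify_groove <- function(structure, chain = "A", features = NULL) {
  d_ca <- if (!is.null(features)) {
    unname(features["d_V337_V447_CA"])
  } else {
    ca1 <- atom_coords(structure, select_atoms(structure, chain, 337, "CA"))
    ca2 <- atom_coords(structure, select_atoms(structure, chain, 447, "CA"))
    sqrt(sum((ca1 - ca2)^2))
  }
  d_lock <- min_residue_distance(structure, c(chain, 302), c(chain, 343))
  d_min <- min_residue_distance(structure, c(chain, 337), c(chain, 447))
  list(occluded = d_ca <= OCCLUSION_CUTOFF_CA,
       tm3_tm4_engaged = d_lock <= TM3_TM4_ENGAGED_CUTOFF,
       direct_contact = d_min < DIRECT_CONTACT_CUTOFF,
       d_V337_V447_CA = d_ca, d_L302_I343_min = d_lock,
       d_V337_V447_min = d_min)
}

#' Groove hydration counts
#'
#' `region = "groove"`: a water counts if any of its atoms lies within
#' `radius` (default 3 A, inclusive) of any sidechain atom of the
#' groove-lining residues. `region = "slab"`: a water counts if any atom's z
#' lies between the membrane planes defined by the T381 and Q436 Calpha z
#' coordinates (inclusive); this slab is called the extracellular vestibule
#' or the central region of the groove depending on context, so the plane
#' residues are recorded in the result.
#'
#' @param structure a `gf_structure`.
#' @param region `"groove"` or `"slab"`.
#' @param chain protomer chain.
#' @param radius membership radius, Angstrom (groove rule).
#' @param water_names residue names identifying waters.
#' @param lining_residues residue numbers whose sidechains define the groove.
#' @return list with `count`, `region`, `water_residues` (numbers counted)
#'   and region metadata.
#' @export
count_region_waters <- function(structure, region = c("groove", "slab"),
                                chain = "A", radius = 3,
                                water_names = c("HOH", "TIP3", "WAT", "SOL"),
                                lining_residues = GROOVE_LINING_RESIDUES) {
  region <- match.arg(region)
  a <- structure$atoms
  wi <- which(a$residue_name %in% water_names)
  if (!length(wi)) {
    .gf_log("no waters in frame")
    return(list(count = 0L, region = region, water_residues = integer(0)))
  }
  wat <- a[wi, ]
  if (region == "groove") {
    present <- intersect(lining_residues,
                         a$residue_number[a$chain_id == chain])
    sel <- select_atoms(structure, chain, present, "sidechain_heavy")
    sc <- atom_coords(structure, sel)
    d2 <- .cross_dist2(as.matrix(wat[, c("x", "y", "z")]), sc)
    hit <- apply(d2 <= radius^2, 1, any)
    meta <- list(lining_residues = present, radius = radius)
  } else {
    z1 <- .ca_z(structure, chain, 381L)
    z2 <- .ca_z(structure, chain, 436L)
    lo <- min(z1, z2); hi <- max(z1, z2)
    hit <- wat$z >= lo & wat$z <= hi
    meta <- list(plane_residues = c(381L, 436L), z_planes = c(lo, hi))
  }
  counted <- unique(wat$residue_number[hit])
  c(list(count = length(counted), region = region,
         water_residues = counted), meta)
}

.ca_z <- function(structure, chain, resnum) {
  sel <- select_atoms(structure, chain, resnum, "CA")
  structure$atoms$z[sel$indices]
}

# head atoms of supported lipid types (non-hydrogen), down to the C21-O21 /
# C31-O32 carbonyls; everything else non-hydrogen is tail.
.LIPID_HEAD_ATOMS <- list(
  TLP = c("PH1", "PH2"),
  POPE = c("N", "C12", "C11", "P", "O13", "O14", "O12", "O11",
           "C1", "C2", "C3", "O21", "C21", "O22", "O31", "C31", "O32"),
  POPG = c("C13", "OC3", "C12", "OC2", "C11", "P", "O13", "O14", "O12",
           "O11", "C1", "C2", "C3", "O21", "C21", "O22", "O31", "C31", "O32"),
  POPC = c("N", "C15", "C14", "C13", "C12", "C11", "P", "O13", "O14",
           "O12", "O11", "C1", "C2", "C3", "O21", "C21", "O22", "O31",
           "C31", "O32"))

#' Lipid head/tail penetration into the groove
#'
#' For each lipid, the fraction of head (resp. tail) non-hydrogen atoms
#' within `radius` (default 5 A, inclusive) of any sidechain atom of the
#' interior groove residues, normalized by the total number of such atoms.
#' The reported `head_fraction`/`tail_fraction` are the per-lipid maxima,
#' identifying the (single) most-penetrating lipid; the full per-lipid
#' breakdown is returned alongside.
#'
#' @param structure a `gf_structure`.
#' @param chain protomer chain.
#' @param radius membership radius, Angstrom.
#' @param interior_residues residues lining the groove interior.
#' @return list with `head_fraction`, `tail_fraction` and `per_lipid`
#'   data.frame (lipid residue number, residue name, fractions).
#' @export
lipid_penetration <- function(structure, chain = "A", radius = 5,
                              interior_residues = GROOVE_INTERIOR_RESIDUES) {
  a <- structure$atoms
  li <- which(a$residue_name %in% names(.LIPID_HEAD_ATOMS))
  unknown <- setdiff(unique(a$residue_name[a$chain_id == "L"]),
                     names(.LIPID_HEAD_ATOMS))
  if (length(unknown)) {
    stop("unknown lipid residue name(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(names(.LIPID_HEAD_ATOMS), collapse = ", "))
  }
  if (!length(li)) {
    return(list(head_fraction = 0, tail_fraction = 0,
                per_lipid = data.frame()))
  }
  present <- intersect(interior_residues,
                       a$residue_number[a$chain_id == chain])
  sel <- select_atoms(structure, chain, present, "sidechain_heavy")
  sc <- atom_coords(structure, sel)
  lip <- a[li, ]
  keys <- unique(paste(lip$chain_id, lip$residue_number))
  rows <- lapply(keys, function(k) {
    sub <- lip[paste(lip$chain_id, lip$residue_number) == k, ]
    heavy <- sub[toupper(sub$element) != "H", ]
    head_set <- .LIPID_HEAD_ATOMS[[heavy$residue_name[1]]]
    is_head <- heavy$atom_name %in% head_set
    d2 <- .cross_dist2(as.matrix(heavy[, c("x", "y", "z")]), sc)
    near <- apply(d2 <= radius^2, 1, any)
    data.frame(chain_id = heavy$chain_id[1],
               residue_number = heavy$residue_number[1],
               residue_name = heavy$residue_name[1],
               head_fraction = if (any(is_head)) mean(near[is_head]) else 0,
               tail_fraction = if (any(!is_head)) mean(near[!is_head]) else 0,
               stringsAsFactors = FALSE)
  })
  per_lipid <- do.call(rbind, rows)
  list(head_fraction = max(per_lipid$head_fraction),
       tail_fraction = max(per_lipid$tail_fraction),
       per_lipid = per_lipid)
}

#' Per-frame groove feature table for a trajectory
#'
#' Runs [groove_feature_vector()], [classify_groove()], water counts and
#' lipid penetration over every frame and returns one row per frame;
#' the workhorse behind the feature-extraction stage of the pipeline.
#'
#' @param trajectory a `gf_trajectory`.
#' @param chain protomer chain.
#' @param hydration,lipids logical switches for the optional metrics.
#' @return data.frame, one row per frame.
#' @export
trajectory_features <- function(trajectory, chain = "A", hydration = TRUE,
                                lipids = TRUE) {
  rows <- lapply(seq_along(trajectory$frames), function(i) {
    st <- trajectory_frame(trajectory, i)
    fv <- groove_feature_vector(st, chain = chain)
    lab <- classify_groove(st, chain = chain, features = fv)
    row <- data.frame(frame = trajectory$frame_index[i], t(unclass(fv)))
    row$occluded <- lab$occluded
    row$tm3_tm4_engaged <- lab$tm3_tm4_engaged
    row$direct_contact <- lab$direct_contact
    if (hydration) {
      row$n_groove_waters <- count_region_waters(st, "groove", chain)$count
      row$n_slab_waters <- count_region_waters(st, "slab", chain)$count
    }
    if (lipids) {
      lp <- lipid_penetration(st, chain)
      row$head_fraction <- lp$head_fraction
      row$tail_fraction <- lp$tail_fraction
    }
    row
  })
  do.call(rbind, rows)
}
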