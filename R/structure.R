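#' Structure container
#'
#' A `gf_structure` wraps an atom table (one row per atom, stable order) plus
#' a title. Columns: `serial`, `atom_name`, `altloc`, `residue_name`,
#' `chain_id`, `residue_number`, `icode`, `x`, `y`, `z`, `occupancy`,
#' `element`, `vdw_radius`, `partial_charge`.
#'
#' @param atoms data.frame of atom records (missing optional columns are
#'   filled with defaults).
#' @param title character scalar stored with the structure.
#' @return object of class `gf_structure`.
#' @export
gf_structure <- function(atoms, title = "") {
  req <- c("atom_name", "residue_name", "chain_id", "residue_number",
           "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1.0
  if (is.null(atoms$element)) {
    atoms$element <- guess_element(atoms$atom_name, atoms$residue_name)
  }
  if (is.null(atoms$vdw_radius)) {
    atoms$vdw_radius <- assign_vdw_radii(atoms$element)
  }
  if (is.null(atoms$partial_charge)) atoms$partial_charge <- NA_real_
  atoms$residue_number <- as.integer(atoms$residue_number)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")
  if (any(atoms$vdw_radius <= 0, na.rm = TRUE)) {
    stop("vdw_radius must be > 0 where assigned")
  }
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$icode,
               atoms$atom_name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, icode, atom_name) records: ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "gf_structure")
}

#' @export
print.gf_structure <- function(x, ...) {
  cat(sprintf("<gf_structure> %d atoms, %d chains%s\n",
              nrow(x$atoms), length(unique(x$atoms$chain_id)),
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param structure a `gf_structure`.
#' @param sel optional integer indices (e.g. from [select_atoms()]).
#' @return N x 3 numeric matrix in Angstrom.
#' @export
atom_coords <- function(structure, sel = NULL) {
  a <- structure$atoms
  if (!is.null(sel)) {
    if (inherits(sel, "gf_selection")) sel <- sel$indices
    a <- a[sel, , drop = FALSE]
  }
  m <- as.matrix(a[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace atom coordinates
#' @param structure a `gf_structure`.
#' @param coords N x 3 matrix matching the structure's atom count.
#' @return a new `gf_structure` with updated coordinates.
#' @export
set_coords <- function(structure, coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(structure$atoms), ncol(coords) == 3)
  structure$atoms$x <- coords[, 1]
  structure$atoms$y <- coords[, 2]
  structure$atoms$z <- coords[, 3]
  structure
}

# ---------------------------------------------------------------------------
# PDB / PQR reading

.parse_pdb_num <- function(txt, lines_no, what) {
  v <- suppressWarnings(as.numeric(txt))
  bad <- is.na(v) & nzchar(trimws(txt))
  bad[is.na(v) & !nzchar(trimws(txt))] <- TRUE
  if (any(bad)) {
    stop(sprintf("malformed %s field in PDB record at line %d",
                 what, lines_no[which(bad)[1]]))
  }
  v
}

#' Read a structure from PDB or PQR
#'
#' All ATOM/HETATM records are represented. Alternate locations are resolved
#' to a single conformer: the highest-occupancy altloc per atom, ties broken
#' in favour of altloc "A" (then alphabetically). For multi-model files only
#' the first MODEL is read (use [read_trajectory()] for all frames). PQR
#' input populates `partial_charge` and `vdw_radius` from the file.
#'
#' @param path file path.
#' @param format `"pdb"` or `"pqr"`; default guessed from the extension.
#' @return a [gf_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pqr")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "pqr") return(.read_pqr(lines, path))
  .read_pdb(lines, path, first_model_only = TRUE)$structure
}

.read_pdb <- function(lines, path, first_model_only = TRUE) {
  title <- ""
  t_idx <- grep("^TITLE", lines)
  if (length(t_idx)) {
    title <- trimws(paste(substring(lines[t_idx], 11), collapse = " "))
  }
  endmdl <- grep("^ENDMDL", lines)
  model_starts <- grep("^MODEL", lines)
  n_models <- max(length(model_starts), 1L)
  if (first_model_only && length(endmdl)) {
    lines_use <- lines[seq_len(endmdl[1])]
  } else {
    lines_use <- lines
  }
  rec <- grep("^(ATOM  |HETATM)", lines_use)
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  ln <- lines_use[rec]
  ln <- formatC(ln, width = 80, flag = "-")
  atoms <- data.frame(
    serial = as.integer(.parse_pdb_num(substr(ln, 7, 11), rec, "serial")),
    atom_name = trimws(substr(ln, 13, 16)),
    altloc = trimws(substr(ln, 17, 17)),
    residue_name = trimws(substr(ln, 18, 20)),
    chain_id = trimws(substr(ln, 22, 22)),
    residue_number = as.integer(.parse_pdb_num(substr(ln, 23, 26), rec,
                                               "residue number")),
    icode = trimws(substr(ln, 27, 27)),
    x = .parse_pdb_num(substr(ln, 31, 38), rec, "x"),
    y = .parse_pdb_num(substr(ln, 39, 46), rec, "y"),
    z = .parse_pdb_num(substr(ln, 47, 54), rec, "z"),
    occupancy = {
      o <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
      o[is.na(o)] <- 1.0
      o
    },
    element = trimws(substr(ln, 77, 78)),
    stringsAsFactors = FALSE)
  blank_el <- !nzchar(atoms$element)
  if (any(blank_el)) {
    atoms$element[blank_el] <- guess_element(atoms$atom_name[blank_el],
                                             atoms$residue_name[blank_el])
  }
  atoms <- .resolve_altlocs(atoms)
  atoms$vdw_radius <- assign_vdw_radii(atoms$element)
  atoms$partial_charge <- NA_real_
  list(structure = gf_structure(atoms, title = title), n_models = n_models)
}

.resolve_altlocs <- function(atoms) {
  if (!any(nzchar(atoms$altloc))) return(atoms)
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$icode,
               atoms$atom_name)
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    occ <- atoms$occupancy[idx]
    best <- idx[occ == max(occ)]
    if (length(best) > 1) {
      al <- atoms$altloc[best]
      best <- if (any(al == "A")) best[al == "A"][1] else best[order(al)][1]
    }
    keep[setdiff(idx, best)] <- FALSE
  }
  atoms <- atoms[keep, , drop = FALSE]
  atoms$altloc <- ""
  rownames(atoms) <- NULL
  atoms
}

.read_pqr <- function(lines, path) {
  rec_i <- grep("^(ATOM|HETATM)", lines)
  if (!length(rec_i)) stop("no ATOM/HETATM records in ", path)
  rows <- lapply(rec_i, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    # with chain: rec serial name resname chain resnum x y z q r  (11 fields)
    # without:    rec serial name resname resnum x y z q r        (10 fields)
    if (length(f) == 11L) {
      chain <- f[5]; rest <- f[6:11]
    } else if (length(f) == 10L) {
      chain <- "A"; rest <- f[5:10]
    } else {
      stop(sprintf("malformed PQR record at line %d (%d fields)",
                   i, length(f)))
    }
    num <- suppressWarnings(as.numeric(rest))
    if (any(is.na(num))) stop("malformed PQR numeric field at line ", i)
    data.frame(serial = as.integer(f[2]), atom_name = f[3],
               residue_name = f[4], chain_id = chain,
               residue_number = as.integer(num[1]),
               x = num[2], y = num[3], z = num[4],
               partial_charge = num[5], vdw_radius = num[6],
               stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  atoms$element <- guess_element(atoms$atom_name, atoms$residue_name)
  bad_r <- atoms$vdw_radius <= 0
  if (any(bad_r)) {
    # PQR hydrogens occasionally carry zero radii; fall back to the table
    atoms$vdw_radius[bad_r] <- assign_vdw_radii(atoms$element[bad_r])
  }
  gf_structure(atoms, title = basename(path))
}

# ---------------------------------------------------------------------------
# Writing

#' Write a structure to PDB or PQR
#'
#' Emits standard-conformant fixed-width records; coordinates keep the PDB
#' format's 0.001 A precision, identifiers round-trip exactly.
#'
#' @param structure a `gf_structure`.
#' @param path output file path.
#' @param format `"pdb"` or `"pqr"`.
#' @export
write_structure <- function(structure, path, format = c("pdb", "pqr")) {
  format <- match.arg(format)
  a <- structure$atoms
  if (format == "pdb") {
    lines <- .format_pdb_lines(a)
  } else {
    q <- a$partial_charge
    q[is.na(q)] <- 0
    lines <- sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f %7.4f %6.4f",
                     a$serial %% 100000, .pdb_atom_name(a$atom_name, a$element),
                     a$residue_name, a$chain_id, a$residue_number,
                     a$x, a$y, a$z, q, a$vdw_radius)
  }
  header <- if (nzchar(structure$title)) {
    sprintf("TITLE     %s", structure$title)
  } else character(0)
  writeLines(c(header, lines, "END"), path)
  invisible(path)
}

.pdb_atom_name <- function(name, element) {
  # one-letter elements are indented one column per the PDB convention
  ifelse(nchar(name) >= 4 | nchar(element) >= 2,
         formatC(name, width = 4, flag = "-"),
         paste0(" ", formatC(name, width = 3, flag = "-")))
}

.format_pdb_lines <- function(a) {
  rec <- ifelse(a$residue_name %in% .AMINO3, "ATOM  ", "HETATM")
  sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial %% 100000,
          .pdb_atom_name(a$atom_name, a$element),
          a$altloc, a$residue_name, a$chain_id, a$residue_number, a$icode,
          a$x, a$y, a$z, a$occupancy, 0, formatC(a$element, width = 2))
}

# ---------------------------------------------------------------------------
# Trajectories

#' Read a trajectory
#'
#' Multi-model PDB files (MODEL/ENDMDL) or CSV frame tables with columns
#' `frame, atom_index, x, y, z` are supported. CSV input requires a
#' `reference` structure defining atom order.
#'
#' @param path file path.
#' @param format `"pdb"` or `"csv"` (guessed from the extension by default).
#' @param reference a `gf_structure` giving atom order for CSV input.
#' @return a `gf_trajectory`: list with `reference` (a `gf_structure`) and
#'   `frames` (list of N x 3 coordinate matrices), plus `frame_index`.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "csv"),
                            reference = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "pdb"
  }
  if (format == "csv") {
    if (is.null(reference)) stop("CSV trajectories require a reference structure")
    tab <- utils::read.csv(path, comment.char = "#")
    req <- c("frame", "atom_index", "x", "y", "z")
    if (!all(req %in% names(tab))) {
      stop("trajectory CSV must have columns: ", paste(req, collapse = ", "))
    }
    n_at <- nrow(reference$atoms)
    fr_ids <- sort(unique(tab$frame))
    frames <- lapply(fr_ids, function(f) {
      sub <- tab[tab$frame == f, ]
      sub <- sub[order(sub$atom_index), ]
      if (nrow(sub) != n_at) {
        stop(sprintf("frame %d has %d atoms; reference has %d",
                     f, nrow(sub), n_at))
      }
      unname(as.matrix(sub[, c("x", "y", "z")]))
    })
    return(new_trajectory(reference, frames, frame_index = as.integer(fr_ids)))
  }
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (!length(starts)) {
    parsed <- .read_pdb(lines, path)
    return(new_trajectory(parsed$structure,
                          list(atom_coords(parsed$structure)), 1L))
  }
  if (length(starts) != length(ends)) stop("unbalanced MODEL/ENDMDL in ", path)
  ref <- NULL
  frames <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1):(ends[i] - 1)]
    st <- .read_pdb(block, path)$structure
    if (is.null(ref)) {
      ref <- st
    } else if (nrow(st$atoms) != nrow(ref$atoms)) {
      stop(sprintf("model %d atom count (%d) differs from model 1 (%d)",
                   i, nrow(st$atoms), nrow(ref$atoms)))
    }
    frames[[i]] <- atom_coords(st)
  }
  new_trajectory(ref, frames, seq_along(frames))
}

#' Construct a trajectory in memory
#' @param reference a `gf_structure` defining atom order.
#' @param frames list of N x 3 coordinate matrices.
#' @param frame_index integer frame labels (strictly increasing).
#' @export
new_trajectory <- function(reference, frames, frame_index = seq_along(frames)) {
  stopifnot(inherits(reference, "gf_structure"))
  n_at <- nrow(reference$atoms)
  for (f in frames) {
    if (nrow(f) != n_at) stop("frame atom count mismatch with reference")
  }
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != length(frames) ||
      (length(frame_index) > 1 && any(diff(frame_index) <= 0))) {
    stop("frame_index must be strictly increasing, one per frame")
  }
  structure(list(reference = reference, frames = frames,
                 frame_index = frame_index), class = "gf_trajectory")
}

#' Extract one frame of a trajectory as a structure
#' @param trajectory a `gf_trajectory`.
#' @param i frame position (1-based).
#' @export
trajectory_frame <- function(trajectory, i) {
  set_coords(trajectory$reference, trajectory$frames[[i]])
}

#' Write a trajectory as a multi-model PDB
#' @param trajectory a `gf_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(trajectory, path) {
  out <- character(0)
  for (i in seq_along(trajectory$frames)) {
    st <- trajectory_frame(trajectory, i)
    out <- c(out, sprintf("MODEL %8d", trajectory$frame_index[i]),
             .format_pdb_lines(st$atoms), "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Selection

#' Select atoms by chain, residues and atom class
#'
#' Atom classes: `backbone` = N, CA, C, O; `CA`; `heavy` = non-hydrogen;
#' `sidechain_heavy` = heavy atoms beyond the backbone; `all`. For glycine,
#' `sidechain_heavy` falls back to CA (the sidechain terminus convention) so
#' selections are never silently empty; this is logged.
#'
#' @param structure a `gf_structure`.
#' @param chain chain identifier.
#' @param residues integer vector of residue numbers.
#' @param atom_class one of `all`, `heavy`, `backbone`, `sidechain_heavy`, `CA`.
#' @return object of class `gf_selection` with `indices` and `description`.
#' @export
select_atoms <- function(structure, chain, residues,
                         atom_class = c("all", "heavy", "backbone",
                                        "sidechain_heavy", "CA")) {
  atom_class <- match.arg(atom_class)
  a <- structure$atoms
  residues <- as.integer(residues)
  in_res <- a$chain_id == chain & a$residue_number %in% residues
  missing_res <- setdiff(residues, a$residue_number[a$chain_id == chain])
  if (length(missing_res)) {
    stop(sprintf("residue(s) %s absent from chain %s",
                 paste(missing_res, collapse = ", "), chain))
  }
  backbone_names <- c("N", "CA", "C", "O")
  is_h <- toupper(a$element) == "H"
  keep <- switch(atom_class,
    all = in_res,
    heavy = in_res & !is_h,
    CA = in_res & a$atom_name == "CA",
    backbone = in_res & a$atom_name %in% backbone_names,
    sidechain_heavy = in_res & !is_h & !(a$atom_name %in% backbone_names))
  if (atom_class == "sidechain_heavy") {
    # glycine: no sidechain heavy atoms; use CA as the sidechain terminus
    for (r in residues) {
      ri <- in_res & a$residue_number == r
      if (!any(keep & ri)) {
        if (any(a$residue_name[ri] == "GLY")) {
          keep <- keep | (ri & a$atom_name == "CA")
          .gf_log("GLY %s/%d: using CA as sidechain terminus", chain, r)
        }
      }
    }
  }
  idx <- which(keep)
  if (!length(idx)) {
    stop(sprintf("empty selection: chain %s residues %s atom_class %s",
                 chain, paste(residues, collapse = ","), atom_class))
  }
  structure(list(indices = idx,
                 description = sprintf("chain %s res %s [%s]", chain,
                                       paste(residues, collapse = ","),
                                       atom_class)),
            class = "gf_selection")
}
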