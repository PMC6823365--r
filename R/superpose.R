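#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` using the Kabsch
#' SVD algorithm; the returned rotation is proper (det = +1).
#'
#' @param mobile N x 3 coordinate matrix.
#' @param reference N x 3 coordinate matrix, same N.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom). The transform maps mobile coordinates as
#'   `coords %*% t(rotation) + translation`.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    stop("mobile and reference must be N x 3 matrices of equal size")
  }
  n <- nrow(mobile)
  if (n < 3) stop("superposition requires at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1)) {
    stop("rank-deficient (collinear) point configuration")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(sum((moved - Q)^2) / n)
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)), rmsd = rmsd)
}

#' Backbone/atom-class RMSD over named residue ranges
#'
#' Selects exactly the named atoms in both structures (error listing any
#' residue missing from either), superposes them optimally, and reports the
#' post-superposition RMSD. Atoms are matched by (chain, residue, atom name).
#'
#' @param a,b `gf_structure` objects.
#' @param residue_ranges data.frame with columns `chain`, `start`, `end`
#'   (inclusive residue ranges).
#' @param atom_class atom class as in [select_atoms()]; default `"backbone"`.
#' @param on_missing `"error"` (default; residues named in a range but absent
#'   from either structure are an error, listed) or `"trim"` (use the
#'   residues present in both; needed when comparing against models with
#'   unresolved segments).
#' @return RMSD in Angstrom.
#' @export
region_rmsd <- function(a, b, residue_ranges, atom_class = "backbone",
                        on_missing = c("error", "trim")) {
  on_missing <- match.arg(on_missing)
  stopifnot(all(c("chain", "start", "end") %in% names(residue_ranges)))
  tab_a <- .region_atoms(a, residue_ranges, atom_class, "a", on_missing)
  tab_b <- .region_atoms(b, residue_ranges, atom_class, "b", on_missing)
  key_a <- paste(tab_a$chain_id, tab_a$residue_number, tab_a$atom_name)
  key_b <- paste(tab_b$chain_id, tab_b$residue_number, tab_b$atom_name)
  common <- intersect(key_a, key_b)
  if (length(common) < 3) stop("fewer than 3 matched atoms between structures")
  dropped <- length(union(key_a, key_b)) - length(common)
  if (dropped > 0) {
    .gf_log("region_rmsd: %d unmatched atoms dropped", dropped)
  }
  ma <- as.matrix(tab_a[match(common, key_a), c("x", "y", "z")])
  mb <- as.matrix(tab_b[match(common, key_b), c("x", "y", "z")])
  superpose(ma, mb)$rmsd
}

.region_atoms <- function(s, ranges, atom_class, label,
                          on_missing = "error") {
  out <- list(); missing_res <- character(0)
  for (i in seq_len(nrow(ranges))) {
    ch <- ranges$chain[i]
    res <- seq.int(ranges$start[i], ranges$end[i])
    present <- intersect(res, s$atoms$residue_number[s$atoms$chain_id == ch])
    absent <- setdiff(res, present)
    if (length(absent)) {
      missing_res <- c(missing_res, sprintf("%s:%s", ch,
                                            paste(absent, collapse = ",")))
    }
    if (length(present)) {
      sel <- select_atoms(s, ch, present, atom_class)
      out[[length(out) + 1]] <- s$atoms[sel$indices, ]
    }
  }
  if (length(missing_res)) {
    if (on_missing == "error") {
      stop(sprintf("structure '%s' lacks residues %s", label,
                   paste(missing_res, collapse = "; ")))
    }
    .gf_log("region_rmsd: trimmed missing residues %s in '%s'",
            paste(missing_res, collapse = "; "), label)
  }
  do.call(rbind, out)
}
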