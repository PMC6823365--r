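# Approximate TM-helix residue ranges of the fungal scramblase, exposed as
# config because the exact ranges behind published whole-TM RMSD figures are
# not recorded; derived from the X-ray structure's helix annotations and
# adjustable per run.
#' Default transmembrane helix ranges
#'
#' @param chain chain id applied to every range.
#' @return data.frame with columns `chain`, `start`, `end`, `helix`.
#' @export
tm_helix_ranges <- function(chain = "A") {
  data.frame(chain = chain,
             start = c(198, 235, 283, 326, 361, 423, 490, 518, 552, 583),
             end = c(224, 263, 312, 354, 386, 453, 512, 545, 578, 611),
             helix = paste0("TM", 1:10), stringsAsFactors = FALSE)
}

#' Groove-lining helix ranges (TM3-TM6)
#' @inheritParams tm_helix_ranges
#' @export
groove_tm_ranges <- function(chain = "A") {
  r <- tm_helix_ranges(chain)
  r[r$helix %in% c("TM3", "TM4", "TM5", "TM6"), ]
}

#' Structural measurements on deposited coordinates
#'
#' Runs the deterministic structural measurements that compare deposited
#' models of the scramblase groove: the extracellular-gate salt-bridge
#' distances (E313/E318 to R432), whole-TM and groove-TM backbone RMSDs,
#' and the minimum pore diameter of the ion-conductive protomer. Requires
#' locally available coordinate files (they are not bundled):
#' `dir` must contain `4wis.pdb`, `6oy3.pdb` and `6qma.pdb`.
#'
#' @param dir directory with the deposited PDB files.
#' @param chain protomer chain analysed.
#' @return named list of measurements (Angstrom) with elements
#'   `d_E313_R432_4wis`, `d_E318_R432_4wis`, `d_E313_R432_6oy3`,
#'   `d_E318_R432_6oy3`, `rmsd_tm_4wis_6oy3`, `rmsd_groove_4wis_6qma`,
#'   `min_diameter_6oy3`.
#' @export
measure_deposited_targets <- function(dir, chain = "A") {
  paths <- file.path(dir, c("4wis.pdb", "6oy3.pdb", "6qma.pdb"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("deposited coordinate file(s) not found: ",
         paste(missing, collapse = ", "),
         " (download from the PDB and place them there)")
  }
  wt <- read_structure(paths[1])
  em <- read_structure(paths[2])
  im <- read_structure(paths[3])
  prof <- profile_pore(em, chain = chain)
  list(
    d_E313_R432_4wis = glu_arg_distance(wt, c(chain, 313), c(chain, 432)),
    d_E318_R432_4wis = glu_arg_distance(wt, c(chain, 318), c(chain, 432)),
    d_E313_R432_6oy3 = glu_arg_distance(em, c(chain, 313), c(chain, 432)),
    d_E318_R432_6oy3 = glu_arg_distance(em, c(chain, 318), c(chain, 432)),
    rmsd_tm_4wis_6oy3 = region_rmsd(wt, em, tm_helix_ranges(chain),
                                    on_missing = "trim"),
    rmsd_groove_4wis_6qma = region_rmsd(wt, im, groove_tm_ranges(chain),
                                        on_missing = "trim"),
    min_diameter_6oy3 = min_pore(prof)$diameter)
}
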