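#' Van der Waals radii
#'
#' Built-in Bondi-style element radii (Angstrom) used wherever a structure
#' lacks explicit radii (PDB input; PQR input carries its own). The table can
#' be overridden entry-wise via `override`.
#'
#' @param override optional named numeric vector of radii keyed by element
#'   symbol (upper case), taking precedence over the built-in values.
#' @return named numeric vector of radii in Angstrom.
#' @export
vdw_radius_table <- function(override = NULL) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
           NA. = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.60)
  names(tab)[names(tab) == "NA."] <- "NA"
  if (!is.null(override)) {
    stopifnot(is.numeric(override), !is.null(names(override)))
    tab[toupper(names(override))] <- override
  }
  tab
}

# Fallback radius for elements missing from the table (warned once per call).
.DEFAULT_VDW <- 1.70

assign_vdw_radii <- function(elements, override = NULL) {
  tab <- vdw_radius_table(override)
  r <- unname(tab[toupper(elements)])
  miss <- is.na(r)
  if (any(miss)) {
    warning(sprintf("unknown element(s) %s: using fallback vdW radius %.2f A",
                    paste(unique(elements[miss]), collapse = ", "),
                    .DEFAULT_VDW))
    r[miss] <- .DEFAULT_VDW
  }
  r
}

# Derive an element symbol from a PDB atom name when columns 77-78 are blank.
# PDB convention: the element occupies the first of the four name columns for
# two-letter elements; hydrogens may start with a digit.
guess_element <- function(atom_name, residue_name = "") {
  nm <- toupper(trimws(atom_name))
  nm <- sub("^[0-9']+", "", nm)
  two <- substr(nm, 1, 2)
  known2 <- c("CL", "BR", "NA", "MG", "ZN", "FE")
  ifelse(residue_name %in% c("CA") & nm == "CA", "CA",
    ifelse(two %in% known2 & !(residue_name %in% .AMINO3 & two %in% c("NA")),
           two, substr(nm, 1, 1)))
}

.AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL", "HSD", "HSE", "HSP")
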