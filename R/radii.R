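#' Built-in van der Waals radius table
#'
#' Bondi-style vdW radii (in Angstrom) used to assign a radius to every atom
#' read from a structure file. Keys are upper-case element symbols. Values can
#' be overridden per call via the `radii` argument of [read_ensemble()].
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vdw_radii()[["C"]]  # 1.7
vdw_radii <- function() {
  c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
    P = 1.80, S = 1.80, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    B = 1.92, SI = 2.10,
    # common ions; generous defaults
    NA. = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.52,
    MN = 1.61, CU = 1.40)
}

# Element symbol from a PDB atom: prefer the element column, fall back to the
# leading letters of the atom name (digits and primes stripped, "CA" in a
# protein residue is carbon).
.guess_element <- function(elesy, name) {
  e <- toupper(trimws(elesy))
  if (!is.na(e) && nzchar(e)) return(sub("^NA$", "NA.", e))
  nm <- gsub("[^A-Za-z]", "", toupper(trimws(name)))
  if (!nzchar(nm)) return(NA_character_)
  two <- substr(nm, 1, 2)
  if (two %in% c("CL", "BR", "SE", "SI", "MG", "ZN", "FE", "MN", "CU")) return(two)
  substr(nm, 1, 1)
}

.assign_vdw <- function(atoms, radii = NULL) {
  tab <- vdw_radii()
  if (!is.null(radii)) tab[toupper(names(radii))] <- radii
  el <- vapply(seq_len(nrow(atoms)),
               function(i) .guess_element(atoms$element[i], atoms$name[i]),
               character(1))
  r <- unname(tab[el])
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop("unknown element for atom serial ", atoms$serial[bad],
         " (name '", atoms$name[bad], "', element '", atoms$element[bad],
         "'); extend the `radii` table to cover it", call. = FALSE)
  }
  atoms$element <- el
  atoms$vdw <- r
  atoms
}
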