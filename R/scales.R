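# Residue-level lookup tables used across the package.

#' Amino-acid property scales
#'
#' Kyte-Doolittle hydropathy values and Zamyatnin residue volumes for the 20
#' standard amino acids, plus the three-letter/one-letter code table. These
#' back the per-heptad-position composition statistics.
#'
#' @return `aa_scales()` returns a tibble with columns `aa` (one-letter code),
#'   `hydropathy` (Kyte-Doolittle units) and `volume` (cubic Angstrom).
#' @export
#' @examples
#' aa_scales()
aa_scales <- function() {
  tibble::tibble(
    aa = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    hydropathy = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
                   3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2),
    volume = c(88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4, 60.1, 153.2,
               166.7, 166.7, 168.6, 162.9, 189.9, 112.7, 89.0, 116.1, 227.8,
               193.6, 140.0)
  )
}

# three-letter -> one-letter map (standard residues only)
aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

aa_one_to_three <- setNames(names(aa_three_to_one), unname(aa_three_to_one))

#' Heptad position letters
#'
#' The seven heptad repeat positions in order.
#' @return Character vector `c("a","b","c","d","e","f","g")`.
#' @export
heptad_letters <- function() letters[1:7]

# surface-exposed heptad positions (everything outside the a/d core and
# core-flanking e/g is solvent facing; e and g themselves are peripheral
# and accessible to an amine crosslinker)
surface_positions <- c("b", "c", "e", "f", "g")
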