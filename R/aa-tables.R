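#' Per-residue coarse-grained bead parameters
#'
#' One-bead-per-residue parameter tables used by [build_ca_protein()]:
#' average residue masses (Da), bead radii (Angstrom) and formal charges
#' (elementary charge units).
#'
#' Radii are derived from the Zamyatnin (1972) amino-acid volumes V as the
#' radius of the sphere of equal volume, r = (3V / 4pi)^(1/3).  Charges
#' are +1 for Lys/Arg, -1 for Asp/Glu and 0 otherwise (His neutral).  These
#' tables are this package's documented choice for a generic Calpha model;
#' any column can be overridden when building a protein.
#'
#' @return A data.frame with one row per standard amino acid and columns
#'   `aa` (one-letter code), `aa3` (three-letter code), `mass`, `volume`,
#'   `radius` and `charge`.
#' @examples
#' tab <- aa_bead_params()
#' tab[tab$aa == "K", ]
#' @export
aa_bead_params <- function() {
  tab <- data.frame(
    aa  = c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V"),
    aa3 = c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
            "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL"),
    mass = c(71.0788, 156.1875, 114.1038, 115.0886, 103.1388,
             128.1307, 129.1155, 57.0519, 137.1411, 113.1594,
             113.1594, 128.1741, 131.1926, 147.1766, 97.1167,
             87.0782, 101.1051, 186.2132, 163.1760, 99.1326),
    volume = c(88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4, 60.1,
               153.2, 166.7, 166.7, 168.6, 162.9, 189.9, 112.7, 89.0,
               116.1, 227.8, 193.6, 140.0),
    stringsAsFactors = FALSE
  )
  tab$radius <- (3 * tab$volume / (4 * pi))^(1 / 3)
  tab$charge <- ifelse(tab$aa %in% c("K", "R"), 1,
                       ifelse(tab$aa %in% c("D", "E"), -1, 0))
  tab
}

.aa3to1 <- function(aa3) {
  tab <- aa_bead_params()
  idx <- match(toupper(aa3), tab$aa3)
  out <- tab$aa[idx]
  out[is.na(out)] <- "X"
  out
}
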