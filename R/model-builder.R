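#' Construct a coarse-grained one-bead-per-residue protein
#'
#' Low-level constructor for the `cg_protein` class: one bead per residue
#' placed at the Calpha position, with per-bead mass, radius and formal
#' charge.  [build_ca_protein()] builds one from a PDB structure; this
#' constructor is used directly for synthetic chains.
#'
#' @param positions n x 3 numeric matrix of bead coordinates (Angstrom).
#' @param sequence character vector of one-letter residue codes (length n),
#'   or a single string; defaults to all-alanine.
#' @param native_positions n x 3 matrix of reference (native) coordinates;
#'   defaults to `positions`.
#' @param masses,radii,charges optional per-bead overrides; defaults come
#'   from [aa_bead_params()] via the sequence.
#' @param resno optional integer residue numbers (1-based default).
#' @param validate check chain-geometry invariants (consecutive native
#'   Calpha-Calpha distances within 2.8-4.5 Angstrom).
#' @return An object of class `cg_protein`.
#' @examples
#' pos <- cbind(seq(0, by = 3.8, length.out = 5), 0, 0)
#' p <- cg_protein(pos, sequence = "GAKAG")
#' p$charges
#' @export
cg_protein <- function(positions, sequence = NULL, native_positions = NULL,
                       masses = NULL, radii = NULL, charges = NULL,
                       resno = NULL, validate = TRUE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (n < 2L || ncol(positions) != 3L)
    stop("positions must be an n x 3 matrix with n >= 2")
  if (is.null(native_positions)) native_positions <- positions
  native_positions <- as.matrix(native_positions)
  if (!all(dim(native_positions) == dim(positions)))
    stop("native_positions must match positions in shape")
  if (is.null(sequence)) sequence <- rep("A", n)
  if (length(sequence) == 1L && nchar(sequence) == n)
    sequence <- strsplit(sequence, "")[[1]]
  if (length(sequence) != n) stop("sequence length must equal n_residues")
  tab <- aa_bead_params()
  idx <- match(sequence, tab$aa)
  if (is.null(masses))  masses  <- ifelse(is.na(idx), 110.0, tab$mass[idx])
  if (is.null(radii))   radii   <- ifelse(is.na(idx), 3.2,  tab$radius[idx])
  if (is.null(charges)) charges <- ifelse(is.na(idx), 0,    tab$charge[idx])
  if (any(radii <= 0)) stop("all radii must be > 0")
  if (any(masses <= 0)) stop("all masses must be > 0")
  if (is.null(resno)) resno <- seq_len(n)
  if (validate) {
    d <- sqrt(rowSums((native_positions[-1, , drop = FALSE] -
                       native_positions[-n, , drop = FALSE])^2))
    if (any(d < 2.8 | d > 4.5))
      stop(sprintf(
        "consecutive native Calpha-Calpha distance out of [2.8, 4.5] A at bond %d (%.2f A)",
        which(d < 2.8 | d > 4.5)[1], d[which(d < 2.8 | d > 4.5)[1]]))
  }
  structure(list(
    n_residues = n, positions = positions,
    native_positions = native_positions,
    masses = as.numeric(masses), radii = as.numeric(radii),
    charges = as.numeric(charges), sequence = sequence,
    resno = as.integer(resno)
  ), class = "cg_protein")
}

#' @export
print.cg_protein <- function(x, ...) {
  cat(sprintf("cg_protein: %d residues, net charge %+g\n",
              x$n_residues, sum(x$charges)))
  cat(" sequence:", paste(x$sequence, collapse = ""), "\n")
  invisible(x)
}

#' Build a Calpha coarse-grained protein from a native PDB structure
#'
#' Selects the Calpha atoms of one chain of a PDB structure and produces a
#' one-bead-per-residue [cg_protein()] whose native reference coordinates are
#' the crystal coordinates.  Bead masses, radii and charges come from
#' [aa_bead_params()].
#'
#' @param native_structure a `bio3d` pdb object (from [read_pdb()] /
#'   `bio3d::read.pdb`) or a path to a PDB file.
#' @param chain_id chain identifier to extract; `NULL` uses the whole file
#'   (which must then be a single chain).
#' @return A `cg_protein`.
#' @seealso [compute_native_contacts()], [write_cg_pdb()]
#' @export
build_ca_protein <- function(native_structure, chain_id = NULL) {
  pdb <- if (is.character(native_structure)) read_pdb(native_structure)
         else native_structure
  if (!inherits(pdb, "pdb")) stop("native_structure must be a pdb object or path")
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM") & at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain_id)) at <- at[at$chain %in% chain_id, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty chain: no ATOM records for the selected chain")
  # drop alternate locations other than the first
  if (!is.null(at$alt)) at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  key <- paste(at$resno, at$insert)
  ca <- at[at$elety == "CA", , drop = FALSE]
  res_all <- unique(key)
  res_ca <- paste(ca$resno, ca$insert)
  missing <- setdiff(res_all, res_ca)
  if (length(missing) > 0L)
    stop(sprintf("residue %s has no Calpha atom",
                 strsplit(missing[1], " ")[[1]][1]))
  if (any(duplicated(res_ca)))
    stop(sprintf("residue %s has multiple Calpha atoms after altloc filtering",
                 res_ca[duplicated(res_ca)][1]))
  # preserve file order
  ca <- ca[order(match(res_ca, res_all)), , drop = FALSE]
  pos <- cbind(ca$x, ca$y, ca$z)
  seq1 <- .aa3to1(ca$resid)
  cg_protein(pos, sequence = seq1, resno = ca$resno)
}

#' Native contact map of a coarse-grained protein
#'
#' Enumerates all residue pairs (i, j) with sequence separation
#' `j >= i + min_seq_sep` whose native Calpha-Calpha distance does not exceed
#' `cutoff` (inclusive).  These pairs define the fraction of native contacts
#' Q and anchor the contact-closed loops of the entanglement analysis.
#'
#' @param protein a [cg_protein()] with native coordinates.
#' @param cutoff native-contact distance cutoff in Angstrom (default 8.0).
#' @param min_seq_sep minimum sequence separation (default 4, i.e. j > i+3).
#' @return An object of class `native_contact_map`: a list with `contacts`
#'   (data.frame `i`, `j`, `d_native`), `N` (count) and `min_seq_sep`.
#' @examples
#' p <- make_miniprotein("hairpin", 16)
#' cm <- compute_native_contacts(p)
#' cm$N
#' @export
compute_native_contacts <- function(protein, cutoff = 8.0, min_seq_sep = 4L) {
  stopifnot(inherits(protein, "cg_protein"))
  pos <- protein$native_positions
  n <- protein$n_residues
  ii <- integer(0); jj <- integer(0); dd <- numeric(0)
  if (n >= min_seq_sep + 1L) {
    d <- as.matrix(stats::dist(pos))
    pair <- which(upper.tri(d), arr.ind = TRUE)
    sel <- (pair[, 2] - pair[, 1]) >= min_seq_sep & d[pair] <= cutoff
    ii <- pair[sel, 1]; jj <- pair[sel, 2]; dd <- d[pair][sel]
    o <- order(ii, jj)
    ii <- ii[o]; jj <- jj[o]; dd <- dd[o]
  }
  structure(list(
    contacts = data.frame(i = as.integer(ii), j = as.integer(jj),
                          d_native = as.numeric(dd)),
    N = length(ii), cutoff = cutoff, min_seq_sep = as.integer(min_seq_sep)
  ), class = "native_contact_map")
}

#' @export
print.native_contact_map <- function(x, ...) {
  cat(sprintf("native_contact_map: %d contacts (cutoff %.1f A, |j-i| >= %d)\n",
              x$N, x$cutoff, x$min_seq_sep))
  invisible(x)
}

#' Is a native contact formed in the current frame?
#'
#' A native contact is formed when the current Calpha-Calpha distance does
#' not exceed `tolerance_factor` times its native distance (inclusive).
#'
#' @param current_dist current distance(s), Angstrom.
#' @param d_native native distance(s), Angstrom; must be positive.
#' @param tolerance_factor formation tolerance (default 1.2).
#' @return logical vector.
#' @examples
#' contact_formed(7.1, 6.0)  # TRUE: 7.1 <= 7.2
#' contact_formed(7.3, 6.0)  # FALSE
#' @export
contact_formed <- function(current_dist, d_native, tolerance_factor = 1.2) {
  if (any(d_native <= 0)) stop("d_native must be > 0")
  current_dist <= tolerance_factor * d_native
}

#' Write a contact map as plain text
#'
#' One line per contact: `i j d_native`.
#'
#' @param map a `native_contact_map`.
#' @param path output file path.
#' @export
write_contact_map <- function(map, path) {
  write.table(map$contacts, path, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a plain-text contact map written by [write_contact_map()]
#'
#' @param path input file path.
#' @param min_seq_sep sequence-separation convention recorded in the map.
#' @return a `native_contact_map`.
#' @export
read_contact_map <- function(path, min_seq_sep = 4L) {
  df <- read.table(path, col.names = c("i", "j", "d_native"))
  structure(list(contacts = df, N = nrow(df), cutoff = max(df$d_native, 8.0),
                 min_seq_sep = as.integer(min_seq_sep)),
            class = "native_contact_map")
}
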