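#' Principal-axis dimensions of a molecule
#'
#' Eigen-decomposes the (unit-weight) coordinate covariance tensor of a set
#' of atomic positions, projects the points onto each principal axis, and
#' returns the extent (max minus min projection) along each axis, sorted in
#' descending order.
#'
#' @param atom_coords m x 3 numeric matrix of atomic coordinates (Angstrom),
#'   m >= 2.
#' @param mass_weighted use mass-weighted coordinates for the tensor;
#'   requires a `masses` attribute or argument.  Default `FALSE`
#'   (geometric tensor).
#' @param masses optional per-atom masses for `mass_weighted = TRUE`.
#' @return numeric length-3 vector `(dim_a, dim_b, dim_c)`, descending.
#' @examples
#' principal_dimensions(rbind(c(0, 0, 0), c(10, 0, 0)))  # c(10, 0, 0)
#' @export
principal_dimensions <- function(atom_coords, mass_weighted = FALSE,
                                 masses = NULL) {
  X <- as.matrix(atom_coords)
  if (nrow(X) < 2L || ncol(X) != 3L) stop("need >= 2 points in 3D")
  w <- if (mass_weighted) {
    if (is.null(masses)) stop("mass_weighted = TRUE requires masses")
    masses / sum(masses)
  } else rep(1 / nrow(X), nrow(X))
  ctr <- colSums(X * w)
  Xc <- sweep(X, 2, ctr)
  C <- crossprod(Xc * sqrt(w))           # weighted covariance (up to scale)
  if (max(abs(C)) < 1e-12) return(c(0, 0, 0))  # all points coincident
  ev <- eigen(C, symmetric = TRUE)
  proj <- Xc %*% ev$vectors
  dims <- apply(proj, 2, function(p) max(p) - min(p))
  sort(dims, decreasing = TRUE)
}

#' Synthetic or measured table of small-molecule dimensions
#'
#' Container for per-molecule principal-axis dimensions and molecular
#' weights, the population whose medians parameterize the generic ligand.
#'
#' @param dims n x 3 matrix (rows sorted descending: a >= b >= c, Angstrom).
#' @param molecular_weight per-molecule weight, Da.
#' @param id optional molecule identifiers.
#' @return object of class `drug_dimension_table` (a data.frame).
#' @export
drug_dimension_table <- function(dims, molecular_weight, id = NULL) {
  dims <- as.matrix(dims)
  if (ncol(dims) != 3L) stop("dims must have 3 columns")
  if (any(dims < 0)) stop("all dimensions must be >= 0")
  if (any(dims[, 1] < dims[, 2] | dims[, 2] < dims[, 3]))
    stop("each row must be sorted descending (a >= b >= c)")
  if (any(molecular_weight <= 0)) stop("molecular weights must be > 0")
  if (is.null(id)) id <- sprintf("mol%04d", seq_len(nrow(dims)))
  structure(data.frame(id = id, dim_a = dims[, 1], dim_b = dims[, 2],
                       dim_c = dims[, 3],
                       molecular_weight = molecular_weight,
                       stringsAsFactors = FALSE),
            class = c("drug_dimension_table", "data.frame"))
}

#' Median dimensions and weight of a molecule population
#'
#' Component-wise medians of the (descending-sorted) per-molecule
#' principal-axis dimensions, plus the median and mean molecular weight.
#' With no table, returns the published defaults for FDA-approved small
#' molecule drugs: 11.46 x 6.11 x 3.35 Angstrom, mean weight 388.46 Da.
#'
#' @param table a [drug_dimension_table()], or `NULL` for the defaults.
#' @return list with `dims` (length-3, descending), `median_weight`,
#'   `mean_weight`.
#' @export
median_dimensions <- function(table = NULL) {
  if (is.null(table)) {
    return(list(dims = c(11.46, 6.11, 3.35),
                median_weight = 388.46, mean_weight = 388.46))
  }
  if (nrow(table) == 0L) stop("empty dimension table")
  list(dims = c(median(table$dim_a), median(table$dim_b),
                median(table$dim_c)),
       median_weight = median(table$molecular_weight),
       mean_weight = mean(table$molecular_weight))
}

#' Build the generic nine-site octahedral coarse-grained ligand
#'
#' Constructs a rigid-ish octahedral bead model of a generic small-molecule
#' ligand: one site at the origin and eight distributed along the three
#' principal axes.  The longest axis carries four sites which, together with
#' the central site, evenly divide the span `[-a/2, +a/2]` (sites at
#' +/- a/4 and +/- a/2); the other two axes carry two sites each at
#' +/- b/2 and +/- c/2.  Every peripheral site is bonded to the center, and
#' the two outer long-axis sites are additionally bonded to their inner
#' neighbours.  All sites share one mass (total mass divided by 9), the
#' weak-interaction well depth `eps_i = 0.000132` kcal/mol, and radius
#' `R_i = 3.415358` Angstrom; sites carry no charge.
#'
#' @param dims length-3 descending dimensions (a, b, c) in Angstrom;
#'   defaults to the published medians via [median_dimensions()].
#' @param total_mass ligand mass in Da (default 388.46).
#' @param site_eps,site_radius per-site nonbonded parameters.
#' @param K_b bond force constant, kcal/mol/Angstrom^2.
#' @return object of class `cg_ligand`: list with `sites` (9 x 3 matrix),
#'   `bonds` (data.frame `a`, `b`, `b0`), `site_mass`, `site_eps`,
#'   `site_radius`, `total_mass`, `K_b`.
#' @examples
#' lig <- build_generic_ligand()
#' range(lig$sites[, 1])   # +/- 5.73 along the long axis
#' @export
build_generic_ligand <- function(dims = NULL, total_mass = 388.46,
                                 site_eps = 0.000132,
                                 site_radius = 3.415358, K_b = 50) {
  if (is.null(dims)) dims <- median_dimensions()$dims
  if (length(dims) != 3L || any(diff(dims) > 1e-12))
    stop("dims must be three values sorted descending (a >= b >= c)")
  if (any(dims < 0)) stop("dims must be >= 0")
  a <- dims[1]; b <- dims[2]; cc <- dims[3]
  sites <- rbind(
    c(0, 0, 0),
    c(-a / 2, 0, 0), c(-a / 4, 0, 0), c(a / 4, 0, 0), c(a / 2, 0, 0),
    c(0, -b / 2, 0), c(0, b / 2, 0),
    c(0, 0, -cc / 2), c(0, 0, cc / 2))
  rownames(sites) <- c("C0", "X1", "X2", "X3", "X4", "Y1", "Y2", "Z1", "Z2")
  # star topology plus outer->inner long-axis bonds
  bond_idx <- rbind(cbind(1L, 2:9), c(2L, 3L), c(5L, 4L))
  b0 <- sqrt(rowSums((sites[bond_idx[, 1], , drop = FALSE] -
                      sites[bond_idx[, 2], , drop = FALSE])^2))
  structure(list(
    sites = sites,
    bonds = data.frame(a = bond_idx[, 1], b = bond_idx[, 2], b0 = b0),
    site_mass = total_mass / 9, site_eps = site_eps,
    site_radius = site_radius, total_mass = total_mass,
    dims = dims, K_b = K_b
  ), class = "cg_ligand")
}

#' @export
print.cg_ligand <- function(x, ...) {
  cat(sprintf(
    "cg_ligand: 9 sites, dims %.2f x %.2f x %.2f A, mass %.2f Da (%d bonds)\n",
    x$dims[1], x$dims[2], x$dims[3], x$total_mass, nrow(x$bonds)))
  invisible(x)
}

#' Read a plain coordinate table of molecule structures
#'
#' Accepts a CSV/TSV-like table with columns `id`, `x`, `y`, `z` (one row
#' per atom) and computes per-molecule principal dimensions, returning a
#' [drug_dimension_table()].  Molecular weights may be supplied via a
#' `weight` column (constant per molecule) or default to 388.46 Da.
#'
#' @param path file path.
#' @return a `drug_dimension_table`.
#' @export
read_molecule_table <- function(path) {
  df <- read.table(path, header = TRUE)
  if (!all(c("id", "x", "y", "z") %in% names(df)))
    stop("molecule table needs columns id, x, y, z")
  ids <- unique(df$id)
  dims <- t(vapply(ids, function(i) {
    principal_dimensions(as.matrix(df[df$id == i, c("x", "y", "z")]))
  }, numeric(3)))
  w <- if ("weight" %in% names(df)) {
    vapply(ids, function(i) df$weight[df$id == i][1], numeric(1))
  } else rep(388.46, length(ids))
  drug_dimension_table(dims, w, id = as.character(ids))
}

#' Write a coarse-grained ligand as PDB plus a bond list
#'
#' Sites are written as HETATM records (residue LIG); the bond list file has
#' one `a b b0` line per bond.
#'
#' @param ligand a [build_generic_ligand()] object.
#' @param path output PDB path; the bond list goes to `<path>.bonds`.
#' @export
write_cg_ligand <- function(ligand, path) {
  n <- nrow(ligand$sites)
  lines <- vapply(seq_len(n), function(i) {
    sprintf("HETATM%5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, substr(rownames(ligand$sites)[i], 1, 4), "LIG", 1L,
            ligand$sites[i, 1], ligand$sites[i, 2], ligand$sites[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  write.table(ligand$bonds, paste0(path, ".bonds"), row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}
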