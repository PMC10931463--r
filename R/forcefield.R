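#' 12-10-6 pair potential
#'
#' The well form used for ligand internal pairs, weak non-native pairs and
#' ligand-ribosome interactions: `eps * (13 s^12 - 18 s^10 + 4 s^6)` with
#' `s = R/r`.  Its minimum is exactly `-eps` at *r* = *R*; it has a small
#' positive desolvation-like barrier (about `0.1427 eps`) near
#' *r* = 1.4485 *R*.  A C1 cubic switching ramp takes it smoothly to zero over
#' the last `switch_width` Angstrom before `cutoff` (no cutoff by default).
#'
#' @param r distance(s), Angstrom; must be > 0.
#' @param eps well depth, kcal/mol.
#' @param R well position, Angstrom.
#' @param cutoff cutoff distance (default `Inf`, no truncation).
#' @param switch_width switching-ramp width, Angstrom.
#' @return energy in kcal/mol (vectorized over `r`).
#' @examples
#' pair_12_10_6(3.0, 1.0, 3.0)   # -1 at the well
#' @export
pair_12_10_6 <- function(r, eps, R, cutoff = Inf, switch_width = 2) {
  if (any(r <= 0)) stop("r must be > 0 (bead overlap)")
  s2 <- (R / r)^2
  e <- eps * (13 * s2^6 - 18 * s2^5 + 4 * s2^3)
  if (is.finite(cutoff)) {
    S <- .switch_fun(r, cutoff, switch_width)
    e <- e * S
  }
  e
}

.switch_fun <- function(r, cutoff, w) {
  S <- rep(1, length(r))
  S[r >= cutoff] <- 0
  ramp <- r > cutoff - w & r < cutoff
  t <- (r[ramp] - (cutoff - w)) / w
  S[ramp] <- 1 - 3 * t^2 + 2 * t^3
  S
}

#' 12-6 pair potential
#'
#' The Lennard-Jones form used for ligand/binding-site pairs:
#' `eps * (s^12 - 2 s^6)`, `s = R/r`.  Minimum exactly `-eps` at *r* = *R*;
#' no distance cutoff or switching is applied to binding pairs.
#'
#' @inheritParams pair_12_10_6
#' @return energy in kcal/mol (vectorized over `r`).
#' @export
pair_12_6 <- function(r, eps, R) {
  if (any(r <= 0)) stop("r must be > 0 (bead overlap)")
  s6 <- (R / r)^6
  eps * (s6^2 - 2 * s6)
}

#' Spherical restraint energy
#'
#' Flat-bottom harmonic confinement: `K_sp (d - d0)^2` outside the sphere
#' radius `d0`, zero inside.  In co-translational simulations `d` is the
#' distance from each ligand site to a fixed center (default `(160, 0, 0)`,
#' `d0 = 100`); post-translationally `d` is the ligand-COM to protein-COM
#' distance with `d0 = 200`.
#'
#' @param d distance(s), Angstrom (>= 0).
#' @param K_sp force constant, kcal/mol/Angstrom^2 (default 0.1).
#' @param d0 sphere radius, Angstrom.
#' @return energy in kcal/mol (vectorized).
#' @examples
#' spherical_restraint_energy(101, 0.1, 100)  # 0.1
#' @export
spherical_restraint_energy <- function(d, K_sp = 0.1, d0 = 100) {
  ifelse(d > d0, K_sp * (d - d0)^2, 0)
}

#' Force-field parameter set
#'
#' Tunable parameters of the substituted Calpha structure-based model and
#' the ligand terms.  `combine_eps` selects the pair combination rule for
#' the weak non-native well depths: `"geometric"` (default,
#' `sqrt(eps_i eps_j)`) or `"product"` (`eps_i * eps_j`); the radius rule is
#' always `R_ij = R_i + R_j`.
#'
#' @param K_b virtual-bond force constant, kcal/mol/Angstrom^2.
#' @param K_angle angle force constant, kcal/mol/rad^2.
#' @param K_dih1,K_dih3 dihedral amplitudes of the
#'   `K1(1 - cos(phi - phi0)) + K3(1 - cos 3(phi - phi0))` double well.
#' @param contact_eps native-contact well depth, kcal/mol.
#' @param nonnative_eps weak per-bead well depth, kcal/mol.
#' @param cutoff,switch_width cutoff scheme applied to 12-10-6 terms.
#' @param combine_eps `"geometric"` or `"product"`.
#' @return a list of class `ff_params`.
#' @export
ff_params <- function(K_b = 50, K_angle = 30, K_dih1 = 1.0, K_dih3 = 0.5,
                      contact_eps = 1.0, nonnative_eps = 0.000132,
                      cutoff = 20, switch_width = 2,
                      combine_eps = c("geometric", "product")) {
  combine_eps <- match.arg(combine_eps)
  stopifnot(K_b > 0, cutoff > 0, switch_width >= 0)
  structure(list(K_b = K_b, K_angle = K_angle, K_dih1 = K_dih1,
                 K_dih3 = K_dih3, contact_eps = contact_eps,
                 nonnative_eps = nonnative_eps, cutoff = cutoff,
                 switch_width = switch_width, combine_eps = combine_eps),
            class = "ff_params")
}

.combine_eps <- function(ei, ej, rule) {
  if (rule == "product") ei * ej else sqrt(ei * ej)
}

#' Ligand binding-site specification
#'
#' The set of (protein residue, ligand site) pairs that carry the 12-6
#' binding wells, with per-pair `R_ij` chosen to reproduce a predefined
#' binding pose, and a common well depth `eps_bind` (the quantity scanned
#' by [run_affinity_scan()]).
#'
#' @param pairs data.frame with columns `resid` (protein residue index),
#'   `site` (ligand site index 1-9), `R_ij` (Angstrom, > 0).
#' @param eps_bind well depth, kcal/mol.
#' @return object of class `binding_site_spec`.
#' @export
binding_site_spec <- function(pairs, eps_bind = 1.0) {
  stopifnot(all(c("resid", "site", "R_ij") %in% names(pairs)))
  if (any(pairs$R_ij <= 0)) stop("all R_ij must be > 0")
  structure(list(pairs = pairs, eps_bind = eps_bind),
            class = "binding_site_spec")
}

#' Simplified ribosome wall specification
#'
#' A static occluding half-space `x > x_wall` with a cylindrical exit
#' tunnel of radius `r_tunnel` about the x axis.  Protein beads feel a
#' harmonic repulsion from the wall (and radial confinement inside the
#' tunnel); ligand sites interact with the wall plane through the 12-10-6
#' ribosome form with the weak combined parameters.
#'
#' @param x_wall wall plane position, Angstrom (default 160, the
#'   co-translational sphere center).
#' @param r_tunnel exit-tunnel radius, Angstrom.
#' @param k_rep protein-wall force constant, kcal/mol/Angstrom^2.
#' @return object of class `wall_spec`.
#' @export
wall_spec <- function(x_wall = 160, r_tunnel = 7.5, k_rep = 50) {
  structure(list(x_wall = x_wall, r_tunnel = r_tunnel, k_rep = k_rep),
            class = "wall_spec")
}

#' Spherical-restraint specification
#'
#' @param mode `"none"`, `"point"` (per-ligand-site distance to a fixed
#'   center; co-translational default `d0 = 100`, center `(160, 0, 0)`), or
#'   `"com"` (ligand-COM to protein-COM; post-translational default
#'   `d0 = 200`).
#' @param K_sp force constant (default 0.1 kcal/mol/Angstrom^2).
#' @param d0 sphere radius, Angstrom; defaults by mode.
#' @param center fixed center for `"point"` mode.
#' @return object of class `restraint_spec`.
#' @export
restraint_spec <- function(mode = c("none", "point", "com"), K_sp = 0.1,
                           d0 = NULL, center = c(160, 0, 0)) {
  mode <- match.arg(mode)
  if (is.null(d0)) d0 <- switch(mode, none = 0, point = 100, com = 200)
  structure(list(mode = mode, K_sp = K_sp, d0 = d0, center = center),
            class = "restraint_spec")
}

#' Assemble a simulation system
#'
#' Combines a protein, an optional ligand, an optional binding-site spec,
#' the force-field parameters, and optional wall/restraint specs into a
#' `cg_system` holding the flattened interaction lists used by the compiled
#' energy/force kernel.  Bead order is protein residues first, then ligand
#' sites.
#'
#' @param protein a [cg_protein()], or `NULL` for a ligand-only system.
#' @param ligand a [build_generic_ligand()] object, or `NULL`.
#' @param site a [binding_site_spec()], or `NULL`.
#' @param contact_map precomputed [compute_native_contacts()]; computed from
#'   the protein when `NULL`.
#' @param ff a [ff_params()] list.
#' @param wall a [wall_spec()] or `NULL`.
#' @param restraint a [restraint_spec()] or `NULL`.
#' @param chain_length active nascent-chain length (protein beads beyond
#'   this index are excluded); default full length.
#' @param ligand_positions starting ligand site coordinates (default: ideal
#'   geometry at the origin).
#' @return object of class `cg_system`.
#' @export
build_cg_system <- function(protein = NULL, ligand = NULL, site = NULL,
                            contact_map = NULL, ff = ff_params(),
                            wall = NULL, restraint = NULL,
                            chain_length = NULL, ligand_positions = NULL) {
  if (is.null(protein) && is.null(ligand))
    stop("need at least a protein or a ligand")
  np_full <- if (is.null(protein)) 0L else protein$n_residues
  L <- if (is.null(chain_length)) np_full else as.integer(chain_length)
  if (L > np_full) stop("chain_length exceeds protein length")
  if (!is.null(protein) && is.null(contact_map))
    contact_map <- compute_native_contacts(protein)
  nl <- if (is.null(ligand)) 0L else nrow(ligand$sites)
  n <- L + nl

  pos <- matrix(0, n, 3)
  masses <- numeric(n); radii <- numeric(n); eps_i <- numeric(n)
  if (L > 0L) {
    pos[1:L, ] <- protein$positions[1:L, , drop = FALSE]
    masses[1:L] <- protein$masses[1:L]
    radii[1:L] <- protein$radii[1:L]
    eps_i[1:L] <- ff$nonnative_eps
  }
  if (nl > 0L) {
    lp <- if (is.null(ligand_positions)) ligand$sites else ligand_positions
    pos[L + 1:nl, ] <- lp
    masses[L + 1:nl] <- ligand$site_mass
    radii[L + 1:nl] <- ligand$site_radius
    eps_i[L + 1:nl] <- ligand$site_eps
  }

  bonds <- NULL; angles <- NULL; dihedrals <- NULL
  p1210 <- NULL; p126 <- NULL
  if (L >= 2L) {
    nat <- protein$native_positions
    d <- sqrt(rowSums((nat[2:L, , drop = FALSE] -
                       nat[1:(L - 1), , drop = FALSE])^2))
    bonds <- cbind(1:(L - 1), 2:L, d, ff$K_b)
  }
  if (L >= 3L) {
    th0 <- vapply(1:(L - 2), function(i)
      .angle3(protein$native_positions[i, ], protein$native_positions[i + 1, ],
              protein$native_positions[i + 2, ]), numeric(1))
    angles <- cbind(1:(L - 2), 2:(L - 1), 3:L, th0, ff$K_angle)
  }
  if (L >= 4L) {
    phi0 <- vapply(1:(L - 3), function(i)
      .dihedral4(protein$native_positions[i, ],
                 protein$native_positions[i + 1, ],
                 protein$native_positions[i + 2, ],
                 protein$native_positions[i + 3, ]), numeric(1))
    dihedrals <- cbind(1:(L - 3), 2:(L - 2), 3:(L - 1), 4:L, phi0,
                       ff$K_dih1, ff$K_dih3)
  }
  if (L >= 2L && !is.null(contact_map)) {
    cc <- contact_map$contacts
    cc <- cc[cc$j <= L, , drop = FALSE]
    if (nrow(cc) > 0L)
      p1210 <- cbind(cc$i, cc$j, ff$contact_eps, cc$d_native, 1)
    # weak non-native repulsion for all remaining pairs with |j - i| >= 4
    if (L >= contact_map$min_seq_sep + 1L) {
      pr <- which(outer(1:L, 1:L, function(a, b) b - a) >=
                  contact_map$min_seq_sep, arr.ind = TRUE)
      key <- paste(pr[, 1], pr[, 2])
      ckey <- paste(cc$i, cc$j)
      pr <- pr[!key %in% ckey, , drop = FALSE]
      if (nrow(pr) > 0L) {
        ei <- .combine_eps(eps_i[pr[, 1]], eps_i[pr[, 2]], ff$combine_eps)
        p1210 <- rbind(p1210, cbind(pr[, 1], pr[, 2], ei,
                                    radii[pr[, 1]] + radii[pr[, 2]], 1))
      }
    }
  }
  if (nl > 0L) {
    lb <- cbind(L + ligand$bonds$a, L + ligand$bonds$b, ligand$bonds$b0,
                ligand$K_b)
    bonds <- rbind(bonds, lb)
    # ligand internal nonbonded pairs: all site pairs not directly bonded
    pairs <- which(outer(1:nl, 1:nl, function(a, b) b > a), arr.ind = TRUE)
    bkey <- paste(pmin(ligand$bonds$a, ligand$bonds$b),
                  pmax(ligand$bonds$a, ligand$bonds$b))
    keep <- !paste(pairs[, 1], pairs[, 2]) %in% bkey
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) > 0L) {
      ei <- .combine_eps(ligand$site_eps, ligand$site_eps, ff$combine_eps)
      p1210 <- rbind(p1210, cbind(L + pairs[, 1], L + pairs[, 2], ei,
                                  2 * ligand$site_radius, 1))
    }
  }
  if (L > 0L && nl > 0L) {
    bind_pairs <- NULL
    if (!is.null(site)) {
      sp <- site$pairs
      if (any(sp$resid < 1 | sp$resid > np_full))
        stop("binding site references out-of-range residue")
      sp <- sp[sp$resid <= L, , drop = FALSE]
      if (nrow(sp) > 0L) {
        p126 <- cbind(sp$resid, L + sp$site, site$eps_bind, sp$R_ij)
        bind_pairs <- paste(sp$resid, sp$site)
      }
    }
    cross <- expand.grid(i = 1:L, j = 1:nl)
    if (!is.null(bind_pairs))
      cross <- cross[!paste(cross$i, cross$j) %in% bind_pairs, , drop = FALSE]
    ei <- .combine_eps(eps_i[cross$i], ligand$site_eps, ff$combine_eps)
    p1210 <- rbind(p1210, cbind(cross$i, L + cross$j, ei,
                                radii[cross$i] + ligand$site_radius, 1))
  }

  wall_par <- NULL
  if (!is.null(wall)) {
    lig_idx <- if (nl > 0L) L + 1:nl else integer(0)
    ei <- if (nl > 0L)
      rep(.combine_eps(ligand$site_eps, ligand$site_eps, ff$combine_eps), nl)
      else numeric(0)
    wall_par <- list(active = TRUE, x_wall = wall$x_wall,
                     r_tunnel = wall$r_tunnel, k_rep = wall$k_rep,
                     protein_idx = if (L > 0L) 1:L else integer(0),
                     protein_radius = radii[seq_len(L)],
                     ligand_idx = as.integer(lig_idx),
                     ligand_eps = ei,
                     ligand_R = rep(2 * if (nl > 0L) ligand$site_radius else 0,
                                    nl))
  }
  restr_par <- list(mode = 0L)
  if (!is.null(restraint) && restraint$mode != "none") {
    if (nl == 0L) stop("spherical restraint requires a ligand")
    if (restraint$mode == "point") {
      restr_par <- list(mode = 1L, K = restraint$K_sp, d0 = restraint$d0,
                        center = as.numeric(restraint$center),
                        sites = as.integer(L + 1:nl))
    } else {
      if (L == 0L) stop("COM-COM restraint requires a protein")
      restr_par <- list(mode = 2L, K = restraint$K_sp, d0 = restraint$d0,
                        group_a = as.integer(L + 1:nl),
                        group_b = as.integer(1:L))
    }
  }

  par <- list(n_beads = n, bonds = bonds, angles = angles,
              dihedrals = dihedrals, pairs_12_10_6 = p1210,
              pairs_12_6 = p126, anchors = NULL,
              cutoff = ff$cutoff, switch_width = ff$switch_width,
              masses = masses, wall = wall_par, restraint = restr_par)
  structure(list(protein = protein, ligand = ligand, site = site,
                 contact_map = contact_map, ff = ff, wall = wall,
                 restraint = restraint, chain_length = L,
                 n_protein = L, n_ligand = nl, n_beads = n,
                 positions = pos, masses = masses, radii = radii,
                 params = par),
            class = "cg_system")
}

.angle3 <- function(p1, p2, p3) {
  a <- p1 - p2; b <- p3 - p2
  acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
}

.dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
         n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("cg_system: %d protein beads + %d ligand sites\n",
              x$n_protein, x$n_ligand))
  invisible(x)
}

#' Total potential energy and analytic forces of a system
#'
#' Evaluates every term of the model (bonds, angles, dihedrals, 12-10-6
#' pairs, 12-6 binding pairs, wall, spherical restraint, anchors) and the
#' negative analytic gradient.
#'
#' @param system a [build_cg_system()] object.
#' @param positions optional n x 3 coordinate matrix overriding
#'   `system$positions`.
#' @return list with `energy` (kcal/mol), `forces` (n x 3,
#'   kcal/mol/Angstrom) and `components` (named breakdown).
#' @export
total_energy_forces <- function(system, positions = NULL) {
  stopifnot(inherits(system, "cg_system"))
  pos <- if (is.null(positions)) system$positions else as.matrix(positions)
  if (nrow(pos) != system$n_beads) stop("positions have wrong bead count")
  out <- eval_energy_forces_cpp(pos, system$params)
  if (!is.finite(out$energy))
    stop("non-finite energy: overlapping beads (r = 0) or diverged state")
  out
}

#' Ligand internal energy
#'
#' Bond terms `K_b (b - b0)^2` plus the weak 12-10-6 wells between all
#' non-bonded site pairs, for a given ligand conformation.
#'
#' @param ligand a [build_generic_ligand()] object.
#' @param positions 9 x 3 site coordinates; default the ideal geometry
#'   (bond term exactly zero).
#' @param ff force-field parameters (cutoff scheme, combination rule).
#' @return list with `energy`, `bond`, `pair` (kcal/mol).
#' @export
ligand_internal_energy <- function(ligand, positions = NULL,
                                   ff = ff_params()) {
  sys <- build_cg_system(ligand = ligand, ff = ff,
                         ligand_positions = positions)
  out <- total_energy_forces(sys)
  list(energy = out$energy, bond = unname(out$components["bond"]),
       pair = unname(out$components["pair_12_10_6"]))
}

#' Protein-ligand interaction energy
#'
#' Binding-site pairs use the 12-6 well at `(eps_bind, R_ij)`, with no
#' cutoff; every other protein-ligand pair uses the weak 12-10-6 term with
#' combined parameters.
#'
#' @param protein a [cg_protein()] (current `positions` are used).
#' @param ligand a [build_generic_ligand()] object.
#' @param ligand_positions current 9 x 3 ligand coordinates.
#' @param site a [binding_site_spec()] or `NULL`.
#' @param ff force-field parameters.
#' @return interaction energy, kcal/mol.
#' @export
protein_ligand_energy <- function(protein, ligand, ligand_positions,
                                  site = NULL, ff = ff_params()) {
  sys <- build_cg_system(protein, ligand, site = site, ff = ff,
                         ligand_positions = ligand_positions)
  pos <- rbind(protein$positions, ligand_positions)
  out <- eval_energy_forces_cpp(pos, sys$params)
  # cross terms only: subtract protein-internal and ligand-internal parts
  psys <- build_cg_system(protein, ff = ff, contact_map = sys$contact_map)
  lsys <- build_cg_system(ligand = ligand, ff = ff,
                          ligand_positions = ligand_positions)
  out$energy - eval_energy_forces_cpp(protein$positions, psys$params)$energy -
    eval_energy_forces_cpp(ligand_positions, lsys$params)$energy
}

#' Derive a binding-site specification from a docked pose
#'
#' Given a ligand pose (site coordinates placed at the binding site), pairs
#' every listed binding-site residue with every ligand site within
#' `max_pair_dist` in the pose and sets each pair's `R_ij` to its pose
#' distance, so the 12-6 wells jointly reproduce the pose at their minimum.
#'
#' @param protein a [cg_protein()] (native positions are used).
#' @param residues binding-site residue indices.
#' @param ligand_pose 9 x 3 matrix of ligand site coordinates in the pose.
#' @param eps_bind well depth, kcal/mol.
#' @param max_pair_dist only pairs closer than this in the pose carry a
#'   well (default 10 Angstrom).
#' @return a [binding_site_spec()].
#' @export
design_binding_site <- function(protein, residues, ligand_pose,
                                eps_bind = 1.0, max_pair_dist = 10) {
  P <- protein$native_positions[residues, , drop = FALSE]
  Lp <- as.matrix(ligand_pose)
  pairs <- expand.grid(ri = seq_along(residues), si = seq_len(nrow(Lp)))
  d <- sqrt(rowSums((P[pairs$ri, , drop = FALSE] -
                     Lp[pairs$si, , drop = FALSE])^2))
  keep <- d <= max_pair_dist
  if (!any(keep)) stop("no residue-site pair within max_pair_dist in the pose")
  binding_site_spec(data.frame(resid = residues[pairs$ri[keep]],
                               site = pairs$si[keep], R_ij = d[keep]),
                    eps_bind = eps_bind)
}
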