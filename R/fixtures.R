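#' Ideal Hopf link fixture
#'
#' Two polygonal circles in orthogonal planes with centres one radius
#' apart: true topological linking number +/-1.  Moving the centres three
#' radii apart (`separation = 3`) unlinks them (linking 0).
#'
#' @param radius circle radius, Angstrom.
#' @param n_segments polygon segments per circle (>= 8).
#' @param separation centre separation in units of the radius (default 1).
#' @return list with closed-curve point matrices `a` and `b`.
#' @export
make_hopf_link <- function(radius = 5, n_segments = 200L, separation = 1) {
  if (n_segments < 8L) stop("n_segments must be >= 8")
  th <- seq(0, 2 * pi, length.out = n_segments + 1L)[-(n_segments + 1L)]
  a <- cbind(radius * cos(th), radius * sin(th), 0)
  b <- cbind(separation * radius + radius * cos(th), 0, radius * sin(th))
  list(a = a, b = b)
}

#' Single-chain lasso fixture
#'
#' A planar polygonal loop whose two ends form a native contact (the chord
#' between beads 1 and `loop_size` equals the bead spacing), followed by a
#' tail.  With `thread = TRUE` the tail rises above the loop centroid and
#' pierces straight through it perpendicular to the loop plane (known
#' rounded partial linking magnitude 1); with `thread = FALSE` the tail
#' runs radially away in the loop plane (linking 0).
#'
#' @param loop_size beads in the loop (>= 8).
#' @param thread whether the tail threads the loop.
#' @param spacing bead spacing, Angstrom (default 3.8).
#' @return list with `coords` (n x 3), `contact` `(i, j) = (1, loop_size)`,
#'   `n_loop`, `n_total`.
#' @export
make_lasso_chain <- function(loop_size = 20L, thread = TRUE, spacing = 3.8) {
  if (loop_size < 8L) stop("loop_size must be >= 8")
  L <- as.integer(loop_size)
  R <- L * spacing / (2 * pi)
  th <- 2 * pi * (seq_len(L) - 1L) / L
  loop <- cbind(R * cos(th), R * sin(th), 0)
  pL <- loop[L, ]
  if (thread) {
    # approach: 4 beads from the rim up to a point above the centroid,
    # then a straight thread down through the loop centre
    top <- c(0, 0, 15)
    appr <- t(vapply(1:4, function(k) pL + (top - pL) * k / 5, numeric(3)))
    Tlen <- 4 * R
    nz <- max(4L, ceiling((15 + Tlen) / spacing))
    zs <- seq(15, -Tlen, length.out = nz + 1L)
    thread_pts <- cbind(0, 0, zs)
    coords <- rbind(loop, appr, thread_pts)
  } else {
    nt <- 10L
    dir <- pL / sqrt(sum(pL^2))
    tail_pts <- t(vapply(seq_len(nt), function(k) pL + dir * spacing * k,
                         numeric(3)))
    coords <- rbind(loop, tail_pts)
  }
  list(coords = coords, contact = c(1L, L), n_loop = L,
       n_total = nrow(coords))
}

#' Foldable miniprotein fixtures
#'
#' Desk-scale two-state test systems with a defined native geometry and at
#' least three native contacts: a two-strand beta-hairpin (`"hairpin"`) or
#' a two-helix bundle (`"helix_bundle"`).
#'
#' @param kind `"hairpin"` or `"helix_bundle"`.
#' @param n_beads chain length, in `[12, 60]`.
#' @return a [cg_protein()] whose `native_positions` define the fold.
#' @examples
#' p <- make_miniprotein("hairpin", 16)
#' compute_native_contacts(p)$N  # >= 3
#' @export
make_miniprotein <- function(kind = c("hairpin", "helix_bundle"),
                             n_beads = 16L) {
  kind <- match.arg(kind)
  n <- as.integer(n_beads)
  if (n < 12L || n > 60L) stop("n_beads must be in [12, 60]")
  if (kind == "hairpin") {
    s <- (n - 1L) %/% 2L           # strand 1 length; 1 turn apex bead
    pos <- matrix(0, n, 3)
    for (k in seq_len(s))
      pos[k, ] <- c(0, 3.8 * (k - 1), 0.4 * (-1)^k)
    ytop <- 3.8 * (s - 1)
    pos[s + 1L, ] <- c(2.5, ytop + 2.9, 0)   # turn apex
    for (k in (s + 2L):n)
      pos[k, ] <- c(5.0, ytop - 3.8 * (k - s - 2L), 0.4 * (-1)^k)
  } else {
    r <- 2.3; rise <- 1.5; dphi <- 100 * pi / 180
    h <- (n - 1L) %/% 2L           # per-helix length; 1 loop bead
    helix <- function(m, up = TRUE) {
      k <- seq_len(m) - 1L
      z <- if (up) rise * k else rise * (m - 1L - k)
      cbind(r * cos(dphi * k), r * sin(dphi * k), z)
    }
    h1 <- helix(h, up = TRUE)
    h2 <- helix(n - h - 1L, up = FALSE)
    # translate helix 2 so its first bead sits 7.6 A from helix 1's top,
    # with one loop bead midway
    target <- h1[h, ] + c(7.6, 0, 0)
    h2 <- sweep(h2, 2, target - h2[1L, ], `+`)
    loop_bead <- (h1[h, ] + h2[1L, ]) / 2
    pos <- rbind(h1, loop_bead, h2)
  }
  cg_protein(pos, sequence = rep("A", n))
}

#' Synthetic drug-dimension table
#'
#' Random ellipsoidal point clouds with known generating principal-axis
#' extents, emulating a small-molecule size survey.  Extents are drawn
#' log-normally around 11.46 x 6.11 x 3.35 Angstrom and weights around
#' 388.46 Da; the six axis-extreme points are included in each cloud so
#' the generating extents are exact, then each cloud is randomly rotated
#' and translated.
#'
#' @param n_molecules number of molecules (>= 1).
#' @param seed RNG seed (fixture is deterministic given the seed).
#' @param n_points surface points per cloud (before the 6 extremes).
#' @return list with `table` (a [drug_dimension_table()] carrying the true
#'   extents), `coords` (list of point matrices) and `seed`.
#' @export
make_drug_table <- function(n_molecules = 50L, seed = 1L, n_points = 200L) {
  if (n_molecules < 1L) stop("need n_molecules >= 1")
  set.seed(seed)
  base <- c(11.46, 6.11, 3.35)
  dims <- matrix(0, n_molecules, 3)
  coords <- vector("list", n_molecules)
  for (m in seq_len(n_molecules)) {
    d <- sort(base * exp(rnorm(3, 0, 0.2)), decreasing = TRUE)
    dims[m, ] <- d
    u <- matrix(rnorm(3 * n_points), n_points, 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u, 2, d / 2, `*`)
    ext <- rbind(c(d[1] / 2, 0, 0), c(-d[1] / 2, 0, 0),
                 c(0, d[2] / 2, 0), c(0, -d[2] / 2, 0),
                 c(0, 0, d[3] / 2), c(0, 0, -d[3] / 2))
    pts <- rbind(pts, ext)
    Rm <- .random_rotation()
    pts <- pts %*% t(Rm)
    pts <- sweep(pts, 2, rnorm(3, 0, 20), `+`)
    coords[[m]] <- pts
  }
  w <- 388.46 * exp(rnorm(n_molecules, 0, 0.3))
  list(table = drug_dimension_table(dims, w), coords = coords, seed = seed)
}

#' Synthetic discrete state trajectory with known loop-erased answer
#'
#' Random label sequence over an alphabet: each step revisits an
#' already-seen label with probability `revisit_prob`, otherwise draws
#' uniformly from the alphabet.  The reference loop-erased route is
#' computed by an independent cut-first-cycle implementation (collapse
#' consecutive repeats, then repeatedly excise the first closed cycle).
#'
#' @param alphabet state labels to draw from.
#' @param length sequence length (>= 1).
#' @param revisit_prob probability of a deliberate revisit.
#' @param seed RNG seed.
#' @return list with `sequence` and `reference` (the loop-erased route).
#' @export
make_discrete_traj <- function(alphabet = paste0("P", 1:8), length = 50L,
                               revisit_prob = 0.3, seed = 1L) {
  if (length < 1L) stop("length must be >= 1")
  set.seed(seed)
  s <- character(length)
  s[1] <- sample(alphabet, 1L)
  for (k in seq_len(length - 1L)) {
    seen <- unique(s[seq_len(k)])
    s[k + 1L] <- if (runif(1) < revisit_prob && length(seen) > 0L)
      sample(seen, 1L) else sample(alphabet, 1L)
  }
  list(sequence = s, reference = .loop_erase_reference(s), seed = seed)
}

# Independent oracle: collapse repeats, then repeatedly find the first
# position whose label already occurred and excise the cycle between the
# two occurrences (keeping the first), until no label repeats.
.loop_erase_reference <- function(s) {
  v <- rle(as.character(s))$values
  repeat {
    dup_at <- NA_integer_
    for (p in seq_along(v)) {
      q <- match(v[p], v[seq_len(p - 1L)])
      if (p > 1L && !is.na(q)) { dup_at <- p; first <- q; break }
    }
    if (is.na(dup_at)) return(v)
    v <- v[-(seq.int(first + 1L, dup_at))]
  }
}

#' Frozen toy protein-ligand binding system
#'
#' The desk-scale system used for binding-affinity properties: the 16-bead
#' beta-hairpin with the generic ligand docked flat against the outer face
#' of strand 1 (long axis along the strand, centre of mass 7 Angstrom off
#' the face).  Binding-site residues 2, 4 and 6 pair with every ligand
#' site within 8 Angstrom of the pose ([design_binding_site()]); the
#' ligand is confined by a COM-COM restraint of radius 25 Angstrom and
#' initially placed at random (5 Angstrom clearance) in a 20 Angstrom
#' sphere about the protein.
#'
#' @param eps_bind binding well depth, kcal/mol.
#' @param seed placement seed.
#' @return a ready-to-run [build_cg_system()].
#' @export
toy_binding_system <- function(eps_bind, seed = 1L) {
  p <- make_miniprotein("hairpin", 16)
  cm <- compute_native_contacts(p)
  lig <- build_generic_ligand()
  pose <- sweep(lig$sites[, c(2, 1, 3)], 2,
                colMeans(p$native_positions[c(2, 4, 6), ]) + c(-7, 0, 0),
                `+`)
  site <- design_binding_site(p, c(2, 4, 6), pose, eps_bind = eps_bind,
                              max_pair_dist = 8)
  sys <- build_cg_system(p, lig, site, contact_map = cm,
                         restraint = restraint_spec("com", d0 = 25))
  place_ligand_randomly(sys, list(center = colMeans(p$positions),
                                  radius = 20),
                        seed = seed, min_dist = 5)
}
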