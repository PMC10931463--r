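#' Simulation configuration
#'
#' Langevin-dynamics parameters.  Defaults follow the coarse-grained
#' protocol: 15 fs timestep, collision frequency 0.05 ps^-1, 310 K.  The
#' `time_mapping_factor` records the nominal simulation-to-experimental
#' timescale mapping (dimensionless) and is carried as metadata only.
#'
#' @param timestep integration step, ps (default 0.015).
#' @param friction collision frequency, ps^-1 (default 0.05).
#' @param temperature thermostat temperature, K (default 310).
#' @param n_steps number of integration steps.
#' @param seed RNG seed, recorded in all outputs.
#' @param save_interval save a frame every this many steps.
#' @param time_mapping_factor nominal timescale mapping (default 5e6).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(timestep = 0.015, friction = 0.05, temperature = 310,
                       n_steps = 100000L, seed = 1L, save_interval = 1000L,
                       time_mapping_factor = 5e6) {
  stopifnot(timestep > 0, friction >= 0, temperature >= 0, n_steps >= 1,
            save_interval >= 1)
  structure(list(timestep = timestep, friction = friction,
                 temperature = temperature, n_steps = as.integer(n_steps),
                 seed = as.integer(seed),
                 save_interval = as.integer(save_interval),
                 time_mapping_factor = time_mapping_factor),
            class = "sim_config")
}

.mb_velocities <- function(masses, temperature) {
  n <- length(masses)
  sig <- sqrt(.kB * temperature / (masses / .mass_conv))
  matrix(rnorm(3 * n), n, 3) * sig
}

.frames_to_list <- function(res, n) {
  ns <- res$n_saved
  fr <- res$frames
  lapply(seq_len(ns), function(k) {
    m <- matrix(fr[(k - 1) * 3 * n + seq_len(3 * n)], nrow = 3)
    t(m)[, , drop = FALSE]
  })
}

#' Run Langevin dynamics
#'
#' Propagates a system with the BAOAB splitting of Langevin dynamics.  With
#' zero friction (or zero temperature and zero friction) the scheme reduces
#' to velocity Verlet and conserves energy to integrator accuracy.  A given
#' `(seed, config, initial state)` reproduces the trajectory exactly on one
#' platform; Gaussian noise is drawn from R's RNG.
#'
#' @param system a [build_cg_system()] object.
#' @param config a [sim_config()].
#' @param positions optional starting coordinates (default
#'   `system$positions`).
#' @param velocities optional starting velocities, Angstrom/ps (default
#'   Maxwell-Boltzmann at `config$temperature`).
#' @return object of class `cg_trajectory`: list with `frames` (list of
#'   n x 3 matrices), `times` (ps), `epot`, `ekin` (kcal/mol),
#'   `n_protein` per frame, `final_positions`, `final_velocities`, and a
#'   `config` echo including the seed.
#' @export
run_langevin <- function(system, config, positions = NULL,
                         velocities = NULL) {
  stopifnot(inherits(system, "cg_system"), inherits(config, "sim_config"))
  pos <- if (is.null(positions)) system$positions else as.matrix(positions)
  set.seed(config$seed)
  vel <- if (is.null(velocities))
    .mb_velocities(system$masses, config$temperature)
  else as.matrix(velocities)
  res <- run_langevin_cpp(pos, vel, system$params, config$timestep,
                          config$friction, config$temperature,
                          config$n_steps, config$save_interval)
  if (res$error_step >= 0)
    stop(sprintf("non-finite energy at step %d: simulation aborted",
                 res$error_step))
  n <- system$n_beads
  structure(list(frames = .frames_to_list(res, n),
                 times = res$times[seq_len(res$n_saved)],
                 epot = res$epot[seq_len(res$n_saved)],
                 ekin = res$ekin[seq_len(res$n_saved)],
                 ekin_mid = res$ekin_mid[seq_len(res$n_saved)],
                 n_protein = rep(system$n_protein, res$n_saved),
                 final_positions = res$final_positions,
                 final_velocities = res$final_velocities,
                 config = config, seed = config$seed,
                 n_beads = n),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d frames, %d beads, %.1f ps (seed %d)\n",
              length(x$frames), x$n_beads, max(x$times), x$seed))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`.
#' @export
n_frames <- function(traj) length(traj$frames)

.cat_traj <- function(a, b) {
  # concatenate two trajectories (b's time axis shifted after a's)
  off <- if (length(a$times)) max(a$times) else 0
  a$frames <- c(a$frames, b$frames)
  a$times <- c(a$times, b$times + off)
  a$epot <- c(a$epot, b$epot)
  a$ekin <- c(a$ekin, b$ekin)
  a$ekin_mid <- c(a$ekin_mid, b$ekin_mid)
  a$n_protein <- c(a$n_protein, b$n_protein)
  a$final_positions <- b$final_positions
  a$final_velocities <- b$final_velocities
  a$n_beads <- b$n_beads
  a
}


#' Steepest-descent energy minimization
#'
#' Displacement-capped steepest descent with adaptive step size, used to
#' relax strained configurations (e.g. freshly inserted residues during
#' nascent-chain elongation) before dynamics.
#'
#' @param system a [build_cg_system()] object.
#' @param positions starting coordinates (default `system$positions`).
#' @param max_steps iteration cap (default 200).
#' @param fmax convergence threshold on the largest force component,
#'   kcal/mol/Angstrom (default 10).
#' @param max_disp largest per-coordinate displacement per step, Angstrom.
#' @return the relaxed n x 3 coordinate matrix.
#' @export
minimize_energy <- function(system, positions = NULL, max_steps = 200L,
                            fmax = 10, max_disp = 0.2) {
  pos <- if (is.null(positions)) system$positions else as.matrix(positions)
  out <- eval_energy_forces_cpp(pos, system$params)
  alpha <- 1e-3
  for (it in seq_len(max_steps)) {
    fm <- max(abs(out$forces))
    if (!is.finite(out$energy) || fm < fmax) break
    step <- out$forces * alpha
    step[step > max_disp] <- max_disp
    step[step < -max_disp] <- -max_disp
    trial <- pos + step
    out2 <- eval_energy_forces_cpp(trial, system$params)
    if (is.finite(out2$energy) && out2$energy <= out$energy) {
      pos <- trial; out <- out2; alpha <- alpha * 1.2
    } else {
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
  }
  pos
}

#' Simulate nascent-chain elongation against the ribosome wall
#'
#' Grows the protein one residue at a time: for each entry of `schedule`
#' the current chain (with its C-terminal bead harmonically tethered to the
#' tunnel-exit anchor) is propagated for that dwell time; then the chain is
#' translocated one virtual-bond length down the tunnel axis (a rigid
#' shift, so no internal strain is introduced) and the next bead appears
#' at the anchor.  After the last residue is appended the tether is
#' released and a final segment of `config$n_steps` steps is run at full
#' length.
#'
#' @param system a [build_cg_system()] with an active [wall_spec()] and a
#'   `chain_length` shorter than the protein's full length.
#' @param schedule per-residue dwell times in ps, one per residue still to
#'   be synthesized (must not be shorter than the remaining residues).
#' @param config a [sim_config()]; `n_steps` is the post-synthesis segment.
#' @param anchor tunnel-exit anchor point; default
#'   `(x_wall + 1.9, 0, 0)`.
#' @param K_tether tether force constant, kcal/mol/Angstrom^2.
#' @return a `cg_trajectory` whose frames grow in bead count at elongation
#'   events (`n_protein` records the per-frame chain length).
#' @export
elongate_nascent_chain <- function(system, schedule, config,
                                   anchor = NULL, K_tether = 10) {
  stopifnot(inherits(system, "cg_system"))
  if (is.null(system$wall)) stop("elongation requires an active ribosome wall")
  protein <- system$protein
  L0 <- system$chain_length
  remaining <- protein$n_residues - L0
  if (remaining <= 0L) stop("protein is already full length")
  if (length(schedule) < remaining)
    stop(sprintf("schedule has %d dwell times but %d residues remain",
                 length(schedule), remaining))
  if (is.null(anchor)) anchor <- c(system$wall$x_wall + 1.9, 0, 0)
  set.seed(config$seed)

  pos <- system$positions
  traj <- structure(list(frames = list(), times = numeric(0),
                         epot = numeric(0), ekin = numeric(0),
                         ekin_mid = numeric(0),
                         n_protein = integer(0), config = config,
                         seed = config$seed),
                    class = "cg_trajectory")
  vel <- NULL
  L <- L0
  for (k in seq_len(remaining)) {
    sys_k <- build_cg_system(protein, system$ligand, system$site,
                             system$contact_map, system$ff, system$wall,
                             system$restraint, chain_length = L)
    sys_k$params$anchors <- matrix(c(L, anchor, K_tether), nrow = 1)
    pos <- minimize_energy(sys_k, pos)   # relax insertion strain
    sys_k$positions <- pos
    n_steps_k <- max(1L, as.integer(round(schedule[k] / config$timestep)))
    if (schedule[k] > 0) {
      cfg_k <- config
      cfg_k$n_steps <- n_steps_k
      cfg_k$save_interval <- min(config$save_interval, n_steps_k)
      if (is.null(vel)) vel <- .mb_velocities(sys_k$masses,
                                              config$temperature)
      res <- run_langevin_cpp(pos, vel, sys_k$params, config$timestep,
                              config$friction, config$temperature,
                              cfg_k$n_steps, cfg_k$save_interval)
      if (res$error_step >= 0)
        stop(sprintf("non-finite energy at step %d during elongation",
                     res$error_step))
      seg <- structure(list(frames = .frames_to_list(res, sys_k$n_beads),
                            times = res$times[seq_len(res$n_saved)],
                            epot = res$epot[seq_len(res$n_saved)],
                            ekin = res$ekin[seq_len(res$n_saved)],
                            ekin_mid = res$ekin_mid[seq_len(res$n_saved)],
                            n_protein = rep(L, res$n_saved),
                            final_positions = res$final_positions,
                            final_velocities = res$final_velocities,
                            n_beads = sys_k$n_beads),
                       class = "cg_trajectory")
      traj <- .cat_traj(traj, seg)
      pos <- res$final_positions
      vel <- res$final_velocities
    }
    # translocate the chain one bond length out of the tunnel (rigid
    # shift: no internal energy change) and add the new bead at the
    # vacated C-terminal position
    new_bead <- pos[L, ]
    shifted <- pos[seq_len(L), , drop = FALSE]
    shifted[, 1] <- shifted[, 1] - 3.8
    npos <- rbind(shifted, new_bead)
    if (system$n_ligand > 0L)
      npos <- rbind(npos, pos[L + seq_len(system$n_ligand), , drop = FALSE])
    pos <- npos
    if (!is.null(vel)) {
      sig <- sqrt(.kB * config$temperature /
                  (protein$masses[L + 1L] / .mass_conv))
      nv <- rbind(vel[seq_len(L), , drop = FALSE], rnorm(3) * sig)
      if (system$n_ligand > 0L)
        nv <- rbind(nv, vel[L + seq_len(system$n_ligand), , drop = FALSE])
      vel <- nv
    }
    L <- L + 1L
  }
  # full length: release the tether and run the post-synthesis segment
  sys_f <- build_cg_system(protein, system$ligand, system$site,
                           system$contact_map, system$ff, system$wall,
                           system$restraint, chain_length = L)
  pos <- minimize_energy(sys_f, pos)
  sys_f$positions <- pos
  if (is.null(vel)) vel <- .mb_velocities(sys_f$masses, config$temperature)
  res <- run_langevin_cpp(pos, vel, sys_f$params, config$timestep,
                          config$friction, config$temperature,
                          config$n_steps, config$save_interval)
  if (res$error_step >= 0)
    stop(sprintf("non-finite energy at step %d after elongation",
                 res$error_step))
  seg <- structure(list(frames = .frames_to_list(res, sys_f$n_beads),
                        times = res$times[seq_len(res$n_saved)],
                        epot = res$epot[seq_len(res$n_saved)],
                        ekin = res$ekin[seq_len(res$n_saved)],
                        ekin_mid = res$ekin_mid[seq_len(res$n_saved)],
                        n_protein = rep(L, res$n_saved),
                        final_positions = res$final_positions,
                        final_velocities = res$final_velocities,
                        n_beads = sys_f$n_beads),
                   class = "cg_trajectory")
  .cat_traj(traj, seg)
}

#' Place the ligand at a random position and orientation
#'
#' Draws the ligand centre of mass uniformly from a spherical region,
#' applies a uniformly random rigid rotation, and resamples (up to 1000
#' times) until no ligand site lies within `min_dist` of any protein bead.
#'
#' @param system a [build_cg_system()] with a ligand.
#' @param region list with `center` (length 3) and `radius`; must lie
#'   inside the system's restraint sphere when one is active.
#' @param seed optional RNG seed.
#' @param min_dist minimum allowed inter-bead distance (default 2).
#' @return the system with updated ligand coordinates in `positions`.
#' @export
place_ligand_randomly <- function(system, region, seed = NULL,
                                  min_dist = 2) {
  stopifnot(inherits(system, "cg_system"))
  if (system$n_ligand == 0L) stop("system has no ligand")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(system$restraint) && system$restraint$mode == "point") {
    dc <- sqrt(sum((region$center - system$restraint$center)^2))
    if (dc + region$radius > system$restraint$d0 + 1e-9)
      stop("placement region extends outside the restraint sphere")
  }
  L <- system$n_protein
  lig0 <- sweep(system$ligand$sites, 2,
                colMeans(system$ligand$sites))  # COM at origin
  ppos <- if (L > 0L) system$positions[seq_len(L), , drop = FALSE] else NULL
  for (trial in seq_len(1000L)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    com <- region$center + region$radius * runif(1)^(1 / 3) * u
    Rm <- .random_rotation()
    lp <- lig0 %*% t(Rm)
    lp <- sweep(lp, 2, com, `+`)
    ok <- TRUE
    if (!is.null(ppos)) {
      d2min <- min(vapply(seq_len(nrow(lp)), function(i)
        min(rowSums(sweep(ppos, 2, lp[i, ])^2)), numeric(1)))
      ok <- d2min > min_dist^2
    }
    if (ok) {
      if (L > 0L) system$positions[L + seq_len(nrow(lp)), ] <- lp
      else system$positions <- lp
      return(system)
    }
  }
  stop("failed to place ligand without overlap after 1000 attempts")
}

.random_rotation <- function() {
  # uniform rotation from a random quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
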