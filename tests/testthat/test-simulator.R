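test_that("identical seed and config reproduce the trajectory exactly", {
  p <- make_miniprotein("hairpin", 16)
  sys <- build_cg_system(p)
  cfg <- sim_config(n_steps = 2000, save_interval = 100, seed = 42)
  t1 <- run_langevin(sys, cfg)
  t2 <- run_langevin(sys, cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$final_velocities, t2$final_velocities)
  t3 <- run_langevin(sys, sim_config(n_steps = 2000, save_interval = 100,
                                     seed = 43))
  expect_false(identical(t1$final_positions, t3$final_positions))
})

test_that("zero-friction zero-temperature propagation conserves energy", {
  chain <- cg_protein(cbind(seq(0, by = 3.8, length.out = 10), 0, 0))
  sys <- build_cg_system(chain, ff = ff_params(K_angle = 0, K_dih1 = 0,
                                               K_dih3 = 0))
  set.seed(1)
  v0 <- matrix(rnorm(30, 0, 0.5), 10, 3)
  cfg <- sim_config(friction = 0, temperature = 0, n_steps = 1e5,
                    save_interval = 100, seed = 1)
  tr <- run_langevin(sys, cfg, velocities = v0)
  E <- tr$epot + tr$ekin
  drift <- abs(mean(tail(E, 100)) - mean(head(E, 100)))
  expect_lt(drift, 0.01)
})

test_that("hairpin shows two-state behaviour across its melting point", {
  # fixture folding temperature ~520 K (from a Q(T) scan of this model)
  p <- make_miniprotein("hairpin", 16)
  cm <- compute_native_contacts(p)
  sys <- build_cg_system(p)
  q_at <- function(temp, seed, dt = 0.015) {
    # halved step at 2x the melting temperature: hot unfolded chains
    # cross the soft excluded-volume cores too fast for the 15 fs step
    cfg <- sim_config(temperature = temp, timestep = dt,
                      n_steps = round(3000 / dt), save_interval = 500,
                      seed = seed)
    tr <- run_langevin(sys, cfg)
    Q <- vapply(tr$frames, function(X) compute_Q(X, cm), numeric(1))
    mean(Q[-seq_len(n_frames(tr) / 2)])
  }
  expect_gt(q_at(260, 21), 0.9)   # 0.5x folding temperature: folded
  expect_lt(q_at(1040, 22, dt = 0.0075), 0.3)  # 2x: unfolded
})

test_that("diverging simulations abort with a step index", {
  p <- make_miniprotein("hairpin", 16)
  sys <- build_cg_system(p)
  pos <- p$positions
  pos[10, ] <- pos[1, ] + c(1e-7, 0, 0)  # deep overlap on a pair term
  cfg <- sim_config(n_steps = 1000, save_interval = 100, seed = 1)
  expect_error(run_langevin(sys, cfg, positions = pos),
               "non-finite energy at step")
})

test_that("nascent-chain elongation grows the chain against the wall", {
  p <- make_miniprotein("hairpin", 16)
  wall <- wall_spec(x_wall = 30, r_tunnel = 6)
  sys <- build_cg_system(p, wall = wall, chain_length = 12L)
  # start the stub near the tunnel exit
  sys$positions[1:12, ] <- cbind(31.9 - 3.8 * ((12:1) - 1), 0, 0)
  cfg <- sim_config(n_steps = 5000, save_interval = 500, seed = 7,
                    temperature = 200)
  traj <- elongate_nascent_chain(sys, schedule = rep(30, 4), cfg)
  expect_equal(max(traj$n_protein), 16L)
  expect_true(all(diff(traj$n_protein) >= 0))
  # per-frame bead count equals the chain length at that frame
  expect_true(all(vapply(seq_along(traj$frames),
                         function(f) nrow(traj$frames[[f]]) ==
                           traj$n_protein[f], logical(1))))
  # no bead outside the tunnel penetrates the wall interior
  ok <- vapply(traj$frames, function(X) {
    rho <- sqrt(X[, 2]^2 + X[, 3]^2)
    all(X[, 1] < 30 + 0.5 | rho < 6)
  }, logical(1))
  expect_true(all(ok))
})

test_that("zero dwell reaches full length immediately", {
  p <- make_miniprotein("hairpin", 16)
  sys <- build_cg_system(p, wall = wall_spec(x_wall = 30),
                         chain_length = 14L)
  sys$positions[1:14, ] <- cbind(31.9 - 3.8 * ((14:1) - 1), 0, 0)
  cfg <- sim_config(n_steps = 500, save_interval = 100, seed = 3,
                    temperature = 100)
  traj <- elongate_nascent_chain(sys, schedule = c(0, 0), cfg)
  expect_true(all(traj$n_protein == 16L))
  expect_error(elongate_nascent_chain(sys, schedule = c(0), cfg),
               "schedule")
})

test_that("random ligand placement is reproducible and overlap-free", {
  p <- make_miniprotein("hairpin", 16)
  lig <- build_generic_ligand()
  sys <- build_cg_system(p, lig, restraint = restraint_spec("com", d0 = 40))
  region <- list(center = colMeans(p$positions), radius = 25)
  s1 <- place_ligand_randomly(sys, region, seed = 5)
  s2 <- place_ligand_randomly(sys, region, seed = 5)
  expect_identical(s1$positions, s2$positions)
  s3 <- place_ligand_randomly(sys, region, seed = 6)
  expect_false(identical(s1$positions, s3$positions))
  dmin <- min(vapply(17:25, function(i)
    min(sqrt(rowSums(sweep(s1$positions[1:16, ], 2,
                           s1$positions[i, ])^2))), numeric(1)))
  expect_gt(dmin, 2)
})

test_that("ligand COM sampling is uniform within the sphere", {
  lig <- build_generic_ligand()
  sys <- build_cg_system(ligand = lig,
                         restraint = restraint_spec("point", d0 = 60,
                                                    center = c(0, 0, 0)))
  region <- list(center = c(0, 0, 0), radius = 30)
  set.seed(77)
  r3 <- vapply(1:2000, function(k) {
    s <- place_ligand_randomly(sys, region)
    com <- colMeans(s$positions)
    (sqrt(sum((com - region$center)^2)) / region$radius)^3
  }, numeric(1))
  # r^3 is uniform on [0,1] for a uniform sphere; chi-square on 10 shells
  h <- table(cut(r3, seq(0, 1, 0.1)))
  expect_gt(chisq.test(h)$p.value, 0.01)
})

test_that("placement region must sit inside the restraint sphere", {
  lig <- build_generic_ligand()
  sys <- build_cg_system(ligand = lig,
                         restraint = restraint_spec("point", d0 = 20,
                                                    center = c(0, 0, 0)))
  expect_error(place_ligand_randomly(sys, list(center = c(15, 0, 0),
                                               radius = 10), seed = 1),
               "outside the restraint sphere")
})

test_that("the spherical restraint confines the ligand at 310 K", {
  lig <- build_generic_ligand()
  sys <- build_cg_system(ligand = lig,
                         restraint = restraint_spec("point", d0 = 20,
                                                    center = c(0, 0, 0)))
  cfg <- sim_config(n_steps = 2e5, save_interval = 20, seed = 13)
  tr <- run_langevin(sys, cfg)
  d <- vapply(tr$frames, function(X)
    max(sqrt(rowSums(X^2))), numeric(1))
  expect_lt(mean(d > 20 + 10), 1e-3)
})

test_that("restraint distances stay near the flat-bottom boundary", {
  # harmonic confinement: fraction of frames beyond d0 + 10 A is tiny,
  # but excursions slightly beyond d0 do occur (the boundary is soft)
  lig <- build_generic_ligand()
  sys <- build_cg_system(ligand = lig,
                         restraint = restraint_spec("point", d0 = 20,
                                                    center = c(0, 0, 0)))
  tr <- run_langevin(sys, sim_config(n_steps = 1e5, save_interval = 50,
                                     seed = 14))
  d <- vapply(tr$frames, function(X) max(sqrt(rowSums(X^2))), numeric(1))
  expect_gt(max(d), 20)        # the wall is soft, not hard
  expect_lt(max(d), 20 + 10)   # but strongly confining
})
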