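test_that("Gauss estimator recovers the Hopf link and unlinked circles", {
  hl <- make_hopf_link(5, 200)
  expect_equal(abs(discrete_gauss_linking(hl$a, hl$b, TRUE, TRUE)), 1,
               tolerance = 0.01)
  ul <- make_hopf_link(5, 200, separation = 3)
  expect_lt(abs(discrete_gauss_linking(ul$a, ul$b, TRUE, TRUE)), 0.01)
  # coplanar disjoint circles are exactly unlinked
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  a <- cbind(5 * cos(th), 5 * sin(th), 0)
  b <- cbind(20 + 5 * cos(th), 5 * sin(th), 0)
  expect_lt(abs(discrete_gauss_linking(a, b, TRUE, TRUE)), 0.01)
})

test_that("coarse 20-segment estimates agree with 10x refinement", {
  set.seed(31)
  for (rep in 1:5) {
    A_fine <- fourier_curve(200, scale = 10, offset = c(0, 0, 0))
    B_fine <- fourier_curve(200, scale = 10, offset = c(25, 0, 0))
    A <- A_fine[seq(1, 201, by = 10), ]
    B <- B_fine[seq(1, 201, by = 10), ]
    g_coarse <- discrete_gauss_linking(A, B, FALSE, FALSE)
    g_fine <- discrete_gauss_linking(A_fine, B_fine, FALSE, FALSE)
    expect_lt(abs(g_coarse - g_fine), 0.05)
  }
})

test_that("linking is antisymmetric under orientation reversal and rigid", {
  set.seed(33)
  for (rep in 1:5) {
    A <- fourier_curve(30, scale = 8)
    B <- fourier_curve(30, scale = 8, offset = c(12, 3, 0))
    g <- discrete_gauss_linking(A, B, FALSE, FALSE)
    expect_equal(discrete_gauss_linking(A[rev(seq_len(nrow(A))), ], B,
                                        FALSE, FALSE), -g,
                 tolerance = 1e-9)
    Rm <- random_rotation(); shift <- rnorm(3, 0, 40)
    g2 <- discrete_gauss_linking(
      sweep(A %*% t(Rm), 2, shift, `+`),
      sweep(B %*% t(Rm), 2, shift, `+`), FALSE, FALSE)
    expect_equal(g2, g, tolerance = 1e-8)
  }
})

test_that("closed-curve estimates round to the same integer at any pose", {
  set.seed(35)
  hl <- make_hopf_link(5, 60)
  g0 <- round(discrete_gauss_linking(hl$a, hl$b, TRUE, TRUE))
  for (rep in 1:5) {
    Rm <- random_rotation(); shift <- rnorm(3, 0, 50)
    g <- discrete_gauss_linking(sweep(hl$a %*% t(Rm), 2, shift, `+`),
                                sweep(hl$b %*% t(Rm), 2, shift, `+`),
                                TRUE, TRUE)
    expect_equal(round(g), g0)
  }
})

test_that("degenerate segments are rejected", {
  A <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  B <- rbind(c(5, 0, 0), c(5, 1, 0), c(5, 1, 1))
  expect_error(discrete_gauss_linking(A, B, FALSE, FALSE), "degenerate")
  expect_error(discrete_gauss_linking(B[1:2, ], B, FALSE, FALSE), ">= 3")
})

test_that("contact linking detects the threaded lasso", {
  lc <- make_lasso_chain(20, thread = TRUE)
  lr <- contact_linking(lc$coords, lc$contact)
  expect_equal(abs(lr$g_round), 1)
  expect_equal(lr$g_N, 0)  # no N-tail on this chain
  expect_false(is.na(lr$crossing_guess))
  lc0 <- make_lasso_chain(20, thread = FALSE)
  expect_equal(contact_linking(lc0$coords, lc0$contact)$g_round, 0)
  # thread moved 50 A away: unthreaded
  moved <- lc$coords
  moved[25:nrow(moved), 1] <- moved[25:nrow(moved), 1] + 50
  expect_equal(contact_linking(moved, lc$contact)$g_round, 0)
  expect_error(contact_linking(lc$coords, c(5, 3)), "out of range")
})

test_that("Q is 1 on the native frame, 0 when extended, 0.5 when half", {
  p <- make_miniprotein("hairpin", 16)
  cm <- compute_native_contacts(p)
  expect_equal(compute_Q(p$native_positions, cm), 1.0)
  ext <- cbind(seq(0, by = 3.8, length.out = 16), 0, 0)
  expect_equal(compute_Q(ext, cm), 0.0)
  # craft a map with exactly two contacts, one formed
  cm2 <- cm
  cm2$contacts <- data.frame(i = c(1L, 1L), j = c(6L, 12L),
                             d_native = c(
                               sqrt(sum((p$native_positions[1, ] -
                                         p$native_positions[6, ])^2)), 5.0))
  cm2$N <- 2L
  expect_equal(compute_Q(p$native_positions, cm2), 0.5)
  expect_error(compute_Q(p$native_positions, cm, I = 3, J = 4),
               "no native contacts")
})

test_that("Q(I|J) restricts to contacts between the residue sets", {
  p <- make_miniprotein("hairpin", 16)
  cm <- compute_native_contacts(p)
  q <- compute_Q(p$native_positions, cm, I = 1:8, J = 9:16)
  expect_equal(q, 1.0)
  expect_error(compute_Q(p$native_positions, cm, I = 1:8), "both I and J")
})

test_that("entanglement fractions vanish on the native frame", {
  lc <- make_lasso_chain(20, thread = TRUE)
  p <- cg_protein(lc$coords, validate = FALSE)
  cm <- compute_native_contacts(p)
  links <- native_contact_links(p, cm)
  ent <- compute_entanglement_fractions(p$native_positions, cm, links)
  expect_equal(ent$G_gain, 0)
  expect_equal(ent$G_loss, 0)
  expect_equal(ent$G, 0)
  expect_equal(ent$Q_overall, 1.0)
})

test_that("fully unfolded frames have zero gain/loss (conjunction with nc)", {
  p <- make_miniprotein("hairpin", 16)
  cm <- compute_native_contacts(p)
  links <- native_contact_links(p, cm)
  ext <- cbind(seq(0, by = 3.8, length.out = 16), 0, 0)
  ent <- compute_entanglement_fractions(ext, cm, links)
  expect_equal(ent$n_formed, 0L)
  expect_equal(ent$G_gain + ent$G_loss + ent$G, 0)
})

test_that("a single gained linking among 4 native contacts gives 0.25", {
  lc <- make_lasso_chain(20, thread = TRUE)
  X <- lc$coords
  # constructed map: the threaded loop contact plus three unformed pairs
  cm <- structure(list(
    contacts = data.frame(i = c(1L, 3L, 5L, 2L), j = c(20L, 10L, 15L, 12L),
                          d_native = c(3.8, 5.0, 5.0, 5.0)),
    N = 4L, cutoff = 8.0, min_seq_sep = 4L), class = "native_contact_map")
  links <- data.frame(i = cm$contacts$i, j = cm$contacts$j,
                      g_native = 0, g_native_round = 0)
  # (1,20) is formed at its native distance and threaded (|g| = 1);
  # the other three pairs are far beyond 1.2 x 5 A in this frame
  d <- as.matrix(dist(X))
  expect_true(d[1, 20] <= 1.2 * 3.8)
  expect_true(all(d[cbind(c(3, 5, 2), c(10, 15, 12))] > 6))
  ent <- compute_entanglement_fractions(X, cm, links)
  expect_equal(ent$G_gain, 0.25)
  expect_equal(ent$G_loss, 0)
  expect_equal(ent$G, 0.25)
})

test_that("gain/loss fractions never grow when formed contacts are removed", {
  lc <- make_lasso_chain(16, thread = TRUE)
  p <- cg_protein(lc$coords, validate = FALSE)
  cm <- compute_native_contacts(p)
  links <- native_contact_links(p, cm)
  # a frame where the loop is intact but the thread is pulled out
  # sideways: formed loop contacts lose their native linking
  X <- lc$coords
  X[21:nrow(X), 1] <- X[21:nrow(X), 1] + 60
  ent_full <- compute_entanglement_fractions(X, cm, links)
  expect_gt(ent_full$G_loss, 0)
  # drop contacts one by one; fractions are non-increasing
  for (k in seq_len(cm$N)) {
    cm_k <- cm
    cm_k$contacts <- cm$contacts[-k, , drop = FALSE]
    # N (the denominator) stays the full native count
    ent_k <- compute_entanglement_fractions(X, cm_k, links[-k, ,
                                                           drop = FALSE])
    expect_lte(ent_k$G_gain, ent_full$G_gain)
    expect_lte(ent_k$G_loss, ent_full$G_loss)
  }
})

test_that("native-entanglement detection applies the stated thresholds", {
  expect_true(native_entanglement_formed(rep(0, 120), "full_length"))
  expect_false(native_entanglement_formed(rep(0.05, 120), "full_length"))
  # alternating 0 / 0.03 averages to 0.015 < 0.02
  expect_true(native_entanglement_formed(rep(c(0, 0.03), 60),
                                         "full_length"))
  expect_false(native_entanglement_formed(rep(c(0, 0.03), 60), "nascent"))
  expect_true(native_entanglement_formed(rep(0.001, 150), "nascent"))
  expect_error(native_entanglement_formed(rep(0, 50), "full_length"),
               "50 frames")
})

test_that("binding detection uses the inclusive 8 A shortest distance", {
  frame <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0),  # protein
                 c(0, 8, 0), c(3, 30, 0))                 # ligand sites
  expect_true(binding_detected(frame, 3))   # exactly 8.0
  frame[4, 2] <- 8.1
  expect_false(binding_detected(frame, 3))
  frame[4, ] <- c(1, 7.8, 1)
  # brute-force oracle
  dmin <- min(sapply(1:3, function(i) sapply(4:5, function(j)
    sqrt(sum((frame[i, ] - frame[j, ])^2)))))
  expect_equal(binding_detected(frame, 3), dmin <= 8)
  expect_error(binding_detected(frame[1:3, ], 3), "no ligand")
})

test_that("entanglement reports carry Q, G and binding per frame", {
  p <- make_miniprotein("hairpin", 16)
  cm <- compute_native_contacts(p)
  sys <- build_cg_system(p)
  tr <- run_langevin(sys, sim_config(n_steps = 2000, save_interval = 500,
                                     seed = 2, temperature = 200))
  rep_df <- entanglement_report(tr, p, cm,
                                segments = list(s12 = list(I = 1:8,
                                                           J = 9:16)))
  expect_equal(nrow(rep_df), n_frames(tr))
  expect_true(all(c("time", "Q_overall", "G_gain", "G_loss", "G",
                    "Q_s12", "bound") %in% names(rep_df)))
  expect_true(all(rep_df$Q_overall >= 0 & rep_df$Q_overall <= 1))
  expect_true(all(is.na(rep_df$bound)))  # no ligand present
})
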