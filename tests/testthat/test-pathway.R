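test_that("state assignment is nearest-centroid with a lowest-index tie rule", {
  model <- state_model(c("A", "B", "C"),
                       rbind(c(0, 0), c(1, 0), c(0.5, 1)))
  expect_equal(assign_states(rbind(c(1, 0)), model), "B")
  # exactly equidistant between A and B -> lower index wins
  expect_equal(assign_states(rbind(c(0.5, 0)), model), "A")
  expect_error(assign_states(rbind(c(0, 0, 0)), model), "dimension")
  expect_error(state_model(c("A", "A"), rbind(c(0, 0), c(1, 1))), "unique")
})

test_that("state assignment matches a brute-force scan on random frames", {
  set.seed(41)
  model <- state_model(paste0("S", 1:6), matrix(runif(12), 6, 2))
  op <- matrix(runif(2000), 1000, 2)
  got <- assign_states(op, model)
  rng <- apply(model$centroids, 2, function(v) diff(range(v)))
  oracle <- vapply(seq_len(1000), function(f) {
    d2 <- vapply(1:6, function(s)
      sum(((op[f, ] - model$centroids[s, ]) / rng)^2), numeric(1))
    model$labels[which.min(d2)]
  }, character(1))
  expect_identical(got, oracle)
})

test_that("loop erasure collapses repeats and truncates revisits", {
  expect_equal(extract_pathway(c("P2", "P5", "P2", "P3", "P14"))$states,
               c("P2", "P3", "P14"))
  expect_equal(extract_pathway("A")$states, "A")
  expect_equal(extract_pathway(c("A", "B", "C"))$states, c("A", "B", "C"))
  expect_equal(extract_pathway(c("A", "A", "B", "B", "A", "C"))$states,
               c("A", "C"))
  expect_error(extract_pathway(character(0)), "empty")
})

test_that("loop erasure matches the independent oracle on 1000 sequences", {
  for (seed in 1:1000) {
    td <- make_discrete_traj(paste0("P", 1:6), length = 40,
                             revisit_prob = 0.4, seed = seed)
    route <- extract_pathway(td$sequence)$states
    expect_identical(route, td$reference)
    expect_false(any(duplicated(route)))
    expect_identical(route[1], td$sequence[1])
  }
})

test_that("threading-path classification follows event ordering", {
  lc <- make_lasso_chain(20, thread = TRUE)
  threaded <- lc$coords
  unthreaded <- threaded
  unthreaded[25:nrow(unthreaded), 1] <- unthreaded[25:nrow(unthreaded), 1] + 50
  open_loop <- threaded
  open_loop[1, ] <- open_loop[1, ] + c(-6, -6, 0)  # break the (1,20) contact
  open_unthreaded <- unthreaded
  open_unthreaded[1, ] <- open_unthreaded[1, ] + c(-6, -6, 0)

  # thread placed first (frames 1-2), loop closes at frame 3 -> wrap
  expect_equal(
    as.character(classify_threading_path(
      list(open_loop, open_loop, threaded, threaded),
      lc$contact, d_native = 3.8, thread = "C")), "Path1")
  # loop closed first, thread arrives later -> pierce
  expect_equal(
    as.character(classify_threading_path(
      list(unthreaded, unthreaded, threaded, threaded),
      lc$contact, d_native = 3.8, thread = "C")), "Path2")
  # both events at the entanglement frame -> tie favours wrap
  expect_equal(
    as.character(classify_threading_path(
      list(open_unthreaded, threaded), lc$contact, d_native = 3.8,
      thread = "C")), "Path1")
  # never entangled
  expect_equal(
    as.character(classify_threading_path(
      list(unthreaded, unthreaded), lc$contact, d_native = 3.8,
      thread = "C")), "unformed")
})

test_that("time reversal swaps the path classes on symmetric scripts", {
  lc <- make_lasso_chain(20, thread = TRUE)
  threaded <- lc$coords
  unthreaded <- threaded
  unthreaded[25:nrow(unthreaded), 1] <- unthreaded[25:nrow(unthreaded), 1] + 50
  open_loop <- threaded
  open_loop[1, ] <- open_loop[1, ] + c(-6, -6, 0)
  # forward: thread first then close (Path1); reversed script ends
  # entangled too, but the loop-closure event now precedes the thread
  fwd <- list(open_loop, threaded)
  rev_script <- list(unthreaded, threaded)
  expect_equal(as.character(classify_threading_path(fwd, lc$contact, 3.8,
                                                    "C")), "Path1")
  expect_equal(as.character(classify_threading_path(rev_script, lc$contact,
                                                    3.8, "C")), "Path2")
})

test_that("pathway probabilities count and bootstrap correctly", {
  pws <- lapply(1:10, function(k)
    structure(list(states = if (k <= 7) c("A", "X", "B") else c("A", "B")),
              class = "pathway"))
  pr <- pathway_probabilities(pws, function(p) "X" %in% p$states,
                              n_boot = 2000, seed = 4)
  expect_equal(pr$estimate, 0.7)
  expect_true(pr$ci[1] <= 0.7 && pr$ci[2] >= 0.7)
  all_in <- pathway_probabilities(pws, function(p) "A" %in% p$states,
                                  n_boot = 500, seed = 4)
  expect_equal(all_in$estimate, 1.0)
  expect_equal(unname(all_in$ci), c(1, 1))
  expect_error(pathway_probabilities(list(), function(p) TRUE), "no pathways")
})

test_that("bootstrap CI agrees with Clopper-Pearson on Bernoulli draws", {
  set.seed(12)
  x <- rbinom(100, 1, 0.5)
  pws <- lapply(x, function(v)
    structure(list(states = if (v == 1) "H" else "T"), class = "pathway"))
  pr <- pathway_probabilities(pws, function(p) p$states == "H",
                              n_boot = 10000, seed = 1)
  cp <- binom.test(sum(x), 100)$conf.int
  # intervals overlap and widths agree within 20%
  expect_lt(max(pr$ci[1], cp[1]), min(pr$ci[2], cp[2]))
  expect_lt(abs(diff(pr$ci) - diff(cp)) / diff(cp), 0.2)
})

test_that("pathway probabilities are invariant under reordering", {
  pws <- lapply(1:10, function(k)
    structure(list(states = if (k %% 3 == 0) "A" else "B"),
              class = "pathway"))
  p1 <- pathway_probabilities(pws, function(p) p$states == "A",
                              n_boot = 1000, seed = 9)
  p2 <- pathway_probabilities(rev(pws), function(p) p$states == "A",
                              n_boot = 1000, seed = 9)
  expect_equal(p1$estimate, p2$estimate)
  expect_equal(p1$ci, p2$ci)
})

test_that("binding-probability traces bin, average and gap correctly", {
  bound <- list(rep(1, 10), rep(1, 10))
  axis <- list(1:10, 1:10)
  tr <- binding_probability_trace(bound, axis, breaks = c(0, 5, 10))
  expect_equal(tr$P_binding, c(1, 1))
  tr0 <- binding_probability_trace(list(rep(0, 10)), list(1:10),
                                   breaks = c(0, 5, 10))
  expect_equal(tr0$P_binding, c(0, 0))
  # empty bin -> NA gap
  trg <- binding_probability_trace(list(rep(1, 5)), list(1:5),
                                   breaks = c(0, 5.5, 10))
  expect_true(is.na(trg$P_binding[2]))
  set.seed(8)
  bern <- lapply(1:40, function(k) rbinom(50, 1, 0.6))
  trb <- binding_probability_trace(bern, rep(list(1:50), 40),
                                   breaks = c(0, 25, 50), seed = 2)
  expect_true(all(trb$lower <= 0.6 & trb$upper >= 0.6))
})

test_that("epsilon selection applies the CAT-III and DDLB rules", {
  grid <- c(0, 0.5, 1.0, 1.5, 2.0)
  scan <- data.frame(eps = grid,
                     P_Native = c(0.2, 0.4, 0.6, 0.7, 0.6),
                     P_Binding = c(0.1, 0.4, 0.8, 1.0, 1.0))
  expect_equal(select_epsilon(scan, "CATIII"), 1.0)
  scan2 <- data.frame(eps = grid,
                      P_Native = c(0.4, 0.8, 1.0, 1.0, 1.0),
                      P_Binding = c(0.2, 0.4, 0.6, 0.9, 1.0))
  expect_equal(select_epsilon(scan2, "DDLB"), 1.0)
  # P_Binding = 1.0 exactly fails the strict upper bound of the CAT-III rule
  scan3 <- data.frame(eps = grid,
                      P_Native = c(0.6, 0.7, 0.8, 0.9, 1.0),
                      P_Binding = c(0.2, 0.6, 1.0, 1.0, 1.0))
  expect_equal(select_epsilon(scan3, "CATIII"), 0.5)
  scan4 <- data.frame(eps = grid, P_Native = rep(0.3, 5),
                      P_Binding = rep(0.2, 5))
  expect_true(is.na(select_epsilon(scan4, "CATIII")))
  expect_true(is.na(select_epsilon(scan4, "DDLB")))
})

test_that("surrogate state models find basins on a bimodal surface", {
  set.seed(30)
  G <- c(rnorm(400, 0.05, 0.02), rnorm(400, 0.5, 0.03))
  Q <- c(rnorm(400, 0.9, 0.03), rnorm(400, 0.3, 0.04))
  model <- build_state_model(G, Q, nbins = 10)
  expect_gte(nrow(model$centroids), 2L)
  lab <- assign_states(cbind(G, Q), model)
  # the two generating basins land in different states
  expect_false(lab[1] == lab[800])
})

test_that("affinity scans are reproducible and score both probabilities", {
  cfg <- sim_config(n_steps = 4000, save_interval = 100, seed = 17)
  scan1 <- run_affinity_scan(toy_binding_system, grid = c(0, 2),
                             n_runs = 2, config = cfg, window = 20,
                             binding_score = "window", n_boot = 200)
  scan2 <- run_affinity_scan(toy_binding_system, grid = c(0, 2),
                             n_runs = 2, config = cfg, window = 20,
                             binding_score = "window", n_boot = 200)
  expect_identical(scan1$P_Binding, scan2$P_Binding)
  expect_identical(scan1$P_Native, scan2$P_Native)
  expect_true(all(scan1$P_Native >= 0 & scan1$P_Native <= 1))
  expect_true(all(scan1$P_Native_lo <= scan1$P_Native &
                  scan1$P_Native_hi >= scan1$P_Native))
})
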