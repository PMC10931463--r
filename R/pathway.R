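#' Metastable-state model in order-parameter space
#'
#' A set of labelled centroids in (G, Q, ...) order-parameter space used
#' for nearest-centroid state assignment.
#'
#' @param labels unique state labels.
#' @param centroids matrix with one row per state (columns = order
#'   parameters, e.g. G and Q).
#' @param radius optional per-state assignment radius (unused by the
#'   nearest-centroid rule, carried as metadata).
#' @return object of class `state_model`.
#' @export
state_model <- function(labels, centroids, radius = NULL) {
  centroids <- as.matrix(centroids)
  if (length(labels) != nrow(centroids)) stop("one label per centroid row")
  if (any(duplicated(labels))) stop("state labels must be unique")
  if (any(!is.finite(centroids))) stop("centroids must be finite")
  structure(list(labels = as.character(labels), centroids = centroids,
                 radius = radius), class = "state_model")
}

#' Build a surrogate state model from a free-energy surface
#'
#' Histograms the sampled (G, Q) points on a 2D grid, forms the surface
#' `-ln P`, and takes the local minima (populated cells not exceeded by
#' any of their 8 neighbours) as metastable states, with centroids at the
#' minimum-cell centres.  This is a deliberately simple surrogate for
#' cluster-derived metastable states; labels are `S1, S2, ...` ordered by
#' increasing `-ln P`.
#'
#' @param G,Q per-frame order-parameter values.
#' @param nbins grid resolution per axis (default 12).
#' @return a [state_model()] with columns `G`, `Q`.
#' @export
build_state_model <- function(G, Q, nbins = 12L) {
  stopifnot(length(G) == length(Q), length(G) > 0)
  gb <- seq(min(G), max(G), length.out = nbins + 1L)
  qb <- seq(min(Q), max(Q), length.out = nbins + 1L)
  gi <- pmin(pmax(findInterval(G, gb, rightmost.closed = TRUE), 1L), nbins)
  qi <- pmin(pmax(findInterval(Q, qb, rightmost.closed = TRUE), 1L), nbins)
  H <- matrix(0L, nbins, nbins)
  for (k in seq_along(gi)) H[gi[k], qi[k]] <- H[gi[k], qi[k]] + 1L
  nlp <- ifelse(H > 0, -log(H / sum(H)), Inf)
  mins <- NULL
  for (a in seq_len(nbins)) for (b in seq_len(nbins)) {
    if (!is.finite(nlp[a, b])) next
    nb <- nlp[max(1, a - 1):min(nbins, a + 1),
              max(1, b - 1):min(nbins, b + 1)]
    if (nlp[a, b] <= min(nb)) mins <- rbind(mins, c(a, b, nlp[a, b]))
  }
  if (is.null(mins)) stop("no populated cells to build states from")
  mins <- mins[order(mins[, 3]), , drop = FALSE]
  ctr <- cbind(G = (gb[mins[, 1]] + gb[mins[, 1] + 1L]) / 2,
               Q = (qb[mins[, 2]] + qb[mins[, 2] + 1L]) / 2)
  state_model(sprintf("S%d", seq_len(nrow(ctr))), ctr)
}

#' Assign frames to metastable states
#'
#' Nearest-centroid assignment in normalized order-parameter space (each
#' coordinate scaled by the centroid range; degenerate ranges are left
#' unscaled).  Ties go to the lowest state index.
#'
#' @param op matrix of per-frame order parameters (columns matching the
#'   model's centroids).
#' @param model a [state_model()].
#' @return character vector of state labels (a discrete trajectory).
#' @export
assign_states <- function(op, model) {
  stopifnot(inherits(model, "state_model"))
  op <- as.matrix(op)
  C <- model$centroids
  if (nrow(C) == 0L) stop("empty state model")
  if (ncol(op) != ncol(C)) stop("order-parameter dimension mismatch")
  rng <- apply(C, 2, function(v) diff(range(v)))
  rng[rng < 1e-12] <- 1
  opn <- sweep(op, 2, rng, "/")
  Cn <- sweep(C, 2, rng, "/")
  lab <- vapply(seq_len(nrow(opn)), function(f) {
    d2 <- rowSums(sweep(Cn, 2, opn[f, ])^2)
    which.min(d2)  # ties -> lowest index
  }, integer(1))
  model$labels[lab]
}

#' Loop-erased pathway of a discrete trajectory
#'
#' Collapses consecutive repeats, then erases loops scanning left to
#' right: a revisit to a state already on the route truncates the route
#' back to that state.  The result records only the on-pathway states, in
#' order, with no repeated label.
#'
#' @param discrete character (or factor) vector of per-frame state labels.
#' @return object of class `pathway`: list with `states` (the loop-free
#'   route) and `n_frames`.
#' @examples
#' extract_pathway(c("P2", "P5", "P2", "P3", "P14"))$states  # P2 P3 P14
#' @export
extract_pathway <- function(discrete) {
  discrete <- as.character(discrete)
  if (length(discrete) == 0L) stop("empty discrete trajectory")
  collapsed <- rle(discrete)$values
  route <- character(0)
  for (s in collapsed) {
    hit <- match(s, route)
    if (is.na(hit)) route <- c(route, s) else route <- route[seq_len(hit)]
  }
  structure(list(states = route, n_frames = length(discrete)),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat("pathway:", paste(x$states, collapse = " -> "), "\n")
  invisible(x)
}

#' Classify how a lasso entanglement forms: wrap vs pierce
#'
#' An entanglement can form by placing the threading segment first and
#' then closing the loop around it (`Path1`, wrap), or by closing the loop
#' first and then piercing it with the thread (`Path2`).  The entanglement
#' is formed at the first frame `t*` where the loop contact is formed and
#' the thread's rounded partial linking with the (contact-closed) loop
#' region is nonzero.  The loop-closure event is the first frame from
#' which the contact stays formed through `t*`; the thread-positioning
#' event is the first frame from which the rounded linking stays at its
#' `t*` value.  `Path1` when the thread event is not later than the loop
#' event (ties favour wrap), else `Path2`.
#'
#' @param frames list of per-frame chain coordinate matrices.
#' @param contact the loop contact `(i, j)`.
#' @param d_native native distance of the contact, Angstrom.
#' @param thread `"N"` or `"C"`: which tail is the threading segment.
#' @param tail_exclusion see [contact_linking()].
#' @param tolerance_factor contact-formation tolerance.
#' @return `"Path1"`, `"Path2"` or `"unformed"`, with attributes
#'   `t_star`, `loop_event`, `thread_event` (frame indices) when formed.
#' @export
classify_threading_path <- function(frames, contact, d_native,
                                    thread = c("C", "N"),
                                    tail_exclusion = 5L,
                                    tolerance_factor = 1.2) {
  thread <- match.arg(thread)
  i <- contact[1]; j <- contact[2]
  formed <- logical(length(frames))
  gthr <- numeric(length(frames))
  for (f in seq_along(frames)) {
    X <- as.matrix(frames[[f]])
    d <- sqrt(sum((X[i, ] - X[j, ])^2))
    formed[f] <- contact_formed(d, d_native, tolerance_factor)
    lr <- contact_linking(X, contact, tail_exclusion)
    gthr[f] <- if (thread == "N") lr$g_N_round else lr$g_C_round
  }
  cand <- which(formed & abs(gthr) >= 1)
  if (length(cand) == 0L) return("unformed")
  t_star <- cand[1]
  g_star <- gthr[t_star]
  loop_event <- t_star
  while (loop_event > 1L && formed[loop_event - 1L]) loop_event <- loop_event - 1L
  thread_event <- t_star
  while (thread_event > 1L && gthr[thread_event - 1L] == g_star)
    thread_event <- thread_event - 1L
  out <- if (thread_event <= loop_event) "Path1" else "Path2"
  attr(out, "t_star") <- t_star
  attr(out, "loop_event") <- loop_event
  attr(out, "thread_event") <- thread_event
  out
}

#' Pathway probability with a bootstrap confidence interval
#'
#' Point estimate: the weighted fraction of trajectories whose pathway
#' satisfies `predicate`.  The confidence interval is a seeded percentile
#' bootstrap resampling whole trajectories.
#'
#' @param pathways list of [extract_pathway()] results; each may carry a
#'   `weight`/`count` element (default 1 trajectory each).
#' @param predicate function of a pathway returning `TRUE`/`FALSE`
#'   (e.g. passes through a state).
#' @param n_boot bootstrap resamples (default 10000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return list with `estimate`, `ci` (length 2), `n` (trajectories),
#'   `n_boot`.
#' @export
pathway_probabilities <- function(pathways, predicate, n_boot = 10000L,
                                  conf = 0.95, seed = 1L) {
  if (length(pathways) == 0L) stop("no pathways supplied")
  w <- vapply(pathways, function(p) {
    cnt <- p$weight %||% p$count %||% 1
    as.integer(cnt)
  }, integer(1))
  hit <- vapply(pathways, function(p) isTRUE(predicate(p)), logical(1))
  x <- rep(hit, w)          # one indicator per trajectory
  est <- mean(x)
  set.seed(seed)
  n <- length(x)
  bs <- vapply(seq_len(n_boot), function(b) mean(x[sample.int(n, n, TRUE)]),
               numeric(1))
  a <- (1 - conf) / 2
  list(estimate = est, ci = unname(quantile(bs, c(a, 1 - a))), n = n,
       n_boot = n_boot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binding-probability trace with bootstrap confidence intervals
#'
#' Bins per-frame binding indicators along an axis (time or nascent-chain
#' length), averages within each trajectory and bin, then averages over
#' trajectories; the per-bin confidence interval is a seeded percentile
#' bootstrap over trajectories.  Empty bins yield `NA` (a gap).
#'
#' @param bound list over trajectories of per-frame 0/1 binding
#'   indicators.
#' @param axis list over trajectories of matching per-frame axis values.
#' @param breaks bin boundaries along the axis.
#' @param n_boot,conf,seed bootstrap parameters.
#' @return data.frame with `bin_mid`, `P_binding`, `lower`, `upper`, `n`.
#' @export
binding_probability_trace <- function(bound, axis, breaks, n_boot = 1000L,
                                      conf = 0.95, seed = 1L) {
  stopifnot(length(bound) == length(axis))
  nb <- length(breaks) - 1L
  # per-trajectory, per-bin means
  M <- matrix(NA_real_, length(bound), nb)
  for (t in seq_along(bound)) {
    bi <- findInterval(axis[[t]], breaks, rightmost.closed = TRUE)
    for (b in seq_len(nb)) {
      v <- bound[[t]][bi == b]
      if (length(v)) M[t, b] <- mean(v)
    }
  }
  set.seed(seed)
  a <- (1 - conf) / 2
  out <- lapply(seq_len(nb), function(b) {
    v <- M[!is.na(M[, b]), b]
    if (length(v) == 0L)
      return(data.frame(bin_mid = (breaks[b] + breaks[b + 1]) / 2,
                        P_binding = NA_real_, lower = NA_real_,
                        upper = NA_real_, n = 0L))
    bs <- vapply(seq_len(n_boot), function(k)
      mean(v[sample.int(length(v), length(v), TRUE)]), numeric(1))
    data.frame(bin_mid = (breaks[b] + breaks[b + 1]) / 2,
               P_binding = mean(v),
               lower = unname(quantile(bs, a)),
               upper = unname(quantile(bs, 1 - a)), n = length(v))
  })
  do.call(rbind, out)
}

#' Binding affinity scan over the ligand-site well depth
#'
#' For each well depth in `grid`, runs `n_runs` independent simulations of
#' the system returned by `system_builder(eps, seed)`, scores each run by
#' (a) formation of the native entanglement at the end of the run
#' ([native_entanglement_formed()] on the per-frame G or G_gain trace) and
#' (b) ligand binding in the final frame ([binding_detected()]), and
#' reports `P_Native` and `P_Binding` per grid point with percentile
#' bootstrap confidence intervals.
#'
#' @param system_builder function `(eps, seed)` returning a ready-to-run
#'   [build_cg_system()] (including any random ligand placement).
#' @param grid well depths, kcal/mol (default `c(0, 0.5, 1, 1.5, 2)`).
#' @param n_runs independent runs per grid point (default 10).
#' @param config a [sim_config()]; its seed is combined with the run index.
#' @param mode entanglement mode for [native_entanglement_formed()].
#' @param window trailing-frame window for the entanglement average.
#' @param binding_score `"final"` scores a run by [binding_detected()] on
#'   the final frame; `"window"` scores it by the majority binding status
#'   over the last `binding_window` frames (suppresses final-instant
#'   flicker, parallel to the trailing-window entanglement average).
#' @param binding_window trailing frames for `binding_score = "window"`.
#' @param n_boot,conf bootstrap parameters.
#' @return object of class `scan_result`: data.frame with `eps`,
#'   `P_Native`, `P_Native_lo/hi`, `P_Binding`, `P_Binding_lo/hi`,
#'   `n_runs`, `n_failed`.
#' @export
run_affinity_scan <- function(system_builder, grid = c(0, 0.5, 1, 1.5, 2),
                              n_runs = 10L, config = sim_config(),
                              mode = "full_length", window = 100L,
                              binding_score = c("final", "window"),
                              binding_window = 20L,
                              n_boot = 1000L, conf = 0.95) {
  binding_score <- match.arg(binding_score)
  rows <- lapply(seq_along(grid), function(gi) {
    eps <- grid[gi]
    native <- logical(0); bound <- logical(0); failed <- 0L
    for (r in seq_len(n_runs)) {
      seed_r <- (config$seed + 7919L * gi + r) %% .Machine$integer.max
      res <- tryCatch({
        sys <- system_builder(eps, seed_r)
        cfg <- config; cfg$seed <- seed_r
        traj <- run_langevin(sys, cfg)
        rep_df <- entanglement_report(traj, sys$protein, sys$contact_map)
        trace <- if (mode == "full_length") rep_df$G else rep_df$G_gain
        nb <- n_frames(traj)
        bnd <- if (binding_score == "final") {
          binding_detected(traj$frames[[nb]], sys$n_protein)
        } else {
          w <- min(binding_window, nb)
          mean(vapply(traj$frames[(nb - w + 1L):nb], binding_detected,
                      logical(1), n_protein = sys$n_protein)) > 0.5
        }
        list(native = native_entanglement_formed(trace, mode, window),
             bound = bnd)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- failed + 1L
        warning(sprintf("run failed at eps = %g (run %d): %s", eps, r,
                        conditionMessage(res)), call. = FALSE)
      } else {
        native <- c(native, res$native)
        bound <- c(bound, res$bound)
      }
    }
    boot_ci <- function(x) {
      if (length(x) == 0L) return(c(NA_real_, NA_real_))
      bs <- vapply(seq_len(n_boot), function(k)
        mean(x[sample.int(length(x), length(x), TRUE)]), numeric(1))
      a <- (1 - conf) / 2
      unname(quantile(bs, c(a, 1 - a)))
    }
    set.seed(config$seed + gi)
    cin <- boot_ci(native); cib <- boot_ci(bound)
    data.frame(eps = eps,
               P_Native = if (length(native)) mean(native) else NA_real_,
               P_Native_lo = cin[1], P_Native_hi = cin[2],
               P_Binding = if (length(bound)) mean(bound) else NA_real_,
               P_Binding_lo = cib[1], P_Binding_hi = cib[2],
               n_runs = length(native), n_failed = failed)
  })
  structure(do.call(rbind, rows), class = c("scan_result", "data.frame"))
}

#' Select the working well depth from a scan
#'
#' The CAT-III rule takes the smallest well depth with `P_Native >= 0.5`
#' and `0.5 < P_Binding < 1.0` (good rescue with moderate, reversible
#' binding); the DDLB rule takes the smallest with `P_Native = 1`.
#'
#' @param scan a [run_affinity_scan()] result (or any data.frame with
#'   `eps`, `P_Native`, `P_Binding`).
#' @param rule `"CATIII"` or `"DDLB"`.
#' @return the selected well depth, or `NA` if no grid point qualifies.
#' @export
select_epsilon <- function(scan, rule = c("CATIII", "DDLB")) {
  rule <- match.arg(rule)
  if (nrow(scan) == 0L) stop("empty scan")
  o <- order(scan$eps)
  s <- scan[o, , drop = FALSE]
  ok <- if (rule == "CATIII") {
    s$P_Native >= 0.5 & s$P_Binding > 0.5 & s$P_Binding < 1.0
  } else {
    abs(s$P_Native - 1) < 1e-12
  }
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(NA_real_)
  s$eps[which(ok)[1]]
}
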