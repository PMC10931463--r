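#' Discrete Gauss linking number of two curves
#'
#' Midpoint/segment-vector discretization of the Gauss double integral:
#' `g = (1/4pi) sum_a sum_b (m_a - m_b) . (t_a x t_b) / |m_a - m_b|^3`
#' over all segment pairs, where `m` are segment midpoints and `t` segment
#' vectors.  For two closed curves the estimate converges to the integer
#' topological linking number; for open curves it is a real-valued degree
#' of mutual winding.
#'
#' @param curve_a,curve_b ordered point matrices (>= 3 points each).
#' @param closed_a,closed_b close the respective curve by a segment from
#'   its last point back to its first.
#' @return the linking estimate (dimensionless real).
#' @examples
#' hl <- make_hopf_link(5, 100)
#' abs(discrete_gauss_linking(hl$a, hl$b, TRUE, TRUE))  # ~1
#' @export
discrete_gauss_linking <- function(curve_a, curve_b, closed_a = FALSE,
                                   closed_b = FALSE) {
  A <- as.matrix(curve_a); B <- as.matrix(curve_b)
  if (nrow(A) < 3L || nrow(B) < 3L) stop("each curve needs >= 3 points")
  gauss_linking_cpp(A, B, closed_a, closed_b)
}

#' Linking of a contact-closed loop with the chain tails
#'
#' For a native contact `(i, j)` the backbone loop is the polyline
#' `i..j` closed by a straight virtual segment from `j` back to `i`.  Its
#' partial linking numbers with the N-tail (residues `1..i - delta`) and
#' C-tail (residues `j + delta..n`) are estimated with
#' [discrete_gauss_linking()]; `delta` residues adjacent to the loop
#' anchors are excluded.  The total linking number `g` is the partial value
#' of maximal absolute value (sign preserved); nearest-integer rounded
#' values are attached for the gain/loss comparisons.
#'
#' @param chain_coords n x 3 matrix of chain coordinates.
#' @param contact length-2 integer vector `(i, j)`, 1-based, `i < j`.
#' @param tail_exclusion residues excluded next to each loop anchor
#'   (default 5).
#' @return object of class `linking_record`: list with `contact`, `g_N`,
#'   `g_C`, `g`, `g_N_round`, `g_C_round`, `g_round` and
#'   `crossing_guess` (approximate crossing residue: the tail bead whose
#'   segment midpoint lies closest to the loop centroid; NA when the
#'   rounded linking is zero).
#' @export
contact_linking <- function(chain_coords, contact, tail_exclusion = 5L) {
  X <- as.matrix(chain_coords)
  n <- nrow(X)
  i <- as.integer(contact[1]); j <- as.integer(contact[2])
  if (i < 1L || j > n || i >= j) stop("contact indices out of range")
  loop <- X[i:j, , drop = FALSE]
  d <- as.integer(tail_exclusion)
  g_N <- 0; g_C <- 0
  ntail <- NULL; ctail <- NULL
  if (i - d >= 2L) {
    ntail <- X[1:(i - d), , drop = FALSE]
    g_N <- gauss_linking_cpp(loop, ntail, TRUE, FALSE)
  }
  if (n - (j + d) + 1L >= 2L) {
    ctail <- X[(j + d):n, , drop = FALSE]
    g_C <- gauss_linking_cpp(loop, ctail, TRUE, FALSE)
  }
  g <- if (abs(g_N) >= abs(g_C)) g_N else g_C
  cross_guess <- NA_integer_
  if (round(g) != 0) {
    tail <- if (abs(g_N) >= abs(g_C)) ntail else ctail
    off <- if (abs(g_N) >= abs(g_C)) 0L else j + d - 1L
    if (!is.null(tail) && nrow(tail) >= 2L) {
      ctr <- colMeans(loop)
      mid <- (tail[-1, , drop = FALSE] + tail[-nrow(tail), , drop = FALSE]) / 2
      k <- which.min(rowSums(sweep(mid, 2, ctr)^2))
      cross_guess <- off + k
    }
  }
  structure(list(contact = c(i, j), g_N = g_N, g_C = g_C, g = g,
                 g_N_round = round(g_N), g_C_round = round(g_C),
                 g_round = round(g), crossing_guess = cross_guess,
                 tail_exclusion = d),
            class = "linking_record")
}

#' Native linking numbers for every native contact
#'
#' Computes [contact_linking()] on the native structure for each contact,
#' giving the per-contact reference `g_native` used by
#' [compute_entanglement_fractions()].
#'
#' @param protein a [cg_protein()].
#' @param contact_map a [compute_native_contacts()] result.
#' @param tail_exclusion see [contact_linking()].
#' @return data.frame with columns `i`, `j`, `g_native`, `g_native_round`.
#' @export
native_contact_links <- function(protein, contact_map, tail_exclusion = 5L) {
  cc <- contact_map$contacts
  g <- vapply(seq_len(nrow(cc)), function(k)
    contact_linking(protein$native_positions, c(cc$i[k], cc$j[k]),
                    tail_exclusion)$g, numeric(1))
  data.frame(i = cc$i, j = cc$j, g_native = g, g_native_round = round(g))
}

#' Fraction of native contacts Q(I|J)
#'
#' Ratio of formed to native contacts restricted to residue sets `I` and
#' `J` (a contact counts when one index is in `I` and the other in `J`,
#' with `j > i + 3`).  A contact is formed when its current distance does
#' not exceed `tolerance_factor` times its native distance.
#'
#' @param frame n x 3 coordinate matrix of the current structure.
#' @param contact_map a [compute_native_contacts()] result.
#' @param I,J residue index sets; both `NULL` (default) uses all contacts.
#' @param tolerance_factor formation tolerance (default 1.2).
#' @return fraction in `[0, 1]`.
#' @export
compute_Q <- function(frame, contact_map, I = NULL, J = NULL,
                      tolerance_factor = 1.2) {
  cc <- contact_map$contacts
  if (!is.null(I) || !is.null(J)) {
    if (is.null(I) || is.null(J)) stop("provide both I and J, or neither")
    sel <- (cc$i %in% I & cc$j %in% J) | (cc$i %in% J & cc$j %in% I)
    cc <- cc[sel, , drop = FALSE]
  }
  if (nrow(cc) == 0L)
    stop("no native contacts between the requested residue sets")
  X <- as.matrix(frame)
  d <- sqrt(rowSums((X[cc$i, , drop = FALSE] - X[cc$j, , drop = FALSE])^2))
  mean(contact_formed(d, cc$d_native, tolerance_factor))
}

#' Entanglement gain/loss fractions of a frame
#'
#' For each native contact that is formed in the frame, compares the
#' rounded total linking number `g` with its rounded native reference:
#' `G_gain` is the fraction of native contacts (denominator: all `N`
#' native contacts) that are formed with `|g| > |g_native|`, `G_loss` the
#' fraction formed with `|g| < |g_native|`, and `G` the fraction formed
#' whose rounded `g` differs from the rounded native value (a superset
#' that also counts chirality flips).
#'
#' @param frame n x 3 coordinate matrix.
#' @param contact_map a [compute_native_contacts()] result.
#' @param native_links output of [native_contact_links()].
#' @param tail_exclusion see [contact_linking()].
#' @param tolerance_factor contact-formation tolerance.
#' @return object of class `entanglement_summary`: list with `G_gain`,
#'   `G_loss`, `G`, `Q_overall`, `n_formed`, `N` and the per-formed-contact
#'   `records` data.frame.
#' @export
compute_entanglement_fractions <- function(frame, contact_map, native_links,
                                           tail_exclusion = 5L,
                                           tolerance_factor = 1.2) {
  cc <- contact_map$contacts
  N <- contact_map$N
  X <- as.matrix(frame)
  if (N == 0L)
    return(structure(list(G_gain = 0, G_loss = 0, G = 0, Q_overall = NA,
                          n_formed = 0L, N = 0L,
                          records = NULL), class = "entanglement_summary"))
  d <- sqrt(rowSums((X[cc$i, , drop = FALSE] - X[cc$j, , drop = FALSE])^2))
  formed <- contact_formed(d, cc$d_native, tolerance_factor)
  gain <- 0L; loss <- 0L; changed <- 0L
  recs <- NULL
  if (any(formed)) {
    idx <- which(formed)
    g_cur <- vapply(idx, function(k)
      contact_linking(X, c(cc$i[k], cc$j[k]), tail_exclusion)$g_round,
      numeric(1))
    g_nat <- native_links$g_native_round[idx]
    gain <- sum(abs(g_cur) > abs(g_nat))
    loss <- sum(abs(g_cur) < abs(g_nat))
    changed <- sum(g_cur != g_nat)
    recs <- data.frame(i = cc$i[idx], j = cc$j[idx], g_round = g_cur,
                       g_native_round = g_nat)
  }
  structure(list(G_gain = gain / N, G_loss = loss / N, G = changed / N,
                 Q_overall = mean(formed), n_formed = sum(formed), N = N,
                 records = recs),
            class = "entanglement_summary")
}

#' @export
print.entanglement_summary <- function(x, ...) {
  cat(sprintf(
    "entanglement_summary: Q = %.3f, G_gain = %.4f, G_loss = %.4f, G = %.4f (%d/%d formed)\n",
    x$Q_overall, x$G_gain, x$G_loss, x$G, x$n_formed, x$N))
  invisible(x)
}

#' Has the native entanglement formed at the end of a trajectory?
#'
#' Averages an entanglement metric over the last `window` saved frames and
#' applies the stated acceptance threshold: mean `G` below 0.02 for a
#' full-length chain, or mean `G_gain` below 0.002 for a nascent chain.
#'
#' @param metric_trace per-frame values of `G` (full_length mode) or
#'   `G_gain` (nascent mode).
#' @param mode `"full_length"` or `"nascent"`.
#' @param window number of trailing frames to average (default 100).
#' @param threshold override the mode's default threshold.
#' @return logical.
#' @export
native_entanglement_formed <- function(metric_trace,
                                       mode = c("full_length", "nascent"),
                                       window = 100L, threshold = NULL) {
  mode <- match.arg(mode)
  if (length(metric_trace) < window)
    stop(sprintf("trajectory has %d frames; %d required",
                 length(metric_trace), window))
  if (is.null(threshold))
    threshold <- if (mode == "full_length") 0.02 else 0.002
  tail_mean <- mean(metric_trace[(length(metric_trace) - window + 1L):
                                   length(metric_trace)])
  tail_mean < threshold
}

#' Is the ligand bound in a frame?
#'
#' The binding criterion: the shortest distance between any ligand site
#' and any protein bead is no greater than `cutoff` (inclusive).
#'
#' @param frame coordinate matrix, protein beads first then ligand sites.
#' @param n_protein number of protein beads in the frame.
#' @param cutoff binding distance, Angstrom (default 8.0).
#' @return logical.
#' @export
binding_detected <- function(frame, n_protein, cutoff = 8.0) {
  X <- as.matrix(frame)
  n <- nrow(X)
  if (n_protein >= n) stop("frame contains no ligand sites")
  if (n_protein < 1L) stop("frame contains no protein beads")
  P <- X[seq_len(n_protein), , drop = FALSE]
  Lg <- X[(n_protein + 1L):n, , drop = FALSE]
  dmin <- min(vapply(seq_len(nrow(Lg)), function(k)
    min(sqrt(rowSums(sweep(P, 2, Lg[k, ])^2))), numeric(1)))
  dmin <= cutoff
}

#' Per-frame entanglement report for a trajectory
#'
#' Computes, for each saved frame, the overall Q, optional named Q(I|J)
#' values, the entanglement fractions and the ligand-binding indicator,
#' as a data.frame ready to be written as a TSV report.
#'
#' @param traj a `cg_trajectory`.
#' @param protein the [cg_protein()] the trajectory was run on.
#' @param contact_map a [compute_native_contacts()] result.
#' @param segments optional named list of `list(I =, J =)` residue-set
#'   pairs for Q(I|J) columns.
#' @param tail_exclusion see [contact_linking()].
#' @return data.frame with columns `time`, `Q_overall`, any `Q_<name>`,
#'   `G_gain`, `G_loss`, `G`, `bound`.
#' @export
entanglement_report <- function(traj, protein, contact_map,
                                segments = NULL, tail_exclusion = 5L) {
  links <- native_contact_links(protein, contact_map, tail_exclusion)
  out <- lapply(seq_along(traj$frames), function(f) {
    X <- traj$frames[[f]]
    np <- traj$n_protein[f]
    P <- X[seq_len(np), , drop = FALSE]
    # contacts within the synthesized chain only
    cm <- contact_map
    keep <- cm$contacts$j <= np
    cm$contacts <- cm$contacts[keep, , drop = FALSE]
    # N stays the full native count, per the G definitions
    ent <- compute_entanglement_fractions(P, cm, links[keep, , drop = FALSE],
                                          tail_exclusion)
    row <- data.frame(time = traj$times[f],
                      Q_overall = if (cm$N > 0 && nrow(cm$contacts) > 0)
                        compute_Q(P, cm) else NA_real_,
                      G_gain = ent$G_gain, G_loss = ent$G_loss, G = ent$G)
    if (!is.null(segments)) {
      for (nm in names(segments)) {
        q <- tryCatch(compute_Q(P, cm, segments[[nm]]$I, segments[[nm]]$J),
                      error = function(e) NA_real_)
        row[[paste0("Q_", nm)]] <- q
      }
    }
    row$bound <- if (nrow(X) > np)
      as.integer(binding_detected(X, np)) else NA_integer_
    row
  })
  do.call(rbind, out)
}
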