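# Independent oracles and small utilities shared across tests.

# O(n^2) brute-force native-contact scan
brute_contacts <- function(pos, cutoff = 8.0, min_seq_sep = 4L) {
  n <- nrow(pos)
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j >= i + min_seq_sep) {
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (d <= cutoff) out <- rbind(out, c(i, j, d))
    }
  }
  out
}

# random rigid rotation matrix (uses current RNG state)
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# central-difference force check: max |F_analytic - F_numeric|
max_force_error <- function(sys, pos, h = 1e-5, beads = seq_len(nrow(pos))) {
  out <- total_energy_forces(sys, pos)
  err <- 0
  for (i in beads) for (d in 1:3) {
    pp <- pos; pp[i, d] <- pp[i, d] + h
    pm <- pos; pm[i, d] <- pm[i, d] - h
    fn <- -(total_energy_forces(sys, pp)$energy -
            total_energy_forces(sys, pm)$energy) / (2 * h)
    err <- max(err, abs(fn - out$forces[i, d]))
  }
  err
}

# smooth random open curve from a low-order Fourier series, sampled at m+1
# points (m segments)
fourier_curve <- function(m, scale = 10, offset = c(0, 0, 0)) {
  a <- matrix(rnorm(9), 3, 3); b <- matrix(rnorm(9), 3, 3)
  t <- seq(0, pi, length.out = m + 1L)
  X <- vapply(1:3, function(d) {
    colSums(sapply(t, function(tt)
      a[, d] * cos(seq_len(3) * tt) + b[, d] * sin(seq_len(3) * tt)))
  }, numeric(m + 1L))
  sweep(X * scale / 3, 2, offset, `+`)
}

# a tiny 3-residue PDB written as text
write_toy_pdb <- function(path, drop_ca_res = NULL) {
  res <- c("GLY", "ALA", "GLY")
  lines <- character(0)
  for (i in 1:3) {
    x <- (i - 1) * 3.8
    if (!identical(drop_ca_res, i))
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i * 2 - 1, res[i], i, x, 0, 0))
    lines <- c(lines, sprintf(
      "ATOM  %5d  O   %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      i * 2, res[i], i, x, 1.4, 0))
  }
  writeLines(c(lines, "END"), path)
  path
}
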