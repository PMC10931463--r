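#' Read a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb` with a light pre-scan that reports
#' malformed ATOM/HETATM records by line number.
#'
#' @param path PDB file path.
#' @return a `bio3d` pdb object.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM|HETATM)", lines)
  for (ln in rec) {
    l <- lines[ln]
    if (nchar(l) < 54 ||
        is.na(suppressWarnings(as.numeric(substr(l, 31, 38)))) ||
        is.na(suppressWarnings(as.numeric(substr(l, 39, 46)))) ||
        is.na(suppressWarnings(as.numeric(substr(l, 47, 54)))))
      stop(sprintf("malformed PDB record at line %d", ln))
  }
  bio3d::read.pdb(path)
}

#' Write a PDB structure
#'
#' Writes a `bio3d` pdb object (preserving chain, residue numbering and
#' insertion codes) via `bio3d::write.pdb`.
#'
#' @param pdb a `bio3d` pdb object.
#' @param path output path.
#' @export
write_pdb <- function(pdb, path) {
  bio3d::write.pdb(pdb, file = path)
  invisible(path)
}

#' Write a coarse-grained protein as a Calpha-only PDB
#'
#' One CA ATOM record per bead (coordinates at the format's 0.001 Angstrom
#' precision), using the bead sequence and residue numbers.
#'
#' @param protein a [cg_protein()].
#' @param path output path.
#' @param use_native write `native_positions` instead of `positions`.
#' @export
write_cg_pdb <- function(protein, path, use_native = FALSE) {
  tab <- aa_bead_params()
  aa3 <- tab$aa3[match(protein$sequence, tab$aa)]
  aa3[is.na(aa3)] <- "UNK"
  pos <- if (use_native) protein$native_positions else protein$positions
  lines <- vapply(seq_len(protein$n_residues), function(i) {
    sprintf("ATOM  %5d  CA  %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, aa3[i], protein$resno[i], pos[i, 1], pos[i, 2], pos[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a trajectory
#'
#' `"xyz"` is a plain-text format (frame count may grow between frames, as
#' in nascent-chain runs); `"dcd"` is the CHARMM binary format and
#' requires a constant bead count.
#'
#' @param traj a `cg_trajectory`.
#' @param path output path.
#' @param format `"xyz"` or `"dcd"` (default from the file extension).
#' @export
write_traj <- function(traj, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "xyz"
  format <- match.arg(format, c("xyz", "dcd"))
  if (length(traj$frames) == 0L) stop("trajectory has no frames")
  counts <- vapply(traj$frames, nrow, integer(1))
  if (format == "dcd") {
    if (length(unique(counts)) != 1L)
      stop("growing-chain trajectory cannot be written as DCD; use XYZ")
    .write_dcd(traj, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_along(traj$frames)) {
      X <- traj$frames[[f]]
      writeLines(as.character(nrow(X)), con)
      writeLines(sprintf("time= %.6f", traj$times[f]), con)
      writeLines(sprintf("CA %12.6f %12.6f %12.6f",
                         X[, 1], X[, 2], X[, 3]), con)
    }
  }
  invisible(path)
}

# minimal CHARMM-format DCD writer (readable by bio3d::read.dcd)
.write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- length(traj$frames)
  natom <- nrow(traj$frames[[1]])
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(9)
  icntrl[1] <- nf; icntrl[2] <- 0L; icntrl[3] <- 1L; icntrl[4] <- nf
  writeBin(icntrl, con, size = 4)
  dt <- if (length(traj$times) > 1L) diff(traj$times)[1] else 1
  writeBin(dt, con, size = 4)                    # delta as 4-byte float
  writeBin(c(integer(9), 24L), con, size = 4)    # no cell; CHARMM version
  writeBin(84L, con, size = 4)
  title <- sprintf("%-80s", "lassofold trajectory")
  writeBin(84L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(84L, con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(as.integer(natom), con, size = 4)
  writeBin(4L, con, size = 4)
  for (f in seq_len(nf)) {
    X <- traj$frames[[f]]
    for (d in 1:3) {
      writeBin(as.integer(4 * natom), con, size = 4)
      writeBin(as.numeric(X[, d]), con, size = 4)
      writeBin(as.integer(4 * natom), con, size = 4)
    }
  }
  invisible(path)
}

#' Read a trajectory
#'
#' Reads XYZ (text, written by [write_traj()]) or DCD (via
#' `bio3d::read.dcd`).  Truncated XYZ files raise an error naming the
#' frame index; empty trajectories are errors.
#'
#' @param path input path.
#' @param format `"xyz"` or `"dcd"` (default from the extension).
#' @return a `cg_trajectory` (frames and times only).
#' @export
read_traj <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "xyz"
  format <- match.arg(format, c("xyz", "dcd"))
  if (format == "dcd") {
    M <- bio3d::read.dcd(path, verbose = FALSE)
    if (nrow(M) == 0L) stop("zero-frame trajectory")
    frames <- lapply(seq_len(nrow(M)), function(f)
      matrix(M[f, ], ncol = 3, byrow = TRUE))
    times <- seq_len(nrow(M))
  } else {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0L) stop("zero-frame trajectory")
    frames <- list(); times <- numeric(0)
    p <- 1L; f <- 0L
    while (p <= length(lines)) {
      f <- f + 1L
      n <- suppressWarnings(as.integer(lines[p]))
      if (is.na(n) || p + 1L + n > length(lines))
        stop(sprintf("truncated XYZ trajectory at frame %d", f))
      tm <- suppressWarnings(as.numeric(sub(".*time= *", "", lines[p + 1L])))
      rows <- lines[p + 1L + seq_len(n)]
      sp <- strsplit(trimws(rows), "[[:space:]]+")
      X <- t(vapply(sp, function(v) as.numeric(v[2:4]), numeric(3)))
      if (any(!is.finite(X)))
        stop(sprintf("truncated XYZ trajectory at frame %d", f))
      frames[[f]] <- X
      times <- c(times, if (is.na(tm)) f else tm)
      p <- p + 2L + n
    }
  }
  structure(list(frames = frames, times = times,
                 n_protein = vapply(frames, nrow, integer(1)),
                 n_beads = nrow(frames[[length(frames)]])),
            class = "cg_trajectory")
}

#' Default run configuration
#'
#' One structured document collecting the model's tunable parameters with
#' their standard defaults: 15 fs timestep, collision frequency 0.05
#' ps^-1, K_b = 50 kcal/mol/A^2, K_sp = 0.1 with sphere radii 100
#' (co-translational) / 200 (post-translational) Angstrom, the well-depth
#' grid 0-2 kcal/mol, entanglement thresholds 0.02 / 0.002, and the 8
#' Angstrom contact/binding criteria.
#'
#' @param seed RNG seed recorded in the provenance block.
#' @return a nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    force_field = list(K_b = 50, K_angle = 30, K_dih1 = 1.0, K_dih3 = 0.5,
                       contact_eps = 1.0, nonnative_eps = 0.000132,
                       cutoff = 20, switch_width = 2,
                       combine_eps = "geometric"),
    simulation = list(timestep = 0.015, friction = 0.05, temperature = 310,
                      n_steps = 100000L, save_interval = 1000L,
                      time_mapping_factor = 5e6),
    restraint = list(K_sp = 0.1, d0_cotranslational = 100,
                     d0_posttranslational = 200, center = c(160, 0, 0)),
    contacts = list(cutoff = 8.0, min_seq_sep = 4L, tolerance_factor = 1.2),
    entanglement = list(tail_exclusion = 5L, window = 100L,
                        G_threshold = 0.02, G_gain_threshold = 0.002),
    scan = list(grid = c(0, 0.5, 1.0, 1.5, 2.0), n_runs = 10L),
    binding = list(cutoff = 8.0),
    provenance = list(tool = "lassofold",
                      version = as.character(packageVersion("lassofold")),
                      seed = as.integer(seed), input_hashes = list())
  ), class = "run_config")
}

#' Write a run configuration as YAML
#' @param config a `run_config` list.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Parse-serialize-parse is the identity; unknown top-level sections are
#' rejected.
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("force_field", "simulation", "restraint", "contacts",
             "entanglement", "scan", "binding", "provenance")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Record input-file hashes in a config's provenance block
#' @param config a `run_config`.
#' @param paths files to hash (md5).
#' @export
record_input_hashes <- function(config, paths) {
  h <- tools::md5sum(paths)
  config$provenance$input_hashes <- as.list(h)
  config
}
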