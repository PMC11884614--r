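#' Trajectory and time-series containers
#'
#' A trajectory is a tidy tibble with one row per atom per frame and columns
#' `frame` (1-based integer), `residue` (1-based, contiguous per frame),
#' `atom` (within-frame running index), `x`, `y`, `z` (nm) and `mass`
#' (atomic mass units; 1 when the source format carries none). The frame
#' interval `dt` (ps) is stored as an attribute: no coordinate format carries
#' time reliably, so `dt` is always supplied by the caller (default 100 ps,
#' the saving interval of the all-atom trajectories this pipeline targets).
#'
#' @param df data frame with columns frame, residue, atom, x, y, z, mass.
#' @param dt frame interval in ps (> 0).
#' @return a `idp_trajectory` tibble.
#' @export
as_trajectory <- function(df, dt = 100) {
  stopifnot(is.data.frame(df))
  need <- c("frame", "residue", "atom", "x", "y", "z", "mass")
  if (!all(need %in% names(df))) {
    abort(paste("trajectory needs columns:", paste(need, collapse = ", ")))
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) abort("dt must be a positive scalar")
  df <- as_tibble(df)[need]
  df$frame <- as.integer(df$frame)
  df$residue <- as.integer(df$residue)
  df$atom <- as.integer(df$atom)
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    abort("coordinates must be finite")
  }
  if (any(df$mass <= 0)) abort("masses must be positive")
  frames <- unique(df$frame)
  if (!identical(frames, seq_along(frames))) {
    df$frame <- match(df$frame, frames)
  }
  key1 <- df[df$frame == 1L, c("residue", "atom")]
  nf <- max(df$frame)
  if (nrow(df) != nf * nrow(key1)) {
    abort("all frames must share an identical atom structure")
  }
  res <- sort(unique(key1$residue))
  if (!identical(res, seq_along(res))) {
    abort("residue indices must form a contiguous 1..N range")
  }
  structure(df, class = c("idp_trajectory", class(tibble())), dt = dt)
}

#' @rdname as_trajectory
#' @param x object to query.
#' @export
traj_dt <- function(x) {
  dt <- attr(x, "dt")
  if (is.null(dt)) abort("object has no dt attribute; was it built with as_trajectory()?")
  dt
}

#' @rdname as_trajectory
#' @export
n_frames <- function(x) max(x$frame)

#' @rdname as_trajectory
#' @export
n_residues <- function(x) max(x$residue)

#' Extract one frame of a trajectory
#'
#' @param traj trajectory tibble.
#' @param t frame index (1-based).
#' @return tibble of the atoms in that frame (same columns, dt kept).
#' @export
get_frame <- function(traj, t) {
  if (t < 1 || t > n_frames(traj)) abort("frame index out of range")
  out <- traj[traj$frame == t, , drop = FALSE]
  attr(out, "dt") <- attr(traj, "dt")
  out
}

# element -> atomic mass (amu); anything unknown falls back to 1.0 so that
# mass-weighted centers degrade gracefully to geometric centers
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, "NA" = 22.99, CL = 35.45
)

#' Read a multi-MODEL PDB file as a trajectory
#'
#' Coordinates are converted from the PDB's angstrom to nm. Residue identity
#' is (chain, residue number, insertion code), renumbered contiguously from 1
#' in order of first appearance. Masses come from the element column when
#' present, otherwise 1.
#'
#' @param path PDB file with one or more MODEL...ENDMDL blocks (a single
#'   coordinate block is treated as one frame).
#' @param dt frame interval in ps (default 100, the saving interval used for
#'   the microsecond-scale IDP simulations this package analyzes).
#' @return trajectory tibble.
#' @export
read_multiframe_pdb <- function(path, dt = 100) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 0) {
    # pre-scan: per-MODEL atom counts must agree, and the error must name
    # the offending model (bio3d's own failure there is uninformative)
    model_id <- cumsum(startsWith(lines, "MODEL"))
    counts <- tapply(is_atom, model_id, sum)
    counts <- counts[names(counts) != "0"]
    if (length(unique(counts)) > 1) {
      bad <- names(counts)[counts != counts[1]][1]
      abort(sprintf(
        "inconsistent atom count across MODELs: MODEL %s has %d atoms, expected %d",
        bad, counts[[bad]], counts[[1]]
      ))
    }
  }
  if (!any(is_atom)) abort("no ATOM/HETATM records found")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) abort(paste("PDB parse error:", conditionMessage(e)))
  )
  at <- pdb$atom
  rid <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  residue <- as.integer(factor(rid, levels = unique(rid)))
  elem <- toupper(trimws(at$elesy))
  mass <- unname(.element_masses[elem])
  mass[is.na(mass)] <- 1.0
  xyz <- pdb$xyz                      # n_models x 3*n_atoms, angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- length(residue)
  df <- tibble(
    frame = rep(seq_len(nf), each = na),
    residue = rep(residue, nf),
    atom = rep(seq_len(na), nf),
    x = as.vector(t(xyz[, seq(1, 3 * na, 3), drop = FALSE])) / 10,
    y = as.vector(t(xyz[, seq(2, 3 * na, 3), drop = FALSE])) / 10,
    z = as.vector(t(xyz[, seq(3, 3 * na, 3), drop = FALSE])) / 10,
    mass = rep(mass, nf)
  )
  as_trajectory(df, dt = dt)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' nm coordinates are written in angstrom. Every residue is emitted as
#' chain A with CA atom names (the reader only relies on residue numbering),
#' so round trips preserve coordinates and residue structure, not atom names.
#'
#' @param traj trajectory tibble.
#' @param path output path.
#' @export
write_multiframe_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(n_frames(traj))) {
    fr <- traj[traj$frame == t, ]
    writeLines(sprintf("MODEL     %4d", t), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      fr$atom, fr$residue, fr$x * 10, fr$y * 10, fr$z * 10
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an XYZ trajectory (one bead per residue)
#'
#' Standard XYZ: an atom-count line, a comment line, then that many
#' `label x y z` lines per frame. Coordinates are interpreted as nm (this
#' format is used only for the package's own coarse-grained chains, which are
#' generated in nm). Each bead becomes a one-atom residue with mass 1.
#'
#' @param path XYZ file.
#' @param dt frame interval in ps.
#' @return trajectory tibble.
#' @export
read_xyz <- function(path, dt = 100) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("XYZ parse error: empty file")
  out <- list()
  i <- 1L; fr <- 0L
  while (i <= length(lines)) {
    cnt <- suppressWarnings(as.integer(trimws(lines[i])))
    fr <- fr + 1L
    if (is.na(cnt) || cnt < 1) {
      abort(sprintf("XYZ parse error at frame %d: bad atom-count line", fr))
    }
    if (i + 1 + cnt > length(lines)) {
      abort(sprintf("XYZ parse error at frame %d: body shorter than count line", fr))
    }
    body <- lines[(i + 2):(i + 1 + cnt)]
    parts <- strsplit(trimws(body), "\\s+")
    if (any(lengths(parts) < 4)) {
      abort(sprintf("XYZ parse error at frame %d: malformed coordinate line", fr))
    }
    coords <- matrix(as.double(unlist(lapply(parts, `[`, 2:4))), ncol = 3, byrow = TRUE)
    if (any(!is.finite(coords))) {
      abort(sprintf("XYZ parse error at frame %d: non-numeric coordinates", fr))
    }
    out[[fr]] <- coords
    i <- i + 2L + cnt
  }
  if (length(unique(vapply(out, nrow, 1L))) != 1) {
    abort("XYZ structural error: frames differ in bead count")
  }
  nb <- nrow(out[[1]])
  coords <- do.call(rbind, out)
  df <- tibble(
    frame = rep(seq_along(out), each = nb),
    residue = rep(seq_len(nb), length(out)),
    atom = rep(seq_len(nb), length(out)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    mass = 1
  )
  as_trajectory(df, dt = dt)
}

#' Write a trajectory in XYZ format (nm, one line per atom)
#'
#' @param traj trajectory tibble.
#' @param path output path.
#' @param labels optional per-atom labels (default "C").
#' @export
write_xyz <- function(traj, path, labels = NULL) {
  na <- nrow(traj[traj$frame == 1L, ])
  if (is.null(labels)) labels <- rep("C", na)
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(n_frames(traj))) {
    fr <- traj[traj$frame == t, ]
    writeLines(as.character(na), con)
    writeLines(sprintf("frame %d", t), con)
    writeLines(sprintf("%s %.9f %.9f %.9f", labels, fr$x, fr$y, fr$z), con)
  }
  invisible(path)
}

#' Per-residue centers of mass
#'
#' @param frames a trajectory tibble or a single-frame subset of one.
#' @return tibble with columns frame, residue, x, y, z (mass-weighted means).
#' @export
residue_centers <- function(frames) {
  frames |>
    group_by(.data$frame, .data$residue) |>
    summarise(
      x = sum(.data$x * .data$mass) / sum(.data$mass),
      y = sum(.data$y * .data$mass) / sum(.data$mass),
      z = sum(.data$z * .data$mass) / sum(.data$mass),
      .groups = "drop"
    ) |>
    arrange(.data$frame, .data$residue)
}

#' Build a scalar time series tibble
#'
#' @param values numeric vector (length >= 2, finite).
#' @param dt sampling interval (ps for simulation series, s for experimental).
#' @param t0 time of the first sample (default 0).
#' @return `idp_series` tibble with columns time, value and a dt attribute.
#' @export
time_series <- function(values, dt, t0 = 0) {
  values <- as.double(values)
  if (length(values) < 2) abort("time series needs length >= 2")
  if (!all(is.finite(values))) abort("time series values must be finite")
  if (!is.numeric(dt) || dt <= 0) abort("dt must be positive")
  structure(
    tibble(time = t0 + dt * (seq_along(values) - 1), value = values),
    class = c("idp_series", class(tibble())), dt = as.double(dt)
  )
}

#' End-to-end (or arbitrary residue-pair) distance series
#'
#' Per-frame Euclidean distance between the mass-weighted centers of two
#' residues; with the defaults this is the end-to-end distance R_ee between
#' the terminal residues, the global conformational coordinate whose power
#' spectrum the temporal analysis operates on.
#'
#' @param traj trajectory tibble.
#' @param i,j residue indices (1-based; defaults: first and last residue).
#' @return `idp_series` tibble (nm), dt copied from the trajectory.
#' @export
end_to_end_series <- function(traj, i = 1L, j = n_residues(traj)) {
  N <- n_residues(traj)
  if (i < 1 || i > N || j < 1 || j > N) abort("residue index out of range")
  if (i == j) abort("i and j must name distinct residues")
  ctr <- residue_centers(traj[traj$residue %in% c(i, j), ])
  a <- ctr[ctr$residue == i, ]
  b <- ctr[ctr$residue == j, ]
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  time_series(d, dt = traj_dt(traj))
}

#' Radius of gyration of a point set
#'
#' sqrt(sum m_i |r_i - rbar|^2 / sum m_i) with rbar the (mass-weighted)
#' centroid; unit masses by default.
#'
#' @param points n x 3 matrix or data frame with x, y, z columns (nm).
#' @param masses optional positive weights.
#' @return scalar nm.
#' @export
radius_of_gyration <- function(points, masses = NULL) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- matrix(as.double(points), ncol = 3)
  if (nrow(points) == 0) abort("empty point set")
  if (is.null(masses)) masses <- rep(1, nrow(points))
  if (any(masses <= 0)) abort("masses must be positive")
  ctr <- colSums(points * masses) / sum(masses)
  dev <- sweep(points, 2, ctr)
  sqrt(sum(masses * rowSums(dev^2)) / sum(masses))
}

#' Write / read a scalar time series as two-column TSV
#'
#' @param ts `idp_series` tibble.
#' @param path file path.
#' @export
write_series_tsv <- function(ts, path) {
  utils::write.table(
    data.frame(time = ts$time, value = ts$value),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_series_tsv
#' @param dt optional override; inferred from the time column when absent.
#' @export
read_series_tsv <- function(path, dt = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (ncol(df) < 2) abort("series TSV needs two columns (time, value)")
  names(df)[1:2] <- c("time", "value")
  if (is.null(dt)) dt <- series_dt(df)
  time_series(df$value, dt = dt, t0 = df$time[1])
}
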