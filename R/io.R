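## Element lookup tables used to fill Topology defaults.
ELEMENT_DATA <- data.frame(
  element   = c("H", "C", "N", "O", "P", "S"),
  electrons = c(1L, 6L, 7L, 8L, 15L, 16L),
  vdw       = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80),
  mass      = c(1.008, 12.011, 14.007, 15.999, 30.974, 32.06),
  stringsAsFactors = FALSE)

#' Per-atom topology table
#'
#' Validates and completes a per-atom metadata table. Missing `electrons`,
#' `vdw` and `mass` are filled from the element; `role` tags atoms for the
#' membrane analyses (`"water"`, `"chain"`, `"head"`, `"pore"`,
#' `"peptide"`, ...), `monomer` groups atoms into peptide monomers.
#'
#' @param df Data frame with at least `name`, `element`, `resid`,
#'   `resname`; optional `electrons`, `vdw`, `mass`, `role`, `monomer`.
#' @return A `Topology` (data.frame subclass).
#' @export
topology <- function(df) {
  req <- c("name", "element", "resid", "resname")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("topology missing columns: ", paste(miss, collapse = ", "))
  idx <- match(df$element, ELEMENT_DATA$element)
  if (anyNA(idx)) {
    unknown <- is.na(idx)
    if (is.null(df$electrons) || anyNA(df$electrons[unknown]))
      stop("unknown element(s) without explicit electron counts: ",
           paste(unique(df$element[unknown]), collapse = ", "))
  }
  if (is.null(df$electrons)) df$electrons <- ELEMENT_DATA$electrons[idx]
  if (is.null(df$vdw)) df$vdw <- ELEMENT_DATA$vdw[idx]
  if (is.null(df$mass)) df$mass <- ELEMENT_DATA$mass[idx]
  if (is.null(df$role)) df$role <- "other"
  if (is.null(df$monomer)) df$monomer <- 1L
  df$resid <- as.integer(df$resid)
  class(df) <- c("Topology", "data.frame")
  df
}

#' Multi-frame trajectory container
#'
#' Coordinates are stored as an `n_atoms x 3 x n_frames` array in Angstrom,
#' with a periodic box (Angstrom, per frame or constant) and a time stamp
#' (ps) per frame. The box is centred on the origin.
#'
#' @param coords `n_atoms x 3 x n_frames` array (a single `n x 3` matrix is
#'   promoted to one frame).
#' @param time Numeric vector of frame times (ps).
#' @param box Length-3 vector or `n_frames x 3` matrix of box lengths.
#' @return A `Trajectory`.
#' @export
trajectory <- function(coords, time = NULL, box = c(100, 100, 100)) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3, 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  nf <- dim(coords)[3]
  if (is.null(time)) time <- seq_len(nf) - 1
  if (length(time) != nf) stop("time length must match frame count")
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  structure(list(coords = coords, time = as.numeric(time), box = box),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("<Trajectory>", dim(x$coords)[1], "atoms x", dim(x$coords)[3],
      "frames,", sprintf("t = %g..%g ps\n", min(x$time), max(x$time)))
  invisible(x)
}

#' @export
print.Topology <- function(x, ...) {
  cat("<Topology>", nrow(x), "atoms,", length(unique(x$resid)), "residues;",
      "roles:", paste(unique(x$role), collapse = ", "), "\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an n x 3 coordinate matrix
#'
#' @param traj A `Trajectory`.
#' @param i Frame index.
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Read a PDB file into a Topology and coordinates
#'
#' Parsing is delegated to [bio3d::read.pdb()]. When the element column is
#' absent the element is inferred from the first alphabetic character of
#' the atom name (with a message).
#'
#' @param path PDB file.
#' @return List with `topology` and `coords` (`n x 3` matrix).
#' @export
read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- at$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  if (any(blank)) {
    inferred <- sub("^[0-9]*", "", trimws(at$elety[blank]))
    inferred <- toupper(substr(inferred, 1, 1))
    elem[blank] <- inferred
    message("read_pdb: inferred element from atom name for ",
            sum(blank), " atom(s)")
  }
  top <- topology(data.frame(
    name = trimws(at$elety), element = trimws(elem),
    resid = at$resno, resname = trimws(at$resid),
    stringsAsFactors = FALSE))
  coords <- cbind(at$x, at$y, at$z)
  colnames(coords) <- c("x", "y", "z")
  list(topology = top, coords = coords)
}

#' Write a Topology + coordinates as PDB
#'
#' @param top A `Topology`.
#' @param coords `n x 3` coordinate matrix (or a `Trajectory`, in which
#'   case `frame` selects the frame written).
#' @param path Output file.
#' @param frame Frame index when `coords` is a `Trajectory`.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(top, coords, path, frame = 1) {
  if (inherits(coords, "Trajectory")) coords <- frame_coords(coords, frame)
  stopifnot(nrow(top) == nrow(coords))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords)),
                   resno = top$resid, resid = top$resname,
                   eleno = seq_len(nrow(top)), elety = top$name,
                   elesy = top$element)
  invisible(path)
}

#' Write a Trajectory in the package text format
#'
#' Self-describing plain text: a header comment block (provenance), then
#' per frame a line `frame <i> time <t> box <bx> <by> <bz>` followed by one
#' `x y z` line per atom (4 decimals).
#'
#' @param traj A `Trajectory`.
#' @param path Output file.
#' @param seed Optional seed recorded in the header for provenance.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# amdtk trajectory v1",
               sprintf("# atoms %d frames %d", n_atoms(traj), n_frames(traj)),
               if (!is.null(seed)) sprintf("# seed %d", as.integer(seed))),
             con)
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("frame %d time %.6g box %.4f %.4f %.4f",
                       i, traj$time[i],
                       traj$box[i, 1], traj$box[i, 2], traj$box[i, 3]), con)
    xyz <- frame_coords(traj, i)
    writeLines(sprintf("%.4f %.4f %.4f", xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a Trajectory from the package text format
#'
#' @param path Input file.
#' @param topology Optional `Topology`; if given, the per-frame atom count
#'   must match it.
#' @return A `Trajectory`.
#' @export
read_trajectory <- function(path, topology = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  hdr_idx <- grep("^frame ", lines)
  if (!length(hdr_idx)) stop("no frame headers found in ", path)
  n_at <- diff(c(hdr_idx, length(lines) + 1L)) - 1L
  if (length(unique(n_at)) != 1)
    stop("frame ", which(n_at != n_at[1])[1],
         ": atom count differs from first frame")
  n_at <- n_at[1]
  if (!is.null(topology) && n_at != nrow(topology))
    stop("atom count ", n_at, " does not match topology (", nrow(topology), ")")
  nf <- length(hdr_idx)
  hdr <- strsplit(lines[hdr_idx], "[[:space:]]+")
  time <- vapply(hdr, function(h) as.numeric(h[4]), 0)
  box <- t(vapply(hdr, function(h) as.numeric(h[6:8]), numeric(3)))
  body <- lines[-hdr_idx]
  vals <- scan(text = body, quiet = TRUE)
  if (length(vals) != 3 * n_at * nf)
    stop("malformed coordinate line (expected ", 3 * n_at * nf,
         " values, got ", length(vals), ")")
  coords <- array(NA_real_, c(n_at, 3, nf))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  for (i in seq_len(nf))
    coords[, , i] <- m[((i - 1) * n_at + 1):(i * n_at), ]
  trajectory(coords, time = time, box = box)
}

#' Read/write per-frame boosted energy series as CSV
#'
#' Columns: `time`, `V_total`, `V_dihed`, `dV_total`, `dV_dihed`. Header
#' comment lines (`#`) carry provenance and are skipped on read.
#'
#' @param energies Data frame in the column layout above.
#' @param path File path.
#' @param seed Optional provenance seed.
#' @return The data frame (read) or `path` invisibly (write).
#' @export
write_energy_series <- function(energies, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# amdtk energy series v1",
               if (!is.null(seed)) sprintf("# seed %d", as.integer(seed))), con)
  utils::write.csv(energies, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_energy_series
#' @export
read_energy_series <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time", "V_total", "V_dihed", "dV_total", "dV_dihed")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("energy series missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$dV_total < 0) || any(df$dV_dihed < 0))
    stop("negative boost energies in ", path)
  df
}

#' Write a free-energy surface as a CSV grid
#'
#' One row per occupied or empty bin: bin centers, probability, PMF
#' (kcal mol^-1, `NA` for empty bins) and occupancy count.
#'
#' @param fes An `fe_surface` (see [reweighted_pmf()]).
#' @param path Output file.
#' @param seed Optional provenance seed.
#' @return `path`, invisibly.
#' @export
write_fes_csv <- function(fes, path, seed = NULL) {
  stopifnot(inherits(fes, "fe_surface"))
  if (fes$dims == 1) {
    df <- data.frame(x = fes$centers[[1]], prob = as.numeric(fes$prob),
                     pmf = as.numeric(fes$pmf), count = as.numeric(fes$counts))
  } else {
    g <- expand.grid(x = fes$centers[[1]], y = fes$centers[[2]])
    df <- data.frame(g, prob = as.numeric(fes$prob),
                     pmf = as.numeric(fes$pmf), count = as.numeric(fes$counts))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# amdtk free-energy surface v1",
               sprintf("# kT %.6g", fes$kT),
               if (!is.null(seed)) sprintf("# seed %d", as.integer(seed))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a volumetric grid in OpenDX format
#'
#' The OpenDX scalar format is readable by VMD (`mol new file.dx`).
#'
#' @param grid 3-D numeric array.
#' @param origin Length-3 grid origin (Angstrom).
#' @param spacing Grid spacing (Angstrom).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, origin, spacing, path) {
  stopifnot(length(dim(grid)) == 3, length(origin) == 3, spacing > 0)
  d <- dim(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# amdtk volumetric grid",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", origin[1], origin[2], origin[3]),
    sprintf("delta %.4f 0 0", spacing),
    sprintf("delta 0 %.4f 0", spacing),
    sprintf("delta 0 0 %.4f", spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  ## DX wants z as the fastest-running index: permute to [z, y, x] and flatten
  vals <- as.numeric(aperm(grid, c(3, 2, 1)))
  writeLines(vapply(split(vals, ceiling(seq_along(vals) / 3)),
                    function(v) paste(sprintf("%.6g", v), collapse = " "),
                    character(1)), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field'), con)
  invisible(path)
}

#' Read an analysis run configuration
#'
#' YAML key-value configuration with a mandatory `seed`; analysis blocks
#' are passed through untouched.
#'
#' @param path YAML file.
#' @return Named list with at least `seed` (integer).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must declare a seed")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
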