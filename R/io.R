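# Trajectory file input/output.
#
# PDB and DCD are delegated to bio3d; GRO (text, nm units) and the DCD writer
# are implemented here. Coordinates are stored in Angstrom internally
# regardless of the on-disk unit (GRO native nm is converted on load/save).

#' Read a (multi-frame) GRO file
#'
#' Parses the fixed-column GROMACS GRO format. Several concatenated frames
#' (as written by `trjconv` or [write_gro()]) are read into a multi-frame
#' trajectory. Coordinates are converted from nm to Angstrom. GRO carries no
#' chain ids: chains are inferred from decreases in the residue-id sequence
#' (each restart opens a new chain, labelled A, B, C, ...).
#'
#' @param path Path to a `.gro` file.
#' @param dt Frame spacing in ns used to assign times when the title line
#'   carries no `t=` field (default 1 ns).
#' @return A [trajectory()].
#' @export
read_gro <- function(path, dt = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  frames <- list(); boxes <- list(); times <- numeric(0)
  atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) ) { i <- i + 1L; next }
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1L) stop("malformed GRO: bad atom count at line ", i + 1L)
    if (i + 1L + nat + 1L > length(lines)) stop("malformed GRO: truncated frame at line ", i)
    al <- lines[(i + 2L):(i + 1L + nat)]
    xyz <- cbind(as.numeric(substr(al, 21, 28)),
                 as.numeric(substr(al, 29, 36)),
                 as.numeric(substr(al, 37, 44))) * 10  # nm -> A
    if (anyNA(xyz)) stop("malformed GRO: unreadable coordinates in frame starting line ", i)
    if (is.null(atoms)) {
      resid <- as.integer(substr(al, 1, 5))
      resname <- trimws(substr(al, 6, 10))
      name <- trimws(substr(al, 11, 15))
      chain_brk <- c(FALSE, diff(resid) < 0)
      chain <- LETTERS[pmin(cumsum(chain_brk) + 1L, 26L)]
      atoms <- data.frame(name = name, resname = resname, resid = resid,
                          chain = chain, charge = NA_real_, radius = NA_real_,
                          stringsAsFactors = FALSE)
    }
    bx <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "[[:space:]]+")[[1]])[1:3] * 10
    tm <- NA_real_
    if (grepl("t=", title)) {
      tm <- suppressWarnings(as.numeric(sub(".*t=\\s*([-0-9.eE+]+).*", "\\1", title)))
      if (!is.na(tm)) tm <- tm / 1000  # GROMACS titles carry ps
    }
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- bx
    times <- c(times, tm)
    i <- i + 2L + nat + 1L
  }
  if (length(frames) == 0L) stop("GRO file contains no frames: ", path)
  nf <- length(frames); na <- nrow(frames[[1]])
  coords <- array(NA_real_, c(nf, na, 3))
  for (k in seq_len(nf)) coords[k, , ] <- frames[[k]]
  if (anyNA(times)) times <- (seq_len(nf) - 1) * dt
  trajectory(coords, do.call(rbind, boxes), times, atoms)
}

#' Write a trajectory as a (multi-frame) GRO file
#'
#' Coordinates are converted from Angstrom to nm and written in the
#' fixed-column GRO format (one concatenated block per frame, with the frame
#' time in ps in the title line). Precision is the format's 0.001 nm.
#'
#' @param trajectory A [trajectory()].
#' @param path Output path.
#' @param frames Frames to write (default all).
#' @return `path`, invisibly.
#' @export
write_gro <- function(trajectory, path, frames = seq_len(n_frames(trajectory))) {
  at <- trajectory$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    writeLines(sprintf("poreflux t= %.4f", trajectory$times[f] * 1000), con)
    writeLines(sprintf("%5d", n_atoms(trajectory)), con)
    xyz <- trajectory$coords[f, , , drop = TRUE] / 10
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       at$resid %% 100000L, substr(at$resname, 1, 5),
                       substr(at$name, 1, 5), seq_len(nrow(at)) %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", trajectory$box[f, 1] / 10,
                       trajectory$box[f, 2] / 10, trajectory$box[f, 3] / 10), con)
  }
  invisible(path)
}

#' Write a trajectory in DCD format
#'
#' Emits a CHARMM-flavour binary DCD (single-precision coordinates in
#' Angstrom, no unit-cell records, native endianness) readable by
#' `bio3d::read.dcd` and any standard MD tool. Box lengths are not stored in
#' the DCD; keep the topology frame (GRO/PDB) alongside.
#'
#' @inheritParams write_gro
#' @return `path`, invisibly.
#' @export
write_dcd <- function(trajectory, path) {
  nf <- n_frames(trajectory); na <- n_atoms(trajectory)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: payload length prefix/suffix in bytes
    writer()
  }
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L  # CHARMM version stamp -> single precision frames
  writeBin(icntrl[1:9], con, size = 4)
  dt <- if (nf > 1) diff(trajectory$times[1:2]) else 1
  writeBin(as.numeric(dt), con, size = 4)  # delta, stored as float32
  writeBin(icntrl[11:20], con, size = 4)
  writeBin(84L, con, size = 4)
  title <- sprintf("%-80s", "poreflux trajectory (lengths in Angstrom)")
  writeBin(4L + 80L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(4L + 80L, con, size = 4)
  writeBin(4L, con, size = 4); writeBin(na, con, size = 4); writeBin(4L, con, size = 4)
  nb <- 4L * na
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      writeBin(nb, con, size = 4)
      writeBin(as.numeric(trajectory$coords[f, , d]), con, size = 4)
      writeBin(nb, con, size = 4)
    }
  }
  invisible(path)
}

# Read a PDB (single- or multi-model) through bio3d into a Trajectory.
read_pdb_traj <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  coords <- array(NA_real_, c(nf, na, 3))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, 3 * na, by = 3), drop = FALSE]
  chain <- pdb$atom$chain
  chain[is.na(chain)] <- "A"
  atoms <- data.frame(name = pdb$atom$elety, resname = pdb$atom$resid,
                      resid = pdb$atom$resno, chain = chain,
                      charge = NA_real_, radius = NA_real_,
                      stringsAsFactors = FALSE)
  # PDB CRYST1 box if present, else a generous bounding box
  box <- rep(NA_real_, 3)
  cr <- grep("^CRYST1", readLines(path, n = 500), value = TRUE)
  if (length(cr) >= 1)
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24), substr(cr[1], 25, 33)))
  if (anyNA(box) || any(box <= 0))
    box <- apply(coords, 3, function(m) diff(range(m))) + 20
  trajectory(coords, box, (seq_len(nf) - 1), atoms)
}

#' Load topology + trajectory files
#'
#' Reads a topology (`.pdb` or `.gro`) and optionally a coordinate
#' trajectory (`.dcd` via bio3d, or a multi-frame `.gro`). Atom metadata
#' comes from the topology; coordinates are in Angstrom whatever the source
#' unit. DCD files carry no box information here, so the topology box is
#' replicated across frames.
#'
#' @param topology_path Path to `.pdb` or `.gro`.
#' @param trajectory_path Optional path to `.dcd` or multi-frame `.gro`.
#'   XTC is not supported; convert to DCD or GRO first.
#' @param dt Frame spacing in ns for formats that store no times (default 1).
#' @return A [trajectory()].
#' @export
load_trajectory <- function(topology_path, trajectory_path = NULL, dt = 1) {
  if (!file.exists(topology_path)) stop("topology file not found: ", topology_path)
  ext <- function(p) tolower(sub(".*\\.", "", p))
  top <- switch(ext(topology_path),
                gro = read_gro(topology_path, dt = dt),
                pdb = read_pdb_traj(topology_path),
                stop("unsupported topology format '.", ext(topology_path),
                     "' (supported: .pdb, .gro)"))
  if (is.null(trajectory_path)) return(top)
  if (!file.exists(trajectory_path)) stop("trajectory file not found: ", trajectory_path)
  te <- ext(trajectory_path)
  if (te == "xtc")
    stop("XTC is not supported; supply a DCD or multi-frame GRO ",
         "(e.g. 'gmx trjconv -f in.xtc -o out.gro')")
  if (te == "gro") {
    tr <- read_gro(trajectory_path, dt = dt)
    if (n_atoms(tr) != n_atoms(top))
      stop(sprintf("atom count mismatch: topology has %d atoms, trajectory has %d",
                   n_atoms(top), n_atoms(tr)))
    return(trajectory(tr$coords, tr$box, tr$times, top$atoms))
  }
  if (te == "dcd") {
    xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    nf <- nrow(xyz); na <- ncol(xyz) / 3
    if (nf < 1L) stop("trajectory contains 0 frames: ", trajectory_path)
    if (na != n_atoms(top))
      stop(sprintf("atom count mismatch: topology has %d atoms, trajectory has %d",
                   n_atoms(top), na))
    coords <- array(NA_real_, c(nf, na, 3))
    for (d in 1:3) coords[, , d] <- xyz[, seq(d, 3 * na, by = 3), drop = FALSE]
    box <- matrix(rep(top$box[1, ], each = nf), nrow = nf)
    return(trajectory(coords, box, (seq_len(nf) - 1) * dt, top$atoms))
  }
  stop("unsupported trajectory format '.", te, "' (supported: .dcd, .gro)")
}
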